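# Tabular file I/O for waveforms: CSV body with a '#'-prefixed metadata header
# carrying the defining spec.

#' Write a waveform to a tabular file
#'
#' Columns `time_s`, `accel_dps2`, `vel_dps`, `pos_deg`, preceded by
#' `# key: value` header lines carrying the perturbation spec.
#'
#' @param w A `waveform` from [design_waveform()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_waveform <- function(w, path) {
  spec <- attr(w, "spec")
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in c("axis", "direction", "peak_accel", "peak_vel", "displacement",
               "command_rate")) {
    writeLines(sprintf("# %s: %s", nm, spec[[nm]]), con)
  }
  utils::write.csv(as.data.frame(w), con, row.names = FALSE)
  invisible(path)
}

#' Read a waveform written by [write_waveform()]
#'
#' @param path File path.
#' @return A `waveform` data frame with its `perturbation_spec` attribute
#'   restored.
#' @export
read_waveform <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    key <- sub(":.*$", "", kv)
    meta[[trimws(key)]] <- trimws(sub("^[^:]*:", "", kv))
  }
  w <- utils::read.csv(text = lines[!grepl("^#", lines)])
  spec <- perturbation_spec(meta$axis, meta$direction,
                            as.numeric(meta$peak_accel),
                            as.numeric(meta$peak_vel),
                            as.numeric(meta$displacement),
                            as.numeric(meta$command_rate))
  attr(w, "spec") <- spec
  class(w) <- c("waveform", "data.frame")
  w
}
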