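# End-to-end pipeline: design -> synthesize (or load) -> QC -> metrics ->
# condition-dependence trends and asymmetry, with tabular per-stage outputs
# and a run manifest.

#' Pipeline run configuration
#'
#' Validated container for one pipeline run. Unknown fields are rejected.
#'
#' @param generator A [generator_spec()] describing the synthetic input; the
#'   pipeline's `seed` overrides the generator's.
#' @param thresholds QC thresholds, see [qc_thresholds()].
#' @param windows Analysis windows, see [analysis_windows()].
#' @param out_dir Output directory for per-stage tables and the manifest, or
#'   `NULL` to keep everything in memory.
#' @param seed Master seed for the run.
#' @param ... Reserved; any argument here is an error.
#' @return List of class `run_config`.
#' @export
run_config <- function(generator = generator_spec(),
                       thresholds = qc_thresholds(),
                       windows = analysis_windows(),
                       out_dir = NULL, seed = 1, ...) {
  extra <- list(...)
  if (length(extra) > 0L) {
    stop("unknown config fields: ", paste(names(extra), collapse = ", "))
  }
  stopifnot(inherits(generator, "generator_spec"),
            inherits(thresholds, "qc_thresholds"))
  structure(list(generator = generator, thresholds = thresholds,
                 windows = windows, out_dir = out_dir, seed = seed),
            class = "run_config")
}

# signed window-mean metrics: inverting a negative-direction trial flips the
# sign of its window means (window_mean is linear), so pooling mirrored
# directions for the trend analysis reduces to multiplying by the direction
# sign
.signed_metrics <- function(metrics) {
  s <- direction_sign(metrics$direction)
  metrics$short_mean_pooled <- s * metrics$short_mean
  metrics$medium_mean_pooled <- s * metrics$medium_mean
  metrics
}

#' Run the full analysis pipeline on synthetic trials
#'
#' Stages: enumerate conditions, generate trials, apply QC, compute per-trial
#' metrics, test condition dependence (two-way ANOVA gated regression) for
#' each axis, stimulus set, channel and window, and compute the directional
#' asymmetry index per axis with Fisher-combined p-values across animals and
#' stimulus profiles. Deterministic for a fixed config and seed.
#'
#' @param config A [run_config()].
#' @return List of class `run_manifest`: `conditions`, `qc_summary`,
#'   `metrics` (tidy per-trial table), `trends`, `asymmetry`, `counts`,
#'   `seed`. When `out_dir` is set, the tables are also written as CSV plus a
#'   JSON manifest.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  gen <- config$generator
  gen$seed <- config$seed

  trials <- generate_trial_set(gen)
  qc <- lapply(trials, qc_trial, thresholds = config$thresholds)
  keep <- vapply(qc, function(r) r$keep, TRUE)
  qc_summary <- summarize_exclusions(qc)
  kept <- trials[keep]
  if (length(kept) == 0L) stop("pipeline aborted at stage 'qc': no trials survive")

  metrics <- .signed_metrics(metrics_table(kept, windows = config$windows))

  base_accel <- 500; base_vel <- 40
  sets <- list(velocity = list(filter = metrics$peak_accel == base_accel,
                               predictor = "peak_vel"),
               acceleration = list(filter = metrics$peak_vel == base_vel,
                                   predictor = "peak_accel"))
  trends <- list()
  for (ax in unique(metrics$axis)) {
    for (set_name in names(sets)) {
      st <- sets[[set_name]]
      for (chan in unique(metrics$channel)) {
        for (win in c("short", "medium")) {
          sub <- metrics[metrics$axis == ax & st$filter &
                           metrics$channel == chan, ]
          if (length(unique(sub[[st$predictor]])) < 2L) next
          val <- sub[[paste0(win, "_mean_pooled")]]
          tab <- data.frame(animal_id = sub$animal_id,
                            condition = sub[[st$predictor]], value = val)
          tr <- condition_trend(tab)
          tr <- cbind(data.frame(axis = ax, set = set_name, channel = chan,
                                 window = win, n = nrow(sub)), tr)
          trends[[length(trends) + 1L]] <- tr
        }
      }
    }
  }
  trends <- do.call(rbind, trends)

  asym <- .pipeline_asymmetry(kept)

  manifest <- structure(
    list(conditions = gen$conditions, qc_summary = qc_summary,
         metrics = metrics, trends = trends, asymmetry = asym,
         counts = c(conditions = length(gen$conditions),
                    trials_generated = length(trials),
                    trials_kept = length(kept),
                    metric_rows = nrow(metrics)),
         seed = config$seed),
    class = "run_manifest")

  if (!is.null(config$out_dir)) .write_manifest(manifest, config$out_dir)
  manifest
}

# per-(axis, animal, profile) asymmetry on the CoP channel, Fisher-combined
# across animals and stimulus profiles within each axis
.pipeline_asymmetry <- function(trials) {
  info <- data.frame(
    axis = vapply(trials, function(tr) tr$condition$axis, ""),
    direction = vapply(trials, function(tr) tr$condition$direction, ""),
    A = vapply(trials, function(tr) tr$condition$peak_accel, 0),
    V = vapply(trials, function(tr) tr$condition$peak_vel, 0),
    animal = vapply(trials, function(tr) tr$animal_id, "")
  )
  rows <- list(); combined <- list()
  for (ax in unique(info$axis)) {
    dirs <- .AXIS_DIRECTIONS[[ax]]
    ps <- c()
    sub <- info[info$axis == ax, ]
    for (an in unique(sub$animal)) {
      for (key in unique(paste(sub$A, sub$V))) {
        av <- as.numeric(strsplit(key, " ")[[1]])
        pick <- function(dir) {
          trials[info$axis == ax & info$animal == an & info$A == av[1] &
                   info$V == av[2] & info$direction == dir]
        }
        t1 <- pick(dirs[1]); t2 <- pick(dirs[2])
        if (length(t1) < 2L || length(t2) < 2L) next
        res <- asymmetry_index(response_traces(t1, "cop"),
                               response_traces(t2, "cop"))
        ps <- c(ps, res$p_value)
        rows[[length(rows) + 1L]] <- data.frame(
          axis = ax, animal_id = an, peak_accel = av[1], peak_vel = av[2],
          index = res$index, p_value = res$p_value)
      }
    }
    if (length(ps)) {
      combined[[length(combined) + 1L]] <- data.frame(
        axis = ax, n_tests = length(ps),
        fisher_p = fisher_combine(pmin(pmax(ps, .Machine$double.xmin), 1)))
    }
  }
  list(per_test = if (length(rows)) do.call(rbind, rows) else NULL,
       combined = if (length(combined)) do.call(rbind, combined) else NULL)
}

.write_manifest <- function(manifest, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  conds <- do.call(rbind, lapply(manifest$conditions, function(cs) {
    data.frame(axis = cs$axis, direction = cs$direction,
               peak_accel = cs$peak_accel, peak_vel = cs$peak_vel,
               displacement = cs$displacement)
  }))
  utils::write.csv(conds, file.path(out_dir, "conditions.csv"),
                   row.names = FALSE)
  utils::write.csv(manifest$qc_summary, file.path(out_dir, "qc_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(manifest$metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(manifest$trends, file.path(out_dir, "trends.csv"),
                   row.names = FALSE)
  if (!is.null(manifest$asymmetry$per_test)) {
    utils::write.csv(manifest$asymmetry$per_test,
                     file.path(out_dir, "asymmetry.csv"), row.names = FALSE)
  }
  jsonlite::write_json(
    list(seed = manifest$seed, counts = as.list(manifest$counts),
         r_version = R.version.string),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(NULL)
}
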