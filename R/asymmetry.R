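# Directional-symmetry analysis: pairwise mean-absolute-percentage-error
# (MAPE) distributions over same-direction and pooled opposite-direction
# response pairs, an asymmetry index, Welch t-test inference and Fisher
# combination of p-values.

#' Pairwise MAPE between two response traces
#'
#' Trace-level normalization: `100 * mean(|a - b|) / mean(|r|)` with reference
#' `r = a` in `"reference"` mode, or `r` the average of the two trace
#' magnitudes in `"symmetric"` mode. Per-sample percentage errors are unstable
#' for oscillatory, zero-crossing responses, so the percentage is taken at the
#' trace level.
#'
#' @param a,b Equal-length numeric traces on a shared grid.
#' @param mode `"reference"` (normalize by `mean(|a|)`) or `"symmetric"`
#'   (normalize by `(mean(|a|) + mean(|b|)) / 2`, order-invariant).
#' @return MAPE in percent (>= 0).
#' @export
pairwise_mape <- function(a, b, mode = c("reference", "symmetric")) {
  mode <- match.arg(mode)
  if (length(a) != length(b)) stop("structural error: traces differ in length")
  denom <- switch(mode,
                  reference = mean(abs(a)),
                  symmetric = (mean(abs(a)) + mean(abs(b))) / 2)
  if (denom < 1e-12) {
    stop("degenerate normalization: reference trace is (near) all-zero")
  }
  100 * mean(abs(a - b)) / denom
}

# all unordered-pair MAPEs within one list of traces
.mape_pairs <- function(traces, mode) {
  n <- length(traces)
  if (n < 2L) return(numeric(0))
  out <- numeric(n * (n - 1) / 2)
  k <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      k <- k + 1L
      out[k] <- pairwise_mape(traces[[i]], traces[[j]], mode = mode)
    }
  }
  out
}

#' Asymmetry index between mirrored perturbation directions
#'
#' The within-direction distribution collects the pairwise MAPE over all
#' same-direction response pairs, combined across the two directions. For the
#' across-direction distribution, the second direction's responses are
#' inverted (negated) and the MAPE is computed over all pairs of the pooled
#' set regardless of direction (`across = "pooled"`, the literal reading; the
#' cross-direction-only pairs are available via `across = "cross-only"`). The
#' index is `mean(across) - mean(within)`; 0 indicates mirror-symmetric
#' responses. Significance is a two-tailed Welch t-test between the two
#' distributions (null: symmetry).
#'
#' @param dir1_traces,dir2_traces Lists (>= 2 each) of equal-length response
#'   traces for the two opposite directions.
#' @param mode MAPE normalization passed to [pairwise_mape()]; default
#'   `"symmetric"` so unordered pair enumeration is order-invariant.
#' @param across `"pooled"` or `"cross-only"`.
#' @return List of class `asymmetry_result` with `within_mapes`,
#'   `across_mapes`, `index` (percentage points), `t` and `p_value`.
#' @export
asymmetry_index <- function(dir1_traces, dir2_traces,
                            mode = c("symmetric", "reference"),
                            across = c("pooled", "cross-only")) {
  mode <- match.arg(mode)
  across <- match.arg(across)
  if (length(dir1_traces) < 2L || length(dir2_traces) < 2L) {
    stop("need at least 2 trials per direction")
  }
  within <- c(.mape_pairs(dir1_traces, mode), .mape_pairs(dir2_traces, mode))
  inv2 <- lapply(dir2_traces, function(x) -x)
  across_mapes <- if (across == "pooled") {
    .mape_pairs(c(dir1_traces, inv2), mode)
  } else {
    unlist(lapply(dir1_traces, function(a) {
      vapply(inv2, function(b) pairwise_mape(a, b, mode = mode), 0)
    }))
  }
  index <- mean(across_mapes) - mean(within)
  # degenerate case: both distributions constant; equal means = perfect symmetry
  if (stats::var(within) < 1e-24 && stats::var(across_mapes) < 1e-24) {
    p <- if (abs(index) < 1e-12) 1 else 0
    tt <- list(statistic = c(t = if (abs(index) < 1e-12) 0 else Inf),
               p.value = p)
  } else {
    tt <- stats::t.test(across_mapes, within, var.equal = FALSE)
  }
  structure(list(within_mapes = within, across_mapes = across_mapes,
                 index = index, t = unname(tt$statistic),
                 p_value = tt$p.value, mode = mode, across = across),
            class = "asymmetry_result")
}

#' @export
print.asymmetry_result <- function(x, ...) {
  cat(sprintf(
    "<asymmetry_result> index = %.3f%% (within %.2f%%, n=%d; across %.2f%%, n=%d), p = %.4g\n",
    x$index, mean(x$within_mapes), length(x$within_mapes),
    mean(x$across_mapes), length(x$across_mapes), x$p_value))
  invisible(x)
}

#' Combine p-values with Fisher's method
#'
#' `X = -2 * sum(log(p_i))` is referred to the upper tail of a chi-square
#' distribution with `2k` degrees of freedom.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Combined p-value.
#' @export
fisher_combine <- function(p_values) {
  if (length(p_values) == 0L) stop("no p-values to combine")
  if (any(p_values <= 0)) {
    stop("p-value of 0 diverges under Fisher's method; clip to a small ",
         "positive value (e.g. .Machine$double.xmin) before combining")
  }
  if (any(p_values > 1)) stop("p-values must lie in (0, 1]")
  X <- -2 * sum(log(p_values))
  stats::pchisq(X, df = 2 * length(p_values), lower.tail = FALSE)
}

#' Response traces for asymmetry analysis
#'
#' Extracts one channel from each trial, restricted to the platform-motion
#' span, for use with [asymmetry_index()].
#'
#' @param trials List of [trial_record()]s sharing one condition grid.
#' @param role Channel role: `"cop"`, `"head_vel"` or `"head_acc"`.
#' @return List of numeric traces.
#' @export
response_traces <- function(trials, role = c("cop", "head_vel", "head_acc")) {
  role <- match.arg(role)
  lapply(trials, function(trial) {
    ch <- trial_channels(trial)
    nm <- axis_channels(trial$condition$axis)[[role]]
    mask <- ch$time >= 0 & ch$time <= trial$motion_end
    ch[[nm]][mask]
  })
}
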