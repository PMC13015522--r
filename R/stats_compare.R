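# Condition-dependence statistics: unbalanced two-way ANOVA (animal x
# condition, Type-II sums of squares, no interaction) at p < 0.025, and pooled
# ordinary-least-squares regression of the metric on the varied stimulus
# parameter, run only after a significant condition effect.

#' Unbalanced two-way ANOVA for animal and condition effects
#'
#' Fits `value ~ animal + condition` (both as factors, no interaction) and
#' tests each main effect with Type-II sums of squares, which handle unequal
#' cell sizes. The significance threshold for both factors is 0.025
#' (controlling for the two comparisons across factors). Degenerate
#' zero-residual tables are resolved by the exact limits: a factor with zero
#' sum of squares gets p = 1, a nonzero factor tested against a zero residual
#' gets p = 0.
#'
#' @param table Data frame with columns `animal_id`, `condition` (factor or
#'   coercible; the stimulus level) and `value`; >= 2 levels of each factor,
#'   no missing values.
#' @param alpha Significance threshold for both factors.
#' @return List of class `anova_result` with `p_condition`, `p_animal`,
#'   significance flags, and the underlying Type-II table.
#' @export
two_way_anova <- function(table, alpha = 0.025) {
  need <- c("animal_id", "condition", "value")
  if (!all(need %in% names(table))) {
    stop("table must have columns ", paste(need, collapse = ", "))
  }
  if (anyNA(table[need])) stop("missing metric values are not allowed")
  d <- data.frame(animal = factor(table$animal_id),
                  condition = factor(table$condition),
                  value = table$value)
  if (nlevels(d$animal) < 2L) stop("animal factor has a single level")
  if (nlevels(d$condition) < 2L) stop("condition factor has a single level")
  fit <- stats::lm(value ~ animal + condition, data = d)
  a2 <- tryCatch(car::Anova(fit, type = 2), error = function(e) {
    if (!grepl("residual sum of squares is 0", conditionMessage(e))) stop(e)
    # zero-residual fit: assemble the Type-II table from model comparisons
    rss_full <- stats::deviance(fit)
    ss_cond <- stats::deviance(stats::lm(value ~ animal, data = d)) - rss_full
    ss_anim <- stats::deviance(stats::lm(value ~ condition, data = d)) - rss_full
    out <- data.frame(`Sum Sq` = c(ss_anim, ss_cond, rss_full),
                      Df = c(nlevels(d$animal) - 1L, nlevels(d$condition) - 1L,
                             fit$df.residual),
                      `F value` = NA_real_, `Pr(>F)` = NA_real_,
                      check.names = FALSE)
    rownames(out) <- c("animal", "condition", "Residuals")
    out
  })
  ss <- a2[["Sum Sq"]]
  names(ss) <- rownames(a2)
  p <- a2[["Pr(>F)"]]
  names(p) <- rownames(a2)
  total_ss <- sum(ss)
  rel <- function(s) if (total_ss > 0) s / total_ss else 0
  fix_p <- function(term) {
    pv <- p[[term]]
    if (rel(ss[["Residuals"]]) < 1e-12) {
      pv <- if (rel(ss[[term]]) < 1e-12) 1 else 0
    }
    pv
  }
  p_animal <- fix_p("animal")
  p_condition <- fix_p("condition")
  structure(list(p_condition = p_condition, p_animal = p_animal,
                 significant_condition = p_condition < alpha,
                 significant_animal = p_animal < alpha,
                 alpha = alpha, table = a2),
            class = "anova_result")
}

#' Pooled linear regression of a metric on a stimulus parameter
#'
#' Ordinary least squares of the metric on the varied stimulus parameter over
#' all pooled trials (all animals), with a two-sided test of the slope at
#' alpha = 0.05.
#'
#' @param table Data frame with columns `predictor` (numeric stimulus value,
#'   deg/s or deg/s^2) and `value`.
#' @param alpha Slope significance threshold.
#' @return List of class `trend_result` with `slope` (metric units per
#'   stimulus unit), `slope_se`, `intercept`, `p_value`, `significant`, and
#'   the `lm` fit.
#' @export
condition_regression <- function(table, alpha = 0.05) {
  need <- c("predictor", "value")
  if (!all(need %in% names(table))) {
    stop("table must have columns ", paste(need, collapse = ", "))
  }
  if (length(unique(table$predictor)) < 2L) {
    stop("constant predictor: regression is undefined")
  }
  fit <- stats::lm(value ~ predictor, data = table)
  cf <- summary(fit)$coefficients
  structure(list(slope = cf["predictor", "Estimate"],
                 slope_se = cf["predictor", "Std. Error"],
                 intercept = cf["(Intercept)", "Estimate"],
                 p_value = cf["predictor", "Pr(>|t|)"],
                 significant = cf["predictor", "Pr(>|t|)"] < alpha,
                 fit = fit),
            class = "trend_result")
}

#' Condition-dependence test with the study's gating
#'
#' Runs the unbalanced two-way ANOVA and, only when the condition main effect
#' is significant at 0.025, the pooled regression of the metric on the
#' stimulus parameter. Expects the metric table of one stimulus set
#' (velocity set or acceleration set) for one channel and window.
#'
#' @param table Data frame with columns `animal_id`, `condition` (stimulus
#'   level, numeric), `value`.
#' @return One-row data frame: `anova_p_condition`, `anova_p_animal`,
#'   `anova_significant`, `regression_slope`, `regression_se`, `regression_p`,
#'   `regression_significant` (regression fields `NA` when the gate is
#'   closed).
#' @export
condition_trend <- function(table) {
  an <- two_way_anova(table)
  out <- data.frame(anova_p_condition = an$p_condition,
                    anova_p_animal = an$p_animal,
                    anova_significant = an$significant_condition,
                    regression_slope = NA_real_, regression_se = NA_real_,
                    regression_p = NA_real_, regression_significant = NA)
  if (an$significant_condition) {
    reg <- condition_regression(
      data.frame(predictor = as.numeric(table$condition), value = table$value))
    out$regression_slope <- reg$slope
    out$regression_se <- reg$slope_se
    out$regression_p <- reg$p_value
    out$regression_significant <- reg$significant
  }
  out
}
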