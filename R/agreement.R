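#' Intraclass correlation from one-way mean squares
#'
#' Agreement between two assay methods summarised as the one-way
#' random-effects intraclass correlation,
#' \deqn{ICC = (MSB - MSW) / (MSB + (k - 1) MSW),}
#' where MSB and MSW are the between-subject and within-subject mean squares
#' of an ANOVA treating each subject's k method readings as repeats. For a
#' two-method comparison k = 2.
#'
#' @param msb between-subject mean square, (ng/mL)^2; non-negative.
#' @param msw within-subject mean square, (ng/mL)^2; non-negative.
#' @param k number of methods/raters per subject, >= 2.
#' @return The ICC, a dimensionless value <= 1.
#' @examples
#' icc_from_components(102.08, 3.87, k = 2)   # 0.927 -> "high consistency"
#' @export
icc_from_components <- function(msb, msw, k = 2) {
  stopifnot(is.finite(msb), is.finite(msw), msb >= 0, msw >= 0,
            k >= 2, k == as.integer(k))
  denom <- msb + (k - 1) * msw
  if (denom <= 0) {
    stop("ICC undefined: MSB + (k-1) MSW must be positive", call. = FALSE)
  }
  (msb - msw) / denom
}

#' Intraclass correlation of the two assay results
#'
#' Computes the one-way ANOVA mean squares with subjects as groups and the
#' (CLIA, LC-MS/MS) pair as k = 2 repeated measures, then applies
#' [icc_from_components()].
#'
#' @param data a [paired_dataset()] with at least 3 samples.
#' @return A list of class `icc_result` with fields `msb`, `msw`, `k`, `icc`
#'   and `n`.
#' @export
icc <- function(data) {
  stopifnot(inherits(data, "paired_dataset"))
  n <- nrow(data)
  if (n < 3) stop("ICC needs at least 3 samples", call. = FALSE)
  y <- cbind(data$clia, data$lcms)
  k <- 2L
  grand <- mean(y)
  subj_means <- rowMeans(y)
  ssb <- k * sum((subj_means - grand)^2)
  ssw <- sum((y - subj_means)^2)
  msb <- ssb / (n - 1)
  msw <- ssw / (n * (k - 1))
  structure(list(msb = msb, msw = msw, k = k, n = n,
                 icc = icc_from_components(msb, msw, k)),
            class = "icc_result")
}

#' Bland-Altman limits of agreement
#'
#' Mean and sample standard deviation (n - 1 denominator) of the paired
#' differences LC-MS/MS minus CLIA, with limits of agreement
#' `mean difference +/- 1.96 * SD`. The multiplier 1.96 is fixed, matching
#' the conventional printed formula, rather than a configurable quantile.
#'
#' @param data a [paired_dataset()] with at least 2 samples.
#' @return A list of class `bland_altman_result` with fields `mean_diff`,
#'   `sd_diff`, `loa_lower`, `loa_upper` (all ng/mL) and `n`.
#' @export
bland_altman <- function(data) {
  stopifnot(inherits(data, "paired_dataset"))
  n <- nrow(data)
  if (n < 2) stop("Bland-Altman needs at least 2 samples", call. = FALSE)
  m <- mean(data$diff)
  s <- stats::sd(data$diff)
  structure(list(mean_diff = m, sd_diff = s,
                 loa_lower = m - 1.96 * s, loa_upper = m + 1.96 * s,
                 n = n),
            class = "bland_altman_result")
}

#' Paired t-test on the inter-method differences
#'
#' Two-sided paired t-test of LC-MS/MS against CLIA (df = n - 1).
#'
#' @param data a [paired_dataset()] with at least 2 samples and non-constant
#'   differences.
#' @return A list of class `paired_t_result` with fields `statistic`, `df`,
#'   `p_value`, `mean_diff`, `n`.
#' @export
paired_t <- function(data) {
  stopifnot(inherits(data, "paired_dataset"))
  n <- nrow(data)
  if (n < 2) stop("paired t-test needs at least 2 samples", call. = FALSE)
  if (stats::sd(data$diff) == 0) {
    stop("paired t-test undefined: differences have zero variance",
         call. = FALSE)
  }
  tt <- stats::t.test(data$lcms, data$clia, paired = TRUE,
                      alternative = "two.sided")
  structure(list(statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_value = tt$p.value,
                 mean_diff = unname(tt$estimate),
                 n = n),
            class = "paired_t_result")
}

#' Comparison regression of LC-MS/MS on CLIA
#'
#' Ordinary least squares of the reference-method result on the
#' comparison-method result, `lcms = p1 * clia + p2`, with 95% coefficient
#' confidence intervals from the t distribution on n - 2 df. Reported
#' alongside: R^2, adjusted R^2, residual sum of squares (SSE) and
#' RMSE = sqrt(SSE / (n - 2)).
#'
#' @param data a [paired_dataset()] with n >= 3 and non-constant CLIA.
#' @return A list of class `regression_fit`.
#' @export
comparison_regression <- function(data) {
  stopifnot(inherits(data, "paired_dataset"))
  n <- nrow(data)
  if (n < 3) stop("regression needs at least 3 samples", call. = FALSE)
  if (stats::sd(data$clia) == 0) {
    stop("singular design: CLIA values are constant", call. = FALSE)
  }
  fit <- stats::lm(lcms ~ clia, data = data)
  sm <- summary(fit)
  ci <- stats::confint(fit, level = 0.95)
  sse <- sum(stats::residuals(fit)^2)
  structure(list(
    slope = unname(stats::coef(fit)["clia"]),
    intercept = unname(stats::coef(fit)["(Intercept)"]),
    r2 = sm$r.squared,
    adj_r2 = sm$adj.r.squared,
    sse = sse,
    rmse = sqrt(sse / (n - 2)),
    slope_ci95 = unname(ci["clia", ]),
    intercept_ci95 = unname(ci["(Intercept)", ]),
    n = n
  ), class = "regression_fit")
}

#' Cohen's kappa for a 2x2 method cross-classification
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e)/(1 - p_e)} with
#' observed agreement `p_o = (n_pp + n_nn)/n` and expected agreement `p_e`
#' from the row-by-column marginal products. When a marginal is degenerate
#' (`p_e = 1`, e.g. every sample on the same side for both methods) kappa is
#' undefined; a flagged `NaN` is returned with a warning so batch pipelines
#' survive degenerate draws.
#'
#' @param n_pp,n_pn,n_np,n_nn cell counts; first index is the CLIA class
#'   (`p` = at/above threshold), second the LC-MS/MS class.
#' @return Kappa in `[-1, 1]`, or `NaN` for degenerate marginals.
#' @examples
#' cohen_kappa(60, 5, 7, 66)   # 0.826, strong agreement
#' @export
cohen_kappa <- function(n_pp, n_pn, n_np, n_nn) {
  counts <- c(n_pp, n_pn, n_np, n_nn)
  stopifnot(all(counts >= 0), all(counts == as.integer(counts)))
  n <- sum(counts)
  if (n == 0) stop("kappa undefined for an empty table", call. = FALSE)
  po <- (n_pp + n_nn) / n
  p_row <- c(n_pp + n_pn, n_np + n_nn) / n   # CLIA marginals
  p_col <- c(n_pp + n_np, n_pn + n_nn) / n   # LC-MS/MS marginals
  pe <- sum(p_row * p_col)
  if (pe >= 1) {
    warning("degenerate marginals (expected agreement = 1); kappa undefined",
            call. = FALSE)
    return(NaN)
  }
  (po - pe) / (1 - pe)
}

#' Wilson score interval for a binomial proportion
#'
#' @param successes non-negative integer count.
#' @param n positive integer total.
#' @param level confidence level in (0, 1); z is the standard-normal
#'   quantile at `(1 + level)/2`.
#' @return Numeric length-2 vector `c(lower, upper)`, a sub-interval of
#'   `[0, 1]` containing `successes/n`.
#' @examples
#' wilson_ci(12, 138)   # 5.0% - 14.6%
#' @export
wilson_ci <- function(successes, n, level = 0.95) {
  stopifnot(n > 0, successes >= 0, successes <= n,
            level > 0, level < 1)
  z <- stats::qnorm((1 + level) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- (z / denom) * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Cross-classify both methods at a clinical threshold
#'
#' Counts the 2x2 table of CLIA vs LC-MS/MS classified at a threshold
#' (values exactly at the threshold count as "at/above", matching the
#' convention of labelling the sufficient class ">= 20 ng/mL"), and derives
#' the agreement rate `(n_pp + n_nn)/n`, Cohen's kappa, the discordant
#' count, and a Wilson 95% CI on the discordant proportion.
#'
#' @param data a [paired_dataset()].
#' @param threshold decision threshold, ng/mL.
#' @return A list of class `crosstab_result`.
#' @export
threshold_crosstab <- function(data, threshold) {
  stopifnot(inherits(data, "paired_dataset"), is.finite(threshold))
  n <- nrow(data)
  if (n < 1) stop("empty dataset", call. = FALSE)
  cp <- data$clia >= threshold
  lp <- data$lcms >= threshold
  n_pp <- sum(cp & lp)
  n_pn <- sum(cp & !lp)
  n_np <- sum(!cp & lp)
  n_nn <- sum(!cp & !lp)
  disc <- n_pn + n_np
  structure(list(
    threshold = threshold,
    n_pp = n_pp, n_pn = n_pn, n_np = n_np, n_nn = n_nn,
    n = n,
    agreement_rate = (n_pp + n_nn) / n,
    kappa = cohen_kappa(n_pp, n_pn, n_np, n_nn),
    discordant = disc,
    discordant_wilson_ci = wilson_ci(disc, n, 0.95)
  ), class = "crosstab_result")
}

#' Multi-threshold reclassification analysis
#'
#' Cross-classifies the two methods at each clinical threshold (defaults:
#' 20 ng/mL deficiency and 30 ng/mL insufficiency cutoffs) and pools the
#' samples that change diagnostic category at any threshold into one
#' discordant proportion with a Wilson 95% CI.
#'
#' @param data a [paired_dataset()].
#' @param thresholds positive thresholds, ng/mL.
#' @return A list of class `reclassification_result` with fields
#'   `per_threshold` (list of [threshold_crosstab()] results), `n`,
#'   `pooled_discordant`, `pooled_proportion`, `pooled_wilson_ci`.
#' @export
reclassification <- function(data, thresholds = c(20, 30)) {
  stopifnot(inherits(data, "paired_dataset"),
            length(thresholds) > 0, all(thresholds > 0))
  n <- nrow(data)
  tabs <- lapply(thresholds, function(th) threshold_crosstab(data, th))
  names(tabs) <- paste0("threshold_", thresholds)
  discordant_any <- rep(FALSE, n)
  for (th in thresholds) {
    discordant_any <- discordant_any |
      ((data$clia >= th) != (data$lcms >= th))
  }
  pooled <- sum(discordant_any)
  structure(list(
    per_threshold = tabs,
    thresholds = thresholds,
    n = n,
    pooled_discordant = pooled,
    pooled_proportion = pooled / n,
    pooled_wilson_ci = wilson_ci(pooled, n, 0.95)
  ), class = "reclassification_result")
}

#' Run the full paired-agreement battery
#'
#' Convenience wrapper: ICC, Bland-Altman, paired t-test, comparison
#' regression and reclassification in one report.
#'
#' @param data a [paired_dataset()].
#' @param thresholds thresholds passed to [reclassification()].
#' @return A list of class `agreement_report`.
#' @export
agreement_battery <- function(data, thresholds = c(20, 30)) {
  structure(list(
    n = nrow(data),
    icc = icc(data),
    bland_altman = bland_altman(data),
    paired_t = paired_t(data),
    regression = comparison_regression(data),
    reclassification = reclassification(data, thresholds)
  ), class = "agreement_report")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("One-way ICC (k = %d, n = %d): %.4f  [MSB %.3f, MSW %.3f]\n",
              x$k, x$n, x$icc, x$msb, x$msw))
  invisible(x)
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): mean diff %.2f ng/mL, SD %.2f; LOA [%.2f, %.2f]\n",
              x$n, x$mean_diff, x$sd_diff, x$loa_lower, x$loa_upper))
  invisible(x)
}

#' @export
print.crosstab_result <- function(x, ...) {
  cat(sprintf("Cross-classification at %.3g ng/mL (n = %d)\n",
              x$threshold, x$n))
  cat(sprintf("  [CLIA>=, LCMS>=] %d  [CLIA>=, LCMS<] %d\n", x$n_pp, x$n_pn))
  cat(sprintf("  [CLIA<,  LCMS>=] %d  [CLIA<,  LCMS<] %d\n", x$n_np, x$n_nn))
  cat(sprintf("  agreement %.1f%%, kappa %.3f, discordant %d (Wilson 95%% CI %.1f%%-%.1f%%)\n",
              100 * x$agreement_rate, x$kappa, x$discordant,
              100 * x$discordant_wilson_ci[1], 100 * x$discordant_wilson_ci[2]))
  invisible(x)
}
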