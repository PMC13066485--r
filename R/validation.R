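#' Dichotomize inter-method differences into high/low
#'
#' Labels each sample's difference (LC-MS/MS minus CLIA) as `"high"` when it
#' is at or above the threshold, `"low"` otherwise. The boundary is
#' inclusive on the high side. `threshold = "mean"` resolves to the
#' dataset's own mean difference, the convention used when a verification
#' cohort defines "high" relative to its average discrepancy.
#'
#' @param data a non-empty [paired_dataset()].
#' @param threshold numeric ng/mL, or the string `"mean"`.
#' @return A list of class `dichotomy` with `labels` (factor high/low),
#'   `threshold` (resolved numeric) and `n_high`.
#' @export
dichotomize_difference <- function(data, threshold = "mean") {
  stopifnot(inherits(data, "paired_dataset"), nrow(data) > 0)
  th <- if (identical(threshold, "mean")) mean(data$diff) else {
    stopifnot(is.numeric(threshold), is.finite(threshold))
    threshold
  }
  lab <- factor(ifelse(data$diff >= th, "high", "low"),
                levels = c("high", "low"))
  structure(list(labels = lab, threshold = th, n_high = sum(lab == "high")),
            class = "dichotomy")
}

#' Assign samples to the experimental or control group
#'
#' Default demographic predicate: women aged 30-40 years (both bounds
#' inclusive) form the experimental group; men, and women outside the
#' window, form the control group.
#'
#' @param data a [paired_dataset()].
#' @param sex experimental-group sex (default `"female"`).
#' @param age_window inclusive age interval in years (default `c(30, 40)`).
#' @return Factor with levels `experimental`/`control`, one per sample.
#' @export
group_membership <- function(data, sex = "female", age_window = c(30, 40)) {
  stopifnot(inherits(data, "paired_dataset"),
            length(age_window) == 2, age_window[1] <= age_window[2])
  is_exp <- data$sex == sex &
    data$age >= age_window[1] & data$age <= age_window[2]
  factor(ifelse(is_exp, "experimental", "control"),
         levels = c("experimental", "control"))
}

#' Relative risk of a high inter-method difference
#'
#' For the 2x2 table of group (experimental/control) by difference class
#' (high/low): RR = (a/(a+b)) / (c/(c+d)), with the 95% CI from the
#' log-RR normal approximation
#' \deqn{\exp(\log RR \pm 1.96 \sqrt{1/a - 1/(a+b) + 1/c - 1/(c+d)}).}
#' A zero high-count in the control group gives an infinite RR, flagged
#' with a warning and an undefined CI; `correction = TRUE` adds the
#' Haldane-style 0.5 to every cell before computing instead.
#'
#' @param n_exp_high,n_exp_low experimental-group counts (a, b).
#' @param n_ctrl_high,n_ctrl_low control-group counts (c, d).
#' @param correction add 0.5 to each cell (default FALSE).
#' @return A list of class `rr_result` with the counts, group proportions
#'   `p_exp`/`p_ctrl`, `rr` and `ci95`.
#' @examples
#' relative_risk(15, 13, 7, 24)   # RR 2.37, CI excludes 1
#' @export
relative_risk <- function(n_exp_high, n_exp_low, n_ctrl_high, n_ctrl_low,
                          correction = FALSE) {
  counts <- c(n_exp_high, n_exp_low, n_ctrl_high, n_ctrl_low)
  stopifnot(all(counts >= 0))
  if (n_exp_high + n_exp_low == 0 || n_ctrl_high + n_ctrl_low == 0) {
    stop("both group totals must be positive", call. = FALSE)
  }
  a <- n_exp_high; b <- n_exp_low; c <- n_ctrl_high; d <- n_ctrl_low
  if (correction) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  p_exp <- a / (a + b)
  p_ctrl <- c / (c + d)
  if (p_ctrl == 0) {
    warning("no high differences in the control group; RR infinite, CI undefined",
            call. = FALSE)
    rr <- Inf
    ci <- c(lower = NA_real_, upper = NA_real_)
  } else {
    rr <- p_exp / p_ctrl
    if (a == 0) {
      warning("no high differences in the experimental group; CI undefined",
              call. = FALSE)
      ci <- c(lower = NA_real_, upper = NA_real_)
    } else {
      se <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
      ci <- c(lower = rr * exp(-1.96 * se), upper = rr * exp(1.96 * se))
    }
  }
  structure(list(
    n_exp_high = n_exp_high, n_exp_low = n_exp_low,
    n_ctrl_high = n_ctrl_high, n_ctrl_low = n_ctrl_low,
    p_exp = p_exp, p_ctrl = p_ctrl,
    rr = rr, ci95 = ci, correction = correction
  ), class = "rr_result")
}

#' Verification analysis: demographic relative risk of high differences
#'
#' Wires the three verification steps together: dichotomize the differences
#' (default at the cohort mean), split the cohort by the demographic
#' predicate (default women aged 30-40), and compute the relative risk of a
#' high difference in the experimental group.
#'
#' @param data a [paired_dataset()] (the verification cohort).
#' @param threshold passed to [dichotomize_difference()].
#' @param sex,age_window passed to [group_membership()].
#' @return An `rr_result` with the resolved `threshold` and group sizes
#'   attached.
#' @export
verify_difference_risk <- function(data, threshold = "mean",
                                   sex = "female", age_window = c(30, 40)) {
  di <- dichotomize_difference(data, threshold)
  grp <- group_membership(data, sex, age_window)
  high <- di$labels == "high"
  res <- relative_risk(sum(grp == "experimental" & high),
                       sum(grp == "experimental" & !high),
                       sum(grp == "control" & high),
                       sum(grp == "control" & !high))
  res$threshold <- di$threshold
  res$n_experimental <- sum(grp == "experimental")
  res$n_control <- sum(grp == "control")
  res
}

#' @export
print.rr_result <- function(x, ...) {
  cat(sprintf("Relative risk of high difference: %.3f (95%% CI %.3f-%.3f)\n",
              x$rr, x$ci95[1], x$ci95[2]))
  cat(sprintf("  experimental %d/%d high (%.1f%%); control %d/%d high (%.1f%%)\n",
              x$n_exp_high, x$n_exp_high + x$n_exp_low, 100 * x$p_exp,
              x$n_ctrl_high, x$n_ctrl_high + x$n_ctrl_low, 100 * x$p_ctrl))
  invisible(x)
}
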