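test_that("ICC from mean squares matches the closed form and its limits", {
  # printed one-way components of the reference comparison
  expect_equal(round(icc_from_components(102.08, 3.87, k = 2), 2), 0.93)
  expect_equal(icc_from_components(102.08, 3.87, 2),
               (102.08 - 3.87) / (102.08 + 3.87), tolerance = 1e-12)
  # no between-subject excess / perfect within-subject agreement
  for (m in c(0.5, 1, 7)) expect_equal(icc_from_components(m, m, 2), 0)
  expect_equal(icc_from_components(5, 0, 2), 1)
  expect_error(icc_from_components(0, 0, 2), "undefined")
})

test_that("ICC is monotone in its components", {
  msb <- seq(1, 50, length.out = 20)
  vals <- vapply(msb, icc_from_components, numeric(1), msw = 2, k = 2)
  expect_true(all(diff(vals) > 0))
  msw <- seq(0.5, 20, length.out = 20)
  vals <- vapply(msw, function(w) icc_from_components(30, w, 2), numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("dataset ICC equals a sums-of-squares ANOVA oracle", {
  d <- make_dataset(clia = c(5, 10, 15, 20, 25), lcms = c(5, 10, 15, 20, 25))
  expect_equal(icc(d)$icc, 1)

  syn <- generate_cohort(synthetic_config(n = 200, seed = 31))
  got <- icc(syn)
  # oracle: long-format one-way ANOVA via stats::aov, subjects as groups
  long <- data.frame(y = c(syn$clia, syn$lcms),
                     subj = factor(rep(syn$sample_id, 2)))
  tab <- summary(stats::aov(y ~ subj, data = long))[[1]]
  msb <- tab["subj", "Mean Sq"]
  msw <- tab["Residuals", "Mean Sq"]
  expect_equal(got$msb, msb, tolerance = 1e-10)
  expect_equal(got$msw, msw, tolerance = 1e-10)
  expect_equal(got$icc, (msb - msw) / (msb + msw), tolerance = 1e-10)

  # independent methods: ICC near zero at large n
  ind <- withr::with_seed(8, {
    make_dataset(clia = runif(5000, 5, 45), lcms = runif(5000, 5, 45))
  })
  expect_lt(abs(icc(ind)$icc), 0.05)

  expect_error(icc(make_dataset(c(1, 2), c(1, 2))), "at least 3")
})

test_that("Bland-Altman limits follow mean +/- 1.96 SD exactly", {
  # arithmetic on the reference study's printed mean/SD of the differences
  d <- withr::with_seed(4, {
    base <- rnorm(100)
    diffs <- 1.33 + 3.71 * scale(base)[, 1]   # exact mean 1.33, sd 3.71
    make_dataset(clia = rep(20, 100), lcms = 20 + diffs)
  })
  ba <- bland_altman(d)
  expect_equal(ba$mean_diff, 1.33, tolerance = 1e-9)
  expect_equal(ba$sd_diff, 3.71, tolerance = 1e-9)
  expect_equal(ba$loa_lower, 1.33 - 1.96 * 3.71, tolerance = 1e-9)  # -5.9416
  expect_equal(ba$loa_upper, 1.33 + 1.96 * 3.71, tolerance = 1e-9)  #  8.6016

  # identical differences collapse the limits onto the mean
  flat <- make_dataset(clia = c(10, 20, 30), lcms = c(12, 22, 32))
  bf <- bland_altman(flat)
  expect_equal(bf$sd_diff, 0)
  expect_equal(c(bf$loa_lower, bf$loa_upper), c(2, 2))

  # two-pass oracle on synthetic data
  syn <- generate_cohort(synthetic_config(n = 200, seed = 13))
  bs <- bland_altman(syn)
  m <- sum(syn$diff) / 200
  s <- sqrt(sum((syn$diff - m)^2) / 199)
  expect_equal(bs$mean_diff, m, tolerance = 1e-12)
  expect_equal(bs$sd_diff, s, tolerance = 1e-12)

  # LOA identity as a property over seeds
  for (s in 1:5) {
    b <- bland_altman(generate_cohort(synthetic_config(n = 50, seed = s)))
    expect_identical(b$loa_lower, b$mean_diff - 1.96 * b$sd_diff)
    expect_identical(b$loa_upper, b$mean_diff + 1.96 * b$sd_diff)
    expect_true(b$loa_lower <= b$mean_diff && b$mean_diff <= b$loa_upper)
  }
})

test_that("paired t-test matches an independent t CDF evaluation", {
  # symmetric jitter around zero: t = 0, p = 1
  null_d <- make_dataset(clia = rep(20, 6),
                         lcms = 20 + c(-3, 3, -2, 2, -1, 1) * 1e-3)
  expect_equal(paired_t(null_d)$p_value, 1)

  syn <- generate_cohort(synthetic_config(n = 138, seed = 21))
  got <- paired_t(syn)
  tstat <- mean(syn$diff) / (sd(syn$diff) / sqrt(138))
  expect_equal(got$statistic, tstat, tolerance = 1e-10)
  expect_equal(got$p_value, 2 * stats::pt(-abs(tstat), df = 137),
               tolerance = 1e-12)
  expect_lt(got$p_value, 0.01)   # the generator's +1.33 ng/mL shift

  expect_error(paired_t(make_dataset(10, 12)), "at least 2")
  expect_error(paired_t(make_dataset(c(10, 20), c(12, 22))),
               "zero variance")
})

test_that("comparison regression recovers exact and generated lines", {
  x <- seq(5, 50, length.out = 10)
  exact <- make_dataset(clia = x, lcms = 2 * x + 1)
  r <- suppressWarnings(comparison_regression(exact))  # "perfect fit" notice
  expect_equal(r$slope, 2, tolerance = 1e-10)
  expect_equal(r$intercept, 1, tolerance = 1e-9)
  expect_equal(r$r2, 1, tolerance = 1e-12)
  expect_equal(r$sse, 0, tolerance = 1e-18)

  syn <- generate_cohort(synthetic_config(n = 500, seed = 17))
  rs <- comparison_regression(syn)
  expect_true(rs$slope_ci95[1] <= 1.161 && 1.161 <= rs$slope_ci95[2])
  expect_true(rs$intercept_ci95[1] <= -2.009 && -2.009 <= rs$intercept_ci95[2])
  expect_equal(rs$rmse^2 * (rs$n - 2), rs$sse, tolerance = 1e-8)
  expect_true(rs$slope_ci95[1] <= rs$slope && rs$slope <= rs$slope_ci95[2])

  expect_error(comparison_regression(make_dataset(rep(20, 3), c(1, 2, 3))),
               "singular")
})

test_that("Cohen's kappa reproduces the printed table and its limits", {
  k <- cohen_kappa(60, 5, 7, 66)
  expect_equal(round(k, 2), 0.83)
  # independent recomputation from marginal products
  n <- 138; po <- 126 / 138
  pe <- (65 / n) * (67 / n) + (73 / n) * (71 / n)
  expect_equal(k, (po - pe) / (1 - pe), tolerance = 1e-12)

  expect_equal(cohen_kappa(50, 0, 0, 50), 1)
  expect_equal(cohen_kappa(25, 25, 25, 25), 0)
  expect_warning(kd <- cohen_kappa(10, 0, 0, 0), "degenerate")
  expect_true(is.nan(kd))

  # kappa = 1 iff both off-diagonal counts are zero (non-degenerate case)
  withr::with_seed(5, {
    for (i in 1:20) {
      cts <- rmultinom(1, 60, c(0.4, 0.1, 0.1, 0.4))[, 1]
      kv <- suppressWarnings(cohen_kappa(cts[1], cts[2], cts[3], cts[4]))
      if (!is.nan(kv)) {
        expect_equal(kv == 1, cts[2] == 0 && cts[3] == 0)
      }
    }
  })
})

test_that("Wilson interval matches prop.test and stays in bounds", {
  ci <- wilson_ci(12, 138)
  expect_equal(round(100 * ci[["lower"]], 1), 5.0)
  expect_equal(round(100 * ci[["upper"]], 1), 14.6)
  # independent oracle: score interval from prop.test without correction
  pt <- stats::prop.test(12, 138, correct = FALSE)$conf.int
  expect_equal(unname(ci), as.numeric(pt), tolerance = 1e-10)

  expect_equal(wilson_ci(0, 50)[["lower"]], 0)
  expect_equal(wilson_ci(50, 50)[["upper"]], 1)

  withr::with_seed(11, {
    for (i in 1:25) {
      n <- sample(2:400, 1); x <- sample(0:n, 1)
      ci <- wilson_ci(x, n)
      expect_true(ci[["lower"]] >= 0 && ci[["upper"]] <= 1)
      expect_true(ci[["lower"]] <= x / n && x / n <= ci[["upper"]])
    }
  })
})

test_that("threshold cross-tab counts match a per-row loop oracle", {
  d <- make_crosstab_cohort()
  ct <- threshold_crosstab(d, 20)
  expect_equal(c(ct$n_pp, ct$n_pn, ct$n_np, ct$n_nn), c(60, 5, 7, 66))
  expect_equal(ct$agreement_rate, 126 / 138)
  expect_equal(round(ct$agreement_rate, 3), 0.913)
  expect_equal(round(ct$kappa, 2), 0.83)

  # boundary value counts as at/above
  b <- make_dataset(clia = c(20, 19.999), lcms = c(20, 20))
  cb <- threshold_crosstab(b, 20)
  expect_equal(c(cb$n_pp, cb$n_np), c(1, 1))

  syn <- generate_cohort(synthetic_config(n = 300, seed = 23))
  cs <- threshold_crosstab(syn, 20)
  pp <- pn <- np <- nn <- 0
  for (i in 1:300) {
    cp <- syn$clia[i] >= 20; lp <- syn$lcms[i] >= 20
    if (cp && lp) pp <- pp + 1 else if (cp) pn <- pn + 1
    else if (lp) np <- np + 1 else nn <- nn + 1
  }
  expect_equal(c(cs$n_pp, cs$n_pn, cs$n_np, cs$n_nn), c(pp, pn, np, nn))

  same <- make_dataset(clia = c(25, 30, 40), lcms = c(26, 31, 39))
  cw <- suppressWarnings(threshold_crosstab(same, 20))
  expect_equal(cw$agreement_rate, 1)
  expect_true(is.nan(cw$kappa))
})

test_that("reclassification pools discordance across thresholds", {
  d <- make_crosstab_cohort()   # 12 discordant at 20, none at 30
  # every sample is below 30 for both methods: kappa degenerate there
  rc <- suppressWarnings(reclassification(d, thresholds = c(20, 30)))
  expect_equal(rc$pooled_discordant, 12)
  expect_equal(round(rc$pooled_proportion, 4), 0.087)
  expect_equal(round(100 * rc$pooled_wilson_ci[["lower"]], 1), 5.0)
  expect_equal(round(100 * rc$pooled_wilson_ci[["upper"]], 1), 14.6)

  conc <- make_dataset(clia = c(25, 10, 35), lcms = c(26, 11, 36))
  expect_equal(reclassification(conc)$pooled_discordant, 0)

  syn <- generate_cohort(synthetic_config(n = 300, seed = 29))
  rs <- reclassification(syn, c(20, 30))
  oracle <- sum(vapply(1:300, function(i) {
    any(vapply(c(20, 30), function(th) {
      (syn$clia[i] >= th) != (syn$lcms[i] >= th)
    }, logical(1)))
  }, logical(1)))
  expect_equal(rs$pooled_discordant, oracle)
})
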