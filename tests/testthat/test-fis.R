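test_that("a single-rule linear FIS collapses to four-input OLS", {
  d <- generate_cohort(synthetic_config(n = 250, seed = 5))
  fis <- build_fis(d, config = fcm_config(n_clusters = 1, seed = 5),
                   consequents = "linear")
  sexc <- ifelse(d$sex == "female", 1, 0)
  ols <- stats::lm(d$diff ~ d$clia + d$lcms + sexc + d$age)
  pred <- fis_predict(fis, d$clia, d$lcms, as.character(d$sex), d$age)
  expect_lt(max(abs(pred - stats::fitted(ols))), 1e-6)
})

test_that("the generated system has one rule per cluster and refines OLS", {
  d <- generate_cohort(synthetic_config(n = 400, seed = 9))
  fis <- build_fis(d, config = fcm_config(seed = 9))
  expect_equal(fis$n_rules, 3)
  expect_equal(nrow(fis$mf_centers), 3)
  expect_equal(dim(fis$theta), c(5, 3))

  # least-squares refinement: the 3-rule linear fit cannot be worse than
  # the global linear model on the same inputs
  fl <- build_fis(d, config = fcm_config(seed = 9), consequents = "linear")
  sexc <- ifelse(d$sex == "female", 1, 0)
  ols <- stats::lm(d$diff ~ d$clia + d$lcms + sexc + d$age)
  rmse_fis <- sqrt(mean((fis_predict(fl, d$clia, d$lcms,
                                     as.character(d$sex), d$age) - d$diff)^2))
  rmse_ols <- sqrt(mean(stats::resid(ols)^2))
  expect_lte(rmse_fis, rmse_ols + 1e-9)
})

test_that("predictions are convex combinations of rule outputs", {
  d <- generate_cohort(synthetic_config(n = 300, seed = 14))
  fis <- build_fis(d, config = fcm_config(seed = 14))
  consequent_levels <- fis$theta["const", ]   # constant consequents
  pred <- fis_predict(fis, d$clia, d$lcms, as.character(d$sex), d$age)
  expect_true(all(pred >= min(consequent_levels) - 1e-9))
  expect_true(all(pred <= max(consequent_levels) + 1e-9))
})

test_that("vectorized prediction equals a per-point loop", {
  d <- generate_cohort(synthetic_config(n = 80, seed = 25))
  fis <- build_fis(d, config = fcm_config(seed = 25))
  batch <- fis_predict(fis, d$clia, d$lcms, as.character(d$sex), d$age)
  loop <- vapply(seq_len(80), function(i) {
    fis_predict(fis, d$clia[i], d$lcms[i], as.character(d$sex[i]), d$age[i])
  }, numeric(1))
  expect_equal(batch, loop, tolerance = 1e-12)
})

test_that("prediction is continuous in each input", {
  d <- generate_cohort(synthetic_config(n = 200, seed = 33))
  fis <- build_fis(d, config = fcm_config(seed = 33))
  base <- c(clia = 22, lcms = 24, age = 45)
  p0 <- fis_predict(fis, base["clia"], base["lcms"], "female", base["age"])
  h <- 1e-6
  steps <- c(
    fis_predict(fis, base["clia"] + h, base["lcms"], "female", base["age"]),
    fis_predict(fis, base["clia"], base["lcms"] + h, "female", base["age"]),
    fis_predict(fis, base["clia"], base["lcms"], "female", base["age"] + h)
  )
  expect_true(all(abs(steps - p0) < 1e-3))
})

test_that("swapping the sex codes leaves predictions unchanged", {
  d <- generate_cohort(synthetic_config(n = 250, seed = 19))
  f01 <- build_fis(d, sex_encoding(0, 1), fcm_config(seed = 19))
  f10 <- build_fis(d, sex_encoding(1, 0), fcm_config(seed = 19))
  q <- list(clia = c(12, 20, 33), lcms = c(13, 22, 36),
            sex = c("female", "male", "female"), age = c(28, 45, 62))
  expect_equal(fis_predict(f01, q$clia, q$lcms, q$sex, q$age),
               fis_predict(f10, q$clia, q$lcms, q$sex, q$age),
               tolerance = 1e-8)
})

test_that("output normalization maps the training range onto [0, 1]", {
  norm <- c(min = -4, max = 12)
  expect_equal(normalize_output(-4, norm), 0)
  expect_equal(normalize_output(12, norm), 1)
  expect_equal(normalize_output(4, norm), 0.5)
  expect_warning(z <- normalize_output(c(-10, 20), norm), "clamped")
  expect_equal(z, c(0, 1))
  expect_error(normalize_output(1, c(3, 3)), "degenerate")
})

test_that("rule weights are a probability vector over rules", {
  d <- generate_cohort(synthetic_config(n = 300, seed = 41))
  fis <- build_fis(d, config = fcm_config(seed = 41))
  w <- rule_weight_summary(fis, d)$weights
  expect_equal(sum(w), 1, tolerance = 1e-9)
  expect_true(all(w > 0))

  one <- build_fis(d, config = fcm_config(n_clusters = 1, seed = 2))
  expect_equal(rule_weight_summary(one, d)$weights, 1)

  # two identical rules split the weight evenly
  twin <- fis
  twin$n_rules <- 2L
  twin$mf_centers <- fis$mf_centers[c(1, 1), ]
  twin$mf_sigmas <- fis$mf_sigmas[c(1, 1), ]
  twin$labels <- fis$labels[c(1, 1), ]
  twin$theta <- fis$theta[, c(1, 1)]
  expect_equal(unname(rule_weight_summary(twin, d)$weights), c(0.5, 0.5),
               tolerance = 1e-12)
})

test_that("the rule surface agrees with pointwise prediction", {
  d <- generate_cohort(synthetic_config(n = 250, seed = 47))
  fis <- build_fis(d, config = fcm_config(seed = 47))
  g <- 12
  s <- rule_surface(fis, "age", "lcms",
                    fixed = list(sex = "female", clia = 20), grid = g)
  expect_equal(dim(s), c(g, g))
  expect_true(all(s >= 0 & s <= 1))
  ax_a <- attr(s, "axis_a"); ax_b <- attr(s, "axis_b")
  cells <- withr::with_seed(3, cbind(sample(g, 10, TRUE), sample(g, 10, TRUE)))
  for (r in seq_len(nrow(cells))) {
    i <- cells[r, 1]; j <- cells[r, 2]
    p <- fis_predict(fis, 20, ax_b[j], "female", ax_a[i])
    expect_equal(s[i, j],
                 suppressWarnings(normalize_output(p, fis$output_norm)),
                 tolerance = 1e-6)
  }

  # single-rule constant system: flat surface
  flat <- build_fis(d, config = fcm_config(n_clusters = 1, seed = 2))
  sf <- rule_surface(flat, "age", "lcms",
                     fixed = list(sex = "female", clia = 20), grid = 5)
  expect_equal(max(sf) - min(sf), 0, tolerance = 1e-12)

  expect_error(rule_surface(fis, "age", "age",
                            fixed = list(sex = "female", clia = 20)), "dim")
})

test_that("age profiles are total and bounded", {
  d <- generate_cohort(synthetic_config(n = 200, seed = 53))
  fis <- build_fis(d, config = fcm_config(seed = 53))
  for (sex in c("female", "male")) {
    p <- age_profile(fis, sex, ages = c(1, 18, 35, 60, 119))
    expect_true(all(is.finite(p$output)))
    expect_true(all(p$output >= 0 & p$output <= 1))
  }
})

test_that("too-small datasets and singular systems are handled", {
  small <- make_dataset(clia = c(10, 20, 30), lcms = c(12, 22, 32))
  expect_error(build_fis(small, config = fcm_config(n_clusters = 3)),
               "at least")
  # constant CLIA column makes the linear blocks collinear with the
  # constant term: falls back to constant consequents with a warning
  dd <- generate_cohort(synthetic_config(n = 60, seed = 3))
  dd$clia <- 20
  dd$diff <- dd$lcms - dd$clia
  expect_warning(fb <- build_fis(dd, config = fcm_config(seed = 3),
                                 consequents = "linear"),
                 "singular")
  expect_equal(fb$consequents, "constant")
})
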