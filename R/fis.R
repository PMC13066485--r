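#' Generate a Takagi-Sugeno fuzzy inference system from FCM clusters
#'
#' Builds a Sugeno system mapping the four inputs (CLIA, LC-MS/MS, sex
#' code, age) to the inter-method difference, the way GENFIS-style
#' generators extract rules from fuzzy C-means clusters:
#'
#' 1. The joint input-output matrix `[clia, lcms, sex, age, diff]` is
#'    clustered with [fcm_fit()] (N clusters, fuzzifier m from `config`).
#'    Rules come from input-output patterns, so clustering runs in the
#'    joint space while antecedents use only the four input projections.
#'    By default the clustering runs in natural units
#'    (`clustering_scale = "none"`), which on cohorts of this shape yields
#'    the assay-level- and age-banded clusters with female-leaning sex
#'    centers that make the generated rules readable; `"minmax"` scales
#'    every dimension to `[0, 1]` first, which hands the binary sex axis
#'    the largest inter-point distance and makes it the primary split.
#' 2. Each cluster becomes one rule. Its antecedent is a product of
#'    Gaussian membership functions, one per input: center = the cluster
#'    center's projection, sigma = the membership-weighted standard
#'    deviation of that input around the center (weights \eqn{\mu^m}),
#'    floored at 5% of the input's observed range so tight clusters cannot
#'    collapse into numerically dead spike functions.
#' 3. Rule consequents are fitted jointly by least squares on the
#'    normalized firing strengths. The default is zeroth-order
#'    (`consequents = "constant"`): one level per rule, so the prediction
#'    is a firing-weighted blend of per-cluster difference levels and the
#'    rule layer carries all of the model's structure. First-order
#'    (`"linear"`) consequents are supported, but note that because the
#'    output is by construction `lcms - clia`, the global least-squares
#'    fit of linear consequents recovers that identity exactly and the
#'    fuzzy layer becomes inert (every rule receives the same
#'    coefficients); it is the right mode for checking the least-squares
#'    machinery, not for interpreting demographic structure. A singular
#'    linear system falls back to constant consequents with a warning.
#' 4. The observed difference range is stored as `(min, max)` for
#'    [normalize_output()].
#'
#' Each rule also carries low/medium/high labels per input from ranking the
#' cluster centers on that input (ties broken by cluster index).
#'
#' @param data a [paired_dataset()] with at least `2 * n_clusters` rows.
#' @param encoding a [sex_encoding()]; predictions are invariant to
#'   swapping the two codes.
#' @param config an [fcm_config()]; `n_clusters = 3`, `fuzzifier = 2` is
#'   the standard configuration for this analysis.
#' @param consequents `"constant"` (default) or `"linear"`.
#' @param clustering_scale `"none"` (default; natural units) or `"minmax"`.
#' @return A list of class `sugeno_fis`.
#' @export
build_fis <- function(data, encoding = sex_encoding(),
                      config = fcm_config(),
                      consequents = c("constant", "linear"),
                      clustering_scale = c("none", "minmax")) {
  stopifnot(inherits(data, "paired_dataset"))
  consequents <- match.arg(consequents)
  clustering_scale <- match.arg(clustering_scale)
  n <- nrow(data)
  N <- config$n_clusters
  if (n < 2 * N) {
    stop("need at least 2 * n_clusters samples to generate rules",
         call. = FALSE)
  }
  input_names <- c("clia", "lcms", "sex", "age")
  M <- cbind(clia = data$clia, lcms = data$lcms,
             sex = encode_sex(data$sex, encoding), age = data$age,
             diff = data$diff)

  # model space: identity for "none", [0,1] per dimension for "minmax"
  sc_all <- minmax_fit(M)
  if (clustering_scale == "minmax") {
    Z <- minmax_apply(M, sc_all)
    scaling <- list(lo = sc_all$lo[1:4], span = sc_all$span[1:4])
  } else {
    Z <- M
    scaling <- list(lo = stats::setNames(rep(0, 4), input_names),
                    span = stats::setNames(rep(1, 4), input_names))
  }
  fcm <- fcm_fit(Z, config, scale = FALSE)

  Zin <- Z[, 1:4, drop = FALSE]
  u <- fcm$memberships
  um <- u^config$fuzzifier
  mf_centers <- fcm$centers[, 1:4, drop = FALSE]
  mf_sigmas <- matrix(0, N, 4)
  for (j in seq_len(N)) {
    w <- um[, j] / sum(um[, j])
    dev2 <- sweep(Zin, 2, mf_centers[j, ], "-")^2
    mf_sigmas[j, ] <- sqrt(colSums(w * dev2))
  }
  obs_span <- apply(Zin, 2, function(z) diff(range(z)))
  obs_span[obs_span == 0] <- 1
  mf_sigmas <- pmax(mf_sigmas, 0.05 * matrix(obs_span, N, 4, byrow = TRUE))
  colnames(mf_centers) <- colnames(mf_sigmas) <- input_names

  level_names <- if (N == 3) c("low", "medium", "high") else
    paste0("level", seq_len(N))
  labels <- apply(mf_centers, 2, function(cc) {
    level_names[rank(cc, ties.method = "first")]
  })
  labels <- matrix(labels, N, 4, dimnames = list(NULL, input_names))

  W <- firing_strengths(Zin, mf_centers, mf_sigmas)   # n x N, rows sum to 1
  y <- M[, "diff"]
  if (consequents == "linear") {
    blocks <- lapply(seq_len(N), function(j) W[, j] * cbind(Zin, const = 1))
    design <- do.call(cbind, blocks)                  # n x 5N
    qrd <- qr(design)
    if (qrd$rank < ncol(design)) {
      warning("singular consequent system; falling back to constant consequents",
              call. = FALSE)
      consequents <- "constant"
    } else {
      theta <- matrix(qr.coef(qrd, y), nrow = 5, ncol = N)
    }
  }
  if (consequents == "constant") {
    cc <- qr.coef(qr(W), y)
    cc[is.na(cc)] <- mean(y)   # aliased rule (duplicate firing column)
    theta <- rbind(matrix(0, 4, N), matrix(cc, 1, N))
  }
  rownames(theta) <- c(input_names, "const")

  structure(list(
    input_names = input_names,
    n_rules = N,
    mf_centers = mf_centers,      # model (clustering) space
    mf_sigmas = mf_sigmas,
    labels = labels,
    theta = theta,                # 5 x N consequent coefficients (model space)
    consequents = consequents,
    clustering_scale = clustering_scale,
    scaling = scaling,            # natural units -> model space transform
    input_ranges = list(lo = sc_all$lo[1:4], hi = sc_all$hi[1:4]),
    output_norm = c(min = min(y), max = max(y)),
    encoding = unclass(encoding),
    training_meta = list(n = n, seed = config$seed,
                         n_clusters = N, fuzzifier = config$fuzzifier,
                         fcm_objective = fcm$objective,
                         fcm_iterations = fcm$iterations)
  ), class = "sugeno_fis")
}

# normalized firing strengths, log-domain for underflow safety.
# Zin: n x 4 model-space inputs; returns n x N with rows summing to 1.
firing_strengths <- function(Zin, centers, sigmas) {
  n <- nrow(Zin); N <- nrow(centers)
  logw <- matrix(0, n, N)
  for (j in seq_len(N)) {
    dev2 <- sweep(Zin, 2, centers[j, ], "-")^2
    logw[, j] <- -rowSums(sweep(dev2, 2, 2 * sigmas[j, ]^2, "/"))
  }
  logw <- logw - apply(logw, 1, max)
  w <- exp(logw)
  w / rowSums(w)
}

# map a query matrix of natural-unit inputs into the FIS's model space
fis_scale_inputs <- function(fis, X) {
  sweep(sweep(as.matrix(X), 2, fis$scaling$lo, "-"), 2, fis$scaling$span, "/")
}

#' Predict the inter-method difference for one or more input points
#'
#' Sugeno inference: the firing strength of each rule is the product of its
#' Gaussian memberships at the query; the output is the
#' firing-strength-weighted convex combination of the rule consequents, in
#' ng/mL. Firing strengths are evaluated in the log domain and renormalized,
#' so far-from-data queries cannot divide by zero.
#'
#' @param fis a [build_fis()] model.
#' @param clia,lcms assay results, ng/mL.
#' @param sex `"male"`/`"female"` (or a numeric already matching the model's
#'   encoding).
#' @param age years.
#' @return Numeric vector of predicted differences (LC-MS/MS minus CLIA),
#'   ng/mL.
#' @export
fis_predict <- function(fis, clia, lcms, sex, age) {
  stopifnot(inherits(fis, "sugeno_fis"))
  sex_code <- if (is.numeric(sex)) sex else encode_sex(sex, fis$encoding)
  X <- cbind(clia = clia, lcms = lcms, sex = sex_code, age = age)
  if (!all(is.finite(X))) stop("inputs must be finite", call. = FALSE)
  Z <- fis_scale_inputs(fis, X)
  W <- firing_strengths(Z, fis$mf_centers, fis$mf_sigmas)
  rule_out <- cbind(Z, 1) %*% fis$theta      # n x N consequent outputs
  rowSums(W * rule_out)
}

#' Normalize a difference to the model's [0, 1] output scale
#'
#' `(value - min) / (max - min)` using the difference range observed at
#' training time. Values outside the range clamp to `[0, 1]` with a warning.
#'
#' @param value difference(s), ng/mL.
#' @param norm length-2 `(min, max)` vector, `max > min`; typically
#'   `fis$output_norm`.
#' @return Values in `[0, 1]`.
#' @export
normalize_output <- function(value, norm) {
  lo <- norm[[1]]; hi <- norm[[2]]
  if (!(hi > lo)) stop("degenerate normalization range (max <= min)",
                       call. = FALSE)
  z <- (value - lo) / (hi - lo)
  if (any(z < 0 | z > 1)) {
    warning("value(s) outside the training range; clamped to [0, 1]",
            call. = FALSE)
    z <- pmin(pmax(z, 0), 1)
  }
  z
}

#' Summarize rule importance over a dataset
#'
#' The "normalized weight" of each rule: its mean normalized firing
#' strength across the dataset. Weights are non-negative and sum to 1.
#' (No canonical definition exists for cluster-generated rule weights;
#' this one is recorded in reports so alternatives can be compared.)
#'
#' @param fis a [build_fis()] model.
#' @param data a non-empty [paired_dataset()].
#' @return A list of class `rule_weight_summary` with `weights` (length
#'   `n_rules`, sums to 1) and the per-rule labels.
#' @export
rule_weight_summary <- function(fis, data) {
  stopifnot(inherits(fis, "sugeno_fis"), inherits(data, "paired_dataset"),
            nrow(data) > 0)
  X <- cbind(data$clia, data$lcms, encode_sex(data$sex, fis$encoding),
             data$age)
  Z <- fis_scale_inputs(fis, X)
  W <- firing_strengths(Z, fis$mf_centers, fis$mf_sigmas)
  w <- colMeans(W)
  structure(list(weights = w / sum(w), labels = fis$labels,
                 n = nrow(data)),
            class = "rule_weight_summary")
}

#' Evaluate the rule surface over two inputs
#'
#' Normalized model output over a Cartesian grid spanning the observed
#' (training) range of two inputs, the others held fixed — the data behind
#' the usual 3-D rule-surface plot. Rows index `dim_a` ascending, columns
#' `dim_b` ascending.
#'
#' @param fis a [build_fis()] model.
#' @param dim_a,dim_b distinct input names among
#'   `c("clia", "lcms", "sex", "age")`.
#' @param fixed named list/vector of values for the remaining inputs (sex
#'   may be `"male"`/`"female"`).
#' @param grid points per axis, >= 2 (default 25).
#' @return A `grid x grid` matrix of normalized outputs in `[0, 1]`, with
#'   formatted axis values in `dimnames` and the full-precision axes in
#'   attributes `axis_a` and `axis_b`.
#' @export
rule_surface <- function(fis, dim_a, dim_b, fixed, grid = 25) {
  stopifnot(inherits(fis, "sugeno_fis"), grid >= 2)
  nms <- fis$input_names
  stopifnot(dim_a %in% nms, dim_b %in% nms, dim_a != dim_b)
  others <- setdiff(nms, c(dim_a, dim_b))
  fixed <- as.list(fixed)
  if (!all(others %in% names(fixed))) {
    stop("fixed must supply values for: ", paste(others, collapse = ", "),
         call. = FALSE)
  }
  if ("sex" %in% names(fixed) && !is.numeric(fixed$sex)) {
    fixed$sex <- encode_sex(fixed$sex, fis$encoding)
  }
  ia <- match(dim_a, nms); ib <- match(dim_b, nms)
  ax_a <- seq(fis$input_ranges$lo[ia], fis$input_ranges$hi[ia],
              length.out = grid)
  ax_b <- seq(fis$input_ranges$lo[ib], fis$input_ranges$hi[ib],
              length.out = grid)
  pts <- expand.grid(a = ax_a, b = ax_b)   # column-major: a varies fastest
  args <- list(clia = NULL, lcms = NULL, sex = NULL, age = NULL)
  args[[dim_a]] <- pts$a
  args[[dim_b]] <- pts$b
  for (nm in others) args[[nm]] <- rep(fixed[[nm]], nrow(pts))
  pred <- fis_predict(fis, args$clia, args$lcms, args$sex, args$age)
  z <- suppressWarnings(normalize_output(pred, fis$output_norm))
  out <- matrix(z, nrow = grid, ncol = grid,
                dimnames = list(format(ax_a, digits = 6),
                                format(ax_b, digits = 6)))
  attr(out, "axis_a") <- stats::setNames(ax_a, NULL)
  attr(out, "axis_b") <- stats::setNames(ax_b, NULL)
  out
}

#' Normalized output along age for one sex
#'
#' Evaluates the model along an age grid at fixed sex, with both assay
#' inputs pinned to a reference policy. The default policy is the
#' "consistency locus": both methods reading exactly the 20 ng/mL clinical
#' threshold, so the profile isolates the demographic contribution to the
#' predicted difference.
#'
#' @param fis a [build_fis()] model.
#' @param sex `"male"` or `"female"`.
#' @param ages ages in years (default 18..80).
#' @param clia,lcms reference assay inputs, ng/mL (default both 20).
#' @return A data frame with columns `age` and `output` (normalized to
#'   `[0, 1]`).
#' @export
age_profile <- function(fis, sex, ages = 18:80, clia = 20, lcms = 20) {
  stopifnot(inherits(fis, "sugeno_fis"), length(ages) > 0)
  pred <- fis_predict(fis, rep(clia, length(ages)), rep(lcms, length(ages)),
                      rep(sex, length(ages)), ages)
  data.frame(age = ages,
             output = suppressWarnings(normalize_output(pred,
                                                        fis$output_norm)))
}

#' @export
print.sugeno_fis <- function(x, ...) {
  cat(sprintf("Sugeno FIS: %d rules, %s consequents, trained on n = %d (seed %d)\n",
              x$n_rules, x$consequents, x$training_meta$n,
              x$training_meta$seed))
  for (j in seq_len(x$n_rules)) {
    cat(sprintf("  R%d: %s\n", j,
                paste(sprintf("%s is %s", x$input_names, x$labels[j, ]),
                      collapse = " & ")))
  }
  cat(sprintf("  output range [%.3f, %.3f] ng/mL\n",
              x$output_norm[1], x$output_norm[2]))
  invisible(x)
}

#' @export
print.rule_weight_summary <- function(x, ...) {
  cat("Normalized rule weights (mean firing strength over n =",
      x$n, "samples):\n")
  for (j in seq_along(x$weights)) {
    cat(sprintf("  R%d: %.3f\n", j, x$weights[j]))
  }
  invisible(x)
}
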