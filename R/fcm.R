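#' Fuzzy C-means configuration
#'
#' @param n_clusters number of clusters N (default 3, the standard choice
#'   for biomedical rule extraction here).
#' @param fuzzifier overlap exponent m > 1 (default 2); m near 1 approaches
#'   hard k-means assignment, larger m gives softer memberships.
#' @param tol stop when the objective changes by less than this (default 1e-6).
#' @param max_iter iteration cap per restart (default 300).
#' @param n_restarts independent seeded restarts, keeping the best objective
#'   (default 5); guards against local minima of the non-convex objective.
#' @param seed integer seed driving all restarts.
#' @return A list of class `fcm_config`.
#' @export
fcm_config <- function(n_clusters = 3, fuzzifier = 2, tol = 1e-6,
                       max_iter = 300, n_restarts = 5, seed = 1L) {
  stopifnot(n_clusters >= 1, n_clusters == as.integer(n_clusters),
            fuzzifier > 1, tol > 0, max_iter >= 1, n_restarts >= 1,
            is.finite(seed))
  structure(list(n_clusters = as.integer(n_clusters), fuzzifier = fuzzifier,
                 tol = tol, max_iter = as.integer(max_iter),
                 n_restarts = as.integer(n_restarts),
                 seed = as.integer(seed)),
            class = "fcm_config")
}

#' Fuzzy C-means objective
#'
#' The weighted within-cluster scatter
#' \deqn{J_m = \sum_{i=1}^{D} \sum_{j=1}^{N} \mu_{ij}^m \|x_i - c_j\|^2,}
#' with D data points, N cluster centers \eqn{c_j}, memberships
#' \eqn{\mu_{ij}} and fuzzifier m. Pure function: used both inside
#' [fcm_fit()] and as an external audit of its trace.
#'
#' @param X D x d data matrix.
#' @param centers N x d center matrix.
#' @param memberships D x N membership matrix.
#' @param m fuzzifier, > 1.
#' @return The scalar objective value.
#' @export
fcm_objective <- function(X, centers, memberships, m) {
  X <- as.matrix(X); centers <- as.matrix(centers)
  memberships <- as.matrix(memberships)
  if (ncol(X) != ncol(centers) || nrow(memberships) != nrow(X) ||
      ncol(memberships) != nrow(centers)) {
    stop("shape mismatch between X, centers and memberships", call. = FALSE)
  }
  stopifnot(m > 1)
  sum(memberships^m * sqdist(X, centers))
}

# D x N matrix of squared Euclidean distances
sqdist <- function(X, C) {
  d2 <- outer(rowSums(X^2), rep(1, nrow(C))) +
    outer(rep(1, nrow(X)), rowSums(C^2)) - 2 * X %*% t(C)
  pmax(d2, 0)   # clip tiny negatives from cancellation
}

# membership update for fixed centers; handles coincident point/center by
# splitting full membership across the zero-distance centers. Distances are
# normalized by each row's minimum before exponentiation so small m-1 (large
# exponents) cannot overflow.
fcm_memberships <- function(d2, m) {
  expo <- 1 / (m - 1)
  rmin <- apply(d2, 1, min)
  zero <- d2 <= .Machine$double.eps
  hit <- rowSums(zero) > 0
  safe_min <- ifelse(rmin > 0, rmin, 1)
  ratio <- d2 / safe_min            # >= 1 on each row's minimum
  inv <- ratio^(-expo)              # in (0, 1]; no overflow
  u <- inv / rowSums(inv)
  if (any(hit)) {
    u[hit, ] <- 0
    u[hit, ] <- zero[hit, , drop = FALSE] /
      rowSums(zero[hit, , drop = FALSE])
  }
  u
}

#' Fit fuzzy C-means
#'
#' Alternating optimization of the [fcm_objective()]: membership update
#' \eqn{\mu_{ij} = 1 / \sum_k (\|x_i - c_j\| / \|x_i - c_k\|)^{2/(m-1)}},
#' center update \eqn{c_j = \sum_i \mu_{ij}^m x_i / \sum_i \mu_{ij}^m},
#' until the objective changes by less than `tol` or `max_iter` is reached.
#' Each restart initializes from a random row-normalized membership matrix;
#' the best restart (lowest final objective) is returned.
#'
#' When `scale = TRUE` (default) each column is min-max scaled to `[0, 1]`
#' before clustering — age in years and concentrations in ng/mL are
#' incommensurate, and unscaled Euclidean distance would be dominated by the
#' widest axis. The transform is stored in the result and centers are also
#' reported back in original units.
#'
#' @param X D x d numeric matrix (rows = data points), all entries finite.
#' @param config an [fcm_config()].
#' @param scale min-max scale columns before clustering (default TRUE).
#' @return A list of class `fcm_result`: `centers` (original units),
#'   `centers_scaled`, `memberships` (D x N, rows sum to 1),
#'   `objective_trace` (non-increasing J_m per iteration, in the clustering
#'   space), `objective`, `converged`, `iterations`, `scaling`, `config`.
#' @export
fcm_fit <- function(X, config = fcm_config(), scale = TRUE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) stop("X contains non-finite values", call. = FALSE)
  D <- nrow(X); d <- ncol(X); N <- config$n_clusters
  if (D < N) stop("need at least as many points as clusters", call. = FALSE)
  scaling <- minmax_fit(X)
  Z <- if (scale) minmax_apply(X, scaling) else X
  m <- config$fuzzifier

  best <- NULL
  seeds <- config$seed + seq_len(config$n_restarts) - 1L
  for (s in seeds) {
    run <- withr::with_seed(s, fcm_single_run(Z, N, m, config$tol,
                                              config$max_iter))
    if (is.null(best) || run$objective < best$objective) best <- run
  }
  centers <- if (scale) minmax_invert(best$centers, scaling) else best$centers
  structure(list(
    centers = centers,
    centers_scaled = best$centers,
    memberships = best$memberships,
    objective_trace = best$trace,
    objective = best$objective,
    converged = best$converged,
    iterations = best$iterations,
    scaled = scale,
    scaling = scaling,
    config = config
  ), class = "fcm_result")
}

fcm_single_run <- function(Z, N, m, tol, max_iter) {
  D <- nrow(Z)
  u <- matrix(stats::runif(D * N), D, N)
  u <- u / rowSums(u)
  trace <- numeric(0)
  j_prev <- Inf
  converged <- FALSE
  it <- 0L
  centers <- NULL
  repeat {
    it <- it + 1L
    um <- u^m
    centers <- t(um) %*% Z / colSums(um)
    d2 <- sqdist(Z, centers)
    u <- fcm_memberships(d2, m)
    j <- sum(u^m * d2)
    trace <- c(trace, j)
    if (is.finite(j_prev) && abs(j_prev - j) < tol) {
      converged <- TRUE
      break
    }
    if (it >= max_iter) break
    j_prev <- j
  }
  list(centers = centers, memberships = u, trace = trace,
       objective = trace[length(trace)], converged = converged,
       iterations = it)
}

# -- min-max scaling helpers (shared with the FIS builder) ------------------

minmax_fit <- function(X) {
  lo <- apply(X, 2, min)
  hi <- apply(X, 2, max)
  span <- hi - lo
  span[span == 0] <- 1   # constant column maps to 0; inverse restores lo
  list(lo = lo, hi = hi, span = span)
}

minmax_apply <- function(X, sc) {
  sweep(sweep(as.matrix(X), 2, sc$lo, "-"), 2, sc$span, "/")
}

minmax_invert <- function(Z, sc) {
  sweep(sweep(as.matrix(Z), 2, sc$span, "*"), 2, sc$lo, "+")
}

#' @export
print.fcm_result <- function(x, ...) {
  cat(sprintf("Fuzzy C-means: %d clusters, m = %g, J_m = %.6g (%s in %d iterations)\n",
              nrow(x$centers), x$config$fuzzifier, x$objective,
              if (x$converged) "converged" else "iteration cap",
              x$iterations))
  print(round(x$centers, 4))
  invisible(x)
}
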