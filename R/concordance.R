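# Hierarchical concordance of principal axes: is the first principal axis of
# individual variation aligned with the first principal axis of variation
# among population means? The angle between the two eigenvectors is compared
# to a null built by permuting population-centered residuals across
# populations.

.first_eigenvector <- function(S, warn_label) {
  e <- eigen(S, symmetric = TRUE)
  ev <- e$values
  if (length(ev) > 1) {
    gap <- (ev[1] - ev[2]) / max(ev[1], .Machine$double.eps)
    if (is.finite(gap) && gap < 1e-10)
      warning("tied leading eigenvalues in ", warn_label,
              "; leading direction is ill-defined")
  }
  e$vectors[, 1]
}

#' Angle between individual-level and population-level first principal axes
#'
#' Computes the first eigenvector of the covariance of individual
#' observations and of the covariance of population mean vectors, and returns
#' the angle `acos(|v1 . v2|)` in degrees. The absolute dot product makes the
#' result invariant to eigenvector sign, so angles lie in `[0, 90]`.
#'
#' @param x numeric matrix of individual observations (rows) by traits, or a
#'   [trait_matrix()] / aligned [landmark_set()].
#' @param population population labels (taken from the object if present).
#' @return angle in degrees.
#' @export
pc1_angle <- function(x, population = NULL) {
  b <- .block_matrix(x, population)
  if (length(unique(b$population)) < 2)
    stop("at least 2 populations are required")
  v1 <- .first_eigenvector(stats::cov(b$values), "individual-level covariance")
  pm <- population_means(b$values, b$population)
  v2 <- .first_eigenvector(stats::cov(pm), "population-mean covariance")
  acos(min(1, abs(sum(v1 * v2)))) * 180 / pi
}

#' Permutation test for concordance of principal axes across levels
#'
#' Tests whether the angle between the individual-level and population-level
#' first principal axes is larger than expected at random. The null treats
#' among-population divergence as sampling noise of the pooled within-
#' population variation: population-centered residuals are permuted as units
#' across all individuals (hence across populations), pseudo-population
#' means are the group means of the permuted residuals, and the permuted
#' angle is recomputed between the first principal axes of the pooled
#' residuals and of those pseudo-means. The observed angle is compared
#' one-sidedly to the permuted angles with the add-one rule
#' `p = (1 + #\{theta* >= theta_obs\}) / (1 + n_perm)`.
#'
#' @inheritParams pc1_angle
#' @param n_perm number of permutations (default 999; fewer than 99 gives a
#'   warning about coarse p resolution).
#' @param seed optional integer seed for the permutation stream.
#' @return an object of class `angle_perm` with `theta_obs` (degrees),
#'   `p_value`, `n_perm`, and the permuted angle sample `theta_null`.
#' @export
angle_permutation_test <- function(x, population = NULL, n_perm = 999,
                                   seed = NULL) {
  b <- .block_matrix(x, population)
  if (n_perm < 1) stop("n_perm must be at least 1")
  if (n_perm < 99) warning("n_perm < 99 gives coarse p-value resolution")
  theta_obs <- pc1_angle(b$values, b$population)
  pm <- population_means(b$values, b$population)
  resid <- b$values - pm[b$population, , drop = FALSE]
  n <- nrow(resid)
  f <- factor(b$population, unique(b$population))
  cnt <- as.vector(table(f))
  v1w <- suppressWarnings(
    .first_eigenvector(stats::cov(resid), "pooled residual covariance"))
  run <- function() {
    theta_null <- numeric(n_perm)
    for (k in seq_len(n_perm)) {
      rs <- resid[sample.int(n), , drop = FALSE]
      pm_star <- rowsum(rs, f) / cnt
      v2s <- suppressWarnings(
        .first_eigenvector(stats::cov(pm_star), "permuted mean covariance"))
      theta_null[k] <- acos(min(1, abs(sum(v1w * v2s)))) * 180 / pi
    }
    theta_null
  }
  theta_null <- if (is.null(seed)) run() else .with_seed(seed, run())
  p <- (1 + sum(theta_null >= theta_obs)) / (1 + n_perm)
  structure(list(theta_obs = theta_obs, p_value = p, n_perm = n_perm,
                 theta_null = theta_null),
            class = "angle_perm")
}

#' @export
print.angle_perm <- function(x, ...) {
  cat(sprintf("PC1 concordance test: theta = %.1f deg, p = %.3f (%d permutations)\n",
              x$theta_obs, x$p_value, x$n_perm))
  invisible(x)
}
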