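# Trait preprocessing and morphospace summaries: sex-mean-centering,
# size/shape decomposition by PCA, generalized Procrustes superimposition,
# within-population disparity, and among-population divergence.

#' Center traits to the sex-specific mean
#'
#' Removes sexual dimorphism before pooled analysis: every trait is centered
#' on the mean of the individual's sex class, so each sex has mean zero in
#' every trait afterwards while contrasts among individuals of the same sex
#' are untouched.
#'
#' @param traits a [trait_matrix()] with sex labels.
#' @return a [trait_matrix()] of sex-mean-centered values.
#' @export
sex_center <- function(traits) {
  stopifnot(inherits(traits, "trait_matrix"))
  sx <- traits$sex
  if (anyNA(sx)) stop("sex labels are required for sex-mean-centering")
  tab <- table(sx)
  small <- names(tab)[tab < 2]
  if (length(small))
    stop("sex class with fewer than 2 individuals: ", paste(small, collapse = ", "))
  v <- traits$values
  for (s in names(tab)) {
    idx <- sx == s
    v[idx, ] <- sweep(v[idx, , drop = FALSE], 2,
                      colMeans(v[idx, , drop = FALSE]))
  }
  trait_matrix(v, traits$population, traits$sex, block = traits$block)
}

#' Decompose traits into body size and body shape
#'
#' Principal components of the covariance matrix of (sex-mean-centered)
#' traits. PC1 is oriented so the sum of its loadings is positive — larger
#' animals score higher — and treated as body size; the remaining axes form a
#' multivariate size-corrected body shape. Covariance-scale PCA is used
#' because traits within a block share units and PC1 is interpreted through
#' equal-sign loadings.
#'
#' @param traits a [trait_matrix()] (typically sex-centered biometry).
#' @return an object of class `size_shape` with elements `size` (PC1 scores),
#'   `shape` (scores on the remaining axes), `eigenvalues`, `eigenvectors`,
#'   `population`, `sex`.
#' @export
size_shape_decompose <- function(traits) {
  stopifnot(inherits(traits, "trait_matrix"))
  v <- traits$values
  pc <- stats::prcomp(v, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  rank <- sum(ev > max(ev) * 1e-12)
  if (rank < ncol(v)) {
    warning("rank-deficient trait matrix; truncating to ", rank, " axes")
  }
  rot <- pc$rotation[, seq_len(rank), drop = FALSE]
  scores <- pc$x[, seq_len(rank), drop = FALSE]
  if (sum(rot[, 1]) < 0) { rot[, 1] <- -rot[, 1]; scores[, 1] <- -scores[, 1] }
  structure(list(size = scores[, 1],
                 shape = scores[, -1, drop = FALSE],
                 eigenvalues = ev[seq_len(rank)],
                 eigenvectors = rot,
                 population = traits$population, sex = traits$sex),
            class = "size_shape")
}

#' @export
print.size_shape <- function(x, ...) {
  share <- 100 * x$eigenvalues[1] / sum(x$eigenvalues)
  cat(sprintf("Size/shape decomposition: PC1 (size) explains %.1f%% of variance; %d shape axes\n",
              share, ncol(x$shape)))
  invisible(x)
}

.centroid_size <- function(m) sqrt(sum(sweep(m, 2, colMeans(m))^2))

# proper orthogonal rotation of config a onto b (both centered)
.opa_rotate <- function(a, b) {
  s <- svd(crossprod(b, a))
  R <- s$v %*% t(s$u)
  if (det(R) < 0) {            # restrict to rotations (no reflection)
    u <- s$u; u[, ncol(u)] <- -u[, ncol(u)]
    R <- s$v %*% t(u)
  }
  a %*% R
}

#' Generalized Procrustes superimposition
#'
#' Translates each configuration to zero centroid, scales to unit centroid
#' size, and iteratively rotates all configurations to the current mean shape
#' until the mean changes by less than `tol` (root summed squares).
#' Reflections are not allowed.
#'
#' @param landmarks a raw [landmark_set()].
#' @param tol convergence tolerance on the mean shape.
#' @param max_iter iteration cap; exceeding it is an error.
#' @return the aligned [landmark_set()] with original centroid sizes stored.
#' @export
procrustes_align <- function(landmarks, tol = 1e-8, max_iter = 100) {
  stopifnot(inherits(landmarks, "landmark_set"))
  co <- landmarks$coords
  n <- dim(co)[1]
  cs <- numeric(n)
  for (i in seq_len(n)) {
    m <- co[i, , ]
    m <- sweep(m, 2, colMeans(m))
    cs[i] <- sqrt(sum(m^2))
    if (cs[i] <= 0) stop("degenerate (all-coincident) configuration at index ", i)
    co[i, , ] <- m / cs[i]
  }
  mshape <- co[1, , ]
  mshape <- mshape / sqrt(sum(mshape^2))
  for (it in seq_len(max_iter)) {
    for (i in seq_len(n)) co[i, , ] <- .opa_rotate(co[i, , ], mshape)
    newm <- apply(co, c(2, 3), mean)
    newm <- sweep(newm, 2, colMeans(newm))
    newm <- newm / sqrt(sum(newm^2))
    delta <- sqrt(sum((newm - mshape)^2))
    mshape <- newm
    if (delta < tol) {
      out <- landmark_set(co, landmarks$population, landmarks$sex,
                          aligned = TRUE, centroid_size = cs)
      attr(out, "mean_shape") <- mshape
      attr(out, "iterations") <- it
      return(out)
    }
  }
  stop("Procrustes superimposition did not converge in ", max_iter, " iterations")
}

# flatten an aligned landmark set to individuals x 2k (X1,Y1,...,Xk,Yk)
.flatten_landmarks <- function(landmarks) {
  k <- dim(landmarks$coords)[2]
  m <- matrix(NA_real_, dim(landmarks$coords)[1], 2 * k)
  m[, seq(1, 2 * k, 2)] <- landmarks$coords[, , 1]
  m[, seq(2, 2 * k, 2)] <- landmarks$coords[, , 2]
  colnames(m) <- as.vector(rbind(paste0("X", seq_len(k)), paste0("Y", seq_len(k))))
  m
}

# extract a plain numeric matrix + population labels from supported blocks
.block_matrix <- function(block, population = NULL) {
  if (inherits(block, "trait_matrix"))
    return(list(values = block$values, population = block$population))
  if (inherits(block, "landmark_set")) {
    if (!block$aligned) stop("landmarks must be Procrustes-aligned first")
    return(list(values = .flatten_landmarks(block), population = block$population))
  }
  if (is.numeric(block) && is.null(dim(block)))
    block <- matrix(block, ncol = 1, dimnames = list(NULL, "value"))
  if (is.null(population)) stop("population labels required for matrix input")
  list(values = as.matrix(block), population = as.character(population))
}

#' Within-population diversity: mean distance to the population centroid
#'
#' For every population, the Euclidean distance of each individual's trait
#' vector (or flattened aligned coordinates, or size scalar) to the
#' population mean vector, averaged over individuals. Populations with fewer
#' than `min_n` individuals are excluded with a warning.
#'
#' @param block a [trait_matrix()], an aligned [landmark_set()], a numeric
#'   matrix, or a numeric vector (univariate, e.g. body size scores).
#' @param population population labels (taken from the object if present).
#' @param min_n minimum individuals per population (default 3; distance to
#'   the centroid of n <= 2 is degenerate).
#' @return named numeric vector of per-population diversity values.
#' @export
mean_distance_to_centroid <- function(block, population = NULL, min_n = 3) {
  b <- .block_matrix(block, population)
  pops <- unique(b$population)
  keep <- pops[table(factor(b$population, pops))[pops] >= min_n]
  dropped <- setdiff(pops, keep)
  if (length(dropped))
    warning("populations below minimum n excluded: ", paste(dropped, collapse = ", "))
  out <- vapply(keep, function(p) {
    m <- b$values[b$population == p, , drop = FALSE]
    ctr <- colMeans(m)
    mean(sqrt(rowSums(sweep(m, 2, ctr)^2)))
  }, numeric(1))
  names(out) <- keep
  out
}

#' Among-population divergence: distances between population means
#'
#' Euclidean distance between population mean vectors of the block
#' (absolute mean difference in the univariate case, e.g. body size).
#'
#' @inheritParams mean_distance_to_centroid
#' @return a phenotypic [pop_dist()] matrix.
#' @export
pairwise_divergence <- function(block, population = NULL, min_n = 3) {
  b <- .block_matrix(block, population)
  pops <- unique(b$population)
  keep <- pops[table(factor(b$population, pops))[pops] >= min_n]
  dropped <- setdiff(pops, keep)
  if (length(dropped))
    warning("populations below minimum n excluded: ", paste(dropped, collapse = ", "))
  f <- factor(b$population, keep)
  ok <- !is.na(f)
  means <- rowsum(b$values[ok, , drop = FALSE], f[ok]) /
    as.vector(table(f[ok]))
  d <- as.matrix(stats::dist(means))
  pop_dist(d, labels = keep, kind = "phenotypic")
}

#' Population mean vectors of a trait block
#'
#' @inheritParams mean_distance_to_centroid
#' @return matrix of population means (populations x traits).
#' @export
population_means <- function(block, population = NULL) {
  b <- .block_matrix(block, population)
  pops <- unique(b$population)
  f <- factor(b$population, pops)
  m <- rowsum(b$values, f) / as.vector(table(f))
  rownames(m) <- pops
  colnames(m) <- colnames(b$values)
  m
}
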