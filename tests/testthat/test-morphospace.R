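test_that("sex-mean-centering removes dimorphism and is idempotent", {
  v <- matrix(c(1, 2, 3), ncol = 1, dimnames = list(NULL, "t"))
  tm <- trait_matrix(v, rep("A", 3), rep("f", 3))
  expect_equal(as.vector(sex_center(tm)$values), c(-1, 0, 1))

  # equal within-sex deviations: centered values ignore the sex offset
  dev <- c(-1, 0, 1)
  v2 <- matrix(c(dev + 10, dev + 4), ncol = 1, dimnames = list(NULL, "t"))
  tm2 <- trait_matrix(v2, rep("A", 6), rep(c("m", "f"), each = 3))
  expect_equal(as.vector(sex_center(tm2)$values), rep(dev, 2))

  centered <- sex_center(tiny_traits())
  expect_equal(sex_center(centered)$values, centered$values)
  for (s in c("m", "f"))
    expect_equal(colMeans(centered$values[centered$sex == s, ]),
                 c(t1 = 0, t2 = 0))

  bad <- trait_matrix(v2, rep("A", 6), c("m", rep("f", 5)))
  expect_error(sex_center(bad), "m")
})

test_that("size/shape decomposition has the expected spectral structure", {
  # two perfectly correlated traits of equal variance
  set.seed(3)
  z <- rnorm(30)
  v <- cbind(t1 = z, t2 = z)
  tm <- trait_matrix(v, rep(c("A", "B"), 15), rep("f", 30))
  ss <- suppressWarnings(size_shape_decompose(tm))
  expect_equal(abs(ss$eigenvectors[, 1]), c(t1 = 1, t2 = 1) / sqrt(2))
  expect_length(ss$eigenvalues, 1) # zero axis truncated with warning
  expect_warning(size_shape_decompose(tm), "rank")

  # variance conservation and PC1 orientation
  tm2 <- tiny_traits()
  ss2 <- size_shape_decompose(tm2)
  expect_equal(sum(ss2$eigenvalues), sum(diag(cov(tm2$values))))
  expect_gt(sum(ss2$eigenvectors[, 1]), 0)
  expect_equal(crossprod(ss2$eigenvectors), diag(2), ignore_attr = TRUE)
})

test_that("PC1 variance share matches the generating covariance eigenstructure", {
  cfg <- simulation_config(n_pops = 4, n_per_pop = 120, env_effect = 0,
                           seed = 77)
  st <- simulate_study(cfg)
  biom <- trait_matrix(st$traits$values[, biometry_traits()],
                       st$traits$population, st$traits$sex)
  ss <- size_shape_decompose(sex_center(biom))
  # oracle: eigen-decomposition of the implied covariance lambda s2 lambda' + D
  base <- c(55, 28, 14, 8.2, 5.8, 18, 28.5)
  lam <- base / 55
  sigma <- 16 * tcrossprod(lam) + diag((0.035 * base)^2)
  share_oracle <- eigen(sigma)$values[1] / sum(diag(sigma))
  share_obs <- ss$eigenvalues[1] / sum(ss$eigenvalues)
  expect_lt(abs(share_obs - share_oracle), 0.05)
})

test_that("Procrustes superimposition removes nuisance transformations", {
  set.seed(9)
  base <- matrix(rnorm(24 * 2), 24, 2)
  n <- 8
  co <- array(NA_real_, c(n, 24, 2))
  for (i in seq_len(n)) {
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    co[i, , ] <- sweep(base %*% R * runif(1, 0.5, 3), 2, rnorm(2, 0, 10), "+")
  }
  al <- procrustes_align(landmark_set(co, rep("A", n)))
  flat <- morphodiv:::.flatten_landmarks(al)
  expect_lt(max(dist(flat)), 1e-6)
  # normalization of every aligned configuration and of the mean shape
  for (i in seq_len(n)) {
    expect_equal(colMeans(al$coords[i, , ]), c(0, 0), tolerance = 1e-8)
    expect_equal(sum(al$coords[i, , ]^2), 1, tolerance = 1e-8)
  }
  m <- attr(al, "mean_shape")
  expect_equal(colMeans(m), c(0, 0), tolerance = 1e-8)
  expect_equal(sum(m^2), 1, tolerance = 1e-8)
})

test_that("two-configuration alignment matches the closed-form OPA solution", {
  t1 <- matrix(c(0, 0, 4, 0, 1, 3), 3, 2, byrow = TRUE)
  t2 <- matrix(c(0, 0.2, 3.5, -0.1, 0.8, 2.6), 3, 2, byrow = TRUE)
  center_unit <- function(m) {
    m <- sweep(m, 2, colMeans(m)); m / sqrt(sum(m^2))
  }
  x1 <- center_unit(t1); x2 <- center_unit(t2)
  # closed form: optimal rotation via SVD of x2' x1 (proper rotation)
  s <- svd(crossprod(x2, x1))
  sig <- diag(c(1, sign(det(s$v %*% t(s$u)))))
  d_oracle <- sqrt(max(0, 2 - 2 * sum(diag(sig) * s$d)))

  co <- array(NA_real_, c(2, 3, 2)); co[1, , ] <- t1; co[2, , ] <- t2
  al <- procrustes_align(landmark_set(co, rep("A", 2)), tol = 1e-12)
  d_gpa <- sqrt(sum((al$coords[1, , ] - al$coords[2, , ])^2))
  expect_equal(d_gpa, d_oracle, tolerance = 1e-6)
})

test_that("mean distance to centroid matches hand and brute-force oracles", {
  expect_equal(unname(mean_distance_to_centroid(
    matrix(c(0, 4, 1), ncol = 1), rep("A", 3))["A"]),
    mean(abs(c(0, 4, 1) - 5 / 3)))
  v <- matrix(c(0, 4, 0, 0), 2, 2)
  expect_equal(unname(suppressWarnings(
    mean_distance_to_centroid(v, c("A", "A"), min_n = 2))["A"]), 2)

  set.seed(17)
  x <- matrix(rnorm(60), 20, 3)
  pops <- rep(c("A", "B"), 10)
  got <- mean_distance_to_centroid(x, pops)
  # naive double loop
  for (p in c("A", "B")) {
    m <- x[pops == p, ]
    ctr <- colMeans(m)
    acc <- 0
    for (i in seq_len(nrow(m))) acc <- acc + sqrt(sum((m[i, ] - ctr)^2))
    expect_equal(unname(got[p]), acc / nrow(m))
  }
  # identical individuals give zero, small populations are excluded
  expect_equal(unname(mean_distance_to_centroid(
    matrix(1, 4, 2), rep("A", 4))["A"]), 0)
  expect_warning(mean_distance_to_centroid(x, c(rep("A", 18), "B", "B")),
                 "excluded")
})

test_that("pairwise divergence is a Euclidean distance among population means", {
  v <- matrix(c(rep(3, 3), rep(7, 3)), ncol = 1)
  d <- pairwise_divergence(v, rep(c("A", "B"), each = 3))
  expect_equal(d["A", "B"], 4)
  expect_equal(diag(d), c(A = 0, B = 0))

  # identical population means: all-zero matrix
  v2 <- matrix(rep(c(1, 2, 3), 2), ncol = 1)
  d2 <- pairwise_divergence(v2, rep(c("A", "B"), each = 3))
  expect_equal(max(d2), 0)

  # symmetry, zero diagonal, triangle inequality across random studies
  set.seed(23)
  for (rep in 1:100) {
    x <- matrix(rnorm(45), 15, 3)
    pops <- rep(c("A", "B", "C"), 5)
    d3 <- pairwise_divergence(x, pops)
    expect_equal(unclass(d3), t(unclass(d3)), ignore_attr = TRUE)
    expect_true(all(diag(d3) == 0))
    expect_lte(d3["A", "C"], d3["A", "B"] + d3["B", "C"] + 1e-12)
  }
})
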