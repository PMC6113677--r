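make_spt <- function(seed = 3, beta = c(0.3, 0.5, 0.4), b0 = 0.2,
                     noise = 0, extra_null = FALSE) {
  set.seed(seed)
  n <- 9
  xy <- matrix(runif(2 * n, 0, 100), ncol = 2)
  geo <- as.matrix(dist(xy))
  rownames(geo) <- colnames(geo) <- paste0("P", 1:n)
  ut <- upper.tri(geo)
  k <- quantile(geo[ut], c(0, .5, 1), names = FALSE)
  eta <- b0 + as.vector(ispline_basis(geo[ut], k) %*% beta)
  resp <- matrix(0, n, n)
  resp[ut] <- 1 - exp(-eta) + rnorm(sum(ut), 0, noise)
  resp[ut] <- pmin(pmax(resp[ut], 0), 0.999)
  resp <- resp + t(resp)
  preds <- list(geographic = pop_dist(geo, rownames(geo), "geographic"))
  if (extra_null) {
    preds$nullmat <- pop_dist(as.matrix(dist(matrix(runif(2 * n), ncol = 2))),
                              rownames(geo), "environmental")
    preds$nullscalar <- rnorm(n)
  }
  site_pair_table(pop_dist(resp, rownames(geo), "phenotypic"), preds)
}

test_that("the I-spline basis is monotone with pinned boundaries", {
  k <- c(0, 2, 10)
  expect_equal(as.vector(ispline_basis(0, k)), c(0, 0, 0))
  expect_equal(as.vector(ispline_basis(10, k)), c(1, 1, 1))
  grid <- seq(-1, 11, length.out = 400)
  B <- ispline_basis(grid, k)
  expect_true(all(diff(B[, 1]) >= -1e-12))
  expect_true(all(diff(B[, 2]) >= -1e-12))
  expect_true(all(diff(B[, 3]) >= -1e-12))
  expect_true(all(B >= 0 & B <= 1))
  expect_warning(ispline_basis(1:5, c(0, 0, 1)), "duplicate")
  expect_error(ispline_basis(1:5, c(3)), "constant")
})

test_that("a noiseless monotone response is recovered almost exactly", {
  spt <- make_spt()
  m <- fit_gdm(spt)
  expect_gt(m$deviance_explained, 99)
  expect_true(all(unlist(m$coefficients) >= 0))
  # importance equals summed coefficients equals max partial response height
  pr <- gdm_partial_response(m, "geographic")
  expect_equal(unname(m$importance["geographic"]),
               sum(m$coefficients$geographic))
  expect_equal(max(pr$f), unname(m$importance["geographic"]), tolerance = 1e-10)
  expect_true(all(diff(pr$f) >= -1e-10))
})

test_that("shuffled predictors explain essentially nothing", {
  spt <- make_spt(seed = 6)
  set.seed(31)
  perm <- sample(9)
  sptp <- morphodiv:::.permute_spt(spt, perm)
  m <- fit_gdm(sptp)
  expect_lt(m$deviance_explained, 30)
  m0 <- fit_gdm(make_spt(seed = 6, beta = c(0, 0, 0), b0 = 0.4, noise = 0.05))
  expect_lt(m0$deviance_explained, 40)
  expect_lt(max(gdm_partial_response(m0, "geographic")$f), 0.5)
})

test_that("dropping a retained predictor cannot increase deviance explained", {
  spt <- make_spt(seed = 9, noise = 0.05, extra_null = TRUE)
  full <- fit_gdm(spt)
  for (drop in names(spt$predictors)) {
    sub <- spt
    sub$predictors <- spt$predictors[setdiff(names(spt$predictors), drop)]
    m <- fit_gdm(sub)
    expect_lte(m$deviance_explained, full$deviance_explained + 1e-6)
  }
})

test_that("rescaling the raw response distances leaves the fit invariant", {
  set.seed(4)
  n <- 9
  d <- as.matrix(dist(matrix(runif(2 * n, 0, 50), ncol = 2)))
  resp <- matrix(0, n, n); ut <- upper.tri(resp)
  resp[ut] <- d[ut] * 0.7 + runif(sum(ut), 0, 2); resp <- resp + t(resp)
  rownames(resp) <- colnames(resp) <- rownames(d) <- colnames(d) <- paste0("P", 1:n)
  p <- list(geographic = pop_dist(d, rownames(d), "geographic"))
  m1 <- fit_gdm(site_pair_table(pop_dist(resp, rownames(d), "phenotypic"), p))
  m2 <- fit_gdm(site_pair_table(pop_dist(resp / 7, rownames(d), "phenotypic"), p))
  expect_equal(m1$deviance_explained, m2$deviance_explained, tolerance = 1e-6)
  expect_equal(m1$importance, m2$importance, tolerance = 1e-5)
})

test_that("permutation significance flags signal and spares irrelevant predictors", {
  spt <- make_spt(seed = 12, noise = 0.02, extra_null = TRUE)
  m <- fit_gdm(spt)
  sig <- gdm_permutation_significance(spt, m, n_perm = 99, seed = 7)
  expect_equal(sig$model_p, 1 / 100)       # deterministic strong signal floor
  expect_lt(sig$p_values["geographic"], 0.05)
  expect_gt(sig$p_values["nullmat"], 0.1)
  expect_warning(gdm_permutation_significance(spt, m, n_perm = 19, seed = 1),
                 "coarse")
})

test_that("backward selection returns a subset and an honest empty model", {
  spt <- make_spt(seed = 15, noise = 0.02, extra_null = TRUE)
  final <- gdm_backward_select(spt, alpha = 0.05, n_perm = 99, seed = 3)
  expect_true(all(names(final$importance) %in% names(spt$predictors)))
  expect_true("geographic" %in% names(final$importance))
  expect_true(all(final$p_values < 0.05))

  # all-null predictors: empty final model reported as 0.00 / 1.000
  spt0 <- make_spt(seed = 16, beta = c(0, 0, 0), b0 = 0.4, noise = 0.05)
  final0 <- gdm_backward_select(spt0, alpha = 0.05, n_perm = 99, seed = 3)
  expect_length(final0$importance, 0)
  expect_equal(final0$deviance_explained, 0)
  expect_equal(final0$model_p, 1)
})
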