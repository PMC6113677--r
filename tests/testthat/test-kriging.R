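test_that("variogram fitting recovers structure and degenerates gracefully", {
  set.seed(21)
  xy <- matrix(runif(100, 0, 100), ncol = 2)
  y <- sim_exp_field(xy, 20)
  v <- fit_variogram(y, xy)
  expect_false(v$flat)
  expect_gte(v$nugget, 0)
  expect_gt(v$psill, 0)
  # semivariance at lag 0 equals the nugget for the fitted curve
  expect_equal(morphodiv:::.vgm_curve(v$model, 1e-12, v$nugget, v$psill,
                                      v$range),
               v$nugget, tolerance = 1e-6)

  vflat <- fit_variogram(rep(3, 10), xy[1:10, ])
  expect_true(vflat$flat)
  expect_error(fit_variogram(rnorm(3), xy[1:3, ]), "at least")
})

test_that("a known exponential field's range is recovered within a factor of 2", {
  set.seed(22)
  hits <- 0
  for (r in 1:15) {
    xy <- matrix(runif(100, 0, 100), ncol = 2)
    y <- sim_exp_field(xy, 15)
    v <- fit_variogram(y, xy)
    # effective range of the fitted model (95% of sill)
    eff <- switch(v$model, spherical = v$range, exponential = 3 * v$range,
                  gaussian = sqrt(3) * v$range)
    if (eff > 0.5 * 3 * 15 && eff < 2 * 3 * 15) hits <- hits + 1
  }
  expect_gt(hits, 7)
})

test_that("ordinary kriging weights sum to one and honour the data", {
  set.seed(23)
  xy <- matrix(runif(30, 0, 10), ncol = 2)
  y <- rnorm(15, 10)
  v <- fit_variogram(y, xy, min_sites = 5)
  v$nugget <- 0
  ks <- krige(y, xy, v, grid = list(nx = 8, ny = 8))
  expect_lt(max(abs(rowSums(ks$weights) - 1)), 1e-8)
  # exact interpolation at the data sites with zero nugget
  at_sites <- krige(y, xy, v, grid = xy)
  expect_equal(at_sites$grid$pred, y, tolerance = 1e-6)

  # weights match an independently assembled linear solve at one node
  p0 <- matrix(c(5, 5), 1, 2)
  k0 <- krige(y, xy, v, grid = p0)
  n <- length(y)
  D <- as.matrix(dist(xy))
  G <- morphodiv:::.vgm_curve(v$model, D, v$nugget, v$psill, v$range)
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  g0 <- morphodiv:::.vgm_curve(v$model,
                               sqrt(colSums((t(xy) - c(5, 5))^2)),
                               v$nugget, v$psill, v$range)
  w <- unname(solve(A, c(g0, 1))[1:n])
  expect_equal(as.vector(k0$weights), w, tolerance = 1e-8)
  expect_equal(k0$grid$pred, sum(w * y), tolerance = 1e-10)
})

test_that("constant fields produce flat surfaces and duplicate sites error", {
  xy <- matrix(runif(20, 0, 10), ncol = 2)
  ks <- krige(rep(2, 10), xy, grid = list(nx = 5, ny = 5))
  expect_equal(ks$flag, "flat")
  expect_true(all(ks$grid$pred == 2))
  expect_true(all(ks$grid$var == 0))

  xy2 <- rbind(xy, xy[1, ])
  v <- list(model = "exponential", nugget = 0, psill = 1, range = 3,
            flat = FALSE)
  class(v) <- "variogram"
  expect_error(krige(c(rep(2, 10), 3), xy2, v, grid = list(nx = 3, ny = 3)),
               "singular|duplicate")
})

test_that("divergence surfaces are accurate under isolation-by-distance and not under noise", {
  set.seed(25)
  n <- 9
  xy <- matrix(runif(2 * n, 0, 100), ncol = 2)
  geo <- as.matrix(dist(xy))
  rownames(geo) <- colnames(geo) <- paste0("P", 1:n)
  D <- pop_dist(1 - exp(-geo / 40), rownames(geo), "phenotypic")
  s <- krige_divergence(D, xy, grid = list(nx = 6, ny = 6))
  expect_length(s$surfaces, n)
  expect_gt(s$n_accurate, n / 2)

  # spatially shuffled distances: mostly inaccurate surfaces
  set.seed(26)
  acc <- integer(0)
  for (r in 1:5) {
    perm <- sample(n)
    Dp <- pop_dist(unclass(D)[perm, perm], rownames(geo), "phenotypic")
    sp <- suppressWarnings(krige_divergence(Dp, xy, grid = list(nx = 4, ny = 4)))
    acc <- c(acc, sp$n_accurate)
  }
  expect_lt(mean(acc), n / 2)

  # surfaces invariant to site ordering
  ord <- sample(n)
  s2 <- krige_divergence(pop_dist(unclass(D)[ord, ord], rownames(geo)[ord],
                                  "phenotypic"),
                         xy[ord, ], grid = list(nx = 6, ny = 6))
  expect_equal(s2$surfaces[["P1"]]$grid$pred, s$surfaces[["P1"]]$grid$pred,
               tolerance = 1e-8)
})

test_that("surface export writes XYZ and ESRI ASCII text", {
  set.seed(27)
  xy <- matrix(runif(20, 0, 10), ncol = 2)
  y <- rnorm(10)
  ks <- krige(y, xy, grid = list(nx = 4, ny = 3))
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".asc")
  write_surface(ks, f1, "xyz")
  d <- read.delim(f1)
  expect_equal(nrow(d), 12)
  write_surface(ks, f2, "asciigrid")
  hdr <- readLines(f2, n = 6)
  expect_match(hdr[1], "ncols 4")
  expect_match(hdr[2], "nrows 3")
})
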