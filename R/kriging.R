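# Ordinary kriging of per-population values (diversity, or per-focal
# divergence) on a regular grid, with empirical variogram fitting and
# leave-one-out accuracy screening of the resulting surfaces.

.VGM_MODELS <- c("spherical", "exponential", "gaussian")

.vgm_curve <- function(model, h, nugget, psill, range) {
  g <- switch(model,
              spherical = ifelse(h < range,
                                 psill * (1.5 * h / range - 0.5 * (h / range)^3),
                                 psill),
              exponential = psill * (1 - exp(-h / range)),
              gaussian = psill * (1 - exp(-(h / range)^2)))
  ifelse(h > 0, nugget + g, 0)
}

#' Fit an empirical variogram
#'
#' Builds a binned empirical semivariogram (equal-width lags to ~2/3 of the
#' maximum distance, at least 4 bins) and fits spherical, exponential, and
#' gaussian models by pair-count-weighted least squares, returning the model
#' with the lowest weighted residual sum of squares. Identical values at all
#' sites yield a degenerate variogram flagged `flat`.
#'
#' @param values numeric vector of site values.
#' @param coords two-column matrix of site coordinates.
#' @param n_bins number of distance bins (default 6).
#' @param min_sites minimum number of sites (default 5).
#' @return an object of class `variogram` with `model`, `nugget`, `psill`,
#'   `range`, the empirical `bins`, and a `flat` flag.
#' @export
fit_variogram <- function(values, coords, n_bins = 6, min_sites = 5) {
  values <- as.numeric(values)
  coords <- as.matrix(coords)
  n <- length(values)
  if (n < min_sites) stop("at least ", min_sites, " sites are required")
  D <- as.matrix(stats::dist(coords))
  if (stats::sd(values) == 0) {
    out <- list(model = "flat", nugget = 0, psill = 0, range = max(D),
                bins = NULL, rss = 0, flat = TRUE)
    class(out) <- "variogram"
    return(out)
  }
  ij <- .pair_index(n)
  h <- D[ij]
  sv <- 0.5 * (values[ij[, 1]] - values[ij[, 2]])^2
  n_bins <- max(4, n_bins)
  cut_max <- max(h) * 2 / 3
  edges <- seq(0, cut_max, length.out = n_bins + 1)
  bin <- findInterval(h, edges, rightmost.closed = TRUE)
  keep <- bin >= 1 & bin <= n_bins
  bins <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    idx <- keep & bin == b
    if (!any(idx)) return(NULL)
    data.frame(lag = mean(h[idx]), semivariance = mean(sv[idx]),
               n_pairs = sum(idx))
  }))
  if (is.null(bins) || nrow(bins) < 3)
    stop("too few populated distance bins for variogram estimation")
  vtot <- stats::var(values)
  fits <- lapply(.VGM_MODELS, function(mod) {
    obj <- function(par) {
      g <- .vgm_curve(mod, bins$lag, par[1], par[2], par[3])
      sum(bins$n_pairs * (bins$semivariance - g)^2)
    }
    o <- stats::optim(c(0, vtot, max(bins$lag) / 2), obj, method = "L-BFGS-B",
                      lower = c(0, 1e-12 * vtot, 1e-6 * max(bins$lag)),
                      upper = c(2 * vtot, 5 * vtot, 10 * max(bins$lag)))
    list(model = mod, par = o$par, rss = o$value)
  })
  best <- fits[[which.min(vapply(fits, function(f) f$rss, numeric(1)))]]
  out <- list(model = best$model, nugget = best$par[1], psill = best$par[2],
              range = best$par[3], bins = bins, rss = best$rss, flat = FALSE)
  class(out) <- "variogram"
  out
}

#' @export
print.variogram <- function(x, ...) {
  if (x$flat) cat("Variogram: degenerate (constant field)\n")
  else cat(sprintf("Variogram (%s): nugget %.4g, partial sill %.4g, range %.4g\n",
                   x$model, x$nugget, x$psill, x$range))
  invisible(x)
}

# solve the ordinary kriging system for prediction points P (m x 2);
# returns list(pred, var, weights) with weights m x n
.ok_solve <- function(values, coords, vgm, P) {
  n <- length(values)
  D <- as.matrix(stats::dist(coords))
  if (any(D[upper.tri(D)] == 0))
    stop("duplicate coordinates make the kriging system singular: sites ",
         paste(which(D == 0 & upper.tri(D), arr.ind = TRUE)[1, ], collapse = ","))
  G <- .vgm_curve(vgm$model, D, vgm$nugget, vgm$psill, vgm$range)
  d0 <- sqrt(outer(P[, 1], coords[, 1], "-")^2 +
               outer(P[, 2], coords[, 2], "-")^2)
  g0 <- .vgm_curve(vgm$model, d0, vgm$nugget, vgm$psill, vgm$range)
  rhs <- rbind(t(g0), 1)
  # a near-flat fitted variogram makes the system numerically singular;
  # retry with a graduated ridge on the off-diagnostic structure
  sol <- NULL
  scale <- max(vgm$nugget + vgm$psill, stats::var(values), .Machine$double.eps)
  for (eps in c(0, 1e-10, 1e-8, 1e-6, 1e-4) * scale) {
    A <- rbind(cbind(G + diag(eps, n), 1), c(rep(1, n), 0))
    sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
    if (!is.null(sol)) {
      if (eps > 0) warning("kriging system ill-conditioned; ridge of ",
                           format(eps), " applied")
      break
    }
  }
  if (is.null(sol))
    stop("kriging system singular; check for duplicate coordinates")
  W <- t(sol[seq_len(n), , drop = FALSE])
  mu <- sol[n + 1, ]
  pred <- as.vector(W %*% values)
  kvar <- rowSums(W * g0) + mu
  list(pred = pred, var = pmax(kvar, 0), weights = W)
}

#' Ordinary kriging of site values onto a grid
#'
#' Best linear unbiased prediction with weights constrained to sum to one at
#' every node, driven by a fitted [fit_variogram()]. Leave-one-out accuracy
#' (Pearson r and RMSE of predictions at each held-out site) classifies the
#' surface as `accurate` (LOO r at or above `threshold` and nonzero spatial
#' variance), `inaccurate`, or `flat`.
#'
#' @param values numeric site values.
#' @param coords two-column matrix of site coordinates.
#' @param variogram optional fitted [fit_variogram()]; fitted internally if
#'   missing.
#' @param grid either a list `list(nx, ny, xlim, ylim)` or a two-column
#'   matrix of prediction points.
#' @param threshold LOO Pearson r at or above which the surface is flagged
#'   accurate (default 0.5).
#' @return an object of class `kriged_surface` with the prediction `grid`
#'   (`x`, `y`, `pred`, `var`), the kriging `weights`, `loo` predictions,
#'   `accuracy` (`r`, `rmse`), and `flag`.
#' @export
krige <- function(values, coords, variogram = NULL, grid = list(nx = 25, ny = 25),
                  threshold = 0.5) {
  values <- as.numeric(values)
  coords <- as.matrix(coords)
  n <- length(values)
  if (is.null(variogram)) variogram <- fit_variogram(values, coords,
                                                     min_sites = min(5, n))
  if (is.list(grid) && !is.data.frame(grid)) {
    xl <- if (!is.null(grid$xlim)) grid$xlim else range(coords[, 1])
    yl <- if (!is.null(grid$ylim)) grid$ylim else range(coords[, 2])
    P <- as.matrix(expand.grid(x = seq(xl[1], xl[2], length.out = grid$nx),
                               y = seq(yl[1], yl[2], length.out = grid$ny)))
  } else P <- as.matrix(grid)[, 1:2, drop = FALSE]

  if (variogram$flat) {
    out <- list(grid = data.frame(x = P[, 1], y = P[, 2],
                                  pred = mean(values), var = 0),
                weights = NULL, loo = rep(mean(values), n),
                accuracy = list(r = NA_real_, rmse = 0), flag = "flat",
                variogram = variogram)
    class(out) <- "kriged_surface"
    return(out)
  }
  ok <- .ok_solve(values, coords, variogram, P)
  loo <- vapply(seq_len(n), function(i) {
    .ok_solve(values[-i], coords[-i, , drop = FALSE], variogram,
              coords[i, , drop = FALSE])$pred
  }, numeric(1))
  r <- if (stats::sd(loo) > 0) stats::cor(values, loo) else NA_real_
  rmse <- sqrt(mean((values - loo)^2))
  flag <- if (nrow(P) > 1 && stats::sd(ok$pred) == 0) "flat"
  else if (is.finite(r) && r >= threshold) "accurate" else "inaccurate"
  out <- list(grid = data.frame(x = P[, 1], y = P[, 2], pred = ok$pred,
                                var = ok$var),
              weights = ok$weights, loo = loo,
              accuracy = list(r = r, rmse = rmse), flag = flag,
              variogram = variogram)
  class(out) <- "kriged_surface"
  out
}

#' @export
print.kriged_surface <- function(x, ...) {
  cat(sprintf("Kriged surface (%s): %d nodes, LOO r = %s, RMSE = %.4g\n",
              x$flag, nrow(x$grid),
              if (is.finite(x$accuracy$r)) sprintf("%.2f", x$accuracy$r) else "NA",
              x$accuracy$rmse))
  invisible(x)
}

#' Kriged surfaces of per-focal-population divergence
#'
#' For each focal population, interpolates its phenotypic distances to all
#' other populations over the grid and screens the surface by leave-one-out
#' accuracy, reporting how many focal surfaces are accurate.
#'
#' @param D a phenotypic [pop_dist()] matrix.
#' @param coords two-column matrix of population coordinates (rows aligned
#'   with `D`).
#' @param grid grid specification as in [krige()].
#' @param threshold LOO accuracy threshold (default 0.5).
#' @return list of class `divergence_surfaces`: per-focal `surfaces`, the
#'   `n_accurate` count, and `flags`.
#' @export
krige_divergence <- function(D, coords, grid = list(nx = 25, ny = 25),
                             threshold = 0.5) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 5) stop("at least 5 populations are required")
  coords <- as.matrix(coords)
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("pop", seq_len(n))
  surfaces <- vector("list", n); names(surfaces) <- labels
  for (i in seq_len(n)) {
    v <- fit_variogram(D[i, -i], coords[-i, , drop = FALSE],
                       min_sites = min(4, n - 1))
    surfaces[[i]] <- krige(D[i, -i], coords[-i, , drop = FALSE], v, grid,
                           threshold)
  }
  flags <- vapply(surfaces, function(s) s$flag, character(1))
  out <- list(surfaces = surfaces, flags = flags,
              n_accurate = sum(flags == "accurate"))
  class(out) <- "divergence_surfaces"
  out
}

#' @export
print.divergence_surfaces <- function(x, ...) {
  cat(sprintf("Divergence surfaces: %d of %d focal populations accurate\n",
              x$n_accurate, length(x$surfaces)))
  invisible(x)
}

#' Write a kriged surface as delimited XYZ text or an ESRI ASCII grid
#'
#' @param surface a `kriged_surface`.
#' @param path output file.
#' @param format `"xyz"` (x, y, prediction, variance; tab-separated) or
#'   `"asciigrid"` (ESRI ASCII raster of the predictions; requires a regular
#'   grid).
#' @return `path`, invisibly.
#' @export
write_surface <- function(surface, path, format = c("xyz", "asciigrid")) {
  format <- match.arg(format)
  g <- surface$grid
  if (format == "xyz") {
    utils::write.table(g, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    xs <- sort(unique(g$x)); ys <- sort(unique(g$y))
    if (length(xs) * length(ys) != nrow(g))
      stop("ASCII grid export requires a regular grid")
    m <- matrix(g$pred[order(-g$y, g$x)], nrow = length(ys), byrow = TRUE)
    con <- file(path, "w"); on.exit(close(con))
    cell <- if (length(xs) > 1) xs[2] - xs[1] else 1
    writeLines(c(paste("ncols", length(xs)), paste("nrows", length(ys)),
                 paste("xllcorner", min(xs) - cell / 2),
                 paste("yllcorner", min(ys) - cell / 2),
                 paste("cellsize", cell), "NODATA_value -9999"), con)
    utils::write.table(m, con, sep = " ", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
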