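# Generalized Dissimilarity Modelling: monotone I-spline regression of
# pairwise phenotypic dissimilarity on genetic, environmental, and geographic
# predictors, under the negative-exponential link mu = 1 - exp(-eta), with
# non-negativity-constrained deviance minimisation, Monte Carlo permutation
# significance, and backward predictor selection.

#' Order-2 monotone I-spline basis
#'
#' Three (for three knots; in general `length(knots)`) monotone
#' non-decreasing piecewise-quadratic basis functions mapping the knot span
#' to `[0, 1]`: every basis is 0 at the minimum knot and 1 at the maximum.
#' Values outside the span are clamped.
#'
#' @param x numeric predictor values.
#' @param knots strictly increasing knot locations (ties collapsed with a
#'   warning); by default placed at the 0/50/100th percentiles at fit time.
#' @return numeric matrix `length(x)` x `length(knots)`.
#' @export
ispline_basis <- function(x, knots) {
  knots <- sort(knots)
  if (anyDuplicated(knots)) {
    warning("duplicate knots collapsed")
    knots <- unique(knots)
  }
  m <- length(knots)
  if (m < 2) stop("constant predictor: no I-spline basis definable")
  x <- pmin(pmax(x, knots[1]), knots[m])
  t <- c(knots[1], knots, knots[m])   # (t_i, t_{i+1}, t_{i+2}) triples
  B <- matrix(0, length(x), m)
  for (i in seq_len(m)) {
    t0 <- t[i]; t1 <- t[i + 1]; t2 <- t[i + 2]
    lo <- x <= t0
    mid1 <- x > t0 & x <= t1
    mid2 <- x > t1 & x <= t2
    hi <- x > t2
    if (t1 > t0) B[mid1, i] <- (x[mid1] - t0)^2 / ((t2 - t0) * (t1 - t0))
    if (t2 > t1) B[mid2, i] <- 1 - (t2 - x[mid2])^2 / ((t2 - t0) * (t2 - t1))
    B[hi, i] <- 1
  }
  B
}

#' Build the site-pair table for GDM
#'
#' One row per unordered population pair. The response is the phenotypic
#' dissimilarity divided by `1.01 * max` so it lies in `[0, 1)` (the link's
#' codomain); matrix predictors (Fst, genD, Dxy, geographic distance)
#' contribute their pairwise entry, scalar predictors (environmental
#' variables, genetic diversity) contribute the values at both sites.
#'
#' @param response a phenotypic [pop_dist()] (or plain symmetric matrix).
#' @param predictors named list; each element either an n x n matrix
#'   ([pop_dist()]) or a per-population numeric vector aligned with
#'   `rownames(response)`.
#' @return an object of class `site_pair_table`.
#' @export
site_pair_table <- function(response, predictors) {
  response <- as.matrix(response)
  n <- nrow(response)
  labels <- rownames(response)
  if (is.null(labels)) labels <- paste0("pop", seq_len(n))
  if (is.null(names(predictors)) || any(names(predictors) == ""))
    stop("predictors must be a named list")
  ij <- .pair_index(n)
  raw <- response[ij]
  scale_max <- max(raw) * 1.01
  if (scale_max <= 0) scale_max <- 1
  y <- raw / scale_max
  pred <- list()
  for (nm in names(predictors)) {
    p <- predictors[[nm]]
    if (is.matrix(p) || inherits(p, "pop_dist")) {
      p <- as.matrix(p)
      if (!all(dim(p) == n)) stop("matrix predictor ", nm, " has wrong dimension")
      pred[[nm]] <- list(type = "matrix", pair = p[ij], matrix = p)
    } else {
      p <- as.numeric(p)
      if (length(p) != n) stop("scalar predictor ", nm, " has wrong length")
      pred[[nm]] <- list(type = "scalar", site = p)
    }
  }
  structure(list(y = y, ij = ij, n_pops = n, labels = labels,
                 predictors = pred, response_scale = scale_max),
            class = "site_pair_table")
}

#' @export
print.site_pair_table <- function(x, ...) {
  cat(sprintf("Site-pair table: %d pairs from %d populations, %d predictors\n",
              length(x$y), x$n_pops, length(x$predictors)))
  invisible(x)
}

# design matrix: one block of length(knots) columns per predictor.
# matrix predictors: I-splines of the pairwise value; scalar predictors:
# |I(x_i) - I(x_j)| of the splined site values.
.gdm_design <- function(spt, knots_q = c(0, 0.5, 1), knots = NULL) {
  blocks <- list(); kn <- list()
  for (nm in names(spt$predictors)) {
    p <- spt$predictors[[nm]]
    vals <- if (p$type == "matrix") p$pair else p$site
    if (length(unique(vals)) < 2)
      stop("constant predictor: ", nm)
    k <- if (!is.null(knots) && !is.null(knots[[nm]])) knots[[nm]] else
      unique(stats::quantile(vals, knots_q, names = FALSE))
    if (length(k) < 2)
      stop("constant predictor: ", nm)
    kn[[nm]] <- k
    if (p$type == "matrix") {
      blocks[[nm]] <- ispline_basis(p$pair, k)
    } else {
      Bsite <- ispline_basis(p$site, k)
      blocks[[nm]] <- abs(Bsite[spt$ij[, 1], , drop = FALSE] -
                            Bsite[spt$ij[, 2], , drop = FALSE])
    }
  }
  Z <- do.call(cbind, blocks)
  colnames(Z) <- unlist(lapply(names(blocks), function(nm)
    paste0(nm, ".s", seq_len(ncol(blocks[[nm]])))))
  list(Z = Z, knots = kn,
       index = rep(names(blocks), vapply(blocks, ncol, integer(1))))
}

# binomial-type deviance of y in [0,1) against mu = 1 - exp(-eta)
.gdm_deviance <- function(y, eta) {
  mu <- pmin(pmax(1 - exp(-eta), 1e-9), 1 - 1e-9)
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  t2 <- ifelse(y < 1, (1 - y) * log((1 - y) / (1 - mu)), 0)
  2 * sum(t1 + t2)
}

.gdm_fit_coefs <- function(y, Z) {
  X <- cbind(1, Z)
  p <- ncol(X)
  ybar <- mean(y)
  start <- c(max(-log(1 - min(ybar, 1 - 1e-6)), 1e-4), rep(0, p - 1))
  fn <- function(b) .gdm_deviance(y, as.vector(X %*% b))
  gr <- function(b) {
    eta <- as.vector(X %*% b)
    mu <- pmin(pmax(1 - exp(-eta), 1e-9), 1 - 1e-9)
    # dD/deta = 2[(1 - y) - y (1 - mu)/mu]
    g <- 2 * ((1 - y) - y * (1 - mu) / mu)
    as.vector(crossprod(X, g))
  }
  opt <- stats::optim(start, fn, gr, method = "L-BFGS-B",
                      lower = rep(0, p),
                      control = list(maxit = 500, factr = 1e4))
  if (opt$convergence != 0 && opt$convergence != 52)
    stop("GDM fit did not converge: ", opt$convergence, " ", opt$message)
  opt
}

#' Fit a generalized dissimilarity model
#'
#' Predicted dissimilarity is `mu = 1 - exp(-eta)` with
#' `eta = b0 + sum_pred sum_k b_k I_k(.)`; all coefficients are constrained
#' non-negative, which guarantees monotone non-decreasing partial response
#' curves. Coefficients minimize the binomial-type deviance of the `[0,1)`
#' responses; `deviance_explained = 100 (1 - D_model / D_null)` with the null
#' deviance from the intercept-only model. The per-predictor importance is
#' the sum of its I-spline coefficients, which equals the maximum height of
#' its partial response curve.
#'
#' @param spt a [site_pair_table()].
#' @param knots_q quantiles at which knots are placed (default 0/50/100th
#'   percentiles, three I-splines per predictor).
#' @return an object of class `gdm_model`.
#' @export
fit_gdm <- function(spt, knots_q = c(0, 0.5, 1)) {
  stopifnot(inherits(spt, "site_pair_table"))
  if (length(spt$y) < 10) stop("at least 10 site pairs are required")
  if (length(spt$predictors) < 1) return(.gdm_null_model(spt))
  des <- .gdm_design(spt, knots_q)
  opt <- .gdm_fit_coefs(spt$y, des$Z)
  b0 <- opt$par[1]; b <- opt$par[-1]
  dev <- opt$value
  dev_null <- .gdm_deviance(spt$y, rep(-log(1 - mean(spt$y)), length(spt$y)))
  dev_expl <- if (dev_null <= .Machine$double.eps) 0 else
    100 * max(0, 1 - dev / dev_null)
  coefs <- split(b, factor(des$index, unique(des$index)))
  importance <- vapply(coefs, sum, numeric(1))
  structure(list(intercept = b0, coefficients = coefs, knots = des$knots,
                 deviance = dev, null_deviance = dev_null,
                 deviance_explained = dev_expl,
                 importance = importance,
                 predictors = names(spt$predictors),
                 knots_q = knots_q, spt = spt),
            class = "gdm_model")
}

.gdm_null_model <- function(spt) {
  dev_null <- .gdm_deviance(spt$y, rep(-log(1 - mean(spt$y)), length(spt$y)))
  structure(list(intercept = -log(1 - mean(spt$y)),
                 coefficients = list(), knots = list(),
                 deviance = dev_null, null_deviance = dev_null,
                 deviance_explained = 0,
                 importance = stats::setNames(numeric(0), character(0)),
                 predictors = character(0), knots_q = c(0, 0.5, 1),
                 spt = spt),
            class = "gdm_model")
}

#' @export
print.gdm_model <- function(x, ...) {
  cat(sprintf("GDM: %.2f%% deviance explained", x$deviance_explained))
  if (!is.null(x$model_p)) cat(sprintf(" (model p = %.3f)", x$model_p))
  cat("\n")
  if (length(x$importance)) {
    cat("  predictor importance (summed I-spline coefficients):\n")
    for (nm in names(x$importance)) {
      cat(sprintf("    %-14s %.3f", nm, x$importance[nm]))
      if (!is.null(x$p_values) && nm %in% names(x$p_values))
        cat(sprintf("  (p = %.3f)", x$p_values[nm]))
      cat("\n")
    }
  } else cat("  no significant model (intercept only)\n")
  invisible(x)
}

#' Partial response curve of a fitted GDM predictor
#'
#' @param model a fitted `gdm_model`.
#' @param predictor predictor name.
#' @param newx values at which to evaluate (defaults to a grid over the knot
#'   span).
#' @return data.frame with `x` and the monotone partial response `f`.
#' @export
gdm_partial_response <- function(model, predictor, newx = NULL) {
  stopifnot(inherits(model, "gdm_model"))
  if (!predictor %in% names(model$coefficients))
    stop("predictor not in model: ", predictor)
  k <- model$knots[[predictor]]
  if (is.null(newx)) newx <- seq(k[1], k[length(k)], length.out = 200)
  f <- as.vector(ispline_basis(newx, k) %*% model$coefficients[[predictor]])
  data.frame(x = newx, f = f)
}

# rebuild a site-pair table with population identities permuted in the
# predictors (response kept fixed); `only` restricts to one predictor
.permute_spt <- function(spt, perm, only = NULL) {
  out <- spt
  for (nm in names(spt$predictors)) {
    if (!is.null(only) && nm != only) next
    p <- spt$predictors[[nm]]
    if (p$type == "matrix") {
      pm <- p$matrix[perm, perm]
      out$predictors[[nm]] <- list(type = "matrix", pair = pm[spt$ij],
                                   matrix = pm)
    } else {
      out$predictors[[nm]] <- list(type = "scalar", site = p$site[perm])
    }
  }
  out
}

#' Monte Carlo significance of a fitted GDM
#'
#' The whole-model p-value permutes population identities in all predictors
#' (rebuilding the site-pair table and refitting) and reports the add-one
#' proportion of permuted fits whose deviance explained is at least the
#' observed. Per-predictor p-values permute only that predictor's site
#' assignment.
#'
#' @param spt the [site_pair_table()] the model was fitted to.
#' @param model the fitted `gdm_model`.
#' @param n_perm number of permutations (default 500; fewer than 49 warns).
#' @param seed optional integer seed.
#' @return list with `model_p` and named vector `p_values`.
#' @export
gdm_permutation_significance <- function(spt, model, n_perm = 500,
                                         seed = NULL) {
  stopifnot(inherits(spt, "site_pair_table"), inherits(model, "gdm_model"))
  if (n_perm < 49) warning("n_perm < 49 gives coarse p-value resolution")
  obs <- model$deviance_explained
  run <- function() {
    de_model <- numeric(n_perm)
    de_pred <- matrix(NA_real_, n_perm, length(spt$predictors),
                      dimnames = list(NULL, names(spt$predictors)))
    for (k in seq_len(n_perm)) {
      perm <- sample.int(spt$n_pops)
      de_model[k] <- fit_gdm(.permute_spt(spt, perm),
                             model$knots_q)$deviance_explained
      for (nm in names(spt$predictors)) {
        permp <- sample.int(spt$n_pops)
        de_pred[k, nm] <- fit_gdm(.permute_spt(spt, permp, only = nm),
                                  model$knots_q)$deviance_explained
      }
    }
    list(de_model = de_model, de_pred = de_pred)
  }
  de <- if (is.null(seed)) run() else .with_seed(seed, run())
  model_p <- (1 + sum(de$de_model >= obs)) / (1 + n_perm)
  p_values <- apply(de$de_pred, 2, function(v)
    (1 + sum(v >= obs)) / (1 + n_perm))
  list(model_p = model_p, p_values = p_values)
}

#' Backward predictor selection for GDM by Monte Carlo permutation
#'
#' Fits the full model, then iteratively removes predictors with zero
#' importance and the predictor with the largest non-significant permutation
#' p-value, refitting until every retained predictor is significant at
#' `alpha` or none remain. An empty final model (intercept only) is reported
#' with 0 deviance explained and model p of 1.
#'
#' @param spt a [site_pair_table()] with the full predictor set.
#' @param alpha significance level (default 0.05).
#' @param n_perm permutations per significance assessment (default 500).
#' @param seed optional integer seed.
#' @param knots_q knot quantiles passed to [fit_gdm()].
#' @return the final `gdm_model` with `p_values`, `model_p`, and a `trace`
#'   of dropped predictors.
#' @export
gdm_backward_select <- function(spt, alpha = 0.05, n_perm = 500, seed = NULL,
                                knots_q = c(0, 0.5, 1)) {
  stopifnot(inherits(spt, "site_pair_table"))
  keep <- names(spt$predictors)
  trace <- character(0)
  seed_k <- if (is.null(seed)) NULL else seed
  repeat {
    if (!length(keep)) {
      final <- .gdm_null_model(spt)
      final$model_p <- 1
      final$p_values <- stats::setNames(numeric(0), character(0))
      final$trace <- trace
      return(final)
    }
    sub <- spt
    sub$predictors <- spt$predictors[keep]
    model <- fit_gdm(sub, knots_q)
    sig <- gdm_permutation_significance(sub, model, n_perm, seed = seed_k)
    if (!is.null(seed_k)) seed_k <- seed_k + 1L
    model$p_values <- sig$p_values
    model$model_p <- sig$model_p
    zero <- names(model$importance)[model$importance <= 1e-10]
    nonsig <- names(sig$p_values)[sig$p_values >= alpha]
    drop <- unique(c(zero,
                     if (length(nonsig))
                       nonsig[which.max(sig$p_values[nonsig])]))
    drop <- intersect(drop, keep)
    if (!length(drop)) { model$trace <- trace; return(model) }
    trace <- c(trace, drop)
    keep <- setdiff(keep, drop)
  }
}
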