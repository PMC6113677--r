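# Synthetic study generator. Emulates a two-species-style field design:
# ~9 populations x ~30 adults of both sexes, 7 linear biometric traits (mm)
# dominated by a shared latent body-size factor plus sexual dimorphism,
# 4 meristic scalation counts, 24 2D head landmarks digitised with arbitrary
# position/orientation/scale, 9 microsatellite loci under an island model
# with optional null alleles, and a 623 bp mtDNA fragment on a star tree.

.BIOMETRY <- c("SVL", "TRL", "HL", "HW", "HH", "FLL", "HLL")
.SCALATION <- c("GSN", "VSN", "FPN", "SCGN")

.biom_base <- c(SVL = 55, TRL = 28, HL = 14, HW = 8.2, HH = 5.8,
                FLL = 18, HLL = 28.5)
.scal_base <- c(GSN = 25, VSN = 27, FPN = 19, SCGN = 10)
.scal_sd   <- c(GSN = 1.8, VSN = 1.4, FPN = 1.0, SCGN = 1.5)

#' Configuration of a synthetic study
#'
#' Defaults describe the emulated field design: 9 populations of 30 adults on
#' a 100 km square landscape, six spatially autocorrelated environmental
#' variables, a dominant latent size factor (SD 4 mm on snout-vent length),
#' sexual size dimorphism, 9 microsatellite loci with 8 alleles each under an
#' island model calibrated to a target Fst, and a 623 bp mtDNA fragment.
#'
#' @param n_pops number of populations (>= 2).
#' @param n_per_pop individuals sampled per population.
#' @param extent landscape width/height in km.
#' @param env_range spatial autocorrelation range (km) of the exponential
#'   Gaussian process generating each environmental variable.
#' @param n_env number of mutually independent environmental variables.
#' @param size_sd SD (mm, on the snout-vent-length scale) of the latent
#'   body-size factor shared by all biometric traits.
#' @param sex_effect additive male-female offset (mm, on the SVL scale),
#'   applied along the size loadings.
#' @param env_effect slope of population trait means on the first (biometry)
#'   and second (scalation) environmental variable, and scale of the
#'   environment-driven head-shape deformation (third variable); 0 gives
#'   identical population means.
#' @param within_cov_scale multiplier of the within-population trait
#'   covariance (applied as `sqrt()` to the latent factor and trait noise);
#'   0 collapses every population onto its mean.
#' @param n_loci,n_alleles microsatellite loci and alleles per locus.
#' @param fst_target drift parameter of the island model in `[0, 1)`;
#'   population allele frequencies are Dirichlet with concentration
#'   `(1 - fst_target) / fst_target` times the ancestral frequencies, so the
#'   expected Weir-Cockerham theta equals `fst_target`.
#' @param null_allele_rate probability that any single allele copy fails to
#'   amplify (apparent homozygote if one copy drops, missing `0` if both).
#' @param mtdna_theta per-site mutation parameter of the star-tree branches
#'   leading to each population's mtDNA ancestor.
#' @param mtdna_theta_within per-site rate of private singleton mutations
#'   within populations (default `mtdna_theta / 5`).
#' @param mtdna_length alignment length in bp.
#' @param seed integer seed; fully determines the study.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(n_pops = 9, n_per_pop = 30, extent = 100,
                              env_range = 30, n_env = 6,
                              size_sd = 4, sex_effect = 3, env_effect = 1.5,
                              within_cov_scale = 1,
                              n_loci = 9, n_alleles = 8, fst_target = 0.2,
                              null_allele_rate = 0,
                              mtdna_theta = 0.01,
                              mtdna_theta_within = mtdna_theta / 5,
                              mtdna_length = 623, seed = 1) {
  stopifnot(n_pops >= 1, n_per_pop >= 1, n_loci >= 1, n_alleles >= 1,
            n_env >= 1, mtdna_length >= 1, extent > 0)
  if (fst_target < 0 || fst_target >= 1) stop("fst_target must lie in [0, 1)")
  if (null_allele_rate < 0 || null_allele_rate >= 1)
    stop("null_allele_rate must lie in [0, 1)")
  cfg <- list(n_pops = as.integer(n_pops), n_per_pop = as.integer(n_per_pop),
              extent = extent, env_range = env_range, n_env = as.integer(n_env),
              size_sd = size_sd, sex_effect = sex_effect,
              env_effect = env_effect, within_cov_scale = within_cov_scale,
              n_loci = as.integer(n_loci), n_alleles = as.integer(n_alleles),
              fst_target = fst_target, null_allele_rate = null_allele_rate,
              mtdna_theta = mtdna_theta,
              mtdna_theta_within = mtdna_theta_within,
              mtdna_length = as.integer(mtdna_length),
              seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  cfg
}

# local RNG scope so each stage is reproducible from config$seed alone
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

.rdirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) <= 0) { g <- alpha } # numerically degenerate shape; fall back on mean
  g / sum(g)
}

#' Simulate a landscape of populations with spatially structured environments
#'
#' Sites are uniform on the square extent; each environmental variable is an
#' independent zero-mean, unit-variance Gaussian process with exponential
#' covariance `exp(-d / env_range)` evaluated at the sites.
#'
#' @param config a [simulation_config()].
#' @return a `data.frame` (class `pop_table`) with columns `population`,
#'   `x`, `y`, and `env1..envK`.
#' @export
simulate_landscape <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$n_pops < 2) stop("n_pops must be >= 2: pairwise analyses are undefined")
  .with_seed(config$seed + 101L, {
    n <- config$n_pops
    xy <- matrix(stats::runif(2 * n, 0, config$extent), ncol = 2)
    D <- as.matrix(stats::dist(xy))
    S <- if (config$env_range <= 0) diag(n) else exp(-D / config$env_range)
    L <- chol(S + diag(1e-10, n))
    env <- crossprod(L, matrix(stats::rnorm(n * config$n_env), n))
    colnames(env) <- paste0("env", seq_len(config$n_env))
    out <- data.frame(population = paste0("P", seq_len(n)),
                      x = xy[, 1], y = xy[, 2], env,
                      stringsAsFactors = FALSE)
    class(out) <- c("pop_table", "data.frame")
    out
  })
}

# fixed head outline (24 landmarks) and a fixed unit deformation direction
.base_shape <- function() {
  t <- seq(0, 2 * pi, length.out = 25)[1:24]
  s <- cbind(cos(t), 0.7 * sin(t))
  s <- sweep(s, 2, colMeans(s))
  s / sqrt(sum(s^2))
}
.deform_dir <- function() {
  t <- seq(0, 2 * pi, length.out = 25)[1:24]
  u <- cbind(sin(3 * t), cos(2 * t))
  u <- sweep(u, 2, colMeans(u))
  u / sqrt(sum(u^2))
}

#' Simulate individual phenotypes on a landscape
#'
#' Biometric traits are a population mean (baseline plus an environmental
#' slope along the size loadings), a sex offset, a shared latent size factor,
#' and independent trait noise; negative lengths are truncation-resampled.
#' Scalation counts are rounded Gaussians with an analogous structure. Head
#' landmarks are the population mean shape plus isotropic shape-space noise,
#' then randomly rotated, translated, and scaled per individual so that
#' Procrustes superimposition is required downstream.
#'
#' @param populations output of [simulate_landscape()].
#' @param config the same [simulation_config()].
#' @param retry_cap maximum truncation-resampling attempts per individual.
#' @return list with elements `traits` (a [trait_matrix()] holding biometry
#'   and scalation), `landmarks` (a raw [landmark_set()]), and `truth`.
#' @export
simulate_phenotypes <- function(populations, config, retry_cap = 100) {
  stopifnot(inherits(config, "simulation_config"))
  .with_seed(config$seed + 202L, {
    npop <- nrow(populations)
    n <- config$n_per_pop
    N <- npop * n
    lam <- .biom_base / .biom_base["SVL"]      # size loadings
    noise_sd <- 0.035 * .biom_base
    wscale <- sqrt(config$within_cov_scale)

    pop <- rep(populations$population, each = n)
    sex <- rep(rep(c("m", "f"), length.out = n), npop)
    env <- as.matrix(populations[, grep("^env", names(populations)), drop = FALSE])

    biom <- matrix(NA_real_, N, length(.BIOMETRY),
                   dimnames = list(NULL, .BIOMETRY))
    scal <- matrix(NA_real_, N, length(.SCALATION),
                   dimnames = list(NULL, .SCALATION))
    popmean_b <- outer(env[, 1], lam * config$env_effect) +
      matrix(.biom_base, npop, length(lam), byrow = TRUE)
    e2 <- if (ncol(env) >= 2) env[, 2] else rep(0, npop)
    popmean_s <- outer(e2, .scal_sd * 0.6 * config$env_effect / 1.5) +
      matrix(.scal_base, npop, length(.SCALATION), byrow = TRUE)

    for (p in seq_len(npop)) {
      rows <- (p - 1) * n + seq_len(n)
      z <- stats::rnorm(n, 0, config$size_sd) * wscale
      sx <- ifelse(sex[rows] == "m", config$sex_effect / 2, -config$sex_effect / 2)
      for (i in seq_len(n)) {
        r <- rows[i]
        for (try in seq_len(retry_cap + 1L)) {
          eps <- stats::rnorm(length(lam), 0, noise_sd) * wscale
          v <- popmean_b[p, ] + sx[i] * lam + z[i] * lam + eps
          if (all(v > 0)) break
          if (try > retry_cap)
            stop("truncation-resampling exceeded retry cap; traits not positive")
        }
        biom[r, ] <- v
        sexsign <- if (sex[r] == "m") 0.5 else -0.5
        scal[r, ] <- round(popmean_s[p, ] +
                             sexsign * (config$sex_effect / 3) * 0.8 * .scal_sd +
                             stats::rnorm(4, 0, .scal_sd) * wscale)
      }
    }

    # landmarks: pop mean shape + individual shape noise, then nuisance
    base <- .base_shape(); u <- .deform_dir()
    k <- nrow(base)
    coords <- array(NA_real_, c(N, k, 2))
    e3 <- if (ncol(env) >= 3) env[, 3] else rep(0, npop)
    lm_sd <- 0.01 * wscale
    for (p in seq_len(npop)) {
      mshape <- base + 0.015 * config$env_effect * e3[p] * u
      rows <- (p - 1) * n + seq_len(n)
      for (r in rows) {
        cfg_i <- mshape + matrix(stats::rnorm(2 * k, 0, lm_sd), k, 2)
        th <- stats::runif(1, 0, 2 * pi)
        R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
        sc <- exp(stats::rnorm(1, 3, 0.15))   # digitising scale, px per unit
        tr <- stats::rnorm(2, 0, 5)
        coords[r, , ] <- sweep(cfg_i %*% R * sc, 2, tr, "+")
      }
    }

    ids <- paste0(pop, "_", rep(sprintf("%02d", seq_len(n)), npop))
    values <- cbind(biom, scal)
    rownames(values) <- ids
    traits <- trait_matrix(values, pop, sex)
    landmarks <- landmark_set(coords, pop, sex, aligned = FALSE)
    truth <- list(size_loadings = lam, popmean_biometry = popmean_b,
                  popmean_scalation = popmean_s, noise_sd = noise_sd,
                  mean_shapes = lapply(seq_len(npop), function(p)
                    base + 0.015 * config$env_effect * e3[p] * u))
    list(traits = traits, landmarks = landmarks, truth = truth)
  })
}

#' Simulate microsatellite genotypes under an island model
#'
#' Ancestral allele frequencies are Dirichlet(1); population frequencies are
#' Dirichlet with concentration `(1 - fst_target) / fst_target` times the
#' ancestral frequencies, so `Var(p) = p(1-p) * fst_target` and the expected
#' Weir-Cockerham theta equals `fst_target`. Genotypes are drawn
#' multinomially; each allele copy is independently hidden with probability
#' `null_allele_rate` (apparent homozygote, or `0` if both copies drop).
#'
#' @inheritParams simulate_phenotypes
#' @return a [genotype_matrix()] with a `truth` attribute holding the
#'   generating frequencies.
#' @export
simulate_microsats <- function(populations, config) {
  stopifnot(inherits(config, "simulation_config"))
  .with_seed(config$seed + 303L, {
    npop <- nrow(populations); n <- config$n_per_pop
    K <- config$n_alleles; L <- config$n_loci
    codes <- 100L + 2L * (seq_len(K) - 1L)
    anc <- lapply(seq_len(L), function(l) .rdirichlet(rep(1, K)))
    conc <- if (config$fst_target == 0) Inf else
      (1 - config$fst_target) / config$fst_target
    popfreq <- lapply(seq_len(L), function(l) {
      t(vapply(seq_len(npop), function(p) {
        if (is.infinite(conc)) anc[[l]] else .rdirichlet(conc * anc[[l]])
      }, numeric(K)))
    })
    N <- npop * n
    alleles <- array(0L, c(N, L, 2))
    pop <- rep(populations$population, each = n)
    for (l in seq_len(L)) {
      for (p in seq_len(npop)) {
        rows <- (p - 1) * n + seq_len(n)
        draws <- matrix(sample(codes, 2 * n, replace = TRUE,
                               prob = popfreq[[l]][p, ]), n, 2)
        alleles[rows, l, ] <- draws
      }
    }
    if (config$null_allele_rate > 0) {
      drop <- array(stats::runif(length(alleles)) < config$null_allele_rate,
                    dim(alleles))
      for (i in seq_len(N)) for (l in seq_len(L)) {
        d <- drop[i, l, ]
        if (all(d)) alleles[i, l, ] <- 0L
        else if (d[1]) alleles[i, l, 1] <- alleles[i, l, 2]
        else if (d[2]) alleles[i, l, 2] <- alleles[i, l, 1]
      }
    }
    G <- genotype_matrix(alleles, pop)
    attr(G, "truth") <- list(ancestral = anc, popfreq = popfreq, codes = codes)
    G
  })
}

#' Simulate an mtDNA haplotype alignment on a star tree
#'
#' A random ancestral sequence receives, on the branch to each population's
#' ancestor, `Poisson(mtdna_theta * L)` substitutions at sites private to
#' that branch (sites are allocated without replacement across branches, so
#' two population ancestors differ at exactly the sum of their branch
#' counts). Each sequence then receives private singleton mutations at rate
#' `mtdna_theta_within` per site.
#'
#' @inheritParams simulate_phenotypes
#' @return a [haplotype_alignment()] with one sequence per individual.
#' @export
simulate_mtdna <- function(populations, config) {
  stopifnot(inherits(config, "simulation_config"))
  .with_seed(config$seed + 404L, {
    npop <- nrow(populations); n <- config$n_per_pop
    L <- config$mtdna_length
    bases <- c("A", "C", "G", "T")
    anc <- sample(bases, L, replace = TRUE)
    k_branch <- stats::rpois(npop, config$mtdna_theta * L)
    if (sum(k_branch) > L)
      stop("requested mutation count exceeds available sites; lower mtdna_theta")
    free <- sample.int(L)
    popanc <- matrix(rep(anc, npop), npop, L, byrow = TRUE)
    used <- 0L
    for (p in seq_len(npop)) {
      if (k_branch[p] == 0) next
      sites <- free[used + seq_len(k_branch[p])]
      used <- used + k_branch[p]
      for (s in sites)
        popanc[p, s] <- sample(setdiff(bases, popanc[p, s]), 1)
    }
    seqs <- character(npop * n)
    pop <- rep(populations$population, each = n)
    for (p in seq_len(npop)) {
      for (i in seq_len(n)) {
        s <- popanc[p, ]
        m <- stats::rpois(1, config$mtdna_theta_within * L)
        if (m > 0) {
          at <- sample.int(L, min(m, L))
          for (a in at) s[a] <- sample(setdiff(bases, s[a]), 1)
        }
        seqs[(p - 1) * n + i] <- paste(s, collapse = "")
      }
    }
    H <- haplotype_alignment(seqs, pop)
    attr(H, "truth") <- list(ancestor = paste(anc, collapse = ""),
                             branch_mutations = k_branch,
                             pop_ancestors = apply(popanc, 1, paste, collapse = ""))
    H
  })
}

#' Simulate a complete synthetic study
#'
#' Composes [simulate_landscape()], [simulate_phenotypes()],
#' [simulate_microsats()] and [simulate_mtdna()]; the configuration seed
#' fully determines the result.
#'
#' @param config a [simulation_config()].
#' @return a list of class `synthetic_study` with elements `traits`,
#'   `landmarks`, `genotypes`, `haplotypes`, `populations`, `truth`, and
#'   `config`.
#' @export
simulate_study <- function(config = simulation_config()) {
  populations <- simulate_landscape(config)
  ph <- simulate_phenotypes(populations, config)
  G <- simulate_microsats(populations, config)
  H <- simulate_mtdna(populations, config)
  structure(list(traits = ph$traits, landmarks = ph$landmarks,
                 genotypes = G, haplotypes = H, populations = populations,
                 truth = list(phenotypes = ph$truth,
                              microsats = attr(G, "truth"),
                              mtdna = attr(H, "truth")),
                 config = config),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("Synthetic study: %d populations x %d individuals (seed %d)\n",
              x$config$n_pops, x$config$n_per_pop, x$config$seed))
  invisible(x)
}

#' Names of the biometric and scalation trait blocks
#' @return character vector of column names.
#' @export
biometry_traits <- function() .BIOMETRY

#' @rdname biometry_traits
#' @export
scalation_traits <- function() .SCALATION
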