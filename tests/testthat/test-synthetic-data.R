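test_that("the same seed reproduces a byte-identical study", {
  cfg <- small_config(seed = 123)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$traits$values, s2$traits$values)
  expect_identical(s1$landmarks$coords, s2$landmarks$coords)
  expect_identical(s1$genotypes$alleles, s2$genotypes$alleles)
  expect_identical(s1$haplotypes$seqs, s2$haplotypes$seqs)
  expect_identical(s1$populations, s2$populations)
})

test_that("landscape limits behave as white noise and constant field", {
  # near-zero range: environmental values uncorrelated with distance
  cfg0 <- simulation_config(n_pops = 40, env_range = 1e-6, seed = 5)
  land0 <- simulate_landscape(cfg0)
  D <- as.matrix(dist(land0[, c("x", "y")]))
  ut <- upper.tri(D)
  prod_env <- outer(land0$env1, land0$env1)[ut]
  expect_lt(abs(cor(D[ut], prod_env)), 0.15)

  # range >> extent: all sites nearly identical
  cfgI <- simulation_config(n_pops = 40, env_range = 1e5, extent = 100, seed = 5)
  landI <- simulate_landscape(cfgI)
  expect_lt(var(landI$env1), 0.05) # << process variance of 1

  expect_error(simulate_landscape(simulation_config(n_pops = 1)),
               "pairwise")
})

test_that("phenotype generator honours null effects and degenerate settings", {
  cfg <- simulation_config(sex_effect = 0, seed = 21)
  st <- simulate_study(cfg)
  pm <- population_means(
    trait_matrix(st$traits$values[st$traits$sex == "m", , drop = FALSE],
                 st$traits$population[st$traits$sex == "m"]), NULL)
  pf <- population_means(
    trait_matrix(st$traits$values[st$traits$sex == "f", , drop = FALSE],
                 st$traits$population[st$traits$sex == "f"]), NULL)
  # sex differences are sampling noise only: small relative to trait scale
  expect_lt(max(abs(pm[, "SVL"] - pf[, "SVL"])), 3 * 4 / sqrt(15) * 2)

  cfg0 <- simulation_config(env_effect = 0, within_cov_scale = 0, seed = 22)
  st0 <- simulate_study(cfg0)
  biom <- st0$traits$values[, biometry_traits()]
  div <- pairwise_divergence(biom, st0$traits$population)
  expect_lt(max(div), 1e-8)
})

test_that("dominant latent size factor drives PC1 of simulated biometry", {
  cfg <- simulation_config(size_sd = 6, seed = 31)
  st <- simulate_study(cfg)
  biom <- trait_matrix(st$traits$values[, biometry_traits()],
                       st$traits$population, st$traits$sex)
  ss <- size_shape_decompose(sex_center(biom))
  expect_gt(ss$eigenvalues[1] / sum(ss$eigenvalues), 0.6)
})

test_that("island-model genotypes hit the null-allele and panmixia limits", {
  st <- simulate_study(small_config(null_allele_rate = 0, seed = 41))
  expect_false(any(st$genotypes$alleles == 0L))

  stn <- simulate_study(small_config(null_allele_rate = 0.3, seed = 41))
  expect_true(any(stn$genotypes$alleles == 0L))

  st0 <- simulate_study(simulation_config(n_pops = 6, n_per_pop = 30,
                                          fst_target = 0, seed = 42))
  th <- attr(wc_fst(st0$genotypes), "global")
  expect_lt(abs(th), 0.02)
})

test_that("mtDNA star tree yields exact divergence counts and zero-theta identity", {
  cfg0 <- small_config(mtdna_theta = 0, mtdna_theta_within = 0, seed = 51)
  st0 <- simulate_study(cfg0)
  expect_length(unique(st0$haplotypes$seqs), 1L)
  d <- mtdna_diversity(st0$haplotypes)
  expect_equal(d$Hd, rep(0, nrow(d)))
  expect_equal(d$pi, rep(0, nrow(d)))

  # two populations, no within-pop mutation: Dxy = (k1 + k2) / L exactly
  cfg2 <- simulation_config(n_pops = 2, n_per_pop = 5, mtdna_theta = 0.02,
                            mtdna_theta_within = 0, mtdna_length = 623,
                            seed = 52)
  land <- simulate_landscape(cfg2)
  H <- simulate_mtdna(land, cfg2)
  k <- sum(attr(H, "truth")$branch_mutations)
  hud <- suppressWarnings(dxy_and_hudson_fst(H))
  expect_equal(hud$dxy[1, 2], k / 623)

  expect_error(simulate_mtdna(land, simulation_config(n_pops = 2,
                                                      mtdna_theta = 2,
                                                      mtdna_length = 100)),
               "exceeds")
})
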