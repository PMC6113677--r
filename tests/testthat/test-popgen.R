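test_that("expected heterozygosity and allele counts match hand values", {
  # one locus, two diploids A/B and A/B: p = (.5, .5), Hexp = (4/3)(.5)
  G <- make_genotypes(list(A = cbind(c(100L, 100L), c(102L, 102L))))
  d <- msat_diversity(G)
  expect_equal(d$Hexp, 2 / 3)
  expect_equal(d$Na, 2)

  # monomorphic locus
  Gm <- make_genotypes(list(A = cbind(c(100L, 100L, 100L), 100L)))
  dm <- msat_diversity(Gm)
  expect_equal(dm$Hexp, 0)
  expect_equal(dm$Na, 1)

  # invariance to allele relabeling
  Gr <- make_genotypes(list(A = cbind(c(200L, 200L), c(250L, 250L))))
  expect_equal(msat_diversity(Gr)$Na, d$Na)
  expect_equal(msat_diversity(Gr)$Hexp, d$Hexp)
})

test_that("Weir-Cockerham theta hits fixed-difference and panmixia limits", {
  G1 <- make_genotypes(list(A = cbind(rep(100L, 5), 100L),
                            B = cbind(rep(102L, 5), 102L)))
  expect_equal(wc_fst(G1)["A", "B"], 1)

  set.seed(2)
  pool <- sample(c(100L, 102L, 104L), 200, replace = TRUE, prob = c(.5, .3, .2))
  G0 <- genotype_matrix(array(pool, c(50, 1, 2)), rep(c("A", "B"), each = 25))
  expect_lt(abs(wc_fst(G0)["A", "B"]), 0.08)

  # monomorphic pair undefined
  Gm <- make_genotypes(list(A = cbind(rep(100L, 4), 100L),
                            B = cbind(rep(100L, 4), 100L)))
  expect_warning(fm <- wc_fst(Gm), "monomorphic")
  expect_true(is.na(fm["A", "B"]))
})

test_that("theta matches a direct transcription of the variance components", {
  # 2 pops x 5 diploids, one biallelic locus, fixed genotypes
  gA <- cbind(c(100L, 100L, 100L, 102L, 100L), c(100L, 102L, 100L, 102L, 100L))
  gB <- cbind(c(102L, 102L, 100L, 102L, 102L), c(102L, 102L, 102L, 102L, 100L))
  G <- make_genotypes(list(A = gA, B = gB))

  # literal scalar transcription for allele "100", r = 2 populations
  n1 <- 5; n2 <- 5; r <- 2
  p1 <- mean(c(gA) == 100L); p2 <- mean(c(gB) == 100L)
  h1 <- mean(xor(gA[, 1] == 100L, gA[, 2] == 100L))
  h2 <- mean(xor(gB[, 1] == 100L, gB[, 2] == 100L))
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  theta_oracle <- (2 * a) / (2 * (a + b + cc)) # both alleles contribute equally
  expect_equal(wc_fst(G)["A", "B"], theta_oracle, tolerance = 1e-12)
})

test_that("chord distance has its closed-form extremes and a no-op correction", {
  Gsame <- make_genotypes(list(
    A = cbind(c(100L, 102L, 100L), c(102L, 100L, 102L)),
    B = cbind(c(100L, 102L, 100L), c(102L, 100L, 102L))))
  expect_equal(cse_chord_distance(Gsame)["A", "B"], 0)

  Gfix <- make_genotypes(list(A = cbind(rep(100L, 4), 100L),
                              B = cbind(rep(102L, 4), 102L)))
  expect_equal(cse_chord_distance(Gfix)["A", "B"], (2 / pi) * sqrt(2))

  # no nulls simulated: corrected and uncorrected distances agree closely
  # (the EM attributes at most a small spurious null frequency to sampling
  # noise in homozygote counts at n = 30)
  st <- simulate_study(simulation_config(n_pops = 4, n_per_pop = 30,
                                         n_loci = 4, null_allele_rate = 0,
                                         seed = 61))
  d0 <- cse_chord_distance(st$genotypes, null_correction = FALSE)
  d1 <- cse_chord_distance(st$genotypes, null_correction = TRUE)
  expect_lt(max(abs(d0 - d1)), 0.03)
})

test_that("null-allele EM recovers a substantial null frequency from blanks", {
  set.seed(8)
  n <- 300; pnull <- 0.25
  truth <- sample(c(100L, 102L, 0L), 2 * n, replace = TRUE,
                  prob = c(0.45, 0.3, pnull))
  m <- matrix(truth, n, 2)
  vis <- m
  blank <- m[, 1] == 0L & m[, 2] == 0L
  one_null <- xor(m[, 1] == 0L, m[, 2] == 0L)
  vis[one_null, ] <- pmax(m[one_null, 1], m[one_null, 2]) # apparent homozygote
  em <- morphodiv:::.em_null_freq(vis[!blank, ], sum(blank))
  expect_lt(abs(em$r - pnull), 0.05)
})

test_that("haplotype and nucleotide diversity match hand arithmetic", {
  H <- make_haps(c("AAAA", "AAAA", "TTTA"), rep("A", 3))
  d <- mtdna_diversity(H)
  expect_equal(d$Hd, (3 / 2) * (1 - (4 / 9 + 1 / 9)))

  H2 <- make_haps(c("ACGT", "ACGA"), c("A", "A"))
  expect_equal(mtdna_diversity(H2)$pi, 0.25)

  Hsame <- make_haps(rep("ACGT", 3), rep("A", 3))
  expect_equal(mtdna_diversity(Hsame)$Hd, 0)
  expect_equal(mtdna_diversity(Hsame)$pi, 0)

  # ambiguous sites excluded pairwise
  Hn <- make_haps(c("ACNT", "ACGA"), c("A", "A"))
  expect_equal(mtdna_diversity(Hn)$pi, 1 / 3)

  expect_warning(mtdna_diversity(make_haps(c("AAAA", "AAAT"), c("A", "B"))),
                 "single sequence")
})

test_that("Dxy and Hudson Fst match enumerated pair counts", {
  Hfix <- make_haps(c("AAAA", "AAAA", "TTTT", "TTTT"),
                    rep(c("A", "B"), each = 2))
  r <- dxy_and_hudson_fst(Hfix)
  expect_equal(r$dxy["A", "B"], 1)
  expect_equal(r$fst_mt["A", "B"], 1)

  # hand-enumerated: Hw = .25, Hb = .5
  H <- make_haps(c("AAAA", "AAAT", "AATT", "ATTT"),
                 rep(c("A", "B"), each = 2))
  r2 <- dxy_and_hudson_fst(H)
  expect_equal(r2$dxy["A", "B"], 0.5)
  expect_equal(r2$fst_mt["A", "B"], 0.5)

  # merging two identical populations: Fst ~ 0
  set.seed(5)
  pool <- replicate(6, paste(sample(c("A", "C", "G", "T"), 200, TRUE),
                             collapse = ""))
  seqs <- sample(pool, 24, replace = TRUE)
  r3 <- dxy_and_hudson_fst(make_haps(seqs, rep(c("A", "B"), 12)))
  expect_lt(abs(r3$fst_mt["A", "B"]), 0.1)

  # order invariance of the estimators
  G <- simulate_study(small_config(seed = 62))$genotypes
  perm <- sample(seq_along(G$population))
  Gp <- genotype_matrix(G$alleles[perm, , , drop = FALSE], G$population[perm])
  f1 <- wc_fst(G); f2 <- wc_fst(Gp)
  expect_equal(unclass(f1)[rownames(f2), colnames(f2)], unclass(f2),
               ignore_attr = TRUE, tolerance = 1e-12)
})
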