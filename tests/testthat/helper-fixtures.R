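# Small deterministic fixtures shared across tests.

# tiny two-population trait matrix with a known mean offset
tiny_traits <- function(offset = c(2, 0), n = 6, seed = 11) {
  set.seed(seed)
  v <- matrix(rnorm(2 * n * 2), 2 * n, 2, dimnames = list(NULL, c("t1", "t2")))
  v[(n + 1):(2 * n), ] <- sweep(v[(n + 1):(2 * n), ], 2, offset, "+")
  trait_matrix(v, rep(c("A", "B"), each = n),
               rep(c("m", "f"), n))
}

# genotype matrix from a list of per-individual locus genotypes
# g: list per population of matrices with 2 columns per locus
make_genotypes <- function(per_pop) {
  pops <- names(per_pop)
  alleles <- do.call(rbind, per_pop)
  genotype_matrix(as.matrix(alleles), rep(pops, vapply(per_pop, nrow, 1L)))
}

make_haps <- function(seqs, pops) haplotype_alignment(seqs, pops)

# simulate a spatially correlated Gaussian field at given coords
sim_exp_field <- function(coords, range, sigma2 = 1) {
  D <- as.matrix(dist(coords))
  L <- chol(sigma2 * exp(-D / range) + diag(1e-10, nrow(coords)))
  as.vector(crossprod(L, rnorm(nrow(coords))))
}

small_config <- function(...) {
  simulation_config(n_pops = 5, n_per_pop = 12, n_loci = 4, n_alleles = 5,
                    mtdna_length = 200, ...)
}
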