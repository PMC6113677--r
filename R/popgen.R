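# Microsatellite and mtDNA summary statistics used as genetic predictors:
# within-population diversity (Na, Hexp, Hd, pi) and among-population
# differentiation (Weir-Cockerham theta, Cavalli-Sforza & Edwards chord
# distance with an optional null-allele correction, Hudson's Fst, Dxy).

# per-population, per-locus allele counts; returns list of named count vectors
.allele_counts <- function(G) {
  pops <- unique(G$population)
  L <- dim(G$alleles)[2]
  out <- vector("list", length(pops)); names(out) <- pops
  for (p in pops) {
    rows <- G$population == p
    out[[p]] <- lapply(seq_len(L), function(l) {
      a <- c(G$alleles[rows, l, 1], G$alleles[rows, l, 2])
      a <- a[a != 0L]
      table(a)
    })
  }
  out
}

#' Microsatellite diversity: alleles per locus and expected heterozygosity
#'
#' `Na` is the number of distinct alleles per locus averaged over loci;
#' `Hexp` is the unbiased expected heterozygosity
#' `(2n/(2n-1)) (1 - sum p_a^2)` per locus (n = non-missing diploids),
#' averaged over loci. Loci with fewer than 2 non-missing genotypes in a
#' population are skipped for that population with a warning.
#'
#' @param G a [genotype_matrix()].
#' @param unbiased apply the `2n/(2n-1)` small-sample correction (default).
#' @return data.frame with columns `population`, `Na`, `Hexp`.
#' @export
msat_diversity <- function(G, unbiased = TRUE) {
  stopifnot(inherits(G, "genotype_matrix"))
  pops <- unique(G$population)
  L <- dim(G$alleles)[2]
  res <- data.frame(population = pops, Na = NA_real_, Hexp = NA_real_)
  skipped <- character(0)
  for (pi in seq_along(pops)) {
    rows <- G$population == pops[pi]
    na_l <- hex_l <- rep(NA_real_, L)
    for (l in seq_len(L)) {
      a <- c(G$alleles[rows, l, 1], G$alleles[rows, l, 2])
      a <- a[a != 0L]
      n <- length(a) / 2
      if (n < 2) { skipped <- c(skipped, paste0(pops[pi], ":", G$loci[l])); next }
      p <- as.vector(table(a)) / length(a)
      na_l[l] <- length(p)
      h <- 1 - sum(p^2)
      hex_l[l] <- if (unbiased) (2 * n / (2 * n - 1)) * h else h
    }
    if (all(is.na(na_l)))
      stop("population ", pops[pi], " has no usable genotypes at any locus")
    res$Na[pi] <- mean(na_l, na.rm = TRUE)
    res$Hexp[pi] <- mean(hex_l, na.rm = TRUE)
  }
  if (length(skipped))
    warning("loci skipped for populations with < 2 genotypes: ",
            paste(skipped, collapse = ", "))
  res
}

# Weir & Cockerham (1984) variance components for one locus over r
# populations. Returns c(a, b, c) summed over alleles.
.wc_components <- function(alleles_by_pop) {
  # alleles_by_pop: list per population of a 2-column matrix of allele codes
  # (rows = non-missing diploids)
  r <- length(alleles_by_pop)
  n_i <- vapply(alleles_by_pop, nrow, integer(1))
  if (any(n_i < 1) || r < 2) return(c(0, 0, 0))
  all_codes <- sort(unique(unlist(lapply(alleles_by_pop, as.vector))))
  if (length(all_codes) < 2) return(c(0, 0, 0))
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  a_tot <- b_tot <- c_tot <- 0
  for (A in all_codes) {
    p_i <- vapply(alleles_by_pop, function(m) mean(m == A), numeric(1))
    h_i <- vapply(alleles_by_pop, function(m)
      mean(xor(m[, 1] == A, m[, 2] == A)), numeric(1))
    pbar <- sum(n_i * p_i) / (r * nbar)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - ((r - 1) / r) * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    a_tot <- a_tot + a; b_tot <- b_tot + b; c_tot <- c_tot + cc
  }
  c(a_tot, b_tot, c_tot)
}

.locus_alleles <- function(G, rows, l) {
  m <- cbind(G$alleles[rows, l, 1], G$alleles[rows, l, 2])
  m[m[, 1] != 0L & m[, 2] != 0L, , drop = FALSE]
}

#' Weir-Cockerham Fst (theta) between population pairs
#'
#' The theta estimator from the standard among-population / among-individual /
#' within-individual variance-components decomposition, with per-locus
#' components combined as a ratio of sums across loci. Pairs monomorphic at
#' every locus are undefined and reported as `NA` with a warning.
#'
#' @param G a [genotype_matrix()].
#' @return a genetic [pop_dist()] matrix of pairwise theta. The multi-
#'   population (global) theta across all populations is attached as
#'   attribute `"global"`.
#' @export
wc_fst <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  pops <- unique(G$population)
  L <- dim(G$alleles)[2]
  npop <- length(pops)
  th <- matrix(0, npop, npop, dimnames = list(pops, pops))
  undef <- character(0)
  for (i in seq_len(npop - 1)) for (j in (i + 1):npop) {
    acc <- c(0, 0, 0)
    for (l in seq_len(L)) {
      ml <- list(.locus_alleles(G, G$population == pops[i], l),
                 .locus_alleles(G, G$population == pops[j], l))
      if (any(vapply(ml, nrow, integer(1)) < 1)) next
      acc <- acc + .wc_components(ml)
    }
    denom <- sum(acc)
    if (abs(denom) < .Machine$double.eps) {
      th[i, j] <- th[j, i] <- NA_real_
      undef <- c(undef, paste0(pops[i], "-", pops[j]))
    } else th[i, j] <- th[j, i] <- acc[1] / denom
  }
  if (length(undef))
    warning("theta undefined (monomorphic pair): ", paste(undef, collapse = ", "))
  acc <- c(0, 0, 0)
  for (l in seq_len(L)) {
    ml <- lapply(pops, function(p) .locus_alleles(G, G$population == p, l))
    ml <- ml[vapply(ml, nrow, integer(1)) >= 1]
    if (length(ml) >= 2) acc <- acc + .wc_components(ml)
  }
  # slightly negative pairwise estimates are legitimate for theta; kept as-is
  out <- pop_dist(th, labels = pops, kind = "genetic")
  attr(out, "global") <- if (sum(acc) != 0) acc[1] / sum(acc) else NA_real_
  out
}

#' Multi-population Weir-Cockerham theta
#'
#' The global theta over all populations jointly (ratio of summed variance
#' components across loci and alleles), without the pairwise matrix.
#'
#' @param G a [genotype_matrix()].
#' @return a single theta estimate.
#' @export
wc_theta_global <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  pops <- unique(G$population)
  L <- dim(G$alleles)[2]
  acc <- c(0, 0, 0)
  for (l in seq_len(L)) {
    ml <- lapply(pops, function(p) .locus_alleles(G, G$population == p, l))
    ml <- ml[vapply(ml, nrow, integer(1)) >= 1]
    if (length(ml) >= 2) acc <- acc + .wc_components(ml)
  }
  if (sum(acc) == 0) return(NA_real_)
  acc[1] / sum(acc)
}

# EM estimate of the null-allele frequency at one locus in one population
# (Dempster EM under HWE with one null allele; apparent homozygotes may be
# visible/null heterozygotes, blanks are null/null).
.em_null_freq <- function(m, n_blank, tol = 1e-8, max_iter = 200) {
  # m: 2-col matrix of visible genotypes, n_blank: count of 0/0 genotypes
  codes <- sort(unique(as.vector(m)))
  N <- nrow(m) + n_blank
  if (N == 0 || length(codes) == 0)
    return(list(p = numeric(0), r = 0, codes = codes))
  p <- as.vector(table(factor(as.vector(m), codes))) / (2 * nrow(m))
  r <- max(sqrt(n_blank / N), 0.01)
  p <- p * (1 - r)
  hom <- m[, 1] == m[, 2]
  for (it in seq_len(max_iter)) {
    cnt <- stats::setNames(numeric(length(codes)), codes)
    r_cnt <- 2 * n_blank
    # heterozygotes contribute their two visible alleles
    het <- m[!hom, , drop = FALSE]
    if (nrow(het)) {
      tb <- table(factor(as.vector(het), codes))
      cnt <- cnt + as.vector(tb)
    }
    # apparent homozygote AA: true AA with prob pA^2/(pA^2 + 2 pA r)
    for (A in codes) {
      nA <- sum(hom & m[, 1] == A)
      if (nA == 0) next
      pA <- p[match(A, codes)]
      wAA <- pA^2 / (pA^2 + 2 * pA * r + .Machine$double.eps)
      cnt[as.character(A)] <- cnt[as.character(A)] + nA * (2 * wAA + (1 - wAA))
      r_cnt <- r_cnt + nA * (1 - wAA)
    }
    newp <- cnt / (2 * N); newr <- r_cnt / (2 * N)
    if (max(abs(c(newp - p, newr - r))) < tol) { p <- newp; r <- newr; break }
    p <- newp; r <- newr
  }
  list(p = as.vector(p), r = r, codes = codes)
}

#' Cavalli-Sforza & Edwards chord distance, with null-allele correction
#'
#' Per-locus chord distance
#' `d_l = (2/pi) sqrt(2 (1 - sum_a sqrt(p_a q_a)))`, averaged over loci with
#' data in both populations. With `null_correction = TRUE` the visible allele
#' frequencies at each locus in each population are re-estimated by an EM fit
#' that treats apparent homozygote excess and blank genotypes as evidence of
#' a null allele, and the estimated null is included as an additional shared
#' allele state before the chord computation (the INA convention). The exact
#' correction used in the original analysis is not published; this EM/INA
#' choice is a documented stand-in.
#'
#' @param G a [genotype_matrix()].
#' @param null_correction logical.
#' @return a genetic [pop_dist()] matrix (`genD`).
#' @export
cse_chord_distance <- function(G, null_correction = FALSE) {
  stopifnot(inherits(G, "genotype_matrix"))
  pops <- unique(G$population)
  L <- dim(G$alleles)[2]
  npop <- length(pops)
  freq <- vector("list", npop); names(freq) <- pops
  for (p in pops) {
    rows <- G$population == p
    freq[[p]] <- lapply(seq_len(L), function(l) {
      m <- .locus_alleles(G, rows, l)
      n_blank <- sum(G$alleles[rows, l, 1] == 0L & G$alleles[rows, l, 2] == 0L)
      if (nrow(m) == 0) return(NULL)
      if (null_correction) {
        em <- .em_null_freq(m, n_blank)
        stats::setNames(c(em$p, em$r), c(as.character(em$codes), ".null"))
      } else {
        tb <- table(as.vector(m))
        stats::setNames(as.vector(tb) / sum(tb), names(tb))
      }
    })
  }
  d <- matrix(0, npop, npop, dimnames = list(pops, pops))
  for (i in seq_len(npop - 1)) for (j in (i + 1):npop) {
    dl <- rep(NA_real_, L)
    for (l in seq_len(L)) {
      f1 <- freq[[i]][[l]]; f2 <- freq[[j]][[l]]
      if (is.null(f1) || is.null(f2)) next
      alleles <- union(names(f1), names(f2))
      p1 <- stats::setNames(rep(0, length(alleles)), alleles); p1[names(f1)] <- f1
      p2 <- stats::setNames(rep(0, length(alleles)), alleles); p2[names(f2)] <- f2
      s <- sum(sqrt(p1 * p2))
      dl[l] <- (2 / pi) * sqrt(2 * max(0, 1 - s))
    }
    if (all(is.na(dl))) stop("no shared loci with data for pair ",
                             pops[i], "-", pops[j])
    d[i, j] <- d[j, i] <- mean(dl, na.rm = TRUE)
  }
  pop_dist(d, labels = pops, kind = "genetic")
}

# pairwise sequence difference per site, with pairwise deletion of sites
# carrying N or a gap in either sequence
.seq_diff <- function(s1, s2) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  n_ok <- sum(ok)
  if (n_ok == 0) return(NA_real_)
  sum(a[ok] != b[ok]) / n_ok
}

#' mtDNA diversity per population: haplotype and nucleotide diversity
#'
#' `Hd = (n/(n-1)) (1 - sum h_i^2)` over haplotype frequencies, and `pi` is
#' the mean per-site pairwise difference over all within-population sequence
#' pairs (sites with N or a gap in either member of a pair are excluded
#' pairwise). Populations with a single sequence are reported as `NA` with a
#' warning.
#'
#' @param H a [haplotype_alignment()].
#' @return data.frame with columns `population`, `n`, `Hd`, `pi`.
#' @export
mtdna_diversity <- function(H) {
  stopifnot(inherits(H, "haplotype_alignment"))
  pops <- unique(H$population)
  res <- data.frame(population = pops, n = NA_integer_, Hd = NA_real_,
                    pi = NA_real_)
  small <- character(0)
  for (k in seq_along(pops)) {
    s <- H$seqs[H$population == pops[k]]
    n <- length(s)
    res$n[k] <- n
    if (n < 2) { small <- c(small, pops[k]); next }
    h <- as.vector(table(s)) / n
    res$Hd[k] <- (n / (n - 1)) * (1 - sum(h^2))
    pr <- utils::combn(n, 2)
    res$pi[k] <- mean(apply(pr, 2, function(ij) .seq_diff(s[ij[1]], s[ij[2]])),
                      na.rm = TRUE)
  }
  if (length(small))
    warning("populations with a single sequence have undefined Hd/pi: ",
            paste(small, collapse = ", "))
  res
}

#' Between-population sequence divergence: Dxy and Hudson's Fst
#'
#' `Dxy` is the mean per-site difference over all between-population sequence
#' pairs. Hudson's Fst is `1 - Hw/Hb` where `Hw` is the simple average of the
#' two within-population mean pairwise differences and `Hb` is the between-
#' population mean (`Dxy`). Pairs with `Hb = 0` have undefined Fst and are
#' reported `NA` with a warning.
#'
#' @param H a [haplotype_alignment()].
#' @return list with elements `dxy` and `fst_mt`, both [pop_dist()] matrices.
#' @export
dxy_and_hudson_fst <- function(H) {
  stopifnot(inherits(H, "haplotype_alignment"))
  pops <- unique(H$population)
  npop <- length(pops)
  within <- vapply(pops, function(p) {
    s <- H$seqs[H$population == p]
    if (length(s) < 2) return(NA_real_)
    pr <- utils::combn(length(s), 2)
    mean(apply(pr, 2, function(ij) .seq_diff(s[ij[1]], s[ij[2]])), na.rm = TRUE)
  }, numeric(1))
  dxy <- fst <- matrix(0, npop, npop, dimnames = list(pops, pops))
  undef <- character(0)
  for (i in seq_len(npop - 1)) for (j in (i + 1):npop) {
    s1 <- H$seqs[H$population == pops[i]]
    s2 <- H$seqs[H$population == pops[j]]
    db <- outer(seq_along(s1), seq_along(s2),
                Vectorize(function(a, b) .seq_diff(s1[a], s2[b])))
    hb <- mean(db, na.rm = TRUE)
    dxy[i, j] <- dxy[j, i] <- hb
    hw <- mean(c(within[i], within[j]))
    if (!is.finite(hb) || hb == 0 || !is.finite(hw)) {
      fst[i, j] <- fst[j, i] <- NA_real_
      if (is.finite(hb) && hb == 0)
        undef <- c(undef, paste0(pops[i], "-", pops[j]))
    } else fst[i, j] <- fst[j, i] <- 1 - hw / hb
  }
  if (length(undef))
    warning("Hudson Fst undefined (no between-population variation): ",
            paste(undef, collapse = ", "))
  list(dxy = pop_dist(dxy, labels = pops, kind = "genetic"),
       fst_mt = pop_dist(fst, labels = pops, kind = "genetic"))
}
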