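#' Individual-level trait table
#'
#' Bundles a numeric individuals x traits matrix with population and sex
#' labels. This is the unit of all morphology analyses: biometric traits are
#' linear measurements in mm, scalation traits are meristic counts treated as
#' continuous.
#'
#' @param values numeric matrix, individuals in rows, traits in columns
#'   (column names required).
#' @param population character or factor of population labels, one per row.
#' @param sex character or factor of sex labels, one per row.
#' @param block optional label for the trait set ("biometry", "scalation", ...).
#' @return an object of class `trait_matrix`.
#' @export
trait_matrix <- function(values, population, sex = NULL, block = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) stop("trait columns must be named")
  if (anyNA(values)) stop("trait values contain missing entries")
  if (!is.numeric(values)) stop("trait values must be numeric")
  if (length(population) != nrow(values))
    stop("one population label per individual is required")
  population <- as.character(population)
  if (is.null(sex)) sex <- rep(NA_character_, nrow(values))
  sex <- as.character(sex)
  if (length(sex) != nrow(values)) stop("one sex label per individual is required")
  structure(list(values = values, population = population, sex = sex,
                 block = block),
            class = "trait_matrix")
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat(sprintf("Trait matrix%s: %d individuals x %d traits, %d populations\n",
              if (is.null(x$block)) "" else paste0(" [", x$block, "]"),
              nrow(x$values), ncol(x$values), length(unique(x$population))))
  cat("  traits:", paste(colnames(x$values), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.trait_matrix <- function(x) dim(x$values)

#' Set of 2D landmark configurations
#'
#' @param coords numeric array individuals x landmarks x 2, raw digitised or
#'   Procrustes-aligned coordinates.
#' @param population population label per individual.
#' @param sex optional sex label per individual.
#' @param aligned logical; `TRUE` once configurations have been superimposed.
#' @param centroid_size numeric vector of original centroid sizes (filled in
#'   by [procrustes_align()]).
#' @return an object of class `landmark_set`.
#' @export
landmark_set <- function(coords, population, sex = NULL, aligned = FALSE,
                         centroid_size = NULL) {
  if (length(dim(coords)) != 3L || dim(coords)[3] != 2L)
    stop("coords must be an individuals x landmarks x 2 array")
  if (dim(coords)[1] != length(population))
    stop("one population label per configuration is required")
  population <- as.character(population)
  if (is.null(sex)) sex <- rep(NA_character_, dim(coords)[1])
  structure(list(coords = coords, population = population,
                 sex = as.character(sex), aligned = isTRUE(aligned),
                 centroid_size = centroid_size),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("Landmark set: %d configurations, %d landmarks x 2 (%s)\n",
              dim(x$coords)[1], dim(x$coords)[2],
              if (x$aligned) "aligned" else "raw"))
  invisible(x)
}

#' Diploid multilocus genotype matrix
#'
#' Alleles are integer codes (microsatellite lengths in bp); `0` marks a
#' missing allele. Genotypes with a single missing allele are coerced to
#' fully missing with a warning, since one observed allele of a diploid
#' genotype cannot be used in frequency estimation without bias.
#'
#' @param alleles integer array individuals x loci x 2 (allele codes, 0 =
#'   missing) or a matrix with two adjacent columns per locus.
#' @param population population label per individual.
#' @param loci optional locus names.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(alleles, population, loci = NULL) {
  if (is.matrix(alleles)) {
    if (ncol(alleles) %% 2 != 0) stop("matrix input needs two columns per locus")
    L <- ncol(alleles) / 2
    a <- array(0L, dim = c(nrow(alleles), L, 2))
    a[, , 1] <- as.integer(alleles[, 2 * seq_len(L) - 1])
    a[, , 2] <- as.integer(alleles[, 2 * seq_len(L)])
    alleles <- a
  }
  if (length(dim(alleles)) != 3L || dim(alleles)[3] != 2L)
    stop("alleles must be individuals x loci x 2")
  if (any(alleles < 0)) stop("allele codes must be non-negative (0 = missing)")
  half <- xor(alleles[, , 1, drop = FALSE] == 0L, alleles[, , 2, drop = FALSE] == 0L)
  if (any(half)) {
    warning("genotypes with a single missing allele coerced to fully missing")
    idx <- which(half[, , 1], arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) alleles[idx[r, 1], idx[r, 2], ] <- 0L
  }
  if (is.null(loci)) loci <- paste0("locus", seq_len(dim(alleles)[2]))
  if (dim(alleles)[1] != length(population))
    stop("one population label per individual is required")
  structure(list(alleles = alleles, population = as.character(population),
                 loci = loci),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d diploids x %d loci, %d populations\n",
              dim(x$alleles)[1], dim(x$alleles)[2],
              length(unique(x$population))))
  invisible(x)
}

#' Aligned haplotype sequences
#'
#' @param seqs character vector of equal-length aligned sequences over
#'   `A,C,G,T,N,-` (case-insensitive).
#' @param population population label per sequence.
#' @return an object of class `haplotype_alignment`.
#' @export
haplotype_alignment <- function(seqs, population) {
  seqs <- toupper(as.character(seqs))
  if (length(unique(nchar(seqs))) != 1L)
    stop("sequences must be aligned to equal length")
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad)) stop("sequences contain characters outside A,C,G,T,N,-")
  if (length(seqs) != length(population))
    stop("one population label per sequence is required")
  structure(list(seqs = seqs, population = as.character(population),
                 length = nchar(seqs[1])),
            class = "haplotype_alignment")
}

#' @export
print.haplotype_alignment <- function(x, ...) {
  cat(sprintf("Haplotype alignment: %d sequences of %d bp, %d populations\n",
              length(x$seqs), x$length, length(unique(x$population))))
  invisible(x)
}

#' Labelled pairwise distance matrix among populations
#'
#' @param d symmetric, zero-diagonal, non-negative numeric matrix.
#' @param labels population labels (defaults to `rownames(d)`).
#' @param kind one of "phenotypic", "genetic", "environmental", "geographic".
#' @return a numeric matrix of class `pop_dist` with a `kind` attribute.
#' @export
pop_dist <- function(d, labels = rownames(d),
                     kind = c("phenotypic", "genetic", "environmental",
                              "geographic")) {
  kind <- match.arg(kind)
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (is.null(labels)) labels <- paste0("pop", seq_len(nrow(d)))
  if (max(abs(d - t(d)), na.rm = TRUE) > 1e-8) stop("distance matrix must be symmetric")
  diag(d) <- 0
  dimnames(d) <- list(labels, labels)
  structure(d, class = c("pop_dist", "matrix", "array"), kind = kind)
}

#' @export
print.pop_dist <- function(x, ...) {
  cat(sprintf("%s distance matrix among %d populations\n",
              tools::toTitleCase(attr(x, "kind")), nrow(x)))
  print(round(unclass(x)[, , drop = FALSE], 4))
  invisible(x)
}

# internal: strict lower-triangle pairs of a pop_dist, in (i < j) order
.pair_index <- function(n) {
  ij <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  ij[order(ij[, 2], ij[, 1]), c(2, 1), drop = FALSE] # (i, j) with i < j
}
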