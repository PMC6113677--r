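# Delimited-text readers and writers for the study's file formats: trait
# tables (id, population, sex, traits), landmark tables (id, population,
# sex, X1,Y1,...,X24,Y24), two-columns-per-locus genotype tables (0 =
# missing), FASTA haplotypes with the population in a header field, and
# population tables (coordinates + environmental covariates).

#' Read and write individual trait tables
#'
#' Layout: columns `id`, `population`, `sex`, then one column per trait.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return [trait_matrix()] for the reader; `path` invisibly for the writer.
#' @export
read_traits <- function(path, sep = "\t") {
  d <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                         stringsAsFactors = FALSE)
  need <- c("id", "population", "sex")
  if (!all(need %in% names(d)))
    stop("trait table must have columns id, population, sex")
  v <- as.matrix(d[, setdiff(names(d), need), drop = FALSE])
  rownames(v) <- d$id
  trait_matrix(v, d$population, d$sex)
}

#' @param traits a [trait_matrix()].
#' @rdname read_traits
#' @export
write_traits <- function(traits, path, sep = "\t") {
  d <- data.frame(id = if (is.null(rownames(traits$values)))
    seq_len(nrow(traits$values)) else rownames(traits$values),
    population = traits$population, sex = traits$sex,
    traits$values, check.names = FALSE)
  utils::write.table(d, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write landmark tables
#'
#' Layout: `id`, `population`, `sex`, then interleaved coordinate columns
#' `X1,Y1,...,Xk,Yk`.
#'
#' @inheritParams read_traits
#' @param aligned whether the stored coordinates are already superimposed.
#' @return [landmark_set()] for the reader; `path` invisibly for the writer.
#' @export
read_landmarks <- function(path, sep = "\t", aligned = FALSE) {
  d <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                         stringsAsFactors = FALSE)
  xc <- grep("^X[0-9]+$", names(d)); yc <- grep("^Y[0-9]+$", names(d))
  if (length(xc) == 0 || length(xc) != length(yc))
    stop("landmark table needs matched X1..Xk / Y1..Yk columns")
  k <- length(xc)
  co <- array(NA_real_, c(nrow(d), k, 2))
  co[, , 1] <- as.matrix(d[, paste0("X", seq_len(k))])
  co[, , 2] <- as.matrix(d[, paste0("Y", seq_len(k))])
  landmark_set(co, d$population, d$sex, aligned = aligned)
}

#' @param landmarks a [landmark_set()].
#' @rdname read_landmarks
#' @export
write_landmarks <- function(landmarks, path, sep = "\t") {
  m <- .flatten_landmarks(landmarks)
  d <- data.frame(id = seq_len(nrow(m)), population = landmarks$population,
                  sex = landmarks$sex, m, check.names = FALSE)
  utils::write.table(d, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write multilocus genotype tables
#'
#' Layout: `id`, `population`, then two adjacent columns per locus
#' (`locus.a`, `locus.b`) holding allele codes; `0` marks missing data.
#'
#' @inheritParams read_traits
#' @return [genotype_matrix()] for the reader; `path` invisibly for the
#'   writer.
#' @export
read_genotypes <- function(path, sep = "\t") {
  d <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                         stringsAsFactors = FALSE)
  need <- c("id", "population")
  if (!all(need %in% names(d)))
    stop("genotype table must have columns id and population")
  cols <- setdiff(names(d), need)
  if (length(cols) %% 2 != 0) stop("two allele columns per locus are required")
  loci <- unique(sub("\\.[ab]$", "", cols))
  genotype_matrix(as.matrix(d[, cols]), d$population, loci = loci)
}

#' @param G a [genotype_matrix()].
#' @rdname read_genotypes
#' @export
write_genotypes <- function(G, path, sep = "\t") {
  L <- dim(G$alleles)[2]
  m <- matrix(0L, dim(G$alleles)[1], 2 * L)
  m[, seq(1, 2 * L, 2)] <- G$alleles[, , 1]
  m[, seq(2, 2 * L, 2)] <- G$alleles[, , 2]
  colnames(m) <- as.vector(rbind(paste0(G$loci, ".a"), paste0(G$loci, ".b")))
  d <- data.frame(id = seq_len(nrow(m)), population = G$population, m,
                  check.names = FALSE)
  utils::write.table(d, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write haplotype alignments as FASTA
#'
#' Population labels live in a `|`-separated header field
#' (default `>id|population`).
#'
#' @inheritParams read_traits
#' @param field which `|`-separated header field holds the population label.
#' @return [haplotype_alignment()] for the reader; `path` invisibly for the
#'   writer.
#' @export
read_haplotypes <- function(path, field = 2) {
  dna <- ape::read.FASTA(path)
  seqs <- vapply(as.character(dna), paste, character(1), collapse = "")
  pops <- vapply(strsplit(names(dna), "|", fixed = TRUE), function(f) {
    if (length(f) < field) stop("FASTA header lacks population field: ", f[1])
    f[field]
  }, character(1))
  haplotype_alignment(toupper(seqs), pops)
}

#' @param H a [haplotype_alignment()].
#' @rdname read_haplotypes
#' @export
write_haplotypes <- function(H, path) {
  ids <- sprintf("seq%03d|%s", seq_along(H$seqs), H$population)
  dna <- ape::as.DNAbin(lapply(stats::setNames(H$seqs, ids), function(s)
    strsplit(tolower(s), "")[[1]]))
  ape::write.FASTA(dna, path)
  invisible(path)
}

#' Read and write population tables
#'
#' Layout: `population`, `x`, `y`, then environmental covariates.
#'
#' @inheritParams read_traits
#' @return data.frame of class `pop_table` for the reader; `path` invisibly
#'   for the writer.
#' @export
read_pop_table <- function(path, sep = "\t") {
  d <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (!all(c("population", "x", "y") %in% names(d)))
    stop("population table must have columns population, x, y")
  class(d) <- c("pop_table", "data.frame")
  d
}

#' @param populations a `pop_table` data.frame.
#' @rdname read_pop_table
#' @export
write_pop_table <- function(populations, path, sep = "\t") {
  utils::write.table(populations, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a pairwise distance matrix with labelled headers
#'
#' @param d a [pop_dist()] matrix.
#' @param path output file.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_dist_matrix <- function(d, path, sep = "\t") {
  utils::write.table(data.frame(population = rownames(d), as.matrix(d),
                                check.names = FALSE),
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write all components of a synthetic study to a directory
#'
#' Emits the same formats the readers consume: `traits.tsv`,
#' `landmarks.tsv`, `genotypes.tsv`, `haplotypes.fasta`, `populations.tsv`.
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_traits(study$traits, file.path(dir, "traits.tsv"))
  write_landmarks(study$landmarks, file.path(dir, "landmarks.tsv"))
  write_genotypes(study$genotypes, file.path(dir, "genotypes.tsv"))
  write_haplotypes(study$haplotypes, file.path(dir, "haplotypes.fasta"))
  write_pop_table(study$populations, file.path(dir, "populations.tsv"))
  invisible(dir)
}

#' Geographic distance matrix among populations
#'
#' Euclidean distance for projected (km) coordinates, or great-circle
#' (haversine, km) distance when coordinates are longitude/latitude degrees.
#'
#' @param populations a `pop_table` with `x`, `y` columns.
#' @param method `"euclidean"` or `"greatcircle"`.
#' @return a geographic [pop_dist()] matrix.
#' @export
geographic_distance <- function(populations,
                                method = c("euclidean", "greatcircle")) {
  method <- match.arg(method)
  xy <- as.matrix(populations[, c("x", "y")])
  if (method == "euclidean") {
    d <- as.matrix(stats::dist(xy))
  } else {
    rad <- pi / 180
    lon <- xy[, 1] * rad; lat <- xy[, 2] * rad
    n <- nrow(xy)
    d <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      a <- sin((lat[j] - lat[i]) / 2)^2 +
        cos(lat[i]) * cos(lat[j]) * sin((lon[j] - lon[i]) / 2)^2
      d[i, j] <- 2 * 6371.0088 * asin(min(1, sqrt(a)))
    }
  }
  pop_dist(d, labels = populations$population, kind = "geographic")
}
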