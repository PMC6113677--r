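# End-to-end orchestration: from a synthetic study (or ingested files) to
# the full result bundle — preprocessing, concordance tests, diversity and
# divergence, genetic summaries, spatial GLS screens, GDM selection, and
# kriged surfaces — reproducible from a single seed.

#' Assemble a study from input files
#'
#' Reads the delimited trait, landmark, genotype, population tables and the
#' FASTA haplotypes written by [write_study()] (the layouts described in the
#' readers), checking that population labels are consistent across
#' components.
#'
#' @param dir directory holding `traits.tsv`, `landmarks.tsv`,
#'   `genotypes.tsv`, `haplotypes.fasta`, `populations.tsv`.
#' @return a list of class `synthetic_study` (without a `truth` element).
#' @export
read_study <- function(dir) {
  study <- list(traits = read_traits(file.path(dir, "traits.tsv")),
                landmarks = read_landmarks(file.path(dir, "landmarks.tsv")),
                genotypes = read_genotypes(file.path(dir, "genotypes.tsv")),
                haplotypes = read_haplotypes(file.path(dir, "haplotypes.fasta")),
                populations = read_pop_table(file.path(dir, "populations.tsv")))
  pops <- study$populations$population
  offenders <- character(0)
  for (comp in c("traits", "landmarks", "genotypes", "haplotypes")) {
    extra <- setdiff(unique(study[[comp]]$population), pops)
    if (length(extra))
      offenders <- c(offenders, paste0(comp, ": ", paste(extra, collapse = ",")))
  }
  if (length(offenders))
    stop("population labels not in the population table — ",
         paste(offenders, collapse = "; "))
  class(study) <- "synthetic_study"
  study
}

#' Run the full analysis pipeline on a study
#'
#' Per trait block (biometry-derived size and shape, head shape, scalation):
#' sex-mean-centering, size/shape decomposition of biometry, Procrustes
#' superimposition of landmarks, hierarchical-concordance angle tests for
#' the multivariate blocks, within-population diversity (mean distance to
#' centroid) with a spatial GLS screen against genetic-diversity and
#' environmental predictors, among-population divergence with GDM backward
#' selection against genetic, environmental, and geographic predictors, and
#' kriged diversity/divergence surfaces.
#'
#' @param study a `synthetic_study` (from [simulate_study()] or
#'   [read_study()]).
#' @param n_perm_angle permutations for the concordance test.
#' @param n_perm_gdm permutations per GDM significance assessment.
#' @param alpha significance level used throughout.
#' @param seed integer seed controlling all permutation streams.
#' @param grid kriging grid specification (see [krige()]).
#' @param krige_surfaces logical; compute kriged surfaces (the slowest
#'   stage).
#' @param geo_method geographic distance method (see
#'   [geographic_distance()]).
#' @param out_dir optional directory; if given, tabular results are written
#'   as delimited text alongside a plain-text manifest.
#' @return a list of class `study_results` with elements `concordance`,
#'   `diversity`, `divergence`, `genetics`, `gls`, `gdm`, `surfaces`,
#'   `manifest`.
#' @export
run_study <- function(study, n_perm_angle = 999, n_perm_gdm = 200,
                      alpha = 0.05, seed = 1, grid = list(nx = 15, ny = 15),
                      krige_surfaces = TRUE,
                      geo_method = c("euclidean", "greatcircle"),
                      out_dir = NULL) {
  stopifnot(inherits(study, "synthetic_study"))
  geo_method <- match.arg(geo_method)
  seed <- as.integer(seed)

  # --- preprocessing ---------------------------------------------------
  biom_cols <- intersect(biometry_traits(), colnames(study$traits$values))
  scal_cols <- intersect(scalation_traits(), colnames(study$traits$values))
  biom <- trait_matrix(study$traits$values[, biom_cols, drop = FALSE],
                       study$traits$population, study$traits$sex, "biometry")
  scal <- trait_matrix(study$traits$values[, scal_cols, drop = FALSE],
                       study$traits$population, study$traits$sex, "scalation")
  biom_c <- sex_center(biom)
  scal_c <- sex_center(scal)
  ss <- size_shape_decompose(biom_c)
  aligned <- procrustes_align(study$landmarks)
  head_c <- sex_center(trait_matrix(.flatten_landmarks(aligned),
                                    aligned$population, aligned$sex,
                                    "headshape"))
  pop <- study$traits$population
  blocks <- list(size = matrix(ss$size, ncol = 1,
                               dimnames = list(NULL, "size")),
                 shape = ss$shape, headshape = head_c$values,
                 scalation = scal_c$values)

  # --- concordance of principal axes (multivariate blocks) -------------
  concord <- list(
    biometry = angle_permutation_test(biom_c$values, pop, n_perm_angle,
                                      seed = seed + 11L),
    scalation = angle_permutation_test(scal_c$values, pop, n_perm_angle,
                                       seed = seed + 12L),
    headshape = angle_permutation_test(head_c$values, pop, n_perm_angle,
                                       seed = seed + 13L))

  # --- diversity and divergence per block ------------------------------
  diversity <- lapply(blocks, mean_distance_to_centroid, population = pop)
  divergence <- lapply(blocks, pairwise_divergence, population = pop)

  # --- genetic summaries ----------------------------------------------
  msat <- msat_diversity(study$genotypes)
  mt <- mtdna_diversity(study$haplotypes)
  fst_msat <- wc_fst(study$genotypes)
  genD <- cse_chord_distance(study$genotypes,
                             null_correction = any(study$genotypes$alleles == 0L))
  hud <- dxy_and_hudson_fst(study$haplotypes)
  genetics <- list(msat = msat, mtdna = mt, fst_msat = fst_msat, genD = genD,
                   dxy = hud$dxy, fst_mt = hud$fst_mt)

  # --- GLS screen of within-population diversity ----------------------
  popt <- study$populations
  ord <- match(popt$population, msat$population)
  env_cols <- grep("^env", names(popt), value = TRUE)
  predictors <- data.frame(Hexp = msat$Hexp[ord], Na = msat$Na[ord],
                           Hd = mt$Hd[match(popt$population, mt$population)],
                           pi = mt$pi[match(popt$population, mt$population)],
                           popt[, env_cols, drop = FALSE])
  coords <- as.matrix(popt[, c("x", "y")])
  responses <- lapply(diversity, function(v)
    v[match(popt$population, names(v))])
  gls <- select_structure_and_screen(responses, predictors, coords, alpha)

  # --- GDM of among-population divergence ------------------------------
  geo <- geographic_distance(popt, geo_method)
  env_scalars <- as.list(popt[, env_cols, drop = FALSE])
  gdm_predictors <- c(list(fst_msat = fst_msat, genD = genD,
                           fst_mt = hud$fst_mt, dxy = hud$dxy,
                           geographic = geo), env_scalars)
  gdm_predictors <- Filter(function(p) !anyNA(as.matrix(p)), gdm_predictors)
  plabels <- popt$population
  gdm <- list()
  for (bl in names(divergence)) {
    d <- as.matrix(divergence[[bl]])[plabels, plabels]
    spt <- site_pair_table(pop_dist(d, plabels, "phenotypic"), gdm_predictors)
    gdm[[bl]] <- gdm_backward_select(spt, alpha, n_perm_gdm,
                                     seed = seed + 100L + match(bl, names(divergence)))
  }

  # --- kriged surfaces --------------------------------------------------
  surfaces <- NULL
  if (krige_surfaces) {
    surfaces <- list(
      diversity = lapply(responses, function(v) krige(v, coords, grid = grid)),
      divergence = lapply(divergence, function(D) {
        d <- as.matrix(D)[plabels, plabels]
        krige_divergence(pop_dist(d, plabels, "phenotypic"), coords, grid)
      }))
  }

  manifest <- list(seed = seed, n_perm_angle = n_perm_angle,
                   n_perm_gdm = n_perm_gdm, alpha = alpha,
                   geo_method = geo_method,
                   n_pops = nrow(popt), n_individuals = nrow(study$traits$values),
                   timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  out <- list(concordance = concord, diversity = diversity,
              divergence = divergence, genetics = genetics, gls = gls,
              gdm = gdm, surfaces = surfaces, size_shape = ss,
              aligned_landmarks = aligned, manifest = manifest)
  class(out) <- "study_results"
  if (!is.null(out_dir)) .write_results(out, out_dir)
  out
}

#' @export
print.study_results <- function(x, ...) {
  cat("Study results\n-------------\n")
  cat("Concordance of principal axes:\n")
  for (bl in names(x$concordance))
    cat(sprintf("  %-10s theta = %5.1f deg, p = %.3f\n", bl,
                x$concordance[[bl]]$theta_obs, x$concordance[[bl]]$p_value))
  cat(sprintf("Significant GLS associations: %d of %d screened\n",
              sum(x$gls$significant), nrow(x$gls)))
  cat("GDM final models:\n")
  for (bl in names(x$gdm)) {
    m <- x$gdm[[bl]]
    cat(sprintf("  %-10s %%expl = %5.2f, p = %.3f, retained: %s\n", bl,
                m$deviance_explained, if (is.null(m$model_p)) NA else m$model_p,
                if (length(m$importance)) paste(names(m$importance), collapse = ", ")
                else "(none)"))
  }
  invisible(x)
}

#' Tabular summary of GDM final models across trait blocks
#'
#' One row per trait block: percent deviance explained, model p, and the
#' retained predictors with their importance — the shape of a final-model
#' report table.
#'
#' @param results a `study_results` object.
#' @return data.frame.
#' @export
gdm_report <- function(results) {
  rows <- lapply(names(results$gdm), function(bl) {
    m <- results$gdm[[bl]]
    data.frame(block = bl,
               pct_explained = round(m$deviance_explained, 2),
               model_p = if (is.null(m$model_p)) NA_real_ else m$model_p,
               retained = if (length(m$importance))
                 paste(sprintf("%s=%.3f", names(m$importance), m$importance),
                       collapse = "; ") else "")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.write_results <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(results$gls, file.path(dir, "gls_screen.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(gdm_report(results), file.path(dir, "gdm_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  conc <- do.call(rbind, lapply(names(results$concordance), function(bl) {
    a <- results$concordance[[bl]]
    data.frame(block = bl, theta = a$theta_obs, p = a$p_value,
               n_perm = a$n_perm)
  }))
  utils::write.table(conc, file.path(dir, "concordance.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  div <- do.call(rbind, lapply(names(results$diversity), function(bl)
    data.frame(block = bl, population = names(results$diversity[[bl]]),
               diversity = as.numeric(results$diversity[[bl]]))))
  utils::write.table(div, file.path(dir, "diversity.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (bl in names(results$divergence))
    write_dist_matrix(results$divergence[[bl]],
                      file.path(dir, paste0("divergence_", bl, ".tsv")))
  writeLines(c("manifest",
               paste(names(results$manifest),
                     vapply(results$manifest, as.character, character(1)),
                     sep = "\t")),
             file.path(dir, "manifest.txt"))
  invisible(dir)
}
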