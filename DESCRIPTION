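Package: morphodiv
Title: Phenotypic Diversity Within and Divergence Among Populations in a
    Geographic Framework
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for linking morphological variation of natural
    populations to genetic and environmental factors across hierarchical
    levels. Implements sex-mean-centering and size/shape decomposition of
    biometric traits, generalized Procrustes superimposition of 2D
    landmark configurations, morphological disparity (mean distance to
    the population centroid) and among-population divergence matrices, a
    residual-permutation test for the angle between individual-level and
    population-level principal axes, microsatellite and mtDNA summary
    statistics (allelic richness, expected heterozygosity, Weir-Cockerham
    theta, Cavalli-Sforza & Edwards chord distance with null-allele
    correction, haplotype and nucleotide diversity, Dxy, Hudson's Fst),
    spatially-correlated generalized least squares screens with AIC-based
    selection among four correlation structures, generalized
    dissimilarity modelling with monotone I-splines and permutation-based
    backward selection, and ordinary kriging of diversity and divergence
    surfaces with leave-one-out accuracy screening. A synthetic-study
    generator with known truth supports power analysis and end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    nlme,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
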