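---
title: "Linking phenotypic diversity and divergence to genetic and environmental variation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking phenotypic diversity and divergence to genetic and environmental variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphodiv)
```

## The problem

Phenotypic variation in natural populations can be described at two nested
hierarchical levels: *diversity within* populations (how much individuals of
one population differ from each other) and *divergence among* populations
(how much population averages differ from each other). Whether these two
levels follow the same structure, whether either is geographically
organised, and which genetic and environmental factors predict each of them
are distinct questions requiring distinct statistics. `morphodiv`
implements a complete analysis chain for a classic field design — a handful
of populations (order 10), a few dozen adults of both sexes per population,
linear biometric measurements, meristic scale counts, 2D head landmarks,
microsatellite genotypes, and an mtDNA fragment — together with a synthetic
generator so every stage can be exercised and validated against known
truth.

## Trait preprocessing

**Sex-mean-centering** (`sex_center`). Wall lizards and many other taxa are
strongly sexually dimorphic; pooling sexes without adjustment would let
dimorphism masquerade as within-population diversity. Every trait is
centered on its sex-specific mean, which sets both sex means to zero while
leaving contrasts among same-sex individuals untouched. The operation is
idempotent.

**Size/shape decomposition** (`size_shape_decompose`). A PCA of the
covariance matrix (not the correlation matrix: the biometric traits share
units, mm, and the interpretation of PC1 rests on equal-sign loadings) of
sex-centered biometry. PC1 is oriented so its loadings sum positive —
larger animals score higher — and is treated as *body size*; PCs 2..7 form
a multivariate, size-corrected *body shape*. No log transformation is
applied. Rank-deficient inputs are truncated with a warning.

**Procrustes superimposition** (`procrustes_align`). Raw landmark
configurations carry arbitrary digitising position, orientation, and scale.
Generalized Procrustes analysis removes them: translate to zero centroid,
scale to unit centroid size, and iteratively rotate to the mean shape until
the mean moves by less than 1e-8 (root summed squares; cap 100 iterations,
reflections disallowed). Downstream analyses use the flattened aligned
(tangent-space) coordinates directly; no sliding semilandmarks are
involved. Aligned head coordinates are sex-mean-centered like the other
blocks.

**Diversity and divergence** (`mean_distance_to_centroid`,
`pairwise_divergence`). Diversity is the mean Euclidean distance of
individuals to their population centroid, computed per trait block;
populations with fewer than 3 individuals are excluded (the distance to the
centroid of n ≤ 2 is degenerate). Divergence is the Euclidean distance
between population mean vectors — absolute mean difference for the
univariate body-size block. Head-shape population means are arithmetic
means of aligned coordinates.

## Concordance of principal axes across levels

`pc1_angle` measures the angle θ = arccos |v₁·v₂| between the first
eigenvector of the individual-level covariance and the first eigenvector of
the covariance of population means; the absolute dot product makes the
statistic invariant to eigenvector sign, so θ ∈ [0°, 90°].

`angle_permutation_test` asks whether θ is *larger than expected at
random*, i.e. whether divergence is directionally decoupled from individual
variation. The null model treats among-population divergence as nothing but
sampling noise of the pooled within-population variation: population-
centered residuals are permuted as units across all individuals (hence
across populations, ignoring sex), pseudo-population means are the group
means of the permuted residuals, and the permuted angle θ\* is taken
between the first principal axis of the pooled residuals and that of the
pseudo-means. The one-sided p-value uses the add-one rule
p = (1 + #{θ\* ≥ θ_obs}) / (1 + n_perm), so it is never exactly zero.

This construction was a genuinely open design point: a superficially
similar scheme — adding the permuted residuals back onto the observed
population means and recomputing both PCAs — leaves both covariance
matrices essentially unchanged whenever real divergence exceeds the
sampling noise of a population mean, so its p-values pile up near 0.5 and
the test has no power at any angle. The implemented null is the one that
is simultaneously (a) built from permuted population-centered residuals,
(b) calibrated (simulated type-I error 0.045–0.06 at α = 0.05 under the
exchangeable null), and (c) powerful against discordant divergence while
conservative for concordant divergence, which is the behaviour a
discordance test must have. The default `n_perm = 999`; fewer than 99
permutations triggers a coarse-resolution warning.

## Genetic summaries

Microsatellites (allele codes = fragment lengths in bp, 0 = missing;
half-missing genotypes are coerced to fully missing):

* `msat_diversity`: Na (alleles per locus, averaged over loci) and unbiased
  expected heterozygosity Hexp = (2n/(2n−1))(1 − Σp²) per locus, averaged.
* `wc_fst` / `wc_theta_global`: Weir–Cockerham θ from the standard
  a/b/c variance-components decomposition, combined as a ratio of sums
  across loci and alleles. Pairwise estimates may be slightly negative;
  monomorphic pairs are undefined (`NA` with warning).
* `cse_chord_distance`: Cavalli-Sforza & Edwards chord distance
  (2/π)√(2(1 − Σ√(p₁p₂))) per locus, averaged. With
  `null_correction = TRUE`, per-population, per-locus null-allele
  frequencies are first estimated by a Dempster-type EM on apparent
  homozygote excess and blank genotypes, and the estimated null enters the
  chord computation as an additional shared allele state (the INA
  convention). The correction used in the original field study is not
  published; this EM/INA choice is a documented stand-in.

mtDNA (aligned sequences; sites with N or a gap in either member of a pair
are excluded pairwise — with a 623 bp fragment, per-pair information is too
precious for complete deletion):

* `mtdna_diversity`: haplotype diversity Hd = (n/(n−1))(1 − Σh²) and
  nucleotide diversity π (mean per-site pairwise difference).
* `dxy_and_hudson_fst`: Dxy (mean per-site difference over between-
  population pairs) and Hudson's Fst = 1 − Hw/Hb, with Hw the *simple
  average* of the two within-population means — the most common reading of
  the 1992 estimator.

## Spatial GLS screen for within-population diversity

Diversity values at ~9 sites are few and spatially structured, so each
candidate predictor (genetic diversity, environmental covariates) is
screened in a *single-predictor* generalized least squares with spatially
correlated errors — deliberately pairwise, to avoid confounding
interactions among predictors, and deliberately uncorrected for multiple
testing, matching the screening character of the analysis. Four correlation
structures are fitted: linear max(0, 1 − d/ρ), exponential exp(−d/ρ),
gaussian exp(−(d/ρ)²), and rational quadratic 1/(1 + (d/ρ)²). For each, the
range ρ is profiled by a bounded deterministic 1-D search over
(ε, 3·max distance) with closed-form GLS coefficients and σ̂² = RSSΣ/n at
each candidate; estimation is ML (not REML) so AIC (−2ℓ + 2k, k = 4) is
comparable across structures, and the lowest-AIC structure is kept per
pair. No nugget parameter is included. Slope significance is a Wald t with
n − 2 df (SE from the unbiased RSSΣ/(n−2)); effect strength is reported as
the raw Pearson correlation. The profile-ML fit reproduces
`nlme::gls(..., method = "ML", correlation = corExp(...))` to numerical
precision, which the test suite checks.

## Generalized dissimilarity modelling of divergence

Divergence is a matrix of pairwise distances, so ordinary regression does
not apply. GDM regresses the response dissimilarity d_ij — scaled to
[0, 1) by dividing by 1.01 × max, a required departure since Euclidean
distances are unbounded while the link's codomain is [0, 1) — on monotone
transforms of the predictors through the negative-exponential link
μ = 1 − exp(−η), with

η = β₀ + Σ_pred Σ_k β_k I_k(·), all β ≥ 0.

The I_k are three order-2 (piecewise-quadratic) monotone I-splines per
predictor with knots at the 0/50/100th percentiles of the observed values.
Matrix predictors (Fst, genD, Dxy, geographic distance) are splined on
their pairwise value; scalar predictors (environmental variables)
contribute |I_k(x_i) − I_k(x_j)|. Non-negativity of the coefficients makes
every partial response curve non-decreasing, and the summed coefficients of
a predictor equal the maximum height of its response curve — the
*importance* reported in the final tables. Coefficients minimise a
binomial-type deviance (convex in the coefficients under this link, so the
box-constrained L-BFGS-B solution is global); % explained is
100(1 − D_model/D_null), the deviance convention.

Significance is by Monte Carlo permutation of population identities
(rebuild the site-pair table, refit; add-one p on deviance explained ≥
observed), whole-model and per-predictor (permuting only that predictor's
site assignment). `gdm_backward_select` iteratively removes zero-importance
predictors and the largest non-significant p until all retained predictors
are significant at α = 0.05 (default `n_perm = 500`; neither value is
prescribed by the field study, both are configurable). An all-null run
returns the intercept-only model reported as 0.00 % explained with p = 1 —
the "no significant model" pattern.

## Kriged surfaces

The geographic structure of diversity (one value per site) and of
divergence (per focal population, its distances to all others) is
visualised by ordinary kriging: an empirical semivariogram (≥ 4 equal-width
bins to 2/3 of the maximum distance) is fitted by pair-count-weighted least
squares with spherical, exponential, and gaussian candidates (best residual
SS wins), and predictions solve the OK system with the unbiasedness
constraint (weights sum to 1 at every node; checked to 1e−8 in tests; a
near-flat variogram triggers a graduated diagonal ridge with a warning
rather than a hard failure). Surfaces are screened by leave-one-out
accuracy: a surface is *accurate* if the LOO Pearson r is at least 0.5
(configurable) and the surface is not flat. With ~9 sites this screening is
deliberately blunt — the honest message of a noisy field design — and the
reported quantity is the *count* of accurate focal surfaces. The original
study interpolated in a GIS with unpublished settings; this module is a
declared reimplementation with explicit, testable criteria, not an
inference of those settings.

## The synthetic generator

`simulate_study` produces a complete study from a single seed
(`simulation_config`), with defaults chosen to emulate the field design:

| parameter | default | meaning |
|---|---|---|
| `n_pops`, `n_per_pop` | 9, 30 | populations × adults of both sexes |
| `extent` | 100 km | square landscape, projected km |
| `env_range` | 30 km | exponential GP range of each of 6 env variables |
| `size_sd` | 4 mm | SD of the latent size factor (SVL scale) |
| `sex_effect` | 3 mm | male–female offset along the size loadings |
| `env_effect` | 1.5 | slope of population means on env1/env2/env3 |
| `within_cov_scale` | 1 | multiplier of within-population covariance |
| `n_loci`, `n_alleles` | 9, 8 | microsatellite panel |
| `fst_target` | 0.2 | island-model drift parameter |
| `null_allele_rate` | 0 | per-copy amplification failure |
| `mtdna_theta` | 0.01 | per-site star-tree branch mutation parameter |
| `mtdna_length` | 623 bp | alignment length |

Biometric baselines (SVL 55 mm, trunk 28, head 14/8.2/5.8, limbs 18/28.5)
and within-population noise (3.5 % of baseline) are realistic for small
lacertids; size loadings are proportional to baselines, so the latent
factor induces the dominant, equal-sign PC1 observed in real biometry
(share ≈ 85–90 % at the defaults). Scale counts are rounded Gaussians —
matching their treatment as continuous traits — not Poisson. Landmark
configurations perturb a fixed head outline with isotropic shape-space
noise of small variance (so Procrustes distances ≈ Euclidean distances on
aligned coordinates and oracles stay tractable) and are then randomly
rotated, translated, and scaled so that superimposition is genuinely
required. The island model draws population allele frequencies from a
Dirichlet with concentration (1 − Fst)/Fst about Dirichlet(1) ancestral
frequencies, chosen because it gives the analytic expectation
Var(p) = p(1−p)·Fst and hence a known truth for θ-recovery tests. The
mtDNA star tree allocates branch substitutions to disjoint sites, so the
separation of two population ancestors is exactly the sum of their branch
counts; within-population singletons use a separate rate
(`mtdna_theta_within`, default `mtdna_theta/5` — the star-tree description
needs this rate but does not fix it, and a 5:1 between:within ratio gives
the strong phylogeographic structure typical of mtDNA).

What the generator does *not* emulate: coalescent genealogies,
recombination, finite-sites homoplasy beyond the star tree, raster
environmental layers (environments are values at sites), allometric
curvature, or measurement error structure. Tests passing on synthetic data
therefore validate the estimators and the inference machinery, not the
biological realism of any particular field system.

## Numerical choices and degenerate inputs

* PCA via `prcomp`; tied leading eigenvalues (relative gap < 1e−10) warn
  that the leading direction is ill-defined.
* GLS: a numerically non-PD correlation matrix is jittered by 1e−10 with a
  warning; a constant response returns slope 0 and Pearson r 0 with a
  warning; a constant predictor is an error.
* GDM: responses are clamped to [1e−9, 1 − 1e−9] inside the deviance;
  constant predictors are an error (no basis definable); duplicate knots
  collapse with a warning.
* Kriging: duplicate coordinates are an error (singular system); the
  graduated ridge (≤ 1e−4 × scale) rescues near-flat variograms.
* All permutation streams are seeded; the same seed reproduces a result
  bundle bit-for-bit.

## Problem sizes used by the validation suite

The test suite and the acceptance script validate on: exact hand-enumerable
configurations (2–5 diploids, 4 bp haplotypes) for every population-genetic
estimator; 100 island-model replicates at 9 × 30 × 9 loci for θ recovery;
200 replicates each for the type-I calibration of the angle test
(n_perm = 99) and the GDM whole-model p (n_perm = 49); 100–300 exponential
fields at n = 50 for GLS (β, ρ) recovery (the range estimator's true mean
bias under these conditions is ≈ −9.6 %, identical to nlme's, inside the
10 % recovery bound but close to it — ML range estimation at n = 50 is
simply noisy and slightly biased); 36 site pairs for GDM self-consistency;
and 20 end-to-end synthetic studies for GDM selection power (the planted
environmental predictor is retained in 100 % of runs at the default effect
size).

## Known limitations

* The GLS screen is single-predictor by design; it ranks candidate factors
  but does not estimate joint effects.
* GDM importance is scale-coupled to the response normalisation; compare
  importances within a model, not across responses.
* With 9 sites, variogram fitting and the LOO accuracy flag are blunt
  instruments; the accurate-surface count should be read qualitatively.
* The null-allele correction is a stand-in for an unpublished procedure
  and is labelled as such.
* Hudson's Fst and Dxy use pairwise deletion; with heavy missingness the
  effective alignment length varies across pairs.

## A minimal run

```{r example, eval = FALSE}
st  <- simulate_study(simulation_config(seed = 7))
res <- run_study(st, n_perm_angle = 199, n_perm_gdm = 99, seed = 7)
print(res)
gdm_report(res)
```
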