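# glygolgi

Antibody N-glycosylation is set in the Golgi: as each glycan transits the
cisternae it meets mannosidases (Man1, Man2), GlcNAc transferases
(Mgat1–5), the core fucosyltransferase Fut8, and galactosyl-/sialyl-
transferases (GalT, SiaT), and the profile of species a cell line secretes
(Man5, G0, G0F, G1F, G2F, ...) reflects those enzymes' activities and
cisternal placement. `glygolgi` is an R package for two complementary
analyses of this system, aimed at bioprocess and systems-biology groups
working on CHO-produced monoclonal antibodies:

1. **Mechanistic fitting.** A Gillespie stochastic simulation pushes
   independent glycans through K cisternae under a 9-enzyme rule set (with
   Fut8's slow action modelled as a temporary hidden "lock" state).
   Per-enzyme activities θ are fitted to an observed glycan profile by
   ABC-MCMC with the square-difference summary
   d(sim, obs) = Σ_g (sim_g − obs_g)², log-uniform priors, a component-wise
   adaptive random walk, and a tolerance annealed to a multiple of the
   summary's Monte-Carlo noise floor. Two fitted conditions are compared
   per enzyme by posterior-median log2-ratios and Mann-Whitney tests on
   per-chain batch medians (BH-adjusted, Gelman-Rubin-gatekept), plus the
   per-cisterna localization of each enzyme's reaction flux.
2. **Predictive multi-omics.** Glycan profiles are clustered (PCA, k-means
   with a WCSS elbow), and cluster membership is predicted from glycogene
   expression at days 0/6/10 of culture via a multi-block sparse PLS
   discriminant model (design matrix from pairwise sPLS component
   correlations, 10-fold cross-validation, one-vs-rest rank AUC), with
   genes selected in ≥ 7/10 folds reported as stable predictors.

The real datasets motivating this design are confidential, so a first-class
synthetic generator reproduces the study structure — two projects with 2
(Man5/G0F) and 3 (G0/G0F/G1F) glycan clusters, duplicate measurements,
three expression blocks sharing one day-15 label, planted marker genes
(Alg5, Man2a1, Man1c1, Slc35a2, St3gal1, ...) — with full ground truth, so
every method here is validated by recovery experiments rather than by eye.

## Worked example

```r
library(glygolgi)

# simulate a glycan profile under the default 4-cisterna enzyme layout
res <- simulate_profile(default_enzyme_params(), n_glycans = 10000, seed = 1)
round(sort(res$profile, decreasing = TRUE)[1:5], 3)
#>     G0F     G1F     G2F Hyb-M5F      G0
#>   0.362   0.213   0.081   0.052   0.045
round(flux_localization(res, "Mgat1"), 2)
#> cisterna1 cisterna2 cisterna3 cisterna4
#>      0.00      0.91      0.09      0.00

# cluster synthetic project-A profiles and recover the planted structure
ds <- make_profiles(project_spec_a(), seed = 3)
sm <- rowsum(ds$profiles, ds$sample_id) / 2
sm <- sm / rowSums(sm)
best_elbow_k(elbow_curve(sm, 6, seed = 1))
#> [1] 2
km <- kmeans_profiles(sm, 2, seed = 1)
mclust::adjustedRandIndex(km$labels, ds$sample_labels[rownames(sm)])
#> [1] 1
```

The first profile is a realistic G0F-dominant antibody pattern produced by
the default parameters; the Mgat1 flux vector says 91% of Mgat1 reactions
happened in cisterna 2 under this layout. The elbow picks k = 2 on project
A, and k-means recovers the planted Man5-vs-G0F clusters exactly
(adjusted Rand index 1).

The `analysis/` directory holds the full study as numbered drivers —
`01_simulate_data.R` (synthetic projects), `02_cluster_profiles.R`,
`03_predict_clusters.R` (tuned block-sPLS-DA + stability selection),
`04_fit_cluster_models.R` (ABC comparison of a galactosylation-elevated,
G1F-like condition against the G0F-dominant baseline), `05_null_and_recovery_checks.R` — each writing
its tables under `results/`. The methods vignette
(`vignettes/glygolgi-methods.Rmd`) documents the model, the numerical
choices and their rationale, and known limitations.

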