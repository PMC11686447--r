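---
title: "Modelling Golgi N-glycan processing and predicting glycan clusters from glycogene expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling Golgi N-glycan processing and predicting glycan clusters from glycogene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glygolgi)
```

## The scientific problem

The N-glycans attached to a therapeutic antibody's Fc region (Man5, G0F,
G1F, ...) are shaped by the enzymes a glycan meets as it transits the Golgi
— which enzymes, at what activity, and in which cisterna.  Two questions
recur in cell-line development: *can the glycan profile a clone will
eventually produce be predicted early from its transcriptome?* and *which
enzyme-level changes explain the difference between two observed glycan
profiles?*  `glygolgi` implements both halves: a stochastic mechanistic
model of glycan processing fitted by likelihood-free inference, and a
multi-block sparse discriminant workflow that predicts glycan-profile
clusters from glycogene expression at three culture time points.  Because
the motivating industrial datasets are confidential, the package ships a
synthetic-data generator that reproduces the *structure* of such a study
(two projects; 2 or 3 glycan clusters dominated by Man5/G0F or G0/G0F/G1F;
duplicate measurements; three expression blocks sharing one day-15 glycan
label; planted differential glycogenes), so every claim the package makes is
testable end to end against known ground truth.

## The glycan state space and reaction rules

A glycan is a composition vector `(man, agn, fuc, gal, sia)` — mannoses
(3–9), antenna GlcNAcs (0–4), core fucose (0/1), galactoses (≤ agn), sialic
acids (≤ gal) — plus a boolean fucosylation lock.  A tree representation is
deliberately not used: capillary-electrophoresis profiles resolve
composition, not arm isomers, so G1F's two isomers are one species.  Nine
rules encode the canonical pathway: Man1 trims Man9→Man5 one mannose at a
time; Mgat1 commits Man5; Man2 removes two mannoses (collapsed into one rule
because no intermediate is ever resolved in a profile); Mgat2/4/5 extend
antennae; GalT and SiaT elaborate them; Fut8 adds core fucose.  Two ordering
constraints are structural invariants, not rate choices: antennae require
prior trimming to Man5, and second antennae require Man2.  Fut8's guard
demands `gal = 0` — once galactosylated, a glycan is no longer a Fut8
substrate — encoding the competition between fucosylation and
galactosylation in the conservative direction.

Fut8 is much slower than the other transferases, and because activity and
concentration are confounded in this model, its slowness is represented
structurally: firing Fut8 places the glycan in a *locked* intermediate state
in which no other rule can act, resolved into `fuc = 1` at an exponential
`lock_resolution_rate`.  A lock still pending when the glycan leaves the
last cisterna is force-resolved so no glycan is lost.  The artefact this
introduces — glycans held inert across cisternae, hence slightly
under-processed — is bounded by a test: as the resolution rate grows, the
lock model's profile converges in total variation to a lock-free model's.

```{r rules}
vapply(default_rules(), function(r) r$enzyme, character(1))
canonical_name(glycan_state(3, 2, 1, 1))   # biantennary, fucosylated, 1 Gal
```

## The stochastic simulator

Each of `n_glycans` (default 10,000) independent glycans enters cisterna 1
as Man9 and spends a fixed residence time in each of K cisternae (default
K = 4, the classical cis/medial/trans/TGN decomposition; the source model
says only "cisternae", plural).  Within a cisterna, events are sampled
exactly by the Gillespie algorithm: each applicable rule's propensity is
that enzyme's activity in that cisterna, waiting times are
Exponential(total propensity), and the firing rule is chosen proportionally.
Independence between glycans (no competition for enzymes or donors) is a
stated simplification.  Time is dimensionless — only products of activity
and residence time are identifiable — so residence time is fixed to 1 during
fitting.  Terminal states aggregate by canonical name into a profile summing
to exactly 1, and per-rule, per-cisterna firing counts are kept: normalising
an enzyme's row gives its *flux localization*, the readout used to compare
where in the Golgi an enzyme acts between two fitted conditions.

The event loop is compiled (Rcpp) because the fitter needs on the order of
10^5 simulations of 10^4 glycans; a readable R implementation of the same
step/transit logic is retained and the two are cross-checked
distributionally in the test suite.  Correctness is anchored to an
independent oracle: on any sub-network the per-glycan process is a finite
continuous-time Markov chain, so the terminal distribution is computable by
matrix exponentials of the cisterna generators; the empirical distribution
at n = 10,000 must match within total-variation 0.02.

The default activity layout was chosen once to produce a realistic
G0F-dominant antibody profile (G0F ≈ 0.37, G1F ≈ 0.21, G2F ≈ 0.08, with
minor Man5/G0/hybrid species) and serves as the base condition for all
synthetic fitting targets.

## Fitting by ABC-MCMC

Enzyme activities are fitted to an observed profile by approximate Bayesian
computation with MCMC.  The summary statistic is the square difference
`sum_g (sim_g - obs_g)^2`, which in practice emphasises dominant species
(only large fractions can carry large absolute errors).  Priors are
independent log-uniform on [1e-2, 1e2] per activity; proposals are a
component-wise random walk on log-activities (one coordinate per iteration —
poorly identified coordinates then sweep their prior range freely, which
mixes far better at tight tolerances than joint proposals); one fresh
simulation is run per proposal, pseudo-marginal style.  With a flat
log-scale prior and symmetric proposal, acceptance reduces to the indicator
that the proposal is inside the prior box and its simulated distance is
within the tolerance.

Three numerical choices deserve explanation because naive versions fail
measurably:

* **Tolerance.**  A fixed quantile of prior-predictive distances is far too
  loose: on the default network the 20th percentile of 200 pilot draws is
  about 0.42 while the distance between a baseline profile and a
  4-fold-perturbed one is only about 0.21 — a tolerance ball containing both
  conditions cannot resolve the contrasts of interest.  Instead, the final
  tolerance is a multiple (`epsilon_floor_factor`) of the summary's
  Monte-Carlo noise floor `2(1 - sum(obs^2))/n_glycans`, the expected square
  difference between two simulations at identical parameters.  The pilot
  phase still supplies over-dispersed start points and the *starting*
  tolerance, which anneals geometrically over the burn-in.  Three details
  of the schedule each guard against a failure mode observed without them:
  the tolerance never drops below 1.05 times the chain's currently achieved
  distance (a strict greedy schedule freezes the chain, while a generous
  slack lets the distance random-walk upward instead of descending); the
  schedule overshoots, targeting a third of the final tolerance, so the
  chain enters the sampling phase comfortably inside the tolerance ball
  rather than balanced on its boundary; and a chain hopelessly behind the
  schedule teleports to the best point it has seen (burn-in only — the
  sampling-phase kernel is untouched).  A chain that still fails to reach
  the final tolerance by the end of burn-in warns and is excluded from
  claims by the comparison gatekeeping.  The default factor trades
  resolution against desk-scale mixing; being a deterministic function of
  the target profile, it also makes tolerances comparable between the two
  fits of a cluster comparison (the ABC posterior depends on the tolerance,
  so comparing fits run at different tolerances confounds the comparison).
* **Chain comparison units.**  Retained samples are thinned (every 10th
  post-burn-in draw), but their integrated autocorrelation time is still
  5–15 thinning units, and a rank test on pooled dependent draws is sharply
  anticonservative — on identical-profile null fits it flagged the majority
  of parameters.  Mann-Whitney comparisons therefore use per-chain batch
  medians (4 batches per chain) as approximately independent observations,
  the batch-means principle.
* **Gatekeeping and multiplicity.**  Cluster comparisons report, per
  parameter, the posterior-median log2-ratio, the batch-median Mann-Whitney
  p, and Benjamini–Hochberg adjustment across parameters; any parameter with
  Gelman-Rubin R-hat above 1.2 in either fit is excluded from claims.  The
  Gelman-Rubin statistic is the classic between/within formulation (two
  copies of one chain give exactly sqrt((n-1)/n)).

The Mann-Whitney test itself enumerates all group assignments exactly when
both samples have at most 8 observations (correct under ties, where the
common exact routines fall back to approximations) and otherwise uses the
tie-corrected normal approximation with continuity correction.

Parameter-recovery experiments use a dedicated benchmark condition
([`recovery_base_params()`] on the core biantennary topology without
Mgat4/Mgat5/SiaT): tied activities chosen so every active enzyme is
*two-sided* identifiable — trimming is incomplete (Man6–Man9 visible) and
Man5, hybrid, G0-GN, G0/G0F and galactosylated species are all populated.
This matters because a parameter constrained from one side only (a trimming
rate beyond which the profile saturates, or a branching enzyme whose
products sit below the tolerance) has a posterior median that wanders with
the prior, and between-fit noise in such medians can exceed a genuine
4-fold shift.  The generating parameters also lie inside the fitted (tied)
model class, so recovery measures estimation, not robustness to
misspecification.

Fitting supports two parameterizations: the full 9 × K activity matrix, and
a tied mode with one activity per enzyme replicated across cisternae.
Recovery experiments and cluster comparisons default to the tied, 9-parameter
model: a terminal profile constrains mainly each enzyme's total opportunity
to act, so per-cisterna activities are only weakly identified from a profile
alone, and enzyme-level comparison is what the cluster-contrast figures
report.  With the full model, the enzyme-level table (activities summed over
cisternae) is reported alongside the per-parameter one.

## Clustering glycan profiles

Duplicate measurements are averaged (and renormalised) before clustering.
PCA is centred and unscaled by default (fractions share units; unit-variance
scaling is an option).  k-means uses Lloyd iterations from k-means++
seedings, best of 10 restarts by WCSS; the elbow curve is additionally
warm-started from the previous k's solution, which makes WCSS non-increasing
in k, and the selected k is the largest relative WCSS drop — overridable,
since an elbow is ultimately a judgement.  Profiles are clustered on raw
fractions (a CLR option exists for compositional rigour, but the field
clusters raw glycan fractions and the package follows).  Clusters are named
by their dominant glycan (Man5 vs G0F; G0/G0F/G1F), matching practice.

## Predicting clusters from expression

Expression preprocessing is `log2(count + 1)`; centring and unit-scaling are
fitted *within training folds only* (leakage-safe).  The multi-block model
is a sparse generalised canonical correlation construction: per component,
block loadings maximise the design-weighted sum of covariances between block
scores, with each expression block also tied to the class-indicator block;
sparsity is a hard threshold retaining the `keepX` largest-|weight| genes
per block, renormalised; blocks deflate on their own scores.  The design
matrix comes from pairwise one-component sPLS between day blocks: absolute
score correlation ≥ 0.8 links the pair with weight 1, otherwise 0.1.
Prediction projects test samples through the training deflations, averages
block scores, and assigns the nearest class centroid; negative distances
serve as class scores for one-vs-rest rank-based AUC (equal to trapezoidal
ROC integration; verified to 1e-9).  Ten-fold cross-validation is stratified
at the biological-sample level so duplicates never straddle folds;
hyperparameters are tuned by nested CV on the balanced error rate with a
one-standard-error preference for sparser models.  Genes selected in ≥ 7 of
10 folds are reported as stable, annotated with the class in which they are
elevated.

One honest caveat, demonstrated by the package's own permutation
experiments: selection *frequency* is not a calibrated null filter.  Ten
training sets sharing 90% of rows rank genes almost identically whatever the
labels, so even label-permuted data yields several "stable" genes (while,
correctly, permuted AUC collapses to 0.5).  The same mechanism inflates false
positives whenever the tuned sparsity exceeds the true signal: surplus
selection slots fill with the dataset's fold-stable bystanders, so a
keepX of 10 around a 5-gene signal yields several non-markers at high
frequency.  Stable-gene lists should be read together with the AUC, not as
significance statements; only heavier subsampling (e.g. 50% stability
selection) would give frequency a null interpretation, and that is outside
this workflow.

## The synthetic-data generator

Profiles: per sample, a cluster is drawn by weight, a sample-level mean from
a Dirichlet centred on the cluster centroid (precision 80–100 — centroids
are stylised templates, e.g. Man5 = 0.50 in the Man5 cluster, not digitised
from any measured figure), and duplicate rows from a tighter Dirichlet
(precision 2000) around that mean.  Expression: negative-binomial counts
(dispersion 0.1) around per-gene log2 baselines in [3, 9], with per-day
shifts, markers adding their log2 effect in their cluster and day, and an
optional sample-level equicorrelated latent factor (default strength 0.1)
inducing inter-gene correlation — the knob to emulate strongly
intercorrelated time points.  Defaults mirror the study scale: 26/27 samples
per project, 2 replicates, 3 days, the 76-gene N-glycosylation panel plus
background genes.  Planted markers follow the biology the workflow should
recover: Alg5 (LLO synthesis, site occupancy, hence competition for
processing) elevated with under-processed clusters at day 0; the UDP-Gal
transporter Slc35a2 and St3gal1 with the G1F cluster at day 0; Man2a1/Man1c1
with G0F.  What the generator does *not* emulate: full-transcriptome scale,
library-size variation, batch effects, or any real covariance between
glycans and expression beyond the planted markers — so passing tests
demonstrate correctness of the machinery, not biological performance on real
data.

## Problem sizes and determinism

Simulations use 10,000 glycans (the study figure); ABC desk defaults are 4
chains of 2,000 iterations (the 30-chain configuration remains available),
with 5,000-glycan simulations and 2 × 600-iteration chains in the repeated
null-control experiments, where chain agreement rather than posterior
resolution is under test.  Every stochastic entry point takes a seed; one
master seed feeds named substreams per stage, so each stage reproduces
bit-identically in isolation.  The `analysis/` scripts run the whole study
shape on desk hardware in minutes; `scripts/acceptance.R` recomputes the
quantitative checks from scratch.

## Known limitations

One comparison artefact deserves a warning: a parameter that the data
constrain in one condition but not in the other (say, a branching enzyme
whose products are visible only in the more processed condition) can show a
large apparent "shift" that reflects identifiability, not biology — its
posterior is data-pinned on one side and prior-shaped on the other.  Inspect
the two posteriors, not only the shift table, before claiming such a change.

Branch isomers and bisecting GlcNAc (Mgat3) are outside the state space;
LLO/dolichol kinetics enter only as transcriptomic markers; glycans do not
compete for enzymes or donors; residence times are fixed rather than
stochastic (a config option sketches the alternative); per-cisterna
activities are only weakly identified from terminal profiles, which is why
enzyme-level claims are the default; and stability-selection counts have no
null calibration, as discussed above.
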