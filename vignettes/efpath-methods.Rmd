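---
title: "Models and methods behind efpath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind efpath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`efpath` implements a complete gene–brain–behavior analysis of the latent
structure of executive functions (EF): behavioral scoring of a nine-task
battery, confirmatory factor analysis (CFA) of twelve candidate latent
models, connectome-based prediction of factor scores, overlap statistics
for the predictive edge sets, SNP-heritability and genetic-correlation
estimation, gene-set enrichment, and high-dimensional mediation of genetic
effects through connectivity. Because cohorts of this kind are access
restricted, the package ships a synthetic-cohort generator with planted
ground truth; every estimator is validated against the quantities the
generator planted. This vignette records the models, the estimation
choices, and the places where a genuinely open design decision had to be
made.

## The synthetic cohort

`simulate_cohort()` generates, under one master seed, the blocks a real
study would collect. Stage seeds are derived deterministically from the
master seed, so identical configurations reproduce byte-identical cohorts.

**Behavior.** Trial-level data for nine tasks — three inhibiting
(anti-saccade, stop-signal, color–word Stroop), three updating (keep
track, letter 3-back, spatial 2-back), three shifting (number–letter,
color–shape, category switch) — with the full battery's trial counts (90,
256, 96, 36, 90, 72, 160, 160, 96). Reaction times are shifted log-normal
with an ability-dependent location; accuracies are logistic in ability;
the stop-signal task runs a 1-up/1-down staircase on the stop-signal delay
under a horse-race model, converging to roughly 50% stop failure; n-back
tasks draw hits and false alarms from ability-dependent rates. The
per-task abilities are `Λf` for the planted latent model, so the
trial-derived measures inherit the factor structure. The task-score block
is also generated directly from the latent model (`scores = Λf +
covariate effects + ε`, unit total variance), with missingness applied
completely at random (MCAR) per task at 5% by default and mirrored at the
trial level. Gaussian score distributions are an assumption of the
generator, not a claim about any particular dataset.

**Latent truth.** The default generating model is the bifactor "C+S":
a common EF factor on all nine tasks (loadings 0.45–0.65) and an
orthogonal shifting-specific factor on the three switch tasks (loadings
0.50–0.60). These values sit in the range typical for EF batteries;
communalities stay well below 1 so the implied covariance is positive
definite.

**Connectome.** Edges are Fisher-z values over a 264-node parcellation
(34,716 node pairs), `N(0.3, 1)` at baseline, plus a per-edge scanner-site
shift and a head-motion (FD) nuisance component. The shifting-specific
factor drives 100 informative edges with effect size `b = 0.5` on the
correlation scale (marginal edge–score correlation `b/√(1+b²) ≈ 0.45`).
The common factor's informative edges are the mediation block's mediators
(below), so the predictive and mediating edge sets coincide for that
component, as the analysis assumes.

**Genetics.** SNPs are biallelic, in linkage equilibrium, allele
frequencies uniform on [0.05, 0.5]; 5,000 SNPs over 500 genes at desk
scale. Genes sit in well-separated blocks (200 kb apart, SNPs 1 kb apart
within a gene) so the ±25/35/50 kb mapping windows partition SNPs exactly
— boundary arithmetic is testable to the base pair. Causal effects are
drawn on gene-aligned SNP sets and rescaled so the realized genetic
variance share equals the target heritability exactly in the truth
bookkeeping; two traits' effect vectors are drawn with a configurable
correlation (this requires shared causal loci — with disjoint sets the
generator warns and plants zero genetic correlation). Linkage equilibrium
is a documented simplification: it keeps the REML and enrichment oracles
analytic, at the price of not exercising LD-induced biases.

**Mediation.** The common factor is built literally from the mediation
model `Y = Mγ + Zβ + ε`, `M_j = Z B_j + η_j`, with `Z` the standardized
dosages of the causal gene set and `B = b_m w'` rank-one: the mediators
share a heritable latent channel `m = Z b_m + η_m` (channel heritability
0.5, edge loading 0.7). `γ` and `β` are rescaled so that, with
`Var(Z) = I`, the variance indirect effect `VIE = (Bγ)'Var(Z)(Bγ)` equals
`PVM_target × h²` and the variance total effect
`VTE = (Bγ+β)'Var(Z)(Bγ+β)` equals `h²` — so `pvm_from_truth()` on the
stored truth returns the configured target (default 0.19) to 1e-6.
The shared-channel structure is what makes a hundred mediators jointly
explainable: with mutually independent mediators, per-edge correlations of
0.3 with the outcome would require more variance than the outcome has.
When the variance budget cannot close (extreme targets such as PVM = 1),
the generator floors the residual variance at 0.05 and lets `Var(Y)`
exceed 1 rather than refuse; the PVM itself is scale-free.

**Expression.** A log-normal gene × region matrix; the causal genes' mean
log-expression in region 1 is shifted by `log_fold` (default 2). The
log-scale noise SD is 0.35, small enough that a fold of 3 separates the
enhanced set from a few hundred background genes exactly, which pins down
the `select_enhanced_genes()` recovery property.

## Behavioral scoring

Cleaning follows the battery's published rules: trials under 100 ms are
removed everywhere; for RT-based measures, trials outside
`[Q1 − 1.5·IQR, Q3 + 1.5·IQR]` (type-7 quartiles, computed per subject
and task) are removed; subjects with more than 20% no-response trials, or
with fewer correct responses than the 95% quantile of Binomial(N, chance),
are excluded. Two conventions had to be fixed where the rules are silent:
the IQR trial fences are computed **per subject** (the participant is the
unit of the cleaning rules), and the SSRT percentile is **nearest-rank**
on the sorted correct-Go RTs. The stop-failure probability is not assumed
to be 0.5: SSRT = (p-th percentile of correct-Go RT) − (mean stop-signal
delay), with degenerate p ∈ {0, 1} flagged unreliable rather than dropped.

Score finishing: RT measures are negated so higher = better; anti-saccade
error rate becomes `asin(√accuracy)`; the keep-track count becomes a
logit with a 0.5/N continuity adjustment at the boundaries; d′ clamps hit
and false-alarm rates to `[1/(2N), 1 − 1/(2N)]`. Each finished column is
then truncated to `[median − 1.5·IQR, median + 1.5·IQR]`; we use the
median-centered fences for both detection and replacement, which is the
only reading under which truncation is idempotent and the post-condition
"no value outside the fences" holds. Finally scores are residualized on
age and sex by OLS and standardized.

## Confirmatory factor analysis

The twelve candidate models are five correlated-factors structures
(I+U+S; the three two-factor collapses S/I+U, U/I+S, S/U+I; the
one-factor G) and seven bifactor structures (a common factor on all nine
indicators plus orthogonal specific factors: C+I+U+S, C+I+S, C+U+S,
C+I+U, C+I, C+S, C+U). Identification fixes factor variances at 1; the
mean structure is saturated. Degrees of freedom are `45 − q` with `q` the
count of free loadings, residual variances, and factor correlations; the
suite asserts `df + q = 45` for all twelve and the published df values
for the five good-fit models.

Estimation maximizes the multivariate-normal likelihood by L-BFGS-B on an
unconstrained parameterization: free loadings, `log θ` residual
variances (bounded below at 1e-6 of the indicator variance, so Heywood
cases surface as flagged boundary estimates), `atanh` factor
correlations, and — with incomplete data — free means. With complete data
the likelihood is profiled through the sample covariance, so fitting cost
is independent of n. With missing data the likelihood is accumulated per
missingness pattern (FIML); the saturated model is estimated by EM over
the same patterns, and the optimizer warm-starts from the structured fit
to the EM covariance, which sits within O(missing fraction) of the FIML
optimum. `χ² = 2(ℓ_sat − ℓ_model)` (the n-multiplier convention),
`RMSEA = √(max(χ²−df,0)/(df·n))` with denominator n, CFI against the
independence baseline with free variances, SRMR as the RMS difference of
sample versus implied correlations over the strict lower triangle —
under FIML "sample" means the EM-saturated covariance, which is defined
with missingness. AIC/BIC use `−2ℓ + 2q` and `−2ℓ + q log n` with all
estimated parameters counted; only differences between models are
meaningful. Standard errors come from the inverse numerical Hessian
(Wald z for loadings). The optimum is cross-checked in the test suite
against direct `optim()` maximization from 10 random restarts.

Factor scores are regression (Thurstone) scores
`F̂ = ΦΛ'Σ⁻¹(x − μ)`, evaluated per missingness pattern on each
subject's observed sub-vector.

## Connectome-based prediction

Per cross-validation fold: edges are standardized within the training and
the test set separately; each edge's partial correlation with the outcome
(controlling scanner site and mean FD by residualizing both sides) is
thresholded at `p ≤ 0.05` (0.01 and 0.1 are exercised as robustness
points); each subject is summarized by unit-weighted sums of the selected
positive and negative edges; a two-regressor linear model fitted on the
training summaries predicts the held-out subjects. A split's accuracy is
the Pearson r between concatenated held-out predictions and observed
scores (concatenation, rather than per-fold averaging, was chosen because
it uses every subject exactly once per split); accuracies are averaged
over random 10-fold partitions. Significance comes from permuting the
outcome (covariates stay attached to subjects) and re-running the entire
pipeline per permutation; the CV partition is drawn once and shared
between observed and permuted runs, so inference is conditional on the
partition. Contributing edges are those selected in at least 95% of the
`k × splits` training folds (the "950 of 1000" rule, read as ≥).

Implementation: the edge matrix is ~240 MB at study scale, so fold
moments, covariate projections and all edge–outcome correlations are
computed through full-matrix cross products against zero-padded
indicator/outcome columns — row subsets are never materialized, and all
folds' correlations are taken in a single `crossprod`. Standardization
cancels in correlations and enters the summaries as an affine map, so
this is exact; a naive reference implementation is kept internally and
the suite asserts agreement to 1e-10.

A one-off oracle simulation at the planted settings (b = 0.5, 100
informative edges among 34,716, n = 870) measured prediction r ≈ 0.78,
permutation p at its resolution floor, and contributing-edge precision
0.23 with recall 1.00 — the liberal `p ≤ 0.05` selection keeps
threshold-grazing null edges in nearly every fold, which is a property of
the method, not of the implementation; precision rises sharply at
`p ≤ 0.01`. The acceptance floors (precision ≥ 0.15, recall ≥ 0.90) are
frozen from that run.

## Overlap statistics

Dice overlap `2|X∩Y|/(|X|+|Y|)` between contributing-edge sets, with a
permutation null drawing independent uniform subsets of the observed
sizes from the 34,716-edge universe; the sampler is validated against the
closed-form null mean `2|X||Y|/(N(|X|+|Y|))`. Node ranking counts
contributing edges incident to each node (ties break by node id).
Network enrichment at an anchor node compares the observed number of
selected edges into each partner network with the uniform expectation
`possible_l × k/(n_nodes − 1)`; folds below 1 are computed and reported,
with a display flag at ≥ 1. All permutation p-values use the
`(1 + #{null ≥ obs})/(1 + n_perm)` small-sample form.

## Genetics

QC drops SNPs by minor allele frequency (< 5%), missingness (> 5%) and a
1-df chi-square Hardy–Weinberg test (p < 1e-6; the asymptotic test, not
the exact one), then subjects by missingness. The GRM is the GCTA-style
standardized allele-sharing average with per-SNP mean imputation of
missing dosages; relatedness pruning removes a random member of the most
related pair until no pair exceeds the cutoff; ancestry PCs are the GRM's
top eigenvectors with a fixed sign convention.

Variance components are estimated by average-information REML (three EM
warm-up iterations, then AI updates with step-halving; variances floored
at 1e-6·Var(y); convergence at |Δ logL| < 1e-6), with fixed effects
intercept + covariates. The no-genetics null is compared by a
likelihood-ratio test against the `0.5·χ²₀ + 0.5·χ²₁` boundary mixture.
The bivariate model stacks two traits with genetic and residual
(co)variance components sharing one GRM; `r_g = σ_g12/√(σ²_g1 σ²_g2)`
with a delta-method SE from the inverse AI matrix. Partitioned
enrichment fits set and control GRMs jointly; the enrichment fold is
`h²_set / (h²_total × |set|/m)` with a one-sided z test on
`h²_set − expected`. The engine is validated against a brute-force
grid/refinement maximization of the restricted likelihood (logL agreement
1e-4) and parameter-recovery simulations.

One desk-scale adaptation: with m simulated SNPs the null relatedness has
SD ≈ 1/√m, so the pipeline's default pruning threshold is
`max(0.05, 6/√m)`; the conventional absolute 0.05 would discard most of a
cohort simulated with a few thousand markers.

## Gene-set enrichment

An internal per-SNP OLS scan (Wald p) supplies association statistics for
the synthetic loop. SNPs map to every gene whose BED interval ±flank
contains their 1-based position (25/35/50 kb grid; `IRanges` overlap
machinery). A gene's raw score is its best SNP p-value; `−log10` scores
are regressed on gene length and mapped-SNP count (full OLS — the
classical confounder list is open-ended, so the two dominant ones are
used) and genes re-ranked by residual. The enrichment test counts
candidate genes above the 75th (or 95th) percentile of corrected scores
and compares with random same-size gene sets (optionally matched on
SNP-count deciles); with the toy genome's uniform gene structure the
confound regression is degenerate and falls back to raw ranks with a
warning, by design.

## High-dimensional mediation

The estimand follows the variance decomposition
`VTE = (Bγ+β)'Var(Z)(Bγ+β)`, `VIE = (Bγ)'Var(Z)(Bγ)`, `PVM = VIE/VTE`,
with exposures and mediator effects treated as random (the polygenic
convention). The estimation algorithm behind the published model is not
spelled out anywhere we could follow, so the package's estimator is its
own design, validated against the closed-form oracle on planted truth:

1. **VTE** is the exposure-attributable variance of Y from a one-kernel
   REML fit with `K = ZZ'/q` — exactly a SNP-heritability estimate.
2. On a training half, mediator coefficients `γ̂` come from ridge
   regression (λ by 5-fold CV on a fixed grid including 0, closed form
   via SVD) of the GLS-whitened outcome on whitened mediators, the
   whitening taken from the training-half REML fit of Y on K.
3. On the held-out half, the mediated outcome `W = M γ̂` is formed and
   **VIE** is its K-attributable variance by REML; halves are swapped and
   averaged, so the γ̂ entering W is never fit on the subjects whose W
   enters the variance component.

Cross-fitting removes the overfitting bias of plug-in VIE; recovery
simulations at n = 870, q = 200, p = 100 give medians within 0.1 of 0 at
no mediation, within 0.15 of 1 at full mediation, and monotone medians
across planted PVM ∈ {0, 0.25, 0.5, 0.75, 1}. Because both VTE and VIE
are variance components, this estimator cannot produce a negative PVM
(estimators built on cross-covariances can, and negative estimates are a
legitimate outcome of the model; nothing here truncates — the range is a
property of this estimator).

**Permutation scheme.** Permuting the rows of M wholesale is
anti-conservative for any estimator of this form: the observed mediators
carry the Z→M signature while permuted ones do not, so any noise in γ̂
inflates observed VIE relative to the null draws (measured type-I error
0.17–0.27 at α = 0.05). The package therefore imposes the no-mediation
null directly: each permutation shuffles the training-half outcome inside
the coefficient regression (so γ̂ is estimated under γ = 0), leaving the
kernel, the whitening and the held-out REML identical. Measured type-I
error is 0.02–0.05 across the calibration settings, and power at planted
PVM 0.5 (study dimensions) is ~1.

## Pipeline and multiplicity

`run_full_study()` chains the stages with stage-derived seeds and writes
flat per-stage artifacts so any stage can be re-run in isolation. FDR
(Benjamini–Hochberg) families are declared per stage — across CPM
components, across enrichment tests — never inferred. The family
structure is configuration, because the grouping of tests into families
is a reporting decision, not an estimable quantity.

## Problem sizes and what passing tests show

Test-suite and acceptance-script simulations run at desk scale, chosen
once as the package's own benchmark sizes: CFA calibration with 200
replicates at n = 2,000 (complete-data fast path); CPM type-I with 200
meta-replicates at reduced dimensions (60 subjects × 150 edges,
n_perm = 199) and planted-power at the full 870 × 34,716 scale; REML
recovery with 30 replicates at n = 800, m = 2,000 (the 2·SE coverage
property is size-invariant); bivariate recovery at n = 500; mediation
medians at the full n = 870, q = 200, p = 100. The generator draws
independent SNPs, Gaussian scores, and MCAR missingness; passing tests
demonstrate correctness of the estimators under those conditions, not
robustness to LD structure, non-normal scores, informative missingness,
or scanner artifacts beyond additive site/motion effects. Those are the
exact places where real-data behavior can depart from the suite's
guarantees.
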