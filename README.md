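# efpath

Executive functions (EF) — the abilities to inhibit prepotent responses,
update working memory, and shift between task sets — are correlated but
partially separable, the classic *unity/diversity* pattern. A line of
individual-differences research formalizes this with latent-variable
models over a nine-task battery, then asks whether the latent components
are also dissociable in the brain (can resting-state connectivity predict
them, through distinct edges?) and in the genome (do they have distinct
SNP-heritability profiles, gene-set enrichments, and gene→brain→behavior
pathways?). `efpath` implements that entire analysis chain as a tested R
package, exercised end-to-end on synthetic cohorts with planted ground
truth, for methodologists and students who want to run, probe, or extend
the pipeline without access-restricted data.

## What is implemented

* **Synthetic cohorts** (`simulate_cohort()`): trial-level behavior for
  the nine-task battery, task scores from a configurable latent model,
  264-node connectomes with informative edges, genotypes with causal
  traits (target h², genetic correlation), gene annotation/sets, a
  region-enhanced expression matrix, and a mediation channel hitting a
  target proportion of variance mediated (PVM) exactly; all planted
  parameters are kept in a `truth` block.
* **Behavioral scoring** (`clean_trials()`, `compute_ssrt()`,
  `score_task()`, `finalize_scores()`, `residualize_scores()`): 100 ms and
  IQR trial fences, binomial accuracy exclusion
  (the smallest k with `P(X <= k) >= 0.95`, X ~ Binomial(N, chance)),
  percentile-method SSRT, d′ with extreme-rate clamping, arcsine/logit
  transforms, robust truncation, age/sex residualization.
* **CFA** (`model_library()`, `fit_cfa()`, `fit_indices()`,
  `chisq_diff_test()`, `factor_scores()`): the twelve candidate models
  (five correlated-factors, seven bifactor) with
  `Sigma = Lambda Phi Lambda' + Theta`, ML or full-information ML over
  missingness patterns, chi-square vs the EM-estimated saturated model,
  CFI/RMSEA/SRMR/AIC/BIC, nested likelihood-ratio tests, regression
  factor scores.
* **Connectome-based prediction** (`run_cpm()`,
  `cpm_permutation_test()`, `contributing_edges()`, `fdr_bh()`):
  fold-wise edge standardization, partial-correlation edge selection,
  unit-weighted summaries, 10-fold CV over random splits, outcome
  permutation inference, contributing-edge extraction at the 95%
  selection rule.
* **Overlap statistics** (`dice_coefficient()`,
  `dice_permutation_test()`, `rank_nodes()`, `network_enrichment()`).
* **Genetics** (`qc_genotypes()`, `compute_grm()`, `prune_related()`,
  `grm_pca()`, `reml_variance_components()`, `reml_bivariate()`,
  `partition_enrichment()`): GCTA-style GRM, average-information REML for
  h² = σ²g/(σ²g+σ²e), bivariate genetic correlation
  r_g = σ_g12/√(σ²g1·σ²g2), partitioned enrichment
  fold = h²_set / (h²_g · |set|/m).
* **Gene-set enrichment** (`gwas_scan()`, `map_snps_to_genes()`,
  `gene_scores()`, `correct_gene_scores()`, `magenta_test()`,
  `select_enhanced_genes()`): best-SNP gene scores over ±25/35/50 kb
  windows, confound-corrected ranks, permutation enrichment against
  random same-size gene sets, expression fold-change candidate sets.
* **High-dimensional mediation** (`pvm_from_truth()`,
  `estimate_mediation()`, `mediation_permutation_test()`): for
  Y = Mγ + Zβ + ε, M_j = Z B_j + η_j with random effects,
  VTE = (Bγ+β)ᵀVar(Z)(Bγ+β), VIE = (Bγ)ᵀVar(Z)(Bγ), PVM = VIE/VTE,
  estimated by cross-fitted REML/ridge with permutation inference.
* **Orchestration** (`study_config()`, `run_full_study()`,
  `read_study_config()`): the full study under one seed, with flat
  per-stage artifacts and declared FDR families.

File formats: PLINK1 .bed/.bim/.fam, the GCTA binary GRM dialect, GMT,
BED, TSV, JSON, YAML (`write_plink()`, `write_grm()`, `write_gmt()`,
`write_cohort()`, ...).

## A worked example

Simulate 2,000 subjects from the bifactor "C+S" truth (a common factor on
all nine tasks plus an orthogonal shifting-specific factor), push the
scores through the finishing chain, and compare five candidate models:

```r
library(efpath)

scores <- simulate_task_scores(model_library()[["C+S"]], n = 2000,
                               missing_rate = 0.05, seed = 1)
resid <- residualize_scores(finalize_scores(scores$scores)$scores,
                            scores$covariates)
fits <- lapply(model_library()[c("G", "U/I+S", "I+U+S", "C+S", "C+U+S")],
               fit_cfa, scores = resid, se = FALSE)
```

The fit table this prints:

```
 model  chisq df   cfi rmsea  srmr
     G 448.94 27 0.894 0.088 0.064
 U/I+S  22.93 26 1.000 0.000 0.013
 I+U+S  21.30 24 1.000 0.000 0.012
   C+S  16.86 24 1.000 0.000 0.011
 C+U+S  12.84 21 1.000 0.000 0.010
```

The one-factor model `G` fails every good-fit criterion (CFI > 0.95,
RMSEA < 0.05, SRMR < 0.05) — the "diversity" side — while the generating
model and its relatives fit; a chi-square difference test between two
nested survivors is read from the upper tail of χ²(Δdf):

```r
chisq_diff_test(fits[["U/I+S"]], fits[["I+U+S"]])
#> dchisq = 1.63, ddf = 2, p = 0.443
```

(on data simulated under "C+S", collapsing updating into inhibiting loses
nothing — both reduced models fit). `factor_scores(fits[["C+S"]], resid)`
then returns one common and one shifting-specific score per subject,
which are the outcomes for the CPM, genetics, and mediation stages; see
`run_full_study()` for the whole chain and
`vignette("efpath-methods")` for the models and estimation choices.

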