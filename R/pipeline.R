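# End-to-end orchestration of the synthetic study: cohort simulation,
# behavioral scoring, CFA model comparison, factor-score prediction from
# the connectome, overlap statistics, genetics, gene-set enrichment and
# mediation, with one master seed and a consolidated report.

#' Study configuration
#'
#' @param cohort a [cohort_config()].
#' @param models model names to fit (default: all 12).
#' @param score_model model whose factor scores feed the downstream stages
#'   (default the cohort's generating model).
#' @param cpm list: `p_thresh_grid`, `k`, `n_splits`, `n_perm`,
#'   `contributing_threshold`.
#' @param dice_perms Dice permutations.
#' @param genetics list: `relatedness_cutoff`, `n_pcs`.
#' @param magenta list: `flank_kb`, `cutoffs`, `n_perm`, `top_k`.
#' @param mediation_perms mediation permutations (0 skips the permutation
#'   test).
#' @param seed master seed (propagates to every stage).
#' @return `StudyConfig` list.
#' @export
study_config <- function(cohort = cohort_config(),
                         models = names(model_library()),
                         score_model = cohort$model_name,
                         cpm = list(p_thresh_grid = 0.05, k = 10,
                                    n_splits = 10, n_perm = 100,
                                    contributing_threshold = 0.95),
                         dice_perms = 1000,
                         genetics = list(relatedness_cutoff = NULL,
                                         n_pcs = 10),
                         magenta = list(flank_kb = 35, cutoffs = c(75, 95),
                                        n_perm = 2000, top_k = NULL),
                         mediation_perms = 0,
                         seed = cohort$seed) {
  structure(list(cohort = cohort, models = models, score_model = score_model,
                 cpm = cpm, dice_perms = dice_perms, genetics = genetics,
                 magenta = magenta, mediation_perms = mediation_perms,
                 seed = as.integer(seed)),
            class = "efpath_study_config")
}

#' Run the full synthetic study
#'
#' Stages, in the analysis order of the underlying design: simulate the
#' cohort; clean/score/transform/residualize the behavioral trials; fit the
#' candidate CFA models and tabulate fit indices; compute factor scores
#' from the scoring model; CPM per component with permutation p-values,
#' FDR-corrected across components; contributing edges, Dice overlap
#' between components, node ranking and network enrichment at the top
#' node; GRM, relatedness pruning, ancestry PCs, REML heritability per
#' component, bivariate genetic correlation, partitioned enrichment of the
#' candidate-set SNPs; expression-based candidate gene set and MAGENTA
#' enrichment; high-dimensional mediation of the common component through
#' its contributing edges.
#'
#' @param config a [study_config()].
#' @param out_dir optional directory for stage artifacts (TSV/JSON).
#' @param verbose print stage progress.
#' @return `StudyReport` list; see the elements written in the code, each
#'   traceable to one stage.
#' @export
run_full_study <- function(config, out_dir = NULL, verbose = TRUE) {
  t_start <- Sys.time()
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  report <- list(seed = config$seed, stages = character(0))
  stage <- function(name) {
    say("[%s] %s", format(Sys.time(), "%H:%M:%S"), name)
    report$stages <<- c(report$stages, name)
  }

  stage("simulate cohort")
  cohort <- simulate_cohort(config$cohort)

  stage("behavior: clean, score, transform, residualize")
  beh <- score_trials(cohort$trials)
  fin <- finalize_scores(beh$raw)
  resid <- residualize_scores(fin$scores, cohort$covariates)
  report$behavior <- list(
    clean_reports = lapply(beh$reports, function(r)
      r[c("task", "n_removed_100ms", "n_removed_iqr")]),
    truncation_counts = fin$truncation_counts,
    n_scored = nrow(resid))

  stage("CFA: model comparison")
  lib <- model_library()[config$models]
  fits <- lapply(lib, function(sp)
    fit_cfa(resid, sp, missing = "fiml", se = FALSE))
  idx <- lapply(fits, fit_indices)
  fit_table <- data.frame(
    model = names(lib),
    chisq = vapply(fits, `[[`, 0, "chisq"),
    df = vapply(fits, `[[`, 0L, "df"),
    cfi = vapply(idx, `[[`, 0, "cfi"),
    rmsea = vapply(idx, `[[`, 0, "rmsea"),
    srmr = vapply(idx, `[[`, 0, "srmr"),
    aic = vapply(idx, `[[`, 0, "aic"),
    bic = vapply(idx, `[[`, 0, "bic"),
    converged = vapply(fits, `[[`, TRUE, "converged"),
    row.names = NULL, stringsAsFactors = FALSE)
  fit_table$good_fit <- fit_table$cfi > 0.95 & fit_table$rmsea < 0.05 &
    fit_table$srmr < 0.05
  report$cfa <- fit_table

  # nested comparisons among the classic pairs that exist in the model list
  nested_pairs <- list(c("U/I+S", "I+U+S"), c("C+S", "C+U+S"),
                       c("C+S", "C+I+S"))
  report$nested_tests <- do.call(rbind, lapply(nested_pairs, function(pr) {
    if (!all(pr %in% names(fits))) return(NULL)
    ct <- suppressWarnings(chisq_diff_test(fits[[pr[1]]], fits[[pr[2]]]))
    data.frame(restricted = pr[1], full = pr[2], dchisq = ct$dchisq,
               ddf = ct$ddf, p = ct$p, stringsAsFactors = FALSE)
  }))

  stage("factor scores")
  score_fit <- fits[[config$score_model]] %||%
    fit_cfa(resid, model_library()[[config$score_model]], se = FALSE)
  fscores <- factor_scores(score_fit, resid)
  # align to the cohort's canonical subject order before any positional
  # indexing against edges/genotypes
  fscores <- fscores[match(cohort$covariates$subject, fscores$subject), ,
                     drop = FALSE]
  components <- setdiff(names(fscores), "subject")

  stage("CPM per component")
  cov_num <- cbind(site = as.integer(cohort$covariates$site ==
                                       cohort$covariates$site[1L]),
                   fd = cohort$covariates$fd)
  cpm_results <- list()
  cpm_p <- numeric(0)
  for (comp in components) {
    y <- fscores[[comp]]
    ok <- !is.na(y)
    pt <- cpm_permutation_test(cohort$edges[ok, , drop = FALSE], y[ok],
                               covariates = cov_num[ok, , drop = FALSE],
                               k = config$cpm$k,
                               n_splits = config$cpm$n_splits,
                               n_perm = config$cpm$n_perm,
                               p_thresh = config$cpm$p_thresh_grid[1L],
                               seed = derive_seed(config$seed,
                                                  paste0("cpm_", comp)))
    cpm_results[[comp]] <- pt
    cpm_p[comp] <- pt$p
  }
  fdr <- fdr_bh(cpm_p)
  report$cpm <- data.frame(component = components,
                           mean_r = vapply(cpm_results, function(x) x$r_obs, 0),
                           p = cpm_p, p_fdr = fdr$adjusted,
                           row.names = NULL, stringsAsFactors = FALSE)

  stage("contributing edges, Dice, ranking, enrichment")
  masks <- lapply(cpm_results, function(x)
    contributing_edges(x$result$selection_counts,
                       x$result$total_iterations,
                       config$cpm$contributing_threshold))
  E_total <- n_edges(cohort$n_nodes)
  dice_rows <- list()
  if (length(components) >= 2) {
    for (a in seq_along(components)[-length(components)])
      for (b in (a + 1):length(components)) {
        mx <- masks[[a]]; my <- masks[[b]]
        obs <- dice_coefficient(mx, my, universe = E_total)
        dt <- dice_permutation_test(length(mx), length(my), E_total, obs,
                                    n_perm = config$dice_perms,
                                    seed = derive_seed(config$seed, "dice"))
        dice_rows[[paste(a, b)]] <- data.frame(
          comp1 = components[a], comp2 = components[b],
          size1 = length(mx), size2 = length(my),
          dice = obs, p = dt$p, null_mean = dt$null_mean,
          stringsAsFactors = FALSE)
      }
  }
  report$dice <- if (length(dice_rows)) do.call(rbind, dice_rows) else NULL
  report$mask_sizes <- vapply(masks, length, 0L)
  report$node_ranking <- lapply(masks, function(m)
    rank_nodes(m, cohort$parcellation, top_k = 10))
  report$network_enrichment <- lapply(names(masks), function(comp) {
    m <- masks[[comp]]
    if (!length(m)) return(NULL)
    top <- rank_nodes(m, cohort$parcellation, top_k = 1)
    network_enrichment(m, top$node[1], cohort$parcellation)
  })
  names(report$network_enrichment) <- names(masks)

  stage("genetics: GRM, pruning, PCs, REML")
  grm <- compute_grm(cohort$genotypes)
  # with m SNPs the null relatedness has SD ~ 1/sqrt(m); the threshold sits
  # 6 SDs out (floored at the conventional 0.05) so true relatives are
  # caught without decimating a desk-scale cohort
  cutoff <- config$genetics$relatedness_cutoff %||%
    max(0.05, 6 / sqrt(grm$n_snps))
  kept <- prune_related(grm, cutoff,
                        seed = derive_seed(config$seed, "prune"))
  ki <- match(kept, grm$subjects)
  grm_k <- list(A = grm$A[ki, ki], subjects = kept, n_snps = grm$n_snps)
  pcs <- grm_pca(grm_k, config$genetics$n_pcs)
  covg <- cbind(as.matrix(pcs[, -1L]),
                age = cohort$covariates$age[ki],
                sex = cohort$covariates$sex[ki],
                site = as.integer(cohort$covariates$site[ki] ==
                                    cohort$covariates$site[1L]))
  h2_rows <- list()
  for (comp in components) {
    y <- fscores[[comp]][ki]
    ok <- !is.na(y)
    vc <- reml_variance_components(y[ok],
                                   list(A = grm_k$A[ok, ok]),
                                   covariates = covg[ok, , drop = FALSE])
    h2_rows[[comp]] <- data.frame(component = comp, h2 = vc$h2,
                                  h2_se = vc$h2_se, p_lrt = vc$p_lrt,
                                  stringsAsFactors = FALSE)
  }
  report$heritability <- do.call(rbind, h2_rows)
  if (length(components) >= 2) {
    y1 <- fscores[[components[1]]][ki]
    y2 <- fscores[[components[length(components)]]][ki]
    ok <- !is.na(y1) & !is.na(y2)
    bv <- reml_bivariate(y1[ok], y2[ok], list(A = grm_k$A[ok, ok]),
                         covariates = covg[ok, , drop = FALSE])
    report$genetic_correlation <- data.frame(
      comp1 = components[1], comp2 = components[length(components)],
      rg = bv$rg, rg_se = bv$rg_se, unstable = bv$rg_unstable,
      stringsAsFactors = FALSE)
  }

  stage("gene sets: GWAS scan, mapping, MAGENTA")
  y_common <- fscores[[components[1]]][ki]
  okg <- !is.na(y_common)
  gwas <- gwas_scan(y_common[okg], cohort$genotypes[ki, ][okg, ],
                    covariates = covg[okg, , drop = FALSE],
                    variant_info = cohort$variant_info)
  mapping <- map_snps_to_genes(cohort$variant_info, cohort$genes,
                               flank_kb = config$magenta$flank_kb)
  gs <- gene_scores(gwas, mapping)
  gene_len <- data.frame(gene = cohort$genes$gene,
                         length_kb = (cohort$genes$end -
                                        cohort$genes$start) / 1000)
  confounds <- data.frame(gene = gs$gene,
                          length_kb = gene_len$length_kb[match(gs$gene,
                                                               gene_len$gene)],
                          n_snps = gs$n_snps)
  gs <- correct_gene_scores(gs, confounds)
  top_k <- config$magenta$top_k %||% config$cohort$n_enhanced
  cand <- select_enhanced_genes(cohort$expression, 1L, top_k = top_k)
  report$candidate_set <- list(
    genes = cand$genes,
    recall_vs_planted = length(intersect(cand$genes,
                                         cohort$truth$enhanced_genes)) /
      length(cohort$truth$enhanced_genes))
  magenta_rows <- list()
  for (cut in config$magenta$cutoffs) {
    mg <- magenta_test(cand$genes, gs, cutoff_percentile = cut,
                       n_perm = config$magenta$n_perm,
                       seed = derive_seed(config$seed, paste0("mag", cut)))
    magenta_rows[[as.character(cut)]] <- data.frame(
      cutoff = cut, observed = mg$observed, expected = mg$expected,
      expected_nominal = mg$expected_nominal, p = mg$p,
      set_size = mg$set_size, stringsAsFactors = FALSE)
  }
  report$magenta <- do.call(rbind, magenta_rows)

  stage("partitioned heritability of the candidate-set SNPs")
  set_snps <- which(cohort$variant_info$snp %in%
                      mapping$mapping$snp[mapping$mapping$gene %in%
                                            cand$genes])
  pe <- tryCatch(
    partition_enrichment(y_common[okg],
                         set_snps, cohort$genotypes[ki, ][okg, ],
                         covariates = covg[okg, , drop = FALSE]),
    error = function(e) NULL)
  report$partition <- if (!is.null(pe))
    data.frame(h2_set = pe$h2_set, h2_control = pe$h2_control,
               expected = pe$expected, fold = pe$fold, z = pe$z, p = pe$p)

  stage("mediation: gene set -> edges -> common component")
  med_mask <- masks[[components[1]]]
  if (length(med_mask) >= 2 && length(set_snps) >= 2) {
    Z <- scale(cohort$genotypes[ki, set_snps, drop = FALSE][okg, ])
    Z[is.na(Z)] <- 0
    Mmat <- cohort$edges[ki, med_mask, drop = FALSE][okg, , drop = FALSE]
    inputs <- list(Y = y_common[okg] - mean(y_common[okg]),
                   M = sweep(Mmat, 2L, colMeans(Mmat), "-"),
                   Z = Z)
    med_seed <- derive_seed(config$seed, "mediation_est")
    if (config$mediation_perms > 0) {
      mt <- suppressWarnings(
        mediation_permutation_test(inputs, n_perm = config$mediation_perms,
                                   seed = med_seed))
      report$mediation <- data.frame(pvm = mt$pvm_obs, p = mt$p,
                                     n_mediators = length(med_mask),
                                     n_exposures = length(set_snps))
    } else {
      est <- estimate_mediation(inputs, seed = med_seed)
      report$mediation <- data.frame(pvm = est$pvm, p = NA_real_,
                                     n_mediators = length(med_mask),
                                     n_exposures = length(set_snps))
    }
  } else {
    report$mediation <- data.frame(pvm = NA_real_, p = NA_real_,
                                   n_mediators = length(med_mask),
                                   n_exposures = length(set_snps))
  }

  report$runtime_s <- as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  report$truth <- list(pvm = cohort$truth$pvm,
                       target_h2 = cohort$truth$target_h2,
                       target_rg = cohort$truth$target_rg)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(fit_table, file.path(out_dir, "cfa_fit_table.tsv"))
    if (!is.null(report$nested_tests))
      write_tsv(report$nested_tests, file.path(out_dir, "nested_tests.tsv"))
    write_tsv(report$cpm, file.path(out_dir, "cpm_results.tsv"))
    if (!is.null(report$dice))
      write_tsv(report$dice, file.path(out_dir, "dice.tsv"))
    write_tsv(report$heritability, file.path(out_dir, "heritability.tsv"))
    write_tsv(report$magenta, file.path(out_dir, "magenta.tsv"))
    jsonlite::write_json(
      report[c("seed", "mask_sizes", "mediation", "runtime_s", "truth")],
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
      force = TRUE)
  }
  class(report) <- "efpath_study_report"
  report
}

#' @export
print.efpath_study_report <- function(x, ...) {
  cat("Synthetic study report\n")
  cat(sprintf("  good-fit models: %s\n",
              paste(x$cfa$model[x$cfa$good_fit], collapse = ", ")))
  cat(sprintf("  CPM mean r: %s\n",
              paste(sprintf("%s %.3f (p=%.3g)", x$cpm$component,
                            x$cpm$mean_r, x$cpm$p), collapse = "; ")))
  if (!is.null(x$mediation))
    cat(sprintf("  mediation PVM: %.3f\n", x$mediation$pvm[1]))
  cat(sprintf("  runtime: %.1f s\n", x$runtime_s))
  invisible(x)
}

#' Load a study configuration from YAML
#'
#' Flat YAML keys override the defaults of [cohort_config()] and
#' [study_config()]; nested blocks `cohort`, `cpm`, `genetics`, `magenta`
#' are merged field-wise.
#'
#' @param path YAML file.
#' @return `StudyConfig`.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  coh_args <- y$cohort %||% list()
  coh <- do.call(cohort_config, coh_args)
  args <- y[setdiff(names(y), "cohort")]
  merge_block <- function(name) {
    defaults <- formals(study_config)[[name]]
    d <- eval(defaults)
    if (!is.null(args[[name]])) d[names(args[[name]])] <- args[[name]]
    d
  }
  do.call(study_config,
          c(list(cohort = coh),
            args[setdiff(names(args), c("cpm", "genetics", "magenta"))],
            list(cpm = merge_block("cpm"), genetics = merge_block("genetics"),
                 magenta = merge_block("magenta"))))
}
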