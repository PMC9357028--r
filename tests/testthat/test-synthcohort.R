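# Generator properties: determinism, planted moments, staircase
# equilibrium, truth closure.

test_that("trial simulation is deterministic and rejects unknown kinds", {
  a <- simulate_trials("generic_rt", 5, 20, ability = 0.3, seed = 5)
  b <- simulate_trials("generic_rt", 5, 20, ability = 0.3, seed = 5)
  expect_identical(a, b)
  expect_error(simulate_trials("simon", 5, 20), "unknown task_kind")
  expect_error(simulate_trials("generic_rt", 5, 0), "n_trials")
})

test_that("the stop-signal staircase converges to ~50% stop failure", {
  tr <- simulate_trials("stop_signal", 1, 4000, ability = 0, seed = 6)
  stop_tr <- tr[tr$condition == "stop", ]
  # discard the burn-in while the staircase walks to its equilibrium
  stop_tr <- stop_tr[-seq_len(100), ]
  fail_rate <- mean(!is.na(stop_tr$rt_ms))
  expect_gt(fail_rate, 0.45)
  expect_lt(fail_rate, 0.55)
})

test_that("accuracy saturates at the infinite-ability limit", {
  tr <- simulate_trials("generic_rt", 3, 50, ability = Inf, seed = 7,
                        noresp_rate = 0)
  expect_true(all(tr$correct))
})

test_that("simulated task scores reproduce the implied covariance", {
  tr <- cs_truth()
  sim <- simulate_task_scores(tr$spec, tr$lambda, n = 50000,
                              missing_rate = 0,
                              covariate_effects = list(age = 0, sex = 0),
                              seed = 8)
  S <- cov(as.matrix(sim$scores[, -1]))
  expect_lt(max(abs(S - tr$sigma)), 0.02)
  expect_false(anyNA(sim$scores))

  # zero loadings give independent tasks
  lam0 <- tr$lambda * 0
  sim0 <- simulate_task_scores(tr$spec, lam0, n = 20000, missing_rate = 0,
                               covariate_effects = list(age = 0, sex = 0),
                               seed = 9)
  C0 <- cor(as.matrix(sim0$scores[, -1]))
  expect_lt(max(abs(C0[upper.tri(C0)])), 3 / sqrt(20000) * 1.5)

  # the missing mask hits at the configured MCAR rate
  simm <- simulate_task_scores(tr$spec, tr$lambda, n = 5000,
                               missing_rate = 0.1, seed = 10)
  rate <- mean(is.na(as.matrix(simm$scores[, -1])))
  expect_lt(abs(rate - 0.1), 0.01)

  # communalities at or above 1 are rejected as non-positive-definite
  lam_bad <- tr$lambda
  lam_bad[1, 1] <- 1.1
  expect_error(simulate_task_scores(tr$spec, lam_bad, n = 10),
               "positive definite")
})

test_that("connectome edges carry the planted effects and pass the null check", {
  withr::with_seed(11, {
    n <- 870
    sc <- cbind(C = rnorm(n))
    co <- simulate_connectome(n, n_nodes = 264,
                              informative_edges = list(C = 1:100), b = 0.5,
                              component_scores = sc, seed = 12)
    expect_identical(ncol(co$edges), 34716L)
    r_inf <- vapply(1:100, function(j) cor(co$edges[, j], sc[, 1]), 0)
    expect_gt(mean(r_inf), 0.3)  # analytic r = 0.5/sqrt(1.25) ~ 0.447
  })
  # null generator: edge-score p-values are uniform
  withr::with_seed(13, {
    n <- 200
    co0 <- simulate_connectome(n, n_nodes = 80, b = 0, seed = 14)
    y <- rnorm(n)
    st <- efpath:::edge_correlation_stats(co0$edges, y)
    tt <- st$r * sqrt((n - 2) / (1 - st$r^2))
    p <- 2 * pt(-abs(tt), n - 2)
    expect_gt(ks.test(p, "punif")$p.value, 0.01)
  })
  expect_error(simulate_connectome(10, 20, list(C = 1:5), b = Inf,
                                   component_scores = cbind(C = rnorm(10))),
               "finite")
})

test_that("genotype generator hits its allele-frequency and effect targets", {
  sim <- simulate_genotypes_and_annotations(1500, 1000, c(0.1, 0.4),
                                            target_h2 = 0.5,
                                            target_rg = 1, seed = 15)
  # empirical MAF within 3 binomial SDs of the generating frequency
  p_hat <- colMeans(sim$genotypes) / 2
  p_gen <- sim$variant_info$maf
  bound <- 3 * sqrt(p_gen * (1 - p_gen) / (2 * 1500))
  expect_gt(mean(abs(p_hat - p_gen) <= bound), 0.98)
  # rg = 1: the two effect vectors are proportional
  e1 <- sim$truth$effects[[1]][sim$truth$causal_sets[[1]]]
  e2 <- sim$truth$effects[[2]][sim$truth$causal_sets[[2]]]
  expect_gt(abs(cor(e1, e2)), 1 - 1e-10)
  # generative bookkeeping: planted genetic variance share is exact
  W <- scale(sim$genotypes)
  g <- W[, sim$truth$causal_sets[[1]]] %*% e1
  expect_equal(var(drop(g)) * (1499 / 1500), 0.5, tolerance = 1e-2)
  expect_error(simulate_genotypes_and_annotations(10, 100, c(0, 0.5)),
               "maf_range")
  # gene windows partition the SNPs on the toy genome
  mp <- map_snps_to_genes(sim$variant_info, sim$genes, flank_kb = 50)
  expect_identical(mp$n_unmapped, 0L)
  expect_identical(nrow(mp$mapping), nrow(sim$variant_info)) # single gene each
})

test_that("expression generator separates enhanced genes when the fold is large", {
  ex <- simulate_expression(300, 6, enhanced_gene_ids = 1:40, log_fold = 3,
                            seed = 16)
  sel <- select_enhanced_genes(ex, 1L, top_k = 40)
  expect_setequal(sel$genes, rownames(ex)[1:40])
  # zero fold: recovery is at chance
  ex0 <- simulate_expression(300, 6, enhanced_gene_ids = 1:40, log_fold = 0,
                             seed = 17)
  sel0 <- select_enhanced_genes(ex0, 1L, top_k = 40)
  expect_lt(length(intersect(sel0$genes, rownames(ex0)[1:40])), 20)
  # deterministic under a fixed seed
  expect_identical(ex, simulate_expression(300, 6, 1:40, log_fold = 3,
                                           seed = 16))
})

test_that("mediation generator hits the target PVM exactly", {
  for (tp in c(0, 0.19, 0.5, 1)) {
    sim <- simulate_mediation(200, 30, 12, target_pvm = tp, seed = 18)
    o <- suppressWarnings(
      pvm_from_truth(sim$truth$B, sim$truth$gamma, sim$truth$beta,
                     sim$truth$var_Z))
    if (tp == 0) {
      expect_true(all(sim$truth$gamma == 0))
      expect_equal(o$pvm, 0)
    } else if (tp == 1) {
      expect_true(all(sim$truth$beta == 0))
      expect_equal(o$pvm, 1, tolerance = 1e-6)
    } else {
      expect_equal(o$pvm, tp, tolerance = 1e-6)
    }
  }
})

test_that("cohorts are reproducible and their truth block closes the loop", {
  coh <- tiny_cohort()
  coh2 <- simulate_cohort(coh$config)
  expect_identical(coh$scores, coh2$scores)
  expect_identical(coh$edges, coh2$edges)
  expect_identical(coh$genotypes, coh2$genotypes)
  expect_identical(coh$trials, coh2$trials)

  tr <- coh$truth
  # PVM recomputable from stored truth alone
  o <- pvm_from_truth(tr$mediation$B, tr$mediation$gamma, tr$mediation$beta,
                      tr$mediation$var_Z)
  expect_equal(o$pvm, coh$config$mediation$target_pvm, tolerance = 1e-6)
  # informative edge lists are within the edge universe
  E <- n_edges(coh$n_nodes)
  expect_true(all(unlist(tr$informative_edges) <= E))
  # subject ids consistent across blocks
  expect_identical(coh$scores$subject, coh$covariates$subject)
  expect_identical(rownames(coh$edges), coh$covariates$subject)
  expect_identical(rownames(coh$genotypes), coh$covariates$subject)
  expect_true(all(coh$trials$subject %in% coh$covariates$subject))
  # planted factors generate the score block: loadings recoverable
  expect_equal(dim(tr$lambda), c(9L, 2L))
  expect_true(all(tr$theta > 0))
})
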