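# QC filters, GRM construction, pruning, ancestry PCA and the REML engine.

test_that("QC removes SNPs by MAF, missingness and HWE", {
  withr::with_seed(70, {
    n <- 400
    g <- matrix(rbinom(n * 6, 2, 0.3), n)
    # SNP 1: MAF 0.04
    g[, 1] <- rbinom(n, 2, 0.04)
    # SNP 2: 10% missing
    g[sample(n, 40), 2] <- NA
    # SNP 3: gross HWE violation (all heterozygotes)
    g[, 3] <- 1L
    # SNP 4: monomorphic
    g[, 4] <- 0L
    out <- qc_genotypes(g)
    expect_false(1L %in% seq_len(ncol(out$genotypes)) &&
                   any(colMeans(out$genotypes, na.rm = TRUE) / 2 < 0.05))
    expect_identical(ncol(out$genotypes), 2L)  # only SNPs 5 and 6 survive
    expect_gte(out$report$removed_maf, 2L)     # includes the monomorphic SNP
    expect_identical(out$report$removed_missing, 1L)
    expect_identical(out$report$removed_hwe, 1L)
  })
  # exact Hardy-Weinberg counts are retained
  g_hwe <- matrix(rep(c(rep(0L, 25), rep(1L, 50), rep(2L, 25)), 2), 100)
  out2 <- qc_genotypes(g_hwe, maf_min = 0.05)
  expect_identical(ncol(out2$genotypes), 2L)
  # everything removed is an error
  expect_error(qc_genotypes(matrix(0L, 50, 3)), "all SNPs removed")
})

test_that("GRM entries match the standardized-dosage formula", {
  # one SNP, sample frequency 0.5: A_12 = (0-1)(2-1)/(2*0.5*0.5) = -2
  g <- matrix(c(0L, 2L), 2, 1)
  A <- compute_grm(g)$A
  expect_equal(A[1, 2], -2)
  expect_equal(A[1, 1], 2)
  # large unrelated cohort: diagonal ~1, off-diagonal ~0
  withr::with_seed(71, {
    sim <- simulate_genotypes_and_annotations(600, 3000, seed = 72)
    grm <- compute_grm(sim$genotypes)
    expect_gt(mean(diag(grm$A)), 0.98)
    expect_lt(mean(diag(grm$A)), 1.02)
    off <- grm$A[upper.tri(grm$A)]
    expect_lt(abs(mean(off)), 0.005)
  })
  # missing dosages are mean-imputed: equivalent to zero contribution
  gm <- matrix(c(0L, 2L, 1L, NA, 1L, 1L), 3, 2)
  expect_silent(Am <- compute_grm(gm)$A)
  expect_true(all(is.finite(Am)))
})

test_that("relatedness pruning removes one member per flagged pair", {
  A <- diag(4) * 1.0
  A[1, 2] <- A[2, 1] <- 0.3
  grm <- list(A = A, subjects = paste0("s", 1:4), n_snps = 100L)
  kept <- prune_related(grm, cutoff = 0.05, seed = 73)
  expect_length(kept, 3L)
  expect_length(intersect(c("s1", "s2"), kept), 1L)
  # below-cutoff cohorts are untouched
  expect_length(prune_related(list(A = diag(4), subjects = paste0("s", 1:4)),
                              0.05, seed = 74), 4L)
  # deterministic under a fixed seed
  expect_identical(prune_related(grm, 0.05, seed = 75),
                   prune_related(grm, 0.05, seed = 75))
})

test_that("ancestry PCA separates simulated populations", {
  withr::with_seed(76, {
    n <- 300; m <- 800
    p1 <- runif(m, 0.1, 0.5)
    shift <- rnorm(m, 0, 0.12)
    p2 <- pmin(pmax(p1 + shift, 0.05), 0.95)
    pop <- rep(0:1, each = n / 2)
    g <- rbind(matrix(rbinom(n / 2 * m, 2, rep(p1, each = n / 2)), n / 2),
               matrix(rbinom(n / 2 * m, 2, rep(p2, each = n / 2)), n / 2))
    grm <- compute_grm(g)
    pcs <- grm_pca(grm, k = 5)
    expect_gt(abs(cor(pcs$PC1, pop)), 0.9)
    V <- as.matrix(pcs[, -1])
    expect_lt(max(abs(crossprod(V) - diag(5))), 1e-8)
    # the sign convention pins the largest-|loading| entry positive
    expect_true(all(apply(V, 2, function(v) v[which.max(abs(v))] > 0)))
  })
  expect_error(grm_pca(list(A = diag(3), subjects = letters[1:3]), k = 5),
               "exceeds")
})

test_that("AI-REML agrees with a brute-force restricted-likelihood oracle", {
  withr::with_seed(77, {
    sim <- simulate_genotypes_and_annotations(200, 600, target_h2 = 0.5,
                                              seed = 78)
    grm <- compute_grm(sim$genotypes)
    y <- sim$traits[, 1]
    fit <- reml_variance_components(y, grm)
    oracle <- grid_reml_oracle(y, grm$A)
    expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-4)
    expect_equal(unname(fit$sigma2[1]), oracle$s2g, tolerance = 0.05)
  })
})

test_that("null traits land at the heritability boundary", {
  withr::with_seed(79, {
    sim <- simulate_genotypes_and_annotations(500, 1500, seed = 80)
    grm <- compute_grm(sim$genotypes)
    h2s <- ps <- numeric(5)
    for (i in 1:5) {
      fit <- reml_variance_components(rnorm(500), grm)
      h2s[i] <- fit$h2[1]; ps[i] <- fit$p_lrt
    }
    expect_lt(median(h2s), 0.15)
    expect_lte(sum(ps <= 0.05), 1)
  })
})

test_that("bivariate REML recovers the genetic correlation", {
  # identical traits give r_g = 1
  withr::with_seed(81, {
    sim <- simulate_genotypes_and_annotations(400, 1200, target_h2 = 0.5,
                                              seed = 82)
    grm <- compute_grm(sim$genotypes)
    y <- sim$traits[, 1]
    bv <- reml_bivariate(y, y, grm)
    expect_equal(bv$rg, 1, tolerance = 1e-3)
  })
  # planted r_g = 0.5: estimates within 2 SE in most replicates
  reps <- 12
  hits <- 0
  for (i in seq_len(reps)) {
    sim <- simulate_genotypes_and_annotations(500, 1500, target_h2 = 0.5,
                                              target_rg = 0.5,
                                              seed = 800 + i)
    grm <- compute_grm(sim$genotypes)
    bv <- suppressWarnings(reml_bivariate(sim$traits[, 1], sim$traits[, 2],
                                          grm))
    hits <- hits + (abs(bv$rg - 0.5) <= 2 * max(bv$rg_se, 0.05, na.rm = TRUE))
  }
  expect_gte(hits / reps, 0.75)
})

test_that("partitioned heritability finds the causal set's enrichment", {
  withr::with_seed(83, {
    sim <- simulate_genotypes_and_annotations(
      1000, 2000, causal_sets = list(trait1 = 1:200), target_h2 = 0.5,
      seed = 84)
    pe <- partition_enrichment(sim$traits[, 1], 1:200, sim$genotypes)
    # causal SNPs occupy 10% of the genome: enrichment fold ~ 10
    expect_gt(pe$fold, 6)
    expect_gt(pe$z, 2)
    # additivity: set + control heritability near the single-GRM estimate
    single <- reml_variance_components(sim$traits[, 1],
                                       compute_grm(sim$genotypes))
    expect_lt(abs(pe$h2_total - single$h2_total),
              2 * sqrt(sum(single$h2_se^2, na.rm = TRUE)) + 0.1)
  })
  expect_error(partition_enrichment(rnorm(100), integer(0),
                                    matrix(rbinom(1000, 2, .3), 100)),
               "subset")
})

test_that("covariates are absorbed by the fixed effects", {
  withr::with_seed(85, {
    sim <- simulate_genotypes_and_annotations(500, 1500, target_h2 = 0.4,
                                              seed = 86)
    age <- runif(500, 17, 31)
    y <- sim$traits[, 1] + 0.2 * (age - mean(age))
    fit <- reml_variance_components(y, compute_grm(sim$genotypes),
                                    covariates = cbind(age = age))
    expect_lt(abs(fit$h2[1] - 0.4), 0.25)
    expect_equal(unname(fit$beta[2]), 0.2, tolerance = 0.1)
    expect_error(reml_variance_components(y, compute_grm(sim$genotypes),
                                          covariates = cbind(age, age)),
                 "singular")
  })
})
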