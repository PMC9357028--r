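# Synthetic cohorts with planted ground truth.
#
# The real study cohort is available only on request, so every downstream
# stage is exercised on simulated data whose generating parameters are kept
# in a `truth` block: factor loadings for the latent EF model, informative
# connectivity edges, causal variants with target heritability and genetic
# correlation, a latent mediation channel with a target proportion of
# variance mediated, and region-enhanced genes in a toy expression matrix.

#' Simulate trial-level data for one task kind
#'
#' Three behavioral engines cover the nine-task battery:
#' \describe{
#'   \item{generic_rt}{choice RT with a shifted log-normal RT whose location
#'     decreases with ability; optional two-condition design (e.g.
#'     congruent/incongruent, switch/repeat) with an ability-dependent RT
#'     cost on the second condition; accuracy `plogis(acc_base +
#'     acc_slope * ability)`.}
#'   \item{stop_signal}{Go trials as in generic_rt; a configurable fraction
#'     of No-go trials runs a 1-up/1-down staircase on the stop-signal delay
#'     (SSD): under the horse-race model the subject responds on a No-go
#'     trial iff the sampled Go RT is below SSD + true SSRT, and the SSD
#'     steps up after a successful stop and down after a failure, converging
#'     to ~50% stop failure.}
#'   \item{nback}{match/non-match trials with ability-dependent hit and
#'     false-alarm rates.}
#' }
#'
#' @param task_kind one of `"generic_rt"`, `"stop_signal"`, `"nback"`.
#' @param n_subjects number of subjects.
#' @param n_trials trials per subject.
#' @param ability numeric ability, length 1 or `n_subjects` (standardized
#'   latent units; higher = better).
#' @param seed integer seed.
#' @param task task label written to the `task` column.
#' @param conditions condition labels; for generic_rt, 1 label means a
#'   single-condition task, 2 labels mean easy/hard with an RT cost.
#' @param base_rt_shift,base_rt_meanlog,base_rt_sdlog shifted log-normal RT
#'   parameters (ms).
#' @param cost_ms RT cost of the hard condition at ability 0 (ms).
#' @param acc_base,acc_slope accuracy logit intercept/slope.
#' @param noresp_rate baseline no-response probability.
#' @param stop_fraction fraction of No-go trials (stop_signal).
#' @param ssd_start,ssd_step staircase start and step (ms).
#' @param true_ssrt_ms SSRT at ability 0; decreases 30 ms per ability SD.
#' @param match_fraction fraction of match trials (nback).
#' @return `TrialTable` data.frame: `subject`, `task`, `trial`, `condition`,
#'   `rt_ms` (NA for no-response), `correct`, `ssd_ms` (non-NA only on
#'   stop-signal No-go trials).
#' @export
simulate_trials <- function(task_kind, n_subjects, n_trials, ability = 0,
                            seed = 1, task = task_kind,
                            conditions = c("congruent", "incongruent"),
                            base_rt_shift = 200, base_rt_meanlog = log(400),
                            base_rt_sdlog = 0.3, cost_ms = 120,
                            acc_base = 2.2, acc_slope = 0.8,
                            noresp_rate = 0.01,
                            stop_fraction = 0.25, ssd_start = 250,
                            ssd_step = 50, true_ssrt_ms = 250,
                            match_fraction = 0.3) {
  if (!task_kind %in% c("generic_rt", "stop_signal", "nback"))
    stopf("unknown task_kind '%s'", task_kind)
  if (n_trials <= 0) stopf("n_trials must be positive")
  ability <- rep_len(ability, n_subjects)
  with_seed(seed, {
    subj <- rep(seq_len(n_subjects), each = n_trials)
    ab <- ability[subj]
    trial <- rep(seq_len(n_trials), n_subjects)
    N <- n_subjects * n_trials
    draw_rt <- function(ab, extra_ms = 0) {
      base_rt_shift + extra_ms +
        exp(base_rt_meanlog - 0.15 * pmin(ab, 50) + base_rt_sdlog * stats::rnorm(length(ab)))
    }
    if (task_kind == "generic_rt") {
      cond <- sample(conditions, N, replace = TRUE)
      hard <- length(conditions) > 1L & cond == conditions[length(conditions)]
      cost <- ifelse(hard, cost_ms * exp(-0.3 * pmin(ab, 50)), 0)
      rt <- draw_rt(ab, cost)
      acc <- stats::plogis(acc_base + acc_slope * ab)
      correct <- stats::runif(N) < acc
      noresp <- stats::runif(N) < noresp_rate
      rt[noresp] <- NA
      correct[noresp] <- FALSE
      out <- data.frame(subject = paste0("s", subj), task = task,
                        trial = trial, condition = cond, rt_ms = rt,
                        correct = correct, ssd_ms = NA_real_,
                        stringsAsFactors = FALSE)
    } else if (task_kind == "nback") {
      cond <- ifelse(stats::runif(N) < match_fraction, "match", "nonmatch")
      hit <- stats::plogis(1.2 + 0.6 * ab)
      fa <- stats::plogis(-1.5 - 0.3 * ab)
      # two-choice design: a match/non-match response on every trial
      correct <- ifelse(cond == "match", stats::runif(N) < hit,
                        stats::runif(N) >= fa)
      rt <- draw_rt(ab)
      noresp <- stats::runif(N) < noresp_rate
      rt[noresp] <- NA
      correct[noresp] <- FALSE
      out <- data.frame(subject = paste0("s", subj), task = task,
                        trial = trial, condition = cond, rt_ms = rt,
                        correct = correct, ssd_ms = NA_real_,
                        stringsAsFactors = FALSE)
    } else {
      # stop-signal: staircase is sequential in trials but vectorized over
      # subjects
      is_stop <- matrix(stats::runif(N) < stop_fraction, n_subjects, n_trials)
      ssrt <- pmax(true_ssrt_ms - 30 * ability, 50)
      ssd <- rep(ssd_start, n_subjects)
      rt_m <- matrix(NA_real_, n_subjects, n_trials)
      cond_m <- matrix("go", n_subjects, n_trials)
      corr_m <- matrix(TRUE, n_subjects, n_trials)
      ssd_m <- matrix(NA_real_, n_subjects, n_trials)
      acc <- stats::plogis(acc_base + acc_slope * ability)
      for (t in seq_len(n_trials)) {
        st <- is_stop[, t]
        go_rt <- base_rt_shift +
          exp(base_rt_meanlog - 0.15 * pmin(ability, 50) +
                base_rt_sdlog * stats::rnorm(n_subjects))
        # Go trials
        g <- !st
        rt_m[g, t] <- go_rt[g]
        corr_m[g, t] <- stats::runif(sum(g)) < acc[g]
        nr <- g & stats::runif(n_subjects) < noresp_rate
        rt_m[nr, t] <- NA
        corr_m[nr, t] <- FALSE
        # No-go trials: race between go process and stop process
        respond <- st & (go_rt < ssd + ssrt)
        cond_m[st, t] <- "stop"
        ssd_m[st, t] <- ssd[st]
        rt_m[respond, t] <- go_rt[respond]
        corr_m[st, t] <- !respond[st]
        ssd <- ssd + ifelse(st & !respond, ssd_step,
                            ifelse(st & respond, -ssd_step, 0))
        ssd <- pmax(ssd, 0)
      }
      out <- data.frame(subject = paste0("s", subj), task = task,
                        trial = trial, condition = as.vector(t(cond_m)),
                        rt_ms = as.vector(t(rt_m)),
                        correct = as.vector(t(corr_m)),
                        ssd_ms = as.vector(t(ssd_m)),
                        stringsAsFactors = FALSE)
    }
    out
  })
}

# default true loadings for the planted "C+S" bifactor model
default_true_loadings <- function(spec) {
  lam <- matrix(0, length(spec$indicators), ncol(spec$pattern),
                dimnames = list(spec$indicators, spec$factor_names))
  common <- c(antisaccade = 0.55, stopsignal = 0.50, stroop = 0.45,
              keeptrack = 0.60, letter3back = 0.65, spatial2back = 0.60,
              numberletter = 0.50, colorshape = 0.55, categoryswitch = 0.50)
  spec_load <- c(inhibiting = 0.50, updating = 0.55, shifting = 0.55)
  for (k in seq_len(ncol(lam))) {
    ind <- spec$indicators[spec$pattern[, k]]
    if (length(ind) == length(spec$indicators)) {
      lam[ind, k] <- common[ind]
    } else {
      dom <- names(EF_DOMAINS)[vapply(EF_DOMAINS, function(d) all(ind %in% d) ||
                                        all(d %in% ind), TRUE)][1]
      base <- if (!is.na(dom)) spec_load[[dom]] else 0.5
      lam[ind, k] <- base + c(0, 0.05, -0.05)[seq_along(ind) %% 3 + 1]
    }
  }
  lam
}

#' Simulate task scores from a latent factor model
#'
#' `scores = Lambda f + covariate effects + eps`, with factors drawn
#' standard normal under the model's factor covariance (orthogonal for
#' bifactor specs, `phi` otherwise) unless supplied, and residual variances
#' chosen so each score has unit total variance around its covariate trend.
#' Cells are then masked missing completely at random (MCAR) at
#' `missing_rate` per task, mimicking a battery where task absences are
#' unrelated to the unobserved score.
#'
#' @param spec `ModelSpec` for the generating model.
#' @param true_loadings loadings matrix conforming to `spec$pattern`
#'   (default: the package's reference loadings).
#' @param n number of subjects.
#' @param missing_rate per-task MCAR missingness proportion.
#' @param covariate_effects list with `age` and `sex` score effects per SD /
#'   contrast (recycled over tasks).
#' @param seed integer seed.
#' @param factors optional n x k matrix of factor scores to condition on.
#' @param phi factor correlation matrix for correlated-factors specs.
#' @param residual_theta optional residual variances (default
#'   `1 - diag(Lambda Phi Lambda')`).
#' @return list with `scores` (data.frame `subject` + 9 tasks),
#'   `covariates` (`subject`, `age`, `sex`, `site`, `fd`), `factors`,
#'   `lambda`, `phi`, `theta`.
#' @export
simulate_task_scores <- function(spec, true_loadings = NULL, n = 870,
                                 missing_rate = 0.05,
                                 covariate_effects = list(age = -0.05, sex = 0.1),
                                 seed = 1, factors = NULL, phi = NULL,
                                 residual_theta = NULL) {
  check_prob(missing_rate, "missing_rate")
  lam <- true_loadings %||% default_true_loadings(spec)
  if (!all(lam[!spec$pattern] == 0))
    stopf("true_loadings has nonzero entries outside the model pattern")
  k <- ncol(lam)
  if (is.null(phi)) phi <- diag(k)
  comm <- diag(lam %*% phi %*% t(lam))
  theta <- residual_theta %||% (1 - comm)
  if (any(theta <= 0))
    stopf("implied covariance not positive definite: communality >= 1 for %s",
          paste(spec$indicators[theta <= 0], collapse = ", "))
  with_seed(seed, {
    if (is.null(factors)) {
      factors <- matrix(stats::rnorm(n * k), n, k) %*% chol(phi)
      colnames(factors) <- spec$factor_names
    }
    age <- round(stats::runif(n, 17, 31), 1)
    sex <- stats::rbinom(n, 1, 0.45)
    site <- sample(c("siteA", "siteB"), n, replace = TRUE)
    fd <- round(exp(stats::rnorm(n, log(0.12), 0.4)), 4)  # mean FD, mm
    eps <- matrix(stats::rnorm(n * nrow(lam)), n) %*% diag(sqrt(theta))
    sc <- factors %*% t(lam) + eps
    age_z <- (age - mean(age)) / stats::sd(age)
    sc <- sc + outer(age_z, rep_len(covariate_effects$age, nrow(lam))) +
      outer(sex - mean(sex), rep_len(covariate_effects$sex, nrow(lam)))
    colnames(sc) <- spec$indicators
    if (missing_rate > 0)
      sc[matrix(stats::runif(n * nrow(lam)) < missing_rate, n)] <- NA
    list(scores = data.frame(subject = paste0("s", seq_len(n)), sc,
                             stringsAsFactors = FALSE),
         covariates = data.frame(subject = paste0("s", seq_len(n)), age = age,
                                 sex = sex, site = site, fd = fd,
                                 stringsAsFactors = FALSE),
         factors = factors, lambda = lam, phi = phi, theta = theta)
  })
}

#' Simulate a subject x edge connectivity matrix
#'
#' Edges are Fisher-z correlation values, drawn `N(edge_mean, edge_sd^2)`;
#' each informative edge additionally carries `b * component score`. A
#' per-site shift and a head-motion (FD) nuisance component are added when
#' `covariates` are supplied, emulating scanner and motion confounds the
#' prediction pipeline has to adjust for.
#'
#' @param n subjects.
#' @param n_nodes parcellation size (default 264, giving 34,716 edges).
#' @param informative_edges named list: component name -> canonical edge ids.
#' @param b effect size on the correlation scale (scalar or per component).
#' @param component_scores n x components matrix of scores driving the
#'   informative edges.
#' @param covariates optional data.frame with `site` and `fd` for batch
#'   effects.
#' @param edge_mean,edge_sd base Fisher-z mean and SD.
#' @param site_sd,fd_sd batch-effect scales.
#' @param seed integer seed.
#' @return list with `edges` (n x E matrix, subjects in rows), `n_nodes`,
#'   `informative_edges`, `b`.
#' @export
simulate_connectome <- function(n, n_nodes = 264, informative_edges = list(),
                                b = 0.5, component_scores = NULL,
                                covariates = NULL, edge_mean = 0.3,
                                edge_sd = 1, site_sd = 0.1, fd_sd = 0.1,
                                seed = 1) {
  E <- n_edges(n_nodes)
  if (length(informative_edges) &&
      max(unlist(informative_edges)) > E)
    stopf("informative edge index exceeds %d", E)
  if (!all(is.finite(b))) stopf("effect size b must be finite")
  b <- rep_len(b, max(length(informative_edges), 1L))
  with_seed(seed, {
    edges <- matrix(stats::rnorm(n * E, edge_mean, edge_sd), n, E)
    for (ci in seq_along(informative_edges)) {
      comp <- names(informative_edges)[ci]
      sc <- component_scores[, comp]
      ids <- informative_edges[[ci]]
      edges[, ids] <- edges[, ids] + b[ci] * sc
    }
    if (!is.null(covariates)) {
      site_shift <- stats::rnorm(E, 0, site_sd)
      is_b <- as.integer(covariates$site == covariates$site[1L])
      edges <- edges + outer(is_b - mean(is_b), site_shift)
      fd_load <- stats::rnorm(E, 0, fd_sd)
      fd_z <- (covariates$fd - mean(covariates$fd)) / stats::sd(covariates$fd)
      edges <- edges + outer(fd_z, fd_load)
    }
    rownames(edges) <- paste0("s", seq_len(n))
    list(edges = edges, n_nodes = n_nodes,
         informative_edges = informative_edges, b = b)
  })
}

#' Simulate genotypes, a toy gene map and causal traits
#'
#' SNPs are biallelic, in linkage equilibrium, with allele frequencies
#' uniform on `maf_range`; dosages are Binomial(2, p). Genes are placed on a
#' toy chromosome in well-separated blocks (block gap 200 kb, SNPs 1 kb
#' apart within a gene) so that the +/- 25-50 kb flank windows used for
#' SNP-to-gene mapping partition the SNPs exactly. Traits are additive:
#' standardized causal effects are rescaled so that the generative genetic
#' variance share equals `target_h2` exactly in the truth bookkeeping, and
#' two traits' effect vectors are drawn with correlation `target_rg`.
#'
#' @param n subjects.
#' @param m SNP count.
#' @param maf_range allele-frequency range, within (0, 0.5].
#' @param causal_sets named list: trait -> causal SNP indices. Defaults to
#'   two disjoint gene-block-aligned sets.
#' @param target_h2 per-trait heritability (recycled).
#' @param target_rg genetic correlation of the two traits' effects.
#' @param n_genes genes on the toy genome.
#' @param seed integer seed.
#' @return list with `genotypes` (n x m dosage matrix), `variant_info`
#'   (snp, chrom, bp, a1, a2, maf), `genes` (BED-style 0-based half-open
#'   data.frame), `gene_sets` (named list of gene ids), `traits` (n x
#'   traits matrix), `truth` (effects, h2, rg, causal sets).
#' @export
simulate_genotypes_and_annotations <- function(n, m, maf_range = c(0.05, 0.5),
                                               causal_sets = NULL,
                                               target_h2 = 0.5,
                                               target_rg = 0,
                                               n_genes = round(m / 10),
                                               seed = 1) {
  if (maf_range[1] <= 0 || maf_range[2] > 0.5)
    stopf("maf_range must lie in (0, 0.5]")
  snps_per_gene <- floor(m / n_genes)
  if (snps_per_gene < 1L) stopf("m must be at least n_genes")
  with_seed(seed, {
    p <- stats::runif(m, maf_range[1], maf_range[2])
    X <- matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), n, m)
    # toy genome: gene k owns SNP block k; blocks 200 kb apart, SNPs 1 kb apart
    gene_of_snp <- rep(seq_len(n_genes), each = snps_per_gene,
                       length.out = m)
    offset <- (seq_len(m) - 1L) %% snps_per_gene
    bp <- gene_of_snp * 200000L + offset * 1000L + 1L
    snp_ids <- sprintf("rs%06d", seq_len(m))
    variant_info <- data.frame(snp = snp_ids, chrom = "chr1", bp = bp,
                               a1 = "A", a2 = "G", maf = p,
                               stringsAsFactors = FALSE)
    gene_ids <- sprintf("GENE%04d", seq_len(n_genes))
    first_bp <- tapply(bp, gene_of_snp, min)
    last_bp <- tapply(bp, gene_of_snp, max)
    genes <- data.frame(chrom = "chr1", start = as.integer(first_bp - 1L),
                        end = as.integer(last_bp), gene = gene_ids,
                        stringsAsFactors = FALSE)
    if (is.null(causal_sets)) {
      g1 <- seq_len(min(50L, floor(n_genes / 2)))
      g2 <- if (target_rg != 0) g1 else
        max(g1) + seq_len(min(50L, n_genes - max(g1)))
      # a nonzero genetic correlation needs shared causal loci, so the
      # default second trait reuses the first set in that case
      causal_sets <- list(
        trait1 = which(gene_of_snp %in% g1),
        trait2 = which(gene_of_snp %in% g2))
    }
    n_traits <- length(causal_sets)
    target_h2 <- rep_len(target_h2, n_traits)
    for (h in target_h2)
      if (h <= 0 || h >= 1) stopf("target_h2 must be in (0,1)")
    if (abs(target_rg) > 1) stopf("|target_rg| must be <= 1")
    W <- scale(X)  # standardized dosages (sample moments)
    W[is.na(W)] <- 0
    effects <- vector("list", n_traits)
    names(effects) <- names(causal_sets)
    traits <- matrix(0, n, n_traits,
                     dimnames = list(rownames(X), names(causal_sets)))
    u_list <- list()
    for (ti in seq_len(n_traits)) {
      set <- causal_sets[[ti]]
      if (max(set) > m) stopf("causal set exceeds SNP count")
      u <- stats::rnorm(length(set))
      if (ti == 2L && identical(causal_sets[[1]], set)) {
        u1 <- u_list[[1]]
        u <- target_rg * u1 + sqrt(max(1 - target_rg^2, 0)) * u
      } else if (ti == 2L && target_rg != 0) {
        warnf("target_rg requires identical causal sets; traits generated uncorrelated")
      }
      u_list[[ti]] <- u
      g <- drop(W[, set, drop = FALSE] %*% u)
      g <- g / stats::sd(g) * sqrt(target_h2[ti])
      e <- stats::rnorm(n)
      e <- (e - mean(e)) / stats::sd(e) * sqrt(1 - target_h2[ti])
      traits[, ti] <- g + e
      eff <- numeric(m)
      eff[set] <- u / stats::sd(drop(W[, set, drop = FALSE] %*% u)) *
        sqrt(target_h2[ti])
      effects[[ti]] <- eff
    }
    gene_sets <- lapply(causal_sets, function(set)
      unique(gene_ids[gene_of_snp[set]]))
    names(gene_sets) <- paste0(names(causal_sets), "_causal_genes")
    rownames(X) <- paste0("s", seq_len(n))
    colnames(X) <- snp_ids
    list(genotypes = X, variant_info = variant_info, genes = genes,
         gene_sets = gene_sets, traits = traits,
         truth = list(effects = effects, target_h2 = target_h2,
                      target_rg = target_rg, causal_sets = causal_sets,
                      gene_of_snp = gene_of_snp))
  })
}

#' Simulate a gene x region expression matrix
#'
#' Log-normal expression; the enhanced genes' mean log-expression in the
#' target region is shifted up by `log_fold`, emulating region-enhanced
#' transcription against an otherwise exchangeable background.
#'
#' @param n_genes,n_regions matrix dimensions.
#' @param enhanced_gene_ids row indices or names of enhanced genes.
#' @param target_region enhanced region (column index, default 1).
#' @param log_fold log-scale shift (>= 0).
#' @param sdlog log-scale noise SD (default 0.35, small enough that a
#'   log-fold of 3 separates enhanced genes from the background).
#' @param seed integer seed.
#' @return genes x regions numeric matrix with dimnames.
#' @export
simulate_expression <- function(n_genes, n_regions, enhanced_gene_ids,
                                target_region = 1L, log_fold = 2,
                                sdlog = 0.35, seed = 1) {
  if (log_fold < 0) stopf("log_fold must be non-negative")
  with_seed(seed, {
    base <- stats::rnorm(n_genes, 3, 0.5)  # gene-specific baseline
    lx <- matrix(stats::rnorm(n_genes * n_regions, 0, sdlog), n_genes) + base
    rownames(lx) <- sprintf("GENE%04d", seq_len(n_genes))
    colnames(lx) <- sprintf("region%02d", seq_len(n_regions))
    idx <- if (is.character(enhanced_gene_ids))
      match(enhanced_gene_ids, rownames(lx)) else enhanced_gene_ids
    if (anyNA(idx) || (length(idx) && max(idx) > n_genes))
      stopf("enhanced genes outside the gene universe")
    lx[idx, target_region] <- lx[idx, target_region] + log_fold
    exp(lx)
  })
}

#' Simulate high-dimensional mediation inputs with a planted PVM
#'
#' Generates `Z` (n x q standardized exposures), `M = Z B + eta` (n x p
#' mediators) and `Y = M gamma + Z beta + eps` under a latent-channel
#' structure: `B = b_m w'` is rank-`channels`, so the mediators share a
#' heritable channel `m = Z b_m + eta_m` that carries the indirect effect.
#' `gamma` and `beta` are rescaled so that, with `Var(Z) = I` (the
#' generative variance of standardized independent dosages),
#' `VIE = (B gamma)' (B gamma)` equals `target_pvm * target_vte` and
#' `VTE = (B gamma + beta)' (B gamma + beta)` equals `target_vte`, making
#' the closed-form PVM equal `target_pvm` exactly.
#'
#' @param n,q,p dimensions (subjects, exposures, mediators).
#' @param target_pvm proportion of variance mediated in [0, 1].
#' @param target_vte total exposure-attributable variance of Y (equals the
#'   trait's SNP heritability when Y has unit variance).
#' @param h2_channel heritable share of the latent mediator channel.
#' @param edge_loading loading of each mediator on the channel.
#' @param Z optional pre-made exposure matrix (columns standardized).
#' @param seed integer seed.
#' @return list with `Y`, `M`, `Z` (centered), and `truth` (`B`, `gamma`,
#'   `beta`, `var_Z`, `pvm`, `vte`, `vie`, residual SDs).
#' @export
simulate_mediation <- function(n, q, p, target_pvm = 0.19, target_vte = 0.6,
                               h2_channel = 0.5, edge_loading = 0.7,
                               Z = NULL, seed = 1) {
  check_prob(target_pvm, "target_pvm")
  check_prob(target_vte, "target_vte", open_left = TRUE, open_right = TRUE)
  with_seed(seed, {
    if (is.null(Z)) {
      maf <- stats::runif(q, 0.05, 0.5)
      Zraw <- matrix(stats::rbinom(n * q, 2L, rep(maf, each = n)), n, q)
      Z <- scale(Zraw)
      Z[is.na(Z)] <- 0
    }
    b_m <- stats::rnorm(q)
    b_m <- b_m / sqrt(sum(b_m^2)) * sqrt(h2_channel)
    w <- rep(edge_loading, p)
    B <- tcrossprod(b_m, w)                     # q x p
    eta_m_sd <- sqrt(1 - h2_channel)
    m_chan <- drop(Z %*% b_m) + stats::rnorm(n, 0, eta_m_sd)
    edge_noise_sd <- sqrt(max(1 - edge_loading^2, 1e-6))
    Mnoise <- matrix(stats::rnorm(n * p, 0, edge_noise_sd), n, p)
    M <- tcrossprod(m_chan, w) + Mnoise
    # gamma recovers the channel: M gamma = gamma_m * m + gamma' noise
    vie_target <- target_pvm * target_vte
    if (target_pvm == 0) {
      gamma <- rep(0, p)
    } else {
      gamma_m <- sqrt(vie_target / h2_channel)
      gamma <- gamma_m * w / sum(w^2)
    }
    a <- drop(B %*% gamma)                      # = gamma_m * b_m
    if (target_pvm == 1) {
      beta <- rep(0, q)
    } else {
      beta0 <- stats::rnorm(q)
      beta0 <- beta0 / sqrt(sum(beta0^2))
      # solve |a + c beta0|^2 = target_vte for c > 0
      aa <- sum(a^2); ab <- sum(a * beta0)
      disc <- ab^2 - (aa - target_vte)
      if (disc < 0) stopf("infeasible target_pvm/target_vte combination")
      c1 <- -ab + sqrt(disc)
      beta <- c1 * beta0
    }
    total <- a + beta
    vte <- sum(total^2)
    vie <- sum(a^2)
    med_noise_var <- sum(gamma^2) * edge_noise_sd^2 +
      (if (target_pvm > 0) (vie_target / h2_channel) * (1 - h2_channel) else 0)
    # keep Var(Y) at 1 when the budget allows; otherwise floor the residual
    # so extreme targets (e.g. PVM = 1) stay generable with Var(Y) > 1
    eps_var <- max(1 - vte - med_noise_var, 0.05)
    Y <- drop(M %*% gamma) + drop(Z %*% beta) + stats::rnorm(n, 0, sqrt(eps_var))
    Yc <- Y - mean(Y)
    Mc <- sweep(M, 2L, colMeans(M), "-")
    Zc <- sweep(Z, 2L, colMeans(Z), "-")
    list(Y = Yc, M = Mc, Z = Zc,
         truth = list(B = B, gamma = gamma, beta = beta, var_Z = diag(q),
                      pvm = if (vte > 0) vie / vte else NA_real_,
                      vte = vte, vie = vie,
                      var_y = vte + med_noise_var + eps_var,
                      eps_sd = sqrt(eps_var), channel = m_chan))
  })
}

#' Cohort configuration
#'
#' Bundles the generating parameters of a full synthetic cohort. Defaults
#' follow the study conditions the package emulates at desk scale: 870
#' subjects with resting-state + genotype + behavioral data, a planted
#' "C+S" bifactor behavioral model, a 264-node parcellation (34,716 edges)
#' with 100 informative edges per planted component, 5,000 SNPs in linkage
#' equilibrium over 500 genes, common-factor heritability 0.6 routed partly
#' through the connectome (target PVM 0.19), shifting-specific heritability
#' 0.4, and genetic correlation 0 between the two planted traits.
#'
#' @param n_subjects cohort size.
#' @param seed master seed; stage seeds are derived deterministically.
#' @param model_name generating model from [model_library()].
#' @param true_loadings optional loadings override.
#' @param missing_rate per-task MCAR missingness.
#' @param n_nodes parcellation size.
#' @param n_informative informative edges per planted component.
#' @param b connectivity effect size for score-driven informative edges.
#' @param n_snps,maf_range,n_genes genotype block dimensions.
#' @param target_h2 named heritabilities for the planted common and
#'   specific traits.
#' @param target_rg genetic correlation between the two traits.
#' @param mediation list: `target_pvm`, `h2_channel`, `edge_loading`.
#' @param n_regions,n_enhanced,log_fold expression block parameters.
#' @param n_trials_scale multiplier on per-task trial counts (1 = the full
#'   battery; lower for fast tests).
#' @return `CohortConfig` list (validated).
#' @export
cohort_config <- function(n_subjects = 870, seed = 1, model_name = "C+S",
                          true_loadings = NULL, missing_rate = 0.05,
                          n_nodes = 264, n_informative = 100, b = 0.5,
                          n_snps = 5000, maf_range = c(0.05, 0.5),
                          n_genes = 500,
                          target_h2 = c(common = 0.6, specific = 0.4),
                          target_rg = 0,
                          mediation = list(target_pvm = 0.19,
                                           h2_channel = 0.5,
                                           edge_loading = 0.7),
                          n_regions = 8, n_enhanced = 50, log_fold = 2,
                          n_trials_scale = 1) {
  check_prob(missing_rate, "missing_rate")
  check_prob(mediation$target_pvm, "target_pvm")
  for (h in target_h2) check_prob(h, "target_h2", open_left = TRUE, open_right = TRUE)
  if (abs(target_rg) > 1) stopf("|target_rg| must be <= 1")
  spec <- model_library()[[model_name]]
  if (is.null(spec)) stopf("unknown model '%s'", model_name)
  structure(list(n_subjects = n_subjects, seed = as.integer(seed),
                 model_name = model_name, spec = spec,
                 true_loadings = true_loadings, missing_rate = missing_rate,
                 n_nodes = n_nodes, n_informative = n_informative, b = b,
                 n_snps = n_snps, maf_range = maf_range, n_genes = n_genes,
                 target_h2 = target_h2, target_rg = target_rg,
                 mediation = mediation, n_regions = n_regions,
                 n_enhanced = n_enhanced, log_fold = log_fold,
                 n_trials_scale = n_trials_scale),
            class = "efpath_cohort_config")
}

# per-task trial counts of the full battery
BATTERY_TRIALS <- c(antisaccade = 90, stopsignal = 256, stroop = 96,
                    keeptrack = 36, letter3back = 90, spatial2back = 72,
                    numberletter = 160, colorshape = 160, categoryswitch = 96)

simulate_battery_trials <- function(scores_true, seed, scale = 1) {
  # scores_true: n x 9 matrix of per-task true standardized abilities
  tasks <- colnames(scores_true)
  out <- vector("list", length(tasks))
  for (i in seq_along(tasks)) {
    task <- tasks[i]
    nt <- max(8L, round(BATTERY_TRIALS[[task]] * scale))
    ab <- scores_true[, task]
    s <- derive_seed(seed, paste0("trials_", task))
    out[[i]] <- switch(task,
      stopsignal = simulate_trials("stop_signal", nrow(scores_true), nt, ab,
                                   seed = s, task = task),
      letter3back = ,
      spatial2back = simulate_trials("nback", nrow(scores_true), nt, ab,
                                     seed = s, task = task),
      stroop = simulate_trials("generic_rt", nrow(scores_true), nt, ab,
                               seed = s, task = task,
                               conditions = c("congruent", "incongruent")),
      numberletter = ,
      colorshape = ,
      categoryswitch = simulate_trials("generic_rt", nrow(scores_true), nt, ab,
                                       seed = s, task = task,
                                       conditions = c("repeat", "switch")),
      antisaccade = simulate_trials("generic_rt", nrow(scores_true), nt, ab,
                                    seed = s, task = task,
                                    conditions = "target", acc_base = 1.4),
      keeptrack = simulate_trials("generic_rt", nrow(scores_true), nt, ab,
                                  seed = s, task = task,
                                  conditions = "word", acc_base = 0.8,
                                  noresp_rate = 0))
  }
  do.call(rbind, out)
}

#' Simulate a full synthetic cohort
#'
#' Generates every data block with consistent subject ids: trial-level
#' behavior, latent-model task scores and covariates, the connectome with
#' informative edges, genotypes with causal traits tied to the latent
#' factors through a mediation channel, gene annotation and gene sets, and
#' a region-enhanced expression matrix. The `truth` element records every
#' planted quantity (loadings, informative edges, effects, B/gamma/beta,
#' h2, rg, PVM) so each downstream estimate can be checked against its
#' generating value.
#'
#' The common factor is built as `f_C = M gamma + Z beta + eps` over the
#' causal-gene-set exposures `Z` and the mediator edges `M`, so its SNP
#' heritability equals `target_h2["common"]` and the closed-form PVM equals
#' the configured target to 1e-6. The specific factor carries its own
#' additive genetic value (heritability `target_h2["specific"]`, effect
#' correlation `target_rg` with the common trait) and drives a disjoint
#' set of informative edges with effect size `b`.
#'
#' @param config a [cohort_config()].
#' @return `CohortDataset` list: `trials`, `scores`, `covariates`, `edges`
#'   (with `n_nodes`, `parcellation`), `genotypes`, `variant_info`, `genes`,
#'   `gene_sets`, `expression`, `truth`, `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "efpath_cohort_config"))
  n <- config$n_subjects
  spec <- config$spec
  lam <- config$true_loadings %||% default_true_loadings(spec)
  seed <- config$seed

  # --- genotypes, genes, expression --------------------------------------
  geno <- simulate_genotypes_and_annotations(
    n, config$n_snps, config$maf_range, causal_sets = NULL,
    target_h2 = unname(config$target_h2), target_rg = config$target_rg,
    n_genes = config$n_genes, seed = derive_seed(seed, "genotypes"))
  set_common <- geno$truth$causal_sets[[1]]
  set_specific <- geno$truth$causal_sets[[2]]
  enhanced <- match(geno$gene_sets[[1]], sprintf("GENE%04d", seq_len(config$n_genes)))
  expr <- simulate_expression(config$n_genes, config$n_regions,
                              enhanced_gene_ids = enhanced,
                              log_fold = config$log_fold,
                              seed = derive_seed(seed, "expression"))

  # --- mediation channel defines the common factor -----------------------
  W <- scale(geno$genotypes[, set_common, drop = FALSE])
  W[is.na(W)] <- 0
  med <- simulate_mediation(
    n, q = length(set_common), p = config$n_informative,
    target_pvm = config$mediation$target_pvm,
    target_vte = unname(config$target_h2[1]),
    h2_channel = config$mediation$h2_channel,
    edge_loading = config$mediation$edge_loading,
    Z = W, seed = derive_seed(seed, "mediation"))
  f_common <- med$Y / stats::sd(med$Y)  # near-unit variance by design

  # --- specific factor with its own genetic value ------------------------
  sg <- with_seed(derive_seed(seed, "specific_trait"), {
    W2 <- scale(geno$genotypes[, set_specific, drop = FALSE])
    W2[is.na(W2)] <- 0
    u1 <- drop(med$truth$B %*% med$truth$gamma) + med$truth$beta
    u2 <- stats::rnorm(length(set_specific))
    if (length(set_specific) == length(set_common))
      u2 <- config$target_rg * u1 / sqrt(sum(u1^2)) * sqrt(sum(u2^2)) +
        sqrt(max(1 - config$target_rg^2, 0)) * u2
    g2 <- drop(W2 %*% u2)
    h2s <- unname(config$target_h2[2])
    g2 <- g2 / stats::sd(g2) * sqrt(h2s)
    g2 + stats::rnorm(n, 0, sqrt(1 - h2s))
  })
  f_specific <- sg / stats::sd(sg)

  # --- task scores from the latent model ---------------------------------
  k <- ncol(spec$pattern)
  factors <- with_seed(derive_seed(seed, "extra_factors"),
                       matrix(stats::rnorm(n * k), n, k))
  colnames(factors) <- spec$factor_names
  factors[, 1L] <- f_common
  factors[, ncol(factors)] <- f_specific
  beh <- simulate_task_scores(spec, true_loadings = lam, n = n,
                              missing_rate = config$missing_rate,
                              seed = derive_seed(seed, "scores"),
                              factors = factors)

  # --- trials (true per-task ability = Lambda f, standardized) ------------
  eta <- factors %*% t(lam)
  eta <- sweep(eta, 2L, apply(eta, 2L, stats::sd), "/")
  colnames(eta) <- spec$indicators
  trials <- simulate_battery_trials(eta, seed = derive_seed(seed, "trials"),
                                    scale = config$n_trials_scale)
  # the MCAR mask of the score table is mirrored at the trial level, so the
  # behavioral stage reproduces the same missingness pattern
  sc_mat <- as.matrix(beh$scores[, spec$indicators])
  missing_cells <- which(is.na(sc_mat), arr.ind = TRUE)
  if (nrow(missing_cells)) {
    drop_keys <- paste(beh$scores$subject[missing_cells[, 1L]],
                       spec$indicators[missing_cells[, 2L]])
    trials <- trials[!(paste(trials$subject, trials$task) %in% drop_keys), ,
                     drop = FALSE]
  }

  # --- connectome ---------------------------------------------------------
  E <- n_edges(config$n_nodes)
  ids_all <- with_seed(derive_seed(seed, "edge_ids"),
                       sample.int(E, 2L * config$n_informative))
  ids_common <- sort(ids_all[seq_len(config$n_informative)])
  ids_specific <- sort(ids_all[config$n_informative + seq_len(config$n_informative)])
  specific_name <- spec$factor_names[length(spec$factor_names)]
  conn <- simulate_connectome(
    n, config$n_nodes,
    informative_edges = stats::setNames(list(ids_specific), specific_name),
    b = config$b,
    component_scores = factors,
    covariates = beh$covariates,
    seed = derive_seed(seed, "connectome"))
  # mediator edges overwrite their columns: they ARE the common component's
  # informative edges (centered at the base Fisher-z mean)
  conn$edges[, ids_common] <- 0.3 + med$M
  conn$informative_edges[[spec$factor_names[1L]]] <- ids_common

  parcellation <- make_parcellation(config$n_nodes,
                                    seed = derive_seed(seed, "parcellation"))

  truth <- list(lambda = lam, phi = diag(k), theta = beh$theta,
                factors = factors,
                informative_edges = conn$informative_edges, b = config$b,
                causal_sets = geno$truth$causal_sets,
                snp_effects = geno$truth$effects,
                target_h2 = config$target_h2, target_rg = config$target_rg,
                mediation = med$truth,
                genetic_traits = geno$traits,
                enhanced_genes = geno$gene_sets[[1]],
                pvm = med$truth$pvm)

  structure(list(trials = trials, scores = beh$scores,
                 covariates = beh$covariates,
                 edges = conn$edges, n_nodes = config$n_nodes,
                 parcellation = parcellation,
                 genotypes = geno$genotypes, variant_info = geno$variant_info,
                 genes = geno$genes, gene_sets = geno$gene_sets,
                 expression = expr, truth = truth, config = config),
            class = "efpath_cohort")
}

#' Toy parcellation table
#'
#' Node table with MNI-like coordinates and a network label per node,
#' mimicking the structure of the 264-node functional atlas used for
#' whole-brain connectomes.
#'
#' @param n_nodes nodes.
#' @param networks label pool.
#' @param seed integer seed.
#' @return data.frame: `node` (0-based), `x`, `y`, `z`, `network`, `name`.
#' @export
make_parcellation <- function(n_nodes = 264,
                              networks = c("FPN", "CON", "DMN", "SAN",
                                           "VIS", "SMN", "SUB", "AUD"),
                              seed = 1) {
  with_seed(seed, {
    data.frame(node = seq_len(n_nodes) - 1L,
               x = round(stats::runif(n_nodes, -70, 70)),
               y = round(stats::runif(n_nodes, -105, 70)),
               z = round(stats::runif(n_nodes, -45, 75)),
               network = sample(networks, n_nodes, replace = TRUE),
               name = sprintf("node%03d", seq_len(n_nodes) - 1L),
               stringsAsFactors = FALSE)
  })
}
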