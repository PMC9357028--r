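# Genotype QC, genetic relationship matrices, ancestry PCA, relatedness
# pruning, and REML variance components (univariate, bivariate, and
# partitioned) in the GREML tradition: a linear mixed model with one or
# more relationship kernels estimated by average-information REML.

#' Quality-control filters for genotypes
#'
#' Drops SNPs by minor allele frequency, per-SNP missingness and a 1-df
#' chi-square Hardy-Weinberg test on genotype counts, then drops subjects
#' whose missing rate over the retained SNPs exceeds `subj_miss_max`.
#'
#' @param genotypes n x m dosage matrix (0/1/2/NA).
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param miss_max maximum per-SNP missingness (default 0.05).
#' @param hwe_p_min minimum HWE p (default 1e-6).
#' @param subj_miss_max maximum per-subject missingness (default 0.05).
#' @return list with `genotypes` (filtered), `report` (counts per filter,
#'   kept ids).
#' @export
qc_genotypes <- function(genotypes, maf_min = 0.05, miss_max = 0.05,
                         hwe_p_min = 1e-6, subj_miss_max = 0.05) {
  n <- nrow(genotypes)
  miss <- colMeans(is.na(genotypes))
  p1 <- colMeans(genotypes, na.rm = TRUE) / 2
  maf <- pmin(p1, 1 - p1)
  n0 <- colSums(genotypes == 0L, na.rm = TRUE)
  n1 <- colSums(genotypes == 1L, na.rm = TRUE)
  n2 <- colSums(genotypes == 2L, na.rm = TRUE)
  nn <- n0 + n1 + n2
  ph <- (2 * n2 + n1) / (2 * nn)
  e0 <- nn * (1 - ph)^2; e1 <- 2 * nn * ph * (1 - ph); e2 <- nn * ph^2
  chi <- ifelse(e0 > 0 & e1 > 0 & e2 > 0,
                (n0 - e0)^2 / e0 + (n1 - e1)^2 / e1 + (n2 - e2)^2 / e2,
                Inf)
  chi[maf == 0] <- 0   # monomorphic: removed by the MAF filter, not HWE
  hwe_p <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
  fail_maf <- maf < maf_min
  fail_miss <- miss > miss_max
  fail_hwe <- hwe_p < hwe_p_min
  keep_snp <- !(fail_maf | fail_miss | fail_hwe)
  if (!any(keep_snp)) stopf("all SNPs removed by QC (maf %d, miss %d, hwe %d)",
                            sum(fail_maf), sum(fail_miss), sum(fail_hwe))
  g <- genotypes[, keep_snp, drop = FALSE]
  subj_miss <- rowMeans(is.na(g))
  keep_subj <- subj_miss <= subj_miss_max
  g <- g[keep_subj, , drop = FALSE]
  list(genotypes = g,
       report = list(n_snps_in = ncol(genotypes), n_snps_kept = ncol(g),
                     removed_maf = sum(fail_maf),
                     removed_missing = sum(fail_miss & !fail_maf),
                     removed_hwe = sum(fail_hwe & !fail_maf & !fail_miss),
                     n_subjects_removed = sum(!keep_subj),
                     maf = maf, hwe_p = hwe_p))
}

#' Genetic relationship matrix
#'
#' `A_jk = (1/m) sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i))`
#' with `p_i` the sample allele frequency; missing dosages are mean-imputed
#' per SNP before standardization (the GCTA convention). SNPs with
#' `p_i` 0 or 1 are skipped.
#'
#' @param genotypes n x m dosage matrix (QC'd).
#' @return `GRM` list: `A` (n x n), `subjects`, `n_snps` (SNPs used).
#' @export
compute_grm <- function(genotypes) {
  p <- colMeans(genotypes, na.rm = TRUE) / 2
  use <- p > 0 & p < 1
  if (sum(!use)) warnf("%d monomorphic SNPs skipped", sum(!use))
  g <- genotypes[, use, drop = FALSE]
  p <- p[use]
  for (j in seq_len(ncol(g))) {
    nas <- is.na(g[, j])
    if (any(nas)) g[nas, j] <- 2 * p[j]
  }
  W <- sweep(g, 2L, 2 * p, "-")
  W <- sweep(W, 2L, sqrt(2 * p * (1 - p)), "/")
  A <- tcrossprod(W) / ncol(W)
  subjects <- rownames(genotypes) %||% paste0("s", seq_len(nrow(genotypes)))
  rownames(A) <- colnames(A) <- subjects
  list(A = A, subjects = subjects, n_snps = ncol(W))
}

#' Prune related subjects from a GRM
#'
#' While any off-diagonal relatedness exceeds `cutoff`, one member of the
#' currently most related pair is removed (chosen at random, seeded).
#'
#' @param grm `GRM` from [compute_grm()].
#' @param cutoff relatedness threshold (default 0.05).
#' @param seed integer seed for the coin flips.
#' @return character vector of kept subject ids.
#' @export
prune_related <- function(grm, cutoff = 0.05, seed = 1) {
  A <- grm$A
  keep <- seq_len(nrow(A))
  with_seed(seed, {
    repeat {
      B <- A[keep, keep, drop = FALSE]
      diag(B) <- -Inf
      mx <- max(B)
      if (mx <= cutoff || length(keep) <= 1L) break
      ij <- which(B == mx, arr.ind = TRUE)[1L, ]
      drop_local <- ij[[sample.int(2L, 1L)]]
      keep <- keep[-drop_local]
    }
  })
  grm$subjects[keep]
}

#' Ancestry principal components from a GRM
#'
#' Top-k eigenvectors of the GRM (descending eigenvalue), with each PC's
#' sign fixed so its largest-|loading| entry is positive.
#'
#' @param grm `GRM` object (or plain symmetric matrix).
#' @param k components (default 10).
#' @return data.frame with `subject` and `PC1..PCk`; eigenvalues in the
#'   `"eigenvalues"` attribute. A near-flat spectrum (no structure) is
#'   flagged with a warning.
#' @export
grm_pca <- function(grm, k = 10) {
  A <- if (is.list(grm)) grm$A else grm
  if (k > nrow(A)) stopf("k exceeds the number of subjects")
  eig <- eigen(A, symmetric = TRUE)
  vec <- eig$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(vec[, j]))
    if (vec[i_max, j] < 0) vec[, j] <- -vec[, j]
  }
  if (diff(range(eig$values)) < 1e-8 * max(abs(eig$values)))
    warnf("degenerate GRM spectrum: principal components are arbitrary")
  colnames(vec) <- paste0("PC", seq_len(k))
  subjects <- if (is.list(grm)) grm$subjects else
    rownames(A) %||% paste0("s", seq_len(nrow(A)))
  out <- data.frame(subject = subjects, vec, stringsAsFactors = FALSE)
  attr(out, "eigenvalues") <- eig$values
  out
}

# ---- average-information REML ---------------------------------------------
# V = sum_c sigma2_c K_c + sigma2_e I; fixed effects X. EM warm-up then AI
# updates with step-halving; variances clamped at 1e-6 Var(y); covariance
# components (allowed negative) are flagged via `is_cov`.
ai_reml <- function(y, K_list, X, is_cov = rep(FALSE, length(K_list)),
                    max_iter = 100, tol = 1e-6, n_em = 3, verbose = FALSE) {
  n <- length(y)
  nc <- length(K_list) + 1L  # + residual
  K_all <- c(K_list, list(diag(n)))
  is_cov <- c(is_cov, FALSE)
  vy <- stats::var(y)
  floor_v <- 1e-6 * vy
  sig <- rep(vy / nc, nc)
  px <- ncol(X)
  loglik <- function(sig) {
    V <- matrix(0, n, n)
    for (c in seq_len(nc)) V <- V + sig[c] * K_all[[c]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vi <- chol2inv(ch)
    XtViX <- crossprod(X, Vi %*% X)
    chx <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(chx)) return(NULL)
    XtViX_inv <- chol2inv(chx)
    P <- Vi - Vi %*% X %*% XtViX_inv %*% crossprod(X, Vi)
    Py <- P %*% y
    ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chx))) +
                    drop(crossprod(y, Py)) + (n - px) * log(2 * pi))
    list(ll = ll, P = P, Py = Py)
  }
  st <- loglik(sig)
  if (is.null(st)) { sig <- rep(vy / nc, nc); st <- loglik(sig) }
  ll_old <- st$ll
  converged <- FALSE
  AI_inv <- NULL
  for (it in seq_len(max_iter)) {
    P <- st$P; Py <- st$Py
    KPy <- lapply(K_all, function(K) K %*% Py)
    yPKPy <- vapply(KPy, function(v) drop(crossprod(Py, v)), 0)
    trPK <- vapply(K_all, function(K) sum(P * K), 0)
    if (it <= n_em) {
      sig_new <- sig + sig^2 * (yPKPy - trPK) / n
    } else {
      AI <- matrix(0, nc, nc)
      PKPy <- lapply(KPy, function(v) P %*% v)
      for (a in seq_len(nc)) for (b in a:nc) {
        AI[a, b] <- AI[b, a] <- 0.5 * drop(crossprod(KPy[[a]], PKPy[[b]]))
      }
      score <- -0.5 * (trPK - yPKPy)
      AI_inv <- tryCatch(solve(AI), error = function(e) NULL)
      if (is.null(AI_inv)) AI_inv <- solve(AI + diag(1e-8, nc))
      sig_new <- sig + drop(AI_inv %*% score)
    }
    sig_new[!is_cov] <- pmax(sig_new[!is_cov], floor_v)
    # step-halving if the likelihood cannot be evaluated or decreases
    step <- 1
    repeat {
      cand <- sig + step * (sig_new - sig)
      cand[!is_cov] <- pmax(cand[!is_cov], floor_v)
      st_new <- loglik(cand)
      if (!is.null(st_new) && (st_new$ll >= ll_old - 1e-8)) break
      step <- step / 2
      if (step < 1e-4) { st_new <- st; cand <- sig; break }
    }
    sig <- cand
    st <- st_new
    if (verbose) message(sprintf("iter %d logL %.6f", it, st$ll))
    if (abs(st$ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- st$ll
  }
  se <- if (!is.null(AI_inv)) sqrt(pmax(diag(AI_inv), 0)) else rep(NA_real_, nc)
  # fixed-effect estimates at convergence
  V <- matrix(0, n, n)
  for (c in seq_len(nc)) V <- V + sig[c] * K_all[[c]]
  Vi <- chol2inv(chol(V))
  XtViX_inv <- chol2inv(chol(crossprod(X, Vi %*% X)))
  beta <- drop(XtViX_inv %*% crossprod(X, Vi %*% y))
  list(sigma2 = sig, se = se, loglik = st$ll, converged = converged,
       iterations = it, ai_inv = AI_inv, beta = beta)
}

# residual-only REML logL (closed form), for likelihood-ratio tests
reml_null_loglik <- function(y, X) {
  n <- length(y); px <- ncol(X)
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  s2 <- rss / (n - px)
  ldXX <- 2 * sum(log(abs(diag(qr.R(qr(X))))))
  -0.5 * ((n - px) * log(s2) + ldXX + (n - px) + (n - px) * log(2 * pi))
}

#' REML variance components for one or more relationship kernels
#'
#' Fits `y = X b + sum_g u_g + e`, `u_g ~ N(0, sigma2_g A_g)`, by
#' average-information REML (EM warm-up iterations first). Heritability is
#' `h2 = sigma2_g / sum(sigma2)`; its standard error comes from the inverse
#' AI matrix by the delta method. The no-genetics null is compared by a
#' likelihood-ratio test with the boundary mixture `0.5 chi2_0 + 0.5
#' chi2_1` (df = number of kernels).
#'
#' @param y phenotype vector.
#' @param grms a `GRM`, a plain matrix, or a list of them.
#' @param covariates optional numeric covariate matrix (intercept added).
#' @param max_iter,tol AI-REML controls.
#' @return `VCResult` list: `sigma2` (named, incl. residual), `se`, `h2`
#'   (per kernel; total in `h2_total`), `h2_se`, `loglik`, `lrt`, `p_lrt`,
#'   `converged`, `beta` (fixed effects), `ai_inv`.
#' @export
reml_variance_components <- function(y, grms, covariates = NULL,
                                     max_iter = 100, tol = 1e-6) {
  if (is.list(grms) && !is.null(grms$A)) grms <- list(grms)
  if (!is.list(grms)) grms <- list(grms)
  K_list <- lapply(grms, function(g) if (is.list(g)) g$A else g)
  n <- length(y)
  for (K in K_list) if (!all(dim(K) == n)) stopf("GRM dimension mismatch")
  X <- cbind(intercept = rep(1, n), covariates)
  if (qr(X)$rank < ncol(X)) stopf("singular fixed-effects design")
  fit <- ai_reml(y, K_list, X, max_iter = max_iter, tol = tol)
  ng <- length(K_list)
  tot <- sum(fit$sigma2)
  h2 <- fit$sigma2[seq_len(ng)] / tot
  # delta method: h2_g = s_g / sum(s); grad_j = (1[j==g] tot - s_g)/tot^2
  h2_se <- rep(NA_real_, ng)
  if (!is.null(fit$ai_inv)) {
    for (g in seq_len(ng)) {
      grad <- -fit$sigma2[g] / tot^2 + (seq_len(ng + 1L) == g) / tot
      h2_se[g] <- sqrt(max(drop(t(grad) %*% fit$ai_inv %*% grad), 0))
    }
  }
  ll0 <- reml_null_loglik(y, X)
  lrt <- max(2 * (fit$loglik - ll0), 0)
  p_lrt <- 0.5 * stats::pchisq(lrt, df = ng, lower.tail = FALSE) +
    if (ng == 1L) 0 else 0.5 * stats::pchisq(lrt, df = ng - 1L,
                                             lower.tail = FALSE)
  if (lrt == 0) p_lrt <- 1
  structure(list(sigma2 = stats::setNames(fit$sigma2,
                                          c(paste0("g", seq_len(ng)), "e")),
                 se = fit$se, h2 = h2, h2_total = sum(h2), h2_se = h2_se,
                 loglik = fit$loglik, lrt = lrt, p_lrt = p_lrt,
                 converged = fit$converged, beta = fit$beta,
                 ai_inv = fit$ai_inv),
            class = "efpath_vc")
}

#' @export
print.efpath_vc <- function(x, ...) {
  cat(sprintf("REML: h2 = %s (total %.3f), logL = %.3f, LRT p = %.3g\n",
              paste(sprintf("%.3f", x$h2), collapse = ", "),
              x$h2_total, x$loglik, x$p_lrt))
  invisible(x)
}

#' Bivariate REML: genetic correlation of two traits
#'
#' Stacks the two traits into a 2n mixed model with genetic (co)variance
#' components `sigma2_g1`, `sigma2_g2`, `sigma_g12` sharing one GRM, and
#' residual (co)variances; `r_g = sigma_g12 / sqrt(sigma2_g1 sigma2_g2)`
#' with a delta-method SE from the inverse AI matrix.
#'
#' @param y1,y2 trait vectors on the same subjects.
#' @param grm shared `GRM`.
#' @param covariates optional covariate matrix (applied to both traits).
#' @param max_iter,tol AI-REML controls.
#' @return `VCResult` list with `rg`, `rg_se`, per-trait `h2`, `sigma2`,
#'   `loglik`, `converged`; `rg_unstable` flags a boundary genetic variance.
#' @export
reml_bivariate <- function(y1, y2, grm, covariates = NULL,
                           max_iter = 100, tol = 1e-6) {
  A <- if (is.list(grm)) grm$A else grm
  n <- length(y1)
  if (length(y2) != n) stopf("traits must be measured on the same subjects")
  Z <- matrix(0, n, n)
  K_g1 <- rbind(cbind(A, Z), cbind(Z, Z))
  K_g2 <- rbind(cbind(Z, Z), cbind(Z, A))
  K_g12 <- rbind(cbind(Z, A), cbind(A, Z))
  In <- diag(n)
  K_e12 <- rbind(cbind(Z, In), cbind(In, Z))
  # per-trait residual variances: e1 block and e2 block; the shared ai_reml
  # residual acts as the e2 component on the stacked scale
  K_e1 <- rbind(cbind(In, Z), cbind(Z, Z))
  y <- c(y1, y2)
  X1 <- cbind(rep(1, n), covariates)
  X <- rbind(cbind(X1, matrix(0, n, ncol(X1))),
             cbind(matrix(0, n, ncol(X1)), X1))
  fit <- ai_reml(y, list(K_g1, K_g2, K_g12, K_e1, K_e12), X,
                 is_cov = c(FALSE, FALSE, TRUE, FALSE, TRUE),
                 max_iter = max_iter, tol = tol)
  s <- fit$sigma2  # g1 g2 g12 e1 e12 e(=e2)
  rg <- s[3] / sqrt(s[1] * s[2])
  rg <- max(min(rg, 1), -1)
  vy <- stats::var(y)
  unstable <- s[1] < 1e-4 * vy || s[2] < 1e-4 * vy
  if (unstable) warnf("a genetic variance is at the boundary; r_g unstable")
  rg_se <- NA_real_
  if (!is.null(fit$ai_inv)) {
    grad <- c(-0.5 * s[3] / (s[1]^1.5 * sqrt(s[2])),
              -0.5 * s[3] / (s[2]^1.5 * sqrt(s[1])),
              1 / sqrt(s[1] * s[2]), 0, 0, 0)
    rg_se <- sqrt(max(drop(t(grad) %*% fit$ai_inv %*% grad), 0))
  }
  h2_1 <- s[1] / (s[1] + s[4] + s[6])
  h2_2 <- s[2] / (s[2] + s[6])
  structure(list(sigma2 = stats::setNames(s, c("g1", "g2", "g12", "e1",
                                               "e12", "e2")),
                 rg = rg, rg_se = rg_se, rg_unstable = unstable,
                 h2 = c(h2_1, h2_2), loglik = fit$loglik,
                 converged = fit$converged, se = fit$se,
                 ai_inv = fit$ai_inv),
            class = "efpath_vc_biv")
}

#' @export
print.efpath_vc_biv <- function(x, ...) {
  cat(sprintf("Bivariate REML: r_g = %.3f (SE %.3f), h2 = %.3f / %.3f\n",
              x$rg, x$rg_se, x$h2[1], x$h2[2]))
  invisible(x)
}

#' Partitioned-heritability enrichment of a SNP set
#'
#' Builds one GRM from the candidate-set SNPs and one from the remaining
#' (control) SNPs, estimates both components jointly by REML, and compares
#' the set's heritability share with its SNP share:
#' `enrichment = h2_set / h2_set_expected`, `h2_set_expected = h2_g *
#' |set| / m`. Significance is a one-sided z test of
#' `h2_set - h2_set_expected` against the AI standard error of `h2_set`.
#'
#' @param y phenotype.
#' @param set_snps candidate SNP indices (proper non-empty subset).
#' @param genotypes QC'd dosage matrix.
#' @param covariates optional covariate matrix.
#' @return `PartitionResult` list: `h2_set`, `h2_control`, `h2_total`,
#'   `expected`, `fold`, `z`, `p`, `fit` (the joint `VCResult`).
#' @export
partition_enrichment <- function(y, set_snps, genotypes, covariates = NULL) {
  m <- ncol(genotypes)
  set_snps <- unique(as.integer(set_snps))
  if (length(set_snps) == 0L || length(set_snps) >= m)
    stopf("set must be a non-empty proper subset of the %d SNPs", m)
  if (length(set_snps) < 50L)
    warnf("only %d SNPs in the set; the set GRM will be unstable",
          length(set_snps))
  grm_set <- compute_grm(genotypes[, set_snps, drop = FALSE])
  grm_ctl <- compute_grm(genotypes[, -set_snps, drop = FALSE])
  fit <- reml_variance_components(y, list(grm_set, grm_ctl), covariates)
  h2_set <- fit$h2[1]; h2_ctl <- fit$h2[2]
  h2_tot <- h2_set + h2_ctl
  expected <- h2_tot * length(set_snps) / m
  fold <- if (expected > 0) h2_set / expected else NA_real_
  se_set <- fit$h2_se[1]
  z <- if (is.finite(se_set) && se_set > 0)
    (h2_set - expected) / se_set else NA_real_
  p <- if (is.na(z)) NA_real_ else stats::pnorm(z, lower.tail = FALSE)
  list(h2_set = h2_set, h2_control = h2_ctl, h2_total = h2_tot,
       expected = expected, fold = fold, z = z, p = p, fit = fit)
}
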