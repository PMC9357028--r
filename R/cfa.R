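# Confirmatory factor analysis of the nine-task EF battery.
#
# Twelve candidate models formalize the unity/diversity question: five
# correlated-factors models (the full three-factor "I+U+S", three two-factor
# collapses, and a one-general-factor "G") and seven bifactor models (a
# common EF factor loading on all nine tasks plus orthogonal domain-specific
# factors). Estimation maximizes the multivariate-normal likelihood; with
# incomplete rows the likelihood is accumulated per missingness pattern
# (full-information maximum likelihood, FIML).

EF_DOMAINS <- list(
  inhibiting = c("antisaccade", "stopsignal", "stroop"),
  updating   = c("keeptrack", "letter3back", "spatial2back"),
  shifting   = c("numberletter", "colorshape", "categoryswitch")
)

#' Build one CFA model specification
#'
#' @param name model label (e.g. `"C+S"`).
#' @param factors named list mapping factor name to its indicator tasks.
#' @param orthogonal if `TRUE` all factor correlations are fixed to 0
#'   (bifactor identification); otherwise all correlations are free.
#' @param indicators indicator order (defaults to the nine EF tasks).
#' @return `ModelSpec` list: `name`, `indicators`, `pattern` (logical
#'   indicators x factors free-loading matrix), `orthogonal`,
#'   `factor_names`. Factor variances are fixed to 1 for identification.
#' @export
model_spec <- function(name, factors, orthogonal = FALSE,
                       indicators = EF_TASKS) {
  pattern <- vapply(factors, function(ind) indicators %in% ind,
                    logical(length(indicators)))
  pattern <- matrix(pattern, nrow = length(indicators),
                    dimnames = list(indicators, names(factors)))
  if (any(rowSums(pattern) == 0))
    stopf("model '%s': every indicator must load on at least one factor", name)
  structure(list(name = name, indicators = indicators, pattern = pattern,
                 orthogonal = orthogonal, factor_names = names(factors)),
            class = "efpath_model_spec")
}

#' The twelve candidate EF latent-variable models
#'
#' Five correlated-factors models — the full three-factor model `I+U+S`, the
#' three two-factor collapses `S/I+U`, `U/I+S`, `S/U+I`, and the
#' one-general-factor model `G` — and seven bifactor models combining a
#' common factor (on all nine tasks) with orthogonal specific factors:
#' `C+I+U+S`, `C+I+S`, `C+U+S`, `C+I+U`, `C+I`, `C+S`, `C+U`. Task-domain
#' assignment: anti-saccade, stop-signal and Stroop load on inhibiting; keep
#' track and the two n-backs on updating; the three switch tasks on shifting.
#'
#' @return named list of 12 `ModelSpec`s.
#' @export
model_library <- function() {
  I <- EF_DOMAINS$inhibiting; U <- EF_DOMAINS$updating; S <- EF_DOMAINS$shifting
  all9 <- EF_TASKS
  specs <- list(
    model_spec("I+U+S", list(I = I, U = U, S = S)),
    model_spec("S/I+U", list(IS = c(I, S), U = U)),
    model_spec("U/I+S", list(IU = c(I, U), S = S)),
    model_spec("S/U+I", list(US = c(U, S), I = I)),
    model_spec("G", list(G = all9)),
    model_spec("C+I+U+S", list(C = all9, I = I, U = U, S = S), orthogonal = TRUE),
    model_spec("C+I+S", list(C = all9, I = I, S = S), orthogonal = TRUE),
    model_spec("C+U+S", list(C = all9, U = U, S = S), orthogonal = TRUE),
    model_spec("C+I+U", list(C = all9, I = I, U = U), orthogonal = TRUE),
    model_spec("C+I", list(C = all9, I = I), orthogonal = TRUE),
    model_spec("C+S", list(C = all9, S = S), orthogonal = TRUE),
    model_spec("C+U", list(C = all9, U = U), orthogonal = TRUE)
  )
  stats::setNames(specs, vapply(specs, `[[`, "", "name"))
}

#' Model degrees of freedom
#'
#' `df = p(p+1)/2 - q` where `p = 9` indicators give 45 unique second
#' moments and `q` counts free loadings, free residual variances and free
#' factor correlations. Factor variances are fixed to 1; the mean structure
#' is saturated and excluded from the count.
#'
#' @param spec a `ModelSpec`.
#' @return integer df.
#' @examples
#' model_degrees_of_freedom(model_library()[["I+U+S"]]) # 24
#' @export
model_degrees_of_freedom <- function(spec) {
  p <- length(spec$indicators)
  k <- ncol(spec$pattern)
  q <- sum(spec$pattern) + p + if (spec$orthogonal) 0L else k * (k - 1L) / 2L
  df <- as.integer(p * (p + 1) / 2 - q)
  if (df < 0L) stopf("model '%s' is not identified (df = %d)", spec$name, df)
  df
}

# ---- parameter packing -----------------------------------------------------

cfa_par_info <- function(spec, free_mu) {
  p <- length(spec$indicators)
  k <- ncol(spec$pattern)
  n_lam <- sum(spec$pattern)
  n_phi <- if (spec$orthogonal) 0L else as.integer(k * (k - 1L) / 2L)
  list(p = p, k = k, n_lam = n_lam, n_phi = n_phi, free_mu = free_mu,
       n_par = n_lam + p + n_phi + if (free_mu) p else 0L)
}

cfa_unpack <- function(par, spec, info) {
  lam <- matrix(0, info$p, info$k,
                dimnames = list(spec$indicators, spec$factor_names))
  lam[spec$pattern] <- par[seq_len(info$n_lam)]
  theta <- exp(par[info$n_lam + seq_len(info$p)])
  phi <- diag(info$k)
  if (info$n_phi > 0L) {
    rho <- tanh(par[info$n_lam + info$p + seq_len(info$n_phi)])
    phi[upper.tri(phi)] <- rho
    phi[lower.tri(phi)] <- t(phi)[lower.tri(phi)]
  }
  mu <- if (info$free_mu)
    par[info$n_lam + info$p + info$n_phi + seq_len(info$p)] else NULL
  list(lambda = lam, theta = theta, phi = phi, mu = mu)
}

cfa_implied_sigma <- function(est) {
  est$lambda %*% est$phi %*% t(est$lambda) +
    diag(est$theta, nrow = length(est$theta))
}

# Missingness-pattern sufficient statistics: for each pattern, the observed
# column set, count, mean vector and ML (divisor n_g) scatter matrix.
pattern_stats <- function(X) {
  pat <- apply(!is.na(X), 1L, function(r) paste(as.integer(r), collapse = ""))
  groups <- split(seq_len(nrow(X)), pat)
  groups <- groups[names(groups) != paste(rep("0", ncol(X)), collapse = "")]
  lapply(groups, function(ix) {
    obs <- which(!is.na(X[ix[1L], ]))
    Xi <- X[ix, obs, drop = FALSE]
    n <- length(ix)
    m <- colMeans(Xi)
    Xc <- sweep(Xi, 2L, m, "-")
    list(obs = obs, n = n, mean = m, S = crossprod(Xc) / n, rows = ix)
  })
}

# FIML log-likelihood of MVN(mu, sigma) given pattern stats.
fiml_loglik <- function(mu, sigma, pats) {
  ll <- 0
  for (g in pats) {
    o <- g$obs
    Sg <- sigma[o, o, drop = FALSE]
    ch <- tryCatch(chol(Sg), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    logdet <- 2 * sum(log(diag(ch)))
    inv <- chol2inv(ch)
    d <- g$mean - mu[o]
    quad <- sum(inv * g$S) + drop(t(d) %*% inv %*% d)
    ll <- ll - 0.5 * g$n * (length(o) * log(2 * pi) + logdet + quad)
  }
  ll
}

# EM for the saturated (unstructured) MVN with missing data; returns the
# FIML-maximizing mean/covariance and its log-likelihood.
em_saturated <- function(X, pats, max_iter = 1000, tol = 1e-9) {
  p <- ncol(X)
  mu <- colMeans(X, na.rm = TRUE)
  sigma <- stats::cov(X, use = "pairwise.complete.obs")
  sigma[is.na(sigma)] <- 0
  diag(sigma)[diag(sigma) <= 0 | is.na(diag(sigma))] <- 1
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8 * max(ev)) sigma <- sigma + diag(p) * (1e-8 * max(ev) - min(ev))
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    sx <- numeric(p)
    sxx <- matrix(0, p, p)
    n_tot <- 0
    for (g in pats) {
      o <- g$obs; m <- setdiff(seq_len(p), o)
      n_tot <- n_tot + g$n
      Soo_inv <- chol2inv(chol(sigma[o, o, drop = FALSE]))
      if (length(m) == 0L) {
        sx[o] <- sx[o] + g$n * g$mean
        sxx[o, o] <- sxx[o, o] + g$n * (g$S + tcrossprod(g$mean))
        next
      }
      B <- sigma[m, o, drop = FALSE] %*% Soo_inv            # regression coefs
      cond_cov <- sigma[m, m, drop = FALSE] - B %*% sigma[o, m, drop = FALSE]
      Em_mean <- mu[m] + drop(B %*% (g$mean - mu[o]))
      dev_oo <- g$S + tcrossprod(g$mean)                    # E[x_o x_o']
      # E[x_m x_o'] = E[x_m]E[x_o]' + B S_oo ; E[x_m x_m'] adds cond_cov
      Exm_xo <- tcrossprod(Em_mean, g$mean) + B %*% g$S
      Exm_xm <- cond_cov + tcrossprod(Em_mean) + B %*% g$S %*% t(B)
      sx[o] <- sx[o] + g$n * g$mean
      sx[m] <- sx[m] + g$n * Em_mean
      sxx[o, o] <- sxx[o, o] + g$n * dev_oo
      sxx[m, o] <- sxx[m, o] + g$n * Exm_xo
      sxx[o, m] <- sxx[o, m] + g$n * t(Exm_xo)
      sxx[m, m] <- sxx[m, m] + g$n * Exm_xm
    }
    mu_new <- sx / n_tot
    sigma_new <- sxx / n_tot - tcrossprod(mu_new)
    sigma_new <- (sigma_new + t(sigma_new)) / 2
    ll <- fiml_loglik(mu_new, sigma_new, pats)
    mu <- mu_new; sigma <- sigma_new
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  list(mu = mu, sigma = sigma, loglik = ll)
}

# Independence (baseline) model: diagonal sigma; FIML factorizes per column.
baseline_loglik <- function(X) {
  ll <- 0
  for (j in seq_len(ncol(X))) {
    x <- X[, j]; x <- x[!is.na(x)]
    n <- length(x)
    v <- mean((x - mean(x))^2)
    ll <- ll - 0.5 * n * (log(2 * pi) + log(v) + 1)
  }
  ll
}

#' Fit a confirmatory factor model
#'
#' Maximizes the multivariate-normal likelihood of
#' `Sigma(theta) = Lambda Phi Lambda' + Theta` by quasi-Newton (L-BFGS-B) on
#' an unconstrained reparameterization: free loadings, log residual
#' variances, atanh factor correlations, and (under FIML) free means. The
#' model chi-square is the likelihood-ratio statistic
#' `2(logL_saturated - logL_model)`, with the saturated model estimated by EM
#' over missingness patterns when data are incomplete. Standard errors come
#' from the inverse numerical Hessian; loading p-values are Wald z tests.
#'
#' @param scores data.frame (`subject` + task columns) or numeric matrix of
#'   the nine task scores.
#' @param spec a `ModelSpec` from [model_library()] or [model_spec()].
#' @param missing `"fiml"` (default; every subject with at least one observed
#'   indicator contributes), `"listwise"` (complete cases only) or
#'   `"pairwise"` (complete-data ML on the pairwise-complete covariance;
#'   reporting utility, see Details).
#' @param start optional numeric start vector (advanced use).
#' @param max_iter optimizer iteration cap.
#' @param tol convergence tolerance on the scaled objective.
#' @param se compute standard errors (default TRUE; disable in tight
#'   simulation loops).
#' @details Residual variances are bounded below at `1e-6` times the
#'   indicator variance, so Heywood cases surface as boundary estimates with
#'   a warning rather than negative variances. With `missing = "pairwise"`
#'   the pairwise-complete covariance is treated as if complete with the
#'   average pairwise n; inference under this option is approximate and it is
#'   intended for descriptive comparison only.
#' @return `CFAFit` list: `lambda`, `phi`, `theta`, `mu`, `loglik`,
#'   `loglik_sat`, `chisq`, `df`, `n`, `q` (free parameters in the df count),
#'   `converged`, `se_lambda`, `p_lambda`, `implied_sigma`, `spec`,
#'   `missing`, plus `baseline` (independence-model chisq/df) for fit
#'   indices.
#' @export
fit_cfa <- function(scores, spec, missing = c("fiml", "listwise", "pairwise"),
                    start = NULL, max_iter = 500, tol = 1e-10, se = TRUE) {
  missing <- match.arg(missing)
  X <- as.matrix(if (is.data.frame(scores))
    scores[, spec$indicators, drop = FALSE] else scores[, spec$indicators, drop = FALSE])
  storage.mode(X) <- "double"
  X <- X[rowSums(!is.na(X)) > 0L, , drop = FALSE]
  p <- ncol(X)
  n_obs_col <- colSums(!is.na(X))
  if (any(n_obs_col < 2L))
    stopf("indicator(s) with <2 observed values: %s",
          paste(colnames(X)[n_obs_col < 2L], collapse = ", "))

  if (missing == "listwise") X <- X[stats::complete.cases(X), , drop = FALSE]
  n <- nrow(X)
  complete <- !anyNA(X)

  if (missing == "pairwise" && !complete) {
    S <- stats::cov(X, use = "pairwise.complete.obs") * (1 - 1 / n)  # ML-style
    n_eff <- round(mean(crossprod(!is.na(X))[upper.tri(diag(p))]))
    return(fit_cfa_cov(S, colMeans(X, na.rm = TRUE), n_eff, spec, X_for_baseline = X,
                       start = start, max_iter = max_iter, tol = tol, se = se))
  }

  if (complete || missing == "listwise") {
    if (n < p + 1L) stopf("too few complete cases (%d)", n)
    xbar <- colMeans(X)
    Xc <- sweep(X, 2L, xbar, "-")
    S <- crossprod(Xc) / n
    return(fit_cfa_cov(S, xbar, n, spec, X_for_baseline = X,
                       start = start, max_iter = max_iter, tol = tol, se = se))
  }

  # ---- FIML path ----
  pats <- pattern_stats(X)
  info <- cfa_par_info(spec, free_mu = TRUE)
  fn <- function(par) {
    est <- cfa_unpack(par, spec, info)
    sig <- cfa_implied_sigma(est)
    ll <- fiml_loglik(est$mu, sig, pats)
    if (!is.finite(ll)) 1e10 else -ll
  }
  sat <- em_saturated(X, pats)
  if (is.null(start)) {
    # warm start: structured fit to the EM-saturated covariance, which is
    # within O(missing fraction) of the FIML optimum
    warm <- fit_cfa_cov(sat$sigma, sat$mu, n, spec, X_for_baseline = X,
                        start = NULL, max_iter = max_iter, tol = tol,
                        se = FALSE)
    start <- c(warm$lambda[spec$pattern], log(warm$theta),
               if (info$n_phi > 0L) atanh(warm$phi[upper.tri(warm$phi)]),
               sat$mu)
  }
  opt <- cfa_optimize(fn, spec, info, X, start, max_iter, tol)
  est <- cfa_unpack(opt$par, spec, info)
  sig <- cfa_implied_sigma(est)
  ll <- -opt$value
  fit <- cfa_assemble(est, sig, ll, sat$loglik, n, spec, info, opt, X,
                      sample_sigma = sat$sigma, sample_mu = sat$mu,
                      missing_label = "fiml")
  if (se) fit <- cfa_add_se(fit, fn, opt$par, spec, info)
  fit
}

# complete-data ML on a covariance matrix (mean profiled out at xbar)
fit_cfa_cov <- function(S, xbar, n, spec, X_for_baseline,
                        start, max_iter, tol, se) {
  p <- ncol(S)
  info <- cfa_par_info(spec, free_mu = FALSE)
  chS <- chol(S)
  logdetS <- 2 * sum(log(diag(chS)))
  const <- -0.5 * n * p * log(2 * pi)
  fn <- function(par) {
    est <- cfa_unpack(par, spec, info)
    sig <- cfa_implied_sigma(est)
    ch <- tryCatch(chol(sig), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    inv <- chol2inv(ch)
    0.5 * n * (2 * sum(log(diag(ch))) + sum(inv * S)) - const
  }
  opt <- cfa_optimize(fn, spec, info, X_for_baseline, start, max_iter, tol,
                      col_vars = diag(S))
  est <- cfa_unpack(opt$par, spec, info)
  est$mu <- xbar
  sig <- cfa_implied_sigma(est)
  ll <- -opt$value
  ll_sat <- const - 0.5 * n * (logdetS + p)
  fit <- cfa_assemble(est, sig, ll, ll_sat, n, spec, info, opt, X_for_baseline,
                      sample_sigma = S, sample_mu = xbar,
                      missing_label = "complete")
  if (se) fit <- cfa_add_se(fit, fn, opt$par, spec, info)
  fit
}

cfa_optimize <- function(fn, spec, info, X, start, max_iter, tol,
                         col_vars = NULL) {
  if (is.null(col_vars)) col_vars <- apply(X, 2L, stats::var, na.rm = TRUE)
  col_vars[!is.finite(col_vars) | col_vars <= 0] <- 1
  if (is.null(start)) {
    start <- c(rep(0.5, info$n_lam), log(rep(0.5, info$p) * col_vars),
               rep(atanh(0.2), info$n_phi))
    if (info$free_mu) start <- c(start, colMeans(X, na.rm = TRUE))
  }
  lower <- c(rep(-10, info$n_lam), log(1e-6 * col_vars), rep(-5, info$n_phi))
  upper <- c(rep(10, info$n_lam), log(1e3 * col_vars), rep(5, info$n_phi))
  if (info$free_mu) {
    lower <- c(lower, rep(-1e3, info$p)); upper <- c(upper, rep(1e3, info$p))
  }
  opt <- stats::optim(start, fn, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = max_iter, factr = tol / .Machine$double.eps))
  if (opt$convergence != 0) {
    # one restart from jittered start before flagging
    opt2 <- stats::optim(start * 0.9 + 0.05, fn, method = "L-BFGS-B",
                         lower = lower, upper = upper,
                         control = list(maxit = max_iter,
                                        factr = tol / .Machine$double.eps))
    if (opt2$value < opt$value) opt <- opt2
  }
  opt$heywood <- any(abs(opt$par[info$n_lam + seq_len(info$p)] -
                           log(1e-6 * col_vars)) < 1e-6)
  if (opt$heywood) warnf("model '%s': residual variance at lower bound (Heywood case)",
                         spec$name)
  opt
}

cfa_assemble <- function(est, sig, ll, ll_sat, n, spec, info, opt, X,
                         sample_sigma, sample_mu, missing_label) {
  df <- model_degrees_of_freedom(spec)
  chisq <- max(2 * (ll_sat - ll), 0)
  ll_base <- baseline_loglik(X)
  base_chisq <- max(2 * (ll_sat - ll_base), 0)
  p <- info$p
  structure(list(
    lambda = est$lambda, phi = est$phi, theta = est$theta, mu = est$mu,
    loglik = ll, loglik_sat = ll_sat, chisq = chisq, df = df, n = n,
    q = p * (p + 1) / 2 - df, n_par = info$n_par,
    converged = opt$convergence == 0, heywood = isTRUE(opt$heywood),
    implied_sigma = sig, sample_sigma = sample_sigma, sample_mu = sample_mu,
    baseline = list(chisq = base_chisq, df = p * (p + 1) / 2 - p),
    spec = spec, missing = missing_label,
    se_lambda = NULL, p_lambda = NULL), class = "efpath_cfa_fit")
}

cfa_add_se <- function(fit, fn, par, spec, info) {
  H <- tryCatch(stats::optimHess(par, fn), error = function(e) NULL)
  if (is.null(H)) return(fit)
  cov_par <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(cov_par)) {
    cov_par <- tryCatch(solve(H + diag(1e-8, nrow(H))), error = function(e) NULL)
  }
  if (is.null(cov_par)) return(fit)
  se <- sqrt(pmax(diag(cov_par), 0))
  se_lam <- matrix(NA_real_, info$p, info$k,
                   dimnames = dimnames(fit$lambda))
  se_lam[spec$pattern] <- se[seq_len(info$n_lam)]
  z <- fit$lambda / se_lam
  fit$se_lambda <- se_lam
  fit$p_lambda <- 2 * stats::pnorm(-abs(z))
  fit
}

#' @export
print.efpath_cfa_fit <- function(x, ...) {
  cat(sprintf("CFA fit: %s (%s, n = %d)\n", x$spec$name, x$missing, x$n))
  cat(sprintf("  logL = %.3f  chisq = %.3f  df = %d  converged = %s\n",
              x$loglik, x$chisq, x$df, x$converged))
  invisible(x)
}

#' Fit indices for a CFA fit
#'
#' CFI uses the independence model (free variances, zero covariances) fitted
#' on the same data and missingness handling as baseline:
#' `CFI = 1 - max(chisq_M - df_M, 0) / max(chisq_B - df_B, chisq_M - df_M, 0)`.
#' `RMSEA = sqrt(max(chisq_M - df_M, 0) / (df_M * n))`. SRMR is the root mean
#' squared difference between sample and implied correlations over the
#' strictly-lower-triangle entries (under FIML, "sample" is the
#' saturated-model EM covariance, which is defined with missing data).
#' `AIC = -2 logL + 2q`, `BIC = -2 logL + q log n`, with `q` the number of
#' estimated parameters including means.
#'
#' @param fit a `CFAFit`.
#' @return list with `cfi`, `rmsea`, `srmr`, `aic`, `bic`.
#' @export
fit_indices <- function(fit) {
  dM <- fit$chisq - fit$df
  dB <- fit$baseline$chisq - fit$baseline$df
  cfi <- 1 - max(dM, 0) / max(dB, dM, 0)
  rmsea <- if (fit$df == 0) NA_real_ else sqrt(max(dM, 0) / (fit$df * fit$n))
  rs <- stats::cov2cor(fit$sample_sigma)
  ri <- stats::cov2cor(fit$implied_sigma)
  lt <- lower.tri(rs)
  srmr <- sqrt(mean((rs[lt] - ri[lt])^2))
  q_all <- fit$n_par + if (fit$missing == "fiml") 0L else length(fit$mu)
  list(cfi = cfi, rmsea = rmsea, srmr = srmr,
       aic = -2 * fit$loglik + 2 * q_all,
       bic = -2 * fit$loglik + q_all * log(fit$n))
}

#' Chi-square difference test for nested models
#'
#' One-sided likelihood-ratio comparison: `Dchisq = chisq_restricted -
#' chisq_full` referred to the upper tail of `chi^2(Ddf)`. A negative
#' difference (estimation noise at the optimum) is reported as 0 with a
#' warning.
#'
#' @param fit_restricted fit of the restricted (fewer-parameter) model.
#' @param fit_full fit of the full model in which it is nested.
#' @return list with `dchisq`, `ddf`, `p`.
#' @examples
#' chisq_diff_stat(33.24, 2) # p = 6.07e-8 as printed for I+U+S vs U/I+S
#' @export
chisq_diff_test <- function(fit_restricted, fit_full) {
  d <- fit_restricted$chisq - fit_full$chisq
  ddf <- fit_restricted$df - fit_full$df
  if (ddf < 0) stopf("restricted model must have more df than the full model")
  if (d < 0) {
    warnf("negative chi-square difference (%.3g) truncated to 0", d)
    d <- 0
  }
  list(dchisq = d, ddf = ddf, p = chisq_diff_stat(d, ddf)$p)
}

#' Upper-tail p for a chi-square difference statistic
#'
#' @param dchisq difference statistic.
#' @param ddf difference in degrees of freedom.
#' @return list with `dchisq`, `ddf`, `p` (one-sided upper tail; 1 when
#'   `ddf` is 0 and the statistic is 0).
#' @export
chisq_diff_stat <- function(dchisq, ddf) {
  p <- if (ddf == 0) as.numeric(dchisq <= 0) else
    stats::pchisq(dchisq, ddf, lower.tail = FALSE)
  list(dchisq = dchisq, ddf = ddf, p = p)
}

#' Regression (Thurstone) factor scores
#'
#' `F_hat = Phi Lambda' Sigma^-1 (x - mu)`, evaluated on each subject's
#' observed sub-vector (per missingness pattern). Subjects with no observed
#' indicators get `NA` scores.
#'
#' @param fit a converged `CFAFit`.
#' @param scores score table or matrix (defaults to refitting data is not
#'   stored; pass the data used to fit, or any data with the same columns).
#' @return data.frame with `subject` and one column per factor.
#' @export
factor_scores <- function(fit, scores) {
  spec <- fit$spec
  subj <- if (is.data.frame(scores) && "subject" %in% names(scores))
    as.character(scores$subject) else as.character(seq_len(nrow(scores)))
  X <- as.matrix(if (is.data.frame(scores))
    scores[, spec$indicators, drop = FALSE] else scores[, spec$indicators, drop = FALSE])
  storage.mode(X) <- "double"
  sig <- fit$implied_sigma
  mu <- fit$mu
  A_full <- fit$phi %*% t(fit$lambda)   # k x p
  out <- matrix(NA_real_, nrow(X), ncol(fit$lambda),
                dimnames = list(NULL, colnames(fit$lambda)))
  pat <- apply(!is.na(X), 1L, function(r) paste(as.integer(r), collapse = ""))
  for (pp in unique(pat)) {
    ix <- which(pat == pp)
    obs <- which(!is.na(X[ix[1L], ]))
    if (length(obs) == 0L) next
    W <- A_full[, obs, drop = FALSE] %*%
      chol2inv(chol(sig[obs, obs, drop = FALSE]))       # k x |obs|
    Xi <- sweep(X[ix, obs, drop = FALSE], 2L, mu[obs], "-")
    out[ix, ] <- Xi %*% t(W)
  }
  data.frame(subject = subj, out, check.names = FALSE,
             stringsAsFactors = FALSE)
}
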