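# Shared fixtures, built in code and cached for the test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# reference loadings of the planted "C+S" bifactor truth
cs_truth <- function() {
  spec <- model_library()[["C+S"]]
  lam <- matrix(0, 9, 2, dimnames = list(spec$indicators, spec$factor_names))
  lam[, 1] <- c(0.55, 0.50, 0.45, 0.60, 0.65, 0.60, 0.50, 0.55, 0.50)
  lam[spec$pattern[, 2], 2] <- c(0.50, 0.60, 0.55)
  list(spec = spec, lambda = lam, theta = 1 - rowSums(lam^2),
       sigma = lam %*% t(lam) + diag(1 - rowSums(lam^2)))
}

# complete-data scores drawn from the C+S truth
draw_cs_scores <- function(n, seed) {
  tr <- cs_truth()
  withr::with_seed(seed, {
    X <- matrix(stats::rnorm(n * 9), n) %*% chol(tr$sigma)
    colnames(X) <- tr$spec$indicators
    X
  })
}

# small cohort reused by pipeline-level tests
tiny_cohort <- function() {
  fixture("tiny_cohort", function()
    simulate_cohort(cohort_config(n_subjects = 150, n_nodes = 40,
                                  n_snps = 800, n_genes = 80,
                                  n_informative = 30, seed = 42,
                                  n_trials_scale = 0.3)))
}

# independent brute-force restricted likelihood for a single-kernel mixed
# model, used as the REML oracle: grid over the variance ratio, refined by
# golden-section optimize()
grid_reml_oracle <- function(y, A, X = matrix(1, length(y), 1)) {
  n <- length(y)
  px <- ncol(X)
  loglik_at <- function(s2g, s2e) {
    V <- s2g * A + s2e * diag(n)
    ch <- chol(V)
    Vi <- chol2inv(ch)
    XtViX <- crossprod(X, Vi %*% X)
    P <- Vi - Vi %*% X %*% solve(XtViX, crossprod(X, Vi))
    -0.5 * (2 * sum(log(diag(ch))) + determinant(XtViX)$modulus[1] +
              drop(crossprod(y, P %*% y)) + (n - px) * log(2 * pi))
  }
  vy <- stats::var(y)
  grid <- expand.grid(h = seq(0.01, 0.99, by = 0.02),
                      tot = vy * c(0.8, 1, 1.25))
  lls <- mapply(function(h, tot) loglik_at(h * tot, (1 - h) * tot),
                grid$h, grid$tot)
  best <- grid[which.max(lls), ]
  # refine around the best grid point
  f <- function(par) -loglik_at(exp(par[1]), exp(par[2]))
  opt <- stats::optim(log(c(best$h * best$tot, (1 - best$h) * best$tot)), f,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  list(loglik = -opt$value, s2g = exp(opt$par[1]), s2e = exp(opt$par[2]))
}
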