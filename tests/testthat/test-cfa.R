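# Model library, degrees of freedom, ML/FIML estimation, fit indices,
# nested tests and factor scores.

test_that("the model library matches the canonical twelve-model set", {
  lib <- model_library()
  expect_length(lib, 12L)
  expect_setequal(names(lib), c("I+U+S", "S/I+U", "U/I+S", "S/U+I", "G",
                                "C+I+U+S", "C+I+S", "C+U+S", "C+I+U",
                                "C+I", "C+S", "C+U"))
  # one-general-factor: a single factor on all nine indicators
  expect_equal(ncol(lib[["G"]]$pattern), 1L)
  expect_true(all(lib[["G"]]$pattern))
  # C+S: common on all nine plus a shifting-specific factor, orthogonal
  cs <- lib[["C+S"]]
  expect_true(cs$orthogonal)
  expect_true(all(cs$pattern[, "C"]))
  expect_setequal(cs$indicators[cs$pattern[, "S"]],
                  c("numberletter", "colorshape", "categoryswitch"))
  # every spec satisfies the df + q = 45 accounting identity
  for (sp in lib) {
    df <- model_degrees_of_freedom(sp)
    q <- sum(sp$pattern) + 9 +
      if (sp$orthogonal) 0 else ncol(sp$pattern) * (ncol(sp$pattern) - 1) / 2
    expect_identical(df + as.integer(q), 45L, label = sp$name)
  }
})

test_that("published degrees of freedom are reproduced", {
  lib <- model_library()
  expect_identical(model_degrees_of_freedom(lib[["I+U+S"]]), 24L)
  expect_identical(model_degrees_of_freedom(lib[["U/I+S"]]), 26L)
  expect_identical(model_degrees_of_freedom(lib[["C+I+S"]]), 21L)
  expect_identical(model_degrees_of_freedom(lib[["C+U+S"]]), 21L)
  expect_identical(model_degrees_of_freedom(lib[["C+S"]]), 24L)
})

test_that("ML recovers generating parameters from large samples", {
  tr <- cs_truth()
  X <- draw_cs_scores(50000, seed = 21)
  fit <- fit_cfa(as.data.frame(X), tr$spec, se = FALSE)
  expect_true(fit$converged)
  lam <- fit$lambda
  for (k in 1:2) if (sum(lam[, k]) < 0) lam[, k] <- -lam[, k]
  expect_lt(max(abs(lam[tr$spec$pattern] - tr$lambda[tr$spec$pattern])), 0.02)
  expect_lt(max(abs(fit$theta - tr$theta)), 0.02)
})

test_that("FIML on complete data equals complete-data ML", {
  tr <- cs_truth()
  X <- draw_cs_scores(600, seed = 22)
  fit_ml <- fit_cfa(as.data.frame(X), tr$spec, se = FALSE)
  # force the FIML code path by a single missing cell, then compare
  # likelihood per retained subject against listwise ML on the same rows
  Xm <- X
  Xm[1, ] <- NA  # row fully missing: dropped, so same subjects remain
  fit_fiml <- fit_cfa(as.data.frame(Xm[-1, , drop = FALSE]), tr$spec,
                      missing = "fiml", se = FALSE)
  fit_ml2 <- fit_cfa(as.data.frame(X[-1, , drop = FALSE]), tr$spec,
                     se = FALSE)
  expect_equal(fit_fiml$chisq, fit_ml2$chisq, tolerance = 1e-4)
  expect_true(fit_ml$converged && fit_fiml$converged)

  # with genuinely incomplete data the FIML chisq stays calibrated
  withr::with_seed(23, {
    Xq <- draw_cs_scores(1500, seed = 24)
    Xq[matrix(runif(length(Xq)) < 0.1, nrow(Xq))] <- NA
    fit_m <- fit_cfa(as.data.frame(Xq), tr$spec, se = FALSE)
    expect_true(fit_m$converged)
    expect_lt(fit_m$chisq, qchisq(0.999, fit_m$df))
  })
})

test_that("likelihood optimum matches direct maximization from random restarts", {
  tr <- cs_truth()
  X <- draw_cs_scores(400, seed = 25)
  fit <- fit_cfa(as.data.frame(X), tr$spec, se = FALSE)
  # independent route: optim() from 10 random starting points on the same
  # objective, best value kept
  S <- crossprod(sweep(X, 2, colMeans(X))) / nrow(X)
  n <- nrow(X)
  spec <- tr$spec
  nll <- function(par) {
    lam <- matrix(0, 9, 2)
    lam[spec$pattern] <- par[1:12]
    th <- exp(par[13:21])
    sig <- tcrossprod(lam) + diag(th)
    ch <- tryCatch(chol(sig), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    n / 2 * (2 * sum(log(diag(ch))) + sum(chol2inv(ch) * S) + 9 * log(2 * pi))
  }
  best <- Inf
  withr::with_seed(26, {
    for (i in 1:10) {
      st <- c(runif(12, 0.2, 0.8), log(runif(9, 0.3, 0.9)))
      o <- optim(st, nll, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
      best <- min(best, o$value)
    }
  })
  expect_equal(-best, fit$loglik, tolerance = 1e-5 * abs(fit$loglik))
})

test_that("nesting never decreases the maximized likelihood", {
  X <- draw_cs_scores(800, seed = 27)
  lib <- model_library()
  ll <- function(name) fit_cfa(as.data.frame(X), lib[[name]], se = FALSE)$loglik
  # C+S is nested in C+U+S and in C+I+S; U/I+S is nested in I+U+S
  expect_lte(ll("C+S"), ll("C+U+S") + 1e-6)
  expect_lte(ll("C+S"), ll("C+I+S") + 1e-6)
  expect_lte(ll("U/I+S"), ll("I+U+S") + 1e-6)
})

test_that("fit indices behave at their defining boundaries", {
  X <- draw_cs_scores(2000, seed = 28)
  fit <- fit_cfa(as.data.frame(X), model_library()[["C+S"]], se = FALSE)
  idx <- fit_indices(fit)
  expect_true(idx$cfi >= 0 && idx$cfi <= 1)
  expect_gte(idx$rmsea, 0)
  # hand-check the formulas from the stored chisq values
  dM <- fit$chisq - fit$df
  dB <- fit$baseline$chisq - fit$baseline$df
  expect_equal(idx$cfi, 1 - max(dM, 0) / max(dB, dM, 0))
  expect_equal(idx$rmsea, sqrt(max(dM, 0) / (fit$df * fit$n)))
  # SRMR is zero when the implied matrix is the sample matrix
  fit0 <- fit
  fit0$implied_sigma <- fit$sample_sigma
  expect_equal(fit_indices(fit0)$srmr, 0)
})

test_that("chi-square difference test matches the analytic tail", {
  # identical fits: zero difference, p = 1
  X <- draw_cs_scores(500, seed = 29)
  f1 <- fit_cfa(as.data.frame(X), model_library()[["C+S"]], se = FALSE)
  same <- chisq_diff_test(f1, f1)
  expect_equal(same$dchisq, 0)
  expect_equal(same$p, 1)
  # the published statistic maps to the published tail probability
  pub <- chisq_diff_stat(33.24, 2)
  expect_equal(pub$p, 6.07e-8, tolerance = 0.01)
  expect_equal(pub$p, exp(-33.24 / 2), tolerance = 1e-12) # df=2 closed form
})

test_that("regression factor scores recover the latent factors", {
  tr <- cs_truth()
  withr::with_seed(30, {
    n <- 4000
    f <- matrix(rnorm(n * 2), n)
    X <- f %*% t(tr$lambda) +
      matrix(rnorm(n * 9), n) %*% diag(sqrt(tr$theta))
    colnames(X) <- tr$spec$indicators
  })
  fit <- fit_cfa(as.data.frame(X), tr$spec, se = FALSE)
  fs <- factor_scores(fit, as.data.frame(X))
  expect_gt(abs(cor(fs$C, f[, 1])), 0.8)
  expect_gt(abs(cor(fs$S, f[, 2])), 0.7)
  # determinism: scoring twice from the same fit is identical
  fs2 <- factor_scores(fit, as.data.frame(X))
  expect_equal(fs, fs2, tolerance = 1e-8)
  # identity limit: one indicator, unit loading, vanishing uniqueness —
  # the regression score is the standardized indicator itself
  xs <- data.frame(stroop = as.numeric(scale(X[, "stroop"])))
  fit1 <- list(lambda = matrix(1, 1, 1, dimnames = list("stroop", "F")),
               phi = diag(1), theta = 1e-8, mu = c(stroop = 0),
               implied_sigma = matrix(1 + 1e-8, 1, 1,
                                      dimnames = list("stroop", "stroop")),
               spec = model_spec("one", list(F = "stroop"),
                                 indicators = "stroop"))
  s1 <- factor_scores(fit1, xs)
  expect_equal(s1$F, xs$stroop, tolerance = 1e-6)
  # subjects with no observed indicators receive NA scores
  Xna <- as.data.frame(X[1:10, ])
  Xna[1, ] <- NA
  expect_true(all(is.na(factor_scores(fit, Xna)[1, -1])))
})

test_that("pairwise option reproduces the descriptive correlation table route", {
  tr <- cs_truth()
  withr::with_seed(31, {
    X <- draw_cs_scores(1200, seed = 31)
    X[matrix(runif(length(X)) < 0.05, nrow(X))] <- NA
  })
  fit <- fit_cfa(as.data.frame(X), tr$spec, missing = "pairwise", se = FALSE)
  expect_true(fit$converged)
  expect_equal(fit$df, 24L)
})
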