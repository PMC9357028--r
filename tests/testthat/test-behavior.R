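# Trial cleaning, exclusion rules, dependent-measure scoring and the
# transform/truncate/residualize chain.

make_trials <- function(rt, subject = "s1", task = "stroop",
                        condition = "congruent", correct = TRUE,
                        ssd = NA_real_) {
  n <- length(rt)
  data.frame(subject = rep_len(subject, n), task = rep_len(task, n),
             trial = seq_len(n), condition = rep_len(condition, n),
             rt_ms = rt, correct = rep_len(correct, n),
             ssd_ms = rep_len(ssd, n), stringsAsFactors = FALSE)
}

test_that("trial cleaning applies the 100 ms rule and the per-subject IQR fence", {
  rts <- c(90, 300, 320, 340, 5000)
  tr <- make_trials(rts)
  out <- clean_trials(tr, "stroop")
  expect_equal(out$report$n_removed_100ms, 1L)
  # retained after the 100 ms rule: {300, 320, 340, 5000}; type-7 quartiles
  # Q1 = 315, Q3 = 505, IQR = 190 -> upper fence 790, so 5000 is removed
  q <- quantile(c(300, 320, 340, 5000), c(0.25, 0.75), type = 7)
  expect_true(5000 > q[2] + 1.5 * diff(q))
  expect_equal(out$report$n_removed_iqr, 1L)
  expect_equal(sort(out$trials$rt_ms), c(300, 320, 340))

  # degenerate spread: fences collapse onto the common value, nothing removed
  same <- clean_trials(make_trials(rep(400, 20)), "stroop")
  expect_equal(same$report$n_removed_iqr, 0L)
  expect_equal(nrow(same$trials), 20L)

  # empty input is passed through with a warning note
  empty <- clean_trials(make_trials(numeric(0)), "stroop")
  expect_equal(nrow(empty$trials), 0L)
  expect_match(empty$report$warnings, "empty")
})

test_that("subjects exceeding the no-response or binomial thresholds are excluded", {
  rt <- rep(500, 40)
  rt[1:10] <- NA  # 25% no-response
  bad <- make_trials(rt, subject = "s_bad", task = "stroop")
  good <- make_trials(rep(500, 40), subject = "s_good", task = "stroop")
  out <- clean_trials(rbind(bad, good), "stroop")
  expect_equal(out$report$excluded_noresponse, "s_bad")
  expect_false("s_bad" %in% out$trials$subject)
  expect_true("s_good" %in% out$trials$subject)

  # at-chance accuracy fails the binomial rule
  chance <- make_trials(rep(500, 90), subject = "s_chance", task = "stroop",
                        correct = rep(c(TRUE, FALSE, FALSE, FALSE), length.out = 90))
  out2 <- clean_trials(rbind(chance, good), "stroop")
  expect_true("s_chance" %in% out2$report$excluded_binomial)
})

test_that("binomial exclusion threshold matches exact CDF enumeration", {
  # independent oracle: accumulate the binomial pmf term by term
  enum_threshold <- function(n, r, q = 0.95) {
    cdf <- cumsum(dbinom(0:n, n, r))
    (0:n)[which(cdf >= q)[1]]
  }
  expect_identical(exclusion_threshold(90, 0.5), 53L)
  expect_identical(exclusion_threshold(1, 0.5), 1L)
  for (n in c(1, 10, 36, 90, 160)) {
    for (r in c(0.25, 1 / 3, 0.5)) {
      expect_identical(exclusion_threshold(n, r), as.integer(enum_threshold(n, r)),
                       label = sprintf("n=%d r=%.2f", n, r))
    }
  }
  # chance accuracy approaching 0 needs no correct responses
  expect_identical(exclusion_threshold(90, 1e-12), 0L)
  expect_error(exclusion_threshold(90, 0), "chance_rate")
})

test_that("SSRT follows the percentile (integration) rule", {
  go <- make_trials(c(300, 400, 500, 600, 700), task = "stopsignal",
                    condition = "go")
  # stop-failure rate 2/5 = 0.4 -> nearest-rank 40th percentile of Go RTs
  # is 400; mean SSD 200 -> SSRT 200
  stop <- data.frame(subject = "s1", task = "stopsignal", trial = 6:10,
                     condition = "stop",
                     rt_ms = c(350, 360, NA, NA, NA),
                     correct = c(FALSE, FALSE, TRUE, TRUE, TRUE),
                     ssd_ms = 200, stringsAsFactors = FALSE)
  res <- compute_ssrt(rbind(go, stop))
  expect_equal(res$p_respond, 0.4)
  expect_equal(res$ssrt, 200)

  # all SSD equal d with the percentile RT at d gives SSRT 0
  stop0 <- stop
  stop0$ssd_ms <- 400
  expect_equal(compute_ssrt(rbind(go, stop0))$ssrt, 0)

  # degenerate stop-failure rates are flagged, not silently returned
  stop1 <- stop
  stop1$rt_ms <- c(350, 360, 355, 352, 349)  # responded on every stop trial
  expect_warning(r1 <- compute_ssrt(rbind(go, stop1)), "degenerate")
  expect_false(r1$reliable)
})

test_that("task scoring produces the documented dependent measures", {
  # d-prime with hand-computed inverse-normal values
  nb <- data.frame(subject = "s1", task = "letter3back", trial = 1:40,
                   condition = rep(c("match", "nonmatch"), each = 20),
                   rt_ms = 600,
                   correct = c(rep(c(TRUE, TRUE, TRUE, TRUE, FALSE), 4),
                               rep(c(FALSE, TRUE, TRUE, TRUE, TRUE), 4)),
                   ssd_ms = NA_real_, stringsAsFactors = FALSE)
  # hit rate 0.8, false-alarm rate 0.2 -> d' = qnorm(.8) - qnorm(.2) = 1.683
  d <- score_task(nb, "letter3back")$score
  expect_equal(d, qnorm(0.8) - qnorm(0.2), tolerance = 1e-12)
  expect_equal(round(d, 3), 1.683)

  # equal hit and false-alarm rates give d' = 0
  nb0 <- nb
  nb0$correct <- rep(c(TRUE, FALSE), 20)
  expect_equal(score_task(nb0, "letter3back")$score, 0)

  # switch cost is the plain difference of correct-trial RT means
  sw <- data.frame(subject = "s1", task = "numberletter", trial = 1:40,
                   condition = rep(c("repeat", "switch"), each = 20),
                   rt_ms = rep(c(800, 900), each = 20),
                   correct = TRUE, ssd_ms = NA_real_,
                   stringsAsFactors = FALSE)
  expect_equal(score_task(sw, "numberletter")$score, 100)
  # only correct trials enter the RT means
  sw$correct[sw$condition == "switch" & sw$rt_ms == 900][1:10] <- FALSE
  sw$rt_ms[sw$condition == "switch"][1:10] <- 5000
  sw$correct[sw$condition == "switch"][1:10] <- FALSE
  expect_equal(score_task(sw, "numberletter")$score, 100)

  # a subject lacking a required condition scores NA
  half <- sw[sw$condition == "repeat", ]
  expect_true(is.na(score_task(half, "numberletter")$score))
})

test_that("finalize transforms, orients and truncates", {
  raw <- data.frame(subject = paste0("s", 1:7),
                    antisaccade = c(0, 0.1, 0.2, 0.15, 0.12, 0.18, 0.22),
                    keeptrack = c(18, 20, 22, 19, 21, 17, 23),
                    stroop = c(100, 120, 90, 110, 105, 95, 115),
                    stringsAsFactors = FALSE)
  fin <- finalize_scores(raw)$scores
  # zero error rate -> accuracy 1 -> arcsine boundary pi/2 (checked on a
  # constant column so the truncation fences are degenerate)
  bound <- finalize_scores(data.frame(subject = paste0("s", 1:4),
                                      antisaccade = rep(0, 4)))
  expect_equal(bound$scores$antisaccade, rep(pi / 2, 4), tolerance = 1e-12)
  # keep-track proportion 0.5 (18/36) -> logit 0
  expect_equal(fin$keeptrack[1], 0, tolerance = 1e-12)
  # RT measures are negated so higher = better (no clamping at these values:
  # all within median +/- 1.5 IQR)
  expect_equal(fin$stroop, -raw$stroop)

  # truncation clamps to median +/- 1.5 IQR
  x <- c(-1, -0.5, 0, 0.5, 1, 5)
  med <- median(x); iqr <- IQR(x, type = 7)
  raw2 <- data.frame(subject = paste0("s", seq_along(x)), letter3back = x)
  fin2 <- finalize_scores(raw2)
  expect_equal(max(fin2$scores$letter3back), med + 1.5 * iqr)
  expect_equal(fin2$truncation_counts[["letter3back"]], sum(x > med + 1.5 * iqr))

  # the documented arithmetic case: median 0, IQR 2 clamps 5 to 3
  x3 <- c(-2, -1, 0, 0, 1, 2, 5)
  stopifnot(median(x3) == 0, IQR(x3, type = 7) == 2)
  f3 <- finalize_scores(data.frame(subject = paste0("s", 1:7),
                                   letter3back = x3))$scores$letter3back
  expect_equal(max(f3), 3)

  # idempotence: re-finalizing changes nothing
  again <- finalize_scores(cbind(raw2[1], letter3back = fin2$scores$letter3back))
  expect_equal(again$scores$letter3back, fin2$scores$letter3back,
               tolerance = 1e-12)
  expect_equal(unname(again$truncation_counts[["letter3back"]]), 0L)
})

test_that("residualization removes covariates and standardizes", {
  withr::with_seed(7, {
    n <- 300
    cov <- data.frame(subject = paste0("s", 1:n),
                      age = runif(n, 17, 31), sex = rbinom(n, 1, 0.5))
    sc <- data.frame(subject = cov$subject,
                     stroop = rnorm(n) + 0.3 * cov$age,
                     keeptrack = rnorm(n))
    sc$keeptrack[sample(n, 20)] <- NA
    out <- residualize_scores(sc, cov)
    expect_lt(abs(cor(out$stroop, cov$age)), 1e-10)
    expect_equal(mean(out$stroop), 0, tolerance = 1e-10)
    expect_equal(sd(out$stroop), 1, tolerance = 1e-10)
    ok <- !is.na(out$keeptrack)
    expect_equal(mean(out$keeptrack[ok]), 0, tolerance = 1e-10)
    expect_equal(sd(out$keeptrack[ok]), 1, tolerance = 1e-10)

    # a score that is an exact covariate function has zero residual variance
    sc2 <- data.frame(subject = cov$subject, stroop = 2 * cov$age)
    expect_warning(out2 <- residualize_scores(sc2, cov), "zero residual")
    expect_equal(unname(sd(out2$stroop)), 0, tolerance = 1e-10)

    # rank-deficient covariates are rejected
    cov_bad <- cov
    cov_bad$sex <- 1
    expect_error(residualize_scores(sc, cov_bad), "rank-deficient")
  })
})

test_that("higher-ability subjects earn higher finalized scores on every task", {
  withr::with_seed(11, {
    n <- 160
    eta <- matrix(rep(seq(-2, 2, length.out = n), 9), n)
    colnames(eta) <- efpath:::EF_TASKS
    rownames(eta) <- paste0("s", 1:n)
    trials <- efpath:::simulate_battery_trials(eta, seed = 5, scale = 1)
    st <- score_trials(trials)
    fin <- finalize_scores(st$raw)$scores
    for (task in efpath:::EF_TASKS) {
      r <- cor(fin[[task]], eta[match(fin$subject, rownames(eta)), task],
               use = "complete.obs")
      expect_gt(r, 0.4)
    }
  })
})
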