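# Trial-level cleaning, participant exclusion, dependent-measure scoring,
# transformation/orientation, truncation and covariate residualization.
#
# The nine-task battery follows the classic unity/diversity design: three
# inhibiting tasks (anti-saccade, stop-signal, color-word Stroop), three
# updating tasks (keep track, letter 3-back, spatial 2-back) and three
# shifting tasks (number-letter, color-shape, category switch). Each task's
# dependent measure is scored from cleaned trials, oriented so that a high
# score means high ability, transformed where proportions are involved,
# truncated at robust fences and finally residualized on age and sex.

EF_TASKS <- c("antisaccade", "stopsignal", "stroop",
              "keeptrack", "letter3back", "spatial2back",
              "numberletter", "colorshape", "categoryswitch")

# tasks whose dependent measure is an RT difference (trial-level IQR fences apply)
RT_TASKS <- c("stopsignal", "stroop", "numberletter", "colorshape", "categoryswitch")

#' Clean a trial table
#'
#' Removes trials with reaction time under 100 ms for every task. For tasks
#' whose dependent measure is RT-based, additionally removes trials whose RT
#' lies outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`, with quartiles computed per
#' subject from the trials that survived the 100 ms rule. Subjects with more
#' than `max_noresp` no-response trials, or with fewer correct responses than
#' the binomial exclusion threshold (see [exclusion_threshold()]), are flagged
#' for exclusion.
#'
#' @param trials data.frame with columns `subject`, `task`, `trial`,
#'   `condition`, `rt_ms`, `correct` and (stop-signal only) `ssd_ms`.
#'   `rt_ms` is `NA` for no-response trials.
#' @param task_kind task label, one of `EF_TASKS` (determines whether the
#'   trial-level IQR fences apply and the chance accuracy used for exclusion).
#' @param max_noresp maximum tolerated no-response proportion (default 0.2).
#' @param chance_rate chance-level accuracy for the binomial exclusion rule;
#'   defaults depend on the task (0.5 two-choice, 0.25 four-choice Stroop,
#'   1/3 three-choice anti-saccade).
#' @return list with `trials` (cleaned table) and `report` (a `CleanReport`
#'   list: removal counts and excluded subjects). Excluded subjects' trials
#'   are dropped from the output.
#' @export
clean_trials <- function(trials, task_kind,
                         max_noresp = 0.2, chance_rate = NULL) {
  task_kind <- match.arg(task_kind, EF_TASKS)
  if (is.null(chance_rate)) {
    chance_rate <- switch(task_kind,
      stroop = 0.25, antisaccade = 1 / 3, keeptrack = 0.25, 0.5)
  }
  report <- list(task = task_kind, n_removed_100ms = 0L, n_removed_iqr = 0L,
                 excluded_noresponse = character(0),
                 excluded_binomial = character(0),
                 warnings = character(0))
  if (nrow(trials) == 0L) {
    report$warnings <- "empty trial set"
    return(list(trials = trials, report = report))
  }
  trials$subject <- as.character(trials$subject)

  # no-response / accuracy exclusions are judged on the raw trial set
  by_subj <- split(trials, trials$subject)
  noresp <- if (task_kind == "keeptrack") {
    # written recall; no response-time channel
    stats::setNames(rep(0, length(by_subj)), names(by_subj))
  } else if (task_kind == "stopsignal") {
    # No-go trials are supposed to have no response; judge on Go trials
    vapply(by_subj, function(d) {
      go <- d[is.na(d$ssd_ms), , drop = FALSE]
      if (nrow(go) == 0L) return(1)
      mean(is.na(go$rt_ms))
    }, 0)
  } else {
    vapply(by_subj, function(d) mean(is.na(d$rt_ms)), 0)
  }
  report$excluded_noresponse <- names(noresp)[noresp > max_noresp]

  acc_excl <- vapply(by_subj, function(d) {
    if (task_kind == "stopsignal") d <- d[is.na(d$ssd_ms), , drop = FALSE]
    n <- nrow(d)
    if (n == 0L) return(TRUE)
    sum(d$correct, na.rm = TRUE) < exclusion_threshold(n, chance_rate)
  }, TRUE)
  report$excluded_binomial <- setdiff(names(acc_excl)[acc_excl],
                                      report$excluded_noresponse)

  # 100 ms rule (all tasks)
  drop100 <- !is.na(trials$rt_ms) & trials$rt_ms < 100
  report$n_removed_100ms <- sum(drop100)
  trials <- trials[!drop100, , drop = FALSE]

  # per-subject IQR fences for RT-dependent tasks
  if (task_kind %in% RT_TASKS && nrow(trials) > 0L) {
    keep <- unlist(lapply(split(seq_len(nrow(trials)), trials$subject), function(ix) {
      rt <- trials$rt_ms[ix]
      ok <- !is.na(rt)
      if (!any(ok)) return(ix)
      q <- stats::quantile(rt[ok], c(0.25, 0.75), type = 7, names = FALSE)
      iqr <- q[2] - q[1]
      lo <- q[1] - 1.5 * iqr
      hi <- q[2] + 1.5 * iqr
      ix[!ok | (rt >= lo & rt <= hi)]
    }), use.names = FALSE)
    report$n_removed_iqr <- nrow(trials) - length(keep)
    trials <- trials[sort(keep), , drop = FALSE]
  }

  excl <- union(report$excluded_noresponse, report$excluded_binomial)
  trials <- trials[!(trials$subject %in% excl), , drop = FALSE]
  list(trials = trials, report = report)
}

#' Minimum correct count under the binomial exclusion rule
#'
#' A subject completing `n_trials` trials at chance accuracy `chance_rate`
#' must score at least the 95% quantile of Binomial(n, r) correct responses
#' to be retained: the smallest `k` with `P(X <= k) >= 0.95`.
#'
#' @param n_trials number of trials (> 0).
#' @param chance_rate chance-level accuracy in (0, 1).
#' @param quantile_level quantile of the binomial null (default 0.95).
#' @return integer minimum correct count.
#' @examples
#' exclusion_threshold(90, 0.5) # 53
#' @export
exclusion_threshold <- function(n_trials, chance_rate, quantile_level = 0.95) {
  if (n_trials <= 0) stopf("n_trials must be positive")
  if (!is.finite(chance_rate) || chance_rate <= 0 || chance_rate >= 1)
    stopf("chance_rate must be in (0,1)")
  as.integer(stats::qbinom(quantile_level, n_trials, chance_rate))
}

#' Stop-signal reaction time by the integration (percentile) method
#'
#' Let `p` be the proportion of No-go (stop) trials on which the subject
#' responded (the stop-failure rate). The SSRT is the `p`-th percentile of the
#' correct-Go RT distribution minus the mean stop-signal delay over No-go
#' trials. The percentile is nearest-rank on the sorted correct-Go RTs
#' (`ceiling(p * n)`); this does not assume the staircase converged to
#' exactly 50% stopping.
#'
#' @param trials stop-signal trial table (cleaned); No-go trials are the rows
#'   with non-missing `ssd_ms`.
#' @return list with `ssrt` (ms), `p_respond` (stop-failure rate) and
#'   `reliable` (`FALSE` when p is 0 or 1, in which case the percentile is
#'   degenerate and the estimate is flagged).
#' @examples
#' tr <- data.frame(
#'   subject = "s1", task = "stopsignal", trial = 1:10,
#'   condition = rep(c("go", "stop"), each = 5),
#'   rt_ms = c(300, 400, 500, 600, 700, 350, 360, NA, NA, NA),
#'   correct = c(rep(TRUE, 5), rep(FALSE, 2), rep(TRUE, 3)),
#'   ssd_ms = c(rep(NA, 5), rep(200, 5))
#' )
#' compute_ssrt(tr)$ssrt # 400 - 200 = 200
#' @export
compute_ssrt <- function(trials) {
  nogo <- trials[!is.na(trials$ssd_ms), , drop = FALSE]
  go <- trials[is.na(trials$ssd_ms), , drop = FALSE]
  go_rt <- sort(go$rt_ms[go$correct & !is.na(go$rt_ms)])
  if (length(go_rt) < 1L || nrow(nogo) < 1L)
    stopf("need at least one correct Go trial and one No-go trial")
  p <- mean(!is.na(nogo$rt_ms))
  reliable <- TRUE
  if (p <= 0 || p >= 1) {
    warnf("stop-failure rate is %g; SSRT percentile is degenerate", p)
    reliable <- FALSE
  }
  k <- min(max(ceiling(p * length(go_rt)), 1L), length(go_rt))
  ssrt <- go_rt[k] - mean(nogo$ssd_ms)
  list(ssrt = ssrt, p_respond = p, reliable = reliable)
}

# d-prime with extreme rates clamped to [1/(2N), 1 - 1/(2N)]
dprime <- function(hit_rate, fa_rate, n_signal, n_noise) {
  clamp <- function(r, n) min(max(r, 1 / (2 * n)), 1 - 1 / (2 * n))
  stats::qnorm(clamp(hit_rate, n_signal)) - stats::qnorm(clamp(fa_rate, n_noise))
}

#' Score one task from cleaned trials
#'
#' Raw (untransformed, unoriented) dependent measure per subject:
#' \describe{
#'   \item{antisaccade}{proportion of error responses}
#'   \item{stopsignal}{SSRT via [compute_ssrt()]}
#'   \item{stroop}{mean RT(incongruent) - mean RT(congruent), correct trials}
#'   \item{numberletter/colorshape/categoryswitch}{mean RT(switch) - mean
#'     RT(repeat), correct trials}
#'   \item{keeptrack}{number of correctly recalled words}
#'   \item{letter3back/spatial2back}{d-prime = z(hit) - z(false alarm) with
#'     rates clamped to `[1/(2N), 1 - 1/(2N)]`}
#' }
#' RT averages use correct trials only. A subject lacking trials in a
#' required condition gets `NA`.
#'
#' @param trials cleaned trial table for one task.
#' @param task_kind task label.
#' @return data.frame with columns `subject`, `score`.
#' @export
score_task <- function(trials, task_kind) {
  task_kind <- match.arg(task_kind, EF_TASKS)
  subjects <- unique(as.character(trials$subject))
  score_one <- function(d) {
    switch(task_kind,
      antisaccade = mean(!d$correct),
      stopsignal = tryCatch(suppressWarnings(compute_ssrt(d)$ssrt),
                            error = function(e) NA_real_),
      keeptrack = sum(d$correct),
      letter3back = ,
      spatial2back = {
        sig <- d[d$condition == "match", , drop = FALSE]
        noi <- d[d$condition == "nonmatch", , drop = FALSE]
        if (nrow(sig) == 0L || nrow(noi) == 0L) return(NA_real_)
        dprime(mean(sig$correct), mean(!noi$correct), nrow(sig), nrow(noi))
      },
      { # stroop / switch tasks: RT difference over correct trials
        hard_lab <- if (task_kind == "stroop") "incongruent" else "switch"
        easy_lab <- if (task_kind == "stroop") "congruent" else "repeat"
        hard <- d$rt_ms[d$condition == hard_lab & d$correct & !is.na(d$rt_ms)]
        easy <- d$rt_ms[d$condition == easy_lab & d$correct & !is.na(d$rt_ms)]
        if (length(hard) == 0L || length(easy) == 0L) return(NA_real_)
        mean(hard) - mean(easy)
      })
  }
  sc <- vapply(split(trials, factor(as.character(trials$subject), subjects)),
               score_one, 0)
  data.frame(subject = subjects, score = unname(sc),
             stringsAsFactors = FALSE)
}

#' Orient, transform and truncate raw task measures
#'
#' Applies the score-table finishing steps: RT-based measures (SSRT, Stroop
#' and switch costs) are negated so a high score means high ability; the
#' anti-saccade error rate is converted to accuracy and arcsine-(square-root)
#' transformed; the keep-track count is converted to a proportion (out of
#' `keeptrack_total`) and logit transformed with a 0.5/N continuity adjustment
#' at the boundaries; d-prime measures are left as is. Each column is then
#' truncated to `[median - 1.5 IQR, median + 1.5 IQR]` (IQR with
#' linear-interpolation type-7 quartiles): values outside the fences are
#' replaced by the fence.
#'
#' @param raw data.frame with a `subject` column and one column per task
#'   (named as in `EF_TASKS`), holding raw measures from [score_task()].
#' @param keeptrack_total total keep-track words (default 36: 12 lists of
#'   2-4 target categories).
#' @return list with `scores` (transformed, truncated table, same shape) and
#'   `truncation_counts` (per column).
#' @export
finalize_scores <- function(raw, keeptrack_total = 36) {
  scores <- raw
  counts <- integer(0)
  for (task in intersect(EF_TASKS, names(scores))) {
    x <- scores[[task]]
    if (all(is.na(x))) {
      warnf("column '%s' is all-missing; left as is", task)
      counts[task] <- 0L
      next
    }
    x <- switch(task,
      antisaccade = asin(sqrt(pmin(pmax(1 - x, 0), 1))),
      keeptrack = {
        p <- x / keeptrack_total
        p <- pmin(pmax(p, 0.5 / keeptrack_total), 1 - 0.5 / keeptrack_total)
        log(p / (1 - p))
      },
      stopsignal = ,
      stroop = ,
      numberletter = ,
      colorshape = ,
      categoryswitch = -x,
      x)
    med <- stats::median(x, na.rm = TRUE)
    iqr <- stats::IQR(x, na.rm = TRUE, type = 7)
    lo <- med - 1.5 * iqr
    hi <- med + 1.5 * iqr
    counts[task] <- sum(x < lo | x > hi, na.rm = TRUE)
    x <- pmin(pmax(x, lo), hi)
    scores[[task]] <- x
  }
  list(scores = scores, truncation_counts = counts)
}

#' Residualize task scores on age and sex
#'
#' Per column, ordinary least squares on intercept + age + sex over the
#' non-missing cases; residuals are standardized to mean 0, SD 1 (Z-scores).
#' Zero-variance residuals (a score fully explained by the covariates) are
#' left at 0 with a warning.
#'
#' @param scores finalized score table (`subject` + task columns).
#' @param covariates data.frame with `subject`, `age`, `sex` for every scored
#'   subject.
#' @return score table of standardized residuals.
#' @export
residualize_scores <- function(scores, covariates) {
  m <- match(as.character(scores$subject), as.character(covariates$subject))
  if (anyNA(m)) stopf("covariates missing for %d subjects", sum(is.na(m)))
  X <- cbind(1, covariates$age[m], covariates$sex[m])
  if (qr(X)$rank < ncol(X)) stopf("rank-deficient covariates")
  out <- scores
  for (task in setdiff(names(scores), "subject")) {
    y <- scores[[task]]
    ok <- !is.na(y)
    if (sum(ok) < ncol(X) + 1L) next
    r <- stats::lsfit(X[ok, -1, drop = FALSE], y[ok])$residuals
    s <- stats::sd(r)
    if (s < 1e-12) {
      warnf("column '%s' has zero residual variance; left unstandardized", task)
    } else {
      r <- (r - mean(r)) / s
    }
    y[ok] <- r
    out[[task]] <- y
  }
  out
}

#' Score a full multi-task trial table
#'
#' Convenience wrapper running [clean_trials()] and [score_task()] per task
#' and assembling the subjects x tasks raw measure table.
#'
#' @param trials trial table with a `task` column covering one or more of
#'   `EF_TASKS`.
#' @return list with `raw` (wide data.frame) and `reports` (per-task
#'   `CleanReport`s).
#' @export
score_trials <- function(trials) {
  tasks <- intersect(EF_TASKS, unique(as.character(trials$task)))
  subjects <- unique(as.character(trials$subject))
  raw <- data.frame(subject = subjects, stringsAsFactors = FALSE)
  reports <- list()
  for (task in tasks) {
    cl <- clean_trials(trials[trials$task == task, , drop = FALSE], task)
    reports[[task]] <- cl$report
    sc <- score_task(cl$trials, task)
    raw[[task]] <- sc$score[match(subjects, sc$subject)]
  }
  list(raw = raw, reports = reports)
}
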