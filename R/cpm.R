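# Connectome-based predictive modelling (CPM) of factor scores.
#
# Pipeline per cross-validation fold: standardize edges within the training
# and the test set separately; select edges whose partial correlation with
# the outcome (controlling scanner and head motion) passes the p threshold
# on the training set; summarize each subject by the unit-weighted sums of
# the selected positive and negative edges; fit y ~ pos_sum + neg_sum on
# the training set; predict the held-out subjects. Prediction accuracy is
# the Pearson correlation between predicted and observed scores over all
# held-out predictions of a split, averaged over random splits, with
# significance from permutations of the outcome.
#
# Implementation note: the edge matrix is large (34,716 columns at the
# 264-node parcellation), so all fold-wise moments, covariate projections
# and edge-outcome correlations are computed through full-matrix cross
# products against zero-padded indicator/outcome columns — row subsets of
# the edge matrix are never materialized. Column standardization cancels in
# the correlations and enters the unit-weighted sums as an affine map, so
# the algebra is exact, and a naive reference implementation backs it in
# the test suite.

#' Edge selection by partial correlation
#'
#' Partial Pearson correlation between each edge and `y`, residualizing
#' both on the covariates; `t = r sqrt((n - 2 - q) / (1 - r^2))` with
#' two-sided p. Edges with `p <= p_thresh` are split into a positive and a
#' negative mask by the sign of r.
#'
#' @param edges_train n x E edge matrix (training subjects).
#' @param y_train outcome vector.
#' @param covariates optional n x q numeric matrix (e.g. scanner dummy,
#'   mean FD).
#' @param p_thresh selection threshold (default 0.05).
#' @return list with `pos`, `neg` (edge index vectors), `r`, `p` per edge,
#'   and `n_zero_variance` (excluded edges).
#' @export
select_edges <- function(edges_train, y_train, covariates = NULL,
                         p_thresh = 0.05) {
  n <- length(y_train)
  q <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  if (n <= q + 3L) stopf("need n_train > q + 3")
  st <- edge_correlation_stats(edges_train, y_train, covariates)
  r <- st$r
  df <- n - 2L - q
  tt <- r * sqrt(df / pmax(1 - r^2, 1e-12))
  p <- 2 * stats::pt(-abs(tt), df)
  p[st$zero_var] <- NA
  sel <- which(p <= p_thresh)
  list(pos = sel[r[sel] > 0], neg = sel[r[sel] < 0], r = r, p = p,
       n_zero_variance = sum(st$zero_var))
}

# Correlations of every edge with y after projecting out covariates, using
# projection algebra only (no per-edge residual matrices): with Q an
# orthonormal basis of [1, covariates], corr_j = <e_j, y_r> / (||e_j_r|| ||y_r||)
# where x_r = x - Q Q' x.
edge_correlation_stats <- function(edges, y, covariates = NULL) {
  n <- nrow(edges)
  C <- cbind(rep(1, n), if (!is.null(covariates)) as.matrix(covariates))
  Q <- qr.Q(qr(C))
  yr <- y - Q %*% crossprod(Q, y)
  QtE <- crossprod(Q, edges)                    # (q+1) x E
  num <- drop(crossprod(edges, yr))             # e_j' y_r = e_j_r' y_r
  e2 <- colSums(edges^2) - colSums(QtE^2)       # ||e_j_r||^2
  zero_var <- e2 <= 1e-12 * pmax(colSums(edges^2), 1)
  denom <- sqrt(pmax(e2, 1e-300)) * sqrt(sum(yr^2))
  r <- num / denom
  r[zero_var] <- 0
  r <- pmin(pmax(r, -1), 1)
  list(r = r, zero_var = zero_var, yr = drop(yr))
}

#' Unit-weighted network summary scores
#'
#' @param edges n x E edge matrix (already standardized as desired).
#' @param masks list with `pos` and `neg` edge index vectors.
#' @return n x 2 matrix with columns `pos_sum`, `neg_sum` (0 when a mask is
#'   empty; flagged via the `"empty"` attribute).
#' @export
summarize_edges <- function(edges, masks) {
  pos <- if (length(masks$pos))
    rowSums(edges[, masks$pos, drop = FALSE]) else rep(0, nrow(edges))
  neg <- if (length(masks$neg))
    rowSums(edges[, masks$neg, drop = FALSE]) else rep(0, nrow(edges))
  out <- cbind(pos_sum = pos, neg_sum = neg)
  attr(out, "empty") <- c(pos = length(masks$pos) == 0L,
                          neg = length(masks$neg) == 0L)
  out
}

# standardize the columns of a submatrix by that submatrix's own moments
scale_within <- function(x) {
  m <- colMeans(x)
  s <- sqrt(colMeans(x^2) - m^2)
  s[s < 1e-12] <- 1
  sweep(sweep(x, 2L, m, "-"), 2L, s, "/")
}

# ---- fold algebra ----------------------------------------------------------
# Per-fold moments, covariate projections and residual norms for one k-fold
# partition, computed without materializing row subsets of `edges`.
cpm_precompute <- function(edges, folds, covariates = NULL) {
  n <- nrow(edges)
  k <- max(folds)
  q <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  IND <- matrix(0, n, k)
  IND[cbind(seq_len(n), folds)] <- 1            # test-fold indicators
  sum_all <- drop(crossprod(edges, rep(1, n)))
  sum_te <- crossprod(edges, IND)               # E x k
  E2sums <- {
    E2 <- edges^2
    list(all = drop(crossprod(E2, rep(1, n))), te = crossprod(E2, IND))
  }
  # padded orthonormal covariate bases, all folds side by side
  Qpad <- matrix(0, n, k * (q + 1L))
  n_tr <- integer(k)
  for (f in seq_len(k)) {
    tr <- which(folds != f)
    n_tr[f] <- length(tr)
    C <- cbind(rep(1, length(tr)),
               if (q) as.matrix(covariates)[tr, , drop = FALSE])
    Qpad[tr, (f - 1L) * (q + 1L) + seq_len(q + 1L)] <- qr.Q(qr(C))
  }
  QtE <- crossprod(Qpad, edges)                 # k(q+1) x E
  pre <- vector("list", k)
  for (f in seq_len(k)) {
    rows_q <- (f - 1L) * (q + 1L) + seq_len(q + 1L)
    sum_tr <- sum_all - sum_te[, f]
    sumsq_tr <- E2sums$all - E2sums$te[, f]
    m_tr <- sum_tr / n_tr[f]
    s_tr <- sqrt(pmax(sumsq_tr / n_tr[f] - m_tr^2, 0)); s_tr[s_tr < 1e-12] <- 1
    n_te <- n - n_tr[f]
    m_te <- sum_te[, f] / n_te
    s_te <- sqrt(pmax(E2sums$te[, f] / n_te - m_te^2, 0)); s_te[s_te < 1e-12] <- 1
    enorm2 <- sumsq_tr - colSums(QtE[rows_q, , drop = FALSE]^2)
    zero_var <- enorm2 <= 1e-12 * pmax(sumsq_tr, 1)
    pre[[f]] <- list(tr = which(folds != f), te = which(folds == f),
                     Qrows = rows_q, m_tr = m_tr, s_tr = s_tr,
                     m_te = m_te, s_te = s_te,
                     enorm2 = pmax(enorm2, 1e-300), zero_var = zero_var,
                     df = n_tr[f] - 2L - q)
  }
  list(folds = pre, Qpad = Qpad, q = q, n = n, k = k)
}

# Evaluate the full CPM pipeline (selection, summary, fit, prediction) for
# one outcome vector on a precomputed partition. The edge-outcome inner
# products of every fold are taken in a single cross product.
cpm_eval_y <- function(edges, pre, y, p_thresh, cand = NULL) {
  n <- nrow(edges)
  k <- length(pre$folds)
  YR <- matrix(0, n, k)
  for (f in seq_len(k)) {
    fd <- pre$folds[[f]]
    ytr <- y[fd$tr]
    Qf <- pre$Qpad[fd$tr, fd$Qrows, drop = FALSE]
    YR[fd$tr, f] <- ytr - Qf %*% crossprod(Qf, ytr)
  }
  NUM <- crossprod(edges, YR)                   # E x k, all folds at once
  pred <- numeric(n)
  sel_all <- integer(0)
  for (f in seq_len(k)) {
    fd <- pre$folds[[f]]
    yr2 <- sum(YR[fd$tr, f]^2)
    r <- NUM[, f] / (sqrt(fd$enorm2) * sqrt(yr2))
    r[fd$zero_var] <- 0
    r <- pmin(pmax(r, -1), 1)
    tt <- r * sqrt(fd$df / pmax(1 - r^2, 1e-12))
    p <- 2 * stats::pt(-abs(tt), fd$df)
    sel <- which(p <= p_thresh & !fd$zero_var)
    if (!is.null(cand)) sel <- intersect(sel, cand)
    sel_all <- c(sel_all, sel)
    pos <- sel[r[sel] > 0]; neg <- sel[r[sel] < 0]
    ytr <- y[fd$tr]
    if (!length(pos) && !length(neg)) {
      pred[fd$te] <- mean(ytr)
      next
    }
    sums <- function(rows, mm, ss) {
      cbind(pos_sum = if (length(pos))
        drop(edges[rows, pos, drop = FALSE] %*% (1 / ss[pos])) -
          sum(mm[pos] / ss[pos]) else rep(0, length(rows)),
        neg_sum = if (length(neg))
          drop(edges[rows, neg, drop = FALSE] %*% (1 / ss[neg])) -
          sum(mm[neg] / ss[neg]) else rep(0, length(rows)))
    }
    str <- sums(fd$tr, fd$m_tr, fd$s_tr)
    ste <- sums(fd$te, fd$m_te, fd$s_te)
    keep <- c(length(pos) > 0L, length(neg) > 0L)
    fitc <- stats::lsfit(str[, keep, drop = FALSE], ytr)$coefficients
    pred[fd$te] <- fitc[1L] + ste[, keep, drop = FALSE] %*% fitc[-1L]
  }
  list(r = stats::cor(pred, y), selected = sel_all, pred = pred)
}

# Naive reference implementation of one split (explicit standardization of
# materialized train/test submatrices); used as the independent oracle for
# the fold algebra in the test suite.
cpm_reference_split <- function(edges, y, covariates, folds, p_thresh) {
  n <- nrow(edges)
  q <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  pred <- numeric(n)
  selected <- integer(0)
  for (f in seq_len(max(folds))) {
    te <- folds == f; tr <- !te
    Etr <- scale_within(edges[tr, , drop = FALSE])
    Ete <- scale_within(edges[te, , drop = FALSE])
    sel <- select_edges(Etr, y[tr],
                        if (q) as.matrix(covariates)[tr, , drop = FALSE],
                        p_thresh)
    selected <- c(selected, sel$pos, sel$neg)
    str <- summarize_edges(Etr, sel)
    ste <- summarize_edges(Ete, sel)
    keep <- !attr(str, "empty")
    if (!any(keep)) {
      pred[te] <- mean(y[tr])
      next
    }
    fitc <- stats::lsfit(str[, keep, drop = FALSE], y[tr])$coefficients
    pred[te] <- fitc[1L] + ste[, keep, drop = FALSE] %*% fitc[-1L]
  }
  list(r = stats::cor(pred, y), selected = selected)
}

#' Run the CPM cross-validation pipeline
#'
#' `n_splits` random k-fold partitions; within each fold edges are
#' standardized within the training and the test subjects separately,
#' selection and model fitting use the training subjects only, and each
#' split's accuracy is the Pearson r between concatenated held-out
#' predictions and the observed scores. Per-edge selection tallies are
#' accumulated over all `k * n_splits` training folds.
#'
#' @param edges n x E edge matrix (raw; standardization is fold-internal).
#' @param y outcome vector (factor scores).
#' @param covariates optional numeric matrix for the partial correlation.
#' @param k folds (default 10).
#' @param n_splits random re-partitions (default 100).
#' @param p_thresh selection threshold.
#' @param edge_subset optional candidate edge ids (e.g. edges incident to a
#'   node set); selection counts are reported on the full edge universe.
#' @param seed integer seed.
#' @return `CPMResult` list: `r_split` (per-split r), `mean_r`,
#'   `selection_counts` (length E), `total_iterations` (= k * n_splits),
#'   `k`, `n_splits`, `p_thresh`, `n`.
#' @export
run_cpm <- function(edges, y, covariates = NULL, k = 10, n_splits = 100,
                    p_thresh = 0.05, edge_subset = NULL, seed = 1) {
  n <- nrow(edges)
  q <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  if (n < 10 * (q + 3)) stopf("need n >= 10 * (q + 3) subjects")
  E <- ncol(edges)
  counts <- integer(E)
  r_split <- numeric(n_splits)
  for (s in seq_len(n_splits)) {
    folds <- with_seed(derive_seed(seed, paste0("split", s)),
                       sample(rep_len(seq_len(k), n)))
    pre <- cpm_precompute(edges, folds, covariates)
    ev <- cpm_eval_y(edges, pre, y, p_thresh, edge_subset)
    counts <- counts + tabulate(ev$selected, nbins = E)
    r_split[s] <- ev$r
  }
  structure(list(r_split = r_split, mean_r = mean(r_split),
                 selection_counts = counts,
                 total_iterations = k * n_splits,
                 k = k, n_splits = n_splits,
                 p_thresh = p_thresh, n = n),
            class = "efpath_cpm")
}

#' @export
print.efpath_cpm <- function(x, ...) {
  cat(sprintf("CPM: mean r = %.3f over %d split(s) (k = %d, p <= %g)\n",
              x$mean_r, x$n_splits, x$k, x$p_thresh))
  invisible(x)
}

#' Permutation test for CPM prediction accuracy
#'
#' Shuffles the outcome across subjects (covariates stay attached to their
#' subjects) and reruns the full cross-validation pipeline — selection,
#' model fitting, prediction — per permutation;
#' `p = (1 + #\{r_perm >= r_obs\}) / (1 + n_perm)`, one-sided. The
#' cross-validation partition is drawn once and shared by the observed and
#' permuted runs, so the fold-internal edge standardizations and covariate
#' projections (none of which involve y) are precomputed.
#'
#' @param edges,y,covariates,k,p_thresh,edge_subset as in [run_cpm()].
#' @param n_splits splits for the observed statistic.
#' @param n_perm permutations (default 1000).
#' @param seed integer seed.
#' @return list with `p`, `r_obs`, `r_perm`, `result` (the observed
#'   `CPMResult`).
#' @export
cpm_permutation_test <- function(edges, y, covariates = NULL, k = 10,
                                 n_splits = 1, n_perm = 1000,
                                 p_thresh = 0.05, edge_subset = NULL,
                                 seed = 1) {
  if (n_perm < 100) warnf("n_perm = %d gives coarse p-value resolution", n_perm)
  obs <- run_cpm(edges, y, covariates, k, n_splits, p_thresh, edge_subset,
                 seed)
  folds <- with_seed(derive_seed(seed, "split1"),
                     sample(rep_len(seq_len(k), nrow(edges))))
  pre <- cpm_precompute(edges, folds, covariates)
  perms <- with_seed(derive_seed(seed, "cpmperm"), {
    vapply(seq_len(n_perm), function(i) {
      yp <- sample(y)
      cpm_eval_y(edges, pre, yp, p_thresh, edge_subset)$r
    }, 0)
  })
  p <- (1 + sum(perms >= obs$mean_r)) / (1 + n_perm)
  list(p = p, r_obs = obs$mean_r, r_perm = perms, result = obs)
}

#' Contributing edges from cross-validation selection tallies
#'
#' Edges selected in at least `threshold` of all `k * n_splits` training
#' folds (e.g. 950 of 1000 iterations at the default 0.95).
#'
#' @param selection_counts per-edge tally from [run_cpm()].
#' @param total_iterations `k * n_splits`.
#' @param threshold selection-frequency cutoff in [0, 1] (>= comparison).
#' @return integer vector of contributing edge ids.
#' @export
contributing_edges <- function(selection_counts, total_iterations,
                               threshold = 0.95) {
  which(selection_counts >= threshold * total_iterations)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR adjustment with an explicit rejection set. Missing p-values
#' are excluded with a warning and returned as `NA`.
#'
#' @param p_values numeric p-values in [0, 1].
#' @param alpha FDR level for the rejection set (default 0.05).
#' @return list with `adjusted` (same length/order as input) and
#'   `rejected` (indices with adjusted p <= alpha).
#' @export
fdr_bh <- function(p_values, alpha = 0.05) {
  if (anyNA(p_values)) warnf("%d missing p-values excluded", sum(is.na(p_values)))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stopf("p-values must lie in [0, 1]")
  adj <- rep(NA_real_, length(p_values))
  ok <- !is.na(p_values)
  adj[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  list(adjusted = adj, rejected = which(adj <= alpha))
}
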