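# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a parent seed
#'
#' Streams of randomness for different pipeline stages are decoupled by
#' deriving one child seed per stage label. Kept below 2^31 - 1 so the result
#' is always a valid R integer seed.
#'
#' @param seed parent integer seed.
#' @param label character stage label.
#' @return integer seed.
#' @keywords internal
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483629)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_prob <- function(x, name, open_left = FALSE, open_right = FALSE) {
  lo_ok <- if (open_left) x > 0 else x >= 0
  hi_ok <- if (open_right) x < 1 else x <= 1
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || !lo_ok || !hi_ok)
    stopf("`%s` must be a proportion in %s0,1%s, got %s", name,
          if (open_left) "(" else "[", if (open_right) ")" else "]",
          format(x))
  invisible(x)
}

#' Canonical edge enumeration for an undirected graph
#'
#' Edges are node pairs (i, j) with i < j, enumerated in column-major
#' upper-triangle order (the order `upper.tri()` linearizes a matrix in).
#' Edge ids are 1-based and dense in `1..n_nodes*(n_nodes-1)/2`.
#'
#' @param n_nodes number of nodes.
#' @return integer matrix with columns `i`, `j`, one row per edge.
#' @examples
#' nrow(edge_pairs(264)) # 34716
#' @export
edge_pairs <- function(n_nodes) {
  if (n_nodes < 2) stopf("need at least 2 nodes")
  idx <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
  m <- cbind(i = idx[, 1L], j = idx[, 2L])
  storage.mode(m) <- "integer"
  m[order(m[, "j"], m[, "i"]), , drop = FALSE]
}

#' Number of canonical edges for a parcellation
#'
#' @param n_nodes number of nodes.
#' @return integer edge count `n_nodes * (n_nodes - 1) / 2`.
#' @examples
#' n_edges(264)
#' @export
n_edges <- function(n_nodes) as.integer(n_nodes * (n_nodes - 1) / 2)

# Column standardization that tolerates zero-variance columns (left centered).
standardize_cols <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  sweep(sweep(x, 2L, mu, "-"), 2L, sdv, "/")
}
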