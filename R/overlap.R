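# Neural-dissociation statistics over contributing-edge sets: Dice overlap
# with a permutation null, node ranking by contributing-edge degree, and
# network enrichment folds around anchor nodes.

#' Dice similarity coefficient of two edge sets
#'
#' `Dice(X, Y) = 2 |X intersect Y| / (|X| + |Y|)`; 0 by convention when
#' both sets are empty.
#'
#' @param maskX,maskY integer edge-id vectors from the same universe.
#' @param universe universe size N; when supplied, ids are checked against
#'   it (both masks must share it).
#' @return Dice coefficient in [0, 1].
#' @examples
#' dice_coefficient(1:4, 3:6) # 0.5
#' @export
dice_coefficient <- function(maskX, maskY, universe = NULL) {
  maskX <- unique(as.integer(maskX)); maskY <- unique(as.integer(maskY))
  if (!is.null(universe) &&
      ((length(maskX) && max(maskX) > universe) ||
       (length(maskY) && max(maskY) > universe)))
    stopf("edge id exceeds the stated universe (%d)", universe)
  tot <- length(maskX) + length(maskY)
  if (tot == 0L) return(0)
  2 * length(intersect(maskX, maskY)) / tot
}

#' Permutation null for a Dice coefficient
#'
#' Draws `n_perm` pairs of independent uniform random subsets of sizes
#' `|X|` and `|Y|` from a universe of `N` edges and computes their Dice
#' coefficients; `p = (1 + #\{dice_perm >= observed\}) / (1 + n_perm)`.
#' Under this null `E|X intersect Y| = |X||Y|/N`, so the null mean is
#' approximately `2|X||Y| / (N (|X| + |Y|))` — used as the closed-form
#' oracle for the sampler.
#'
#' @param size_x,size_y set sizes.
#' @param universe universe size N (>= both sizes, > 0).
#' @param observed observed Dice coefficient.
#' @param n_perm permutation count.
#' @param seed integer seed.
#' @return `DiceResult` list: `observed`, `p`, `null_mean`,
#'   `null_mean_closed_form`, `null` (permutation draws).
#' @export
dice_permutation_test <- function(size_x, size_y, universe, observed,
                                  n_perm = 1000, seed = 1) {
  if (universe <= 0) stopf("universe must be positive")
  if (size_x > universe || size_y > universe)
    stopf("set sizes exceed the universe")
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      x <- sample.int(universe, size_x)
      y <- sample.int(universe, size_y)
      in_x <- logical(universe)
      in_x[x] <- TRUE
      2 * sum(in_x[y]) / (size_x + size_y)
    }, 0)
  })
  list(observed = observed,
       p = (1 + sum(null >= observed)) / (1 + n_perm),
       null_mean = mean(null),
       null_mean_closed_form = 2 * size_x * size_y /
         (universe * (size_x + size_y)),
       null = null)
}

#' Rank nodes by contributing-edge degree
#'
#' Counts, for every node, the number of contributing edges incident to it
#' and ranks nodes by that count (descending; ties broken by node id for a
#' stable order).
#'
#' @param mask contributing edge ids (canonical enumeration of
#'   [edge_pairs()]).
#' @param parcellation node table from [make_parcellation()] (0-based
#'   `node` column, `network`, `name`).
#' @param top_k rows to return (default all).
#' @return data.frame: `node`, `name`, `network`, `n_edges`, `rank`.
#' @export
rank_nodes <- function(mask, parcellation, top_k = nrow(parcellation)) {
  n_nodes <- nrow(parcellation)
  ep <- edge_pairs(n_nodes)
  if (length(mask) && max(mask) > nrow(ep))
    stopf("edge id outside the parcellation's universe")
  counts <- tabulate(c(ep[mask, "i"], ep[mask, "j"]), nbins = n_nodes)
  ord <- order(-counts, parcellation$node)
  out <- data.frame(node = parcellation$node[ord],
                    name = parcellation$name[ord],
                    network = parcellation$network[ord],
                    n_edges = counts[ord],
                    rank = seq_len(n_nodes),
                    stringsAsFactors = FALSE)
  utils::head(out, top_k)
}

#' Network enrichment of contributing edges at an anchor node
#'
#' For an anchor node with `A` selected (contributing) edges, partner nodes
#' are classed by their network label; with `possible_l` partner nodes in
#' network class l, the expected count is `E_l = possible_l * A /
#' (n_nodes - 1)` (a uniform spread of the anchor's selected edges over its
#' `n_nodes - 1` potential partners) and the enrichment fold is the
#' observed count over `E_l`. Folds >= 1 are flagged for display.
#'
#' @param mask contributing edge ids.
#' @param anchor_node 0-based anchor node id.
#' @param parcellation node table.
#' @return `EnrichmentTable` data.frame: `anchor`, `network_pair`,
#'   `partner_network`, `possible`, `observed`, `expected`, `fold`,
#'   `display` (fold >= 1); fold is `NA` where `expected` is 0.
#' @export
network_enrichment <- function(mask, anchor_node, parcellation) {
  n_nodes <- nrow(parcellation)
  if (!anchor_node %in% parcellation$node) stopf("unknown anchor node")
  ep <- edge_pairs(n_nodes)
  a1 <- anchor_node + 1L   # 1-based
  at_anchor <- mask[ep[mask, "i"] == a1 | ep[mask, "j"] == a1]
  partners <- ifelse(ep[at_anchor, "i"] == a1, ep[at_anchor, "j"],
                     ep[at_anchor, "i"])
  net_of <- parcellation$network[match(seq_len(n_nodes) - 1L,
                                       parcellation$node)]
  anchor_net <- net_of[a1]
  k <- length(at_anchor)
  classes <- sort(unique(net_of))
  possible <- vapply(classes, function(w)
    sum(net_of[-a1] == w), 0L)
  observed <- vapply(classes, function(w)
    sum(net_of[partners] == w), 0L)
  expected <- possible * k / (n_nodes - 1L)
  fold <- ifelse(expected > 0, observed / expected, NA_real_)
  data.frame(anchor = anchor_node,
             network_pair = paste0(anchor_net, "-", classes),
             partner_network = classes,
             possible = possible, observed = observed,
             expected = expected, fold = fold,
             display = !is.na(fold) & fold >= 1,
             row.names = NULL, stringsAsFactors = FALSE)
}
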