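#' @title Random-walk sub-group detection for the restricted permutation null
#' @name community
NULL

#' Symmetrize a directed weight matrix
#'
#' The random-walk community detection operates on an undirected graph, so
#' directed daily networks are symmetrized as `S = W + t(W)` (total
#' interactions per dyad, irrespective of direction). The structural zero
#' diagonal is preserved.
#'
#' @param W non-negative square matrix (or `daily_network`).
#' @return symmetric matrix with zero diagonal.
#' @export
symmetrize <- function(W) {
  if (inherits(W, "daily_network")) W <- W$W
  stopifnot(is.matrix(W), nrow(W) == ncol(W), all(W >= 0))
  S <- W + t(W)
  diag(S) <- 0
  S
}

#' Walktrap sub-group partition
#'
#' Detects sub-groups with the random-walk (Walktrap) agglomerative algorithm
#' on a symmetric weighted graph and returns the merge-tree cut maximizing
#' weighted modularity. The algorithm is deterministic: walk probabilities are
#' computed exactly, so identical inputs always return identical partitions.
#' Isolated vertices (zero strength) become singleton blocks. These blocks are
#' what the restricted quadratic assignment procedure confines its label
#' swaps to.
#'
#' @param S symmetric non-negative weight matrix with named rows/columns (or a
#'   `daily_network`, which is symmetrized first).
#' @param steps random-walk length (default 4, the algorithm's conventional
#'   default).
#' @param day_scope free-text description of which networks were aggregated
#'   to form `S` (stored on the result).
#' @return Object of class `community_partition`: list with `blocks` (list of
#'   node-id character vectors), `membership` (named integer vector),
#'   `modularity`, `day_scope`, `steps`.
#' @export
walktrap_partition <- function(S, steps = 4, day_scope = "") {
  if (inherits(S, "daily_network")) S <- symmetrize(S)
  stopifnot(is.matrix(S), isTRUE(all.equal(S, t(S))), all(S >= 0))
  ids <- rownames(S)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(S)))
  n <- nrow(S)
  if (n == 0L) {
    return(structure(list(blocks = list(), membership = integer(0),
                          modularity = NA_real_, day_scope = day_scope,
                          steps = steps), class = "community_partition"))
  }
  strength <- rowSums(S)
  iso <- strength == 0
  membership <- integer(n)
  if (any(!iso)) {
    Ssub <- S[!iso, !iso, drop = FALSE]
    g <- igraph::graph_from_adjacency_matrix(Ssub, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    wt <- igraph::cluster_walktrap(g, steps = steps,
                                   weights = igraph::E(g)$weight)
    membership[!iso] <- igraph::membership(wt)
  }
  if (any(iso))
    membership[iso] <- max(membership) + seq_len(sum(iso))
  names(membership) <- ids
  blocks <- split(ids, membership)
  names(blocks) <- NULL
  structure(list(blocks = blocks, membership = membership,
                 modularity = weighted_modularity(S, membership),
                 day_scope = day_scope, steps = steps),
            class = "community_partition")
}

#' Weighted Newman modularity of a partition
#'
#' Q = sum over blocks b of \[ w_in(b)/W - (s(b)/2W)^2 \], where `W` is the
#' total edge weight of the symmetric graph, `w_in(b)` the weight inside block
#' b and `s(b)` the total strength of its vertices.
#'
#' @param S symmetric weight matrix.
#' @param membership integer block label per node.
#' @return modularity in \[-1, 1\] (NA for an empty or weightless graph).
#' @export
weighted_modularity <- function(S, membership) {
  W2 <- sum(S)                       # 2W: every undirected edge counted twice
  if (W2 == 0) return(NA_real_)
  q <- 0
  for (b in unique(membership)) {
    in_b <- membership == b
    q <- q + sum(S[in_b, in_b]) / W2 - (sum(S[in_b, ]) / W2)^2
  }
  q
}

#' @export
print.community_partition <- function(x, ...) {
  sizes <- lengths(x$blocks)
  cat("community_partition:", length(x$blocks), "block(s) of sizes",
      paste(sizes, collapse = ", "),
      sprintf("| modularity %.4f", x$modularity),
      if (nzchar(x$day_scope)) paste("|", x$day_scope) else "", "\n")
  invisible(x)
}

#' One-block (unrestricted) partition over a node set
#'
#' Used when the permutation null should not be restricted: all nodes share a
#' single block, so every node permutation is admissible.
#'
#' @param ids node ids.
#' @return `community_partition` with a single block.
#' @export
one_block_partition <- function(ids) {
  membership <- stats::setNames(rep(1L, length(ids)), ids)
  structure(list(blocks = list(as.character(ids)), membership = membership,
                 modularity = NA_real_, day_scope = "unrestricted",
                 steps = NA_integer_), class = "community_partition")
}
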