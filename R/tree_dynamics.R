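## Branching times and lineages-through-time curves from ultrametric
## element phylogenies.

# root-to-node path lengths for every node (tips and internals)
.node_depths <- function(tree) {
  ape::node.depth.edgelength(tree)
}

#' Check and scale an ultrametric tree; branching times of internal nodes
#'
#' Branching time of an internal node is its distance from the root
#' divided by the tree depth, so the root has time 0 and tips time 1.
#' Non-ultrametric trees (root-to-tip depths differing by more than
#' `tol_rel * depth`) are an error. An outgroup tip used for rooting can
#' be pruned first.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param outgroup Optional tip label pruned before scaling.
#' @param tol_rel Relative ultrametricity tolerance.
#' @return data.frame `node` (internal node id), `time` (scaled in
#'   \[0, 1\]), `n_children`.
#' @export
branching_times_scaled <- function(tree, outgroup = NULL, tol_rel = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(outgroup)) {
    abort_if(!outgroup %in% tree$tip.label, "outgroup tip not in tree")
    tree <- ape::drop.tip(tree, outgroup)
  }
  n_tip <- length(tree$tip.label)
  depths <- .node_depths(tree)
  tip_depths <- depths[seq_len(n_tip)]
  depth <- max(tip_depths)
  abort_if(depth <= 0, "tree has zero depth")
  abort_if(max(tip_depths) - min(tip_depths) > tol_rel * depth,
           "tree is not ultrametric within tolerance")
  internal <- (n_tip + 1L):(n_tip + tree$Nnode)
  data.frame(node = internal,
             time = depths[internal] / depth,
             n_children = vapply(internal,
                                 function(nd) sum(tree$edge[, 1] == nd), 0L))
}

#' Per-node branching event counts
#'
#' Number of children of each internal node; polytomies contribute their
#' full child count.
#'
#' @param tree A `phylo` object.
#' @return Named integer vector (internal node id -> child count).
#' @export
branching_event_counts <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  tab <- table(tree$edge[, 1])
  stats::setNames(as.integer(tab), names(tab))
}

#' Lineages-through-time curve on scaled branching times
#'
#' Right-continuous step function starting at one lineage at time 0; at
#' each branching event the lineage count increases by (children - 1).
#' The final value equals the tip count.
#'
#' @param times Scaled branching times of internal nodes.
#' @param counts Child counts of the same nodes.
#' @return data.frame `time`, `lineages` (value from that time onward),
#'   one row per distinct event time plus the origin.
#' @export
ltt_curve <- function(times, counts) {
  stopifnot(length(times) == length(counts))
  ord <- order(times)
  times <- times[ord]; counts <- counts[ord]
  increments <- tapply(counts - 1L, times, sum)
  ev_times <- as.numeric(names(increments))
  lineages <- 1L + cumsum(as.integer(increments))
  if (length(ev_times) == 0L || ev_times[1] > 0) {
    ev_times <- c(0, ev_times)
    lineages <- c(1L, lineages)
  }
  data.frame(time = ev_times, lineages = lineages)
}

#' @rdname ltt_curve
#' @param tree A rooted ultrametric `phylo`.
#' @param ... Passed to [branching_times_scaled()].
#' @export
ltt_from_tree <- function(tree, ...) {
  bt <- branching_times_scaled(tree, ...)
  ltt_curve(bt$time, bt$n_children)
}
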