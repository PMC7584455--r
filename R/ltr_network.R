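## Intra-genome LTR sequence-similarity networks, family merging, and
## divergence since transposition.

#' Build an LTR sequence-similarity network
#'
#' For each LTR (as a query), hits with a bit score greater than or equal
#' to the 10th percentile of all that LTR's hit scores are retained; the
#' edge set is the union over queries, so an edge survives if either of
#' its endpoints retains it. Percentiles use linear interpolation (see
#' [percentile()]).
#'
#' @param hits Hit table (`query`, `subject`, `pct_identity`, `aln_length`,
#'   `bit_score`, `e_value`); self-hits are dropped if present.
#' @param retain_percentile Per-query retention percentile (default 0.10).
#' @param nodes Optional character vector of node ids to include even when
#'   they have no hits (isolated nodes).
#' @return An undirected [igraph::graph] whose edges carry `weight` (the
#'   larger bit score of the two directions).
#' @export
build_similarity_network <- function(hits, retain_percentile = 0.10,
                                     nodes = NULL) {
  abort_if(nrow(hits) == 0L, "hit table is empty")
  hits <- hits[hits$query != hits$subject, ]
  thr <- tapply(hits$bit_score, hits$query,
                function(s) percentile(s, retain_percentile))
  keep <- hits$bit_score >= thr[hits$query]
  kept <- hits[keep, ]
  a <- pmin(kept$query, kept$subject)
  b <- pmax(kept$query, kept$subject)
  key <- paste(a, b, sep = "\r")
  w <- tapply(kept$bit_score, key, max)
  uk <- names(w)
  parts <- strsplit(uk, "\r", fixed = TRUE)
  edges <- cbind(vapply(parts, `[`, "", 1L), vapply(parts, `[`, "", 2L))
  all_nodes <- unique(c(hits$query, hits$subject, nodes))
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2], weight = as.numeric(w),
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = all_nodes, stringsAsFactors = FALSE))
  g
}

#' Merge family labels from network connected components
#'
#' Connected components whose nodes span several input family labels
#' define a composite family named by joining the sorted labels with "/".
#' Families co-occurring in any component are merged transitively. A
#' per-component composition report is returned so merges can be ratified
#' by inspection.
#'
#' @param graph Similarity network from [build_similarity_network()].
#' @param families Named character vector mapping node id to input family;
#'   every node of the graph must be labeled.
#' @return list with `merge_map` (named character: input family ->
#'   composite family) and `report` (data.frame: component, size, labels).
#' @export
merge_family_labels <- function(graph, families) {
  nodes <- igraph::V(graph)$name
  if (length(nodes) == 0L) {
    return(list(merge_map = character(0),
                report = data.frame(component = integer(0), size = integer(0),
                                    labels = character(0))))
  }
  abort_if(!all(nodes %in% names(families)),
           "unlabeled nodes: %s",
           paste(utils::head(setdiff(nodes, names(families))), collapse = ", "))
  comp <- igraph::components(graph)$membership
  lab_by_comp <- split(unname(families[nodes]), comp[nodes])
  report <- data.frame(
    component = as.integer(names(lab_by_comp)),
    size = vapply(lab_by_comp, length, 0L),
    labels = vapply(lab_by_comp,
                    function(l) paste(sort(unique(l)), collapse = "/"), ""),
    stringsAsFactors = FALSE)
  # transitive closure of co-occurrence via a small label graph
  all_fam <- sort(unique(unname(families[nodes])))
  pairs <- do.call(rbind, lapply(lab_by_comp, function(l) {
    u <- sort(unique(l))
    if (length(u) < 2) return(NULL)
    t(utils::combn(u, 2))
  }))
  merge_map <- stats::setNames(all_fam, all_fam)
  if (!is.null(pairs)) {
    fg <- igraph::graph_from_data_frame(as.data.frame(pairs),
                                        directed = FALSE,
                                        vertices = all_fam)
    fc <- igraph::components(fg)$membership
    for (cid in unique(fc)) {
      group <- sort(names(fc)[fc == cid])
      if (length(group) > 1) {
        merge_map[group] <- paste(group, collapse = "/")
      }
    }
  }
  list(merge_map = merge_map, report = report)
}

#' Evolutionary divergence since transposition
#'
#' For each element, the closest relative is the non-self LTR with the
#' highest bit score among hits of the element's representative LTR; the
#' two LTRs of a full-length element never count as each other's
#' relatives, and only one LTR per full-length element (the 5' one)
#' contributes. Divergence is `100 - pct_identity` of the best surviving
#' hit. Ties are broken by lower e-value, longer alignment, then
#' lexicographic subject id.
#'
#' @param annotations Element annotation table with `element_id`,
#'   `element_type` and `ltr_ids` (comma-separated LTR ids, 5' first).
#' @param hits LTR-level hit table.
#' @return data.frame `element_id`, `closest_relative`, `divergence`,
#'   `no_hit` (flag for elements with no surviving hit).
#' @export
divergence_since_transposition <- function(annotations, hits) {
  ltr_lists <- strsplit(annotations$ltr_ids, ",", fixed = TRUE)
  out <- data.frame(element_id = annotations$element_id,
                    closest_relative = NA_character_,
                    divergence = NA_real_, no_hit = TRUE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(annotations))) {
    own <- ltr_lists[[i]]
    rep_ltr <- own[1]
    h <- hits[hits$query == rep_ltr & !(hits$subject %in% own), ]
    if (nrow(h) == 0L) next
    h <- h[order(-h$bit_score, h$e_value, -h$aln_length, h$subject), ]
    out$closest_relative[i] <- h$subject[1]
    out$divergence[i] <- 100 - h$pct_identity[1]
    out$no_hit[i] <- FALSE
  }
  out
}

#' Pairwise divergence-class contrasts between lineages
#'
#' Counts elements at or below versus above a divergence threshold
#' (default 1%) in each lineage and performs a two-sided Fisher exact test
#' for every lineage pair, with Benjamini-Hochberg correction across
#' pairs.
#'
#' @param divergence Numeric vector of per-element divergences (%).
#' @param lineage Factor/character vector parallel to `divergence`.
#' @param threshold Divergence split point in percent.
#' @return data.frame with one row per lineage pair: counts, odds ratio,
#'   raw and adjusted p-values.
#' @export
divergence_class_tests <- function(divergence, lineage, threshold = 1) {
  ok <- !is.na(divergence)
  divergence <- divergence[ok]
  lineage <- as.character(lineage)[ok]
  lev <- sort(unique(lineage))
  abort_if(length(lev) < 2L, "need >= 2 lineages with elements")
  counts <- t(vapply(lev, function(l) {
    d <- divergence[lineage == l]
    c(low = sum(d <= threshold), high = sum(d > threshold))
  }, c(low = 0, high = 0)))
  empty <- rowSums(counts) == 0
  if (any(empty)) {
    warning("lineages with no elements skipped: ",
            paste(lev[empty], collapse = ", "))
    lev <- lev[!empty]
    counts <- counts[!empty, , drop = FALSE]
  }
  pairs <- utils::combn(lev, 2)
  res <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    tab <- rbind(counts[a, ], counts[b, ])
    ft <- stats::fisher.test(tab, alternative = "two.sided")
    data.frame(lineage_a = a, lineage_b = b,
               low_a = counts[a, "low"], high_a = counts[a, "high"],
               low_b = counts[b, "low"], high_b = counts[b, "high"],
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_adj <- bh_adjust(res$p)
  res
}
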