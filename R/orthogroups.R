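## Cross-genome Ty orthogroup inference from alignment-projected
## annotation coordinates.

#' Cluster projected annotations along one alignment dimension
#'
#' One-dimensional DBSCAN with `min_samples = 1` (equivalently,
#' single-linkage chaining at distance <= `eps`) on a representative
#' coordinate of each projected annotation.
#'
#' @param positions data.frame from [project_annotations()] (rows with
#'   `projectable == FALSE` are dropped).
#' @param eps Chaining distance in alignment columns.
#' @param coord Representative coordinate: annotation start (default) or
#'   midpoint.
#' @return The input rows with an integer `cluster` column appended.
#' @export
cluster_positions_1d <- function(positions, eps = 500,
                                 coord = c("start", "midpoint")) {
  coord <- match.arg(coord)
  if ("projectable" %in% names(positions)) {
    positions <- positions[positions$projectable, ]
  }
  if (nrow(positions) == 0L) {
    positions$cluster <- integer(0)
    return(positions)
  }
  x <- if (coord == "start") positions$msa_start else {
    (positions$msa_start + positions$msa_end) / 2
  }
  positions$cluster <- chain_cluster_1d(x, eps = eps)
  positions
}

# Best hit (by bit score, then e-value, longer alignment, subject id) of
# each query within each subject genome, among hits restricted to
# `members`. Returned as a set of "query\rsubject" keys: a pair is linked
# when its hit is the query's best hit in the subject's genome.
.best_hit_keys <- function(hits, members, genome_of) {
  h <- hits[hits$query %in% members & hits$subject %in% members &
              hits$query != hits$subject, ]
  if (nrow(h) == 0L) return(character(0))
  h$subject_genome <- genome_of[h$subject]
  h <- h[order(h$query, h$subject_genome, -h$bit_score, h$e_value,
               -h$aln_length, h$subject), ]
  h <- h[!duplicated(paste(h$query, h$subject_genome, sep = "\r")), ]
  paste(h$query, h$subject, sep = "\r")
}

#' Select confident orthogroups and their coordinate-difference spread
#'
#' Keeps clusters with at most one annotation per genome, uniform strand
#' and uniform family, then keeps members having at least one hit with
#' >= `min_identity` percent identity and an alignment length within
#' `len_range` of both query and subject lengths. Pools the absolute
#' start- and end-coordinate differences across member pairs of the
#' surviving clusters.
#'
#' @param clustered Output of [cluster_positions_1d()]; must carry
#'   `genome`, `strand`, `family`, `msa_start`, `msa_end`, `cluster`.
#' @param hits Element-level hit table (query/subject are element ids).
#' @param lengths Named numeric vector: element id -> sequence length (bp).
#' @param min_identity Minimum percent identity of a qualifying hit.
#' @param len_range Alignment length bounds as fractions of each sequence.
#' @return list with `members` (confident member rows) and `diffs`
#'   (pooled |delta start| and |delta end| values).
#' @export
select_confident_orthogroups <- function(clustered, hits, lengths,
                                         min_identity = 80,
                                         len_range = c(0.9, 1.1)) {
  members_keep <- list(); diffs <- numeric(0)
  qualifying <- hits[
    hits$pct_identity >= min_identity &
      hits$aln_length >= len_range[1] * lengths[hits$query] &
      hits$aln_length <= len_range[2] * lengths[hits$query] &
      hits$aln_length >= len_range[1] * lengths[hits$subject] &
      hits$aln_length <= len_range[2] * lengths[hits$subject], ]
  for (cl in split(clustered, clustered$cluster)) {
    if (nrow(cl) < 2L) next
    if (anyDuplicated(cl$genome)) next
    if (length(unique(cl$strand)) > 1L) next
    if (length(unique(cl$family)) > 1L) next
    q <- qualifying[qualifying$query %in% cl$element_id &
                      qualifying$subject %in% cl$element_id, ]
    ok_ids <- unique(c(q$query, q$subject))
    cl <- cl[cl$element_id %in% ok_ids, ]
    if (nrow(cl) < 2L) next
    members_keep[[length(members_keep) + 1L]] <- cl
    pr <- utils::combn(nrow(cl), 2)
    diffs <- c(diffs,
               abs(cl$msa_start[pr[1, ]] - cl$msa_start[pr[2, ]]),
               abs(cl$msa_end[pr[1, ]] - cl$msa_end[pr[2, ]]))
  }
  list(members = if (length(members_keep)) do.call(rbind, members_keep)
       else clustered[0, ],
       diffs = diffs)
}

#' Derive the coordinate-agreement threshold
#'
#' The stated percentile (default 95th, linear interpolation) of the
#' pooled absolute start/end coordinate differences among confident
#' ortholog pairs.
#'
#' @param diffs Numeric vector of pooled coordinate differences.
#' @param prob Percentile as a probability.
#' @return Threshold in alignment columns.
#' @export
derive_coordinate_threshold <- function(diffs, prob = 0.95) {
  abort_if(length(diffs) == 0L,
           "empty coordinate-difference distribution; supply a configured fallback threshold")
  percentile(diffs, prob)
}

#' Call Ty orthogroups within position clusters
#'
#' Within each cluster, a pair of annotations is orthologous iff at least
#' one direction's best hit links them (the best hit of a query is taken
#' per subject genome, the usual comparative-genomics reading of a best
#' BLAST hit), their start or end alignment coordinates (or both) agree
#' within `threshold`, and they belong to the same (merged) family.
#' Orthology is closed transitively within the cluster; groups with more
#' than one member in any genome are marked discarded.
#'
#' @param clustered Output of [cluster_positions_1d()].
#' @param hits Element-level hit table.
#' @param threshold Coordinate-agreement threshold (alignment columns).
#' @param family_map Optional named vector mapping input family labels to
#'   merged labels (from [merge_family_labels()]).
#' @return data.frame with one row per annotation: `orthogroup_id`,
#'   `element_id`, `genome`, `family` (merged), carried columns, and a
#'   per-orthogroup `discarded` flag.
#' @export
call_orthogroups <- function(clustered, hits, threshold,
                             family_map = NULL) {
  abort_if(threshold < 0, "threshold must be >= 0")
  df <- clustered
  if (!is.null(family_map)) {
    mapped <- unname(family_map[df$family])
    df$family <- ifelse(is.na(mapped), df$family, mapped)
  }
  df$orthogroup_id <- NA_character_
  og_counter <- 0L
  res <- list()
  for (cl in split(df, df$cluster)) {
    n <- nrow(cl)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    genome_of <- stats::setNames(cl$genome, cl$element_id)
    best_keys <- .best_hit_keys(hits, cl$element_id, genome_of)
    if (n > 1L) {
      for (pr in utils::combn(n, 2, simplify = FALSE)) {
        i <- pr[1]; j <- pr[2]
        ei <- cl$element_id[i]; ej <- cl$element_id[j]
        linked <- paste(ei, ej, sep = "\r") %in% best_keys ||
          paste(ej, ei, sep = "\r") %in% best_keys
        if (!linked) next
        if (cl$family[i] != cl$family[j]) next
        ds <- abs(cl$msa_start[i] - cl$msa_start[j])
        de <- abs(cl$msa_end[i] - cl$msa_end[j])
        if (ds <= threshold || de <= threshold) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[rj] <- ri
        }
      }
    }
    roots <- vapply(seq_len(n), find, 0L)
    for (r in unique(roots)) {
      og_counter <- og_counter + 1L
      idx <- which(roots == r)
      grp <- cl[idx, ]
      grp$orthogroup_id <- sprintf("OG%04d", og_counter)
      grp$discarded <- anyDuplicated(grp$genome) > 0L
      res[[length(res) + 1L]] <- grp
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Conservation classes and full-length enrichment
#'
#' Classifies each (non-discarded) orthogroup as private (one genome),
#' conserved (all genomes) or intermediate, and tests, per genome, whether
#' that genome's elements in private orthogroups are enriched in
#' full-length elements relative to its elements in non-private
#' orthogroups (Fisher exact, Benjamini-Hochberg across genomes).
#'
#' @param orthogroups Output of [call_orthogroups()]; rows must carry
#'   `element_type` for the enrichment tests.
#' @param n_genomes Total number of genomes in the comparison.
#' @return list with `classes` (orthogroup_id, n_genomes, class,
#'   discarded) and `tests` (per-genome Fisher results; NULL when
#'   `element_type` is absent).
#' @export
classify_conservation <- function(orthogroups, n_genomes) {
  sp <- split(orthogroups, orthogroups$orthogroup_id)
  classes <- data.frame(
    orthogroup_id = names(sp),
    n_genomes = vapply(sp, function(g) length(unique(g$genome)), 0L),
    discarded = vapply(sp, function(g) any(g$discarded), TRUE),
    stringsAsFactors = FALSE)
  classes$class <- ifelse(classes$n_genomes == 1L, "private",
                          ifelse(classes$n_genomes == n_genomes,
                                 "conserved", "intermediate"))
  tests <- NULL
  if ("element_type" %in% names(orthogroups)) {
    og <- merge(orthogroups, classes[, c("orthogroup_id", "class")],
                by = "orthogroup_id")
    og <- og[!og$discarded, ]
    rows <- lapply(sort(unique(og$genome)), function(g) {
      mine <- og[og$genome == g, ]
      priv <- mine$class == "private"
      fl <- mine$element_type == "full_length"
      tab <- matrix(c(sum(fl & priv), sum(!fl & priv),
                      sum(fl & !priv), sum(!fl & !priv)), nrow = 2)
      p <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) NA_real_
      else stats::fisher.test(tab)$p.value
      data.frame(genome = g,
                 full_private = tab[1, 1], solo_private = tab[2, 1],
                 full_other = tab[1, 2], solo_other = tab[2, 2],
                 p = p, stringsAsFactors = FALSE)
    })
    tests <- do.call(rbind, rows)
    tests$p_adj <- bh_adjust(tests$p)
  }
  list(classes = classes, tests = tests)
}
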