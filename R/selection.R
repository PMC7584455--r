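## Selection-intensity summaries (k, delta-k), fourfold-degenerate
## nucleotide diversity, and the neighbor-gene test battery.

# edge indices of the subtree rooted at `node` (all branches below it)
.clade_edges <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  edges <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[[1]]; stack <- stack[-1]
    rows <- which(tree$edge[, 1] == nd)
    edges <- c(edges, rows)
    kids <- tree$edge[rows, 2]
    stack <- c(stack, kids[kids > n_tip])
  }
  edges
}

#' Branch-length-weighted mean selection intensity of a clade
#'
#' The clade is the smallest subtree containing exactly the given tips
#' (monophyly is required and checked); the average selection intensity
#' is the branch-length-weighted mean of per-branch k over all of the
#' clade's branches, internal branches included.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param k Numeric vector of per-branch selection intensities, parallel
#'   to `tree$edge` rows.
#' @param tips Tip labels spanning the clade.
#' @return Weighted mean k.
#' @export
weighted_clade_k <- function(tree, k, tips) {
  stopifnot(inherits(tree, "phylo"))
  abort_if(length(k) != nrow(tree$edge),
           "k must have one value per branch (%d)", nrow(tree$edge))
  abort_if(anyNA(k), "k missing on some branches")
  abort_if(!all(tips %in% tree$tip.label), "unknown tips")
  if (length(tips) == 1L) {
    e <- which(tree$edge[, 2] == match(tips, tree$tip.label))
    abort_if(tree$edge.length[e] == 0, "zero total branch length")
    return(k[e])
  }
  mrca <- ape::getMRCA(tree, tips)
  edges <- .clade_edges(tree, mrca)
  clade_tips <- tree$tip.label[tree$edge[edges, 2][tree$edge[edges, 2] <=
                                                     length(tree$tip.label)]]
  abort_if(!setequal(clade_tips, tips),
           "tips are not monophyletic (clade also contains: %s)",
           paste(setdiff(clade_tips, tips), collapse = ", "))
  len <- tree$edge.length[edges]
  abort_if(sum(len) == 0, "zero total branch length")
  sum(k[edges] * len) / sum(len)
}

#' Selection-intensity difference between two clades
#'
#' `delta_k = k̄(clade B) - k̄(clade C)` with each clade mean computed by
#' [weighted_clade_k()].
#'
#' @inheritParams weighted_clade_k
#' @param tips_b,tips_c Tip sets of the two clades.
#' @return Numeric delta-k.
#' @export
delta_k <- function(tree, k, tips_b, tips_c) {
  weighted_clade_k(tree, k, tips_b) - weighted_clade_k(tree, k, tips_c)
}

#' Fourfold-degenerate site positions of coding genes
#'
#' Third codon positions whose codon family is fourfold degenerate
#' (codons starting CT, GT, TC, CC, AC, GC, CG or GG), determined from a
#' reference coding sequence.
#'
#' @param cds Reference coding sequence (character, length divisible
#'   by 3, read in frame).
#' @return Integer vector of 1-based positions within `cds`.
#' @export
fourfold_sites <- function(cds) {
  abort_if(nchar(cds) %% 3 != 0, "coding sequence length not divisible by 3")
  n_codon <- nchar(cds) / 3
  starts <- 3 * (seq_len(n_codon) - 1) + 1
  prefixes <- substring(cds, starts, starts + 1)
  ff <- prefixes %in% c("CT", "GT", "TC", "CC", "AC", "GC", "CG", "GG")
  starts[ff] + 2L
}

#' Nucleotide diversity at fourfold-degenerate sites
#'
#' Mean pairwise difference per fourfold-degenerate site within each
#' lineage: for each site the fraction of haplotype pairs that differ,
#' averaged over all fourfold sites (monomorphic sites included).
#'
#' @param haplotypes Character matrix, haplotypes x positions, of bases
#'   over the coding region (columns aligned to `cds` positions).
#' @param cds Reference coding sequence defining the fourfold sites.
#' @param lineages Lineage label per haplotype (row).
#' @param exclude Optional haplotype (row) names to drop before
#'   computation.
#' @return data.frame `lineage`, `pi_s`, `n_haplotypes`, `n_sites`.
#' @export
pi_s <- function(haplotypes, cds, lineages, exclude = NULL) {
  sites <- fourfold_sites(cds)
  abort_if(length(sites) == 0L, "no fourfold-degenerate sites")
  if (!is.null(exclude)) {
    keep <- !(rownames(haplotypes) %in% exclude)
    haplotypes <- haplotypes[keep, , drop = FALSE]
    lineages <- lineages[keep]
  }
  res <- list()
  for (l in sort(unique(as.character(lineages)))) {
    h <- haplotypes[lineages == l, sites, drop = FALSE]
    n <- nrow(h)
    if (n < 2L) {
      res[[l]] <- data.frame(lineage = l, pi_s = NA_real_,
                             n_haplotypes = n, n_sites = length(sites))
      next
    }
    mpd_site <- apply(h, 2, function(col) {
      tab <- table(col)
      npairs <- n * (n - 1) / 2
      same <- sum(tab * (tab - 1) / 2)
      (npairs - same) / npairs
    })
    res[[l]] <- data.frame(lineage = l, pi_s = mean(mpd_site),
                           n_haplotypes = n, n_sites = length(sites),
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Test battery on genes neighboring Ty insertions
#'
#' Given per-gene records of the conservation class of the adjacent Ty
#' insertion, essentiality, physical-interaction counts, omega (dN/dS)
#' and delta-k, runs: (i) pairwise Fisher exact tests on
#' essential/non-essential counts across classes; (ii) pairwise two-
#' tailed Mann-Whitney U tests on interaction counts and on omega across
#' classes (each family of tests Benjamini-Hochberg corrected); (iii)
#' Fisher exact tests of positive/negative delta-k counts, each private
#' class versus the conserved class; (iv) descriptive summaries of
#' distance and orientation.
#'
#' @param records data.frame with columns `class`, `essential` (logical),
#'   `n_interactions`, `omega`, `delta_k`, and optionally `distance_bp`,
#'   `orientation`.
#' @param conserved_class Label of the conserved reference class.
#' @return list with `essential_tests`, `interaction_tests`,
#'   `omega_tests`, `delta_k_tests`, `descriptives`.
#' @export
neighbor_gene_tests <- function(records, conserved_class = "conserved") {
  cls <- sort(unique(as.character(records$class)))
  small <- vapply(cls, function(cl) sum(records$class == cl) < 2L, TRUE)
  if (any(small)) {
    warning("classes with <2 records skipped: ",
            paste(cls[small], collapse = ", "))
    cls <- cls[!small]
  }
  pairwise <- function(fun) {
    if (length(cls) < 2L) return(NULL)
    pr <- utils::combn(cls, 2)
    out <- lapply(seq_len(ncol(pr)), function(m) {
      fun(pr[1, m], pr[2, m])
    })
    out <- do.call(rbind, out)
    out$p_adj <- bh_adjust(out$p)
    out
  }
  ess <- pairwise(function(a, b) {
    ta <- table(factor(records$essential[records$class == a],
                       levels = c(FALSE, TRUE)))
    tb <- table(factor(records$essential[records$class == b],
                       levels = c(FALSE, TRUE)))
    data.frame(class_a = a, class_b = b,
               p = stats::fisher.test(rbind(ta, tb))$p.value,
               stringsAsFactors = FALSE)
  })
  mwu <- function(col) {
    pairwise(function(a, b) {
      xa <- records[[col]][records$class == a]
      xb <- records[[col]][records$class == b]
      p <- if (length(unique(c(xa, xb))) == 1L) 1 else {
        stats::wilcox.test(xa, xb, alternative = "two.sided",
                           exact = FALSE)$p.value
      }
      data.frame(class_a = a, class_b = b, p = p, stringsAsFactors = FALSE)
    })
  }
  dk <- NULL
  if (conserved_class %in% cls) {
    privates <- setdiff(cls, conserved_class)
    rows <- lapply(privates, function(a) {
      ka <- records$delta_k[records$class == a]
      kc <- records$delta_k[records$class == conserved_class]
      tab <- rbind(c(sum(ka > 0), sum(ka < 0)),
                   c(sum(kc > 0), sum(kc < 0)))
      data.frame(class = a, positive = tab[1, 1], negative = tab[1, 2],
                 p = stats::fisher.test(tab)$p.value,
                 stringsAsFactors = FALSE)
    })
    dk <- do.call(rbind, rows)
    if (!is.null(dk)) dk$p_adj <- bh_adjust(dk$p)
  }
  desc <- NULL
  if (all(c("distance_bp", "orientation") %in% names(records))) {
    desc <- do.call(rbind, lapply(cls, function(cl) {
      r <- records[records$class == cl, ]
      data.frame(class = cl, n = nrow(r),
                 median_distance = stats::median(r$distance_bp),
                 prop_same_orientation = mean(r$orientation == "same"),
                 stringsAsFactors = FALSE)
    }))
  }
  list(essential_tests = ess, interaction_tests = mwu("n_interactions"),
       omega_tests = mwu("omega"), delta_k_tests = dk,
       descriptives = desc)
}
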