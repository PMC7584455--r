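## Declustering of non-reference insertion calls, allele matrices, allele
## frequency spectra, and insertion-based PCA.

#' Decluster raw insertion calls
#'
#' Calls are clustered per (strain, family) by one-dimensional chaining at
#' distance <= `eps` (DBSCAN with `min_samples = 1`). A cluster is an
#' accepted insertion locus iff it contains at least one high-quality
#' (flag 8) call; its position is the median of member positions.
#'
#' @param calls data.frame with `strain`, `family`, `position`
#'   (alignment coordinates) and `quality_flag`.
#' @param eps Chaining distance.
#' @param hq_flag Flag value marking high-quality calls.
#' @return data.frame of loci: `strain`, `family`, `position`, `n_calls`,
#'   `accepted`.
#' @export
decluster_calls <- function(calls, eps = 500, hq_flag = 8L) {
  stopifnot(all(c("strain", "family", "position", "quality_flag") %in%
                  names(calls)), all(calls$position >= 0))
  res <- list()
  for (grp in split(calls, list(calls$strain, calls$family), drop = TRUE)) {
    cl <- chain_cluster_1d(grp$position, eps = eps)
    for (id in unique(cl)) {
      m <- grp[cl == id, ]
      res[[length(res) + 1L]] <- data.frame(
        strain = m$strain[1], family = m$family[1],
        position = stats::median(m$position), n_calls = nrow(m),
        accepted = any(m$quality_flag == hq_flag),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  out[order(out$strain, out$family, out$position), ]
}

#' Build a presence/absence allele matrix from accepted loci
#'
#' Accepted loci from different strains are unified into population-level
#' insertion loci by the same chaining rule (within `eps`, per family);
#' the matrix records which strains carry each unified locus.
#'
#' @param loci Output of [decluster_calls()] (rows with
#'   `accepted == FALSE` are dropped).
#' @param strains Character vector of all strains (so strains carrying no
#'   insertion still appear as all-zero rows).
#' @param eps Cross-strain locus-matching distance.
#' @return Binary matrix, strains x loci; locus names are
#'   `family@median-position`.
#' @export
build_allele_matrix <- function(loci, strains = NULL, eps = 500) {
  loci <- loci[loci$accepted, ]
  if (is.null(strains)) strains <- sort(unique(loci$strain))
  cols <- list()
  for (fam in sort(unique(loci$family))) {
    lf <- loci[loci$family == fam, ]
    cl <- chain_cluster_1d(lf$position, eps = eps)
    for (id in unique(cl)) {
      m <- lf[cl == id, ]
      v <- as.integer(strains %in% m$strain)
      cols[[paste0(fam, "@", round(stats::median(m$position)))]] <- v
    }
  }
  if (length(cols) == 0L) {
    return(matrix(integer(0), nrow = length(strains), ncol = 0,
                  dimnames = list(strains, NULL)))
  }
  mat <- do.call(cbind, cols)
  rownames(mat) <- strains
  mat
}

#' Per-lineage insertion allele frequency spectra
#'
#' For each lineage, the carrier frequency of every locus segregating in
#' that lineage (loci absent from all the lineage's strains are
#' excluded).
#'
#' @param allele_matrix Binary strains x loci matrix.
#' @param lineages Lineage label per strain (row).
#' @return data.frame `lineage`, `locus`, `frequency`.
#' @export
allele_frequency_spectrum <- function(allele_matrix, lineages) {
  stopifnot(nrow(allele_matrix) == length(lineages))
  res <- list()
  for (l in sort(unique(as.character(lineages)))) {
    sub <- allele_matrix[lineages == l, , drop = FALSE]
    freq <- colMeans(sub)
    seg <- freq > 0
    if (!any(seg)) next
    res[[l]] <- data.frame(lineage = l,
                           locus = colnames(sub)[seg],
                           frequency = freq[seg],
                           row.names = NULL, stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}

#' PCA on the insertion allele matrix
#'
#' Column-centered (unscaled) principal component analysis of the binary
#' presence/absence matrix.
#'
#' @param allele_matrix Binary strains x loci matrix.
#' @return list with `coordinates` (strains x PCs), `variance_fraction`
#'   per PC, and the `prcomp` object.
#' @export
insertion_pca <- function(allele_matrix) {
  abort_if(ncol(allele_matrix) == 0L, "allele matrix has no loci")
  p <- stats::prcomp(allele_matrix, center = TRUE, scale. = FALSE)
  tot <- sum(p$sdev^2)
  vf <- if (tot > 0) p$sdev^2 / tot else rep(0, length(p$sdev))
  list(coordinates = p$x, variance_fraction = vf, prcomp = p)
}
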