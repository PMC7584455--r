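## gPC/ePC association framework: climate aggregation, PC retention,
## linear models with AIC comparison, and cluster-inconsistency analysis.

#' Aggregate climate records into a z-scored feature table
#'
#' Per (location, variable): the mean, standard deviation, minimum and
#' maximum over the time series. Resulting columns are standardized to
#' zero mean and unit variance; zero-variance columns are dropped with a
#' warning.
#'
#' @param records Long data.frame: `location`, `variable`, `year` (or any
#'   time index), `value`.
#' @return Numeric matrix, locations x features (feature names
#'   `<variable>_<stat>`), z-scored by column.
#' @export
aggregate_climate <- function(records) {
  stopifnot(all(c("location", "variable", "value") %in% names(records)))
  locs <- sort(unique(records$location))
  vars <- sort(unique(records$variable))
  stats_fun <- list(mean = mean, sd = stats::sd, min = min, max = max)
  cols <- list()
  for (v in vars) {
    rv <- records[records$variable == v, ]
    by_loc <- split(rv$value, factor(rv$location, levels = locs))
    for (s in names(stats_fun)) {
      cols[[paste0(v, "_", s)]] <- vapply(by_loc, stats_fun[[s]], 0)
    }
  }
  mat <- do.call(cbind, cols)
  rownames(mat) <- locs
  sds <- apply(mat, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance climate features: ",
            paste(colnames(mat)[sds == 0], collapse = ", "))
    mat <- mat[, sds > 0, drop = FALSE]
  }
  scale(mat)
}

#' Retain leading principal components to a cumulative variance threshold
#'
#' Keeps the smallest leading set of PCs whose cumulative variance
#' fraction reaches at least `cum_threshold`.
#'
#' @param pca A `prcomp` object or a list with `coordinates` and
#'   `variance_fraction` (as from [insertion_pca()]).
#' @param cum_threshold Cumulative variance fraction to reach.
#' @param kind Label for the PC set ("gPC" or "ePC").
#' @return list of class `pc_set`: `kind`, `coordinates` (retained
#'   columns, renamed `<kind>1..`), `variance_fraction` (all PCs),
#'   `retained` (logical per PC).
#' @export
select_pcs <- function(pca, cum_threshold = 0.80, kind = "gPC") {
  if (inherits(pca, "prcomp")) {
    coords <- pca$x
    vf <- pca$sdev^2 / sum(pca$sdev^2)
  } else {
    coords <- pca$coordinates
    vf <- pca$variance_fraction
  }
  cum <- cumsum(vf)
  n_keep <- which(cum >= cum_threshold - 1e-12)[1]
  if (is.na(n_keep)) n_keep <- length(vf)
  retained <- seq_along(vf) <= n_keep
  kept <- coords[, seq_len(n_keep), drop = FALSE]
  colnames(kept) <- paste0(kind, seq_len(n_keep))
  structure(list(kind = kind, coordinates = kept, variance_fraction = vf,
                 retained = retained),
            class = "pc_set")
}

#' Genotype PCA with site preprocessing
#'
#' Keeps biallelic segregating sites and excludes singletons (minor
#' allele observed once), then performs column-centered PCA on the
#' genotype dosage matrix.
#'
#' @param genotypes strains x sites matrix of allele dosages (0/1/2).
#' @return A `prcomp` object.
#' @export
genotype_pca <- function(genotypes) {
  ac <- colSums(genotypes)
  n2 <- 2L * nrow(genotypes)
  keep <- ac > 1L & ac < (n2 - 1L)
  abort_if(!any(keep), "no sites left after filtering")
  stats::prcomp(genotypes[, keep, drop = FALSE], center = TRUE,
                scale. = FALSE)
}

#' Linear models of copy number on structure and climate PCs
#'
#' Fits ordinary least squares (i) `CN ~ gPCs + ePCs` and (ii)
#' `CN ~ gPCs`, reports per-term p-values and the AIC of both, and the
#' difference `delta_aic = AIC(full) - AIC(gPC-only)` (positive values
#' favor the structure-only model).
#'
#' @param cn Numeric response vector (one value per strain).
#' @param gpcs,epcs Matrices of retained PC coordinates (strains x PCs).
#' @return list with `full`, `gpc_only` (each: fit, coefficients, aic)
#'   and `delta_aic`.
#' @export
fit_cn_models <- function(cn, gpcs, epcs) {
  n <- length(cn)
  p_tot <- ncol(gpcs) + ncol(epcs)
  abort_if(n <= p_tot + 1L, "need more strains than predictors + 1")
  X <- cbind(gpcs, epcs)
  abort_if(qr(X)$rank < ncol(X),
           "rank-deficient design; collinear columns: %s",
           paste(colnames(X)[-seq_len(qr(X)$rank)], collapse = ", "))
  df_full <- data.frame(cn = cn, X, check.names = FALSE)
  df_g <- data.frame(cn = cn, gpcs, check.names = FALSE)
  fit_full <- stats::lm(cn ~ ., data = df_full)
  fit_g <- stats::lm(cn ~ ., data = df_g)
  tidy <- function(fit) {
    sm <- summary(fit)$coefficients
    data.frame(term = rownames(sm), estimate = sm[, 1], p = sm[, 4],
               row.names = NULL, stringsAsFactors = FALSE)
  }
  list(full = list(fit = fit_full, coefficients = tidy(fit_full),
                   aic = stats::AIC(fit_full)),
       gpc_only = list(fit = fit_g, coefficients = tidy(fit_g),
                       aic = stats::AIC(fit_g)),
       delta_aic = stats::AIC(fit_full) - stats::AIC(fit_g))
}

#' Affinity propagation clustering
#'
#' Standard affinity propagation on negative squared Euclidean
#' similarities, with the preference set to the median similarity,
#' damping and an iteration cap as configured. Convergence requires the
#' exemplar set to be stable for `conv_iter` consecutive iterations.
#'
#' @param x Numeric matrix (points x dimensions).
#' @param damping Damping factor in \[0.5, 1).
#' @param max_iter Iteration cap.
#' @param conv_iter Stable iterations required for convergence.
#' @param preference Exemplar preference; default the median off-diagonal
#'   similarity.
#' @return list with `labels` (integer cluster per point), `exemplars`
#'   (row indices), `iterations`, `converged`.
#' @export
affinity_propagation <- function(x, damping = 0.8, max_iter = 10000L,
                                 conv_iter = 100L, preference = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  abort_if(n < 2L, "need >= 2 points")
  d2 <- as.matrix(stats::dist(x))^2
  S <- -d2
  if (is.null(preference)) {
    preference <- stats::median(S[upper.tri(S) | lower.tri(S)])
  }
  diag(S) <- preference
  R <- matrix(0, n, n); A <- matrix(0, n, n)
  stable <- 0L; last_ex <- integer(0); it <- 0L
  for (it in seq_len(max_iter)) {
    AS <- A + S
    max1 <- apply(AS, 1, max)
    which1 <- max.col(AS, ties.method = "first")
    AS2 <- AS
    AS2[cbind(seq_len(n), which1)] <- -Inf
    max2 <- apply(AS2, 1, max)
    Rnew <- S - max1
    Rnew[cbind(seq_len(n), which1)] <- S[cbind(seq_len(n), which1)] - max2
    R <- damping * R + (1 - damping) * Rnew
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    colsum <- colSums(Rp)
    Anew <- matrix(rep(colsum, each = n), n, n) - Rp
    dAnew <- diag(Anew)
    Anew <- pmin(Anew, 0)
    diag(Anew) <- dAnew
    A <- damping * A + (1 - damping) * Anew
    ex <- which(diag(A) + diag(R) > 0)
    if (length(ex) > 0L && identical(ex, last_ex)) {
      stable <- stable + 1L
      if (stable >= conv_iter) break
    } else {
      stable <- 0L
      last_ex <- ex
    }
  }
  ex <- which(diag(A) + diag(R) > 0)
  abort_if(length(ex) == 0L || stable < conv_iter,
           "affinity propagation did not converge; adjust damping or preference")
  assign_to <- ex[max.col(S[, ex, drop = FALSE], ties.method = "first")]
  assign_to[ex] <- ex
  labels <- match(assign_to, sort(unique(assign_to)))
  list(labels = labels, exemplars = sort(unique(assign_to)),
       iterations = it, converged = TRUE)
}

#' Cluster inconsistency of copy numbers under structure vs climate
#'
#' Clusters strains by affinity propagation on gPC coordinates, then by
#' seeded k-means on ePC coordinates with the same number of clusters.
#' The inconsistency of a cluster is the standard deviation of copy
#' number within it, per Ty family; gPC-cluster and ePC-cluster SD
#' distributions are compared per family by a two-tailed Mann-Whitney U
#' test, Benjamini-Hochberg corrected across families.
#'
#' @param gpc_coords,epc_coords Retained PC coordinate matrices.
#' @param cn_matrix strains x families matrix of (floored) copy numbers.
#' @param damping,max_iter Affinity propagation parameters.
#' @param kmeans_seed Seed for the k-means multi-start (10 starts).
#' @return list with `gpc_clusters`, `epc_clusters` (labels), `sd_table`
#'   (clustering kind, cluster, family, sd, n), `tests` (per family MWU),
#'   `k`.
#' @export
cluster_inconsistency <- function(gpc_coords, epc_coords, cn_matrix,
                                  damping = 0.8, max_iter = 10000L,
                                  kmeans_seed = 1L) {
  abort_if(nrow(gpc_coords) < 2L, "need >= 2 strains")
  ap <- affinity_propagation(gpc_coords, damping = damping,
                             max_iter = max_iter)
  k <- length(unique(ap$labels))
  abort_if(k > nrow(epc_coords), "more clusters than strains for k-means")
  km <- with_seed(kmeans_seed,
                  stats::kmeans(epc_coords, centers = k, nstart = 10))
  sd_rows <- list()
  collect <- function(labels, kind) {
    for (cl in sort(unique(labels))) {
      sub <- cn_matrix[labels == cl, , drop = FALSE]
      for (fam in colnames(cn_matrix)) {
        sd_rows[[length(sd_rows) + 1L]] <<- data.frame(
          kind = kind, cluster = cl, family = fam,
          sd = if (nrow(sub) > 1) stats::sd(sub[, fam]) else NA_real_,
          n = nrow(sub), stringsAsFactors = FALSE)
      }
    }
  }
  collect(ap$labels, "gPC")
  collect(km$cluster, "ePC")
  sd_table <- do.call(rbind, sd_rows)
  tests <- NULL
  if (k >= 2L) {
    rows <- lapply(colnames(cn_matrix), function(fam) {
      gsd <- sd_table$sd[sd_table$kind == "gPC" & sd_table$family == fam]
      esd <- sd_table$sd[sd_table$kind == "ePC" & sd_table$family == fam]
      gsd <- gsd[!is.na(gsd)]; esd <- esd[!is.na(esd)]
      if (length(gsd) == 0 || length(esd) == 0) {
        return(data.frame(family = fam, p = NA_real_, tie = NA))
      }
      tie <- length(unique(c(gsd, esd))) == 1L
      p <- if (tie) 1 else {
        stats::wilcox.test(gsd, esd, alternative = "two.sided",
                           exact = FALSE)$p.value
      }
      data.frame(family = fam, p = p, tie = tie, stringsAsFactors = FALSE)
    })
    tests <- do.call(rbind, rows)
    tests$p_adj <- bh_adjust(tests$p)
  } else {
    warning("single cluster; inconsistency test skipped")
  }
  list(gpc_clusters = ap$labels, epc_clusters = km$cluster,
       sd_table = sd_table, tests = tests, k = k)
}
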