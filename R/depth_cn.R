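## Normalized read-depth copy number (NRD), control-gene flooring, and
## lineage / mutation-accumulation statistics.

#' Normalized read depth (NRD)
#'
#' `NRD = log2(median_depth) - log2(genome_wide_depth)`. A zero median
#' depth yields `-Inf`, a sentinel later resolved by flooring. Under a
#' diploid convention the genome-wide depth corresponds to copy number 1
#' per haploid genome equivalent, so NRD is log2 copy number.
#'
#' @param median_depth Numeric vector of per-locus median depths.
#' @param genome_wide_depth Genome-wide depth (scalar or vector); must be
#'   > 0.
#' @return Numeric vector of NRD values.
#' @export
normalized_read_depth <- function(median_depth, genome_wide_depth) {
  abort_if(any(genome_wide_depth <= 0), "genome_wide_depth must be > 0")
  abort_if(any(median_depth < 0), "depths must be >= 0")
  log2(median_depth) - log2(genome_wide_depth)
}

#' Control-gene floor for NRD values
#'
#' The floor is the 10th percentile (linear interpolation) of the NRD
#' values of single-copy control genes; values below it (including the
#' `-Inf` sentinel) are replaced by the floor. On the real data this
#' percentile was -1.25.
#'
#' @param control_nrd NRD values of >= 10 control genes.
#' @param prob Floor percentile as probability.
#' @return The floor value.
#' @export
derive_floor <- function(control_nrd, prob = 0.10) {
  abort_if(length(control_nrd) == 0L, "no control genes supplied")
  abort_if(length(control_nrd) < 10L, "need >= 10 control genes")
  percentile(control_nrd, prob)
}

#' @rdname derive_floor
#' @param values NRD values to floor.
#' @param floor Floor value from [derive_floor()].
#' @return `values` with entries below `floor` replaced by `floor`.
#' @export
apply_floor <- function(values, floor) {
  pmax(values, floor)
}

#' Declare Ty families absent from a cross
#'
#' For mutation-accumulation crosses, a (cross, family) combination is
#' declared absent and excluded when its median NRD is below the
#' cross-specific 10th percentile of control-gene NRDs.
#'
#' @param nrd Numeric NRD values of one family in one cross.
#' @param control_nrd Control-gene NRDs of the same cross.
#' @param prob Percentile as probability.
#' @return Logical scalar: `TRUE` when the family is absent.
#' @export
family_absent <- function(nrd, control_nrd, prob = 0.10) {
  stats::median(nrd) < derive_floor(control_nrd, prob)
}

#' Conover post-hoc test after Kruskal-Wallis
#'
#' Two-sided pairwise comparisons on the joint ranks, using the
#' ties-corrected rank variance and the Kruskal-Wallis statistic in the
#' pooled variance term (t distribution with N - k degrees of freedom).
#'
#' @param x Numeric response.
#' @param g Grouping factor.
#' @return data.frame of group pairs with t statistics and raw p-values.
#' @export
conover_test <- function(x, g) {
  g <- factor(g)
  k <- nlevels(g)
  abort_if(k < 2L, "need >= 2 groups")
  N <- length(x)
  r <- rank(x)
  rsum <- tapply(r, g, sum)
  nn <- tapply(r, g, length)
  s2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
  H <- (sum(rsum^2 / nn) - N * (N + 1)^2 / 4) / s2
  pooled <- s2 * (N - 1 - H) / (N - k)
  lev <- levels(g)
  pr <- utils::combn(lev, 2)
  res <- lapply(seq_len(ncol(pr)), function(m) {
    a <- pr[1, m]; b <- pr[2, m]
    tval <- (rsum[a] / nn[a] - rsum[b] / nn[b]) /
      sqrt(pooled * (1 / nn[a] + 1 / nn[b]))
    data.frame(group_a = a, group_b = b, statistic = unname(tval),
               p = 2 * stats::pt(-abs(unname(tval)), df = N - k),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Lineage-wise copy-number tests
#'
#' Per family: a Kruskal-Wallis test of NRD across lineages, followed by
#' pairwise Conover post-hoc tests, Benjamini-Hochberg corrected within
#' family. All pairs are reported; consumers may condition on the
#' Kruskal-Wallis result. Constant values yield p = 1 with a warning.
#'
#' @param cn_matrix strains x families numeric matrix of NRD values.
#' @param lineages Character/factor vector of lineage labels per strain.
#' @return list with `kruskal` (family, statistic, p) and `posthoc`
#'   (family, group pair, statistic, raw and adjusted p).
#' @export
lineage_cn_tests <- function(cn_matrix, lineages) {
  lineages <- factor(lineages)
  abort_if(nlevels(lineages) < 2L, "need >= 2 lineages")
  abort_if(min(table(lineages)) < 2L, "need >= 2 strains per lineage")
  kr <- list(); ph <- list()
  for (fam in colnames(cn_matrix)) {
    x <- cn_matrix[, fam]
    if (length(unique(x)) == 1L) {
      warning("constant NRD for family ", fam, "; p set to 1")
      kr[[fam]] <- data.frame(family = fam, statistic = 0, p = 1)
      next
    }
    kt <- stats::kruskal.test(x, lineages)
    kr[[fam]] <- data.frame(family = fam,
                            statistic = unname(kt$statistic),
                            p = kt$p.value)
    ct <- conover_test(x, lineages)
    ct$p_adj <- bh_adjust(ct$p)
    ct <- cbind(family = fam, ct)
    ph[[fam]] <- ct
  }
  list(kruskal = do.call(rbind, c(kr, list(make.row.names = FALSE))),
       posthoc = if (length(ph)) do.call(rbind, c(ph, list(make.row.names = FALSE))) else NULL)
}

#' Brown-Forsythe test for equality of variances
#'
#' One-way ANOVA on absolute deviations from the group medians.
#'
#' @param x Numeric response.
#' @param g Grouping factor (>= 2 groups).
#' @return list with `statistic`, `df`, `p`.
#' @export
brown_forsythe <- function(x, g) {
  g <- factor(g)
  abort_if(nlevels(g) < 2L, "need >= 2 groups")
  med <- tapply(x, g, stats::median)
  z <- abs(x - med[g])
  if (stats::var(z) == 0) {
    return(list(statistic = 0, df = c(nlevels(g) - 1L,
                                      length(x) - nlevels(g)), p = 1))
  }
  fit <- stats::anova(stats::lm(z ~ g))
  list(statistic = fit$`F value`[1], df = fit$Df, p = fit$`Pr(>F)`[1])
}

#' Copy-number change tests for mutation-accumulation crosses
#'
#' Per (cross, family): a paired Wilcoxon signed-rank test of the end
#' versus initial NRD, and a Brown-Forsythe test of variance equality
#' between the two timepoints. P-values are Benjamini-Hochberg corrected
#' across all (cross, family) combinations within each test type. When
#' all paired differences are zero, the Wilcoxon test is degenerate and
#' reported as p = 1 with a flag.
#'
#' @param records data.frame with columns `cross`, `family`, `line`,
#'   `cn_tini`, `cn_tend`.
#' @param min_lines Minimum lines per cross.
#' @return data.frame with one row per (cross, family).
#' @export
ma_delta_cn_tests <- function(records, min_lines = 6L) {
  stopifnot(all(c("cross", "family", "cn_tini", "cn_tend") %in%
                  names(records)))
  res <- list()
  for (grp in split(records, list(records$cross, records$family),
                    drop = TRUE)) {
    n <- nrow(grp)
    abort_if(n < min_lines, "cross %s has %d lines; need >= %d",
             grp$cross[1], n, min_lines)
    d <- grp$cn_tend - grp$cn_tini
    if (all(d == 0)) {
      w_p <- 1; zero_flag <- TRUE
    } else {
      w_p <- stats::wilcox.test(grp$cn_tend, grp$cn_tini, paired = TRUE,
                                exact = FALSE)$p.value
      zero_flag <- FALSE
    }
    bf <- brown_forsythe(c(grp$cn_tini, grp$cn_tend),
                         rep(c("tini", "tend"), each = n))
    res[[length(res) + 1L]] <- data.frame(
      cross = grp$cross[1], family = grp$family[1], n_lines = n,
      mean_delta = mean(d), wilcoxon_p = w_p, all_zero = zero_flag,
      brown_forsythe_p = bf$p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$wilcoxon_p_adj <- bh_adjust(out$wilcoxon_p)
  out$brown_forsythe_p_adj <- bh_adjust(out$brown_forsythe_p)
  out
}

#' Evolutionary divergence between two strains on a tree
#'
#' The sum of branch lengths on the path connecting the two tips
#' (patristic distance).
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param tip_a,tip_b Tip labels.
#' @return Path length.
#' @export
parental_divergence <- function(tree, tip_a, tip_b) {
  stopifnot(inherits(tree, "phylo"))
  abort_if(!all(c(tip_a, tip_b) %in% tree$tip.label),
           "tip absent from tree: %s",
           paste(setdiff(c(tip_a, tip_b), tree$tip.label), collapse = ", "))
  d <- ape::cophenetic.phylo(tree)
  d[tip_a, tip_b]
}

#' Linear model of mean copy-number change per cross
#'
#' Ordinary least squares of the mean NRD change per cross on the summed
#' parental copy numbers and the parental evolutionary divergence, with
#' intercept. Reports per-term p-values, R-squared, and partial residuals
#' for component-plus-residual plotting.
#'
#' @param mean_delta_cn Numeric vector, one value per cross.
#' @param parental_cn_sum Numeric vector of summed parental copy numbers.
#' @param parental_divergence Numeric vector of parental divergences.
#' @return list with `fit` (the `lm`), `coefficients` (term, estimate, p),
#'   `r_squared`, and `partial_residuals` (matrix, one column per
#'   predictor).
#' @export
fit_delta_cn_model <- function(mean_delta_cn, parental_cn_sum,
                               parental_divergence) {
  abort_if(length(mean_delta_cn) < 4L, "need >= 4 crosses")
  X <- data.frame(delta = mean_delta_cn, cn_sum = parental_cn_sum,
                  divergence = parental_divergence)
  mm <- stats::model.matrix(~ cn_sum + divergence, X)
  abort_if(qr(mm)$rank < ncol(mm),
           "rank-deficient design (collinear predictors)")
  fit <- stats::lm(delta ~ cn_sum + divergence, data = X)
  sm <- summary(fit)
  coefs <- data.frame(term = rownames(sm$coefficients),
                      estimate = sm$coefficients[, 1],
                      p = sm$coefficients[, 4],
                      row.names = NULL, stringsAsFactors = FALSE)
  pres <- stats::residuals(fit) +
    cbind(cn_sum = stats::coef(fit)["cn_sum"] * X$cn_sum,
          divergence = stats::coef(fit)["divergence"] * X$divergence)
  list(fit = fit, coefficients = coefs, r_squared = sm$r.squared,
       partial_residuals = pres)
}
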