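## Growth-curve analysis of the arsenite assay: normalization,
## condition-difference AUC, replicate filtering, variance partitioning.

#' Normalize growth series to their initial reading
#'
#' Subtracts the first (by time) OD value of each (strain, replicate,
#' condition) well from the whole series. Idempotent.
#'
#' @param series Long data.frame with `strain`, `replicate`, `condition`,
#'   `time`, `od`.
#' @return The same data.frame with `od` normalized.
#' @export
normalize_series <- function(series) {
  stopifnot(all(c("strain", "replicate", "condition", "time", "od") %in%
                  names(series)))
  key <- interaction(series$strain, series$replicate, series$condition,
                     drop = TRUE)
  for (k in levels(key)) {
    idx <- which(key == k)
    idx <- idx[order(series$time[idx])]
    series$od[idx] <- series$od[idx] - series$od[idx[1]]
  }
  series
}

#' Condition-difference curves and their AUC
#'
#' For each (strain, replicate): the stressed-minus-control OD difference
#' at every timepoint, its AUC as the plain sum over timepoints
#' (rectangle rule with unit step), and a binned difference curve
#' averaging replicates and consecutive bins of `bin` timepoints.
#'
#' @param series Normalized long data.frame with conditions `SC` and
#'   `As` on a shared time grid per replicate.
#' @param bin Timepoints per bin of the plotted curve (4 x 15 min = 1 h).
#' @return list with `auc` (strain, lineage if present, replicate, auc)
#'   and `curve` (strain, bin, time, mean_diff).
#' @export
difference_auc <- function(series, bin = 4L) {
  auc_rows <- list(); diff_rows <- list()
  for (grp in split(series, list(series$strain, series$replicate),
                    drop = TRUE)) {
    sc <- grp[grp$condition == "SC", ]
    as_ <- grp[grp$condition == "As", ]
    if (nrow(sc) == 0L || nrow(as_) == 0L) next
    sc <- sc[order(sc$time), ]
    as_ <- as_[order(as_$time), ]
    abort_if(nrow(sc) != nrow(as_) || any(sc$time != as_$time),
             "time grid mismatch for strain %s replicate %s",
             grp$strain[1], grp$replicate[1])
    d <- as_$od - sc$od
    auc_rows[[length(auc_rows) + 1L]] <- data.frame(
      strain = grp$strain[1],
      lineage = if ("lineage" %in% names(grp)) grp$lineage[1] else NA,
      replicate = grp$replicate[1], auc = sum(d),
      stringsAsFactors = FALSE)
    diff_rows[[length(diff_rows) + 1L]] <- data.frame(
      strain = grp$strain[1], time = sc$time, diff = d,
      stringsAsFactors = FALSE)
  }
  auc <- do.call(rbind, auc_rows)
  dd <- do.call(rbind, diff_rows)
  dd$bin <- (match(dd$time, sort(unique(dd$time))) - 1L) %/% bin
  agg <- stats::aggregate(cbind(mean_diff = dd$diff, time = dd$time),
                          by = list(strain = dd$strain, bin = dd$bin),
                          FUN = mean)
  list(auc = auc, curve = agg[order(agg$strain, agg$bin), ])
}

#' Detect replicates whose control preculture failed to grow
#'
#' A replicate is flagged failed when its control (SC) curve never gains
#' more than `min_gain` OD over its initial reading.
#'
#' @param series Normalized long growth table.
#' @param min_gain Minimum OD gain for a grown culture.
#' @return data.frame `strain`, `replicate`, `failed`.
#' @export
flag_failed_precultures <- function(series, min_gain = 0.1) {
  sc <- series[series$condition == "SC", ]
  res <- stats::aggregate(od ~ strain + replicate, data = sc, FUN = max)
  data.frame(strain = res$strain, replicate = res$replicate,
             failed = res$od < min_gain, stringsAsFactors = FALSE)
}

#' Filter strains by replicate count and AUC homoscedasticity
#'
#' Drops failed replicates, then strains with fewer than `min_replicates`
#' replicates left, then computes the per-strain replicate SD of AUC,
#' z-scores those SDs across strains, and drops strains outside the
#' \[-1, 1\] z-score range.
#'
#' @param auc data.frame from [difference_auc()]`$auc`.
#' @param failed Optional data.frame from [flag_failed_precultures()].
#' @param min_replicates Minimum surviving replicates per strain.
#' @param z_range Allowed z-score range of per-strain replicate SDs.
#' @return list with `auc` (retained rows), `dropped` (strain, reason).
#' @export
filter_replicates <- function(auc, failed = NULL, min_replicates = 3L,
                              z_range = c(-1, 1)) {
  dropped <- list()
  if (!is.null(failed)) {
    bad <- failed[failed$failed, ]
    if (nrow(bad)) {
      key <- paste(auc$strain, auc$replicate)
      auc <- auc[!(key %in% paste(bad$strain, bad$replicate)), ]
    }
  }
  n_rep <- table(auc$strain)
  few <- names(n_rep)[n_rep < min_replicates]
  if (length(few)) {
    dropped[[length(dropped) + 1L]] <- data.frame(
      strain = few, reason = "fewer than min replicates",
      stringsAsFactors = FALSE)
    auc <- auc[!(auc$strain %in% few), ]
  }
  sds <- tapply(auc$auc, auc$strain, stats::sd)
  z <- if (stats::sd(sds) == 0) rep(0, length(sds)) else {
    (sds - mean(sds)) / stats::sd(sds)
  }
  out_z <- names(sds)[z < z_range[1] | z > z_range[2]]
  if (length(out_z)) {
    dropped[[length(dropped) + 1L]] <- data.frame(
      strain = out_z, reason = "replicate SD outside z-score range",
      stringsAsFactors = FALSE)
    auc <- auc[!(auc$strain %in% out_z), ]
  }
  list(auc = auc,
       dropped = if (length(dropped)) do.call(rbind, dropped) else
         data.frame(strain = character(0), reason = character(0)))
}

#' Tukey HSD letter groups
#'
#' Compact letter display from [stats::TukeyHSD()]: groups that are not
#' significantly different share a letter. Letters correspond to maximal
#' cliques of the not-significantly-different graph, ordered by group
#' mean.
#'
#' @param aov_fit A one-factor `aov` fit.
#' @param alpha Significance level.
#' @return Named character vector: group -> letter string.
#' @export
tukey_letter_groups <- function(aov_fit, alpha = 0.05) {
  tk <- stats::TukeyHSD(aov_fit)[[1]]
  fac <- aov_fit$model[[2]]
  lev <- levels(fac)
  means <- tapply(aov_fit$model[[1]], fac, mean)
  lev <- names(sort(means))
  nsd <- igraph::make_empty_graph(n = length(lev), directed = FALSE)
  nsd <- igraph::set_vertex_attr(nsd, "name", value = lev)
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (i in seq_along(pairs)) {
    if (tk[i, "p adj"] >= alpha) {
      nsd <- igraph::add_edges(nsd, match(pairs[[i]], lev))
    }
  }
  cliques <- igraph::max_cliques(nsd)
  cliques <- cliques[order(vapply(cliques,
                                  function(cl) min(match(names(cl), lev)),
                                  0))]
  out <- stats::setNames(rep("", length(lev)), lev)
  for (ci in seq_along(cliques)) {
    memb <- names(cliques[[ci]])
    out[memb] <- paste0(out[memb], letters[ci])
  }
  out
}

#' Variance partitioning and lineage contrasts of growth AUC
#'
#' Fits a mixed model with lineage as fixed effect and strain as random
#' effect to test the lineage effect, partitions the total variance into
#' lineage, strain and residual components (via a fully random nested
#' model) expressed as percentages summing to 100, and assigns Tukey HSD
#' letter groups to lineages.
#'
#' @param auc data.frame with `strain`, `lineage`, `auc` (one row per
#'   replicate), >= 2 lineages, >= 2 strains per lineage, >= 3 replicates
#'   per strain.
#' @return list with `percentages` (lineage, strain, residual),
#'   `lineage_test` (F statistic and p from the mixed-model ANOVA),
#'   `tukey_letters` (named character vector), `fits`.
#' @export
variance_components <- function(auc) {
  stopifnot(all(c("strain", "lineage", "auc") %in% names(auc)))
  auc$lineage <- factor(auc$lineage)
  auc$strain <- factor(auc$strain)
  abort_if(nlevels(auc$lineage) < 2L, "need >= 2 lineages")
  fixed_fit <- lmerTest::lmer(auc ~ lineage + (1 | strain), data = auc)
  an <- stats::anova(fixed_fit)
  rand_fit <- lme4::lmer(auc ~ 1 + (1 | lineage) + (1 | strain), data = auc)
  vc <- as.data.frame(lme4::VarCorr(rand_fit))
  v <- stats::setNames(vc$vcov, vc$grp)
  comp <- c(lineage = unname(v["lineage"]), strain = unname(v["strain"]),
            residual = unname(v["Residual"]))
  pct <- 100 * comp / sum(comp)
  aov_fit <- stats::aov(auc ~ lineage, data = auc)
  letters <- tukey_letter_groups(aov_fit)
  list(percentages = pct,
       lineage_test = data.frame(F = an$`F value`[1], p = an$`Pr(>F)`[1]),
       tukey_letters = letters,
       fits = list(fixed = fixed_fit, random = rand_fit))
}
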