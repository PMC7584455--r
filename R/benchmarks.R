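## Truth-known benchmark measurements on synthetic data. Each function
## regenerates its inputs from a seed, runs the corresponding analysis
## path end to end, and returns the quantities that summarize how well
## the method recovers the planted truth. They are used by the test
## suite and by scripts/acceptance.R.

#' Orthogroup recovery on a six-genome synthetic landscape
#'
#' Simulates the default six-genome, three-family landscape, perturbs
#' projected annotation coordinates with uniform jitter (emulating
#' assembly and alignment imprecision, at most half the coordinate
#' threshold), derives the threshold from confident orthogroups, calls
#' orthogroups, and compares the called partition with the planted one.
#'
#' @param seed Integer seed.
#' @param coord_jitter Maximum absolute coordinate perturbation (bp).
#' @return list: `recovery_pct` (planted orthogroups recovered exactly,
#'   %), `n_orthogroups`, `family_mixing` (count of called groups mixing
#'   families), `threshold` (derived, bp).
#' @export
benchmark_orthogroup_recovery <- function(seed, coord_jitter = 8L) {
  cfg <- sim_config(seed = seed)
  sim <- simulate_te_genomes(cfg)
  blocks <- filter_msa_blocks(sim$alignment)
  proj <- project_annotations(sim$annotations, blocks)
  set.seed(seed + 10L)
  jit <- function(n) sample(seq(-coord_jitter, coord_jitter), n,
                            replace = TRUE)
  proj$msa_start <- proj$msa_start + jit(nrow(proj))
  proj$msa_end <- proj$msa_end + jit(nrow(proj))
  clustered <- cluster_positions_1d(proj)
  el <- element_sequences(sim)
  hits <- cross_genome_hits(clustered, el)
  lens <- stats::setNames(nchar(el), names(el))
  conf <- select_confident_orthogroups(clustered, hits, lens)
  thr <- derive_coordinate_threshold(conf$diffs)
  ogs <- call_orthogroups(clustered, hits, thr)
  pk <- function(members, groups) {
    sort(unname(vapply(split(members, groups),
                       function(x) paste(sort(x), collapse = "|"), "")))
  }
  truth_keys <- pk(sim$truth$element_id, sim$truth$true_orthogroup)
  called_keys <- pk(ogs$element_id, ogs$orthogroup_id)
  mixing <- sum(vapply(split(ogs$family, ogs$orthogroup_id),
                       function(f) length(unique(f)), 0L) > 1L)
  list(recovery_pct = 100 * mean(truth_keys %in% called_keys),
       n_orthogroups = length(truth_keys),
       family_mixing = mixing,
       threshold = thr)
}

#' Divergence-since-transposition versus true insertion age
#'
#' Simulates the default landscape and correlates the estimated
#' divergence (closest-relative identity) with the planted insertion age
#' across all genomes, on unsaturated elements.
#'
#' @param seed Integer seed.
#' @param saturation_cutoff Elements with estimated divergence above
#'   this value (%) are considered saturated and excluded.
#' @return list: `spearman_rho`, `n_elements`.
#' @export
benchmark_divergence_age <- function(seed, saturation_cutoff = 25) {
  cfg <- sim_config(seed = seed)
  sim <- simulate_te_genomes(cfg)
  parts <- lapply(names(sim$genomes), function(g) {
    hits <- score_hits(ltr_sequences(sim, g))
    ann <- sim$annotations[sim$annotations$genome == g, ]
    d <- divergence_since_transposition(ann, hits)
    merge(d[!d$no_hit, ], sim$truth[sim$truth$genome == g, ],
          by = "element_id")
  })
  m <- do.call(rbind, parts)
  m <- m[m$divergence < saturation_cutoff, ]
  list(spearman_rho = stats::cor(m$true_insertion_time, m$divergence,
                                 method = "spearman"),
       n_elements = nrow(m))
}

#' Copy-number recovery from simulated read depth
#'
#' 100 strains with known copy numbers 1-8 across three families at the
#' configured coverage; reports the mean absolute difference between the
#' normalized read depth and log2 of the true copy number.
#'
#' @param seed Integer seed.
#' @param n_strains Number of strains.
#' @return list: `mean_abs_error`, `n_measurements`.
#' @export
benchmark_cn_recovery <- function(seed, n_strains = 100L) {
  cfg <- sim_config(seed = seed)
  set.seed(seed + 20L)
  cn <- matrix(sample(1:8, n_strains * 3, replace = TRUE), n_strains, 3,
               dimnames = list(sprintf("s%03d", seq_len(n_strains)),
                               cfg$families$name))
  dep <- simulate_depth_tables(cn, cfg)
  fam <- dep[!is.na(dep$family), ]
  nrd <- normalized_read_depth(fam$median_depth, fam$genome_wide_depth)
  list(mean_abs_error = mean(abs(nrd - log2(fam$true_cn))),
       n_measurements = nrow(fam))
}

#' Insertion-call declustering against planted insertions
#'
#' Simulates jittered multi-call insertion evidence with scattered false
#' positives over the default landscape and declusters it.
#'
#' @param seed Integer seed.
#' @return list: `accepted_loci`, `planted_insertions`,
#'   `fp_clusters_accepted` (clusters made purely of false-positive
#'   calls that were accepted; the flag-8 rule keeps this at zero).
#' @export
benchmark_call_declustering <- function(seed) {
  cfg <- sim_config(seed = seed)
  sim <- simulate_te_genomes(cfg)
  calls <- simulate_insertion_calls(sim, cfg)
  loci <- decluster_calls(calls)
  # an accepted cluster is FP-only if no true call of that strain/family
  # lies within eps of its position
  truth_calls <- calls[!calls$is_fp, ]
  fp_accepted <- 0L
  acc <- loci[loci$accepted, ]
  for (i in seq_len(nrow(acc))) {
    near <- truth_calls$strain == acc$strain[i] &
      truth_calls$family == acc$family[i] &
      abs(truth_calls$position - acc$position[i]) <= 500
    if (!any(near)) fp_accepted <- fp_accepted + 1L
  }
  list(accepted_loci = sum(loci$accepted),
       planted_insertions = nrow(sim$truth),
       fp_clusters_accepted = fp_accepted)
}

#' Model selection and cluster inconsistency under decoupled climate
#'
#' Repeatedly simulates structured populations whose copy numbers derive
#' from lineage identity while climate is independent of the structure,
#' and fits the two linear models; also runs the cluster-inconsistency
#' comparison once on the first replicate.
#'
#' @param seed Integer seed.
#' @param n_reps Number of model-comparison replicates.
#' @return list: `gpc_only_aic_win_pct` (replicates where the
#'   structure-only model has lower AIC, %), `inconsistency_mwu_p`
#'   (largest Benjamini-Hochberg adjusted Mann-Whitney p across
#'   families), `n_reps`.
#' @export
benchmark_association <- function(seed, n_reps = 200L) {
  wins <- 0L
  mwu_p <- NA_real_
  for (r in seq_len(n_reps)) {
    cfg <- sim_config(seed = seed + r, climate_coupling = FALSE)
    pop <- simulate_population(cfg)
    gset <- select_pcs(genotype_pca(pop$genotypes))
    eset <- select_pcs(stats::prcomp(aggregate_climate(pop$climate)),
                       kind = "ePC")
    set.seed(seed + 100000L + r)
    lin_levels <- unique(pop$lineages)
    base <- stats::setNames(stats::rnorm(length(lin_levels)), lin_levels)
    cn <- cbind(Ty1 = base[pop$lineages] +
                  stats::rnorm(length(pop$lineages), 0, 0.3))
    rownames(cn) <- names(pop$lineages)
    fit <- fit_cn_models(cn[, 1], gset$coordinates, eset$coordinates)
    wins <- wins + (fit$delta_aic > 0)
    if (r == 1L) {
      ci <- cluster_inconsistency(gset$coordinates, eset$coordinates, cn)
      mwu_p <- max(ci$tests$p_adj)
    }
  }
  list(gpc_only_aic_win_pct = 100 * wins / n_reps,
       inconsistency_mwu_p = mwu_p, n_reps = n_reps)
}

#' Type-I error calibration of the test stages
#'
#' Null simulations for the Kruskal-Wallis lineage stage, the
#' Brown-Forsythe variance stage and the paired Wilcoxon stage.
#'
#' @param seed Integer seed.
#' @param n_reps Null replicates per test.
#' @param alpha Nominal level.
#' @return list of rejection rates: `kruskal_wallis`, `brown_forsythe`,
#'   `wilcoxon`, plus `n_reps`.
#' @export
benchmark_calibration <- function(seed, n_reps = 1000L, alpha = 0.05) {
  set.seed(seed + 30L)
  g3 <- factor(rep(1:3, each = 20))
  kw <- mean(replicate(n_reps, {
    stats::kruskal.test(stats::rnorm(60), g3)$p.value
  }) < alpha)
  g2 <- rep(c("a", "b"), each = 20)
  bf <- mean(replicate(n_reps, {
    brown_forsythe(stats::rnorm(40), g2)$p
  }) < alpha)
  wx <- mean(replicate(n_reps, {
    stats::wilcox.test(stats::rnorm(20), stats::rnorm(20), paired = TRUE,
                       exact = FALSE)$p.value
  }) < alpha)
  list(kruskal_wallis = kw, brown_forsythe = bf, wilcoxon = wx,
       n_reps = n_reps)
}

#' Agreement with brute-force oracles on randomized small instances
#'
#' Compares weighted clade k, branching times, parental divergences,
#' percentile thresholds and Fisher exact p-values with independent
#' brute-force computations.
#'
#' @param seed Integer seed.
#' @param n_reps Randomized instances per quantity.
#' @return list: `max_abs_diff` (largest absolute discrepancy observed),
#'   `n_comparisons`.
#' @export
benchmark_oracles <- function(seed, n_reps = 20L) {
  set.seed(seed + 40L)
  diffs <- c()
  for (i in seq_len(n_reps)) {
    # clade k on the full tree equals the direct weighted sum
    tr <- ape::rtree(sample(5:20, 1))
    k <- stats::runif(nrow(tr$edge), 0, 3)
    diffs <- c(diffs, abs(weighted_clade_k(tr, k, tr$tip.label) -
                            sum(k * tr$edge.length) / sum(tr$edge.length)))
    # branching times against manual root-path accumulation
    tru <- ape::rcoal(sample(5:20, 1))
    bt <- branching_times_scaled(tru)
    n_tip <- length(tru$tip.label)
    depth <- rep(NA_real_, n_tip + tru$Nnode)
    depth[n_tip + 1L] <- 0
    repeat {
      todo <- which(is.na(depth[tru$edge[, 2]]) &
                      !is.na(depth[tru$edge[, 1]]))
      if (!length(todo)) break
      depth[tru$edge[todo, 2]] <- depth[tru$edge[todo, 1]] +
        tru$edge.length[todo]
    }
    h <- max(depth[seq_len(n_tip)])
    diffs <- c(diffs, max(abs(bt$time - depth[bt$node] / h)))
    # parental divergence against root-path algebra
    tips <- sample(tru$tip.label, 2)
    mrca <- ape::getMRCA(tru, tips)
    oracle <- depth[match(tips[1], tru$tip.label)] +
      depth[match(tips[2], tru$tip.label)] - 2 * depth[mrca]
    diffs <- c(diffs, abs(parental_divergence(tru, tips[1], tips[2]) -
                            oracle))
    # percentile against manual linear interpolation
    x <- sort(stats::runif(sample(5:40, 1), 0, 100))
    p <- stats::runif(1)
    hpos <- (length(x) - 1) * p
    manual <- x[floor(hpos) + 1] * (1 - (hpos - floor(hpos))) +
      x[min(floor(hpos) + 2, length(x))] * (hpos - floor(hpos))
    diffs <- c(diffs, abs(percentile(x, p) - manual))
    # Fisher exact against hypergeometric enumeration
    tab <- matrix(sample(0:15, 4, replace = TRUE), 2)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
      r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
      amin <- max(0, c1 - r2); amax <- min(r1, c1)
      prob <- function(a) exp(lchoose(r1, a) + lchoose(r2, c1 - a) -
                                lchoose(sum(tab), c1))
      p_obs <- prob(tab[1, 1])
      enum <- sum(vapply(amin:amax, function(a) {
        pa <- prob(a); if (pa <= p_obs * (1 + 1e-7)) pa else 0
      }, 0))
      diffs <- c(diffs, abs(stats::fisher.test(tab)$p.value - enum))
    }
  }
  list(max_abs_diff = max(diffs), n_comparisons = length(diffs))
}

#' Variance-component recovery for an 8:1:1 growth design
#'
#' Simulates replicated growth AUC values with lineage, strain and
#' residual variances in ratio 8:1:1 and reports the mean estimated
#' percentages over replicates.
#'
#' @param seed Integer seed.
#' @param n_reps Simulation replicates.
#' @return list: `lineage_pct`, `strain_pct`, `residual_pct` (means over
#'   replicates), `max_abs_error` versus the 80/10/10 target, `n_reps`.
#' @export
benchmark_variance_components <- function(seed, n_reps = 30L) {
  set.seed(seed + 50L)
  pcts <- replicate(n_reps, {
    lin <- rep(sprintf("L%02d", 1:12), each = 6 * 4)
    strain <- rep(sprintf("s%03d", 1:72), each = 4)
    y <- stats::rnorm(12, 0, sqrt(8))[as.integer(factor(lin))] +
      stats::rnorm(72, 0, 1)[as.integer(factor(strain))] +
      stats::rnorm(length(strain), 0, 1)
    df <- data.frame(strain = strain, lineage = lin, auc = y)
    suppressMessages(variance_components(df)$percentages)
  })
  m <- rowMeans(pcts)
  list(lineage_pct = unname(m["lineage"]),
       strain_pct = unname(m["strain"]),
       residual_pct = unname(m["residual"]),
       max_abs_error = max(abs(m - c(80, 10, 10))),
       n_reps = n_reps)
}
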