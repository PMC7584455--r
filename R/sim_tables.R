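## Simulators for the tabular inputs of the downstream analyses: depth
## tables, structured populations with climate covariates, insertion-call
## evidence, and growth plates.

# median of per-base negative-binomial depths over a locus of `len`
# positions (variance = mu + dispersion * mu^2 per base); dispersion 0
# means noise-free depth equal to the expectation.
.median_depth_draw <- function(mu, len, dispersion) {
  if (dispersion <= 0) return(mu)
  stats::median(stats::rnbinom(len, mu = mu, size = 1 / dispersion))
}

#' Simulate per-locus depth tables from known copy numbers
#'
#' Depth over a family's internal reference scales linearly with the true
#' copy number (expectation `coverage_mean * CN`); single-copy control
#' genes have expectation `coverage_mean`; genome-wide depth equals
#' `coverage_mean` (copy number 1 per haploid genome equivalent). Noise
#' is negative-binomial with the configured dispersion; a copy number of
#' 0 draws from a background floor near zero.
#'
#' The reported per-locus value is the median of per-base depths over the
#' locus (negative-binomial per base), matching how median depth is
#' extracted from pileups in practice.
#'
#' @param truth Either a `ty_sim` object (its `truth_cn` matrix is used)
#'   or a strains x families matrix of true copy numbers.
#' @param config A [sim_config()] object.
#' @param background_mu Expected per-base depth at copy number 0.
#' @param locus_length Length (bp) of a family's internal reference.
#' @param ctrl_length Length (bp) of a control gene.
#' @return data.frame with `strain`, `locus`, `family` (`NA` for control
#'   genes), `true_cn`, `median_depth`, `genome_wide_depth`.
#' @export
simulate_depth_tables <- function(truth, config, background_mu = 0.1,
                                  locus_length = 5000L,
                                  ctrl_length = 1000L) {
  stopifnot(inherits(config, "sim_config"))
  cn <- if (inherits(truth, "ty_sim")) truth$truth_cn else truth
  stopifnot(is.matrix(cn), !is.null(rownames(cn)), !is.null(colnames(cn)))
  set.seed(config$seed + 1L)
  cov <- config$coverage_mean
  disp <- config$coverage_dispersion
  rows <- list()
  for (s in rownames(cn)) {
    mu <- ifelse(cn[s, ] > 0, cov * cn[s, ], background_mu)
    rows[[length(rows) + 1L]] <- data.frame(
      strain = s, locus = paste0(colnames(cn), "_internal"),
      family = colnames(cn), true_cn = as.integer(cn[s, ]),
      median_depth = vapply(mu, .median_depth_draw, 0,
                            len = locus_length, dispersion = disp),
      genome_wide_depth = cov, stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      strain = s, locus = sprintf("ctrl_%02d", seq_len(config$n_control_genes)),
      family = NA_character_, true_cn = 1L,
      median_depth = vapply(rep(cov, config$n_control_genes),
                            .median_depth_draw, 0,
                            len = ctrl_length, dispersion = disp),
      genome_wide_depth = cov, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Simulate a structured population with climate covariates
#'
#' SNP allele frequencies are differentiated among lineages under a
#' Balding-Nichols model with differentiation parameter `config$fst`
#' (0 means panmixia); hybrid lineages mix their parents' frequencies at
#' the configured proportion. Diploid genotypes are binomial draws.
#' Climate records are yearly series per sampling location; when
#' `climate_coupling` is on, location means share a latent factor with
#' lineage identity, otherwise they are independent of the structure.
#'
#' @param config A [sim_config()] object (`n_snps >= 10` required).
#' @param coupling_strength Effect of the lineage latent factor on
#'   climate means when coupling is on.
#' @return list with `genotypes` (strains x SNPs, 0/1/2), `lineages`
#'   (named character), and `climate` (long data.frame: location,
#'   variable, year, value).
#' @export
simulate_population <- function(config, coupling_strength = 1.5) {
  stopifnot(inherits(config, "sim_config"))
  abort_if(config$n_snps < 10L, "n_snps must be >= 10")
  set.seed(config$seed + 2L)
  tips <- config$lineage_tree$tip.label
  hybrids <- vapply(config$hybrid_events, `[[`, "", "child")
  lineage_names <- c(tips, hybrids)
  nS <- config$n_snps
  p_anc <- stats::runif(nS, 0.05, 0.95)
  F <- config$fst
  freq <- matrix(NA_real_, nrow = length(lineage_names), ncol = nS,
                 dimnames = list(lineage_names, NULL))
  for (l in tips) {
    freq[l, ] <- if (F <= 0) p_anc else {
      stats::rbeta(nS, p_anc * (1 - F) / F, (1 - p_anc) * (1 - F) / F)
    }
  }
  for (h in config$hybrid_events) {
    freq[h$child, ] <- h$proportion * freq[h$parent_a, ] +
      (1 - h$proportion) * freq[h$parent_b, ]
  }
  n_per <- config$n_strains_per_lineage
  strains <- as.vector(t(outer(lineage_names, seq_len(n_per),
                               function(l, i) sprintf("%s_%02d", l, i))))
  lineages <- stats::setNames(rep(lineage_names, each = n_per), strains)
  geno <- matrix(0L, nrow = length(strains), ncol = nS,
                 dimnames = list(strains, paste0("snp", seq_len(nS))))
  for (i in seq_along(strains)) {
    geno[i, ] <- stats::rbinom(nS, 2L, freq[lineages[i], ])
  }
  z_lineage <- stats::setNames(stats::rnorm(length(lineage_names)),
                               lineage_names)
  nV <- config$n_climate_vars
  nY <- config$climate_years
  base <- if (config$climate_coupling) {
    coupling_strength * matrix(z_lineage[lineages[strains]],
                               nrow = length(strains), ncol = nV) +
      matrix(stats::rnorm(length(strains) * nV, 0, 0.5),
             nrow = length(strains))
  } else {
    matrix(stats::rnorm(length(strains) * nV), nrow = length(strains))
  }
  climate <- data.frame(
    location = rep(strains, each = nV * nY),
    variable = rep(rep(sprintf("clim%02d", seq_len(nV)), each = nY),
                   times = length(strains)),
    year = rep(seq_len(nY), times = nV * length(strains)),
    value = rep(as.vector(t(base)), each = nY) +
      stats::rnorm(length(strains) * nV * nY),
    stringsAsFactors = FALSE)
  list(genotypes = geno, lineages = lineages, climate = climate)
}

#' Simulate raw insertion-call evidence
#'
#' Each planted insertion emits 1 + Poisson(1) calls whose positions are
#' jittered around the true alignment coordinate with SD
#' `config$call_jitter_sd`; with probability `config$quality_flag_dist`
#' one of them is a high-quality (flag 8) call, the rest are flag 6.
#' False-positive calls (never flag 8) are scattered uniformly at
#' `config$call_fp_rate` per genome kilobase.
#'
#' @param sim A `ty_sim` object (true per-genome insertion positions are
#'   taken from its events/truth tables), or a data.frame with columns
#'   `strain`, `family`, `position`.
#' @param config A [sim_config()] object.
#' @return data.frame of raw calls: `strain`, `family`, `position`,
#'   `quality_flag`, `is_fp`, `true_orthogroup`.
#' @export
simulate_insertion_calls <- function(sim, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  if (inherits(sim, "ty_sim")) {
    tr <- merge(sim$truth,
                data.frame(true_orthogroup = paste0("og", sim$events$event_id),
                           position = sim$events$msa_start,
                           stringsAsFactors = FALSE),
                by = "true_orthogroup")
    truth <- data.frame(strain = tr$genome, family = tr$family,
                        position = tr$position,
                        true_orthogroup = tr$true_orthogroup,
                        stringsAsFactors = FALSE)
    span <- max(sim$alignment$blocks$msa_end)
    kb <- config$genome_length / 1000
  } else {
    truth <- sim
    truth$true_orthogroup <- if ("true_orthogroup" %in% names(sim)) {
      sim$true_orthogroup
    } else paste0("locus", seq_len(nrow(sim)))
    span <- max(truth$position) + 1e4
    kb <- span / 1000
  }
  fams <- unique(truth$family)
  rows <- list()
  for (i in seq_len(nrow(truth))) {
    k <- 1L + stats::rpois(1L, 1)
    pos <- pmax(0, round(truth$position[i] +
                           stats::rnorm(k, 0, config$call_jitter_sd)))
    flags <- rep(6L, k)
    if (stats::runif(1) < config$quality_flag_dist) {
      flags[sample.int(k, 1L)] <- 8L
    }
    rows[[length(rows) + 1L]] <- data.frame(
      strain = truth$strain[i], family = truth$family[i], position = pos,
      quality_flag = flags, is_fp = FALSE,
      true_orthogroup = truth$true_orthogroup[i], stringsAsFactors = FALSE)
  }
  for (s in unique(truth$strain)) {
    n_fp <- stats::rpois(1L, config$call_fp_rate * kb)
    if (n_fp == 0L) next
    rows[[length(rows) + 1L]] <- data.frame(
      strain = s, family = sample(fams, n_fp, replace = TRUE),
      position = round(stats::runif(n_fp, 0, span)),
      quality_flag = 6L, is_fp = TRUE, true_orthogroup = NA_character_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out[order(out$strain, out$family, out$position), ]
}

#' Simulate growth-curve plates
#'
#' Logistic growth curves on a 15-minute grid for paired control (SC) and
#' stressed (As) conditions; the stressed condition multiplies each
#' strain's growth rate by the lineage-specific factor in
#' `config$growth_stress_factors`. Replicate noise is i.i.d. on the OD
#' readings, plus a small per-replicate rate jitter.
#'
#' @param config A [sim_config()] object.
#' @param n_strains_per_lineage Strains simulated per lineage.
#' @param hours Assay duration (70 h as in a plate-reader run).
#' @param rate_jitter_sd SD of the per-replicate growth-rate jitter.
#' @return Long data.frame: `strain`, `lineage`, `replicate`,
#'   `condition` (SC/As), `time` (h), `od`.
#' @export
simulate_growth_plates <- function(config, n_strains_per_lineage = 5L,
                                   hours = 70, rate_jitter_sd = 0.005) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 4L)
  tgrid <- seq(0, hours, by = 0.25)
  sf <- config$growth_stress_factors
  lineage_names <- names(sf)
  rows <- list()
  for (l in lineage_names) {
    for (i in seq_len(n_strains_per_lineage)) {
      strain <- sprintf("%s_s%02d", l, i)
      r_strain <- stats::rnorm(1, 0.25, 0.02)
      for (rep_i in seq_len(config$growth_replicates)) {
        for (cond in c("SC", "As")) {
          r <- max(r_strain + stats::rnorm(1, 0, rate_jitter_sd), 0.01)
          if (cond == "As") r <- r * sf[l]
          od <- 0.1 + 0.9 / (1 + exp(-r * (tgrid - 20))) +
            stats::rnorm(length(tgrid), 0, config$growth_noise_sd)
          rows[[length(rows) + 1L]] <- data.frame(
            strain = strain, lineage = l, replicate = rep_i,
            condition = cond, time = tgrid, od = od,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}
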