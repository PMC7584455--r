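#' Default lineage tree for the synthetic generator
#'
#' A rooted six-tip tree with branch lengths in substitutions/site that
#' mirrors the topology of North American wild yeast lineages: two deep
#' pure lineages, a third outgroup-like pure lineage, and a nested set of
#' younger lineages. Tip-to-root depth is 0.04 substitutions/site, the
#' order of magnitude of intraspecific divergence in wild *S. paradoxus*.
#'
#' @return An [ape::read.tree()] phylo object with 6 tips.
#' @export
default_lineage_tree <- function() {
  ape::read.tree(text = paste0(
    "((SpB:0.03,(SpC:0.012,(SpCs:0.008,(SpD1:0.004,SpD2:0.004):0.004)",
    ":0.004):0.018):0.01,SpA:0.04);"))
}

#' Default Ty family parameter table
#'
#' Three active families with realistic LTR and internal lengths (LTRs
#' ~300-370 bp, internal sequences ~5 kb). Transposition rates are per unit
#' branch length (substitutions/site) and are scaled so that a six-genome
#' simulation on [default_lineage_tree()] plants on the order of 60
#' orthogroups; the most active family transposes at twice the rate of the
#' others. Solo-LTR formation converts a full-length element to a solo LTR
#' by intra-element recombination at the given rate per unit branch length.
#'
#' @return A data.frame with columns `name`, `ltr_length`, `internal_length`,
#'   `transposition_rate`, `solo_rate`.
#' @export
default_families <- function() {
  data.frame(
    name = c("Ty1", "Ty3p", "Tsu4"),
    ltr_length = c(330L, 340L, 370L),
    internal_length = c(5200L, 4700L, 5600L),
    transposition_rate = c(180, 90, 90),
    solo_rate = c(5, 5, 5),
    stringsAsFactors = FALSE)
}

#' Build a synthetic-data configuration
#'
#' Central parameter container for every `simulate_*` function. Defaults
#' describe the study conditions the downstream analyses assume: six
#' genomes of 2 Mb related by [default_lineage_tree()], three Ty families
#' planting ~60 orthogroups, 30x sequencing coverage, and insertion-call
#' evidence with 100 bp positional jitter.
#'
#' @param seed Integer seed; every simulation is reproducible given it.
#' @param lineage_tree Rooted `phylo` with >= 2 tips and nonnegative branch
#'   lengths (substitutions/site). Tip labels name the genomes/lineages.
#' @param genome_length Ancestral backbone length in bp.
#' @param families Family table as in [default_families()].
#' @param n_ancestral_per_family Full-length elements planted in the root
#'   genome per family (these become candidate conserved orthogroups).
#' @param ancestral_age Extra age (branch-length units) assigned uniformly
#'   at random to ancestral elements, on top of the tree depth. The
#'   default spans the divergence range observed for ancient solo LTRs,
#'   which reach tens of percent of sequence divergence.
#' @param ancestral_solo_prob Probability that an ancestral element is
#'   already a solo LTR at the root. Ancient insertions are mostly
#'   recombined in real genomes, where solo LTRs outnumber full-length
#'   elements roughly tenfold and deeply conserved insertion loci carry a
#'   low full-length ratio.
#' @param hybrid_events List of `list(child=, parent_a=, parent_b=,
#'   proportion=)`: extra genomes built as position-wise mosaics of two tip
#'   genomes, with `proportion` the expected fraction from `parent_a`.
#' @param hybrid_block_mean Mean mosaic block length in bp (geometric).
#' @param tsd_length Target-site duplication length in bp (typical Ty
#'   integration duplicates 5 bp).
#' @param min_anchor_spacing Minimum distance between insertion anchors in
#'   bp; insertion sites violating it are redrawn (bounded retries), so the
#'   generator never nests or tandems elements.
#' @param coverage_mean Expected reads-per-base at copy number 1 (haploid
#'   genome equivalent); genome-wide depth equals this value.
#' @param coverage_dispersion Negative-binomial dispersion of per-locus
#'   depth (variance = mu + dispersion * mu^2); 0 means noise-free depth.
#' @param n_control_genes Single-copy control genes simulated per strain.
#' @param n_snps SNPs simulated by [simulate_population()].
#' @param n_strains_per_lineage Strains per lineage in the population
#'   simulation (207 wild isolates over six lineages motivates ~34).
#' @param fst Lineage differentiation of SNP allele frequencies
#'   (Balding-Nichols F); 0 means panmixia. The default 0.7 reflects
#'   strongly differentiated incipient species, for which the first
#'   genotype PC alone captures about half the total variance.
#' @param climate_coupling If `TRUE`, climate covariates share a latent
#'   factor with lineage structure; if `FALSE` they are independent.
#' @param n_climate_vars Number of raw climate variables (12 as in
#'   gridded climate products).
#' @param climate_years Number of yearly records aggregated per location
#'   (1958-2015 spans 58 years).
#' @param call_jitter_sd SD (bp) of positional jitter on insertion calls.
#' @param call_fp_rate False-positive calls per genome kilobase.
#' @param quality_flag_dist Probability that a true insertion emits at
#'   least one high-quality (flag 8) call.
#' @param growth_stress_factors Named vector: multiplicative effect of the
#'   stressed condition on growth rate, per lineage.
#' @param growth_replicates Replicates per strain in the plate simulation.
#' @param growth_noise_sd SD of i.i.d. OD noise per timepoint.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       lineage_tree = default_lineage_tree(),
                       genome_length = 2e6,
                       families = default_families(),
                       n_ancestral_per_family = 4L,
                       ancestral_age = 0.15,
                       ancestral_solo_prob = 0.8,
                       hybrid_events = list(),
                       hybrid_block_mean = 5e4,
                       tsd_length = 5L,
                       min_anchor_spacing = 2000L,
                       coverage_mean = 30,
                       coverage_dispersion = 0.05,
                       n_control_genes = 50L,
                       n_snps = 1000L,
                       n_strains_per_lineage = 34L,
                       fst = 0.7,
                       climate_coupling = FALSE,
                       n_climate_vars = 12L,
                       climate_years = 58L,
                       call_jitter_sd = 100,
                       call_fp_rate = 0.005,
                       quality_flag_dist = 1.0,
                       growth_stress_factors = NULL,
                       growth_replicates = 5L,
                       growth_noise_sd = 0.01) {
  abort_if(!inherits(lineage_tree, "phylo"), "lineage_tree must be a phylo object")
  abort_if(length(lineage_tree$tip.label) < 2L,
           "lineage_tree must have at least 2 tips")
  abort_if(is.null(lineage_tree$edge.length) ||
             any(lineage_tree$edge.length < 0),
           "lineage_tree must carry nonnegative branch lengths")
  abort_if(!is.data.frame(families) ||
             !all(c("name", "ltr_length", "internal_length",
                    "transposition_rate", "solo_rate") %in% names(families)),
           "families must have columns name, ltr_length, internal_length, transposition_rate, solo_rate")
  abort_if(any(families$ltr_length < 50), "ltr_length must be >= 50 bp")
  abort_if(any(families$transposition_rate < 0) || any(families$solo_rate < 0),
           "family rates must be >= 0")
  for (h in hybrid_events) {
    abort_if(!all(c("child", "parent_a", "parent_b", "proportion") %in% names(h)),
             "each hybrid event needs child, parent_a, parent_b, proportion")
    abort_if(h$proportion < 0 || h$proportion > 1,
             "hybrid mixing proportion must be in [0, 1]")
    abort_if(!all(c(h$parent_a, h$parent_b) %in% lineage_tree$tip.label),
             "hybrid parents must be tips of lineage_tree")
  }
  abort_if(coverage_mean <= 0, "coverage_mean must be > 0")
  abort_if(coverage_dispersion < 0, "coverage_dispersion must be >= 0")
  abort_if(call_jitter_sd < 0 || call_fp_rate < 0, "rates must be >= 0")
  abort_if(quality_flag_dist < 0 || quality_flag_dist > 1,
           "quality_flag_dist is a probability")
  if (is.null(growth_stress_factors)) {
    tips <- lineage_tree$tip.label
    growth_stress_factors <- stats::setNames(rep(0.8, length(tips)), tips)
  }
  cfg <- list(
    seed = as.integer(seed),
    lineage_tree = lineage_tree,
    n_genomes = length(lineage_tree$tip.label) + length(hybrid_events),
    genome_length = as.integer(genome_length),
    families = families,
    n_ancestral_per_family = as.integer(n_ancestral_per_family),
    ancestral_age = ancestral_age,
    ancestral_solo_prob = ancestral_solo_prob,
    hybrid_events = hybrid_events,
    hybrid_block_mean = hybrid_block_mean,
    tsd_length = as.integer(tsd_length),
    min_anchor_spacing = as.integer(min_anchor_spacing),
    coverage_mean = coverage_mean,
    coverage_dispersion = coverage_dispersion,
    n_control_genes = as.integer(n_control_genes),
    n_snps = as.integer(n_snps),
    n_strains_per_lineage = as.integer(n_strains_per_lineage),
    fst = fst,
    climate_coupling = isTRUE(climate_coupling),
    n_climate_vars = as.integer(n_climate_vars),
    climate_years = as.integer(climate_years),
    call_jitter_sd = call_jitter_sd,
    call_fp_rate = call_fp_rate,
    quality_flag_dist = quality_flag_dist,
    growth_stress_factors = growth_stress_factors,
    growth_replicates = as.integer(growth_replicates),
    growth_noise_sd = growth_noise_sd)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_genomes, "genomes,",
      nrow(x$families), "families,",
      x$genome_length, "bp backbone, seed", x$seed, "\n")
  invisible(x)
}
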