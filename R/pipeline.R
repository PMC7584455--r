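## End-to-end orchestration on synthetic inputs: generate, analyse,
## report, with provenance.

#' Run the synthetic end-to-end pipeline
#'
#' Executes the enabled stages in dependency order on a synthetic data
#' set: genome simulation, LTR network and divergence, orthogroup
#' calling, depth-based copy number, insertion-call declustering, and
#' growth analysis. Writes versioned outputs and a provenance log
#' (parameters, seeds, package version) when `outdir` is given, and
#' returns the full result bundle.
#'
#' @param config A [sim_config()] object.
#' @param stages Character vector of stages to run, from
#'   `c("syngen", "ltr", "orthogroups", "cn", "calls", "growth")`.
#' @param outdir Optional output directory (created if missing).
#' @param eps Clustering distance for orthogroups and call declustering.
#' @return Named list of stage results plus `provenance`.
#' @export
run_pipeline <- function(config,
                         stages = c("syngen", "ltr", "orthogroups",
                                    "cn", "calls", "growth"),
                         outdir = NULL, eps = 500) {
  stages <- match.arg(stages, several.ok = TRUE)
  res <- list()
  need <- function(stage, dep) {
    abort_if(!dep %in% names(res),
             "stage '%s' requires output of stage '%s'", stage, dep)
  }
  if ("syngen" %in% stages) {
    res$syngen <- simulate_te_genomes(config)
  }
  if ("ltr" %in% stages) {
    need("ltr", "syngen")
    sim <- res$syngen
    per_genome <- lapply(names(sim$genomes), function(g) {
      seqs <- ltr_sequences(sim, g)
      hits <- score_hits(seqs)
      fam_of <- stats::setNames(
        sim$annotations$family[match(
          sim$ltr_annotations$element_id, sim$annotations$element_id)],
        sim$ltr_annotations$ltr_id)
      net <- build_similarity_network(hits, nodes = names(seqs))
      ann_g <- sim$annotations[sim$annotations$genome == g, ]
      list(genome = g, hits = hits, network = net,
           merge = merge_family_labels(net, fam_of),
           divergence = divergence_since_transposition(ann_g, hits))
    })
    names(per_genome) <- names(sim$genomes)
    res$ltr <- per_genome
  }
  if ("orthogroups" %in% stages) {
    need("orthogroups", "syngen")
    sim <- res$syngen
    blocks <- filter_msa_blocks(sim$alignment)
    proj <- project_annotations(sim$annotations, blocks)
    clustered <- cluster_positions_1d(proj, eps = eps)
    el_seqs <- element_sequences(sim)
    hits <- cross_genome_hits(clustered, el_seqs)
    lens <- stats::setNames(nchar(el_seqs), names(el_seqs))
    conf <- select_confident_orthogroups(clustered, hits, lens)
    thr <- if (length(conf$diffs)) {
      derive_coordinate_threshold(conf$diffs)
    } else 17
    ogs <- call_orthogroups(clustered, hits, thr)
    res$orthogroups <- list(
      blocks = blocks, clustered = clustered, threshold = thr,
      orthogroups = ogs,
      conservation = classify_conservation(ogs, length(sim$genomes)))
  }
  if ("cn" %in% stages) {
    need("cn", "syngen")
    depth <- simulate_depth_tables(res$syngen, config)
    nrd <- normalized_read_depth(depth$median_depth,
                                 depth$genome_wide_depth)
    ctrl <- nrd[is.na(depth$family)]
    floor_val <- derive_floor(ctrl)
    depth$nrd <- apply_floor(nrd, floor_val)
    res$cn <- list(depth = depth, floor = floor_val)
  }
  if ("calls" %in% stages) {
    need("calls", "syngen")
    calls <- simulate_insertion_calls(res$syngen, config)
    loci <- decluster_calls(calls, eps = eps)
    res$calls <- list(raw = calls, loci = loci)
  }
  if ("growth" %in% stages) {
    plates <- simulate_growth_plates(config)
    norm <- normalize_series(plates)
    da <- difference_auc(norm)
    res$growth <- list(auc = da$auc, curve = da$curve)
  }
  res$provenance <- list(
    seed = config$seed,
    n_genomes = config$n_genomes,
    genome_length = config$genome_length,
    eps = eps,
    stages = stages,
    package_version = as.character(utils::packageVersion("tylandscape")),
    timestamp_free = TRUE)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if ("syngen" %in% stages) {
      write_genomes_fasta(res$syngen$genomes,
                          file.path(outdir, "genomes.fa"))
      write_ty_gff(res$syngen$annotations,
                   file.path(outdir, "annotations.gff3"))
      utils::write.table(res$syngen$truth,
                         file.path(outdir, "truth.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if ("orthogroups" %in% names(res)) {
      utils::write.table(res$orthogroups$orthogroups,
                         file.path(outdir, "orthogroups.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if ("cn" %in% names(res)) {
      utils::write.table(res$cn$depth, file.path(outdir, "nrd.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    prov <- res$provenance
    writeLines(paste(names(prov), vapply(prov, function(x)
      paste(as.character(x), collapse = ","), ""), sep = "\t"),
      file.path(outdir, "provenance.tsv"))
  }
  res
}

#' Cross-genome element hits restricted to position clusters
#'
#' Scores element sequences against each other within each 1-D position
#' cluster (other pairs cannot be orthologous, so scoring them would be
#' wasted work).
#'
#' @param clustered Output of [cluster_positions_1d()].
#' @param sequences Named character vector of element sequences.
#' @return Combined hit table.
#' @export
cross_genome_hits <- function(clustered, sequences) {
  parts <- lapply(split(clustered$element_id, clustered$cluster),
                  function(ids) {
                    if (length(ids) < 2L) return(NULL)
                    score_hits(sequences[ids])
                  })
  parts <- Filter(Negate(is.null), parts)
  if (length(parts) == 0L) {
    return(score_hits(stats::setNames(character(0), character(0))))
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
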