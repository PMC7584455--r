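## Truth-known genome simulation: related genomes with planted Ty elements.
##
## Model, in brief:
##  - An ancestral backbone sequence evolves along the lineage tree by
##    Jukes-Cantor-like substitution (per-site substitution probability equal
##    to the branch length; no indels outside element insertions).
##  - Transposition plants a full-length element (LTR-internal-LTR) plus a
##    target-site duplication at a random backbone anchor; new copies are
##    born identical to the family ancestral consensus ("master copy"
##    model), so LTR divergence accumulates with time since insertion.
##  - Intra-element recombination converts a full-length element to a solo
##    LTR at a per-branch-length rate, keeping the 5' LTR.
##  - Anchors keep a minimum spacing, so elements never nest or tandem and
##    every insertion column band in the implied multiple alignment hosts
##    exactly one orthogroup.
##  - Hybrid genomes are position-wise mosaics of two tip genomes with
##    geometric block lengths.

.BASES <- charToRaw("ACGT")

random_dna <- function(n) .BASES[sample.int(4L, n, replace = TRUE)]

# Substitute each site independently with probability p (each mutated site
# moves to one of the three other bases uniformly).
mutate_seq <- function(x, p) {
  if (p <= 0 || length(x) == 0L) return(x)
  n <- stats::rbinom(1L, length(x), min(p, 1))
  if (n == 0L) return(x)
  idx <- sample.int(length(x), n)
  cur <- match(x[idx], .BASES)
  x[idx] <- .BASES[((cur - 1L + sample.int(3L, n, replace = TRUE)) %% 4L) + 1L]
  x
}

# Draw an insertion anchor respecting minimum spacing; bounded retries.
draw_anchor <- function(len, used, spacing, tsd, max_tries = 1000L) {
  lo <- spacing
  hi <- len - spacing - tsd
  abort_if(hi <= lo, "genome too short for the requested insertion spacing")
  for (i in seq_len(max_tries)) {
    a <- sample.int(hi - lo, 1L) + lo
    if (length(used) == 0L || min(abs(a - used)) >= spacing) return(a)
  }
  stop("could not place insertion after ", max_tries,
       " retries; lower transposition rates or min_anchor_spacing",
       call. = FALSE)
}

#' Simulate related genomes with planted Ty elements
#'
#' Generates `config$n_genomes` genome sequences descending from a common
#' ancestor along `config$lineage_tree`, with full-length Ty elements and
#' solo LTRs planted under a master-copy transposition model, and returns
#' the annotations, the ground-truth ledger and the implied whole-genome
#' alignment block structure.
#'
#' @param config A [sim_config()] object.
#' @param block_size Backbone length (bp) of each emitted alignment
#'   block. The default (`NULL`) emits one block per chromosome: the
#'   simulated genomes are collinear, and whole-genome aligners split
#'   blocks only at rearrangements. Pass a smaller size to emulate
#'   fragmented alignments.
#' @return An object of class `ty_sim`: a list with elements
#'   \describe{
#'     \item{genomes}{named character vector of genome sequences.}
#'     \item{annotations}{element-level annotation table (0-based half-open
#'       coordinates; columns element_id, genome, contig, start, end,
#'       strand, family, element_type, ltr_ids).}
#'     \item{ltr_annotations}{LTR-level table (ltr_id, element_id, genome,
#'       start, end).}
#'     \item{truth}{ground truth: one row per planted element instance with
#'       its orthogroup, age and full-length status.}
#'     \item{truth_cn}{genomes x families matrix of full-length copy counts.}
#'     \item{alignment}{`msa_blocks` object recording the true homology map.}
#'     \item{events}{per-orthogroup table with anchor and true alignment
#'       start coordinate.}
#'   }
#' @export
simulate_te_genomes <- function(config, block_size = NULL) {
  if (is.null(block_size)) block_size <- config$genome_length
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tree <- config$lineage_tree
  fams <- config$families
  L <- config$genome_length
  tsd <- config$tsd_length

  consensi <- lapply(seq_len(nrow(fams)), function(i) {
    list(ltr = random_dna(fams$ltr_length[i]),
         internal = random_dna(fams$internal_length[i]))
  })
  names(consensi) <- fams$name
  full_seq <- function(f) {
    c(consensi[[f]]$ltr, consensi[[f]]$internal, consensi[[f]]$ltr)
  }

  env <- new.env()
  env$used_anchors <- integer(0)
  env$next_event <- 1L
  env$events <- list()     # event_id -> list(family, anchor)
  env$tips <- list()       # tip name -> state

  new_element <- function(family, age_mutate, total_age) {
    ev <- env$next_event; env$next_event <- ev + 1L
    a <- draw_anchor(L, env$used_anchors, config$min_anchor_spacing, tsd)
    env$used_anchors <- c(env$used_anchors, a)
    env$events[[ev]] <- list(event_id = ev, family = family, anchor = a)
    list(event = ev, family = family, anchor = a, age = total_age,
         full = TRUE, seq = mutate_seq(full_seq(family), age_mutate))
  }

  maybe_solo <- function(el, rate, span) {
    if (el$full && span > 0 && stats::runif(1) < 1 - exp(-rate * span)) {
      lt <- fams$ltr_length[match(el$family, fams$name)]
      el$full <- FALSE
      el$seq <- el$seq[seq_len(lt)]
    }
    el
  }

  evolve_edge <- function(state, brlen) {
    state$backbone <- mutate_seq(state$backbone, brlen)
    state$elements <- lapply(state$elements, function(el) {
      el$seq <- mutate_seq(el$seq, brlen)
      el$age <- el$age + brlen
      maybe_solo(el, fams$solo_rate[match(el$family, fams$name)], brlen)
    })
    for (i in seq_len(nrow(fams))) {
      n_ins <- stats::rpois(1L, fams$transposition_rate[i] * brlen)
      if (n_ins == 0L) next
      times <- sort(stats::runif(n_ins, 0, brlen))
      for (t in times) {
        el <- new_element(fams$name[i], brlen - t, brlen - t)
        el <- maybe_solo(el, fams$solo_rate[i], brlen - t)
        state$elements <- c(state$elements, list(el))
      }
    }
    state
  }

  # Root state: backbone plus ancestral elements with extra pre-root age.
  root_state <- list(backbone = random_dna(L), elements = list())
  for (i in seq_len(nrow(fams))) {
    for (k in seq_len(config$n_ancestral_per_family)) {
      age0 <- stats::runif(1, 0, config$ancestral_age)
      el <- new_element(fams$name[i], age0, age0)
      if (stats::runif(1) < config$ancestral_solo_prob) {
        el$full <- FALSE
        el$seq <- el$seq[seq_len(fams$ltr_length[i])]
      } else {
        el <- maybe_solo(el, fams$solo_rate[i], age0)
      }
      root_state$elements <- c(root_state$elements, list(el))
    }
  }

  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  children_of <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  recurse <- function(node, state) {
    rows <- children_of[[as.character(node)]]
    if (is.null(rows)) {
      env$tips[[tree$tip.label[node]]] <- state
      return(invisible(NULL))
    }
    for (r in rows) {
      child <- tree$edge[r, 2]
      recurse(child, evolve_edge(state, tree$edge.length[r]))
    }
  }
  recurse(root, root_state)

  # Hybrid mosaics: geometric blocks alternating between the two parents.
  for (h in config$hybrid_events) {
    pa <- env$tips[[h$parent_a]]
    pb <- env$tips[[h$parent_b]]
    bounds <- 0L
    while (utils::tail(bounds, 1) < L) {
      bounds <- c(bounds,
                  utils::tail(bounds, 1) +
                    stats::rgeom(1L, 1 / config$hybrid_block_mean) + 1L)
    }
    bounds[length(bounds)] <- L
    from_a <- stats::runif(length(bounds) - 1L) < h$proportion
    bb <- pa$backbone
    block_of <- function(p) findInterval(p, bounds, left.open = TRUE)
    for (j in which(!from_a)) {
      rng <- (bounds[j] + 1L):bounds[j + 1L]
      bb[rng] <- pb$backbone[rng]
    }
    pick <- function(state, keep_a) {
      Filter(function(el) from_a[block_of(el$anchor)] == keep_a,
             state$elements)
    }
    env$tips[[h$child]] <- list(backbone = bb,
                                elements = c(pick(pa, TRUE), pick(pb, FALSE)))
  }

  genome_names <- names(env$tips)
  events <- do.call(rbind, lapply(env$events, function(e) {
    data.frame(event_id = e$event_id, family = e$family, anchor = e$anchor,
               stringsAsFactors = FALSE)
  }))

  # Assemble tip genomes, annotations and truth.
  genomes <- character(0)
  ann <- list(); ltr_ann <- list(); truth <- list()
  for (g in genome_names) {
    state <- env$tips[[g]]
    els <- state$elements
    if (length(els)) {
      els <- els[order(vapply(els, `[[`, 0, "anchor"))]
    }
    bb <- state$backbone
    pieces <- vector("list", 2L * length(els) + 1L)
    pi <- 0L; cur <- 1L; gpos <- 0L
    for (el in els) {
      a <- el$anchor
      run <- bb[cur:a]
      pi <- pi + 1L; pieces[[pi]] <- run
      gpos <- gpos + length(run)
      seg <- c(bb[(a + 1L):(a + tsd)], el$seq)
      pi <- pi + 1L; pieces[[pi]] <- seg
      start0 <- gpos + tsd
      end0 <- gpos + length(seg)
      gpos <- end0
      cur <- a + 1L
      eid <- paste0(g, ":og", el$event)
      lt <- fams$ltr_length[match(el$family, fams$name)]
      if (el$full) {
        lids <- paste0(eid, c(":L5", ":L3"))
        ltr_ann[[length(ltr_ann) + 1L]] <- data.frame(
          ltr_id = lids, element_id = eid, genome = g,
          start = c(start0, end0 - lt), end = c(start0 + lt, end0),
          stringsAsFactors = FALSE)
      } else {
        lids <- paste0(eid, ":L5")
        ltr_ann[[length(ltr_ann) + 1L]] <- data.frame(
          ltr_id = lids, element_id = eid, genome = g,
          start = start0, end = end0, stringsAsFactors = FALSE)
      }
      ann[[length(ann) + 1L]] <- data.frame(
        element_id = eid, genome = g, contig = "chr1",
        start = start0, end = end0, strand = "+",
        family = el$family,
        element_type = if (el$full) "full_length" else "solo_LTR",
        ltr_ids = paste(lids, collapse = ","), stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        element_id = eid, family = el$family, genome = g,
        true_insertion_time = el$age,
        true_orthogroup = paste0("og", el$event),
        is_full_length = el$full, stringsAsFactors = FALSE)
    }
    pi <- pi + 1L; pieces[[pi]] <- bb[cur:L]
    genomes[g] <- rawToChar(do.call(c, pieces[seq_len(pi)]))
  }
  annotations <- do.call(rbind, ann)
  ltr_annotations <- do.call(rbind, ltr_ann)
  truth_df <- do.call(rbind, truth)

  truth_cn <- matrix(0L, nrow = length(genome_names), ncol = nrow(fams),
                     dimnames = list(genome_names, fams$name))
  fl <- truth_df[truth_df$is_full_length, ]
  if (nrow(fl)) {
    tab <- table(fl$genome, fl$family)
    truth_cn[rownames(tab), colnames(tab)] <- as.integer(tab)
  }

  alignment <- build_alignment_blocks(env$tips, events, config, block_size)

  # True alignment start coordinate (0-based) of each orthogroup's element.
  events$msa_start <- alignment$msa_of_backbone(events$anchor) + 1L + tsd
  events$width <- alignment$event_width[as.character(events$event_id)]

  out <- list(config = config, genomes = genomes,
              annotations = annotations, ltr_annotations = ltr_annotations,
              truth = truth_df, truth_cn = truth_cn,
              alignment = alignment$blocks, events = events)
  class(out) <- "ty_sim"
  out
}

# Build the msa_blocks structure implied by the planted insertions: global
# alignment columns are backbone columns plus one column band per insertion
# event (band width = widest realization of that event across genomes).
build_alignment_blocks <- function(tips, events, config, block_size) {
  L <- config$genome_length
  tsd <- config$tsd_length
  genome_names <- names(tips)

  # realized inserted length (tsd + element length) per event per genome
  carried <- lapply(tips, function(state) {
    if (length(state$elements) == 0L) {
      return(data.frame(event = integer(0), anchor = integer(0),
                        len = integer(0)))
    }
    data.frame(
      event = vapply(state$elements, `[[`, 0L, "event"),
      anchor = vapply(state$elements, `[[`, 0L, "anchor"),
      len = vapply(state$elements, function(e) length(e$seq), 0L) + tsd)
  })
  all_car <- do.call(rbind, carried)
  width_by_event <- tapply(all_car$len, all_car$event, max)
  live <- events[events$event_id %in% as.integer(names(width_by_event)), ]
  live <- live[order(live$anchor), ]
  live$width <- as.integer(width_by_event[as.character(live$event_id)])
  cumw <- c(0L, cumsum(live$width))

  # 0-based alignment column of backbone base p (1-based backbone coord)
  msa_of_backbone <- function(p) {
    (p - 1L) + cumw[findInterval(p - 0.5, live$anchor) + 1L]
  }

  starts <- seq(1L, L, by = as.integer(block_size))
  ends <- pmin(starts + as.integer(block_size) - 1L, L)
  blocks <- data.frame(
    block_id = seq_along(starts),
    msa_start = msa_of_backbone(starts),
    msa_end = ifelse(ends < L, msa_of_backbone(ends + 1L),
                     L + sum(live$width)),
    stringsAsFactors = FALSE)

  segs <- list()
  for (gi in seq_along(genome_names)) {
    g <- genome_names[gi]
    car <- carried[[g]]
    car <- car[order(car$anchor), , drop = FALSE]
    cumins <- c(0L, cumsum(car$len))
    g0 <- function(p) (p - 1L) + cumins[findInterval(p - 0.5, car$anchor) + 1L]
    for (b in seq_along(starts)) {
      b0 <- starts[b]; b1 <- ends[b]
      in_blk <- car[car$anchor >= b0 & car$anchor <= b1, , drop = FALSE]
      cur <- b0
      for (j in seq_len(nrow(in_blk))) {
        a <- in_blk$anchor[j]
        segs[[length(segs) + 1L]] <- data.frame(
          block_id = b, genome = g, msa_start = msa_of_backbone(cur),
          length = a - cur + 1L, genome_start = g0(cur),
          stringsAsFactors = FALSE)
        segs[[length(segs) + 1L]] <- data.frame(
          block_id = b, genome = g, msa_start = msa_of_backbone(a) + 1L,
          length = in_blk$len[j], genome_start = g0(a) + 1L,
          stringsAsFactors = FALSE)
        cur <- a + 1L
      }
      segs[[length(segs) + 1L]] <- data.frame(
        block_id = b, genome = g, msa_start = msa_of_backbone(cur),
        length = b1 - cur + 1L, genome_start = g0(cur),
        stringsAsFactors = FALSE)
    }
  }
  segments <- do.call(rbind, segs)
  segments <- segments[segments$length > 0L, ]
  blk <- msa_blocks(blocks, segments, genome_names)
  list(blocks = blk, msa_of_backbone = msa_of_backbone,
       event_width = stats::setNames(live$width, live$event_id))
}

#' Extract planted LTR sequences for one genome
#'
#' Returns the sequences of all LTR annotations (solo LTRs and both LTRs of
#' full-length elements) of a simulated genome, named by `ltr_id`.
#'
#' @param sim A `ty_sim` object.
#' @param genome Genome name.
#' @return Named character vector of LTR sequences.
#' @export
ltr_sequences <- function(sim, genome) {
  stopifnot(inherits(sim, "ty_sim"))
  la <- sim$ltr_annotations[sim$ltr_annotations$genome == genome, ]
  abort_if(nrow(la) == 0L, "no LTR annotations for genome %s", genome)
  gs <- sim$genomes[[genome]]
  stats::setNames(substring(gs, la$start + 1L, la$end), la$ltr_id)
}

#' Extract full element sequences
#'
#' @param sim A `ty_sim` object.
#' @param element_ids Element ids; default all.
#' @return Named character vector of element sequences.
#' @export
element_sequences <- function(sim, element_ids = NULL) {
  stopifnot(inherits(sim, "ty_sim"))
  a <- sim$annotations
  if (!is.null(element_ids)) a <- a[a$element_id %in% element_ids, ]
  out <- character(nrow(a))
  for (i in seq_len(nrow(a))) {
    out[i] <- substring(sim$genomes[[a$genome[i]]], a$start[i] + 1L, a$end[i])
  }
  stats::setNames(out, a$element_id)
}

#' Pairwise hit table from an internal banded identity scorer
#'
#' Scores every ordered pair of sequences by ungapped comparison over the
#' leading `min(length)` bases: percent identity is matches over the
#' compared length, the pseudo bit score is `2 * matches`, and the e-value
#' is a monotone transform of the bit score. This stands in for an external
#' all-against-all aligner on simulated data, where homologous copies
#' differ by substitutions only; analyses of real data accept an externally
#' produced tabular hit file via [read_hit_table()].
#'
#' @param seqs Named character vector of sequences.
#' @param min_identity Drop hits below this percent identity (default 50,
#'   removing cross-family noise as a score cutoff would in practice).
#' @return A hit table data.frame with columns `query`, `subject`,
#'   `pct_identity`, `aln_length`, `bit_score`, `e_value`. Self-hits are
#'   never emitted.
#' @export
score_hits <- function(seqs, min_identity = 50) {
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  n <- length(seqs)
  raws <- lapply(seqs, charToRaw)
  lens <- lengths(raws)
  rows <- vector("list", n * (n - 1L))
  k <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      m <- min(lens[i], lens[j])
      matches <- sum(raws[[i]][seq_len(m)] == raws[[j]][seq_len(m)])
      pid <- 100 * matches / m
      if (pid < min_identity) next
      k <- k + 1L
      rows[[k]] <- data.frame(
        query = names(seqs)[i], subject = names(seqs)[j],
        pct_identity = pid, aln_length = m, bit_score = 2 * matches,
        e_value = 2^(-min(2 * matches, 1000)) * m,
        stringsAsFactors = FALSE)
    }
  }
  if (k == 0L) {
    return(data.frame(query = character(0), subject = character(0),
                      pct_identity = numeric(0), aln_length = integer(0),
                      bit_score = numeric(0), e_value = numeric(0)))
  }
  do.call(rbind, rows[seq_len(k)])
}
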