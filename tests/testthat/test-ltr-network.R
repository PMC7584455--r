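hit_row <- function(q, s, pid = 95, len = 300, bit = NULL, e = NULL) {
  data.frame(query = q, subject = s, pct_identity = pid, aln_length = len,
             bit_score = if (is.null(bit)) 2 * len * pid / 100 else bit,
             e_value = if (is.null(e)) 1e-50 else e,
             stringsAsFactors = FALSE)
}

test_that("edge retention keeps hits at or above the per-query 10th percentile", {
  hits <- do.call(rbind, lapply(1:10, function(i) {
    hit_row("L0", paste0("S", i), bit = 10 * i)
  }))
  # linear-interpolation 10th percentile of 10..100 is 19
  expect_equal(percentile(hits$bit_score, 0.10), 19)
  g <- build_similarity_network(hits)
  expect_equal(igraph::ecount(g), 9)
  expect_false(igraph::are_adjacent(g, "L0", "S1"))
})

test_that("a single hit is always retained and zero-hit LTRs stay isolated", {
  g <- build_similarity_network(hit_row("A", "B", bit = 5),
                                nodes = c("A", "B", "lonely"))
  expect_equal(igraph::ecount(g), 1)
  expect_true("lonely" %in% igraph::V(g)$name)
  expect_equal(igraph::degree(g)[["lonely"]], 0)
})

test_that("families without cross-hits form separate components", {
  hits <- rbind(hit_row("a1", "a2"), hit_row("a2", "a1"),
                hit_row("b1", "b2"), hit_row("b2", "b1"))
  g <- build_similarity_network(hits)
  expect_equal(igraph::components(g)$no, 2)
})

test_that("re-applying the original retention thresholds changes nothing", {
  set.seed(42)
  qs <- paste0("L", 1:8)
  hits <- do.call(rbind, lapply(qs, function(q) {
    do.call(rbind, lapply(setdiff(qs, q), function(s) {
      hit_row(q, s, bit = round(runif(1, 10, 100)))
    }))
  }))
  thr <- tapply(hits$bit_score, hits$query, percentile, p = 0.10)
  kept <- hits[hits$bit_score >= thr[hits$query], ]
  kept2 <- kept[kept$bit_score >= thr[kept$query], ]
  expect_identical(kept, kept2)
  # and every retained edge meets at least one endpoint's threshold
  g <- build_similarity_network(hits)
  el <- igraph::as_data_frame(g)
  ok <- mapply(function(a, b, w) {
    w >= min(thr[a], thr[b], na.rm = TRUE)
  }, el$from, el$to, el$weight)
  expect_true(all(ok))
})

test_that("components spanning several labels yield sorted composite families", {
  hits <- rbind(hit_row("x1", "x2"), hit_row("x2", "x3"),
                hit_row("y1", "y2"))
  g <- build_similarity_network(hits)
  fams <- c(x1 = "Ty2", x2 = "Ty1", x3 = "Ty1", y1 = "Ty4", y2 = "Ty4")
  m <- merge_family_labels(g, fams)
  expect_equal(unname(m$merge_map["Ty1"]), "Ty1/Ty2")
  expect_equal(unname(m$merge_map["Ty2"]), "Ty1/Ty2")
  expect_equal(unname(m$merge_map["Ty4"]), "Ty4")
  expect_true("Ty1/Ty2" %in% m$report$labels)
  expect_error(merge_family_labels(g, fams[-1]), "unlabeled")
  empty <- merge_family_labels(
    igraph::make_empty_graph(directed = FALSE), character(0))
  expect_equal(length(empty$merge_map), 0)
})

test_that("divergence uses the best non-self hit and excludes partner LTRs", {
  ann <- data.frame(
    element_id = c("e1", "e2"), genome = "g", contig = "c",
    start = c(0L, 1000L), end = c(300L, 6000L), strand = "+",
    family = "Ty1",
    element_type = c("solo_LTR", "full_length"),
    ltr_ids = c("e1:L5", "e2:L5,e2:L3"), stringsAsFactors = FALSE)
  hits <- rbind(
    hit_row("e1:L5", "e2:L5", pid = 100),
    hit_row("e2:L5", "e2:L3", pid = 100),   # intra-element, must be excluded
    hit_row("e2:L5", "e1:L5", pid = 95))
  d <- divergence_since_transposition(ann, hits)
  expect_equal(d$divergence[d$element_id == "e1"], 0)
  expect_equal(d$divergence[d$element_id == "e2"], 5)
  expect_equal(d$closest_relative[d$element_id == "e2"], "e1:L5")
})

test_that("divergence is defined by the record's own best hit, not reciprocity", {
  ann <- data.frame(
    element_id = c("a", "b", "c"), genome = "g", contig = "c",
    start = c(0L, 400L, 800L), end = c(300L, 700L, 1100L), strand = "+",
    family = "Ty1", element_type = "solo_LTR",
    ltr_ids = c("a:L5", "b:L5", "c:L5"), stringsAsFactors = FALSE)
  hits <- rbind(hit_row("a:L5", "b:L5", pid = 97),
                hit_row("b:L5", "c:L5", pid = 99),
                hit_row("c:L5", "b:L5", pid = 99))
  d <- divergence_since_transposition(ann, hits)
  expect_equal(d$divergence[d$element_id == "a"], 3)
  expect_true(d$no_hit[d$element_id == "a"] == FALSE)
})

test_that("zero-substitution simulation gives all-zero divergence and one component per family", {
  cfg <- small_config(lineage_tree = ape::read.tree(
    text = "((a:0,b:0):0,c:0);"), ancestral_age = 0,
    ancestral_solo_prob = 0)
  sim <- simulate_te_genomes(cfg, block_size = 5e4)
  seqs <- ltr_sequences(sim, "a")
  hits <- score_hits(seqs)
  ann <- sim$annotations[sim$annotations$genome == "a", ]
  d <- divergence_since_transposition(ann, hits)
  expect_true(all(d$divergence[!d$no_hit] == 0))
  g <- build_similarity_network(hits)
  fam_of <- stats::setNames(
    ann$family[match(sim$ltr_annotations$element_id[
      sim$ltr_annotations$genome == "a"], ann$element_id)],
    sim$ltr_annotations$ltr_id[sim$ltr_annotations$genome == "a"])
  comp <- igraph::components(g)$membership
  for (fam in unique(fam_of)) {
    expect_equal(length(unique(comp[names(fam_of)[fam_of == fam]])), 1)
  }
})

test_that("divergence-class contrasts match hypergeometric enumeration", {
  # identical ratios -> p = 1
  d <- c(rep(0.5, 5), rep(2, 5), rep(0.5, 5), rep(2, 5))
  l <- rep(c("A", "B"), each = 10)
  res <- divergence_class_tests(d, l)
  expect_equal(res$p, 1)
  # [[9,1],[1,9]] against the enumeration oracle
  d2 <- c(rep(0.5, 9), 2, 0.5, rep(2, 9))
  res2 <- divergence_class_tests(d2, l)
  oracle <- fisher_2x2_enum(matrix(c(9, 1, 1, 9), 2, byrow = TRUE))
  expect_equal(res2$p, oracle, tolerance = 1e-9)
  expect_equal(res2$p, stats::fisher.test(
    matrix(c(9, 1, 1, 9), 2))$p.value, tolerance = 1e-12)
  # three identical lineages -> all corrected p = 1
  d3 <- rep(c(rep(0.5, 4), rep(2, 6)), 3)
  l3 <- rep(c("A", "B", "C"), each = 10)
  res3 <- divergence_class_tests(d3, l3)
  expect_true(all(res3$p_adj == 1))
})
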