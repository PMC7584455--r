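# hand-constructed block sets ------------------------------------------------

# one block, three genomes, optional per-genome gaps
toy_blockset <- function() {
  blocks <- data.frame(block_id = 1L, msa_start = 0, msa_end = 30000)
  segments <- rbind(
    data.frame(block_id = 1L, genome = "gA", msa_start = 0,
               length = 30000, genome_start = 0),
    data.frame(block_id = 1L, genome = "gB", msa_start = 0,
               length = 30000, genome_start = 500),
    # gC is absent from the first 5 kb of columns: the first 10 kb window
    # has 50% informative sites
    data.frame(block_id = 1L, genome = "gC", msa_start = 5000,
               length = 25000, genome_start = 0))
  msa_blocks(blocks, segments, c("gA", "gB", "gC"))
}

test_that("blocks missing a genome are dropped", {
  bs <- toy_blockset()
  bs$segments <- bs$segments[bs$segments$genome != "gC", ]
  out <- filter_msa_blocks(bs)
  expect_equal(nrow(out$blocks), 0)
})

test_that("end windows failing the informative fraction are trimmed, the rest kept", {
  out <- filter_msa_blocks(toy_blockset())
  expect_equal(out$blocks$msa_start, 10000)
  expect_equal(out$blocks$msa_end, 30000)
  # a fully informative window is retained whole
  full <- toy_blockset()
  full$segments$msa_start[full$segments$genome == "gC"] <- 0
  full$segments$length[full$segments$genome == "gC"] <- 30000
  out2 <- filter_msa_blocks(full)
  expect_equal(out2$blocks$msa_start, 0)
  expect_equal(out2$blocks$msa_end, 30000)
})

test_that("a block shorter than one window is evaluated as a single window", {
  blocks <- data.frame(block_id = 1L, msa_start = 0, msa_end = 4000)
  seg <- do.call(rbind, lapply(c("gA", "gB"), function(g) {
    data.frame(block_id = 1L, genome = g, msa_start = 0, length = 4000,
               genome_start = 0)
  }))
  bs <- msa_blocks(blocks, seg, c("gA", "gB"))
  out <- filter_msa_blocks(bs)
  expect_equal(nrow(out$blocks), 1)
})

test_that("projection maps genome coordinates through gap structure", {
  bs <- toy_blockset()
  ann <- data.frame(element_id = c("x", "y"), genome = c("gA", "gC"),
                    start = c(100L, 1000L), end = c(400L, 1300L),
                    strand = "+", family = "Ty1",
                    stringsAsFactors = FALSE)
  pr <- project_annotations(ann, bs)
  expect_equal(pr$msa_start[1], 100)  # gapless: offset preserved
  expect_equal(pr$msa_end[1], 400)
  # gC starts at column 5000 with genome_start 0: shifted by the gap
  expect_equal(pr$msa_start[2], 6000)
  # annotation in a dropped block is unprojectable
  bs2 <- filter_msa_blocks(toy_blockset())
  ann3 <- data.frame(element_id = "z", genome = "gA", start = 100L,
                     end = 200L, strand = "+", family = "Ty1")
  pr3 <- project_annotations(ann3, bs2)
  expect_false(pr3$projectable)
})

test_that("a 10-column gap before the annotation shifts its projection by 10", {
  blocks <- data.frame(block_id = 1L, msa_start = 0, msa_end = 1010)
  segments <- rbind(
    data.frame(block_id = 1L, genome = "gA", msa_start = 0, length = 1010,
               genome_start = 0),
    # gB misses columns 100..109 (10-column gap)
    data.frame(block_id = 1L, genome = "gB", msa_start = 0, length = 100,
               genome_start = 0),
    data.frame(block_id = 1L, genome = "gB", msa_start = 110, length = 900,
               genome_start = 100))
  bs <- msa_blocks(blocks, segments, c("gA", "gB"))
  ann <- data.frame(element_id = "e", genome = "gB", start = 200L,
                    end = 250L, strand = "+", family = "Ty1")
  pr <- project_annotations(ann, bs)
  expect_equal(pr$msa_start, 210)
  expect_equal(pr$msa_end, 260)
})

test_that("1-D chaining clusters match the DBSCAN min_samples=1 behaviour", {
  ids <- chain_cluster_1d(c(100, 550, 2000), eps = 500)
  expect_equal(ids[1], ids[2])
  expect_true(ids[3] != ids[1])
  expect_equal(chain_cluster_1d(42), 1L)
  chain <- chain_cluster_1d(seq(0, 4000, by = 400), eps = 500)
  expect_equal(length(unique(chain)), 1)
  expect_equal(chain_cluster_1d(numeric(0)), integer(0))
})

test_that("raising eps never decreases cluster sizes", {
  set.seed(31)
  pos <- sort(runif(200, 0, 1e5))
  for (i in 1:5) {
    e1 <- runif(1, 100, 1000); e2 <- e1 + runif(1, 100, 1000)
    c1 <- chain_cluster_1d(pos, e1); c2 <- chain_cluster_1d(pos, e2)
    expect_true(length(unique(c2)) <= length(unique(c1)))
    # coarser clustering refines into the finer one
    expect_true(all(tapply(c2, c1, function(x) length(unique(x))) == 1))
  }
})

cluster_fixture <- function() {
  data.frame(
    element_id = c("a1", "b1", "c1", "c2", "d1"),
    genome = c("G1", "G2", "G3", "G3", "G1"),
    strand = "+", family = "Ty1",
    element_type = "full_length",
    msa_start = c(100, 110, 105, 130, 5000),
    msa_end = c(400, 410, 405, 430, 5300),
    cluster = c(1L, 1L, 1L, 1L, 2L), stringsAsFactors = FALSE)
}

perfect_hits <- function(ids, len = 300) {
  do.call(rbind, lapply(ids, function(q) {
    do.call(rbind, lapply(setdiff(ids, q), function(s) {
      data.frame(query = q, subject = s, pct_identity = 99,
                 aln_length = len, bit_score = 2 * len * 0.99,
                 e_value = 1e-60, stringsAsFactors = FALSE)
    }))
  }))
}

test_that("confident clusters require one member per genome and uniform strand/family", {
  cl <- cluster_fixture()
  hits <- perfect_hits(cl$element_id)
  lens <- stats::setNames(rep(300, 5), cl$element_id)
  out <- select_confident_orthogroups(cl, hits, lens)
  # cluster 1 has two G3 members -> excluded; cluster 2 is a singleton
  expect_equal(nrow(out$members), 0)
  cl2 <- cl[cl$element_id != "c2", ]
  out2 <- select_confident_orthogroups(cl2, hits, lens)
  expect_equal(sort(out2$members$element_id), c("a1", "b1", "c1"))
  expect_equal(sort(unique(out2$diffs)), c(5, 10))
  cl3 <- cl2; cl3$strand[2] <- "-"
  expect_equal(nrow(select_confident_orthogroups(cl3, hits,
                                                 lens)$members), 0)
  # hit length outside [90%, 110%] of either sequence disqualifies
  lens_bad <- lens; lens_bad["a1"] <- 600
  out4 <- select_confident_orthogroups(cl2, hits, lens_bad)
  expect_false("a1" %in% out4$members$element_id)
})

test_that("coordinate threshold is the linear-interpolation percentile of the diffs", {
  expect_equal(derive_coordinate_threshold(rep(0, 10)), 0)
  expect_equal(derive_coordinate_threshold(1:20), 19.05)
  expect_error(derive_coordinate_threshold(numeric(0)), "fallback")
})

test_that("orthogroup calling applies the best-hit and coordinate criteria", {
  cl <- cluster_fixture()[c(1, 2), ]  # a1 (100,400), b1 (110,410)
  hits <- perfect_hits(cl$element_id)
  ogs <- call_orthogroups(cl, hits, threshold = 17)
  expect_equal(length(unique(ogs$orthogroup_id)), 1)
  # start and end differences both above threshold -> separate groups
  cl2 <- cl; cl2$msa_start[2] <- 130; cl2$msa_end[2] <- 425
  ogs2 <- call_orthogroups(cl2, hits, threshold = 17)
  expect_equal(length(unique(ogs2$orthogroup_id)), 2)
  # one coordinate within threshold suffices
  cl3 <- cl; cl3$msa_start[2] <- 130; cl3$msa_end[2] <- 410
  ogs3 <- call_orthogroups(cl3, hits, threshold = 17)
  expect_equal(length(unique(ogs3$orthogroup_id)), 1)
  expect_error(call_orthogroups(cl, hits, threshold = -1), ">= 0")
})

test_that("groups with duplicated genomes are discarded, family mixing prevented", {
  cl <- cluster_fixture()[1:4, ]
  hits <- perfect_hits(cl$element_id)
  ogs <- call_orthogroups(cl, hits, threshold = 50)
  grp <- split(ogs, ogs$orthogroup_id)
  big <- grp[[which.max(vapply(grp, nrow, 0L))]]
  expect_true(all(big$discarded))
  # different families never join even with perfect hits and coordinates
  cl2 <- cluster_fixture()[1:2, ]
  cl2$family <- c("Ty1", "Ty3p")
  ogs2 <- call_orthogroups(cl2, perfect_hits(cl2$element_id), 17)
  expect_equal(length(unique(ogs2$orthogroup_id)), 2)
})

test_that("conservation classes follow genome counts and enrichment matches the oracle", {
  og <- data.frame(
    orthogroup_id = c("OG1", "OG1", "OG1", "OG2", "OG3", "OG3"),
    element_id = paste0("e", 1:6),
    genome = c("G1", "G2", "G3", "G1", "G1", "G2"),
    family = "Ty1",
    element_type = c("solo_LTR", "solo_LTR", "solo_LTR", "full_length",
                     "solo_LTR", "solo_LTR"),
    discarded = FALSE, stringsAsFactors = FALSE)
  out <- classify_conservation(og, n_genomes = 3)
  cls <- stats::setNames(out$classes$class, out$classes$orthogroup_id)
  expect_equal(unname(cls[c("OG1", "OG2", "OG3")]),
               c("conserved", "private", "intermediate"))
  # constructed enrichment table checked against the enumeration oracle
  tab <- matrix(c(8, 2, 1, 9), nrow = 2)
  expect_equal(stats::fisher.test(tab)$p.value, fisher_2x2_enum(tab),
               tolerance = 1e-9)
})

test_that("noise-free simulation recovers the planted orthogroup partition exactly", {
  sim <- small_sim()
  blocks <- filter_msa_blocks(sim$alignment)
  proj <- project_annotations(sim$annotations, blocks)
  clustered <- cluster_positions_1d(proj)
  el <- element_sequences(sim)
  hits <- cross_genome_hits(clustered, el)
  lens <- stats::setNames(nchar(el), names(el))
  conf <- select_confident_orthogroups(clustered, hits, lens)
  thr <- derive_coordinate_threshold(conf$diffs)
  expect_equal(thr, 0)
  ogs <- call_orthogroups(clustered, hits, thr)
  kept <- sim$truth[sim$truth$element_id %in% ogs$element_id, ]
  expect_identical(
    partition_key(ogs$element_id, ogs$orthogroup_id),
    partition_key(kept$element_id, kept$true_orthogroup))
  # most members survive projection (short test blocks expose more
  # elements to end-window trimming than the megabase default)
  expect_gte(nrow(ogs), 0.75 * nrow(sim$truth))
  mix <- vapply(split(ogs$family, ogs$orthogroup_id),
                function(f) length(unique(f)), 0L)
  expect_true(all(mix == 1))
})

test_that("MAF round trip preserves gap structure and projections", {
  sim <- small_sim()
  tmp <- tempfile(fileext = ".maf")
  write_maf(sim$alignment, sim$genomes, tmp)
  back <- read_maf(tmp)
  expect_equal(nrow(back$blocks), nrow(sim$alignment$blocks))
  expect_setequal(back$genomes, names(sim$genomes))
  # within-block projections agree up to the block coordinate offset
  ann <- sim$annotations[1:5, ]
  p1 <- project_annotations(ann, sim$alignment)
  p2 <- project_annotations(ann, back)
  off1 <- sim$alignment$blocks$msa_start[match(p1$block_id,
                                               sim$alignment$blocks$block_id)]
  off2 <- back$blocks$msa_start[match(p2$block_id, back$blocks$block_id)]
  expect_equal(p1$msa_start - off1, p2$msa_start - off2)
})
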