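test_that("config validation enforces the documented invariants", {
  expect_error(sim_config(lineage_tree = ape::read.tree(text = "(a:1);")),
               "2 tips")
  bad_fam <- small_families()
  bad_fam$ltr_length[1] <- 40L
  expect_error(small_config(families = bad_fam), "ltr_length")
  expect_error(small_config(hybrid_events = list(
    list(child = "h", parent_a = "g1", parent_b = "g2", proportion = 1.2))),
    "proportion")
  expect_error(small_config(coverage_mean = 0), "coverage_mean")
})

test_that("simulation is byte-identical under a fixed seed", {
  a <- simulate_te_genomes(small_config(), block_size = 5e4)
  b <- simulate_te_genomes(small_config(), block_size = 5e4)
  expect_identical(a$genomes, b$genomes)
  expect_identical(a$annotations, b$annotations)
  expect_identical(a$truth, b$truth)
})

test_that("no-mutation limit yields identical genomes and shared orthogroups", {
  tr <- ape::read.tree(text = "((a:0,b:0):0,c:0);")
  cfg <- small_config(lineage_tree = tr, ancestral_age = 0,
                      ancestral_solo_prob = 0,
                      families = transform(small_families(),
                                           transposition_rate = 0,
                                           solo_rate = 0))
  sim <- simulate_te_genomes(cfg, block_size = 5e4)
  expect_identical(sim$genomes[["a"]], sim$genomes[["b"]])
  expect_identical(sim$genomes[["a"]], sim$genomes[["c"]])
  # every ancestral orthogroup has one member per genome
  tab <- table(sim$truth$true_orthogroup)
  expect_true(all(tab == 3))
  per_genome <- split(sim$annotations[, c("start", "end", "family")],
                      sim$annotations$genome)
  expect_identical(per_genome[["a"]], per_genome[["b"]],
                   ignore_attr = TRUE)
})

test_that("certain solo-LTR formation leaves no full-length elements", {
  fam <- small_families()
  fam$solo_rate <- 1e4
  cfg <- small_config(families = fam, ancestral_solo_prob = 1)
  sim <- simulate_te_genomes(cfg, block_size = 5e4)
  expect_false(any(sim$truth$is_full_length))
  expect_true(all(sim$annotations$element_type == "solo_LTR"))
})

test_that("insertions on a terminal branch are private to that genome", {
  sim <- small_sim()
  carriers <- split(sim$truth$genome, sim$truth$true_orthogroup)
  # at least one private orthogroup exists, and privates have one carrier
  sizes <- lengths(carriers)
  expect_true(any(sizes == 1))
  # conservation: annotation and truth agree element-by-element
  expect_setequal(sim$annotations$element_id, sim$truth$element_id)
})

test_that("planted homology projects to zero coordinate difference", {
  sim <- small_sim()
  proj <- project_annotations(sim$annotations, sim$alignment)
  m <- merge(proj, sim$truth[, c("element_id", "true_orthogroup")],
             by = "element_id")
  spread <- tapply(m$msa_start, m$true_orthogroup,
                   function(x) diff(range(x)))
  expect_true(all(spread == 0))
})

test_that("full-length elements carry two LTRs and solo LTRs one", {
  sim <- small_sim()
  n_ltr <- lengths(strsplit(sim$annotations$ltr_ids, ","))
  expect_identical(n_ltr == 2L,
                   sim$annotations$element_type == "full_length")
})

test_that("depth tables are linear in copy number with exact zero-dispersion limit", {
  cn <- matrix(c(0L, 1L, 2L, 4L, 8L, 3L), nrow = 3,
               dimnames = list(c("s1", "s2", "s3"), c("Ty1", "Ty3p")))
  cfg <- small_config(coverage_dispersion = 0)
  dep <- simulate_depth_tables(cn, cfg)
  fam <- dep[!is.na(dep$family), ]
  expect_equal(fam$median_depth[fam$true_cn > 0],
               cfg$coverage_mean * fam$true_cn[fam$true_cn > 0])
  nrd <- normalized_read_depth(fam$median_depth, fam$genome_wide_depth)
  on <- fam$true_cn > 0
  expect_equal(nrd[on], log2(fam$true_cn[on]), tolerance = 1e-6)
  expect_true(all(fam$median_depth[fam$true_cn == 0] < 1))
})

test_that("mean depth regresses on copy number with slope near coverage", {
  set.seed(11)
  cn <- matrix(sample(0:8, 100, replace = TRUE), ncol = 1,
               dimnames = list(sprintf("s%03d", 1:100), "Ty1"))
  dep <- simulate_depth_tables(cn, small_config(seed = 3L))
  fam <- dep[!is.na(dep$family), ]
  slope <- coef(lm(median_depth ~ true_cn, data = fam))["true_cn"]
  expect_equal(unname(slope), 30, tolerance = 0.05)
})

test_that("population structure drives SNP PCA separation as configured", {
  cfg0 <- small_config(fst = 0, n_snps = 300L,
                       n_strains_per_lineage = 12L)
  pop0 <- simulate_population(cfg0)
  p0 <- genotype_pca(pop0$genotypes)
  expect_lt(abs(silhouette_1d(p0$x[, 1], pop0$lineages)), 0.15)
  cfg1 <- small_config(fst = 0.7, n_snps = 300L,
                       n_strains_per_lineage = 12L)
  pop1 <- simulate_population(cfg1)
  p1 <- genotype_pca(pop1$genotypes)
  expect_gt(silhouette_1d(p1$x[, 1], pop1$lineages), 0.5)
  expect_error(simulate_population(small_config(n_snps = 5L)), "n_snps")
})

test_that("uncoupled climate is independent of lineage structure", {
  cfg <- small_config(climate_coupling = FALSE, n_snps = 50L,
                      n_strains_per_lineage = 20L)
  pop <- simulate_population(cfg)
  clim <- aggregate_climate(pop$climate)
  e1 <- stats::prcomp(clim)$x[, 1]
  fit <- stats::anova(stats::lm(e1 ~ factor(pop$lineages[rownames(clim)])))
  expect_gt(fit$`Pr(>F)`[1], 0.01)
  cfgc <- small_config(climate_coupling = TRUE, n_snps = 50L,
                       n_strains_per_lineage = 20L)
  popc <- simulate_population(cfgc)
  e1c <- stats::prcomp(aggregate_climate(popc$climate))$x[, 1]
  fitc <- stats::anova(stats::lm(e1c ~ factor(popc$lineages)))
  expect_lt(fitc$`Pr(>F)`[1], 1e-6)
})

test_that("insertion-call evidence matches truth in the noise-free limit", {
  cfg <- small_config(call_jitter_sd = 0, call_fp_rate = 0,
                      quality_flag_dist = 1)
  sim <- simulate_te_genomes(cfg, block_size = 5e4)
  calls <- simulate_insertion_calls(sim, cfg)
  expect_true(all(!calls$is_fp))
  loci <- decluster_calls(calls)
  expect_equal(sum(loci$accepted), nrow(sim$truth))
  expect_true(all(loci$position %in% sim$events$msa_start))
})

test_that("flag-8 probability zero leaves every cluster rejected", {
  cfg <- small_config(quality_flag_dist = 0)
  sim <- small_sim()
  calls <- simulate_insertion_calls(sim, cfg)
  loci <- decluster_calls(calls)
  expect_false(any(loci$accepted))
})

test_that("hybrid genomes are mosaics of their parents", {
  cfg <- small_config(hybrid_events = list(
    list(child = "h1", parent_a = "g1", parent_b = "g3",
         proportion = 0.5)))
  sim <- simulate_te_genomes(cfg, block_size = 5e4)
  expect_true("h1" %in% names(sim$genomes))
  # every hybrid element exists in one of the parents at the same anchor
  h_ogs <- sim$truth$true_orthogroup[sim$truth$genome == "h1"]
  parent_ogs <- sim$truth$true_orthogroup[sim$truth$genome %in%
                                            c("g1", "g3")]
  expect_true(all(h_ogs %in% parent_ogs))
})

test_that("growth plates encode lineage-specific stress effects", {
  tree <- small_tree()
  sf <- c(g1 = 1, g2 = 1, g3 = 1)
  cfg <- small_config(growth_stress_factors = sf, growth_noise_sd = 0)
  plates <- simulate_growth_plates(cfg, n_strains_per_lineage = 2L,
                                   hours = 20, rate_jitter_sd = 0)
  da <- difference_auc(normalize_series(plates))
  expect_equal(max(abs(da$auc$auc)), 0, tolerance = 1e-8)
  sd_rep <- tapply(da$auc$auc, da$auc$strain, sd)
  expect_true(all(sd_rep == 0))
  sf2 <- c(g1 = 1, g2 = 1, g3 = 0.2)
  cfg2 <- small_config(growth_stress_factors = sf2, growth_noise_sd = 0)
  da2 <- difference_auc(normalize_series(
    simulate_growth_plates(cfg2, n_strains_per_lineage = 2L, hours = 20,
                           rate_jitter_sd = 0)))
  mean_auc <- tapply(da2$auc$auc, da2$auc$lineage, mean)
  expect_equal(names(which.min(mean_auc)), "g3")
  expect_true(all(mean_auc["g3"] < mean_auc[c("g1", "g2")]))
})
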