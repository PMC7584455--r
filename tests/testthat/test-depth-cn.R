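test_that("NRD arithmetic and sentinels behave as documented", {
  expect_equal(normalized_read_depth(40, 20), 1.0)
  expect_equal(normalized_read_depth(20, 20), 0.0)
  expect_identical(normalized_read_depth(0, 20), -Inf)
  expect_error(normalized_read_depth(10, 0), "> 0")
  # scale equivariance: multiplying all depths by c leaves NRD unchanged
  md <- c(10, 40, 80); gw <- 20
  expect_equal(normalized_read_depth(md * 7, gw * 7),
               normalized_read_depth(md, gw))
})

test_that("flooring replaces low values, is idempotent and order-preserving", {
  v <- c(-3, -1, 0)
  f <- apply_floor(v, -1.25)
  expect_equal(f, c(-1.25, -1, 0))
  expect_equal(apply_floor(f, -1.25), f)
  expect_equal(apply_floor(c(0.1, 0.5), -1.25), c(0.1, 0.5))
  expect_identical(apply_floor(-Inf, -1.25), -1.25)
  set.seed(1)
  x <- rnorm(50)
  fx <- apply_floor(x, -0.5)
  above <- x > -0.5
  expect_true(all(order(x[above]) == order(fx[above])))
})

test_that("the floor is the control-gene 10th percentile and flags absent families", {
  set.seed(2)
  ctrl <- rnorm(50, 0, 0.02)
  fl <- derive_floor(ctrl)
  expect_equal(fl, percentile(ctrl, 0.10))
  expect_lt(abs(fl), 0.1)
  expect_true(family_absent(rep(-2, 10), ctrl))
  expect_false(family_absent(rep(0.5, 10), ctrl))
  expect_error(derive_floor(numeric(0)), "no control")
  expect_error(derive_floor(rnorm(5)), ">= 10")
})

test_that("lineage tests detect a shifted lineage and flag the right pairs", {
  set.seed(3)
  lin <- rep(c("A", "B", "C"), each = 15)
  cn <- cbind(Ty1 = rnorm(45) + ifelse(lin == "C", 3, 0),
              Ty3p = rnorm(45))
  res <- lineage_cn_tests(cn, lin)
  expect_lt(res$kruskal$p[res$kruskal$family == "Ty1"], 1e-6)
  expect_gt(res$kruskal$p[res$kruskal$family == "Ty3p"], 0.01)
  ph <- res$posthoc[res$posthoc$family == "Ty1", ]
  sig <- ph[ph$p_adj < 0.01, ]
  expect_setequal(
    apply(sig[, c("group_a", "group_b")], 1, paste, collapse = ""),
    c("AC", "BC"))
  expect_warning(lineage_cn_tests(cbind(Ty1 = rep(1, 45)), lin),
                 "constant")
})

test_that("the Conover statistic agrees with its rank-formula computed directly", {
  set.seed(4)
  x <- rnorm(30); g <- rep(c("a", "b", "c"), each = 10)
  ct <- conover_test(x, g)
  r <- rank(x); N <- 30; k <- 3
  rs <- tapply(r, g, sum); nn <- tapply(r, g, length)
  s2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
  H <- (sum(rs^2 / nn) - N * (N + 1)^2 / 4) / s2
  t_ab <- (rs["a"] / 10 - rs["b"] / 10) /
    sqrt(s2 * (N - 1 - H) / (N - k) * (2 / 10))
  expect_equal(ct$statistic[ct$group_a == "a" & ct$group_b == "b"],
               unname(t_ab), tolerance = 1e-12)
})

test_that("Brown-Forsythe matches the median-centered Levene oracle", {
  set.seed(5)
  x <- c(rnorm(20, 0, 1), rnorm(20, 0, 3))
  g <- rep(c("a", "b"), each = 20)
  bf <- brown_forsythe(x, g)
  oracle <- car::leveneTest(x, factor(g), center = median)
  expect_equal(bf$p, oracle$`Pr(>F)`[1], tolerance = 1e-10)
  expect_equal(bf$statistic, oracle$`F value`[1], tolerance = 1e-10)
  expect_lt(bf$p, 0.01)
})

test_that("MA copy-number tests handle shifts, equal variance, and degeneracy", {
  set.seed(6)
  base <- rnorm(30)
  rec <- rbind(
    data.frame(cross = "BB1", family = "Ty1", line = 1:30,
               cn_tini = base, cn_tend = base + 0.5),
    data.frame(cross = "BB1", family = "Ty3p", line = 1:30,
               cn_tini = base, cn_tend = base))
  res <- ma_delta_cn_tests(rec)
  expect_lt(res$wilcoxon_p[res$family == "Ty1"], 1e-5)
  expect_true(res$all_zero[res$family == "Ty3p"])
  expect_equal(res$wilcoxon_p[res$family == "Ty3p"], 1)
  expect_true(all(res$wilcoxon_p_adj >= res$wilcoxon_p))
  expect_error(ma_delta_cn_tests(rec[1:4, ]), ">= 6")
})

test_that("parental divergence equals the branch-length path between tips", {
  tree <- ape::read.tree(text = "((P1:0.1,P2:0.2):0.3,P3:0.5);")
  expect_equal(parental_divergence(tree, "P1", "P2"), 0.3)
  expect_equal(parental_divergence(tree, "P1", "P3"), 0.9)
  expect_error(parental_divergence(tree, "P1", "P9"), "absent")
  # oracle equivalence on random trees via root-path depths
  set.seed(7)
  for (i in 1:5) {
    tr <- ape::rtree(12)
    depths <- ape::node.depth.edgelength(tr)
    tips <- sample(tr$tip.label, 2)
    i1 <- match(tips[1], tr$tip.label); i2 <- match(tips[2], tr$tip.label)
    mrca <- ape::getMRCA(tr, tips)
    oracle <- depths[i1] + depths[i2] - 2 * depths[mrca]
    expect_equal(parental_divergence(tr, tips[1], tips[2]), oracle,
                 tolerance = 1e-9)
  }
})

test_that("the delta-CN model recovers exact relationships and rejects collinearity", {
  cn_sum <- c(1, 2, 3, 4, 5, 6)
  div <- c(0.1, 0.5, 0.2, 0.9, 0.4, 0.7)
  fit <- fit_delta_cn_model(-0.5 * cn_sum, cn_sum, div)
  expect_equal(fit$coefficients$estimate[
    fit$coefficients$term == "cn_sum"], -0.5, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_error(fit_delta_cn_model(rnorm(6), cn_sum, cn_sum),
               "rank-deficient")
  expect_error(fit_delta_cn_model(rnorm(3), 1:3, 3:1), ">= 4")
  # pure-noise response yields small slopes
  set.seed(8)
  f2 <- fit_delta_cn_model(rnorm(40), rnorm(40), rnorm(40))
  expect_lt(f2$r_squared, 0.3)
})

test_that("syngen depth with known CN keeps NRD near log2 copy number", {
  set.seed(9)
  cn <- matrix(sample(1:8, 60, replace = TRUE), ncol = 2,
               dimnames = list(sprintf("s%02d", 1:30), c("Ty1", "Ty3p")))
  dep <- simulate_depth_tables(cn, small_config(seed = 12L))
  fam <- dep[!is.na(dep$family), ]
  nrd <- normalized_read_depth(fam$median_depth, fam$genome_wide_depth)
  expect_lt(mean(abs(nrd - log2(fam$true_cn))), 0.1)
})
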