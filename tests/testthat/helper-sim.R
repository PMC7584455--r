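# Shared small fixtures, built once per test run.

small_tree <- function() {
  ape::read.tree(text = "((g1:0.01,g2:0.01):0.01,g3:0.02);")
}

small_families <- function() {
  data.frame(name = c("Ty1", "Ty3p"),
             ltr_length = c(300L, 320L),
             internal_length = c(2000L, 2200L),
             transposition_rate = c(200, 100),
             solo_rate = c(5, 5),
             stringsAsFactors = FALSE)
}

small_config <- function(seed = 7L, ...) {
  args <- list(seed = seed, lineage_tree = small_tree(),
               genome_length = 2e5, n_ancestral_per_family = 2L,
               families = small_families())
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# one shared simulation reused across test files
.small_sim_cache <- new.env()
small_sim <- function() {
  if (is.null(.small_sim_cache$sim)) {
    .small_sim_cache$sim <- simulate_te_genomes(small_config(),
                                                block_size = 2e5)
  }
  .small_sim_cache$sim
}

# partition comparison key: sorted member strings
partition_key <- function(members, groups) {
  sort(unname(vapply(split(members, groups),
                     function(x) paste(sort(x), collapse = "|"), "")))
}

# brute-force two-sided Fisher exact p for a 2x2 table from the
# hypergeometric point probabilities, computed with choose() directly
fisher_2x2_enum <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); n <- sum(tab)
  amin <- max(0, c1 - r2); amax <- min(r1, c1)
  prob <- function(a) {
    exp(lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(n, c1))
  }
  p_obs <- prob(tab[1, 1])
  sum(vapply(amin:amax, function(a) {
    p <- prob(a)
    if (p <= p_obs * (1 + 1e-7)) p else 0
  }, 0))
}

# silhouette of a 1-D embedding against labels (test-side oracle)
silhouette_1d <- function(x, labels) {
  labels <- as.character(labels)
  n <- length(x)
  d <- abs(outer(x, x, "-"))
  s <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), 0))
    (b - a) / max(a, b)
  }, 0)
  mean(s)
}
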