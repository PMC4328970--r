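test_that("overlap contingency matches per-gene tallying", {
  genes <- paste0("g", 1:12)
  a <- setNames(rep(c("m1", "m2"), each = 6), genes)
  expect_identical(overlap_table(a, a)$contingency["m1", "m1"], 6L)
  expect_identical(sum(overlap_table(a, a)$contingency == 0), 2L)

  b <- setNames(rep("k1", 12), genes)
  ct <- overlap_table(a, b)$contingency
  expect_identical(unname(ct[, "k1"]), c(6L, 6L))

  set.seed(71)
  genes <- paste0("g", 1:100)
  a <- setNames(sample(c("m1", "m2", "m3"), 100, TRUE), genes)
  b <- setNames(sample(c("k1", "k2"), 100, TRUE), genes)
  ov <- overlap_table(a, b)
  for (i in rownames(ov$contingency)) for (j in colnames(ov$contingency))
    expect_identical(unname(ov$contingency[i, j]), sum(a == i & b == j))
  # row/column sums reproduce module sizes on the shared universe
  expect_identical(unname(rowSums(ov$contingency)),
                   as.numeric(table(a)[rownames(ov$contingency)]))
  expect_identical(unname(colSums(ov$contingency)),
                   as.numeric(table(b)[colnames(ov$contingency)]))
  expect_error(overlap_table(a, setNames("m1", "zz")), "share no genes")
})

test_that("overlap fractions reproduce the worked percentages", {
  f <- overlap_fractions(1021, 2183, 1417)
  expect_identical(f$percent_a, 47)
  expect_identical(f$percent_b, 72)
  g <- overlap_fractions(100, 261, 177)
  expect_identical(g$percent_a, 38)
  expect_identical(g$percent_b, 56)
  z <- overlap_fractions(0, 10, 20)
  expect_identical(z$percent_a, 0)
  expect_error(overlap_fractions(30, 20, 40), "exceeds")
  expect_error(overlap_fractions(5, 0, 10), "positive")
})

test_that("hypergeometric overlap p equals exhaustive enumeration", {
  expect_equal(hypergeometric_overlap_p(5, 5, 5, 10), 1 / choose(10, 5))
  expect_equal(hypergeometric_overlap_p(0, 5, 5, 10), 1)
  for (universe in c(8, 12, 17)) {
    for (size_a in seq(1, universe, by = 3))
      for (size_b in seq(1, universe, by = 4))
        for (overlap in seq(max(0, size_a + size_b - universe),
                            min(size_a, size_b)))
          expect_equal(
            hypergeometric_overlap_p(overlap, size_a, size_b, universe),
            oracle_hypergeom(overlap, size_a, size_b, universe),
            tolerance = 1e-12)
  }
  # monotone nonincreasing in overlap
  p <- vapply(0:10, hypergeometric_overlap_p, numeric(1),
              size_a = 10, size_b = 15, universe = 40)
  expect_true(all(diff(p) <= 1e-15))
  expect_error(hypergeometric_overlap_p(3, 30, 5, 20), "universe")
})

test_that("preservation calls follow the max-fraction rule", {
  pairs <- data.frame(
    module_a = c("turquoise", "blue", "green"),
    module_b = c("turquoise", "brown", "yellow"),
    overlap = c(1021, 100, 40), size_a = c(1417, 261, 100),
    size_b = c(2183, 177, 100), stringsAsFactors = FALSE)
  pairs$fraction_a <- pairs$overlap / pairs$size_a
  pairs$fraction_b <- pairs$overlap / pairs$size_b
  pairs$p_value <- c(1e-6, 1e-5, 0.5)
  res <- classify_preservation(pairs)
  # 72%/47% passes on the max fraction; 38%/56% passes via 56%;
  # 40%/40% fails the fraction gate regardless of p
  expect_identical(res$pairs$preserved, c(TRUE, TRUE, FALSE))
  expect_identical(res$specific_a, "green")
  expect_identical(res$specific_b, "yellow")

  not_sig <- pairs
  not_sig$p_value <- c(0.01, 0.5, 0.5)
  expect_identical(sum(classify_preservation(not_sig)$pairs$preserved), 0L)
})

test_that("greedy matching keeps each module in at most one preserved pair", {
  pairs <- expand.grid(module_a = c("m1", "m2"), module_b = c("k1", "k2"),
                       stringsAsFactors = FALSE)
  pairs$overlap <- c(90, 60, 50, 85)
  pairs$size_a <- 100; pairs$size_b <- 100
  pairs$fraction_a <- pairs$overlap / 100
  pairs$fraction_b <- pairs$overlap / 100
  pairs$p_value <- c(1e-12, 1e-6, 1e-5, 1e-10)
  res <- classify_preservation(pairs)
  kept <- res$pairs[res$pairs$preserved, ]
  expect_identical(nrow(kept), 2L)
  expect_false(any(duplicated(kept$module_a)))
  expect_false(any(duplicated(kept$module_b)))
  # best-p pair m1-k1 is kept, forcing m2-k2
  expect_setequal(paste(kept$module_a, kept$module_b),
                  c("m1 k1", "m2 k2"))
})

test_that("preservation classification is symmetric in the two networks", {
  set.seed(83)
  genes <- paste0("g", 1:200)
  a <- setNames(sample(c("m1", "m2", "unassigned"), 200, TRUE,
                       prob = c(0.4, 0.4, 0.2)), genes)
  b <- setNames(sample(c("k1", "k2", "unassigned"), 200, TRUE,
                       prob = c(0.5, 0.3, 0.2)), genes)
  ab <- compare_module_sets(a, b)
  ba <- compare_module_sets(b, a)
  pairs_ab <- with(ab$pairs[ab$pairs$preserved, ],
                   sort(paste(module_a, module_b)))
  pairs_ba <- with(ba$pairs[ba$pairs$preserved, ],
                   sort(paste(module_b, module_a)))
  expect_identical(pairs_ab, pairs_ba)
  expect_setequal(ab$specific_a, ba$specific_b)
})

test_that("module backbones are the k strongest intra-module edges", {
  set.seed(89)
  genes <- paste0("g", sprintf("%02d", 1:30))
  w <- matrix(runif(900), 30, dimnames = list(genes, genes))
  w <- (w + t(w)) / 2; diag(w) <- 1
  bb <- module_backbone(w, genes, k = 100)
  expect_identical(nrow(bb), 100L)
  # full-sort oracle over all C(30, 2) pairs
  pairs <- t(combn(genes, 2))
  weights <- w[pairs]
  ord <- order(-weights, pairs[, 1], pairs[, 2])
  expect_equal(bb$weight, weights[ord][1:100])
  expect_identical(bb$gene_i, pairs[ord, 1][1:100])
  # k = 1 returns exactly the single strongest pair
  top <- module_backbone(w, genes, k = 1)
  expect_identical(nrow(top), 1L)
  expect_equal(top$weight, max(w[upper.tri(w)]))
  # small module: all pairs when k is large
  expect_identical(nrow(module_backbone(w, genes[1:3], k = 300)), 3L)
  expect_error(module_backbone(w, character()), "empty")
  expect_error(module_backbone(w, "nope"), "absent")
})

test_that("hub genes are backbone nodes at or above the degree threshold", {
  # star: center connected to 20 leaves
  star <- data.frame(gene_i = "center", gene_j = paste0("leaf", 1:20),
                     weight = 1)
  hubs <- hub_genes(star, min_connections = 15)
  expect_identical(hubs$gene, "center")
  expect_identical(hubs$degree, 20L)
  expect_identical(nrow(hub_genes(star, min_connections = 21)), 0L)
  # random backbone: degrees match a per-edge tally
  set.seed(97)
  edges <- data.frame(gene_i = sample(letters[1:8], 40, TRUE),
                      gene_j = sample(letters[9:16], 40, TRUE), weight = 1)
  hubs <- hub_genes(edges, min_connections = 3)
  tally <- table(c(edges$gene_i, edges$gene_j))
  for (i in seq_len(nrow(hubs)))
    expect_identical(hubs$degree[i], as.integer(tally[hubs$gene[i]]))
  expect_true(all(diff(hubs$degree) <= 0))
})

test_that("planted shared and specific modules are classified correctly", {
  skip_if_not_installed("mclust")
  correct <- vapply(1:10, function(seed) {
    sim <- small_sim(seed)
    modsets <- lapply(sim$datasets, function(ds)
      detect_modules(build_coexpression_network(log2(ds$tpm + 1))))
    pres <- compare_module_sets(modsets$A, modsets$B)
    truth <- setNames(sim$truth$module_A, sim$truth$gene)
    shared_genes <- names(truth)[truth == "M1"]
    kept <- pres$pairs[pres$pairs$preserved, ]
    if (nrow(kept) != 1) return(FALSE)
    in_a <- names(modsets$A$assignment)[
      modsets$A$assignment == kept$module_a]
    mean(shared_genes %in% in_a) > 0.5 &&
      length(pres$specific_a) == nrow(modsets$A$modules) - 1 &&
      length(pres$specific_b) == nrow(modsets$B$modules) - 1
  }, logical(1))
  expect_gte(mean(correct), 0.9)
})
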