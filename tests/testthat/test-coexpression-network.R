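test_that("correlation matrix matches a two-pass textbook computation", {
  x <- c(1, 2, 3, 5, 8)
  m <- rbind(a = x, b = x * 2 + 1, c = -x, d = c(2, 1, 4, 1, 3))
  cc <- correlation_matrix(m)
  expect_equal(unname(cc["a", "b"]), 1)
  expect_equal(unname(cc["a", "c"]), -1)
  set.seed(31)
  r <- matrix(rnorm(40), 5, 8, dimnames = list(paste0("g", 1:5), NULL))
  cc <- correlation_matrix(r)
  naive <- function(u, v) {
    sum((u - mean(u)) * (v - mean(v))) /
      sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))
  }
  for (i in 1:5) for (j in 1:5)
    expect_equal(unname(cc[i, j]), naive(r[i, ], r[j, ]), tolerance = 1e-10)
  # constant genes are excluded with a warning
  expect_warning(cc2 <- correlation_matrix(rbind(r, const = rep(2, 8))),
                 "constant")
  expect_false("const" %in% rownames(cc2))
  expect_error(correlation_matrix(r[, 1:2]), ">= 3 samples")
})

test_that("power adjacency raises |cor| to beta with unit diagonal", {
  cc <- matrix(c(1, 0.9, 0, 0.9, 1, -0.5, 0, -0.5, 1), 3)
  a <- adjacency_from_correlation(cc, beta = 10)
  expect_equal(a[1, 2], 0.9^10)
  expect_equal(a[1, 3], 0)
  expect_equal(a[2, 3], 0.5^10)
  expect_equal(diag(a), rep(1, 3))
  expect_equal(adjacency_from_correlation(cc, beta = 1)[1, 2], 0.9)
  expect_error(adjacency_from_correlation(cc, beta = 0.5), ">= 1")
  # monotonicity: raising beta never increases off-diagonal entries
  set.seed(13)
  for (i in 1:5) {
    r <- matrix(runif(25, -1, 1), 5)
    r <- (r + t(r)) / 2; diag(r) <- 1
    a1 <- adjacency_from_correlation(r, 6)
    a2 <- adjacency_from_correlation(r, 12)
    expect_true(all(a2[upper.tri(a2)] <= a1[upper.tri(a1)] + 1e-15))
  }
})

test_that("topological overlap matches hand-worked and brute-force values", {
  # 2-gene network with a_12 = 1: TOM = (0 + 1) / (1 + 1 - 1) = 1
  a2 <- matrix(c(1, 1, 1, 1), 2)
  expect_equal(topological_overlap(a2)[1, 2], 1)
  # 3-gene network, all off-diagonal 0.5: (0.25 + 0.5) / (1 + 1 - 0.5) = 0.5
  a3 <- matrix(0.5, 3, 3); diag(a3) <- 1
  expect_equal(topological_overlap(a3)[1, 2], 0.5)
  # empty network
  a0 <- diag(4)
  expect_equal(unique(topological_overlap(a0)[upper.tri(a0)]), 0)
  expect_error(topological_overlap(matrix(c(1, 0.2, 0.5, 1), 2)), "symmetric")

  set.seed(41)
  for (i in 1:10) {
    n <- sample(5:30, 1)
    r <- matrix(runif(n * n), n)
    a <- (r + t(r)) / 2
    diag(a) <- 1
    tom <- topological_overlap(a)
    expect_equal(tom, oracle_tom(a), tolerance = 1e-12)
    expect_true(all(tom <= 1 + 1e-12))
    expect_true(all(tom >= 0))
    expect_equal(tom, t(tom))
  }
})

test_that("average-linkage heights reproduce UPGMA", {
  d3 <- matrix(c(0, 0.1, 0.9, 0.1, 0, 0.9, 0.9, 0.9, 0), 3)
  h <- average_linkage_dendrogram(d3)
  expect_equal(h$height, c(0.1, 0.9))
  d0 <- matrix(0, 3, 3)
  expect_equal(average_linkage_dendrogram(d0)$height, c(0, 0))
  set.seed(17)
  for (i in 1:5) {
    n <- 10
    r <- matrix(runif(n * n), n)
    d <- (r + t(r)) / 2; diag(d) <- 0
    expect_equal(average_linkage_dendrogram(d)$height,
                 oracle_upgma_heights(d), tolerance = 1e-12)
  }
  dna <- d3; dna[1, 2] <- NA
  expect_error(average_linkage_dendrogram(dna), "NaN|NA")
})

test_that("static cut labels size-ranked modules and leaves small clusters out", {
  d <- matrix(0.9, 6, 6)
  d[1:3, 1:3] <- 0.05
  d[4:6, 4:6] <- 0.05
  diag(d) <- 0
  rownames(d) <- colnames(d) <- paste0("g", 1:6)
  dend <- average_linkage_dendrogram(d)
  # cut above the root: everything in one module
  all_in <- cut_modules(dend, cut_height = 1, min_module_size = 2)
  expect_identical(nrow(all_in$modules), 1L)
  expect_identical(unname(all_in$modules$module), "turquoise")
  # cut at zero: all singletons, all unassigned when min size > 1
  none <- cut_modules(dend, cut_height = 0, min_module_size = 2)
  expect_identical(nrow(none$modules), 0L)
  expect_true(all(none$assignment == "unassigned"))
  # intermediate cut: two modules of 3
  two <- cut_modules(dend, cut_height = 0.5, min_module_size = 3)
  expect_identical(sort(two$modules$module), c("blue", "turquoise"))
  expect_identical(unname(two$modules$size), c(3L, 3L))
  expect_error(cut_modules(dend, cut_height = -0.1), "cut_height")
})

test_that("planted two-block structure is recovered exactly at low noise", {
  skip_if_not_installed("mclust")
  cfg <- synthetic_expression_config(
    n_genes = 400, module_sizes = c(50, 50), shared_modules = 2,
    specific_modules = 0, within_module_correlation = 0.95,
    dispersion = 0.001, n_replicates_per_stage = 4, seed = 19)
  sim <- generate_expression_dataset(cfg)
  net <- build_coexpression_network(log2(sim$datasets$A$tpm + 1))
  mods <- detect_modules(net, min_module_size = 30)
  truth <- setNames(sim$truth$module_A, sim$truth$gene)
  planted <- names(truth)[truth != "background"]
  # exactly the two planted blocks, each recovered intact
  expect_identical(nrow(mods$modules), 2L)
  expect_equal(ari(truth[planted], mods$assignment[planted]), 1)
})

test_that("planted modules are recovered from moderate-noise data", {
  skip_if_not_installed("mclust")
  # network-level recovery property: 20 samples, modules of >= 40 genes,
  # target correlation 0.8; median ARI over the gene universe >= 0.8
  aris <- vapply(1:10, function(seed) {
    sim <- small_sim(seed, n_genes = 300, module_sizes = c(50, 50),
                     shared = 2, specific = 0, n_rep = 4)
    net <- build_coexpression_network(log2(sim$datasets$A$tpm + 1))
    mods <- detect_modules(net)
    truth <- setNames(sim$truth$module_A, sim$truth$gene)
    ari(truth[net$genes], mods$assignment[net$genes])
  }, numeric(1))
  expect_gte(median(aris), 0.8)
})

test_that("module eigengenes summarize coherent modules completely", {
  x <- c(0.5, -1, 2, 0, -1.5)
  m <- rbind(g1 = x, g2 = 3 * x + 2, g3 = 0.5 * x - 1)
  colnames(m) <- paste0("s", 1:5)
  e <- module_eigengene(m, c("g1", "g2", "g3"))
  expect_equal(e$variance_explained, 1)
  # V1 proportional to the standardized profile, unit norm, positive sign
  z <- (x - mean(x)) / sd(x)
  expect_equal(abs(unname(e$v1)), abs(z / sqrt(sum(z^2))), tolerance = 1e-10)
  expect_gt(cor(unname(e$v1), x), 0.999)
  # opposite profiles: still rank-1; the sign convention resolves the tie
  m2 <- rbind(g1 = x, g2 = -x)
  colnames(m2) <- paste0("s", 1:5)
  e2 <- module_eigengene(m2, c("g1", "g2"))
  expect_equal(e2$variance_explained, 1)
  expect_equal(sum(unname(e2$v1)^2), 1, tolerance = 1e-12)
  expect_error(module_eigengene(m, "g1"), ">= 2")
})

test_that("eigengene equals the dominant eigenvector of the sample covariance", {
  set.seed(53)
  m <- matrix(rnorm(8 * 12), 8, 12,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:12)))
  e <- module_eigengene(m, rownames(m))
  xs <- t(scale(t(m)))
  ev <- eigen(t(xs) %*% xs)
  v <- ev$vectors[, 1]
  expect_equal(abs(unname(e$v1)), abs(v), tolerance = 1e-8)
  expect_equal(e$variance_explained, ev$values[1] / sum(ev$values),
               tolerance = 1e-10)
})

test_that("Kruskal-Wallis reproduces the rank-formula statistic", {
  res <- kruskal_wallis(c(1, 2, 3, 4), c("a", "a", "b", "b"))
  expect_equal(res$statistic, 2.4)
  tied <- kruskal_wallis(rep(5, 6), rep(c("a", "b"), 3))
  expect_equal(tied$statistic, 0)
  expect_equal(tied$p_value, 1)
  expect_error(kruskal_wallis(1:4, rep("a", 4)), ">= 2 groups")
  # permuted labels under the null give roughly uniform p-values
  set.seed(61)
  p <- vapply(1:200, function(i) {
    kruskal_wallis(rnorm(12), sample(rep(c("a", "b", "c"), 4)))$p_value
  }, numeric(1))
  expect_gt(mean(p > 0.5), 0.35)
  expect_lt(mean(p < 0.05), 0.12)
})
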