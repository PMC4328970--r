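#' Pairwise Pearson correlation of gene expression profiles
#'
#' Computes the gene-by-gene Pearson correlation matrix across samples.
#' Signs are retained here; the absolute value enters at the adjacency
#' step. Genes with constant expression (zero variance) have no defined
#' correlation and are excluded with a warning.
#'
#' @param expression Gene-by-sample numeric matrix (>= 3 samples).
#' @return Symmetric correlation matrix with unit diagonal over the
#'   retained genes.
#' @export
correlation_matrix <- function(expression) {
  expression <- as.matrix(expression)
  if (ncol(expression) < 3) stopf("need >= 3 samples, got %d", ncol(expression))
  sds <- apply(expression, 1, sd)
  constant <- sds == 0 | is.na(sds)
  if (any(constant)) {
    warning(sprintf("excluding %d constant-expression gene(s): %s",
                    sum(constant),
                    paste(head(rownames(expression)[constant], 5),
                          collapse = ", ")), call. = FALSE)
    expression <- expression[!constant, , drop = FALSE]
  }
  if (nrow(expression) < 2) stopf("fewer than 2 non-constant genes remain")
  cc <- cor(t(expression))
  diag(cc) <- 1
  cc
}

#' Soft-threshold power adjacency
#'
#' Converts correlations into connection strengths of an unsigned weighted
#' network: `a_ij = |cor_ij|^beta` off the diagonal, `a_ii = 1`.
#'
#' @param cor Correlation matrix.
#' @param beta Soft-threshold power (default 10).
#' @return Adjacency matrix with entries in \[0, 1\].
#' @export
adjacency_from_correlation <- function(cor, beta = 10) {
  if (beta < 1) stopf("beta must be >= 1")
  a <- abs(cor)^beta
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' Unsigned TOM:
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`
#' with connectivity `k_i = sum_{u != i} a_iu` and the sum over shared
#' neighbors `u != i, j`. High values mean two genes share most of their
#' network neighborhood.
#'
#' @param adjacency Symmetric adjacency matrix with entries in \[0, 1\].
#' @return Symmetric TOM with unit diagonal and entries in \[0, 1\].
#' @export
topological_overlap <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (!isSymmetric(unname(a), tol = 1e-10)) stopf("adjacency must be symmetric")
  if (any(a < 0) || any(a > 1 + 1e-12))
    stopf("adjacency entries must be in [0, 1]")
  diag(a) <- 0
  k <- rowSums(a)
  shared <- a %*% a                    # sum_u a_iu a_uj, u != i, j by diag 0
  num <- shared + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  tom
}

#' Average-linkage (UPGMA) dendrogram from a dissimilarity matrix
#'
#' @param dissimilarity Square symmetric matrix with zero diagonal,
#'   typically `1 - TOM`.
#' @return An [stats::hclust] tree with UPGMA heights.
#' @export
average_linkage_dendrogram <- function(dissimilarity) {
  d <- as.matrix(dissimilarity)
  if (any(is.na(d))) stopf("dissimilarity contains NaN/NA entries")
  if (!isSymmetric(unname(d), tol = 1e-10))
    stopf("dissimilarity must be symmetric")
  hclust(as.dist(d), method = "average")
}

#' Cut a dendrogram into modules at a static height
#'
#' Removes all merges above `cut_height`; the resulting clusters with at
#' least `min_module_size` genes become modules, labeled by a fixed color
#' sequence in decreasing size order (largest module = "turquoise", then
#' "blue", "brown", ...). Genes in smaller clusters are labeled
#' `"unassigned"`.
#'
#' @param dendrogram An [stats::hclust] tree over the genes.
#' @param cut_height Static cut height (default 0.995).
#' @param min_module_size Minimum genes per module (default 30).
#' @return A list of class `"module_set"`: `assignment` (named character
#'   vector gene -> label), `modules` (data frame `module`, `size`),
#'   `dendrogram`, `cut_height`, `min_module_size`.
#' @export
cut_modules <- function(dendrogram, cut_height = 0.995, min_module_size = 30) {
  max_h <- if (length(dendrogram$height)) max(dendrogram$height) else 0
  if (cut_height < 0) stopf("cut_height must be in [0, max merge height]")
  cl <- cutree(dendrogram, h = min(cut_height, max_h))
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  # size rank, ties broken by first-formed (lowest) cluster index
  keep <- keep[order(-sizes[keep], as.integer(keep))]
  labels <- setNames(module_labels(length(keep)), keep)
  assignment <- setNames(rep(UNASSIGNED, length(cl)), names(cl))
  hit <- as.character(cl) %in% keep
  assignment[hit] <- labels[as.character(cl)[hit]]
  modules <- data.frame(module = unname(labels),
                        size = as.integer(sizes[keep]),
                        stringsAsFactors = FALSE)
  structure(list(assignment = assignment, modules = modules,
                 dendrogram = dendrogram, cut_height = cut_height,
                 min_module_size = min_module_size),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("module_set: %d modules over %d genes (%d unassigned)\n",
              nrow(x$modules), length(x$assignment),
              sum(x$assignment == UNASSIGNED)))
  if (nrow(x$modules))
    cat(paste(sprintf("  %s: %d", x$modules$module, x$modules$size),
              collapse = "\n"), "\n")
  invisible(x)
}

#' Build a weighted coexpression network
#'
#' Convenience wrapper chaining [correlation_matrix()],
#' [adjacency_from_correlation()] and [topological_overlap()].
#'
#' @param expression Gene-by-sample numeric matrix (typically
#'   `log2(TPM + 1)` of the DEG-filtered genes).
#' @param beta Soft-threshold power (default 10).
#' @return A list of class `"coexpression_network"`: `genes`, `cor`,
#'   `adjacency`, `beta`, `tom`, `tom_dissimilarity`, `dendrogram`.
#' @export
build_coexpression_network <- function(expression, beta = 10) {
  cc <- correlation_matrix(expression)
  adj <- adjacency_from_correlation(cc, beta)
  tom <- topological_overlap(adj)
  diss <- 1 - tom
  diag(diss) <- 0
  structure(list(genes = rownames(cc), cor = cc, adjacency = adj,
                 beta = beta, tom = tom, tom_dissimilarity = diss,
                 dendrogram = average_linkage_dendrogram(diss)),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("coexpression_network: %d genes, beta = %g\n",
              length(x$genes), x$beta))
  invisible(x)
}

#' Detect modules in a coexpression network
#'
#' @param network A [build_coexpression_network()] result.
#' @param cut_height,min_module_size Passed to [cut_modules()].
#' @return A `"module_set"`.
#' @export
detect_modules <- function(network, cut_height = 0.995, min_module_size = 30) {
  cut_modules(network$dendrogram, cut_height, min_module_size)
}

#' Module eigengene by singular value decomposition
#'
#' Standardizes each module gene across samples (zero mean, unit variance),
#' decomposes the module expression matrix, and returns the first right
#' singular vector V1 (the first principal component over samples) as the
#' module eigengene. The sign is fixed so V1 correlates positively with the
#' module's mean standardized profile (tie broken toward the first gene).
#'
#' @param expression Gene-by-sample matrix for the whole network.
#' @param module_genes Character vector of >= 2 gene ids in the module.
#' @return A list of class `"eigengene"`: `v1` (named per-sample values,
#'   unit norm) and `variance_explained` in \[0, 1\].
#' @export
module_eigengene <- function(expression, module_genes) {
  if (length(module_genes) < 2) stopf("module must have >= 2 genes")
  x <- as.matrix(expression)[module_genes, , drop = FALSE]
  xs <- t(scale(t(x)))                  # standardize each gene across samples
  if (any(is.na(xs))) stopf("module contains constant-expression gene(s)")
  dec <- svd(xs)
  v1 <- dec$v[, 1]
  ref <- colMeans(xs)
  s <- sum(v1 * ref)
  if (s == 0) s <- sum(v1 * xs[1, ])
  if (s < 0) v1 <- -v1
  structure(list(v1 = setNames(v1, colnames(x)),
                 variance_explained = dec$d[1]^2 / sum(dec$d^2)),
            class = "eigengene")
}

#' Kruskal-Wallis rank test
#'
#' Rank-based test of whether per-sample values (e.g. a module eigengene)
#' differ across the levels of an indicator variable, with tie correction
#' and a chi-squared p-value on `groups - 1` degrees of freedom. When every
#' value is identical the statistic is defined as 0 with p = 1.
#'
#' @param values Numeric per-sample values.
#' @param groups Per-sample group labels (>= 2 nonempty groups).
#' @return List with `statistic` (H) and `p_value`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stopf("need >= 2 groups")
  if (any(table(groups) == 0)) stopf("every group must be nonempty")
  if (length(values) != length(groups))
    stopf("values and groups must have equal length")
  if (length(unique(values)) == 1L)
    return(list(statistic = 0, p_value = 1))
  kt <- kruskal.test(values, groups)
  list(statistic = unname(kt$statistic), p_value = kt$p.value)
}
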