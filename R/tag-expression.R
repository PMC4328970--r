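#' Normalize tag counts to tags per million (TPM)
#'
#' Scales each library so its tag counts sum to one million:
#' `tpm[g, s] = counts[g, s] / total(s) * 1e6`.
#'
#' @param counts Nonnegative gene-by-sample count matrix.
#' @return Matrix of the same shape; every column with any observed tag sums
#'   to 1e6.
#' @examples
#' normalize_tpm(matrix(c(10, 30), 2, dimnames = list(NULL, "s1")))
#' @export
normalize_tpm <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stopf("counts must be nonnegative")
  totals <- colSums(counts)
  if (any(totals == 0)) {
    bad <- colnames(counts)[totals == 0]
    if (is.null(bad)) bad <- which(totals == 0)
    stopf("sample(s) with zero total tags: %s", paste(bad, collapse = ", "))
  }
  sweep(counts, 2, totals, "/") * 1e6
}

# log posterior-predictive density of observing y tags in library 2 given x
# tags in library 1: p(y|x) = C(x+y, y) (N2/N1)^y / (1 + N2/N1)^(x+y+1),
# i.e. negative binomial with size x+1 and prob N1/(N1+N2)
tag_count_log_density <- function(y, x, n1, n2) {
  dnbinom(y, size = x + 1, prob = n1 / (n1 + n2), log = TRUE)
}

#' Exact two-library tag-count test
#'
#' Tests whether a gene's tag counts in two libraries are consistent with a
#' common underlying rate, using the exact tag-count probability
#' `p(y|x) = ((x+y)!/(x!y!)) (N2/N1)^y / (1+N2/N1)^(x+y+1)`. The two-sided
#' p-value is the minimum-likelihood tail: the sum of all density terms not
#' exceeding the observed one. Note the density conditions on the first
#' library, so the roles of the two libraries are not exactly
#' interchangeable for very small counts; pass libraries in a consistent
#' order.
#'
#' @param x,y Tag counts of the gene in libraries 1 and 2 (vectors are
#'   paired element-wise).
#' @param n1,n2 Total tags in libraries 1 and 2.
#' @return Two-sided p-value(s) in \[0, 1\].
#' @examples
#' tag_count_test(5, 25, 1e6, 1e6)
#' @export
tag_count_test <- function(x, y, n1, n2) {
  if (any(x < 0) || any(y < 0)) stopf("counts must be nonnegative")
  if (n1 <= 0 || n2 <= 0) stopf("library totals must be positive")
  mapply(function(xi, yi) tag_count_test_one(xi, yi, n1, n2), x, y)
}

tag_count_test_one <- function(x, y, n1, n2) {
  prob <- n1 / (n1 + n2)
  size <- x + 1
  # support truncated where the remaining mass is machine-negligible
  ymax <- max(y, qnbinom(1e-16, size = size, prob = prob, lower.tail = FALSE)) + 4
  yv <- 0:ymax
  ld <- dnbinom(yv, size = size, prob = prob, log = TRUE)
  obs <- ld[y + 1L]
  p <- sum(exp(ld[ld <= obs + 1e-12]))
  # beyond ymax the density is decreasing and below the observed term
  p <- p + pnbinom(ymax, size = size, prob = prob, lower.tail = FALSE)
  min(1, p)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR q-values: `q_i = min_{j >= rank(i)} p_(j) * m / j`, capped at
#' one (a thin wrapper over [stats::p.adjust()] with `method = "BH"`).
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Vector of q-values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stopf("p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Detect temporally differentially expressed genes
#'
#' Runs the exact tag-count test for every pairwise stage comparison within
#' a developmental period and calls a gene a DEG in a comparison when it
#' passes all three gates: `|log2 ratio| > log2_threshold`,
#' `p < p_threshold`, and BH `q < q_threshold` (FDR controlled per
#' comparison family). The log2 ratio is computed on TPM with a pseudocount:
#' `log2((tpm_b + c) / (tpm_a + c))`. Replicate libraries of a stage are
#' pooled (counts summed) before testing. The returned DEG set is the union
#' over all comparisons; each retained gene also carries its best-supported
#' (smallest-p) comparison.
#'
#' @param dataset An [expression_dataset()].
#' @param period Optional period to restrict to (`"prenatal"` /
#'   `"postnatal"`).
#' @param log2_threshold,p_threshold,q_threshold The DEG gates (defaults
#'   0.5, 0.009, 0.02).
#' @param pseudocount TPM pseudocount for the ratio (default 1).
#' @param comparisons `"all_pairs"` (default) or `"consecutive"` stages only.
#' @return A list of class `"deg_result"`: `table` (one row per gene x
#'   comparison: `gene`, `comparison`, `log2_ratio`, `p_value`, `q_value`,
#'   `is_deg`), `genes` (the DEG union), and `best` (best-supported row per
#'   DEG).
#' @export
detect_temporal_degs <- function(dataset, period = NULL,
                                 log2_threshold = 0.5, p_threshold = 0.009,
                                 q_threshold = 0.02, pseudocount = 1,
                                 comparisons = c("all_pairs", "consecutive")) {
  comparisons <- match.arg(comparisons)
  dataset <- subset_period(dataset, period)
  stages <- unique(dataset$samples$stage)
  if (length(stages) < 2) stopf("need >= 2 stages, got %d", length(stages))
  # pool replicate libraries per stage
  pooled <- vapply(stages, function(s) {
    rowSums(dataset$counts[, dataset$samples$stage == s, drop = FALSE])
  }, numeric(nrow(dataset$counts)))
  pooled <- matrix(pooled, nrow = nrow(dataset$counts),
                   dimnames = list(rownames(dataset$counts),
                                   as.character(stages)))
  totals <- colSums(pooled)
  tpm <- normalize_tpm(pooled)
  pairs <- if (comparisons == "all_pairs") combn(seq_along(stages), 2) else
    rbind(seq_len(length(stages) - 1L), seq.int(2L, length(stages)))
  rows <- vector("list", ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    lr <- log2((tpm[, b] + pseudocount) / (tpm[, a] + pseudocount))
    pv <- tag_count_test(pooled[, a], pooled[, b], totals[a], totals[b])
    qv <- bh_fdr(pv)
    rows[[j]] <- data.frame(
      gene = rownames(pooled),
      comparison = sprintf("%s_vs_%s", stages[a], stages[b]),
      log2_ratio = lr, p_value = pv, q_value = qv,
      is_deg = abs(lr) > log2_threshold & pv < p_threshold & qv < q_threshold,
      stringsAsFactors = FALSE)
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  hits <- table[table$is_deg, , drop = FALSE]
  genes <- sort(unique(hits$gene))
  best <- hits[order(hits$p_value, hits$q_value, -abs(hits$log2_ratio)), ]
  best <- best[!duplicated(best$gene), , drop = FALSE]
  best <- best[order(best$gene), , drop = FALSE]
  rownames(best) <- NULL
  structure(list(table = table, genes = genes, best = best),
            class = "deg_result")
}

#' @export
print.deg_result <- function(x, ...) {
  cat(sprintf("deg_result: %d DEGs across %d comparisons (%d genes tested)\n",
              length(x$genes), length(unique(x$table$comparison)),
              length(unique(x$table$gene))))
  invisible(x)
}
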