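#' Module membership overlap contingency table
#'
#' Cross-tabulates two module assignments over their shared gene universe:
#' cell (a, b) counts the genes in module `a` of network A that fall in
#' module `b` of network B. Unassigned genes are excluded (the field
#' convention for membership-overlap comparisons); genes present in only
#' one assignment are dropped with a message.
#'
#' @param assignment_a,assignment_b Named character vectors gene -> module
#'   label (as in a `"module_set"` `$assignment`).
#' @param drop_unassigned Drop the `"unassigned"` label before tabulating
#'   (default `TRUE`).
#' @return A list: `contingency` (module-by-module count matrix), `universe`
#'   (character vector of genes entering the tabulation), `sizes_a`,
#'   `sizes_b` (module sizes restricted to the universe).
#' @export
overlap_table <- function(assignment_a, assignment_b, drop_unassigned = TRUE) {
  shared <- intersect(names(assignment_a), names(assignment_b))
  mismatched <- length(assignment_a) + length(assignment_b) - 2 * length(shared)
  if (!length(shared)) stopf("assignments share no genes")
  if (mismatched > 0)
    message(sprintf("overlap_table: %d gene(s) present in only one assignment",
                    mismatched))
  a <- assignment_a[shared]
  b <- assignment_b[shared]
  if (drop_unassigned) {
    keep <- a != UNASSIGNED | b != UNASSIGNED
    universe <- shared[keep]
    a <- a[keep]; b <- b[keep]
  } else universe <- shared
  contingency <- table(module_a = a, module_b = b)
  list(contingency = unclass(contingency), universe = universe,
       sizes_a = table(a)[rownames(contingency)],
       sizes_b = table(b)[colnames(contingency)])
}

#' Overlap fractions and percentages for a module pair
#'
#' @param overlap Number of shared genes.
#' @param size_a,size_b Module sizes (positive).
#' @return List with `fraction_a`, `fraction_b` and the integer-rounded
#'   `percent_a`, `percent_b`.
#' @examples
#' overlap_fractions(1021, 2183, 1417)  # 47% and 72%
#' @export
overlap_fractions <- function(overlap, size_a, size_b) {
  if (size_a <= 0 || size_b <= 0) stopf("module sizes must be positive")
  if (overlap > min(size_a, size_b))
    stopf("overlap (%d) exceeds the smaller module size", overlap)
  list(fraction_a = overlap / size_a, fraction_b = overlap / size_b,
       percent_a = round(100 * overlap / size_a),
       percent_b = round(100 * overlap / size_b))
}

#' Hypergeometric upper-tail p-value for a module overlap
#'
#' Probability of observing at least `overlap` shared genes between a
#' module of `size_a` and a module of `size_b` drawn from a universe of
#' `universe` genes: `P(X >= overlap)` for
#' `X ~ Hypergeometric(universe, size_a, size_b)`.
#'
#' @param overlap Observed shared-gene count.
#' @param size_a,size_b Module sizes.
#' @param universe Size of the shared gene universe.
#' @return Upper-tail p-value in \[0, 1\].
#' @examples
#' hypergeometric_overlap_p(5, 5, 5, 10)  # 1/choose(10, 5)
#' @export
hypergeometric_overlap_p <- function(overlap, size_a, size_b, universe) {
  if (size_a > universe || size_b > universe)
    stopf("module sizes cannot exceed the universe")
  if (overlap > min(size_a, size_b))
    stopf("overlap exceeds the smaller module size")
  phyper(overlap - 1, size_a, universe - size_a, size_b, lower.tail = FALSE)
}

#' Compare two module sets: overlaps, significance, preservation calls
#'
#' Computes, for every pair of modules across two independently built
#' networks, the membership overlap, both overlap fractions, and the
#' hypergeometric upper-tail p-value, then classifies pairs and modules
#' with [classify_preservation()].
#'
#' @param modules_a,modules_b `"module_set"` objects (or named assignment
#'   vectors).
#' @param fraction_threshold,p_threshold Preservation thresholds
#'   (defaults 0.5 and 0.001).
#' @param universe Sampling frame for the hypergeometric test:
#'   `"network"` (default) uses every gene present in both assignments —
#'   the gene set both clusterings drew their modules from — while
#'   `"assigned"` restricts to genes assigned to some module in at least
#'   one network.
#' @return A list of class `"preservation_result"`: `pairs` (data frame
#'   `module_a`, `module_b`, `overlap`, `size_a`, `size_b`, `fraction_a`,
#'   `fraction_b`, `p_value`, `preserved`), `specific_a`, `specific_b`
#'   (condition-specific module labels), `universe_size`.
#' @export
compare_module_sets <- function(modules_a, modules_b,
                                fraction_threshold = 0.5,
                                p_threshold = 0.001,
                                universe = c("network", "assigned")) {
  universe <- match.arg(universe)
  assignment_a <- if (inherits(modules_a, "module_set")) modules_a$assignment else modules_a
  assignment_b <- if (inherits(modules_b, "module_set")) modules_b$assignment else modules_b
  ov <- overlap_table(assignment_a, assignment_b)
  ct <- ov$contingency
  mods_a <- setdiff(rownames(ct), UNASSIGNED)
  mods_b <- setdiff(colnames(ct), UNASSIGNED)
  universe <- if (universe == "network")
    length(intersect(names(assignment_a), names(assignment_b))) else
    length(ov$universe)
  pairs <- expand.grid(module_a = mods_a, module_b = mods_b,
                       stringsAsFactors = FALSE)
  if (nrow(pairs)) {
    pairs$overlap <- mapply(function(a, b) ct[a, b],
                            pairs$module_a, pairs$module_b)
    pairs$size_a <- as.integer(ov$sizes_a[pairs$module_a])
    pairs$size_b <- as.integer(ov$sizes_b[pairs$module_b])
    pairs$fraction_a <- pairs$overlap / pairs$size_a
    pairs$fraction_b <- pairs$overlap / pairs$size_b
    pairs$p_value <- mapply(hypergeometric_overlap_p, pairs$overlap,
                            pairs$size_a, pairs$size_b,
                            MoreArgs = list(universe = universe))
  } else {
    pairs$overlap <- integer(); pairs$size_a <- integer()
    pairs$size_b <- integer(); pairs$fraction_a <- numeric()
    pairs$fraction_b <- numeric(); pairs$p_value <- numeric()
  }
  classify_preservation(pairs, fraction_threshold, p_threshold,
                        universe_size = universe)
}

#' Classify module pairs as preserved and modules as condition-specific
#'
#' A pair qualifies when `max(fraction_a, fraction_b) > fraction_threshold`
#' and `p_value < p_threshold` (the max-fraction reading: a pair counts as
#' preserved when the overlap covers most of at least one of the two
#' modules). Qualifying pairs are greedily matched one-to-one in order of
#' ascending p-value, so each module joins at most one preserved pair. A
#' module participating in no preserved pair is condition-specific.
#'
#' @param pairs Data frame with columns `module_a`, `module_b`, `overlap`,
#'   `size_a`, `size_b`, `fraction_a`, `fraction_b`, `p_value` covering all
#'   module pairs.
#' @param fraction_threshold,p_threshold Thresholds (defaults 0.5, 0.001).
#' @param universe_size Optional universe size carried into the result.
#' @return A `"preservation_result"` (see [compare_module_sets()]).
#' @export
classify_preservation <- function(pairs, fraction_threshold = 0.5,
                                  p_threshold = 0.001, universe_size = NA) {
  pairs$preserved <- FALSE
  cand <- which(pmax(pairs$fraction_a, pairs$fraction_b) > fraction_threshold &
                  pairs$p_value < p_threshold)
  cand <- cand[order(pairs$p_value[cand], -pairs$overlap[cand],
                     pairs$module_a[cand], pairs$module_b[cand])]
  used_a <- character(); used_b <- character()
  for (i in cand) {
    if (pairs$module_a[i] %in% used_a || pairs$module_b[i] %in% used_b) next
    pairs$preserved[i] <- TRUE
    used_a <- c(used_a, pairs$module_a[i])
    used_b <- c(used_b, pairs$module_b[i])
  }
  structure(list(
    pairs = pairs,
    specific_a = setdiff(unique(pairs$module_a), used_a),
    specific_b = setdiff(unique(pairs$module_b), used_b),
    universe_size = universe_size,
    fraction_threshold = fraction_threshold, p_threshold = p_threshold),
    class = "preservation_result")
}

#' @export
print.preservation_result <- function(x, ...) {
  kept <- x$pairs[x$pairs$preserved, , drop = FALSE]
  cat(sprintf(
    "preservation_result: %d preserved pair(s), %d + %d specific modules\n",
    nrow(kept), length(x$specific_a), length(x$specific_b)))
  if (nrow(kept))
    print(kept[, c("module_a", "module_b", "overlap", "fraction_a",
                   "fraction_b", "p_value")], row.names = FALSE)
  invisible(x)
}

#' Strongest intra-module connections (module backbone)
#'
#' Extracts the `k` intra-module gene pairs with the largest network weight
#' (TOM by default), the edge set typically drawn when visualizing a
#' module. Ties are broken by lexicographic gene-pair order.
#'
#' @param weights Symmetric gene-by-gene weight matrix (e.g. the TOM).
#' @param module_genes Nonempty character vector of module gene ids.
#' @param k Number of edges to keep (default 300).
#' @return Data frame `gene_i`, `gene_j`, `weight`, strongest first; fewer
#'   than `k` rows if the module has fewer pairs.
#' @export
module_backbone <- function(weights, module_genes, k = 300) {
  if (!length(module_genes)) stopf("module is empty")
  missing <- setdiff(module_genes, rownames(weights))
  if (length(missing))
    stopf("module gene(s) absent from the network: %s",
          paste(head(missing, 5), collapse = ", "))
  genes <- sort(module_genes)
  if (length(genes) < 2)
    return(data.frame(gene_i = character(), gene_j = character(),
                      weight = numeric()))
  w <- weights[genes, genes]
  idx <- which(upper.tri(w), arr.ind = TRUE)
  edges <- data.frame(gene_i = genes[idx[, 1]], gene_j = genes[idx[, 2]],
                      weight = w[idx], stringsAsFactors = FALSE)
  edges <- edges[order(-edges$weight, edges$gene_i, edges$gene_j), ]
  rownames(edges) <- NULL
  head(edges, k)
}

#' Hub genes of a module backbone
#'
#' Genes whose degree within the backbone edge list reaches the hub
#' threshold, sorted by degree (descending; alphabetical on ties).
#'
#' @param backbone Edge data frame from [module_backbone()].
#' @param min_connections Minimum backbone degree (default 15).
#' @return Data frame `gene`, `degree`.
#' @export
hub_genes <- function(backbone, min_connections = 15) {
  deg <- table(c(backbone$gene_i, backbone$gene_j))
  deg <- deg[deg >= min_connections]
  out <- data.frame(gene = names(deg), degree = as.integer(deg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
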