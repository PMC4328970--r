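KAKS_SENTINEL <- 99
KAKS_CATEGORIES <- c("Conserved", "0", "0-0.1", "0.1-1", ">1", "99")

# cache of per-codon synonymous site counts (computed once per session)
.ng86_env <- new.env(parent = emptyenv())

# NG86 site counting for one codon: each position contributes the fraction
# of its single-base changes that are synonymous, changes to stop codons
# excluded and the fraction renormalized, so every codon has exactly
# 3 = S + N sites
codon_syn_sites <- function(codon) {
  if (is.null(.ng86_env$sites)) {
    tbl <- vapply(sense_codons(), function(cd) {
      nb <- codon_neighbors(cd)
      s <- 0
      for (pos in 1:3) {
        at <- nb[nb$pos == pos & nb$type != "stop", , drop = FALSE]
        if (nrow(at)) s <- s + sum(at$type == "synonymous") / nrow(at)
      }
      s
    }, numeric(1))
    .ng86_env$sites <- tbl
  }
  out <- .ng86_env$sites[codon]
  if (any(is.na(out))) stopf("not a sense codon: %s",
                             paste(codon[is.na(out)], collapse = ", "))
  unname(out)
}

# synonymous/nonsynonymous substitution counts between two codons, averaging
# over all orderings of the differing positions with equal weight; paths
# passing through stop codons are excluded (if every path is blocked, all
# paths are used and stop-involving steps count as nonsynonymous)
codon_sub_counts <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  nd <- length(pos)
  if (nd == 0) return(c(syn = 0, nonsyn = 0))
  perms <- if (nd == 1) list(pos) else {
    pm <- list()
    idx <- seq_len(nd)
    for (ord in asplit(permutations_of(nd), 1)) pm[[length(pm) + 1L]] <- pos[ord]
    pm
  }
  walk <- function(order_pos, allow_stops) {
    cur <- c1
    syn <- 0; nonsyn <- 0
    for (p in order_pos) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      aa1 <- codon_translate(cur); aa2 <- codon_translate(nxt)
      if (!allow_stops && (aa1 == "*" || aa2 == "*")) return(NULL)
      if (aa1 == aa2 && aa1 != "*") syn <- syn + 1 else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    c(syn = syn, nonsyn = nonsyn)
  }
  counted <- Filter(Negate(is.null), lapply(perms, walk, allow_stops = FALSE))
  if (!length(counted)) counted <- lapply(perms, walk, allow_stops = TRUE)
  Reduce(`+`, counted) / length(counted)
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

split_codons <- function(seq) {
  substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
}

#' Nei-Gojobori (1986) Ka/Ks estimation for a pair of coding sequences
#'
#' Counts synonymous (S) and nonsynonymous (N) sites per codon (each
#' position weighted by the fraction of its single-base changes that are
#' synonymous, stop-codon changes excluded; sites averaged over the two
#' sequences), counts synonymous (Sd) and nonsynonymous (Nd) differences
#' with equal-weight averaging over all substitution paths (paths through
#' stop codons excluded), forms the proportions `pS = Sd/S`, `pN = Nd/N`,
#' and applies the Jukes-Cantor correction
#' `d = -(3/4) log(1 - (4/3) p)` to obtain Ks and Ka.
#'
#' The ratio is `Ka/Ks` when `Ks > 0`; the sentinel 99 when `Ks = 0` with
#' `Ka > 0` (no synonymous change to scale by, the convention used when
#' reporting unreliable large omega); and the pair is `"Conserved"` when
#' the sequences are identical and no variation was observed. Ratios are
#' binned as in [bin_ka_ks()]. A proportion of 3/4 or more makes the
#' correction undefined; such records are returned flagged with `NA`
#' estimates.
#'
#' @param seq1,seq2 Aligned coding sequences (equal length, multiple of 3,
#'   plain A/C/G/T, no internal stop codons; a shared terminal stop codon
#'   is trimmed).
#' @param snps_observed Optional flag: were any variant sites observed for
#'   this gene before consensus building? Distinguishes `"Conserved"`
#'   (identical, no variation seen) from category `"0"` (variation seen but
#'   no fixed difference, or only synonymous change) for identical
#'   sequences. Defaults to `FALSE`.
#' @return A list of class `"selection_result"`: `ka`, `ks`, `ratio`,
#'   `category`, plus the intermediates `nd`, `sd`, `n_sites`, `s_sites`,
#'   `pn`, `ps` and a `flagged` logical.
#' @examples
#' ng86_ka_ks("TTT", "TTA")  # Nd = 1, Sd = 0, sentinel ratio 99
#' @export
ng86_ka_ks <- function(seq1, seq2, snps_observed = FALSE) {
  seq1 <- toupper(seq1); seq2 <- toupper(seq2)
  if (nchar(seq1) != nchar(seq2)) stopf("sequences differ in length")
  if (nchar(seq1) %% 3 != 0) stopf("sequence length is not a multiple of 3")
  if (grepl("[^ACGT]", seq1) || grepl("[^ACGT]", seq2))
    stopf("sequences must contain only A, C, G, T")
  cod1 <- split_codons(seq1)
  cod2 <- split_codons(seq2)
  n_cod <- length(cod1)
  aa1 <- codon_translate(cod1); aa2 <- codon_translate(cod2)
  if (aa1[n_cod] == "*" && aa2[n_cod] == "*") {     # shared terminal stop
    cod1 <- cod1[-n_cod]; cod2 <- cod2[-n_cod]
    aa1 <- aa1[-n_cod]; aa2 <- aa2[-n_cod]
  }
  if (any(aa1 == "*") || any(aa2 == "*"))
    stopf("internal stop codon at codon %d",
          min(which(aa1 == "*" | aa2 == "*")))
  s_sites <- (sum(codon_syn_sites(cod1)) + sum(codon_syn_sites(cod2))) / 2
  n_sites <- 3 * length(cod1) - s_sites
  subs <- c(syn = 0, nonsyn = 0)
  for (i in seq_along(cod1)) {
    if (cod1[i] != cod2[i]) subs <- subs + codon_sub_counts(cod1[i], cod2[i])
  }
  sd <- unname(subs["syn"]); nd <- unname(subs["nonsyn"])
  ps <- if (s_sites > 0) sd / s_sites else 0
  pn <- if (n_sites > 0) nd / n_sites else 0
  jc <- function(p) -0.75 * log(1 - 4 * p / 3) + 0  # + 0 avoids -0
  flagged <- ps >= 0.75 || pn >= 0.75
  ka <- if (pn >= 0.75) NA_real_ else jc(pn)
  ks <- if (ps >= 0.75) NA_real_ else jc(ps)
  if (flagged) {
    ratio <- NA_real_; category <- NA_character_
  } else if (nd + sd == 0) {
    ratio <- if (snps_observed) 0 else NA_real_
    category <- if (snps_observed) "0" else "Conserved"
  } else if (ks > 0) {
    ratio <- ka / ks
    category <- if (ratio == 0) "0" else if (ratio < 0.1) "0-0.1"
                else if (ratio <= 1) "0.1-1" else ">1"
  } else {
    ratio <- KAKS_SENTINEL
    category <- "99"
  }
  structure(list(ka = ka, ks = ks, ratio = ratio, category = category,
                 nd = nd, sd = sd, n_sites = n_sites, s_sites = s_sites,
                 pn = pn, ps = ps, flagged = flagged),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "selection_result: Ka = %.4g, Ks = %.4g, ratio = %s, category = %s\n",
    x$ka, x$ks, format(x$ratio), x$category))
  invisible(x)
}

#' Filter SNPs by minor-allele frequency across all individuals
#'
#' Removes records whose alternate-allele frequency over all genotyped
#' individuals (both groups pooled; diploid genotypes, missing calls
#' excluded from the denominator) is below `min_frequency`. Sites at
#' exactly the threshold are retained.
#'
#' @param snp_table A `"snp_table"` (see [generate_snp_table()] /
#'   [read_snp_vcf()]).
#' @param min_frequency Frequency threshold (default 0.05).
#' @return The filtered `"snp_table"`.
#' @export
filter_snps <- function(snp_table, min_frequency = 0.05) {
  if (!nrow(snp_table$samples)) stopf("snp_table has no individuals")
  freq <- alt_allele_frequency(snp_table$gt)
  keep <- !is.na(freq) & freq >= min_frequency
  snp_table$snps <- snp_table$snps[keep, , drop = FALSE]
  snp_table$gt <- snp_table$gt[keep, , drop = FALSE]
  rownames(snp_table$snps) <- NULL
  snp_table
}

# alt-allele frequency per SNP row from diploid "a/b" genotype strings;
# missing genotypes ("./." or NA) drop out of the denominator
alt_allele_frequency <- function(gt) {
  apply(gt, 1, function(row) {
    row <- row[!is.na(row) & !grepl("\\.", row)]
    if (!length(row)) return(NA_real_)
    alleles <- unlist(strsplit(row, "[/|]"))
    mean(alleles != "0")
  })
}

#' Group consensus coding sequence
#'
#' Substitutes, at every SNP position of a gene, the allele carried by the
#' majority of chromosomes within a group of individuals (ties keep the
#' reference base). The output has the reference length and frame.
#'
#' @param reference Reference CDS (character string).
#' @param snp_table A filtered `"snp_table"`.
#' @param gene Gene id selecting the SNP records.
#' @param group Group name (must be nonempty in `snp_table$samples`).
#' @return Consensus CDS as a character string.
#' @export
consensus_sequence <- function(reference, snp_table, gene, group) {
  members <- snp_table$samples$group == group
  if (!any(members)) stopf("group '%s' has no individuals", group)
  rows <- which(snp_table$snps$gene == gene)
  out <- reference
  for (i in rows) {
    rec <- snp_table$snps[i, ]
    if (rec$pos > nchar(reference))
      stopf("SNP position %d beyond CDS length %d for gene %s",
            rec$pos, nchar(reference), gene)
    if (substr(reference, rec$pos, rec$pos) != rec$ref)
      stopf("reference base mismatch for %s at position %d (expected %s)",
            gene, rec$pos, rec$ref)
    freq <- alt_allele_frequency(snp_table$gt[i, members, drop = FALSE])
    if (!is.na(freq) && freq > 0.5) substr(out, rec$pos, rec$pos) <- rec$alt
  }
  out
}

#' Bin Ka/Ks results into selection categories
#'
#' Categories: `Conserved` (no variation observed), `0` (Ka/Ks = 0),
#' `0-0.1` (0 < Ka/Ks < 0.1), `0.1-1` (0.1 <= Ka/Ks <= 1), `>1`
#' (Ka/Ks > 1) and `99` (the Ks = 0 sentinel). Sentinel genes are excluded
#' from the "ratio above 0.1" aggregate because such estimates are not
#' reliable.
#'
#' @param results List of `"selection_result"` objects or a data frame with
#'   a `category` column.
#' @return A list: `counts` (named integer vector over the six categories),
#'   `proportions`, `n`, and the aggregates `prop_below_0.1` (Conserved,
#'   0 and 0-0.1 combined) and `prop_above_0.1` (0.1-1 and >1 combined,
#'   sentinels excluded).
#' @export
bin_ka_ks <- function(results) {
  categories <- if (is.data.frame(results)) results$category else
    vapply(results, function(r) r$category, character(1))
  if (any(is.na(categories)))
    warning(sprintf("%d flagged record(s) without category dropped",
                    sum(is.na(categories))), call. = FALSE)
  categories <- categories[!is.na(categories)]
  bad <- setdiff(unique(categories), KAKS_CATEGORIES)
  if (length(bad)) stopf("uncategorized record(s): %s",
                         paste(bad, collapse = ", "))
  counts <- table(factor(categories, levels = KAKS_CATEGORIES))
  n <- length(categories)
  props <- if (n) counts / n else counts
  list(counts = setNames(as.integer(counts), KAKS_CATEGORIES),
       proportions = setNames(as.numeric(props), KAKS_CATEGORIES),
       n = n,
       prop_below_0.1 = unname(sum(props[c("Conserved", "0", "0-0.1")])),
       prop_above_0.1 = unname(sum(props[c("0.1-1", ">1")])))
}

#' Positively selected genes per module group
#'
#' Selects genes with Ka/Ks strictly above 1 (the 99 sentinel excluded as
#' unreliable) and groups them by module class (e.g. prenatal common vs
#' breed-specific modules).
#'
#' @param results Data frame with columns `gene` and `ratio` (or a list of
#'   named `"selection_result"` objects plus a `gene` attribute each).
#' @param module_assignments Data frame with columns `gene`, `module` and
#'   `class`. Genes in `results` without an assignment are skipped with a
#'   warning.
#' @return Data frame `gene`, `ratio`, `module`, `class` (ratio
#'   descending), with a `by_class` attribute splitting it per class.
#' @export
positively_selected_genes <- function(results, module_assignments) {
  if (!is.data.frame(results))
    results <- data.frame(
      gene = vapply(results, function(r) attr(r, "gene"), character(1)),
      ratio = vapply(results, function(r) r$ratio, numeric(1)),
      stringsAsFactors = FALSE)
  merged <- merge(results, module_assignments, by = "gene")
  missing <- setdiff(results$gene, module_assignments$gene)
  if (length(missing))
    warning(sprintf("%d gene(s) without module assignment skipped: %s",
                    length(missing), paste(head(missing, 5), collapse = ", ")),
            call. = FALSE)
  hits <- merged[!is.na(merged$ratio) & merged$ratio > 1 &
                   merged$ratio != KAKS_SENTINEL, , drop = FALSE]
  hits <- hits[order(-hits$ratio, hits$gene), , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "by_class") <- split(hits, hits$class)
  hits
}
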