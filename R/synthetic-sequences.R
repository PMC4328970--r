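BASES <- c("A", "C", "G", "T")

codon_translate <- function(codon) unname(Biostrings::GENETIC_CODE[codon])

sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

# all 9 single-base neighbors of a codon, classified against the standard code
codon_neighbors <- function(codon) {
  aa <- codon_translate(codon)
  out <- list()
  n <- 0L
  for (pos in 1:3) {
    for (b in setdiff(BASES, substr(codon, pos, pos))) {
      alt <- codon
      substr(alt, pos, pos) <- b
      aa2 <- codon_translate(alt)
      n <- n + 1L
      out[[n]] <- data.frame(
        pos = pos, base = b, codon = alt,
        type = if (aa2 == "*") "stop" else if (aa2 == aa) "synonymous"
               else "nonsynonymous",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Generate a pair of coding sequences with known substitution counts
#'
#' Builds a random in-frame coding sequence free of stop codons, then
#' derives a second sequence differing from it by exactly `n_nonsyn`
#' nonsynonymous and `n_syn` synonymous single-base changes (one change per
#' codon, verified against the standard genetic code; changes never create
#' stop codons). This gives alignments with exact ground-truth Nd and Sd
#' for validating the Ka/Ks estimator.
#'
#' @param codon_length Number of codons; must be at least `n_nonsyn + n_syn`.
#' @param n_nonsyn,n_syn Number of nonsynonymous / synonymous differences to
#'   plant.
#' @param seed Integer seed.
#' @return A list with `reference` and `derived` (character DNA strings of
#'   `3 * codon_length` bases), `nd` and `sd` (the planted counts), and
#'   `changes` (data frame: codon index, position, reference codon, derived
#'   codon, type).
#' @examples
#' aln <- generate_coding_alignment(20, n_nonsyn = 3, n_syn = 2, seed = 1)
#' aln$changes
#' @export
generate_coding_alignment <- function(codon_length, n_nonsyn, n_syn, seed = 1) {
  if (!is_count(codon_length) || codon_length < 1)
    stopf("codon_length must be a positive count")
  if (!is_count(n_nonsyn) || !is_count(n_syn))
    stopf("n_nonsyn and n_syn must be counts")
  if (codon_length < n_nonsyn + n_syn)
    stopf("codon_length (%d) must be >= n_nonsyn + n_syn (%d)",
          codon_length, n_nonsyn + n_syn)
  withr::with_seed(seed, {
    codons <- sample(sense_codons(), codon_length, replace = TRUE)
    derived <- codons
    order_idx <- sample.int(codon_length)
    want <- c(rep("nonsynonymous", n_nonsyn), rep("synonymous", n_syn))
    changes <- list()
    used <- logical(codon_length)
    for (w in seq_along(want)) {
      placed <- FALSE
      for (i in order_idx) {
        if (used[i]) next
        nb <- codon_neighbors(codons[i])
        nb <- nb[nb$type == want[w], , drop = FALSE]
        if (!nrow(nb)) next
        pick <- nb[sample.int(nrow(nb), 1L), ]
        derived[i] <- pick$codon
        used[i] <- TRUE
        changes[[w]] <- data.frame(codon_index = i, position = pick$pos,
                                   ref_codon = codons[i],
                                   derived_codon = pick$codon,
                                   type = want[w], stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
      if (!placed)
        stopf("could not place a %s change: no eligible codon left", want[w])
    }
    changes <- if (length(changes)) do.call(rbind, changes) else
      data.frame(codon_index = integer(), position = integer(),
                 ref_codon = character(), derived_codon = character(),
                 type = character())
    list(reference = paste(codons, collapse = ""),
         derived = paste(derived, collapse = ""),
         nd = n_nonsyn, sd = n_syn,
         changes = changes[order(changes$codon_index), , drop = FALSE])
  })
}

#' Generate a SNP table over reference coding sequences
#'
#' Plants SNPs at random coding positions with controlled alternate-allele
#' frequencies in two groups of diploid individuals (e.g. domestic pigs and
#' wild boars), recording the planted frequencies as ground truth.
#' Alternate alleles are chosen so that substituting them never creates a
#' stop codon, keeping downstream consensus sequences in frame and
#' stop-free.
#'
#' @param cds Named character vector (or `DNAStringSet`) of reference coding
#'   sequences; names are the gene ids.
#' @param n_individuals_per_group Integer vector of length 1 or 2: number of
#'   diploid individuals in each group (recycled if length 1).
#' @param spectrum List of allele-frequency-spectrum parameters:
#'   `n_snps_per_gene` (SNPs planted per sequence); either fixed planted
#'   frequencies `freq_1`/`freq_2` (scalars or per-SNP vectors, recycled)
#'   or `beta_shape1`/`beta_shape2` for independent Beta draws per group.
#' @param groups Length-2 character vector of group names.
#' @param seed Integer seed.
#' @return A list of class `"snp_table"`: `snps` (data frame: `gene`, `pos`
#'   1-based within the CDS, `ref`, `alt`, planted `truth_freq_<group>`
#'   columns), `gt` (character matrix, SNPs x individuals, diploid `"0/0"`
#'   style genotypes), and `samples` (data frame: `individual`, `group`).
#' @examples
#' cds <- c(geneA = "ATGGCTGCTAAA")
#' snps <- generate_snp_table(cds, c(6, 6),
#'   spectrum = list(n_snps_per_gene = 2, freq_1 = 0.5, freq_2 = 0.1),
#'   seed = 3)
#' snps$snps
#' @export
generate_snp_table <- function(cds, n_individuals_per_group,
                               spectrum = list(n_snps_per_gene = 4,
                                               beta_shape1 = 0.7,
                                               beta_shape2 = 0.7),
                               groups = c("domestic", "wild"), seed = 1) {
  cds <- setNames(as.character(cds), names(cds))
  if (!length(cds) || is.null(names(cds)) || any(!nzchar(names(cds))))
    stopf("cds must be a nonempty named set of sequences")
  n_ind <- rep_len(as.integer(n_individuals_per_group), 2L)
  if (any(n_ind < 1)) stopf("n_individuals_per_group must be >= 1")
  n_snps <- spectrum$n_snps_per_gene
  if (is.null(n_snps) || !is_count(n_snps))
    stopf("spectrum$n_snps_per_gene must be a count")
  withr::with_seed(seed, {
    samples <- data.frame(
      individual = sprintf("%s_%02d", rep(groups, n_ind),
                           unlist(lapply(n_ind, seq_len))),
      group = rep(groups, n_ind), stringsAsFactors = FALSE)
    snps <- list()
    for (g in names(cds)) {
      seq_g <- cds[[g]]
      len <- nchar(seq_g)
      if (len %% 3 != 0) stopf("sequence '%s' length is not a multiple of 3", g)
      take <- min(n_snps, len)
      pos <- sort(sample.int(len, take))
      for (p in pos) {
        ref <- substr(seq_g, p, p)
        ci <- (p - 1L) %/% 3L            # 0-based codon index
        codon <- substr(seq_g, ci * 3L + 1L, ci * 3L + 3L)
        within <- p - ci * 3L            # 1..3
        ok <- character()
        for (b in setdiff(BASES, ref)) {
          alt_codon <- codon
          substr(alt_codon, within, within) <- b
          if (codon_translate(alt_codon) != "*") ok <- c(ok, b)
        }
        if (!length(ok)) next            # every change makes a stop; skip site
        alt <- if (length(ok) == 1L) ok else sample(ok, 1L)
        f1 <- if (!is.null(spectrum$freq_1))
          rep_len(spectrum$freq_1, n_snps)[match(p, pos)] else
          rbeta(1, spectrum$beta_shape1, spectrum$beta_shape2)
        f2 <- if (!is.null(spectrum$freq_2))
          rep_len(spectrum$freq_2, n_snps)[match(p, pos)] else
          rbeta(1, spectrum$beta_shape1, spectrum$beta_shape2)
        snps[[length(snps) + 1L]] <- data.frame(
          gene = g, pos = p, ref = ref, alt = alt,
          truth_freq_1 = f1, truth_freq_2 = f2, stringsAsFactors = FALSE)
      }
    }
    snps <- do.call(rbind, snps)
    if (is.null(snps))
      stopf("no SNP site could be planted (all candidate changes create stops)")
    names(snps)[5:6] <- paste0("truth_freq_", groups)
    gt <- matrix("", nrow(snps), nrow(samples),
                 dimnames = list(NULL, samples$individual))
    for (i in seq_len(nrow(snps))) {
      freqs <- ifelse(samples$group == groups[1],
                      snps[[paste0("truth_freq_", groups[1])]][i],
                      snps[[paste0("truth_freq_", groups[2])]][i])
      alleles <- rbinom(nrow(samples), 2L, freqs)
      gt[i, ] <- c("0/0", "0/1", "1/1")[alleles + 1L]
    }
    structure(list(snps = snps, gt = gt, samples = samples),
              class = "snp_table")
  })
}

#' @export
print.snp_table <- function(x, ...) {
  cat(sprintf("snp_table: %d SNPs over %d gene(s), %d individuals (%s)\n",
              nrow(x$snps), length(unique(x$snps$gene)), nrow(x$samples),
              paste(sprintf("%s=%d", names(table(x$samples$group)),
                            table(x$samples$group)), collapse = ", ")))
  invisible(x)
}
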