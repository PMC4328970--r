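# TSV conventions: tab-separated, header row, no quoting, no row names
write_tsv_file <- function(df, path, row_names = FALSE) {
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = row_names, col.names = TRUE)
  invisible(path)
}

#' Write / read a gene-by-sample counts matrix as TSV
#'
#' Genes as rows (first column `gene`), samples as columns with a header
#' row of sample ids.
#'
#' @param counts Gene-by-sample matrix.
#' @param path File path.
#' @return `write_counts_tsv` returns the path; `read_counts_tsv` the
#'   matrix.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  write_tsv_file(df, path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write / read sample metadata as TSV
#'
#' Columns: `sample_id`, `condition`, `stage`, `period`.
#'
#' @param samples Metadata data frame.
#' @param path File path.
#' @export
write_samples_tsv <- function(samples, path) write_tsv_file(samples, path)

#' @rdname write_samples_tsv
#' @export
read_samples_tsv <- function(path)
  read.delim(path, stringsAsFactors = FALSE)

#' Write / read coding sequences as FASTA
#'
#' @param cds Named character vector of sequences.
#' @param path File path.
#' @export
write_cds_fasta <- function(cds, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(cds), path)
  invisible(path)
}

#' @rdname write_cds_fasta
#' @export
read_cds_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write a SNP table as a minimal VCF
#'
#' Emits `CHROM` (gene id), 1-based `POS`, `REF`, `ALT` and one `GT` column
#' per individual. Group membership goes to a companion samples TSV
#' (`individual`, `group`).
#'
#' @param snp_table A `"snp_table"`.
#' @param path VCF path; the samples TSV is written next to it as
#'   `<path>.samples.tsv`.
#' @return The VCF path.
#' @export
write_snp_vcf <- function(snp_table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", snp_table$samples$individual), collapse = "\t")), con)
  s <- snp_table$snps
  for (i in seq_len(nrow(s))) {
    writeLines(paste(c(s$gene[i], s$pos[i], ".", s$ref[i], s$alt[i], ".",
                       "PASS", ".", "GT", snp_table$gt[i, ]),
                     collapse = "\t"), con)
  }
  write_tsv_file(snp_table$samples, paste0(path, ".samples.tsv"))
  invisible(path)
}

#' Read a minimal VCF plus samples TSV into a SNP table
#'
#' @param path VCF path (plain text, GT-only FORMAT).
#' @param samples_path Samples TSV (`individual`, `group`); defaults to
#'   `<path>.samples.tsv`.
#' @return A `"snp_table"`.
#' @export
read_snp_vcf <- function(path, samples_path = paste0(path, ".samples.tsv")) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  fix <- if (is.matrix(fix)) as.data.frame(fix, stringsAsFactors = FALSE) else
    as.data.frame(t(fix), stringsAsFactors = FALSE)
  snps <- data.frame(gene = fix$CHROM, pos = as.integer(fix$POS),
                     ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  samples <- read.delim(samples_path, stringsAsFactors = FALSE)
  gt <- matrix(as.character(gt), nrow = nrow(snps),
               dimnames = list(NULL, colnames(gt)))
  gt <- gt[, samples$individual, drop = FALSE]
  structure(list(snps = snps, gt = gt, samples = samples),
            class = "snp_table")
}

#' Write a dendrogram as a Newick tree with branch heights
#'
#' @param dendrogram An [stats::hclust] tree.
#' @param path File path.
#' @export
write_dendrogram_newick <- function(dendrogram, path) {
  ape::write.tree(ape::as.phylo(dendrogram), file = path)
  invisible(path)
}
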