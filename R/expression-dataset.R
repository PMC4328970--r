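#' Construct an expression dataset
#'
#' Bundles a gene-by-sample tag-count matrix with its sample metadata and the
#' tags-per-million normalization. This is the container every downstream
#' stage (differential expression, network construction) consumes.
#'
#' @param counts Integer matrix, genes as rows (rownames = gene ids), samples
#'   as columns (colnames = sample ids). All entries must be nonnegative.
#' @param samples Data frame with one row per column of `counts`, containing
#'   at least `sample_id`, `condition`, `stage` and `period`
#'   (`"prenatal"` or `"postnatal"`). Row order must match the columns.
#' @return An object of class `"expression_dataset"`: a list with elements
#'   `counts`, `tpm` (tags per million, columns sum to 1e6), `samples` and
#'   `genes`.
#' @examples
#' counts <- matrix(c(10L, 30L, 20L, 40L), 2,
#'   dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' meta <- data.frame(sample_id = c("s1", "s2"), condition = "A",
#'   stage = 1:2, period = "prenatal")
#' ds <- expression_dataset(counts, meta)
#' colSums(ds$tpm)
#' @export
expression_dataset <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stopf("counts must have unique gene rownames")
  if (is.null(colnames(counts)) || anyDuplicated(colnames(counts)))
    stopf("counts must have unique sample colnames")
  if (any(counts < 0) || any(counts != floor(counts)))
    stopf("counts must be nonnegative integers")
  required <- c("sample_id", "condition", "stage", "period")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols))
    stopf("sample metadata lacks column(s): %s",
          paste(missing_cols, collapse = ", "))
  if (!identical(as.character(samples$sample_id), colnames(counts)))
    stopf("samples$sample_id must match counts colnames in order")
  structure(
    list(counts = counts, tpm = normalize_tpm(counts), samples = samples,
         genes = rownames(counts)),
    class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf(
    "expression_dataset: %d genes x %d samples (%s; stages: %s)\n",
    nrow(x$counts), ncol(x$counts),
    paste(unique(x$samples$condition), collapse = "/"),
    paste(unique(x$samples$stage), collapse = ", ")))
  invisible(x)
}

#' Subset an expression dataset to a developmental period
#'
#' @param dataset An [expression_dataset()].
#' @param period `"prenatal"` or `"postnatal"`; `NULL` keeps all samples.
#' @return An `expression_dataset` restricted to the matching samples.
#' @export
subset_period <- function(dataset, period = NULL) {
  if (is.null(period)) return(dataset)
  keep <- dataset$samples$period == period
  if (!any(keep)) stopf("no samples with period '%s'", period)
  expression_dataset(dataset$counts[, keep, drop = FALSE],
                     dataset$samples[keep, , drop = FALSE])
}
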