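#' Pipeline configuration
#'
#' Collects every numeric constant of the analysis chain, with defaults set
#' to the published protocol this package implements: DEG gates
#' `|log2 ratio| > 0.5`, `p < 0.009`, FDR `q < 0.02`; soft-threshold power
#' `beta = 10`; static dendrogram cut at height 0.995 with minimum module
#' size 30; module backbones of the top 300 connections with hub threshold
#' 15; preservation thresholds of 50% overlap and `p < 0.001`; and a 5%
#' SNP-frequency filter.
#'
#' @param synthetic A [synthetic_expression_config()] describing the data
#'   to simulate, or `NULL` when `counts_path`/`samples_path` point at real
#'   input files.
#' @param counts_path,samples_path Optional TSV inputs (formats of
#'   [write_counts_tsv()] / [write_samples_tsv()]) used when `synthetic`
#'   is `NULL`.
#' @param log2_threshold,p_threshold,q_threshold DEG gates.
#' @param beta Soft-threshold power.
#' @param cut_height,min_module_size Module detection parameters.
#' @param backbone_k,hub_min_connections Backbone/hub parameters.
#' @param preservation_fraction,preservation_p Preservation thresholds.
#' @param snp_min_frequency SNP filter threshold.
#' @param cds_codon_length Codon length of the synthetic CDS drawn per
#'   module gene in the selection stage.
#' @param snps_per_gene SNPs planted per gene in the selection stage.
#' @param n_individuals Individuals per group for the synthetic SNP table
#'   (defaults to the 37 domestic / 11 wild design).
#' @param seed Master seed; all stage seeds derive from it.
#' @param output_dir Directory for stage artifacts (created if missing).
#' @return A `"pipeline_config"` list.
#' @export
pipeline_config <- function(synthetic = synthetic_expression_config(),
                            counts_path = NULL, samples_path = NULL,
                            log2_threshold = 0.5, p_threshold = 0.009,
                            q_threshold = 0.02, beta = 10,
                            cut_height = 0.995, min_module_size = 30,
                            backbone_k = 300, hub_min_connections = 15,
                            preservation_fraction = 0.5,
                            preservation_p = 0.001,
                            snp_min_frequency = 0.05,
                            cds_codon_length = 120, snps_per_gene = 3,
                            n_individuals = c(37, 11), seed = 1,
                            output_dir = tempfile("coexmod_run_")) {
  stopifnot(log2_threshold >= 0, p_threshold > 0, p_threshold <= 1,
            q_threshold > 0, q_threshold <= 1, beta >= 1, cut_height >= 0,
            min_module_size >= 1, backbone_k >= 1, hub_min_connections >= 1,
            preservation_fraction >= 0, preservation_fraction <= 1,
            preservation_p > 0, preservation_p <= 1,
            snp_min_frequency >= 0, snp_min_frequency <= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

# JSON-serializable echo of a config (drops classes, keeps values)
config_echo <- function(config) {
  out <- lapply(unclass(config), function(x)
    if (inherits(x, "synthetic_expression_config")) unclass(x) else x)
  out
}

#' Validate pipeline input files
#'
#' Checks a set of input files for format problems before a run: counts
#' matrix shape and integer-ness, metadata completeness against the counts
#' columns, CDS reading frame, and SNP positions against CDS bounds.
#'
#' @param paths Named list with any of `counts`, `samples`, `cds`, `vcf`.
#' @return Data frame `file`, `check`, `status` (`"ok"`, `"warning"` or
#'   `"error"`), `message`.
#' @export
validate_inputs <- function(paths) {
  out <- list()
  note <- function(file, check, status, message = "") {
    out[[length(out) + 1L]] <<- data.frame(
      file = file, check = check, status = status, message = message,
      stringsAsFactors = FALSE)
  }
  counts <- NULL
  if (!is.null(paths$counts)) {
    counts <- tryCatch(read_counts_tsv(paths$counts), error = function(e) e)
    if (inherits(counts, "error")) {
      note(paths$counts, "readable", "error", conditionMessage(counts))
      counts <- NULL
    } else if (any(counts < 0) || any(counts != floor(counts))) {
      note(paths$counts, "nonnegative_integers", "error",
           "counts must be nonnegative integers")
    } else note(paths$counts, "counts_matrix", "ok",
                sprintf("%d genes x %d samples", nrow(counts), ncol(counts)))
  }
  if (!is.null(paths$samples)) {
    meta <- tryCatch(read_samples_tsv(paths$samples), error = function(e) e)
    if (inherits(meta, "error")) {
      note(paths$samples, "readable", "error", conditionMessage(meta))
    } else {
      missing_cols <- setdiff(c("sample_id", "condition", "stage", "period"),
                              names(meta))
      if (length(missing_cols))
        note(paths$samples, "metadata_columns", "error",
             paste("missing:", paste(missing_cols, collapse = ", ")))
      else note(paths$samples, "metadata_columns", "ok", "")
      if (!is.null(counts)) {
        orphan <- setdiff(colnames(counts), meta$sample_id)
        if (length(orphan))
          note(paths$samples, "samples_covered", "error",
               sprintf("sample(s) in counts missing from metadata: %s",
                       paste(orphan, collapse = ", ")))
        else note(paths$samples, "samples_covered", "ok", "")
      }
    }
  }
  cds <- NULL
  if (!is.null(paths$cds)) {
    cds <- tryCatch(read_cds_fasta(paths$cds), error = function(e) e)
    if (inherits(cds, "error")) {
      note(paths$cds, "readable", "error", conditionMessage(cds))
      cds <- NULL
    } else {
      bad <- names(cds)[nchar(cds) %% 3 != 0]
      if (length(bad))
        note(paths$cds, "reading_frame", "error",
             sprintf("length not a multiple of 3: %s",
                     paste(bad, collapse = ", ")))
      else note(paths$cds, "reading_frame", "ok", "")
    }
  }
  if (!is.null(paths$vcf)) {
    snp <- tryCatch(read_snp_vcf(paths$vcf), error = function(e) e)
    if (inherits(snp, "error")) {
      note(paths$vcf, "readable", "error", conditionMessage(snp))
    } else if (!is.null(cds)) {
      len <- nchar(cds)[snp$snps$gene]
      beyond <- which(is.na(len) | snp$snps$pos > len)
      if (length(beyond))
        note(paths$vcf, "positions_in_bounds", "error",
             sprintf("record %d (%s:%d) beyond CDS", beyond[1],
                     snp$snps$gene[beyond[1]], snp$snps$pos[beyond[1]]))
      else note(paths$vcf, "positions_in_bounds", "ok", "")
    }
  }
  if (!length(out))
    return(data.frame(file = character(), check = character(),
                      status = character(), message = character()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

run_stage <- function(name, timings, code) {
  t0 <- proc.time()[["elapsed"]]
  value <- tryCatch(code, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  timings[[name]] <- round(proc.time()[["elapsed"]] - t0, 3)
  list(value = value, timings = timings)
}

#' Run the full analysis pipeline
#'
#' Executes the complete chain on synthetic (or loaded) data: expression
#' simulation, per-condition temporal DEG detection, per-condition network
#' construction and module detection (with eigengenes and a Kruskal-Wallis
#' stage association), cross-condition module preservation with backbones
#' and hub genes, and a Ka/Ks selection screen of the module genes on
#' synthetic coding sequences and SNP tables. All stage artifacts are
#' written to `config$output_dir`; identical config and seed reproduce
#' identical artifacts.
#'
#' @param config A [pipeline_config()].
#' @return A `"run_report"` list: per-stage record counts, per-module hub
#'   counts, the selection category histogram, the config echo, and
#'   per-stage wall times. Also written as `report.json` in the output
#'   directory (timings excluded so the file is deterministic).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  out <- function(...) file.path(config$output_dir, ...)

  ## stage: data ------------------------------------------------------------
  st <- run_stage("data", timings, {
    if (!is.null(config$synthetic)) {
      sim <- generate_expression_dataset(config$synthetic)
      for (cond in names(sim$datasets)) {
        write_counts_tsv(sim$datasets[[cond]]$counts,
                         out(sprintf("counts_%s.tsv", cond)))
        write_samples_tsv(sim$datasets[[cond]]$samples,
                          out(sprintf("samples_%s.tsv", cond)))
      }
      write_tsv_file(sim$truth, out("planted_truth.tsv"))
      sim
    } else {
      counts <- read_counts_tsv(config$counts_path)
      meta <- read_samples_tsv(config$samples_path)
      conds <- unique(meta$condition)
      if (length(conds) != 2)
        stopf("expected 2 conditions, found %d", length(conds))
      datasets <- lapply(conds, function(cond) {
        keep <- meta$condition == cond
        expression_dataset(counts[, meta$sample_id[keep], drop = FALSE],
                           meta[keep, , drop = FALSE])
      })
      list(datasets = setNames(datasets, conds), truth = NULL)
    }
  })
  timings <- st$timings; data <- st$value
  conditions <- names(data$datasets)

  ## stage: differential expression -----------------------------------------
  st <- run_stage("deg", timings, {
    degs <- lapply(conditions, function(cond) {
      res <- detect_temporal_degs(
        data$datasets[[cond]], log2_threshold = config$log2_threshold,
        p_threshold = config$p_threshold, q_threshold = config$q_threshold)
      write_tsv_file(res$table, out(sprintf("deg_table_%s.tsv", cond)))
      res
    })
    setNames(degs, conditions)
  })
  timings <- st$timings; degs <- st$value

  ## stage: networks and modules --------------------------------------------
  st <- run_stage("network", timings, {
    nets <- list()
    for (cond in conditions) {
      genes <- degs[[cond]]$genes
      if (length(genes) < 3) {
        nets[[cond]] <- list(network = NULL, modules = NULL,
                             eigengenes = list())
        next
      }
      ds <- data$datasets[[cond]]
      expr <- log2(ds$tpm[genes, , drop = FALSE] + 1)
      net <- build_coexpression_network(expr, beta = config$beta)
      mods <- detect_modules(net, config$cut_height, config$min_module_size)
      write_tsv_file(
        data.frame(gene = names(mods$assignment),
                   module = unname(mods$assignment)),
        out(sprintf("modules_%s.tsv", cond)))
      write_dendrogram_newick(net$dendrogram,
                              out(sprintf("dendrogram_%s.nwk", cond)))
      eig <- list()
      for (m in mods$modules$module) {
        mg <- names(mods$assignment)[mods$assignment == m]
        e <- module_eigengene(expr[, , drop = FALSE], mg)
        kw <- kruskal_wallis(e$v1, ds$samples$stage)
        eig[[m]] <- c(e, kw)
      }
      if (length(eig)) {
        eig_df <- do.call(rbind, lapply(names(eig), function(m)
          data.frame(module = m, sample = names(eig[[m]]$v1),
                     v1 = unname(eig[[m]]$v1))))
        write_tsv_file(eig_df, out(sprintf("eigengenes_%s.tsv", cond)))
      }
      nets[[cond]] <- list(network = net, modules = mods, eigengenes = eig)
    }
    nets
  })
  timings <- st$timings; nets <- st$value

  ## stage: module comparison -----------------------------------------------
  st <- run_stage("compare", timings, {
    ms_a <- nets[[conditions[1]]]$modules
    ms_b <- nets[[conditions[2]]]$modules
    if (is.null(ms_a) || is.null(ms_b) ||
        !nrow(ms_a$modules) || !nrow(ms_b$modules)) {
      pres <- NULL
    } else {
      pres <- compare_module_sets(ms_a, ms_b, config$preservation_fraction,
                                  config$preservation_p)
      write_tsv_file(pres$pairs, out("preservation.tsv"))
      hubs <- list()
      for (cond in conditions) {
        net <- nets[[cond]]$network
        mods <- nets[[cond]]$modules
        for (m in mods$modules$module) {
          mg <- names(mods$assignment)[mods$assignment == m]
          bb <- module_backbone(net$tom, mg, config$backbone_k)
          write_tsv_file(bb, out(sprintf("backbone_%s_%s.tsv", cond, m)))
          hb <- hub_genes(bb, config$hub_min_connections)
          if (nrow(hb))
            hubs[[length(hubs) + 1L]] <-
              cbind(condition = cond, module = m, hb)
        }
      }
      hubs <- if (length(hubs)) do.call(rbind, hubs) else
        data.frame(condition = character(), module = character(),
                   gene = character(), degree = integer())
      write_tsv_file(hubs, out("hubs.tsv"))
      attr(pres, "hubs") <- hubs
    }
    pres
  })
  timings <- st$timings; pres <- st$value

  ## stage: selection -------------------------------------------------------
  st <- run_stage("selection", timings, {
    module_genes <- unique(unlist(lapply(conditions, function(cond) {
      mods <- nets[[cond]]$modules
      if (is.null(mods)) character() else
        names(mods$assignment)[mods$assignment != UNASSIGNED]
    })))
    if (!length(module_genes)) NULL else {
    groups <- c("domestic", "wild")
    cds <- withr::with_seed(config$seed + 1000L, {
      setNames(vapply(module_genes, function(g)
        paste(sample(sense_codons(), config$cds_codon_length, replace = TRUE),
              collapse = ""), character(1)), module_genes)
    })
    write_cds_fasta(cds, out("module_genes_cds.fasta"))
    snps <- generate_snp_table(
      cds, config$n_individuals,
      spectrum = list(n_snps_per_gene = config$snps_per_gene,
                      beta_shape1 = 0.7, beta_shape2 = 0.7),
      groups = groups, seed = config$seed + 2000L)
    write_snp_vcf(snps, out("module_genes_snps.vcf"))
    kept <- filter_snps(snps, config$snp_min_frequency)
    res <- lapply(module_genes, function(g) {
      observed <- any(kept$snps$gene == g)
      c1 <- consensus_sequence(cds[[g]], kept, g, groups[1])
      c2 <- consensus_sequence(cds[[g]], kept, g, groups[2])
      r <- ng86_ka_ks(c1, c2, snps_observed = observed)
      data.frame(gene = g, ka = r$ka, ks = r$ks, ratio = r$ratio,
                 category = r$category, stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    write_tsv_file(res, out("selection_results.tsv"))
    bins <- bin_ka_ks(res)
    write_tsv_file(
      data.frame(category = names(bins$counts), count = bins$counts,
                 proportion = bins$proportions),
      out("selection_histogram.tsv"))
    # module class: preserved pairs -> common, others -> condition-specific
    classes <- list()
    for (cond in conditions) {
      mods <- nets[[cond]]$modules
      if (is.null(mods)) next
      preserved_mods <- if (!is.null(pres)) {
        col <- if (cond == conditions[1]) "module_a" else "module_b"
        pres$pairs[[col]][pres$pairs$preserved]
      } else character()
      assigned <- mods$assignment[mods$assignment != UNASSIGNED]
      classes[[cond]] <- data.frame(
        gene = names(assigned), module = paste(cond, assigned, sep = "-"),
        class = ifelse(assigned %in% preserved_mods, "common",
                       paste0(cond, "-specific")),
        stringsAsFactors = FALSE)
    }
    assignments <- do.call(rbind, classes)
    positives <- positively_selected_genes(res, assignments)
    write_tsv_file(positives, out("positive_selection.tsv"))
    list(results = res, bins = bins, positives = positives)
    }
  })
  timings <- st$timings; selection <- st$value

  ## report ------------------------------------------------------------------
  report <- list(
    conditions = conditions,
    genes_in = vapply(conditions, function(cond)
      nrow(data$datasets[[cond]]$counts), integer(1)),
    degs = vapply(conditions, function(cond)
      length(degs[[cond]]$genes), integer(1)),
    modules = vapply(conditions, function(cond) {
      m <- nets[[cond]]$modules
      if (is.null(m)) 0L else nrow(m$modules)
    }, integer(1)),
    preserved_pairs = if (is.null(pres)) 0L else sum(pres$pairs$preserved),
    specific_modules = if (is.null(pres)) c(0L, 0L) else
      c(length(pres$specific_a), length(pres$specific_b)),
    hub_genes = if (is.null(pres) || is.null(attr(pres, "hubs"))) 0L else
      nrow(attr(pres, "hubs")),
    selection_histogram = if (is.null(selection)) NULL else
      selection$bins$counts,
    positively_selected = if (is.null(selection)) 0L else
      nrow(selection$positives),
    config = config_echo(config),
    timings = timings)
  class(report) <- "run_report"
  json <- report
  json$timings <- NULL
  jsonlite::write_json(unclass(json), file.path(config$output_dir,
                                                "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report\n")
  cat(sprintf("  conditions: %s\n", paste(x$conditions, collapse = ", ")))
  cat(sprintf("  genes in:   %s\n", paste(x$genes_in, collapse = ", ")))
  cat(sprintf("  DEGs:       %s\n", paste(x$degs, collapse = ", ")))
  cat(sprintf("  modules:    %s\n", paste(x$modules, collapse = ", ")))
  cat(sprintf("  preserved pairs: %d; specific modules: %s\n",
              x$preserved_pairs, paste(x$specific_modules, collapse = ", ")))
  if (!is.null(x$selection_histogram)) {
    cat("  selection histogram:\n")
    for (nm in names(x$selection_histogram))
      cat(sprintf("    %-10s %d\n", nm, x$selection_histogram[[nm]]))
  }
  invisible(x)
}
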