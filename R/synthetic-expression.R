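#' Configuration for the synthetic expression generator
#'
#' Describes a two-condition developmental tag-count experiment with planted
#' coexpression modules. The defaults mirror a digital-gene-expression
#' developmental series: two conditions, five stages per period, one library
#' per stage, libraries of a million tags, and overdispersed counts.
#'
#' Modules are planted as gene blocks sharing a smooth latent stage
#' trajectory. The first `shared_modules` entries of `module_sizes` are
#' planted with identical gene membership (and identical latent trajectory)
#' in both conditions; the remaining `specific_modules` entries are planted
#' in only one condition, alternating between the two, and their genes are
#' uncorrelated background in the other condition.
#'
#' @param n_genes Total number of genes.
#' @param n_stages Number of developmental stages (default 5).
#' @param n_replicates_per_stage Libraries per stage (default 1, the typical
#'   tag-profiling design; raise it to get more samples per condition).
#' @param module_sizes Integer vector of planted module sizes, shared modules
#'   first. `sum(module_sizes)` must not exceed `n_genes`.
#' @param shared_modules Number of leading modules planted in both conditions.
#' @param specific_modules Number of trailing modules planted in one
#'   condition only. `shared_modules + specific_modules` must equal
#'   `length(module_sizes)`.
#' @param within_module_correlation Target pairwise Pearson correlation of
#'   genes within a module, in (0, 1].
#' @param library_size Expected total tags per sample.
#' @param dispersion Negative-binomial overdispersion of counts around their
#'   expected value (variance = mu + dispersion * mu^2); `0` gives Poisson
#'   counts.
#' @param signal_amplitude Standard deviation, in log2 expression units, of
#'   the per-gene latent developmental signal. Larger values make planted
#'   structure dominate counting noise.
#' @param base_log2_tpm_mean,base_log2_tpm_sd Mean and SD of per-gene
#'   baseline abundance on the log2 TPM scale.
#' @param period Developmental period label recorded in the metadata.
#' @param conditions Length-2 character vector of condition names.
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   output.
#' @return A `"synthetic_expression_config"` list.
#' @export
synthetic_expression_config <- function(n_genes = 2000,
                                        n_stages = 5,
                                        n_replicates_per_stage = 1,
                                        module_sizes = c(300, 150, 100),
                                        shared_modules = 2,
                                        specific_modules = 1,
                                        within_module_correlation = 0.8,
                                        library_size = 1e6,
                                        dispersion = 0.05,
                                        signal_amplitude = 2,
                                        base_log2_tpm_mean = 5,
                                        base_log2_tpm_sd = 1.5,
                                        period = "prenatal",
                                        conditions = c("A", "B"),
                                        seed = 1) {
  if (!is_count(n_genes) || n_genes < 1) stopf("n_genes must be a positive count")
  if (!is_count(n_stages) || n_stages < 1) stopf("n_stages must be a positive count")
  if (!is_count(n_replicates_per_stage) || n_replicates_per_stage < 1)
    stopf("n_replicates_per_stage must be a positive count")
  if (any(module_sizes < 1) || any(module_sizes != floor(module_sizes)))
    stopf("module_sizes must be positive counts")
  if (sum(module_sizes) > n_genes)
    stopf("sum of module_sizes (%d) exceeds n_genes (%d)",
          sum(module_sizes), n_genes)
  if (shared_modules + specific_modules != length(module_sizes))
    stopf("shared_modules + specific_modules must equal length(module_sizes)")
  if (!(within_module_correlation > 0 && within_module_correlation <= 1))
    stopf("within_module_correlation must be in (0, 1]")
  if (library_size <= 0) stopf("library_size must be positive")
  if (dispersion < 0) stopf("dispersion must be nonnegative")
  if (length(conditions) != 2L || anyDuplicated(conditions))
    stopf("conditions must be two distinct labels")
  n_genes <- as.integer(n_genes)
  n_stages <- as.integer(n_stages)
  n_replicates_per_stage <- as.integer(n_replicates_per_stage)
  module_sizes <- as.integer(module_sizes)
  shared_modules <- as.integer(shared_modules)
  specific_modules <- as.integer(specific_modules)
  structure(as.list(environment()), class = "synthetic_expression_config")
}

#' Generate a two-condition expression dataset with planted modules
#'
#' Draws, for each condition, a gene-by-sample tag-count matrix in which
#' blocks of genes share a smooth latent stage trajectory (so their pairwise
#' expression correlation approaches the configured target) while background
#' genes are uncorrelated. Counts are negative-binomial around TPM-scaled
#' expected values so each library totals approximately `library_size` tags.
#'
#' @param config A [synthetic_expression_config()].
#' @return A list of class `"synthetic_expression"` with elements
#'   * `datasets`: named list of [expression_dataset()] objects, one per
#'     condition;
#'   * `truth`: data frame `gene`, `module_<condition>` columns giving the
#'     planted module label per condition (`"background"` for unplanted
#'     genes);
#'   * `modules`: data frame `module`, `size`, `specificity` (`"shared"` or
#'     a condition name);
#'   * `latent`: named list of latent expected-count matrices (the noiseless
#'     means the counts were drawn around), one per condition.
#' @examples
#' cfg <- synthetic_expression_config(n_genes = 200, module_sizes = c(40, 30),
#'   shared_modules = 1, specific_modules = 1, seed = 7)
#' sim <- generate_expression_dataset(cfg)
#' sim$datasets$A
#' table(sim$truth$module_A)
#' @export
generate_expression_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_expression_config"))
  withr::with_seed(config$seed, generate_expression_impl(config))
}

generate_expression_impl <- function(cfg) {
  n_samples <- cfg$n_stages * cfg$n_replicates_per_stage
  genes <- sprintf("gene%04d", seq_len(cfg$n_genes))
  n_mod <- length(cfg$module_sizes)
  mod_names <- paste0("M", seq_len(n_mod))
  specificity <- c(rep("shared", cfg$shared_modules),
                   cfg$conditions[1L + (seq_len(cfg$specific_modules) + 1L) %% 2L])
  # block assignment: module genes first, then background
  block <- rep(c(mod_names, "background"),
               c(cfg$module_sizes, cfg$n_genes - sum(cfg$module_sizes)))
  truth <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (k in 1:2) {
    cond <- cfg$conditions[k]
    lab <- block
    drop <- mod_names[specificity != "shared" & specificity != cond]
    lab[lab %in% drop] <- "background"
    truth[[paste0("module_", cond)]] <- lab
  }
  stage_idx <- rep(seq_len(cfg$n_stages), each = cfg$n_replicates_per_stage)
  # per-gene baseline abundance, shared across conditions
  base_log2 <- rnorm(cfg$n_genes, cfg$base_log2_tpm_mean, cfg$base_log2_tpm_sd)
  rho <- cfg$within_module_correlation
  # Smooth latent stage trajectories (random walks), orthogonalized across
  # modules so distinct modules have uncorrelated stage profiles: with only
  # a handful of stages, independent random curves frequently collide by
  # chance, which would merge planted modules. Shared modules reuse the
  # same trajectory in both conditions. At most n_stages - 1 mutually
  # orthogonal centered profiles exist; any excess stays independent.
  new_trajectories <- function(n_new, existing) {
    out <- vector("list", n_new)
    for (i in seq_len(n_new)) {
      u <- cumsum(rnorm(cfg$n_stages))
      u <- u - mean(u)
      if (length(existing) < cfg$n_stages - 1L) {
        for (e in existing) u <- u - sum(u * e) / sum(e * e) * e
      }
      s <- sd(u)
      if (s > .Machine$double.eps) u <- u / s
      out[[i]] <- u
      existing <- c(existing, list(u))
    }
    out
  }
  shared_traj <- new_trajectories(cfg$shared_modules, list())
  datasets <- list()
  latent <- list()
  for (k in 1:2) {
    cond <- cfg$conditions[k]
    lab <- truth[[paste0("module_", cond)]]
    own <- new_trajectories(n_mod - cfg$shared_modules, shared_traj)
    traj <- c(shared_traj, own)
    z <- matrix(rnorm(cfg$n_genes * n_samples), cfg$n_genes, n_samples)
    for (m in seq_len(n_mod)) {
      idx <- which(lab == mod_names[m])
      if (!length(idx)) next
      u <- traj[[m]][stage_idx]
      z[idx, ] <- sqrt(rho) * matrix(u, length(idx), n_samples, byrow = TRUE) +
        sqrt(1 - rho) * z[idx, , drop = FALSE]
    }
    log2_expr <- base_log2 + cfg$signal_amplitude * z
    raw <- 2^log2_expr
    expected_tpm <- sweep(raw, 2, colSums(raw), "/") * 1e6
    mu <- expected_tpm * cfg$library_size / 1e6
    counts <- if (cfg$dispersion > 0) {
      matrix(rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion),
             nrow(mu), ncol(mu))
    } else {
      matrix(rpois(length(mu), lambda = mu), nrow(mu), ncol(mu))
    }
    sample_ids <- sprintf("%s_t%02d_r%d", cond, stage_idx,
                          rep(seq_len(cfg$n_replicates_per_stage), cfg$n_stages))
    dimnames(counts) <- list(genes, sample_ids)
    dimnames(mu) <- dimnames(counts)
    meta <- data.frame(sample_id = sample_ids, condition = cond,
                       stage = stage_idx, period = cfg$period,
                       stringsAsFactors = FALSE)
    datasets[[cond]] <- expression_dataset(counts, meta)
    latent[[cond]] <- mu
  }
  structure(
    list(datasets = datasets, truth = truth,
         modules = data.frame(module = mod_names, size = cfg$module_sizes,
                              specificity = specificity,
                              stringsAsFactors = FALSE),
         latent = latent, config = cfg),
    class = "synthetic_expression")
}

#' @export
print.synthetic_expression <- function(x, ...) {
  cat(sprintf(
    "synthetic_expression: %d genes, conditions %s, %d planted modules (%s)\n",
    x$config$n_genes, paste(names(x$datasets), collapse = "/"),
    nrow(x$modules),
    paste(sprintf("%s[%d,%s]", x$modules$module, x$modules$size,
                  x$modules$specificity), collapse = " ")))
  invisible(x)
}
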