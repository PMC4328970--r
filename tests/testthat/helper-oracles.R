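# Independent brute-force oracles used to validate the implementation.
# These deliberately avoid the package's own code paths.

# O(n^3) triple-loop topological overlap
oracle_tom <- function(adj) {
  a <- adj
  diag(a) <- 0
  n <- nrow(a)
  tom <- diag(n)
  k <- rowSums(a)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}

# naive UPGMA: average of original pairwise distances between cluster members
oracle_upgma_heights <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_len(length(clusters) - 1)) for (j in (i + 1):length(clusters)) {
      h <- mean(d[clusters[[i]], clusters[[j]]])
      if (h < best_h) { best_h <- h; best <- c(i, j) }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# step-up BH, written directly from the definition
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  running <- Inf
  for (r in m:1) {
    running <- min(running, p[ord[r]] * m / r)
    q[ord[r]] <- min(1, running)
  }
  q
}

# exhaustive hypergeometric upper tail
oracle_hypergeom <- function(overlap, size_a, size_b, universe) {
  js <- overlap:min(size_a, size_b)
  sum(choose(size_a, js) * choose(universe - size_a, size_b - js)) /
    choose(universe, size_b)
}

# tag-count density and brute-force minimum-likelihood tail
oracle_tag_density <- function(y, x, n1, n2) {
  q <- n2 / n1
  exp(lchoose(x + y, y) + y * log(q) - (x + y + 1) * log(1 + q))
}
oracle_tag_p <- function(x, y, n1, n2, ymax = 5000) {
  dens <- oracle_tag_density(0:ymax, x, n1, n2)
  obs <- dens[y + 1]
  min(1, sum(dens[dens <= obs * (1 + 1e-9)]))
}

# independent NG86 implementation (recursive path enumeration, explicit
# per-position site fractions); shares only the fixed genetic code table
oracle_ng86 <- function(s1, s2) {
  translate1 <- function(cd) unname(Biostrings::GENETIC_CODE[cd])
  codons <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  syn_sites <- function(cd) {
    total <- 0
    for (pos in 1:3) {
      syn <- 0; valid <- 0
      for (b in setdiff(c("A", "C", "G", "T"), substr(cd, pos, pos))) {
        alt <- cd
        substr(alt, pos, pos) <- b
        if (translate1(alt) == "*") next
        valid <- valid + 1
        if (translate1(alt) == translate1(cd)) syn <- syn + 1
      }
      if (valid > 0) total <- total + syn / valid
    }
    total
  }
  paths <- function(from, to) {
    diff <- which(strsplit(from, "")[[1]] != strsplit(to, "")[[1]])
    if (!length(diff)) return(list(list(syn = 0, nonsyn = 0, blocked = FALSE)))
    out <- list()
    for (p in diff) {
      mid <- from
      substr(mid, p, p) <- substr(to, p, p)
      step_stop <- translate1(mid) == "*"
      step_syn <- !step_stop && translate1(mid) == translate1(from)
      for (rest in paths(mid, to)) {
        out[[length(out) + 1L]] <- list(
          syn = rest$syn + as.numeric(step_syn),
          nonsyn = rest$nonsyn + as.numeric(!step_syn),
          blocked = rest$blocked || step_stop)
      }
    }
    out
  }
  c1 <- codons(s1); c2 <- codons(s2)
  S <- (sum(vapply(c1, syn_sites, 0)) + sum(vapply(c2, syn_sites, 0))) / 2
  N <- 3 * length(c1) - S
  sd_tot <- 0; nd_tot <- 0
  for (i in seq_along(c1)) {
    if (c1[i] == c2[i]) next
    pl <- paths(c1[i], c2[i])
    open <- Filter(function(p) !p$blocked, pl)
    if (!length(open)) open <- pl
    sd_tot <- sd_tot + mean(vapply(open, `[[`, 0, "syn"))
    nd_tot <- nd_tot + mean(vapply(open, `[[`, 0, "nonsyn"))
  }
  list(S = S, N = N, Sd = sd_tot, Nd = nd_tot)
}

# adjusted Rand index between two label vectors
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# small planted two-condition simulation used by several tests
small_sim <- function(seed, n_genes = 400, module_sizes = c(60, 50, 50),
                      shared = 1, specific = 2, n_rep = 2) {
  cfg <- synthetic_expression_config(
    n_genes = n_genes, module_sizes = module_sizes, shared_modules = shared,
    specific_modules = specific, n_replicates_per_stage = n_rep, seed = seed)
  generate_expression_dataset(cfg)
}

# Hand-counted NG86 panel (codon1, codon2, Nd, Sd, S, N). Sites use the
# per-position synonymous fraction with stop-codon changes excluded and
# renormalized; pair sites are the average over both codons; substitution
# paths through stops are excluded from the equal-weight path average.
ng86_panel <- list(
  list("TTT", "TTA", 1,   0,   1 / 2, 5 / 2),   # Phe->Leu
  list("TTT", "TTC", 0,   1,   1 / 3, 8 / 3),   # Phe->Phe
  list("GGG", "GGA", 0,   1,   1,     2),       # Gly->Gly
  list("ATG", "ATT", 1,   0,   1 / 3, 8 / 3),   # Met->Ile
  list("AAA", "CAA", 1,   0,   1 / 3, 8 / 3),   # Lys->Gln
  list("CTG", "TTG", 0,   1,   1,     2),       # Leu->Leu
  list("CGA", "AGA", 0,   1,   7 / 6, 11 / 6),  # Arg->Arg
  list("TCA", "TTA", 1,   0,   5 / 6, 13 / 6),  # Ser->Leu
  # two differences, both substitution orderings open
  list("TTT", "TCA", 1.5, 0.5, 2 / 3, 7 / 3),
  # two differences, one ordering passes through the stop TAA (dropped)
  list("TCA", "TAC", 1,   1,   1,     2),
  # two differences, every ordering fully nonsynonymous
  list("GGG", "CTG", 2,   0,   7 / 6, 11 / 6))
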