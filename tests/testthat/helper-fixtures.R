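# Small in-code fixtures shared across test files.

# tiny deterministic dataset: 3 pairs, hand-chosen FPKM-scale expression,
# built through the generator in exact (noise-free) mode
tiny_exact_sim <- function(n_pairs = 50, seed = 101, ...) {
  cfg <- sim_config(n_pairs = n_pairs, seed = seed, ...)
  generate_dataset(cfg, exact = TRUE)
}

# genotype-mean matrix for hand-written expression values over the six
# genotypes; `rows` is a list of named numeric vectors keyed by genotype
manual_geno_means <- function(gene_id, rows) {
  tbl <- tibble::tibble(gene_id = gene_id)
  for (g in names(rows[[1]])) {
    tbl[[g]] <- vapply(rows, function(r) r[[g]], numeric(1))
  }
  tbl
}

# independent step-up BH oracle: direct double-minimum enumeration
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(sorted[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# two-sided Fisher oracle: enumerate the hypergeometric distribution over
# all tables with the observed margins and sum probabilities <= observed
# (with the conventional 1e-7 relative tie tolerance)
fisher_oracle <- function(a, b, c_, d) {
  m <- a + b
  n <- c_ + d
  k <- a + c_
  lo <- max(0, k - n)
  hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
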