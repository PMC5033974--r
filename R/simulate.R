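#' Draw per-gene regulatory classes and per-pair divergence (ground truth)
#'
#' Assigns each simulated gene a dosage-dependence label (`dependent`,
#' `independent` or `inverse`) independently for the A and C member of every
#' homoeolog pair — so pair-group frequencies follow the product of the
#' marginal class frequencies — and each pair a regulatory-divergence label
#' (`none`, `cis` or `trans`) with per-copy transcription rates.
#'
#' Rate model: each pair shares a lognormal baseline per-copy rate. A
#' cis-divergent pair splits it symmetrically in log2 space
#' (`base * 2^(+/- offset/2)`) in *every* genotype, so the homoeolog ratio is
#' preserved in hybrids. A trans-divergent pair carries the same split in the
#' parental genotypes only and both homoeologs revert to the shared baseline
#' in hybrid genotypes, producing a parental ratio that vanishes in the
#' hybrid (`A != B`, `B = 0`).
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_truth` with elements `genes` (tibble:
#'   `gene_id`, `pair_id`, `subgenome`, `dependence`, `rate_parent`,
#'   `rate_hybrid`, `length_bp`) and `pairs` (tibble: `pair_id`, `a_gene`,
#'   `c_gene`, `divergence`).
#' @examples
#' truth <- assign_regulatory_classes(sim_config(n_pairs = 10, seed = 1))
#' table(truth$genes$dependence)
#' @export
assign_regulatory_classes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_pairs
  pair_id <- sprintf("p%05d", seq_len(n))
  a_gene <- sprintf("gA%05d", seq_len(n))
  c_gene <- sprintf("gC%05d", seq_len(n))

  draw_dependence <- function(n) {
    u <- stats::runif(n)
    ifelse(u < config$fraction_dependent, "dependent",
           ifelse(u < config$fraction_dependent + config$fraction_inverse,
                  "inverse", "independent"))
  }
  dep_a <- draw_dependence(n)
  dep_c <- draw_dependence(n)

  u <- stats::runif(n)
  divergence <- ifelse(
    u < config$fraction_cis_divergent, "cis",
    ifelse(u < config$fraction_cis_divergent + config$fraction_trans_divergent,
           "trans", "none"))

  base_rate <- stats::rlnorm(n, config$baseline_log_mean,
                             config$baseline_log_sd)
  sign <- sample(c(-1, 1), n, replace = TRUE)
  offset <- ifelse(divergence == "cis", config$cis_log2_offset,
                   ifelse(divergence == "trans", config$trans_log2_offset, 0))
  half <- 2^(sign * offset / 2)

  # cis: split persists everywhere; trans: split in parents only
  rate_a_parent <- base_rate * half
  rate_c_parent <- base_rate / half
  rate_a_hybrid <- ifelse(divergence == "cis", rate_a_parent, base_rate)
  rate_c_hybrid <- ifelse(divergence == "cis", rate_c_parent, base_rate)

  lengths <- round(stats::runif(2 * n, config$gene_length_range[1],
                                config$gene_length_range[2]))

  genes <- tibble::tibble(
    gene_id = c(a_gene, c_gene),
    pair_id = rep(pair_id, 2),
    subgenome = rep(c("A", "C"), each = n),
    dependence = c(dep_a, dep_c),
    rate_parent = c(rate_a_parent, rate_c_parent),
    rate_hybrid = c(rate_a_hybrid, rate_c_hybrid),
    length_bp = lengths
  )
  pairs <- tibble::tibble(pair_id = pair_id, a_gene = a_gene,
                          c_gene = c_gene, divergence = divergence)
  structure(list(genes = genes, pairs = pairs), class = "sim_truth")
}

#' Expected expression level of every gene in every genotype
#'
#' Computes the noise-free expected expression (FPKM units) of each simulated
#' gene in each panel genotype from its regulatory class and the genotype's
#' relative subgenome dosage `d`:
#'
#' * dependent: `rate * d` — expression tracks relative dosage, so across the
#'   A-carrying series (AA, AAC, AC, CCAA, CCA) it is proportional to
#'   1 : 2/3 : 1/2 : 1/2 : 1/3;
#' * independent (compensated): `rate * independent_level`, constant in every
#'   carrier genotype;
#' * inverse: `rate * (inverse_floor - d)`, strictly decreasing in dosage yet
#'   always positive.
#'
#' Genes of an absent subgenome (`d = 0`) have expression 0. Parental
#' genotypes (one subgenome only) use the parental per-copy rate; genotypes
#' carrying both subgenomes use the hybrid rate, which is where
#' trans-divergent pairs converge.
#'
#' @param truth A `sim_truth` from [assign_regulatory_classes()].
#' @param panel A `genotype_panel`; default [build_genotype_panel()].
#' @param independent_level,inverse_floor See [sim_config()].
#' @return A long tibble: `gene_id`, `subgenome`, `genotype`, `abundance`.
#' @export
simulate_true_abundance <- function(truth, panel = build_genotype_panel(),
                                    independent_level = 0.5,
                                    inverse_floor = 1.5) {
  stopifnot(inherits(truth, "sim_truth"))
  genes <- truth$genes
  is_hybrid <- panel$copies_a > 0 & panel$copies_c > 0
  out <- tidyr::crossing(genes, genotype = panel$genotype) |>
    dplyr::mutate(
      dosage = relative_dosage(panel, .data$genotype, .data$subgenome),
      rate = ifelse(.data$genotype %in% panel$genotype[is_hybrid],
                    .data$rate_hybrid, .data$rate_parent),
      weight = dplyr::case_when(
        .data$dosage == 0 ~ 0,
        .data$dependence == "dependent" ~ .data$dosage,
        .data$dependence == "inverse" ~ inverse_floor - .data$dosage,
        TRUE ~ independent_level
      ),
      abundance = .data$rate * .data$weight
    )
  out[, c("gene_id", "subgenome", "genotype", "abundance")]
}

#' Sample an overdispersed read-count matrix from expected library shares
#'
#' Given per-sample expected library shares (expected fraction of the
#' sequencing library generated by each gene), draws integer counts by
#' gamma-mixed multinomial sampling: each gene's share is jittered by an
#' independent Gamma(1/dispersion, 1/dispersion) factor (mean 1, variance
#' `dispersion`) and a multinomial of size `library_size` is drawn over the
#' jittered, renormalised shares. Marginally each count is gamma-Poisson
#' (negative-binomial-like) while column sums stay exactly `library_size`
#' when `background = 0`, reflecting competition of transcripts for a fixed
#' library.
#'
#' @param shares A data frame with a `gene_id` column and one numeric column
#'   per sample holding non-negative expected shares.
#' @param config A [sim_config()] supplying `library_size`, `dispersion` and
#'   (optionally) a `seed`; the seed offset keeps sampling reproducible yet
#'   decoupled from class assignment.
#' @param background Non-negative per-sample share (recycled) of the library
#'   absorbed by genes outside the matrix — the rest of the transcriptome.
#'   With the default 0, shares are renormalised over the listed genes only.
#' @return A tibble with `gene_id` and one integer count column per sample.
#' @examples
#' cfg <- sim_config(n_pairs = 1, library_size = 1000, dispersion = 0, seed = 1)
#' shares <- tibble::tibble(gene_id = "g1", s1 = 1)
#' sample_counts(shares, cfg) # count == library_size
#' @export
sample_counts <- function(shares, config, background = 0) {
  stopifnot(inherits(config, "sim_config"))
  shares <- tibble::as_tibble(shares)
  if (!"gene_id" %in% names(shares)) rlang::abort("shares needs a gene_id column")
  smp <- setdiff(names(shares), "gene_id")
  mat <- as.matrix(shares[, smp])
  if (any(mat < 0)) rlang::abort("shares must be non-negative")
  background <- rep_len(background, length(smp))
  if (any(background < 0)) rlang::abort("background share must be non-negative")
  zero <- colSums(mat) + background <= 0
  if (any(zero)) {
    rlang::abort(paste0("all-zero share vector for sample(s): ",
                        paste(smp[zero], collapse = ", ")))
  }
  if (!is.null(config$seed)) set.seed(config$seed + 1L)
  counts <- matrix(0L, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  for (j in seq_along(smp)) {
    p <- mat[, j]
    if (config$dispersion > 0) {
      shape <- 1 / config$dispersion
      p <- p * stats::rgamma(length(p), shape = shape, rate = shape)
    }
    probs <- c(p, background[j])
    draw <- stats::rmultinom(1, size = config$library_size,
                             prob = probs / sum(probs))
    counts[, j] <- draw[seq_along(p), 1]
  }
  out <- tibble::tibble(gene_id = shares$gene_id)
  dplyr::bind_cols(out, tibble::as_tibble(counts))
}

#' Generate a complete synthetic expression dataset with ground truth
#'
#' Runs the full generative model: class assignment, expected abundances,
#' expected library shares per sample (abundance x gene length / 1e9, the
#' inverse of the FPKM formula at the configured library size, with the rest
#' of the library assigned to an implicit background transcriptome), and
#' overdispersed count sampling for `n_replicates` samples per genotype.
#'
#' @inheritParams assign_regulatory_classes
#' @param panel Genotype panel; default [build_genotype_panel()].
#' @param dir Optional directory; when given, the dataset and truth tables
#'   are written as TSV via [write_dataset()] and round-trip losslessly
#'   through [read_dataset()].
#' @param exact If `TRUE`, skip sampling and return the real-valued expected
#'   counts — a noise-free dataset for analytic checks (dependent genes then
#'   give Pearson r = 1 exactly).
#' @return A list of class `sim_dataset` with elements `dataset` (an
#'   [expression_dataset()]) and `truth` (a `sim_truth`).
#' @examples
#' sim <- generate_dataset(sim_config(n_pairs = 50, seed = 1))
#' sim$dataset
#' @export
generate_dataset <- function(config, panel = build_genotype_panel(),
                             dir = NULL, exact = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  truth <- assign_regulatory_classes(config)
  abund <- simulate_true_abundance(truth, panel,
                                   independent_level = config$independent_level,
                                   inverse_floor = config$inverse_floor)

  len <- truth$genes$length_bp[match(abund$gene_id, truth$genes$gene_id)]
  abund$share <- abund$abundance * len / 1e9

  share_wide <- tidyr::pivot_wider(
    abund[, c("gene_id", "genotype", "share")],
    names_from = "genotype", values_from = "share")
  share_wide <- share_wide[match(truth$genes$gene_id, share_wide$gene_id), ]

  samples <- tidyr::crossing(genotype = panel$genotype,
                             replicate = seq_len(config$n_replicates)) |>
    dplyr::mutate(sample_id = paste0(.data$genotype, "_r", .data$replicate),
                  total_reads = config$library_size) |>
    dplyr::select("sample_id", "genotype", "replicate", "total_reads") |>
    dplyr::arrange(match(.data$genotype, panel$genotype), .data$replicate)

  shares <- tibble::tibble(gene_id = share_wide$gene_id)
  for (i in seq_len(nrow(samples))) {
    shares[[samples$sample_id[i]]] <- share_wide[[samples$genotype[i]]]
  }

  gene_mass <- colSums(as.matrix(shares[, -1]))
  if (any(gene_mass > 1)) {
    rlang::abort("expected gene shares exceed the library; lower the baseline rate")
  }
  if (exact) {
    counts <- shares
    counts[, -1] <- counts[, -1] * config$library_size
  } else {
    counts <- sample_counts(shares, config, background = 1 - gene_mass)
  }

  dataset <- expression_dataset(
    counts = counts,
    samples = samples,
    pairs = truth$pairs[, c("pair_id", "a_gene", "c_gene")],
    lengths = truth$genes[, c("gene_id", "length_bp")]
  )
  out <- structure(list(dataset = dataset, truth = truth),
                   class = "sim_dataset")
  if (!is.null(dir)) write_dataset(out, dir)
  out
}
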