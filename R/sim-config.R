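#' Configuration for the synthetic allopolyploid transcriptome generator
#'
#' Defines the study conditions the generator emulates: a panel of six
#' genotypes (two parents, four hybrids/polyploids) with two biological
#' replicates each, a mixture of dosage-dependent (default 60%),
#' dosage-independent/compensated and rare inverse-dosage genes, a small
#' fraction of cis- and trans-divergent homoeolog pairs, per-copy lognormal
#' transcription rates, and gamma-overdispersed multinomial read sampling at a
#' fixed library size.
#'
#' @param n_pairs Number of homoeolog pairs (each contributes one A- and one
#'   C-subgenome gene).
#' @param fraction_dependent Probability that a gene is dosage dependent;
#'   applied independently to the A and C member of each pair.
#' @param fraction_inverse Probability that a gene shows an inverse dosage
#'   effect (expression falling as dosage rises); drawn as a separate small
#'   sub-fraction, so `fraction_dependent + fraction_inverse <= 1` and the
#'   remainder is dosage independent.
#' @param fraction_cis_divergent,fraction_trans_divergent Per-pair
#'   probabilities of cis- and trans-regulatory divergence between the two
#'   homoeologs (mutually exclusive; remainder is non-divergent).
#' @param cis_log2_offset,trans_log2_offset Magnitude (log2) of the expression
#'   ratio between homoeologs of a divergent pair; the sign is randomised per
#'   pair. Cis offsets persist in hybrids; trans offsets exist only between
#'   the parental genotypes and collapse to the pair mean in hybrids.
#' @param baseline_log_mean,baseline_log_sd Meanlog/sdlog of the lognormal
#'   per-copy transcription rate shared by a pair (FPKM units per genome
#'   copy).
#' @param independent_level Constant relative expression level (fraction of
#'   the per-copy rate) of a fully compensated gene in every genotype carrying
#'   its subgenome.
#' @param inverse_floor Inverse-dosage genes express proportionally to
#'   `inverse_floor - dosage`, giving a strictly decreasing, always positive
#'   response; must exceed 1.
#' @param dispersion Gamma overdispersion of replicate-level counts (variance
#'   of the per-gene multiplicative noise factor); 0 gives pure multinomial
#'   sampling.
#' @param library_size Total mapped reads per sample. The homoeolog-pair genes
#'   occupy only part of the library; the remainder stands in for the rest of
#'   the transcriptome, so FPKM denominators behave like genome-wide mapped
#'   totals.
#' @param n_replicates Biological replicates per genotype.
#' @param gene_length_range Range (bases) of uniform gene lengths; lengths
#'   only enter through the FPKM formula.
#' @param seed Integer seed making generation fully reproducible; `NULL` uses
#'   the current RNG state.
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_pairs = 100, seed = 1)
#' @seealso [generate_dataset()], [assign_regulatory_classes()]
#' @export
sim_config <- function(n_pairs = 2000,
                       fraction_dependent = 0.6,
                       fraction_inverse = 0.005,
                       fraction_cis_divergent = 0.1,
                       fraction_trans_divergent = 0.1,
                       cis_log2_offset = 2,
                       trans_log2_offset = 2,
                       baseline_log_mean = 0.6,
                       baseline_log_sd = 1.2,
                       independent_level = 0.5,
                       inverse_floor = 1.5,
                       dispersion = 0.05,
                       library_size = 2e7,
                       n_replicates = 2,
                       gene_length_range = c(500, 5000),
                       seed = NULL) {
  cfg <- list(
    n_pairs = as.integer(n_pairs),
    fraction_dependent = fraction_dependent,
    fraction_inverse = fraction_inverse,
    fraction_cis_divergent = fraction_cis_divergent,
    fraction_trans_divergent = fraction_trans_divergent,
    cis_log2_offset = cis_log2_offset,
    trans_log2_offset = trans_log2_offset,
    baseline_log_mean = baseline_log_mean,
    baseline_log_sd = baseline_log_sd,
    independent_level = independent_level,
    inverse_floor = inverse_floor,
    dispersion = dispersion,
    library_size = library_size,
    n_replicates = as.integer(n_replicates),
    gene_length_range = gene_length_range,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_pairs < 1) rlang::abort("n_pairs must be >= 1")
  props <- c("fraction_dependent", "fraction_inverse",
             "fraction_cis_divergent", "fraction_trans_divergent")
  for (p in props) {
    v <- cfg[[p]]
    if (!is.numeric(v) || v < 0 || v > 1) {
      rlang::abort(paste0(p, " must be a proportion in [0, 1]"))
    }
  }
  if (cfg$fraction_dependent + cfg$fraction_inverse > 1) {
    rlang::abort("fraction_dependent + fraction_inverse must not exceed 1")
  }
  if (cfg$fraction_cis_divergent + cfg$fraction_trans_divergent > 1) {
    rlang::abort(
      "fraction_cis_divergent + fraction_trans_divergent must not exceed 1")
  }
  if (cfg$library_size < 1) rlang::abort("library_size must be >= 1")
  if (cfg$dispersion < 0) rlang::abort("dispersion must be >= 0")
  if (cfg$n_replicates < 1) rlang::abort("n_replicates must be >= 1")
  if (cfg$independent_level <= 0) {
    rlang::abort("independent_level must be positive")
  }
  if (cfg$inverse_floor <= 1) {
    rlang::abort("inverse_floor must exceed the maximum relative dosage of 1")
  }
  if (length(cfg$gene_length_range) != 2 ||
      cfg$gene_length_range[1] < 1 ||
      diff(cfg$gene_length_range) < 0) {
    rlang::abort("gene_length_range must be an increasing pair of lengths")
  }
  invisible(cfg)
}
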