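# Tab-separated on-disk layout:
#   counts.tsv   gene_id + one column per sample
#   fpkm.tsv     same shape (written only when supplied directly)
#   samples.tsv  sample_id, genotype, replicate[, total_reads]
#   pairs.tsv    pair_id, a_gene, c_gene
#   lengths.tsv  gene_id, length_bp
#   truth.tsv    gene_id, pair_id, subgenome, dependence, divergence,
#                rate_parent, rate_hybrid (simulated data only)

#' Write an expression dataset (and optional ground truth) as TSV
#'
#' @param x An [expression_dataset()], or a `sim_dataset` from
#'   [generate_dataset()] in which case the truth table is written too.
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @seealso [read_dataset()]
#' @export
write_dataset <- function(x, dir) {
  truth <- NULL
  if (inherits(x, "sim_dataset")) {
    truth <- x$truth
    x <- x$dataset
  }
  stopifnot(inherits(x, "expression_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(tbl, name) {
    readr::write_tsv(tbl, file.path(dir, name), progress = FALSE)
  }
  if (!is.null(x$counts)) w(x$counts, "counts.tsv")
  if (!is.null(x$fpkm)) w(x$fpkm, "fpkm.tsv")
  w(x$samples, "samples.tsv")
  w(x$pairs, "pairs.tsv")
  w(x$lengths, "lengths.tsv")
  if (!is.null(truth)) {
    genes <- truth$genes
    genes$divergence <-
      truth$pairs$divergence[match(genes$pair_id, truth$pairs$pair_id)]
    w(genes[, c("gene_id", "pair_id", "subgenome", "dependence",
                "divergence", "rate_parent", "rate_hybrid", "length_bp")],
      "truth.tsv")
  }
  invisible(dir)
}

#' Read an expression dataset written by [write_dataset()]
#'
#' @param dir Directory holding the TSV tables.
#' @return An [expression_dataset()].
#' @export
read_dataset <- function(dir) {
  r <- function(name, required = TRUE) {
    path <- file.path(dir, name)
    if (!file.exists(path)) {
      if (required) rlang::abort(paste0("missing file: ", path))
      return(NULL)
    }
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
  counts <- r("counts.tsv", required = FALSE)
  fpkm <- r("fpkm.tsv", required = FALSE)
  if (is.null(counts) && is.null(fpkm)) {
    rlang::abort(paste0("neither counts.tsv nor fpkm.tsv found in ", dir))
  }
  expression_dataset(
    counts = counts, fpkm = fpkm,
    samples = r("samples.tsv"),
    pairs = r("pairs.tsv"),
    lengths = r("lengths.tsv")
  )
}

#' Read a simulation ground-truth table written by [write_dataset()]
#'
#' @param dir Directory holding `truth.tsv`.
#' @return A `sim_truth` list with `genes` and `pairs` tibbles.
#' @export
read_truth <- function(dir) {
  path <- file.path(dir, "truth.tsv")
  if (!file.exists(path)) rlang::abort(paste0("missing file: ", path))
  genes <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  pairs <- genes |>
    dplyr::filter(.data$subgenome == "A") |>
    dplyr::transmute(pair_id = .data$pair_id, a_gene = .data$gene_id,
                     divergence = .data$divergence)
  c_side <- genes |>
    dplyr::filter(.data$subgenome == "C") |>
    dplyr::select(pair_id = "pair_id", c_gene = "gene_id")
  pairs <- dplyr::left_join(pairs, c_side, by = "pair_id")
  structure(list(
    genes = genes[, c("gene_id", "pair_id", "subgenome", "dependence",
                      "rate_parent", "rate_hybrid", "length_bp")],
    pairs = pairs[, c("pair_id", "a_gene", "c_gene", "divergence")]
  ), class = "sim_truth")
}
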