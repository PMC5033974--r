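#' Assemble and validate an expression dataset
#'
#' Bundles the four tables the pipeline consumes: a gene-by-sample count (or
#' FPKM) matrix in wide-tibble form, a sample sheet, the homoeolog-pair table
#' linking each A-subgenome gene to its C-subgenome partner, and gene lengths.
#'
#' @param counts Data frame: `gene_id` plus one numeric column per sample.
#'   May be `NULL` if `fpkm` is supplied directly.
#' @param samples Data frame: `sample_id`, `genotype`, `replicate`, and
#'   optionally `total_reads` (total mapped reads of the whole transcriptome;
#'   used as the FPKM denominator — the gene matrix typically covers only the
#'   homoeolog pairs, a subset of the library).
#' @param pairs Data frame: `pair_id`, `a_gene`, `c_gene`.
#' @param lengths Data frame: `gene_id`, `length_bp` (> 0).
#' @param fpkm Optional precomputed FPKM matrix, same shape as `counts`.
#' @return A list of class `expression_dataset`.
#' @export
expression_dataset <- function(counts = NULL, samples, pairs, lengths,
                               fpkm = NULL) {
  if (is.null(counts) && is.null(fpkm)) {
    rlang::abort("supply at least one of counts or fpkm")
  }
  samples <- tibble::as_tibble(samples)
  pairs <- tibble::as_tibble(pairs)
  lengths <- tibble::as_tibble(lengths)
  for (nm in c("sample_id", "genotype", "replicate")) {
    if (!nm %in% names(samples)) {
      rlang::abort(paste0("sample sheet is missing column ", nm))
    }
  }
  if (anyDuplicated(samples$sample_id)) {
    rlang::abort("duplicated sample identifiers")
  }
  check_matrix <- function(m, what) {
    m <- tibble::as_tibble(m)
    if (!"gene_id" %in% names(m)) {
      rlang::abort(paste0(what, " matrix needs a gene_id column"))
    }
    if (anyDuplicated(m$gene_id)) {
      rlang::abort(paste0("duplicated gene identifiers in ", what, " matrix"))
    }
    extra <- setdiff(samples$sample_id, names(m))
    if (length(extra) > 0) {
      rlang::abort(paste0("sample(s) missing from ", what, " matrix: ",
                          paste(extra, collapse = ", ")))
    }
    m[, c("gene_id", samples$sample_id)]
  }
  if (!is.null(counts)) counts <- check_matrix(counts, "count")
  if (!is.null(fpkm)) fpkm <- check_matrix(fpkm, "fpkm")
  gene_ids <- if (!is.null(counts)) counts$gene_id else fpkm$gene_id
  missing_pairs <- setdiff(c(pairs$a_gene, pairs$c_gene), gene_ids)
  if (length(missing_pairs) > 0) {
    rlang::abort(paste0(length(missing_pairs),
                        " pair member(s) absent from the expression matrix, e.g. ",
                        missing_pairs[1]))
  }
  if (any(lengths$length_bp <= 0)) {
    bad <- lengths$gene_id[which(lengths$length_bp <= 0)[1]]
    rlang::abort(paste0("non-positive gene length for ", bad))
  }
  structure(list(counts = counts, fpkm = fpkm, samples = samples,
                 pairs = pairs, lengths = lengths),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  ng <- if (!is.null(x$counts)) nrow(x$counts) else nrow(x$fpkm)
  cat("<expression_dataset> ", ng, " genes x ", nrow(x$samples),
      " samples (", length(unique(x$samples$genotype)), " genotypes), ",
      nrow(x$pairs), " homoeolog pairs\n", sep = "")
  invisible(x)
}

#' Compute FPKM from counts, gene lengths and mapped totals
#'
#' `FPKM[g, s] = 1e9 * counts[g, s] / (total[s] * length[g])` — fragments per
#' kilobase of transcript per million mapped reads.
#'
#' @param counts Data frame: `gene_id` plus one numeric column per sample.
#' @param lengths Data frame: `gene_id`, `length_bp`; every gene in `counts`
#'   must be present with positive length.
#' @param totals Optional named numeric vector of per-sample total mapped
#'   reads. Defaults to the column sums of `counts`, which is only correct
#'   when the matrix covers the whole transcriptome.
#' @return Tibble of FPKM values, same shape as `counts`.
#' @examples
#' counts <- tibble::tibble(gene_id = "g1", s1 = 10)
#' lengths <- tibble::tibble(gene_id = "g1", length_bp = 1000)
#' compute_fpkm(counts, lengths, c(s1 = 1e6)) # 10
#' @export
compute_fpkm <- function(counts, lengths, totals = NULL) {
  counts <- tibble::as_tibble(counts)
  smp <- setdiff(names(counts), "gene_id")
  len <- lengths$length_bp[match(counts$gene_id, lengths$gene_id)]
  if (anyNA(len)) {
    bad <- counts$gene_id[which(is.na(len))[1]]
    rlang::abort(paste0("no length for gene ", bad))
  }
  if (any(len <= 0)) {
    bad <- counts$gene_id[which(len <= 0)[1]]
    rlang::abort(paste0("non-positive length for gene ", bad))
  }
  mat <- as.matrix(counts[, smp])
  if (is.null(totals)) {
    totals <- colSums(mat)
  } else {
    missing <- setdiff(smp, names(totals))
    if (length(missing) > 0) {
      rlang::abort(paste0("no mapped-read total for sample(s): ",
                          paste(missing, collapse = ", ")))
    }
    totals <- totals[smp]
  }
  if (any(totals <= 0)) {
    bad <- smp[which(totals <= 0)[1]]
    rlang::abort(paste0("non-positive mapped-read total for sample ", bad))
  }
  fpkm <- 1e9 * sweep(mat, 2, totals, "/") / len
  dplyr::bind_cols(tibble::tibble(gene_id = counts$gene_id),
                   tibble::as_tibble(fpkm))
}

#' Dataset FPKM, computing it from counts when absent
#'
#' Returns the dataset's FPKM matrix, using a stored matrix if present and
#' otherwise applying [compute_fpkm()] with the sample sheet's `total_reads`
#' (falling back to column sums).
#'
#' @param dataset An [expression_dataset()].
#' @return Tibble of FPKM values.
#' @export
dataset_fpkm <- function(dataset) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (!is.null(dataset$fpkm)) return(dataset$fpkm)
  totals <- NULL
  if ("total_reads" %in% names(dataset$samples)) {
    totals <- stats::setNames(dataset$samples$total_reads,
                              dataset$samples$sample_id)
  }
  compute_fpkm(dataset$counts, dataset$lengths, totals)
}

#' Average replicate FPKM into one column per genotype
#'
#' @param fpkm Data frame: `gene_id` plus one column per sample.
#' @param samples Sample sheet mapping `sample_id` to `genotype`.
#' @param genotypes Optional character vector fixing the genotype column
#'   order; defaults to order of first appearance in the sample sheet.
#' @return Tibble: `gene_id` plus one replicate-averaged column per genotype.
#' @export
average_replicates <- function(fpkm, samples, genotypes = NULL) {
  fpkm <- tibble::as_tibble(fpkm)
  genotypes <- genotypes %||% unique(samples$genotype)
  out <- tibble::tibble(gene_id = fpkm$gene_id)
  for (g in genotypes) {
    ids <- samples$sample_id[samples$genotype == g]
    if (length(ids) == 0) {
      rlang::abort(paste0("genotype ", g, " has no samples"))
    }
    missing <- setdiff(ids, names(fpkm))
    if (length(missing) > 0) {
      rlang::abort(paste0("sample(s) absent from matrix: ",
                          paste(missing, collapse = ", ")))
    }
    out[[g]] <- rowMeans(as.matrix(fpkm[, ids, drop = FALSE]))
  }
  out
}

#' Keep homoeolog pairs expressed in both diploid parents
#'
#' A pair is retained iff the A member's FPKM in the AA parent *and* the C
#' member's FPKM in the CC parent are strictly greater than `threshold`
#' (default 1.0). Pairs weakly expressed in either progenitor carry no usable
#' dosage signal and are dropped before all downstream analysis.
#'
#' @param pairs Pair table (`pair_id`, `a_gene`, `c_gene`).
#' @param geno_means Genotype-mean FPKM from [average_replicates()]; must
#'   contain the parental columns.
#' @param threshold Strict lower FPKM bound; default 1.0.
#' @param parents Names of the pure A and pure C parental genotypes.
#' @return The retained subset of `pairs`, with a `report` attribute (list:
#'   `n_input`, `n_retained`, `n_removed`, `pct_removed` rounded to the
#'   nearest integer percent) retrievable via [filter_report()].
#' @examples
#' gm <- tibble::tibble(gene_id = c("a1", "c1"), AA = c(22.22, 0), CC = c(0, 15))
#' pr <- tibble::tibble(pair_id = "p1", a_gene = "a1", c_gene = "c1")
#' filter_report(filter_expressed_pairs(pr, gm))
#' @export
filter_expressed_pairs <- function(pairs, geno_means, threshold = 1,
                                   parents = c(A = "AA", C = "CC")) {
  missing <- setdiff(parents, names(geno_means))
  if (length(missing) > 0) {
    rlang::abort(paste0("parental genotype(s) absent from matrix: ",
                        paste(missing, collapse = ", ")))
  }
  a_fpkm <- geno_means[[parents[["A"]]]][match(pairs$a_gene, geno_means$gene_id)]
  c_fpkm <- geno_means[[parents[["C"]]]][match(pairs$c_gene, geno_means$gene_id)]
  if (anyNA(a_fpkm) || anyNA(c_fpkm)) {
    rlang::abort("pair member(s) absent from the genotype-mean matrix")
  }
  keep <- a_fpkm > threshold & c_fpkm > threshold
  out <- pairs[keep, ]
  report <- list(
    n_input = nrow(pairs),
    n_retained = sum(keep),
    n_removed = sum(!keep),
    pct_removed = round(100 * sum(!keep) / max(1, nrow(pairs)))
  )
  attr(out, "report") <- report
  out
}

#' Removal report of a pair filter
#'
#' @param pairs Result of [filter_expressed_pairs()].
#' @return The report list stored by the filter.
#' @export
filter_report <- function(pairs) {
  rep <- attr(pairs, "report")
  if (is.null(rep)) rlang::abort("no filter report attached")
  rep
}

#' Mid-parent expression value per gene
#'
#' `MPV[g] = (FPKM[g, AA] + FPKM[g, CC]) / 2` — the additivity baseline
#' against which hybrid expression is compared. For a subgenome-specific gene
#' the non-carrier parent contributes whatever the matrix holds (0 in
#' synthetic data), so its MPV is about half its carrier-parent level.
#'
#' @param geno_means Genotype-mean FPKM containing the parental columns.
#' @inheritParams filter_expressed_pairs
#' @return Tibble: `gene_id`, `mpv`.
#' @examples
#' gm <- tibble::tibble(gene_id = "g", AA = 22.22, CC = 0)
#' compute_mpv(gm) # 11.11
#' @export
compute_mpv <- function(geno_means, parents = c(A = "AA", C = "CC")) {
  missing <- setdiff(parents, names(geno_means))
  if (length(missing) > 0) {
    rlang::abort(paste0("parental genotype(s) absent from matrix: ",
                        paste(missing, collapse = ", ")))
  }
  tibble::tibble(
    gene_id = geno_means$gene_id,
    mpv = (geno_means[[parents[["A"]]]] + geno_means[[parents[["C"]]]]) / 2
  )
}
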