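#' Fold change of hybrid expression relative to the mid-parent value
#'
#' `FC[g, G] = mean FPKM[g, G] / MPV[g]`. Genes with MPV = 0 cannot be
#' compared to the parental baseline; they are flagged (`zero_mpv`) and
#' excluded from all downstream summaries rather than erroring.
#'
#' @param geno_means Genotype-mean FPKM from [average_replicates()].
#' @param mpv Mid-parent values from [compute_mpv()].
#' @param genotypes Genotypes to evaluate; defaults to every genotype column
#'   present other than the parents used for the MPV.
#' @inheritParams filter_expressed_pairs
#' @return A long tibble of class `fold_change_table`: `gene_id`, `genotype`,
#'   `fc`, `zero_mpv`.
#' @examples
#' gm <- tibble::tibble(gene_id = "g", AA = 10, CC = 0, AAC = 20 / 3)
#' fold_change(gm, compute_mpv(gm)) # FC in AAC = 4/3
#' @export
fold_change <- function(geno_means, mpv, genotypes = NULL,
                        parents = c(A = "AA", C = "CC")) {
  genotypes <- genotypes %||%
    setdiff(names(geno_means), c("gene_id", parents))
  m <- mpv$mpv[match(geno_means$gene_id, mpv$gene_id)]
  if (anyNA(m)) rlang::abort("MPV missing for some genes")
  out <- purrr::map_dfr(genotypes, function(g) {
    tibble::tibble(
      gene_id = geno_means$gene_id,
      genotype = g,
      fc = ifelse(m > 0, geno_means[[g]] / m, NA_real_),
      zero_mpv = m == 0
    )
  })
  class(out) <- c("fold_change_table", class(out))
  out
}

#' Median and interquartile bounds of fold changes
#'
#' Summarises unflagged fold changes per genotype (optionally further by gene
#' annotation, e.g. subgenome or dosage class) with the linear-interpolation
#' quantile convention (R type 7), which is recorded in the output's
#' `quantile_type` attribute so summaries are bit-reproducible.
#'
#' @param fc A `fold_change_table` from [fold_change()].
#' @param gene_info Optional tibble keyed by `gene_id` with annotation
#'   columns to join before grouping (e.g. `subgenome`, `class`).
#' @param by Grouping columns; default `genotype` plus any annotation columns
#'   supplied.
#' @return A tibble with `median`, `q1`, `q3` and `n` per group.
#' @export
summarize_fc <- function(fc, gene_info = NULL, by = NULL) {
  tbl <- dplyr::filter(tibble::as_tibble(fc), !.data$zero_mpv,
                       is.finite(.data$fc))
  if (!is.null(gene_info)) {
    tbl <- dplyr::inner_join(tbl, gene_info, by = "gene_id")
    by <- by %||% c("genotype", setdiff(names(gene_info), "gene_id"))
  } else {
    by <- by %||% "genotype"
  }
  if (nrow(tbl) == 0) rlang::abort("no unflagged fold-change values")
  out <- tbl |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      median = stats::median(.data$fc),
      q1 = stats::quantile(.data$fc, 0.25, type = 7, names = FALSE),
      q3 = stats::quantile(.data$fc, 0.75, type = 7, names = FALSE),
      n = dplyr::n(), .groups = "drop")
  attr(out, "quantile_type") <- 7L
  out
}

#' Wilcoxon comparison of two expression (or fold-change) samples
#'
#' Paired mode runs the signed-rank test on homoeolog differences (zero
#' differences dropped; when every difference is zero there is no evidence
#' against the null and `p = 1` is returned). Unpaired mode runs the
#' rank-sum test. Both are two-sided.
#'
#' @param values_a,values_b Numeric vectors; equal length required when
#'   `paired = TRUE`.
#' @param paired Signed-rank on differences (`TRUE`) or rank-sum (`FALSE`).
#' @return One-row tibble: `statistic`, `p`, `method`, `n_a`, `n_b`.
#' @examples
#' compare_subgenomes(1:20, 101:120) # p << 1e-6
#' @export
compare_subgenomes <- function(values_a, values_b, paired = FALSE) {
  if (paired && length(values_a) != length(values_b)) {
    rlang::abort("paired comparison requires equal-length vectors")
  }
  if (paired && all(values_a == values_b)) {
    return(tibble::tibble(statistic = 0, p = 1,
                          method = "Wilcoxon signed-rank",
                          n_a = length(values_a), n_b = length(values_b)))
  }
  ht <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                            paired = paired,
                                            alternative = "two.sided"))
  tibble::tibble(
    statistic = unname(ht$statistic),
    p = ht$p.value,
    method = if (paired) "Wilcoxon signed-rank" else "Wilcoxon rank-sum",
    n_a = length(values_a), n_b = length(values_b)
  )
}

#' Fold-change binning by dosage class
#'
#' For each genotype and each class label (Ad, Ai, Cd, Ci), counts fold
#' changes inside the closed interval `[bounds[1], bounds[2]]` versus
#' strictly outside it, and tests dependent-vs-independent bin membership per
#' subgenome with a 2x2 chi-square (no continuity correction). Dependent
#' genes track their parents and concentrate inside the band; compensated
#' genes scatter outside it.
#'
#' @param fc A `fold_change_table`.
#' @param results A `dosage_result` from [classify_dosage()] supplying
#'   `subgenome` and `class` per gene.
#' @param bounds Closed fold-change band; default `c(0.5, 1.5)`.
#' @return A list of class `fc_bins`: `bins` (tibble `genotype`,
#'   `class_label`, `n_inside`, `n_outside`, `pct_inside`) and `tests`
#'   (tibble `genotype`, `subgenome`, `statistic`, `p`).
#' @export
bin_fc_by_class <- function(fc, results, bounds = c(0.5, 1.5)) {
  stopifnot(length(bounds) == 2, bounds[1] < bounds[2])
  info <- tibble::tibble(gene_id = results$gene_id,
                         subgenome = results$subgenome,
                         class = results$class)
  tbl <- tibble::as_tibble(fc) |>
    dplyr::filter(!.data$zero_mpv, is.finite(.data$fc)) |>
    dplyr::inner_join(info, by = "gene_id") |>
    dplyr::mutate(
      inside = .data$fc >= bounds[1] & .data$fc <= bounds[2],
      class_label = paste0(.data$subgenome,
                           ifelse(.data$class == "dependent", "d", "i")))
  bins <- tbl |>
    dplyr::group_by(.data$genotype, .data$class_label) |>
    dplyr::summarise(n_inside = sum(.data$inside),
                     n_outside = sum(!.data$inside),
                     .groups = "drop") |>
    dplyr::mutate(pct_inside = 100 * .data$n_inside /
                    (.data$n_inside + .data$n_outside))
  tests <- tbl |>
    dplyr::group_by(.data$genotype, .data$subgenome) |>
    dplyr::summarise(
      statistic = chisq_2x2(.data$inside, .data$class == "dependent")["statistic"],
      p = chisq_2x2(.data$inside, .data$class == "dependent")["p"],
      .groups = "drop")
  structure(list(bins = bins, tests = tests, bounds = bounds),
            class = "fc_bins")
}

# 2x2 chi-square without continuity correction; NA when a margin is empty
chisq_2x2 <- function(x, y) {
  tab <- table(factor(x, levels = c(FALSE, TRUE)),
               factor(y, levels = c(FALSE, TRUE)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(c(statistic = NA_real_, p = NA_real_))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  c(statistic = unname(ct$statistic), p = ct$p.value)
}
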