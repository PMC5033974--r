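#' Histogram of dosage-correlation r-squared by subgenome
#'
#' Mirrors the classic bimodal picture: dependent genes pile up near
#' r2 = 1, compensated genes near 0, with the emergent per-subgenome cutoff
#' drawn as a dashed line.
#'
#' @param object A `dosage_result` from [classify_dosage()].
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dosage_result
#' @export
autoplot.dosage_result <- function(object, bins = 40, ...) {
  cut <- attr(object, "r2_cutoff")
  cut_df <- tibble::tibble(subgenome = names(cut), cutoff = unname(cut))
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$r2, fill = .data$class)) +
    ggplot2::geom_histogram(bins = bins, boundary = 0) +
    ggplot2::geom_vline(data = cut_df[!is.na(cut_df$cutoff), ],
                        ggplot2::aes(xintercept = .data$cutoff),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~subgenome) +
    ggplot2::labs(x = expression(r^2), y = "genes",
                  title = "Dosage-expression correlation by subgenome")
}

#' Fold-change distributions per genotype and subgenome
#'
#' Box plots of fold change relative to the mid-parent value, the package's
#' analogue of the classic dosage-series figure: balanced genotypes sit at
#' FC = 1 for both subgenomes while triploids split above/below 1 with their
#' dosage excess.
#'
#' @param fc A `fold_change_table` from [fold_change()].
#' @param results A `dosage_result` supplying each gene's subgenome.
#' @return A ggplot object.
#' @export
plot_fc_distribution <- function(fc, results) {
  info <- tibble::tibble(gene_id = results$gene_id,
                         subgenome = results$subgenome)
  tbl <- tibble::as_tibble(fc) |>
    dplyr::filter(!.data$zero_mpv, is.finite(.data$fc)) |>
    dplyr::inner_join(info, by = "gene_id")
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$genotype, y = .data$fc,
                                    fill = .data$subgenome)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::coord_cartesian(ylim = c(0, 3)) +
    ggplot2::labs(x = NULL, y = "fold change vs mid-parent value")
}

#' Observed vs expected pair-group percentages
#'
#' @param object A `pair_groups` object from [group_pairs()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pair_groups
#' @export
autoplot.pair_groups <- function(object, ...) {
  long <- tidyr::pivot_longer(object$summary,
                              c("observed_pct", "expected_pct"),
                              names_to = "kind", values_to = "pct")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$pct,
                                     fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "% of pairs",
                  title = "Dosage pair groups: observed vs independence")
}

#' Cis/trans category composition
#'
#' @param object A `cis_trans_calls` tibble from [call_cis_trans()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cis_trans_calls
#' @export
autoplot.cis_trans_calls <- function(object, ...) {
  cats <- c("no_effect", "only_cis", "only_trans", "cis_trans")
  tbl <- tibble::as_tibble(object) |>
    dplyr::mutate(category = factor(.data$category, levels = cats))
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$category)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = NULL, y = "pairs",
                  title = paste0("Cis/trans categories in ",
                                 object$genotype[1]))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
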