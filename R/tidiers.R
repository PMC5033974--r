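#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a dosage classification result
#'
#' @param x A `dosage_result` from [classify_dosage()].
#' @param ... Unused.
#' @return A plain tibble of the per-gene results.
#' @method tidy dosage_result
#' @export
tidy.dosage_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "dosage_result")
  tibble::as_tibble(out)
}

#' One-row summary of a dosage classification
#'
#' @inheritParams tidy.dosage_result
#' @return Tibble with gene counts, dependent fractions per subgenome, the
#'   empirical r-squared cutoffs and the alpha used.
#' @method glance dosage_result
#' @export
glance.dosage_result <- function(x, ...) {
  a <- x$subgenome == "A"
  tibble::tibble(
    n_genes = nrow(x),
    n_dependent_a = sum(x$class[a] == "dependent"),
    n_dependent_c = sum(x$class[!a] == "dependent"),
    frac_dependent_a = mean(x$class[a] == "dependent"),
    frac_dependent_c = mean(x$class[!a] == "dependent"),
    n_inverse = sum(x$inverse_flag),
    r2_cutoff_a = attr(x, "r2_cutoff")[["A"]],
    r2_cutoff_c = attr(x, "r2_cutoff")[["C"]],
    alpha = attr(x, "alpha")
  )
}

#' @method tidy pair_groups
#' @export
tidy.pair_groups <- function(x, ...) x$summary

#' @method glance pair_groups
#' @export
glance.pair_groups <- function(x, ...) {
  tibble::tibble(
    n_pairs = sum(x$summary$n),
    frac_dependent_a = x$marginals[["A_dependent"]],
    frac_dependent_c = x$marginals[["C_dependent"]],
    statistic = x$chisq$statistic,
    df = x$chisq$df,
    p_value = x$chisq$p
  )
}

#' @method tidy cis_trans_calls
#' @export
tidy.cis_trans_calls <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "cis_trans_calls")
  tibble::as_tibble(out)
}

#' Category composition of a cis/trans call set
#'
#' @param x A `cis_trans_calls` tibble from [call_cis_trans()].
#' @param ... Unused.
#' @return One row per call set: pair total, count and percentage per
#'   category, alpha and the balance-test mode.
#' @method glance cis_trans_calls
#' @export
glance.cis_trans_calls <- function(x, ...) {
  cats <- c("no_effect", "only_cis", "only_trans", "cis_trans")
  tb <- table(factor(x$category, levels = cats))
  out <- tibble::tibble(genotype = x$genotype[1], n_pairs = sum(tb))
  for (cat in cats) {
    out[[paste0("n_", cat)]] <- unname(tb[[cat]])
    out[[paste0("pct_", cat)]] <- 100 * unname(tb[[cat]]) / sum(tb)
  }
  out$alpha <- attr(x, "alpha")
  out$balance_mode <- attr(x, "balance_mode")
  out
}

#' @method tidy fc_bins
#' @export
tidy.fc_bins <- function(x, ...) x$bins

#' @method glance fc_bins
#' @export
glance.fc_bins <- function(x, ...) {
  tibble::tibble(lower = x$bounds[1], upper = x$bounds[2],
                 n_groups = nrow(x$bins))
}
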