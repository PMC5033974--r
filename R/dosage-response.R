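#' Pearson correlation between expression and relative dosage
#'
#' Correlates one gene's per-genotype expression with the relative-dosage
#' series and returns the coefficient, its square, and a two-sided p-value
#' from the t transform `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2`
#' degrees of freedom. A constant (zero-variance) expression vector — the
#' perfectly compensated case — is assigned `r = 0`, `p = 1`.
#'
#' @param expr Numeric vector of per-genotype expression values.
#' @param dosage Numeric vector of matching relative dosages (same length,
#'   at least 3 points).
#' @return One-row tibble: `r`, `r2`, `p`.
#' @examples
#' dosage_correlation(c(22.22, 11.37, 7.41, 8.98, 6.34),
#'                    c(1, 2/3, 1/2, 1/2, 1/3)) # r = 0.97
#' @export
dosage_correlation <- function(expr, dosage) {
  if (length(expr) != length(dosage)) {
    rlang::abort("expr and dosage must have equal length")
  }
  if (length(expr) < 3) {
    rlang::abort("at least 3 genotype points are required")
  }
  if (!all(is.finite(expr)) || !all(is.finite(dosage))) {
    rlang::abort("expression and dosage values must be finite")
  }
  res <- correlation_screen(matrix(expr, nrow = 1), dosage)
  tibble::tibble(r = res$r, r2 = res$r2, p = res$p)
}

# vectorised Pearson + t-test over the rows of an expression matrix
correlation_screen <- function(mat, dosage) {
  n <- length(dosage)
  xc <- dosage - mean(dosage)
  mc <- mat - rowMeans(mat)
  sx <- sqrt(sum(xc^2))
  sy <- sqrt(rowSums(mc^2))
  r <- as.vector(mc %*% xc) / (sx * sy)
  const <- sy == 0
  r[const] <- 0
  r <- pmin(1, pmax(-1, r))
  tstat <- r * sqrt(n - 2) / sqrt(pmax(0, 1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[r^2 >= 1] <- 0
  p[const] <- 1
  list(r = r, r2 = r^2, p = p)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (via [stats::p.adjust()]), with
#' input validation: `p_adj(i) = min over j >= i of min(1, m * p(j) / j)` on
#' the ascending sort, restored to input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @examples
#' adjust_bh(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
adjust_bh <- function(p) {
  # tolerate p = 1 + eps from floating-point in upstream exact tests
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1 + 1e-8)) {
    rlang::abort("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pmin(p, 1), method = "BH")
}

#' Classify genes as dosage dependent or independent
#'
#' For every gene of a homoeolog pair, correlates its replicate-averaged FPKM
#' across the genotypes carrying its subgenome (the non-carrier parent is
#' excluded) against the relative dosage series, adjusts p-values by
#' Benjamini-Hochberg within each subgenome family, and labels a gene
#' *dependent* when `p_adj < alpha` with `r > 0`. Significant negative
#' correlations are not dosage dependence; they are flagged as inverse-dosage
#' genes (`inverse_flag`) and remain in the independent class.
#'
#' The empirical r-squared cutoff — the smallest `r2` among dependent genes of
#' a subgenome — is reported per subgenome. It is an emergent consequence of
#' the adaptive BH threshold on each dataset, not a tunable constant.
#'
#' @param geno_means Genotype-mean FPKM from [average_replicates()].
#' @param pairs Pair table (typically after [filter_expressed_pairs()]).
#' @param panel Genotype panel; default [build_genotype_panel()].
#' @param alpha Significance level on adjusted p-values; default 0.05.
#' @return A tibble of class `dosage_result`: `gene_id`, `subgenome`, `r`,
#'   `r2`, `p`, `p_adj`, `class`, `inverse_flag`; attributes `alpha` and
#'   `r2_cutoff` (named per subgenome, `NA` when no gene is dependent).
#' @seealso [group_pairs()], [detect_inverse_dosage()], [glance.dosage_result()]
#' @export
classify_dosage <- function(geno_means, pairs, panel = build_genotype_panel(),
                            alpha = 0.05) {
  if (nrow(pairs) == 0) rlang::abort("empty pair table")
  one_side <- function(genes, subgenome) {
    dv <- dosage_vector(panel, subgenome)
    missing <- setdiff(dv$genotype, names(geno_means))
    if (length(missing) > 0) {
      rlang::abort(paste0("genotype(s) absent from matrix: ",
                          paste(missing, collapse = ", ")))
    }
    idx <- match(genes, geno_means$gene_id)
    if (anyNA(idx)) {
      rlang::abort("pair member(s) absent from the genotype-mean matrix")
    }
    mat <- as.matrix(geno_means[idx, dv$genotype])
    res <- correlation_screen(mat, dv$dosage)
    p_adj <- adjust_bh(res$p)
    tibble::tibble(
      gene_id = genes,
      subgenome = subgenome,
      r = res$r, r2 = res$r2, p = res$p, p_adj = p_adj,
      class = ifelse(p_adj < alpha & res$r > 0, "dependent", "independent"),
      inverse_flag = res$r < 0 & p_adj < alpha
    )
  }
  out <- dplyr::bind_rows(one_side(pairs$a_gene, "A"),
                          one_side(pairs$c_gene, "C"))
  cutoff <- vapply(c(A = "A", C = "C"), function(s) {
    dep <- out$r2[out$subgenome == s & out$class == "dependent"]
    if (length(dep) == 0) NA_real_ else min(dep)
  }, numeric(1))
  attr(out, "alpha") <- alpha
  attr(out, "r2_cutoff") <- cutoff
  class(out) <- c("dosage_result", class(out))
  out
}

#' Group homoeolog pairs by the dosage classes of their members
#'
#' Combines the A- and C-member classes of every pair into the four groups
#' AdCd, AdCi, AiCd, AiCi, compares observed group counts with the
#' expectation under independence (product of the two marginal class
#' proportions), and tests the fit with a chi-square goodness-of-fit test
#' (df = 3, no continuity correction).
#'
#' @param results A `dosage_result` from [classify_dosage()].
#' @param pairs The pair table the classification was run on.
#' @return A list of class `pair_groups`: `pairs` (tibble `pair_id`,
#'   `a_class`, `c_class`, `group`), `summary` (tibble `group`, `n`,
#'   `observed_pct`, `expected_pct`), `marginals`, and `chisq`
#'   (list `statistic`, `df`, `p`).
#' @export
group_pairs <- function(results, pairs) {
  a <- results[results$subgenome == "A", ]
  c_ <- results[results$subgenome == "C", ]
  a_class <- a$class[match(pairs$a_gene, a$gene_id)]
  c_class <- c_$class[match(pairs$c_gene, c_$gene_id)]
  if (anyNA(a_class) || anyNA(c_class)) {
    rlang::abort("unclassified pair member(s); classify both subgenomes first")
  }
  short <- function(cl) ifelse(cl == "dependent", "d", "i")
  grp <- paste0("A", short(a_class), "C", short(c_class))
  levels <- c("AdCd", "AdCi", "AiCd", "AiCi")
  obs <- as.vector(table(factor(grp, levels = levels)))
  n_pairs_total <- nrow(pairs)
  pa <- mean(a_class == "dependent")
  pc <- mean(c_class == "dependent")
  expected_prop <- c(pa * pc, pa * (1 - pc), (1 - pa) * pc,
                     (1 - pa) * (1 - pc))
  chisq <- if (all(expected_prop > 0)) {
    ct <- suppressWarnings(stats::chisq.test(obs, p = expected_prop,
                                             correct = FALSE))
    list(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p = ct$p.value)
  } else {
    list(statistic = NA_real_, df = 3, p = NA_real_)
  }
  structure(list(
    pairs = tibble::tibble(pair_id = pairs$pair_id, a_class = a_class,
                           c_class = c_class, group = grp),
    summary = tibble::tibble(group = levels, n = obs,
                             observed_pct = 100 * obs / n_pairs_total,
                             expected_pct = 100 * expected_prop),
    marginals = c(A_dependent = pa, C_dependent = pc),
    chisq = chisq
  ), class = "pair_groups")
}

#' @export
print.pair_groups <- function(x, ...) {
  cat("<pair_groups> ", sum(x$summary$n), " pairs\n", sep = "")
  print(x$summary)
  cat(sprintf("chi-square GOF: X2 = %.3f, df = %d, p = %.3g\n",
              x$chisq$statistic, x$chisq$df, x$chisq$p))
  invisible(x)
}

#' Inverse-dosage genes (negative expression-dosage correlation)
#'
#' Extracts genes whose expression falls as relative dosage rises. Genes with
#' `r < 0` are listed; the significant subset additionally has
#' `p_adj < alpha` — the alpha stored on the classification result.
#'
#' @param results A `dosage_result` from [classify_dosage()].
#' @return A list: `genes` (tibble of negative-r genes with `significant`
#'   flag) and `summary` (per-subgenome counts of negative and significantly
#'   inverse genes).
#' @export
detect_inverse_dosage <- function(results) {
  neg <- results[results$r < 0, ]
  neg <- tibble::as_tibble(neg)
  neg$significant <- neg$inverse_flag
  summary <- neg |>
    dplyr::group_by(.data$subgenome) |>
    dplyr::summarise(n_negative = dplyr::n(),
                     n_significant = sum(.data$significant),
                     .groups = "drop")
  list(genes = neg[, c("gene_id", "subgenome", "r", "r2", "p", "p_adj",
                       "significant")],
       summary = summary)
}
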