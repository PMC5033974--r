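#' Log2 homoeolog-ratio components of cis/trans divergence
#'
#' For a homoeolog pair with parental expression `PA` (A gene in the AA
#' parent) and `PC` (C gene in the CC parent) and hybrid expression `F1A`,
#' `F1C`, computes `A = log2(PA / PC)` (total divergence, cis plus trans),
#' `B = log2(F1A / F1C)` (cis component: in a common hybrid nucleus the two
#' homoeologs see identical trans factors) and `A - B` (trans component).
#' Zeros are replaced by `pseudocount` before taking logs; non-zero values
#' are left untouched so exact ratios are preserved.
#'
#' @param pa,pc,f1a,f1c Non-negative expression values (vectors recycle).
#' @param pseudocount Positive stand-in for zero values; default 0.5.
#' @return Tibble: `a_stat`, `b_stat`, `trans_stat` with
#'   `trans_stat = a_stat - b_stat` exactly.
#' @examples
#' log_ratio_components(8, 2, 8, 2) # pure cis: A = B = 2, A - B = 0
#' log_ratio_components(8, 2, 4, 4) # pure trans: A = 2, B = 0
#' @export
log_ratio_components <- function(pa, pc, f1a, f1c, pseudocount = 0.5) {
  vals <- list(pa = pa, pc = pc, f1a = f1a, f1c = f1c)
  if (any(unlist(vals) < 0, na.rm = TRUE)) {
    rlang::abort("expression values must be non-negative")
  }
  if (pseudocount <= 0) rlang::abort("pseudocount must be positive")
  stab <- lapply(vals, function(v) ifelse(v == 0, pseudocount, v))
  a_stat <- log2(stab$pa / stab$pc)
  b_stat <- log2(stab$f1a / stab$f1c)
  tibble::tibble(a_stat = a_stat, b_stat = b_stat,
                 trans_stat = a_stat - b_stat)
}

#' Fisher test of parental versus hybrid homoeolog count ratios
#'
#' Two-sided Fisher's exact test on the 2x2 table `[[PA, PC], [F1A, F1C]]` of
#' replicate-summed read counts: does the A:C ratio differ between the
#' parental libraries and the hybrid (`A != B`)?
#'
#' @param pa,pc,f1a,f1c Non-negative integer counts (single values).
#' @return Two-sided p-value.
#' @export
test_ratio_difference <- function(pa, pc, f1a, f1c) {
  counts <- c(pa, pc, f1a, f1c)
  if (any(counts < 0)) rlang::abort("counts must be non-negative")
  if (any(counts != round(counts))) {
    rlang::abort("counts must be integers; round or supply raw counts")
  }
  tab <- matrix(as.integer(round(counts)), nrow = 2, byrow = TRUE)
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}

#' Exact binomial test of hybrid homoeolog balance
#'
#' Tests `B = 0` — equal homoeolog output in the hybrid — by a two-sided
#' exact binomial test of `F1A` successes out of `F1A + F1C` trials against
#' `expected_a_fraction`. The default 1/2 reads the log-ratio literally;
#' passing the genotype's copy fraction (e.g. 2/3 in AAC) instead tests
#' balance after correcting for homoeolog copy number.
#'
#' @param f1a,f1c Non-negative integer counts.
#' @param expected_a_fraction Null A fraction in (0, 1); default 0.5.
#' @return List: `p` (two-sided p-value) and `undefined` (`TRUE` when both
#'   counts are zero, in which case `p = 1`).
#' @export
test_hybrid_balance <- function(f1a, f1c, expected_a_fraction = 0.5) {
  if (f1a < 0 || f1c < 0) rlang::abort("counts must be non-negative")
  if (f1a != round(f1a) || f1c != round(f1c)) {
    rlang::abort("counts must be integers")
  }
  if (expected_a_fraction <= 0 || expected_a_fraction >= 1) {
    rlang::abort("expected_a_fraction must lie strictly between 0 and 1")
  }
  if (f1a + f1c == 0) return(list(p = 1, undefined = TRUE))
  ht <- stats::binom.test(round(f1a), round(f1a + f1c),
                          p = expected_a_fraction,
                          alternative = "two.sided")
  list(p = ht$p.value, undefined = FALSE)
}

#' Four-way cis/trans category from the two adjusted tests
#'
#' Combines the adjusted significance of `A != B` (ratio difference) and
#' `B != 0` (hybrid imbalance) into the category a pair belongs to:
#'
#' | `A != B`? | `B != 0`? | category    |
#' |-----------|-----------|-------------|
#' | no        | yes       | `only_cis`  |
#' | yes       | no        | `only_trans`|
#' | no        | no        | `no_effect` |
#' | yes       | yes       | `cis_trans` |
#'
#' "Equal" means not significant at `alpha` after adjustment.
#'
#' @param p_diff_adj,p_b_adj Adjusted p-values (vectors recycle).
#' @param alpha Significance level; default 0.05.
#' @return Character vector of categories.
#' @examples
#' classify_cis_trans(0.8, 0.001) # only_cis
#' classify_cis_trans(0.001, 0.8) # only_trans
#' @export
classify_cis_trans <- function(p_diff_adj, p_b_adj, alpha = 0.05) {
  diff_sig <- p_diff_adj < alpha
  b_sig <- p_b_adj < alpha
  dplyr::case_when(
    !diff_sig & b_sig ~ "only_cis",
    diff_sig & !b_sig ~ "only_trans",
    !diff_sig & !b_sig ~ "no_effect",
    TRUE ~ "cis_trans"
  )
}

#' Call cis/trans regulatory categories for every pair in one hybrid genotype
#'
#' End-to-end caller: sums replicate counts per group (AA parent, CC parent,
#' hybrid), normalises the three group library sizes to the smallest before
#' rounding (the exact tests need counts on a common depth; the parental A
#' and C values come from different libraries), computes the log-ratio point
#' estimates from genotype-mean FPKM with a pseudocount, runs the Fisher
#' ratio-difference and binomial balance tests per pair, adjusts each test
#' family by Benjamini-Hochberg within the genotype, and assigns the four-way
#' category.
#'
#' @param dataset An [expression_dataset()] with counts.
#' @param genotype Hybrid genotype to call (must carry both subgenomes).
#' @param pairs Pair table; defaults to the dataset's pairs (apply
#'   [filter_expressed_pairs()] first for the analysis set).
#' @param panel Genotype panel; default [build_genotype_panel()].
#' @param alpha Significance level on adjusted p-values.
#' @param copy_correct If `TRUE`, the balance test's expected A fraction is
#'   the genotype's homoeolog copy fraction (2/3 in AAC, 1/3 in CCA) instead
#'   of 1/2, testing imbalance beyond what copy number alone explains.
#' @param pseudocount Zero replacement for the log ratios only; never applied
#'   to the exact tests.
#' @param geno_means Optional precomputed genotype-mean FPKM.
#' @return A tibble of class `cis_trans_calls`: `pair_id`, `genotype`,
#'   `a_stat`, `b_stat`, `trans_stat`, `p_diff`, `p_diff_adj`, `p_b`,
#'   `p_b_adj`, `category`; attributes `alpha` and `balance_mode`.
#' @export
call_cis_trans <- function(dataset, genotype, pairs = NULL,
                           panel = build_genotype_panel(), alpha = 0.05,
                           copy_correct = FALSE, pseudocount = 0.5,
                           geno_means = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (is.null(dataset$counts)) {
    rlang::abort("cis/trans calling needs a count matrix (exact tests)")
  }
  pairs <- pairs %||% dataset$pairs
  if (!genotype %in% hybrid_genotypes(panel)) {
    rlang::abort(paste0(genotype, " does not carry both subgenomes"))
  }
  samples <- dataset$samples
  parent_a <- parent_genotype(panel, "A")
  parent_c <- parent_genotype(panel, "C")
  groups <- list(pa = parent_a, pc = parent_c, f1 = genotype)
  counts <- dataset$counts
  totals <- if ("total_reads" %in% names(samples)) {
    stats::setNames(samples$total_reads, samples$sample_id)
  } else {
    stats::setNames(colSums(as.matrix(counts[, samples$sample_id])),
                    samples$sample_id)
  }
  group_counts <- lapply(groups, function(g) {
    ids <- samples$sample_id[samples$genotype == g]
    if (length(ids) == 0) rlang::abort(paste0("no samples for genotype ", g))
    list(counts = rowSums(as.matrix(counts[, ids, drop = FALSE])),
         total = sum(totals[ids]))
  })
  ref <- min(vapply(group_counts, `[[`, numeric(1), "total"))
  scaled <- lapply(group_counts, function(g) {
    round(g$counts * ref / g$total)
  })
  ia <- match(pairs$a_gene, counts$gene_id)
  ic <- match(pairs$c_gene, counts$gene_id)
  pa <- scaled$pa[ia]; pc <- scaled$pc[ic]
  f1a <- scaled$f1[ia]; f1c <- scaled$f1[ic]

  # point estimates from FPKM genotype means
  geno_means <- geno_means %||%
    average_replicates(dataset_fpkm(dataset), samples)
  gm_a <- match(pairs$a_gene, geno_means$gene_id)
  gm_c <- match(pairs$c_gene, geno_means$gene_id)
  stats_tbl <- log_ratio_components(
    geno_means[[parent_a]][gm_a], geno_means[[parent_c]][gm_c],
    geno_means[[genotype]][gm_a], geno_means[[genotype]][gm_c],
    pseudocount = pseudocount)

  # read counts scale with transcript length, so "equal expression" (B = 0)
  # corresponds to a length-weighted count split, not 1/2; the Fisher test
  # needs no correction because lengths cancel between its two rows
  len_a <- dataset$lengths$length_bp[match(pairs$a_gene,
                                           dataset$lengths$gene_id)]
  len_c <- dataset$lengths$length_bp[match(pairs$c_gene,
                                           dataset$lengths$gene_id)]
  if (anyNA(len_a) || anyNA(len_c)) {
    rlang::abort("gene length missing for some pair members")
  }
  ratio <- if (copy_correct) {
    relative_dosage(panel, genotype, "A") / relative_dosage(panel, genotype, "C")
  } else 1
  expected_a <- ratio * len_a / (ratio * len_a + len_c)

  n <- nrow(pairs)
  p_diff <- numeric(n)
  p_b <- numeric(n)
  for (i in seq_len(n)) {
    p_diff[i] <- test_ratio_difference(pa[i], pc[i], f1a[i], f1c[i])
    p_b[i] <- test_hybrid_balance(f1a[i], f1c[i], expected_a[i])$p
  }
  p_diff_adj <- adjust_bh(p_diff)
  p_b_adj <- adjust_bh(p_b)

  out <- tibble::tibble(
    pair_id = pairs$pair_id,
    genotype = genotype,
    a_stat = stats_tbl$a_stat,
    b_stat = stats_tbl$b_stat,
    trans_stat = stats_tbl$trans_stat,
    p_diff = p_diff, p_diff_adj = p_diff_adj,
    p_b = p_b, p_b_adj = p_b_adj,
    category = classify_cis_trans(p_diff_adj, p_b_adj, alpha)
  )
  attr(out, "alpha") <- alpha
  attr(out, "balance_mode") <- if (copy_correct) "copy_corrected" else "raw_half"
  class(out) <- c("cis_trans_calls", class(out))
  out
}

#' Cross-tabulate cis/trans categories against dosage pair groups
#'
#' Within the `only_cis` and `only_trans` sets, compares the observed counts
#' of AdCd and AiCi pairs with the expectation under independence
#' (category size times the group's overall proportion), using a 2x2
#' chi-square per cell with an enrichment direction flag.
#'
#' @param calls A `cis_trans_calls` tibble.
#' @param groups A `pair_groups` object from [group_pairs()] computed on the
#'   same pairs.
#' @return A tibble of class `cis_trans_crosstab`: `category`, `group`,
#'   `n_category`, `observed`, `expected`, `statistic`, `p`, `direction`
#'   (`"enriched"`/`"depleted"`).
#' @export
crosstab_categories <- function(calls, groups) {
  grp <- groups$pairs
  merged <- dplyr::inner_join(
    tibble::as_tibble(calls)[, c("pair_id", "category")],
    grp[, c("pair_id", "group")], by = "pair_id")
  if (nrow(merged) == 0) {
    rlang::abort("no shared pairs between categories and groups")
  }
  out <- list()
  for (cat in c("only_cis", "only_trans")) {
    in_cat <- merged$category == cat
    if (!any(in_cat)) {
      rlang::warn(paste0("empty category ", cat, "; omitted from cross-tab"))
      next
    }
    for (g in c("AdCd", "AiCi")) {
      in_grp <- merged$group == g
      observed <- sum(in_cat & in_grp)
      expected <- sum(in_cat) * mean(in_grp)
      ts <- chisq_2x2(in_cat, in_grp)
      out[[paste(cat, g)]] <- tibble::tibble(
        category = cat, group = g, n_category = sum(in_cat),
        observed = observed, expected = expected,
        statistic = ts[["statistic"]], p = ts[["p"]],
        direction = ifelse(observed >= expected, "enriched", "depleted"))
    }
  }
  out <- dplyr::bind_rows(out)
  class(out) <- c("cis_trans_crosstab", class(out))
  out
}
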