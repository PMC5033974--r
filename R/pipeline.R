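#' Pipeline configuration
#'
#' Either point the pipeline at an on-disk dataset (`input_dir`) / in-memory
#' [expression_dataset()] (`dataset`), or give a [sim_config()] (`sim`) to
#' analyse freshly simulated data; exactly one source must be supplied.
#'
#' @param input_dir Directory readable by [read_dataset()].
#' @param dataset An [expression_dataset()].
#' @param sim A [sim_config()].
#' @param alpha Significance level used by every test family; default 0.05.
#' @param fpkm_threshold Parental-expression filter threshold; default 1.0.
#' @param fc_bounds Closed fold-change band; default `c(0.5, 1.5)`.
#' @param copy_correct Balance-test mode for cis/trans calling; see
#'   [call_cis_trans()].
#' @param pseudocount Zero replacement for log ratios.
#' @param out_dir Optional output directory for the result bundle.
#' @param seed Seed forwarded to the simulator when `sim` has none.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, dataset = NULL, sim = NULL,
                            alpha = 0.05, fpkm_threshold = 1,
                            fc_bounds = c(0.5, 1.5), copy_correct = FALSE,
                            pseudocount = 0.5, out_dir = NULL, seed = NULL) {
  sources <- !vapply(list(input_dir, dataset, sim), is.null, logical(1))
  if (sum(sources) != 1) {
    rlang::abort("supply exactly one of input_dir, dataset or sim")
  }
  if (!is.numeric(alpha) || alpha < 0 || alpha >= 1) {
    rlang::abort("alpha must lie in [0, 1)")
  }
  if (!is.null(sim)) {
    stopifnot(inherits(sim, "sim_config"))
    if (is.null(sim$seed) && !is.null(seed)) sim$seed <- as.integer(seed)
  }
  structure(list(input_dir = input_dir, dataset = dataset, sim = sim,
                 alpha = alpha, fpkm_threshold = fpkm_threshold,
                 fc_bounds = fc_bounds, copy_correct = copy_correct,
                 pseudocount = pseudocount, out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

#' Run the full dosage-series analysis pipeline
#'
#' Executes, in order: dataset acquisition (read or simulate), FPKM and
#' replicate averaging, the parental-expression pair filter, dosage
#' classification with pair grouping and inverse-dosage detection,
#' mid-parent fold-change analysis with class binning, and per-hybrid
#' cis/trans calling with dosage-class cross-tabulation. Every threshold and
#' mode used is echoed into the summary; given a fixed seed the result
#' bundle is identical across runs.
#'
#' @param config A [pipeline_config()].
#' @param panel Genotype panel; default [build_genotype_panel()].
#' @param quiet Suppress per-stage progress messages.
#' @return A list of class `dosage_pipeline_summary`; written to
#'   `config$out_dir` (TSV tables, JSON summaries and a text report) when set.
#' @export
run_dosage_pipeline <- function(config, panel = build_genotype_panel(),
                                quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(...)

  truth <- NULL
  if (!is.null(config$sim)) {
    say("simulating dataset: ", config$sim$n_pairs, " pairs")
    sim <- generate_dataset(config$sim, panel)
    dataset <- sim$dataset
    truth <- sim$truth
  } else if (!is.null(config$input_dir)) {
    say("reading dataset from ", config$input_dir)
    dataset <- read_dataset(config$input_dir)
  } else {
    dataset <- config$dataset
  }

  present <- unique(dataset$samples$genotype)
  parent_a <- parent_genotype(panel, "A")
  parent_c <- parent_genotype(panel, "C")
  hybrids <- intersect(hybrid_genotypes(panel), present)
  if (!all(c(parent_a, parent_c) %in% present) || length(hybrids) == 0) {
    rlang::abort(paste0("pipeline requires samples for both parents (",
                        parent_a, ", ", parent_c, ") and at least one hybrid"))
  }

  fpkm <- dataset_fpkm(dataset)
  genotypes <- intersect(panel$genotype, present)
  geno_means <- average_replicates(fpkm, dataset$samples, genotypes)
  say("expression: ", nrow(fpkm), " genes, ", length(genotypes), " genotypes")

  filtered <- filter_expressed_pairs(dataset$pairs, geno_means,
                                     threshold = config$fpkm_threshold)
  rep <- filter_report(filtered)
  say("filter (FPKM > ", config$fpkm_threshold, " in both parents): ",
      rep$n_input, " pairs in, ", rep$n_retained, " retained (",
      rep$pct_removed, "% removed)")

  gene_set <- unique(c(filtered$a_gene, filtered$c_gene))
  gm <- geno_means[geno_means$gene_id %in% gene_set, ]

  results <- classify_dosage(gm, filtered, panel, alpha = config$alpha)
  groups <- group_pairs(results, filtered)
  inverse <- detect_inverse_dosage(results)
  say("dosage classes: ",
      sum(results$class == "dependent" & results$subgenome == "A"), " Ad, ",
      sum(results$class == "dependent" & results$subgenome == "C"), " Cd of ",
      nrow(filtered), " pairs per subgenome")

  mpv <- compute_mpv(gm, parents = c(A = parent_a, C = parent_c))
  fc <- fold_change(gm, mpv, genotypes = hybrids,
                    parents = c(A = parent_a, C = parent_c))
  fc_summary <- summarize_fc(
    fc, gene_info = tibble::tibble(gene_id = results$gene_id,
                                   subgenome = results$subgenome))
  bins <- bin_fc_by_class(fc, results, bounds = config$fc_bounds)
  say("fold change: ", nrow(fc), " gene x genotype values summarised")

  calls <- list()
  crosstabs <- list()
  for (g in hybrids) {
    calls[[g]] <- call_cis_trans(dataset, g, pairs = filtered, panel = panel,
                                 alpha = config$alpha,
                                 copy_correct = config$copy_correct,
                                 pseudocount = config$pseudocount,
                                 geno_means = geno_means)
    crosstabs[[g]] <- crosstab_categories(calls[[g]], groups)
    say("cis/trans ", g, ": ",
        paste(names(table(calls[[g]]$category)),
              as.vector(table(calls[[g]]$category)), collapse = ", "))
  }

  summary <- structure(list(
    config = config[c("alpha", "fpkm_threshold", "fc_bounds",
                      "copy_correct", "pseudocount", "seed")],
    genotypes = genotypes,
    filter = rep,
    dosage = list(
      results = results,
      r2_cutoff = attr(results, "r2_cutoff"),
      marginals = groups$marginals,
      groups = groups,
      inverse = inverse
    ),
    fold_change = list(table = fc, summary = fc_summary, bins = bins),
    cis_trans = list(calls = calls, crosstabs = crosstabs),
    truth = truth,
    dataset = dataset
  ), class = "dosage_pipeline_summary")

  if (!is.null(config$out_dir)) {
    write_pipeline_outputs(summary, config$out_dir)
    say("results written to ", config$out_dir)
  }
  summary
}

write_pipeline_outputs <- function(summary, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(tbl, name) {
    readr::write_tsv(tibble::as_tibble(tbl), file.path(dir, name),
                     progress = FALSE)
  }
  if (!is.null(summary$truth)) {
    write_dataset(structure(list(dataset = summary$dataset,
                                 truth = summary$truth),
                            class = "sim_dataset"),
                  file.path(dir, "dataset"))
  }
  w(summary$dosage$results, "dosage_results.tsv")
  w(summary$dosage$groups$pairs, "pair_groups.tsv")
  w(summary$fold_change$table, "fc_table.tsv")
  w(dplyr::bind_rows(lapply(summary$cis_trans$calls, tibble::as_tibble)),
    "cistrans.tsv")

  js <- function(x, name) {
    jsonlite::write_json(x, file.path(dir, name), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
  }
  js(list(marginal_dependent = as.list(summary$dosage$marginals),
          r2_cutoff = as.list(summary$dosage$r2_cutoff),
          groups = summary$dosage$groups$summary,
          chisq = summary$dosage$groups$chisq,
          inverse = summary$dosage$inverse$summary),
     "dosage_summary.json")
  js(list(quantile_type = attr(summary$fold_change$summary, "quantile_type"),
          summary = summary$fold_change$summary,
          bounds = summary$fold_change$bins$bounds,
          bins = summary$fold_change$bins$bins,
          tests = summary$fold_change$bins$tests),
     "fc_summary.json")
  js(lapply(summary$cis_trans$calls, function(x) {
    tb <- table(factor(x$category, levels = c("no_effect", "only_cis",
                                              "only_trans", "cis_trans")))
    list(mode = attr(x, "balance_mode"),
         counts = as.list(tb),
         pct = as.list(round(100 * as.vector(tb) / sum(tb), 1) |>
                         stats::setNames(names(tb))))
  }), "cistrans_summary.json")
  js(list(config = summary$config,
          genotypes = summary$genotypes,
          filter = summary$filter,
          dosage = list(marginal_dependent = as.list(summary$dosage$marginals),
                        r2_cutoff = as.list(summary$dosage$r2_cutoff),
                        groups = summary$dosage$groups$summary),
          fc = summary$fold_change$summary),
     "summary.json")
  writeLines(write_report(summary), file.path(dir, "report.txt"))
  invisible(dir)
}

#' Render a human-readable text report of a pipeline run
#'
#' One section per stage: filter narrative, dosage-class marginals, the
#' four-group table with observed and expected percentages, fold-change
#' medians and interquartile bounds, and the cis/trans category table per
#' genotype.
#'
#' @param summary A `dosage_pipeline_summary` from [run_dosage_pipeline()].
#' @return Character vector of report lines, invisibly printable via
#'   `writeLines()`. Regeneration from the same summary is idempotent.
#' @export
write_report <- function(summary) {
  stopifnot(inherits(summary, "dosage_pipeline_summary"))
  ln <- character(0)
  add <- function(...) ln <<- c(ln, paste0(...))
  add("Dosage-series homoeolog expression analysis")
  add(strrep("=", 44))
  cfg <- summary$config
  add("alpha = ", cfg$alpha, "; FPKM filter > ", cfg$fpkm_threshold,
      "; FC band [", cfg$fc_bounds[1], ", ", cfg$fc_bounds[2],
      "]; balance mode = ",
      if (isTRUE(cfg$copy_correct)) "copy-corrected" else "raw 1/2")
  add("")
  add("Pair filter")
  add("-----------")
  f <- summary$filter
  add(f$n_input, " homoeolog pairs in; ", f$n_retained, " retained; ",
      f$n_removed, " removed (", f$pct_removed, "%)")
  add("")
  add("Dosage classification")
  add("---------------------")
  m <- summary$dosage$marginals
  add(sprintf("dependent: A %.1f%%, C %.1f%%", 100 * m[["A_dependent"]],
              100 * m[["C_dependent"]]))
  cut <- summary$dosage$r2_cutoff
  add(sprintf("empirical r2 cutoff: A %s, C %s",
              format(cut[["A"]], digits = 3), format(cut[["C"]], digits = 3)))
  gs <- summary$dosage$groups$summary
  add(sprintf("%-6s %8s %10s %10s", "group", "n", "obs %", "exp %"))
  for (i in seq_len(nrow(gs))) {
    add(sprintf("%-6s %8d %9.1f%% %9.1f%%", gs$group[i], gs$n[i],
                gs$observed_pct[i], gs$expected_pct[i]))
  }
  ch <- summary$dosage$groups$chisq
  add(sprintf("goodness of fit vs independence: X2 = %.2f, df = %d, p = %.3g",
              ch$statistic, ch$df, ch$p))
  inv <- summary$dosage$inverse$summary
  if (nrow(inv) > 0) {
    add("inverse-dosage genes: ",
        paste(sprintf("%s: %d negative (%d significant)", inv$subgenome,
                      inv$n_negative, inv$n_significant), collapse = "; "))
  }
  add("")
  add("Fold change vs mid-parent")
  add("-------------------------")
  fs <- summary$fold_change$summary
  add(sprintf("%-6s %-4s %8s %8s %8s %8s", "geno", "sub", "median", "q1",
              "q3", "n"))
  for (i in seq_len(nrow(fs))) {
    add(sprintf("%-6s %-4s %8.3f %8.3f %8.3f %8d", fs$genotype[i],
                fs$subgenome[i], fs$median[i], fs$q1[i], fs$q3[i], fs$n[i]))
  }
  add("")
  add("Cis/trans categories")
  add("--------------------")
  if (length(summary$cis_trans$calls) == 0) {
    add("no hybrid genotypes available; section omitted")
  } else {
    cats <- c("no_effect", "only_cis", "only_trans", "cis_trans")
    add(sprintf("%-6s %s", "geno",
                paste(sprintf("%16s", cats), collapse = "")))
    for (g in names(summary$cis_trans$calls)) {
      x <- summary$cis_trans$calls[[g]]
      tb <- table(factor(x$category, levels = cats))
      cells <- sprintf("%6d (%5.1f%%)", as.vector(tb),
                       100 * as.vector(tb) / sum(tb))
      add(sprintf("%-6s %s", g, paste(sprintf("%16s", cells), collapse = "")))
    }
  }
  ln
}
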