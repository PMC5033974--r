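test_that("log-ratio components reproduce the canonical patterns", {
  sym <- log_ratio_components(8, 8, 8, 8)
  expect_equal(unlist(sym), c(a_stat = 0, b_stat = 0, trans_stat = 0))
  cis <- log_ratio_components(8, 2, 8, 2)
  expect_equal(unlist(cis), c(a_stat = 2, b_stat = 2, trans_stat = 0))
  trans <- log_ratio_components(8, 2, 4, 4)
  expect_equal(unlist(trans), c(a_stat = 2, b_stat = 0, trans_stat = 2))
  # pseudocount only touches zeros
  z <- log_ratio_components(8, 0, 8, 2, pseudocount = 0.5)
  expect_equal(z$a_stat, log2(8 / 0.5))
  expect_equal(z$b_stat, 2)
  expect_equal(z$trans_stat, z$a_stat - z$b_stat)
  expect_error(log_ratio_components(-1, 2, 3, 4), "non-negative")
})

test_that("ratio-difference test is Fisher's exact on the 2x2 count table", {
  expect_equal(test_ratio_difference(10, 10, 10, 10), 1)
  expect_lt(test_ratio_difference(50, 5, 5, 50), 1e-10)
  expect_equal(test_ratio_difference(0, 0, 5, 10), 1) # zero margin
  expect_error(test_ratio_difference(1.5, 2, 3, 4), "integers")
})

test_that("Fisher p matches hypergeometric enumeration for totals <= 60", {
  set.seed(41)
  # random small tables plus systematic boundary cases
  tables <- list(c(0, 0, 0, 1), c(1, 0, 0, 1), c(30, 0, 0, 30),
                 c(15, 15, 15, 15), c(60, 0, 0, 0))
  for (i in 1:120) {
    total <- sample(1:60, 1)
    cuts <- sort(sample(0:total, 3, replace = TRUE))
    tables[[length(tables) + 1]] <-
      c(cuts[1], cuts[2] - cuts[1], cuts[3] - cuts[2], total - cuts[3])
  }
  for (tb in tables) {
    got <- test_ratio_difference(tb[1], tb[2], tb[3], tb[4])
    want <- fisher_oracle(tb[1], tb[2], tb[3], tb[4])
    expect_lt(abs(got - want), 1e-10)
  }
})

test_that("hybrid balance test is an exact binomial against the null fraction", {
  expect_equal(test_hybrid_balance(10, 10)$p, 1)
  expect_lt(test_hybrid_balance(100, 0)$p, 1e-20)
  # observed fraction equal to a copy-corrected 2/3 null is maximally null
  b <- test_hybrid_balance(20, 10, expected_a_fraction = 2 / 3)
  expect_gt(b$p, 0.99)
  z <- test_hybrid_balance(0, 0)
  expect_equal(z$p, 1)
  expect_true(z$undefined)
  expect_error(test_hybrid_balance(3, 4, expected_a_fraction = 1), "strictly")
})

test_that("category truth table follows the two significance flags", {
  expect_equal(classify_cis_trans(0.8, 0.001), "only_cis")
  expect_equal(classify_cis_trans(0.001, 0.8), "only_trans")
  expect_equal(classify_cis_trans(0.8, 0.8), "no_effect")
  expect_equal(classify_cis_trans(0.001, 0.001), "cis_trans")
  # vectorised, exhaustive partition
  p <- c(0.8, 0.001)
  grid <- expand.grid(d = p, b = p)
  cats <- classify_cis_trans(grid$d, grid$b)
  expect_setequal(cats, c("no_effect", "only_cis", "only_trans", "cis_trans"))
})

test_that("calls cover every pair exactly once and respect A/C symmetry", {
  sim <- generate_dataset(sim_config(n_pairs = 300, dispersion = 0.01,
                                     seed = 61))
  ds <- sim$dataset
  calls <- call_cis_trans(ds, "AC")
  expect_equal(nrow(calls), 300)
  expect_equal(sort(calls$pair_id), sort(ds$pairs$pair_id))
  expect_true(all(calls$category %in%
                    c("no_effect", "only_cis", "only_trans", "cis_trans")))
  expect_equal(calls$trans_stat, calls$a_stat - calls$b_stat)

  # swapping the subgenome labels everywhere preserves the categories
  swap <- ds
  swap$pairs <- tibble::tibble(pair_id = ds$pairs$pair_id,
                               a_gene = ds$pairs$c_gene,
                               c_gene = ds$pairs$a_gene)
  swap$samples$genotype <- c(AA = "CC", CC = "AA", AC = "AC", AAC = "CCA",
                             CCA = "AAC", CCAA = "CCAA")[ds$samples$genotype]
  swap$samples$sample_id <- paste0(swap$samples$genotype, "_r",
                                   swap$samples$replicate)
  names(swap$counts) <- c("gene_id", swap$samples$sample_id)
  swapped <- call_cis_trans(swap, "AC")
  merged <- dplyr::inner_join(tibble::as_tibble(calls),
                              tibble::as_tibble(swapped), by = "pair_id")
  expect_equal(merged$a_stat.y, -merged$a_stat.x, tolerance = 1e-12)
  expect_equal(merged$category.y, merged$category.x)
})

test_that("a no-divergence multinomial null is dominated by no_effect", {
  # uniform dependence: a mixed-dependence pair is not a ratio null, since
  # its members respond differently to the dosage change between parent and
  # hybrid
  sim <- generate_dataset(sim_config(n_pairs = 400, dispersion = 0,
                                     fraction_dependent = 1,
                                     fraction_cis_divergent = 0,
                                     fraction_trans_divergent = 0,
                                     fraction_inverse = 0, seed = 62))
  ds <- sim$dataset
  gm <- average_replicates(dataset_fpkm(ds), ds$samples)
  filtered <- filter_expressed_pairs(ds$pairs, gm)
  calls <- call_cis_trans(ds, "AC", pairs = filtered)
  # with BH at 0.05 the joint false-positive mass stays small
  expect_gt(mean(calls$category == "no_effect"), 0.85)
})

test_that("cross-tabulation flags the engineered enrichment direction", {
  set.seed(63)
  n <- 400
  groups <- structure(list(pairs = tibble::tibble(
    pair_id = sprintf("p%03d", 1:n),
    a_class = "x", c_class = "x",
    group = sample(c("AdCd", "AdCi", "AiCd", "AiCi"), n, replace = TRUE))),
    class = "pair_groups")
  # attach only_cis exclusively to AiCi pairs
  cat <- ifelse(groups$pairs$group == "AiCi", "only_cis", "no_effect")
  cat[groups$pairs$group == "AdCd"] <-
    ifelse(runif(sum(groups$pairs$group == "AdCd")) < 0.5, "only_trans",
           "no_effect")
  calls <- tibble::tibble(pair_id = groups$pairs$pair_id, category = cat)
  xt <- crosstab_categories(calls, groups)
  cis_aici <- xt[xt$category == "only_cis" & xt$group == "AiCi", ]
  expect_equal(cis_aici$direction, "enriched")
  expect_equal(cis_aici$observed, cis_aici$n_category)
  trans_adcd <- xt[xt$category == "only_trans" & xt$group == "AdCd", ]
  expect_equal(trans_adcd$direction, "enriched")
  expect_lt(trans_adcd$p, 0.001)
})

test_that("uniformly random labels show no systematic enrichment", {
  set.seed(64)
  hits <- 0
  n_rep <- 20
  for (i in seq_len(n_rep)) {
    n <- 300
    groups <- structure(list(pairs = tibble::tibble(
      pair_id = sprintf("p%03d", 1:n), a_class = "x", c_class = "x",
      group = sample(c("AdCd", "AiCi"), n, replace = TRUE))),
      class = "pair_groups")
    calls <- tibble::tibble(
      pair_id = groups$pairs$pair_id,
      category = sample(c("only_cis", "only_trans", "no_effect"), n,
                        replace = TRUE))
    xt <- suppressWarnings(crosstab_categories(calls, groups))
    hits <- hits + any(xt$p < 0.05, na.rm = TRUE)
  }
  # 4 tests per replicate at alpha 0.05: some hits expected, but not most
  expect_lt(hits / n_rep, 0.5)
})
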