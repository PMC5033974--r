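test_that("degenerate mixtures assign every gene the configured class", {
  cfg <- sim_config(n_pairs = 200, fraction_dependent = 1,
                    fraction_inverse = 0, seed = 1)
  truth <- assign_regulatory_classes(cfg)
  expect_true(all(truth$genes$dependence == "dependent"))
  cfg0 <- sim_config(n_pairs = 200, fraction_dependent = 0,
                     fraction_inverse = 0, seed = 1)
  expect_true(all(assign_regulatory_classes(cfg0)$genes$dependence ==
                    "independent"))
})

test_that("label frequencies match configured fractions within binomial CI", {
  cfg <- sim_config(n_pairs = 10000, fraction_dependent = 0.6, seed = 2)
  truth <- assign_regulatory_classes(cfg)
  n <- nrow(truth$genes)
  k <- sum(truth$genes$dependence == "dependent")
  ci <- stats::qbinom(c(0.005, 0.995), n, 0.6) / n
  expect_gt(k / n, ci[1])
  expect_lt(k / n, ci[2])
  # within +/- 2% of the target at this size
  expect_lt(abs(k / n - 0.6), 0.02)
  # A and C labels are drawn independently: product-of-marginals group rates
  a <- truth$genes$dependence[truth$genes$subgenome == "A"] == "dependent"
  c_ <- truth$genes$dependence[truth$genes$subgenome == "C"] == "dependent"
  obs_dd <- mean(a & c_)
  expect_lt(abs(obs_dd - mean(a) * mean(c_)), 0.015)
})

test_that("inconsistent fractions are rejected", {
  expect_error(sim_config(fraction_dependent = 0.9, fraction_inverse = 0.2),
               "must not exceed 1")
  expect_error(sim_config(fraction_cis_divergent = 0.7,
                          fraction_trans_divergent = 0.5),
               "must not exceed 1")
  expect_error(sim_config(fraction_dependent = 1.2), "proportion")
})

test_that("dependent expected expression is proportional to relative dosage", {
  cfg <- sim_config(n_pairs = 30, fraction_dependent = 1, fraction_inverse = 0,
                    fraction_cis_divergent = 0, fraction_trans_divergent = 0,
                    seed = 3)
  truth <- assign_regulatory_classes(cfg)
  ab <- simulate_true_abundance(truth)
  wide <- tidyr::pivot_wider(ab[ab$subgenome == "A", ],
                             names_from = "genotype",
                             values_from = "abundance",
                             id_cols = "gene_id")
  series <- as.matrix(wide[, c("AA", "AAC", "AC", "CCAA", "CCA")])
  expect_equal(sweep(series, 1, series[, "AA"], "/"),
               matrix(rep(c(1, 2 / 3, 1 / 2, 1 / 2, 1 / 3), each = 30), 30, 5,
                      dimnames = dimnames(series)))
  # absent subgenome: zero expression
  expect_true(all(ab$abundance[ab$subgenome == "A" & ab$genotype == "CC"] == 0))
})

test_that("independent genes are constant and inverse genes decrease", {
  cfg <- sim_config(n_pairs = 200, fraction_dependent = 0,
                    fraction_inverse = 0.5, fraction_cis_divergent = 0,
                    fraction_trans_divergent = 0, seed = 4)
  truth <- assign_regulatory_classes(cfg)
  ab <- simulate_true_abundance(truth)
  ab <- dplyr::inner_join(ab, truth$genes[, c("gene_id", "dependence")],
                          by = "gene_id")
  carriers <- ab[ab$subgenome == "A" & ab$genotype != "CC", ]
  ind <- carriers[carriers$dependence == "independent", ]
  spread <- tapply(ind$abundance, ind$gene_id, function(x) diff(range(x)))
  expect_true(all(spread == 0))
  # inverse genes: expression strictly decreasing in dosage
  inv <- carriers[carriers$dependence == "inverse", ]
  inv$dosage <- relative_dosage(build_genotype_panel(), inv$genotype, "A")
  cors <- tapply(seq_len(nrow(inv)), inv$gene_id, function(i) {
    stats::cor(inv$abundance[i], inv$dosage[i])
  })
  expect_true(all(cors < -0.9))
  expect_true(all(inv$abundance > 0))
})

test_that("cis splits persist in hybrids while trans splits collapse", {
  cfg <- sim_config(n_pairs = 400, fraction_dependent = 1, fraction_inverse = 0,
                    fraction_cis_divergent = 0.5, fraction_trans_divergent = 0.5,
                    cis_log2_offset = 2, trans_log2_offset = 2, seed = 5)
  truth <- assign_regulatory_classes(cfg)
  g <- truth$genes
  a <- g[g$subgenome == "A", ]
  c_ <- g[g$subgenome == "C", ]
  div <- truth$pairs$divergence
  ratio_parent <- a$rate_parent / c_$rate_parent
  ratio_hybrid <- a$rate_hybrid / c_$rate_hybrid
  expect_true(all(abs(log2(ratio_parent[div != "none"])) == 2))
  expect_equal(ratio_hybrid[div == "cis"], ratio_parent[div == "cis"])
  expect_true(all(ratio_hybrid[div == "trans"] == 1))
})

test_that("count sampling honours the degenerate and binomial regimes", {
  # one gene owning the whole library, no dispersion: exact library size
  cfg <- sim_config(n_pairs = 1, library_size = 12345, dispersion = 0, seed = 6)
  counts <- sample_counts(tibble::tibble(gene_id = "g1", s1 = 1), cfg)
  expect_identical(counts$s1, 12345L)

  # two genes with equal shares: counts within 3 binomial sd of the mean
  cfg2 <- sim_config(n_pairs = 1, library_size = 1e6, dispersion = 0, seed = 7)
  counts2 <- sample_counts(tibble::tibble(gene_id = c("g1", "g2"),
                                          s1 = c(0.5, 0.5)), cfg2)
  sd3 <- 3 * sqrt(1e6 * 0.25)
  expect_true(all(abs(counts2$s1 - 5e5) < sd3))
  expect_equal(sum(counts2$s1), 1e6)

  # determinism under a fixed seed
  counts3 <- sample_counts(tibble::tibble(gene_id = c("g1", "g2"),
                                          s1 = c(0.5, 0.5)), cfg2)
  expect_identical(counts2, counts3)

  expect_error(sample_counts(tibble::tibble(gene_id = "g1", s1 = 0), cfg),
               "all-zero")
  expect_error(sample_counts(tibble::tibble(gene_id = "g1", s1 = -0.1), cfg),
               "non-negative")
})

test_that("multinomial column sums equal the library size", {
  cfg <- sim_config(n_pairs = 50, library_size = 1e5, dispersion = 0.2, seed = 8)
  shares <- tibble::tibble(gene_id = sprintf("g%02d", 1:50),
                           s1 = runif(50), s2 = runif(50))
  shares$s1 <- shares$s1 / sum(shares$s1)
  shares$s2 <- shares$s2 / sum(shares$s2)
  counts <- sample_counts(shares, cfg)
  expect_equal(colSums(as.matrix(counts[, -1])), c(s1 = 1e5, s2 = 1e5))
})

test_that("generated datasets have the right shape and round-trip via TSV", {
  cfg <- sim_config(n_pairs = 100, n_replicates = 2, seed = 9)
  dir <- withr::local_tempdir()
  sim <- generate_dataset(cfg, dir = dir)
  ds <- sim$dataset
  expect_equal(nrow(ds$counts), 200)
  expect_equal(ncol(ds$counts), 13) # gene_id + 6 genotypes x 2 replicates
  expect_setequal(unique(ds$samples$genotype),
                  c("AA", "CC", "AC", "AAC", "CCA", "CCAA"))

  rt <- read_dataset(dir)
  expect_equal(tibble::as_tibble(rt$counts), tibble::as_tibble(ds$counts))
  expect_equal(rt$samples, ds$samples)
  expect_equal(rt$pairs, ds$pairs)
  expect_equal(rt$lengths, ds$lengths)
  truth_rt <- read_truth(dir)
  expect_equal(truth_rt$genes[, c("gene_id", "dependence")],
               sim$truth$genes[, c("gene_id", "dependence")])
  expect_equal(truth_rt$pairs, sim$truth$pairs)
})

test_that("identical seed and config give bit-identical datasets", {
  cfg <- sim_config(n_pairs = 40, seed = 10)
  s1 <- generate_dataset(cfg)
  s2 <- generate_dataset(cfg)
  expect_identical(s1$dataset$counts, s2$dataset$counts)
  expect_identical(s1$truth, s2$truth)
})
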