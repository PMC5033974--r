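dosage5 <- c(1, 2 / 3, 1 / 2, 1 / 2, 1 / 3)

test_that("dosage correlation matches the worked single-gene examples", {
  res <- dosage_correlation(c(22.22, 11.37, 7.41, 8.98, 6.34), dosage5)
  expect_equal(round(res$r, 2), 0.97)
  expect_equal(res$r2, res$r^2)

  # perfectly proportional expression
  perfect <- dosage_correlation(7 * dosage5, dosage5)
  expect_equal(perfect$r, 1)
  expect_equal(perfect$r2, 1)

  # flat, decorrelated profile
  flat <- dosage_correlation(c(96.35, 71.47, 94.49, 71.31, 99.86), dosage5)
  expect_lt(flat$r2, 1e-4)

  expect_error(dosage_correlation(c(1, 2), c(1, 2)), "3 genotype")
  expect_error(dosage_correlation(c(1, NA, 3), c(1, 2, 3)), "finite")
})

test_that("dosage correlation agrees with cor.test to 1e-10", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(4:9, 1)
    x <- runif(n)
    y <- rnorm(n)
    got <- dosage_correlation(y, x)
    ref <- stats::cor.test(y, x)
    expect_equal(got$r, unname(ref$estimate), tolerance = 1e-10)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("constant expression is defined as uncorrelated", {
  res <- dosage_correlation(rep(4.2, 5), dosage5)
  expect_equal(res$r, 0)
  expect_equal(res$p, 1)
})

test_that("BH adjustment matches p.adjust and the hand-enumerated step-up", {
  expect_equal(adjust_bh(0.05), 0.05)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(c(1, 1)), c(1, 1))
  set.seed(32)
  grid <- c(0, 0.001, 0.01, 0.04, 0.05, 0.2, 0.5, 0.8, 1)
  for (n in 1:8) {
    for (rep in 1:40) {
      p <- sample(grid, n, replace = TRUE)
      expect_equal(adjust_bh(p), bh_oracle(p))
    }
  }
  expect_error(adjust_bh(c(0.2, 1.5)), "0, 1")
  expect_error(adjust_bh(c(-0.1)), "0, 1")
})

test_that("BH is monotone in ranks and idempotent on flat vectors", {
  set.seed(33)
  p <- runif(20)
  adj <- adjust_bh(p)
  expect_equal(order(adj[order(p)]), 1:20) # sorted input -> sorted output
  flat <- rep(0.3, 6)
  expect_equal(adjust_bh(adjust_bh(flat)), adjust_bh(flat))
})

test_that("classification recovers truth on a noise-free dependent dataset", {
  sim <- tiny_exact_sim(n_pairs = 60, fraction_dependent = 1,
                        fraction_inverse = 0, fraction_cis_divergent = 0,
                        fraction_trans_divergent = 0)
  ds <- sim$dataset
  gm <- average_replicates(dataset_fpkm(ds), ds$samples)
  res <- classify_dosage(gm, ds$pairs)
  expect_true(all(res$class == "dependent"))
  expect_equal(unname(attr(res, "r2_cutoff")), c(1, 1), tolerance = 1e-9)
})

test_that("classification partitions genes and an all-null set stays independent", {
  gm <- manual_geno_means(
    c("a1", "a2", "c1", "c2"),
    list(c(AA = 5, AAC = 5, AC = 5, CCAA = 5, CCA = 5, CC = 0),
         c(AA = 3, AAC = 3.1, AC = 2.9, CCAA = 3, CCA = 3.05, CC = 0),
         c(AA = 0, AAC = 4, AC = 4.1, CCAA = 3.9, CCA = 4, CC = 4),
         c(AA = 0, AAC = 2, AC = 2, CCAA = 2, CCA = 2, CC = 2)))
  pairs <- tibble::tibble(pair_id = c("p1", "p2"),
                          a_gene = c("a1", "a2"), c_gene = c("c1", "c2"))
  res <- classify_dosage(gm, pairs)
  expect_equal(nrow(res), 4)
  expect_true(all(res$class == "independent"))
  expect_true(all(is.na(attr(res, "r2_cutoff"))))
  expect_equal(sum(res$class == "dependent") + sum(res$class == "independent"),
               nrow(res))
  expect_error(classify_dosage(gm, pairs[0, ]), "empty")
})

test_that("pair grouping reproduces product-of-marginals expectations", {
  # synthetic results with the study-scale marginals: 8930/14380 dependent A,
  # 8582/14380 dependent C
  n <- 14380
  mk <- function(sub, k) {
    tibble::tibble(
      gene_id = sprintf("%s%05d", tolower(sub), 1:n), subgenome = sub,
      r = 0.9, r2 = 0.81, p = 0.01, p_adj = 0.01,
      class = rep(c("dependent", "independent"), c(k, n - k)),
      inverse_flag = FALSE)
  }
  res <- dplyr::bind_rows(mk("A", 8930), mk("C", 8582))
  pairs <- tibble::tibble(pair_id = sprintf("p%05d", 1:n),
                          a_gene = sprintf("a%05d", 1:n),
                          c_gene = sprintf("c%05d", 1:n))
  grp <- group_pairs(res, pairs)
  expect_equal(round(grp$summary$expected_pct), c(37, 25, 23, 15))
  expect_equal(sum(grp$summary$n), n)
  expect_equal(sum(grp$summary$expected_pct), 100)

  # degenerate marginals: everything dependent
  res2 <- res
  res2$class <- "dependent"
  grp2 <- group_pairs(res2, pairs)
  expect_equal(grp2$summary$n, c(n, 0, 0, 0))
  expect_equal(grp2$summary$observed_pct, c(100, 0, 0, 0))
})

test_that("inverse-dosage genes are detected separately from dependence", {
  res <- tibble::tibble(
    gene_id = c("a1", "a2", "c1"), subgenome = c("A", "A", "C"),
    r = c(-0.99, -0.10, 0.9), r2 = c(0.98, 0.01, 0.81),
    p = c(0.001, 0.9, 0.01), p_adj = c(0.001, 0.9, 0.01),
    class = c("independent", "independent", "dependent"),
    inverse_flag = c(TRUE, FALSE, FALSE))
  inv <- detect_inverse_dosage(res)
  expect_equal(inv$genes$gene_id, c("a1", "a2"))
  expect_equal(inv$genes$significant, c(TRUE, FALSE))
  expect_equal(inv$summary$n_negative, 2)
  expect_equal(inv$summary$n_significant, 1)
})

test_that("strong inverse-dosage genes are recovered from simulation truth", {
  cfg <- sim_config(n_pairs = 2000, fraction_inverse = 0.01,
                    dispersion = 0.01, seed = 44)
  sim <- generate_dataset(cfg)
  ds <- sim$dataset
  gm <- average_replicates(dataset_fpkm(ds), ds$samples)
  filtered <- filter_expressed_pairs(ds$pairs, gm)
  gm_f <- gm[gm$gene_id %in% c(filtered$a_gene, filtered$c_gene), ]
  res <- classify_dosage(gm_f, filtered)
  truth_inv <- sim$truth$genes$gene_id[sim$truth$genes$dependence == "inverse"]
  analysed_inv <- intersect(truth_inv, res$gene_id)
  found <- res$gene_id[res$inverse_flag]
  expect_gte(length(intersect(found, analysed_inv)) / length(analysed_inv),
             0.80)
  # and flagged genes remain in the independent class
  expect_true(all(res$class[res$inverse_flag] == "independent"))
})
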