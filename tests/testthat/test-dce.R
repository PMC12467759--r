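test_that("variance filter keeps the top fraction with the stated count rule", {
  ds <- make_ds(g = 8, n_wt = 5, n_mut = 5, seed = 9)
  vf <- variance_filter(ds, 0.25)
  expect_length(vf$selected, 2L)  # ceil(0.25 * 8)
  expect_gte(min(vf$variance[vf$selected]),
             max(vf$variance[setdiff(ds$genes, vf$selected)]))
  expect_error(variance_filter(ds, 0), "fraction")
})

test_that("variance-filter ties are broken by gene symbol", {
  vals <- matrix(rep(c(1, 2, 3, 4), each = 8), 8, byrow = FALSE,
                 dimnames = list(sprintf("G%d", 8:1), paste0("S", 1:4)))
  ds <- expression_dataset(vals, c("WT", "WT", "MUT", "MUT"))
  vf <- variance_filter(ds, 0.25)
  expect_equal(vf$selected, c("G1", "G2"))
})

test_that("fisher_z is atanh with boundary clamping", {
  expect_equal(fisher_z(0), 0)
  expect_equal(as.numeric(fisher_z(0.75)), 0.9730, tolerance = 1e-4)
  expect_equal(as.numeric(fisher_z(-0.75)), -as.numeric(fisher_z(0.75)))
  z <- fisher_z(c(0.5, 1))
  expect_true(attr(z, "clamped")[2])
  expect_true(is.finite(z[2]))
  expect_error(fisher_z(1.2), "<= 1")
  # strictly increasing, and tanh inverts it
  r <- seq(-0.99, 0.99, length.out = 101)
  z <- as.numeric(fisher_z(r))
  expect_true(all(diff(z) > 0))
  expect_equal(tanh(z), r, tolerance = 1e-12)
})

test_that("the pair z statistic matches published-scale correlation changes", {
  # equal correlations: exact null
  null <- dce_z_statistic(0.4, 50, 0.4, 80)
  expect_equal(null$Z, 0)
  expect_equal(null$p, 1)
  # large-cohort replicated pair, rounded correlations
  t1 <- dce_z_statistic(0.93, 93, 0.75, 415)
  expect_equal(t1$Z, 5.89, tolerance = 0.001)
  expect_equal(t1$p, 3.84e-9, tolerance = 0.01)
  # small-cohort version of the same pair
  t2 <- dce_z_statistic(0.97, 14, 0.62, 166)
  expect_equal(t2$Z, 4.39, tolerance = 0.001)
  expect_error(dce_z_statistic(0.5, 3, 0.2, 50), "exceed 3")
})

test_that("swapping the groups negates Z and preserves p", {
  a <- dce_z_statistic(0.8, 40, 0.2, 60)
  b <- dce_z_statistic(0.2, 60, 0.8, 40)
  expect_equal(a$Z, -b$Z)
  expect_equal(a$p, b$p)
})

test_that("extreme statistics keep log-scale accuracy", {
  ex <- dce_z_statistic(0.9999999, 5000, -0.9999999, 5000)
  expect_lt(ex$log_p, -300 * log(10))
  expect_true(is.finite(ex$log_p))
  ref <- pnorm(abs(ex$Z), lower.tail = FALSE, log.p = TRUE) + log(2)
  expect_equal(ex$log_p, ref)
})

test_that("pairwise Bonferroni thresholds reproduce the published values", {
  expect_equal(signif(bonferroni_pair_threshold(0.05, 5128), 3), 3.80e-9)
  expect_equal(signif(bonferroni_pair_threshold(0.05, 6988), 3), 2.05e-9)
  expect_equal(bonferroni_pair_threshold(0.05, 2), 0.05)
  expect_error(bonferroni_pair_threshold(0.05, 1), "at least 2")
})

test_that("run_dce tests all pairs of filtered genes", {
  ds <- make_ds(g = 5, n_wt = 6, n_mut = 6, seed = 10)
  res <- run_dce(ds, fraction = 1, method = "bonferroni")
  expect_equal(nrow(res), 10L)  # C(5,2)
  expect_true(all(res$gene_a < res$gene_b))
  expect_equal(attr(res, "n_genes_tested"), 5L)
  expect_error(run_dce(make_ds(g = 5, n_wt = 3, n_mut = 6)), "more than 3")
})

test_that("genes with zero within-group variance are excluded", {
  ds <- make_ds(g = 5, n_wt = 6, n_mut = 6, seed = 12)
  vals <- ds$values
  vals[1, ds$labels == "WT"] <- 7  # constant in WT -> PCC undefined
  ds2 <- expression_dataset(vals, as.character(ds$labels))
  expect_message(res <- run_dce(ds2, fraction = 1), "zero within-group")
  expect_false(ds$genes[1] %in% c(res$gene_a, res$gene_b))
  expect_equal(nrow(res), choose(4, 2))
})

test_that("a planted correlation change is found at the Bonferroni level", {
  cfg <- simulation_config(seed = 41, n_genes = 200, n_wt = 93, n_mut = 415,
                           dce_spec = list(list(genes = 1:2, r_wt = 0.9,
                                                r_mut = 0.0)))
  ds <- simulate_dataset(cfg)$dataset
  res <- run_dce(ds, fraction = 1, method = "bonferroni", alpha = 0.05)
  key <- pair_key("G0001", "G0002")
  expect_true(res$significant[res$pair_key == key])
})

test_that("pair overlap matches on canonical keys", {
  a <- fake_dce("X", "Y", 0.9, 0.1, 1e-10, TRUE)
  b <- fake_dce("Y", "X", 0.8, 0.0, 1e-8, TRUE)
  ov <- overlap_pairs(a, b)
  expect_equal(nrow(ov), 1L)
  expect_equal(ov$pair_key, pair_key("X", "Y"))
  expect_true(all(c("r_wt_a", "r_wt_b", "p_a", "p_b") %in% names(ov)))
  c <- fake_dce("P", "Q", 0.9, 0.1, 1e-10, TRUE)
  expect_equal(nrow(overlap_pairs(a, c)), 0L)
})

test_that("the relaxed replication rule is enforced exactly", {
  # GAIN in both, corrected-significant in a, nominal in b -> kept
  a <- fake_dce("A", "B", 0.1, 0.9, 1e-10, TRUE)
  b <- fake_dce("A", "B", 0.2, 0.8, 0.01, FALSE)
  expect_equal(nrow(direction_consistent_pairs(a, b)), 1L)
  # opposite directions, both significant -> dropped
  b2 <- fake_dce("A", "B", 0.9, 0.1, 1e-10, TRUE)
  expect_equal(nrow(direction_consistent_pairs(a, b2)), 0L)
  # corrected-significant in a but not even nominal in b -> dropped
  b3 <- fake_dce("A", "B", 0.2, 0.8, 0.2, FALSE)
  expect_equal(nrow(direction_consistent_pairs(a, b3)), 0L)
})

test_that("genes_from_pairs returns the sorted union", {
  pr <- fake_dce(c("A", "B"), c("B", "C"), 0.5, 0.1, 1e-6, TRUE)
  expect_equal(genes_from_pairs(pr), c("A", "B", "C"))
  expect_equal(genes_from_pairs(pr[0, ]), character())
  pr7 <- fake_dce(sprintf("X%02d", 1:7), sprintf("Y%02d", 1:7),
                  0.5, 0.1, 1e-6, TRUE)
  expect_length(genes_from_pairs(pr7), 14L)
})
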