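test_that("exact enumeration reproduces the fully separated two-sided p", {
  # ranks of x are the most extreme of the 20 labelings: one-sided 1/20
  res <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6), exact = TRUE)
  expect_equal(res$p, 0.1)
  expect_equal(res$W, 6)
})

test_that("identical values across groups are degenerate with p = 1", {
  res <- wilcoxon_rank_sum(c(5, 5, 5), c(5, 5, 5))
  expect_true(res$degenerate)
  expect_equal(res$p, 1)
})

test_that("the test is invariant under strictly monotone transforms", {
  set.seed(4)
  x <- rnorm(15); y <- rnorm(20, 0.5)
  p1 <- wilcoxon_rank_sum(x, y)$p
  p2 <- wilcoxon_rank_sum(exp(x), exp(y))$p
  p3 <- wilcoxon_rank_sum(x^3, y^3)$p
  expect_equal(p1, p2)
  expect_equal(p1, p3)
})

test_that("exchanging group labels leaves p unchanged and flips direction", {
  set.seed(8)
  vals <- matrix(rnorm(40), 2, dimnames = list(c("G1", "G2"), paste0("S", 1:20)))
  vals[1, 11:20] <- vals[1, 11:20] + 1
  lab <- rep(c("WT", "MUT"), each = 10)
  ds <- expression_dataset(vals, lab)
  ds_sw <- expression_dataset(vals, rev(lab))
  a <- run_deg(ds, "bh"); b <- run_deg(ds_sw, "bh")
  expect_equal(a$p, b$p)
  expect_equal(a$direction[1], "UP")
  expect_equal(b$direction[1], "DOWN")
})

test_that("p-value adjustment matches the stated arithmetic", {
  expect_equal(adjust_pvalues(0.01, "bonferroni", m = 5), 0.05)
  expect_equal(adjust_pvalues(0.2, "bonferroni", m = 10), 1)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "bh"),
               rep(0.04, 4))
  expect_error(adjust_pvalues(1.5, "bonferroni"), "0, 1")
  expect_error(adjust_pvalues(c(0.1, 0.2), "bh", m = 1), "family size")
})

test_that("BH equals its brute-force step-up definition", {
  brute_bh <- function(p, m) {
    o <- order(p)
    ps <- p[o]
    # straightforward definition: adj_(i) = min over j >= i of p_(j) * m / j
    adj <- sapply(seq_along(ps), function(i) {
      j <- i:length(ps)
      min(1, min(ps[j] * m / j))
    })
    out <- numeric(length(p))
    out[o] <- adj
    out
  }
  set.seed(21)
  for (rep in 1:50) {
    p <- runif(sample(3:40, 1))
    expect_equal(adjust_pvalues(p, "bh"), brute_bh(p, length(p)),
                 tolerance = 1e-12)
  }
})

test_that("Bonferroni thresholds reproduce the published family sizes", {
  expect_equal(signif(bonferroni_threshold(0.05, 20511), 3), 2.44e-6)
  expect_equal(signif(bonferroni_threshold(0.05, 29377), 3), 1.70e-6)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_error(bonferroni_threshold(0.05, 0), "m must be")
})

test_that("run_deg recovers planted DE genes and respects the family size", {
  cfg <- simulation_config(seed = 31, n_genes = 200, n_wt = 93, n_mut = 415,
                           de_spec = data.frame(gene = 1:10,
                                                shift = rep(c(2, -2), 5)))
  sim <- simulate_dataset(cfg)
  deg <- run_deg(sim$dataset, method = "bonferroni", alpha = 0.05)
  called <- deg$gene[deg$significant]
  m <- recovery_metrics(sim$truth$de$gene, called)
  expect_gte(m["sensitivity"], 0.9)
  expect_lte(m["fdp"], 0.05)
  up <- deg[deg$gene %in% sim$truth$de$gene[sim$truth$de$shift > 0], ]
  expect_true(all(up$direction == "UP"))
  # single-gene dataset: family of one, p_bonf = p
  one <- expression_dataset(sim$dataset$values[1, , drop = FALSE],
                            sim$dataset$labels)
  d1 <- run_deg(one, "bonferroni")
  expect_equal(d1$p_bonf, d1$p)
})

test_that("a null dataset yields no BH-significant genes", {
  cfg <- simulation_config(seed = 33, n_genes = 300, n_wt = 40, n_mut = 40)
  deg <- run_deg(simulate_dataset(cfg)$dataset, method = "bh", alpha = 0.05)
  expect_equal(sum(deg$significant), 0L)
})

test_that("cross-dataset intersection applies the same-direction rule", {
  a <- fake_deg(c("G1", "G2"), c("UP", "DOWN"))
  b <- fake_deg(c("G1", "G2"), c("UP", "UP"))
  expect_equal(intersect_deg(a, b, TRUE)$gene, "G1")
  expect_equal(intersect_deg(a, b, FALSE)$gene, c("G1", "G2"))
  c <- fake_deg(c("G9"), "UP")
  expect_equal(nrow(intersect_deg(a, c, TRUE)), 0L)
  # NONE direction never replicates under the flag
  d <- fake_deg(c("G1"), "NONE")
  e <- fake_deg(c("G1"), "NONE")
  expect_equal(nrow(intersect_deg(d, e, TRUE)), 0L)
})
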