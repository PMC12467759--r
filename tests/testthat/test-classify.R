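test_that("AUC follows the Mann-Whitney definition", {
  expect_equal(auc(c(1, 2, 10, 20), c("WT", "WT", "MUT", "MUT")), 1)
  expect_equal(auc(rep(5, 6), rep(c("WT", "MUT"), 3)), 0.5)
  # 4 pairs: 3 concordant, 1 discordant
  expect_equal(auc(c(0.9, 0.4, 0.5, 0.1), c("MUT", "MUT", "WT", "WT")), 0.75)
  expect_error(auc(1:3, c("WT", "WT", "WT")), "both classes")
})

test_that("AUC symmetries hold without ties", {
  set.seed(43)
  for (i in 1:20) {
    s <- rnorm(30)
    lab <- sample(rep(c("WT", "MUT"), c(12, 18)))
    a <- auc(s, lab)
    expect_equal(auc(-s, lab), 1 - a)
    flipped <- ifelse(lab == "WT", "MUT", "WT")
    expect_equal(auc(s, flipped), 1 - a)
  }
})

test_that("rank AUC equals the trapezoidal area under the empirical ROC", {
  trap_auc <- function(scores, labels) {
    pos <- labels == "MUT"
    th <- sort(unique(scores), decreasing = TRUE)
    tpr <- c(0, vapply(th, function(t) mean(scores[pos] >= t), 0), 1)
    fpr <- c(0, vapply(th, function(t) mean(scores[!pos] >= t), 0), 1)
    sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  }
  set.seed(47)
  for (i in 1:200) {
    n <- sample(8:40, 1)
    scores <- round(rnorm(n), sample(0:2, 1))  # induce ties sometimes
    labels <- sample(c("WT", "MUT"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(auc(scores, labels), trap_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("LASSO selection recovers informative genes", {
  cfg <- simulation_config(seed = 51, n_genes = 200, n_wt = 93, n_mut = 415,
                           de_spec = data.frame(gene = 1:5, shift = 2))
  sim <- simulate_dataset(cfg)
  sel <- l1_select(sim$dataset, seed = 5)
  expect_gte(length(intersect(sel$selected, sim$truth$de$gene)), 4L)
  expect_gt(sel$cv_auc, 0.9)
})

test_that("pure noise gives chance-level cross-validated AUC", {
  cfg <- simulation_config(seed = 53, n_genes = 100, n_wt = 60, n_mut = 60)
  sel <- l1_select(simulate_dataset(cfg)$dataset, seed = 5)
  expect_gte(sel$cv_auc, 0.35)
  expect_lte(sel$cv_auc, 0.65)
})

test_that("a perfectly separating gene is selected with cv AUC near 1", {
  set.seed(55)
  vals <- matrix(rnorm(20 * 60), 20,
                 dimnames = list(sprintf("G%02d", 1:20), paste0("S", 1:60)))
  lab <- rep(c("WT", "MUT"), each = 30)
  vals[7, lab == "MUT"] <- vals[7, lab == "MUT"] + 10
  ds <- expression_dataset(vals, lab)
  sel <- l1_select(ds, seed = 5)
  expect_true("G07" %in% sel$selected)
  expect_gt(sel$cv_auc, 0.99)
})

test_that("cross-platform evaluation transfers a shared planted signal", {
  cfg <- simulation_config(seed = 57, n_genes = 150,
                           n_wt = c(93, 60), n_mut = c(415, 90),
                           de_spec = data.frame(gene = 1:5, shift = 2),
                           shared_fraction = 1)
  sim <- simulate_pair_of_platforms(cfg)
  sel <- l1_select(sim$a$dataset, seed = 5)
  rep <- cross_platform_eval(sel$selected, sim$a$dataset, sim$b$dataset)
  expect_gte(rep$auc, 0.95)
  expect_true(all(rep$mapped %in% sel$selected))
  # label-shuffled target: chance level
  ds_b <- sim$b$dataset
  set.seed(58)
  shuf <- expression_dataset(ds_b$values,
                             sample(as.character(ds_b$labels)))
  rep0 <- cross_platform_eval(sel$selected, sim$a$dataset, shuf)
  expect_gte(rep0$auc, 0.35)
  expect_lte(rep0$auc, 0.65)
  # no selected gene on the target platform -> error
  expect_error(cross_platform_eval(c("NOPE1", "NOPE2"), sim$a$dataset,
                                   sim$b$dataset),
               "no selected gene")
})

test_that("the transfer protocol scores the target with source coefficients", {
  cfg <- simulation_config(seed = 59, n_genes = 50, n_wt = c(80, 40),
                           n_mut = c(80, 40),
                           de_spec = data.frame(gene = 1:3, shift = 2),
                           shared_fraction = 1)
  sim <- simulate_pair_of_platforms(cfg)
  rep <- cross_platform_eval(c("G0001", "G0002", "G0003"),
                             sim$a$dataset, sim$b$dataset,
                             protocol = "transfer")
  expect_gte(rep$auc, 0.9)
  expect_equal(rep$protocol, "transfer")
})
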