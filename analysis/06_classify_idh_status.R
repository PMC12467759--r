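#!/usr/bin/env Rscript
# Stage 6: cross-platform classification of IDH status. LASSO logistic
# regression selects predictor genes among one cohort's significant DEGs
# (penalty at minimum cross-validated loss); a plain logistic model with the
# mapped genes is then fitted on the other cohort and its AUC reported — both
# directions.

suppressMessages(library(dicoex))

dat <- "results/data"
out <- "results/classify"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 1L

ds_a <- read_expression(file.path(dat, "expr_a.tsv"),
                        file.path(dat, "labels_a.tsv"), platform_id = "A")
ds_b <- read_expression(file.path(dat, "expr_b.tsv"),
                        file.path(dat, "labels_b.tsv"), platform_id = "B")
deg_a <- read_table("results/deg/deg_a.tsv")
deg_b <- read_table("results/deg/deg_b.tsv")

eval_dir <- function(src, tgt, deg_src, label) {
  cand <- intersect(deg_src$gene[deg_src$significant], tgt$genes)
  sel <- l1_select(src, cand, n_folds = 10, seed = seed)
  rep <- cross_platform_eval(sel$selected, src, tgt, protocol = "refit")
  message(label, ": ", length(sel$selected), " genes selected (cv AUC ",
          round(sel$cv_auc, 3), "), ", length(rep$mapped),
          " mapped; target AUC ", round(rep$auc, 3))
  data.frame(direction = label, n_selected = length(sel$selected),
             n_mapped = length(rep$mapped), cv_auc_source = sel$cv_auc,
             auc_target = rep$auc,
             selected = paste(sel$selected, collapse = ","))
}

tab <- rbind(eval_dir(ds_a, ds_b, deg_a, "a_to_b"),
             eval_dir(ds_b, ds_a, deg_b, "b_to_a"))
write_table(tab, file.path(out, "classifier_report.tsv"))
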