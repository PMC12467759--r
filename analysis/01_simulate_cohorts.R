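#!/usr/bin/env Rscript
# Stage 1: generate the synthetic two-platform study.
#
# Emulates the two-cohort IDH-status design at desk scale: a large RNA-seq-like
# cohort (93 WT / 415 MUT) and a small unbalanced microarray-like cohort
# (14 WT / 166 MUT), 2,000 genes, 50 planted DE genes (2-SD shifts) and 20
# planted DCE pairs, half of all signals shared across platforms. Also builds
# the companion interaction network (cliques over the first planted genes) and
# a small gene-set collection, so every later stage has inputs.

suppressMessages(library(dicoex))

seed <- 1L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- default_simulation_config(seed = seed)
sim <- simulate_pair_of_platforms(cfg)

for (p in c("a", "b")) {
  s <- sim[[p]]
  write_expression(s$dataset,
                   file.path(out, paste0("expr_", p, ".tsv")),
                   file.path(out, paste0("labels_", p, ".tsv")))
  write_table(s$truth$de, file.path(out, paste0("truth_de_", p, ".tsv")))
  write_table(s$truth$dce, file.path(out, paste0("truth_dce_", p, ".tsv")))
}

genes <- sim$a$dataset$genes
net <- simulate_ppi_network(modules = list(genes[1:10], genes[11:20]),
                            background = genes[21:60], seed = seed)
write_table(net, file.path(out, "network.tsv"))
write_gmt(list(PLANTED_DE = sim$a$truth$de$gene,
               DECOY = genes[201:400]),
          file.path(out, "genesets.gmt"))

shared_de <- intersect(sim$a$truth$de$gene, sim$b$truth$de$gene)
shared_dce <- intersect(sim$a$truth$dce$pair_key, sim$b$truth$dce$pair_key)
message("platform A: ", length(sim$a$dataset$samples), " samples; platform B: ",
        length(sim$b$dataset$samples), " samples; ", length(genes), " genes")
message("planted: ", nrow(sim$a$truth$de), " DE genes (", length(shared_de),
        " shared), ", nrow(sim$a$truth$dce), " DCE pairs (",
        length(shared_dce), " shared)")
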