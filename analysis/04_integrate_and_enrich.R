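#!/usr/bin/env Rscript
# Stage 4: integration and enrichment. The replicated DEG list is intersected
# with the DCE-participating genes (provenance kept), and the DCE gene lists
# of both cohorts are tested for gene-set over-representation; terms
# significant in both cohorts are reported together.

suppressMessages(library(dicoex))

dat <- "results/data"
out <- "results/integrate"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

deg_common <- read_table("results/deg/deg_common.tsv")
dce_genes <- readLines("results/dce/dce_genes_common.txt")

integrated <- deg_dce_overlap(deg_common, dce_genes)
write_table(integrated, file.path(out, "integrated_genes.tsv"))
message(nrow(integrated), " genes called by both the DEG and DCE analyses")

sets <- read_gmt(file.path(dat, "genesets.gmt"))
ds_a_genes <- read_table(file.path(dat, "expr_a.tsv"))[[1]]
ds_b_genes <- read_table(file.path(dat, "expr_b.tsv"))[[1]]

genes_a <- genes_from_pairs({
  d <- read_table("results/dce/dce_a.tsv"); d[d$significant, ]
})
genes_b <- genes_from_pairs({
  d <- read_table("results/dce/dce_b.tsv"); d[d$significant, ]
})
enr_a <- enrich(genes_a, gene_set_collection(sets, ds_a_genes))
enr_b <- enrich(genes_b, gene_set_collection(sets, ds_b_genes))
write_table(enr_a, file.path(out, "enrichment_dce_a.tsv"))
write_table(enr_b, file.path(out, "enrichment_dce_b.tsv"))
common_terms <- intersect_enriched_terms(enr_a, enr_b)
write_table(as.data.frame(common_terms),
            file.path(out, "enrichment_common_terms.tsv"))
message(sum(enr_a$significant), " / ", sum(enr_b$significant),
        " terms significant in A / B; ", NROW(common_terms), " in both")

enr_deg <- enrich(deg_common$gene,
                  gene_set_collection(sets, intersect(ds_a_genes, ds_b_genes)))
write_table(enr_deg, file.path(out, "enrichment_deg_common.tsv"))
message("top term for the replicated DEGs: ", enr_deg$term[1],
        " (FDR ", signif(enr_deg$fdr[1], 3), ")")
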