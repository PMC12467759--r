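#!/usr/bin/env Rscript
# Stage 7: export connectivity-map-ready signatures. The replicated DEGs are
# ranked by the large cohort's p-values (the cohort with the most power) and
# the top 150 up- and downregulated genes are written as GRP files, plus the
# full integrated gene list.

suppressMessages(library(dicoex))

out <- "results/signatures"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

deg_a <- read_table("results/deg/deg_a.tsv")
deg_common <- read_table("results/deg/deg_common.tsv")
integrated <- read_table("results/integrate/integrated_genes.tsv")

ranked <- deg_a[deg_a$gene %in% deg_common$gene, ]
grp <- suppressWarnings(export_grp(ranked, file.path(out, "signature"),
                                   top_k = 150))
writeLines(integrated$gene, file.path(out, "integrated_genes.grp"))
message(length(grp$up), " up / ", length(grp$down),
        " down genes exported; ", nrow(integrated),
        " integrated genes exported as a single list")
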