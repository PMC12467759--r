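#!/usr/bin/env Rscript
# Stage 5: Markov clustering of the integrated genes on the interaction
# network. Clusters are ranked by node count, then induced edge count, and
# labelled CL1, CL2, ...; genes missing from the network stay as singletons.

suppressMessages(library(dicoex))

out <- "results/mcl"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

net <- read_edge_list("results/data/network.tsv")
integrated <- read_table("results/integrate/integrated_genes.tsv")

g <- induced_subgraph_genes(net, integrated$gene)
res <- mcl_cluster(g, inflation = 2)
tab <- cluster_table(res)
write_table(tab, file.path(out, "clusters.tsv"))

message(length(res$clusters), " clusters over ", sum(res$n_nodes),
        " genes (converged: ", res$converged, ")")
top <- res$labels[1]
message(top, ": ", res$n_nodes[1], " genes, ", res$n_edges[1], " edges — ",
        paste(res$clusters[[1]], collapse = ", "))
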