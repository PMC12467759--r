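#' Induced subgraph of an interaction network
#'
#' Restricts a weighted undirected network to a gene list. Every requested
#' gene becomes a node; genes absent from the network simply have no incident
#' edges (isolated nodes), so downstream clustering sees the full input set.
#'
#' @param network data.frame edge list (`gene_a`, `gene_b`, `weight`) or an
#'   igraph object with a `weight` edge attribute.
#' @param genes character vector of gene symbols to keep.
#' @return an undirected weighted igraph with vertices exactly `unique(genes)`.
#' @export
induced_subgraph_genes <- function(network, genes) {
  genes <- sort(unique(genes))
  if (inherits(network, "igraph")) {
    el <- igraph::as_data_frame(network, what = "edges")
    names(el)[1:2] <- c("gene_a", "gene_b")
    if (is.null(el$weight)) el$weight <- 1
  } else {
    el <- as.data.frame(network)
  }
  if (nrow(el) && any(el$weight < 0)) stop("edge weights must be non-negative")
  keep <- el$gene_a %in% genes & el$gene_b %in% genes
  el <- el[keep, c("gene_a", "gene_b", "weight"), drop = FALSE]
  g <- igraph::graph_from_data_frame(el, directed = FALSE,
                                     vertices = data.frame(name = genes))
  igraph::simplify(g, edge.attr.comb = list(weight = "max"))
}

#' Markov clustering (MCL) of a weighted undirected graph
#'
#' Canonical MCL: self-loops are added with weight equal to each node's
#' maximum incident edge weight (1 for isolated nodes), the adjacency matrix
#' is column-normalised, and expansion (matrix power) alternates with
#' inflation (entrywise power + renormalisation) and pruning of small entries
#' until the matrix is stable. Clusters are read from attractor rows;
#' attractor rows sharing nodes are merged, which resolves MCL's overlapping
#' cluster ambiguity deterministically. The output is invariant under
#' permutation of the input node order.
#'
#' @param graph igraph (undirected, non-negative weights) or edge-list
#'   data.frame accepted by [induced_subgraph_genes()].
#' @param inflation inflation exponent (default 2.0, the canonical default).
#' @param expansion expansion power (default 2).
#' @param prune entries below this are zeroed each iteration (default 1e-5).
#' @param max_iter iteration cap (default 100).
#' @param tol convergence tolerance on the max entry change (default 1e-6).
#' @return list of class `McclusterResult`: `clusters` (list of sorted gene
#'   vectors, ranked), `n_nodes`, `n_edges` (induced edge counts per cluster),
#'   `converged`, `iterations`.
#' @export
mcl_cluster <- function(graph, inflation = 2, expansion = 2, prune = 1e-5,
                        max_iter = 100L, tol = 1e-6) {
  if (!inherits(graph, "igraph")) {
    nodes <- sort(unique(c(graph$gene_a, graph$gene_b)))
    graph <- induced_subgraph_genes(graph, nodes)
  }
  w <- igraph::E(graph)$weight
  if (is.null(w)) w <- rep(1, igraph::ecount(graph))
  if (any(w < 0)) stop("edge weights must be non-negative")
  nodes <- sort(igraph::V(graph)$name)
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (igraph::ecount(graph)) {
    el <- igraph::as_data_frame(graph, what = "edges")
    A[cbind(el$from, el$to)] <- el$weight
    A[cbind(el$to, el$from)] <- el$weight
  }
  loop <- apply(A, 2L, max)
  diag(A) <- ifelse(loop > 0, loop, 1)
  M <- sweep(A, 2L, colSums(A), "/")
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    M2 <- M
    for (e in seq_len(expansion - 1L)) M2 <- M2 %*% M
    M2 <- M2^inflation
    M2 <- sweep(M2, 2L, colSums(M2), "/")
    M2[M2 < prune] <- 0
    M2 <- sweep(M2, 2L, colSums(M2), "/")
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("MCL did not converge in ", max_iter,
            " iterations; interpreting current matrix")
  }
  attractors <- which(diag(M) > 1e-8)
  member <- lapply(attractors, function(i) which(M[i, ] > 1e-8))
  # merge attractor rows that share nodes (union-find over overlaps)
  assign <- rep(NA_integer_, n)
  cl_id <- 0L
  for (mem in member) {
    hit <- unique(stats::na.omit(assign[mem]))
    if (!length(hit)) {
      cl_id <- cl_id + 1L
      assign[mem] <- cl_id
    } else {
      tgt <- min(hit)
      assign[mem] <- tgt
      assign[assign %in% hit] <- tgt
    }
  }
  # any node with no attractor mass (numerically orphaned) becomes a singleton
  for (i in which(is.na(assign))) {
    cl_id <- cl_id + 1L
    assign[i] <- cl_id
  }
  clusters <- lapply(split(nodes, assign), sort)
  n_edges <- vapply(clusters, function(cl) {
    sum(A[cl, cl, drop = FALSE][upper.tri(matrix(0, length(cl), length(cl)))] > 0)
  }, 0L)
  res <- structure(
    list(clusters = unname(clusters),
         n_nodes = unname(lengths(clusters)),
         n_edges = unname(n_edges),
         converged = converged, iterations = it),
    class = "McclusterResult"
  )
  rank_clusters(res)
}

#' Rank MCL clusters and assign CL labels
#'
#' Orders clusters by node count (descending), then induced edge count
#' (descending), then smallest member symbol (ascending), and labels them
#' CL1, CL2, ... in that order.
#'
#' @param result a `McclusterResult`.
#' @return the result with clusters reordered and a `labels` element.
#' @export
rank_clusters <- function(result) {
  stopifnot(inherits(result, "McclusterResult"))
  first <- vapply(result$clusters, `[`, "", 1L)
  ord <- order(-result$n_nodes, -result$n_edges, first)
  result$clusters <- result$clusters[ord]
  result$n_nodes <- result$n_nodes[ord]
  result$n_edges <- result$n_edges[ord]
  result$labels <- paste0("CL", seq_along(result$clusters))
  result
}

#' @export
print.McclusterResult <- function(x, ...) {
  cat(sprintf("MCL result: %d clusters over %d nodes (%s)\n",
              length(x$clusters), sum(x$n_nodes),
              if (x$converged) paste0("converged in ", x$iterations, " iterations")
              else "NOT converged"))
  invisible(x)
}

#' Flatten an MCL result to a table
#'
#' @param result a `McclusterResult` (already ranked).
#' @return data.frame `cluster`, `gene`, `n_nodes`, `n_edges`.
#' @export
cluster_table <- function(result) {
  stopifnot(inherits(result, "McclusterResult"))
  do.call(rbind, lapply(seq_along(result$clusters), function(i) {
    data.frame(cluster = result$labels[i], gene = result$clusters[[i]],
               n_nodes = result$n_nodes[i], n_edges = result$n_edges[i],
               stringsAsFactors = FALSE)
  }))
}
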