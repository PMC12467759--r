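#' Gene-set collection with a background universe
#'
#' @param sets named list of character vectors (e.g. from [read_gmt()]).
#' @param universe character vector of background gene symbols.
#' @return a `GeneSetCollection` list with elements `sets` (each intersected
#'   non-trivially with the universe) and `universe`. Sets that do not
#'   intersect the universe are dropped with a warning.
#' @export
gene_set_collection <- function(sets, universe) {
  if (!length(sets) || is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("sets must be a non-empty named list")
  }
  if (any(!lengths(sets))) stop("every set must be non-empty")
  universe <- unique(universe)
  hits <- vapply(sets, function(s) any(s %in% universe), TRUE)
  if (any(!hits)) {
    warning(sum(!hits), " set(s) with no gene in the universe dropped")
    sets <- sets[hits]
  }
  if (!length(sets)) stop("no set intersects the universe")
  structure(list(sets = sets, universe = universe),
            class = "GeneSetCollection")
}

#' Upper-tail hypergeometric p-value
#'
#' P(X >= k) where X counts query genes inside a term of size K, with a query
#' of size n drawn from a universe of size N; the exact tail is evaluated in
#' log space by `phyper`.
#'
#' @param k observed overlap.
#' @param K term size (within the universe).
#' @param n query size (within the universe).
#' @param N universe size.
#' @return upper-tail p-value P(X >= k).
#' @export
hypergeometric_p <- function(k, K, n, N) {
  if (any(k < 0 | K < 0 | n < 0 | N < 1)) stop("counts must be non-negative")
  if (any(k > pmin(K, n)) || any(pmax(K, n) > N)) {
    stop("inconsistent counts: need 0 <= k <= min(K, n) <= N")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation test of a gene list against a collection
#'
#' One hypergeometric upper-tail test per term, BH FDR across the collection's
#' terms. Query genes outside the universe are dropped with a warning.
#'
#' @param query character vector of gene symbols.
#' @param collection a [gene_set_collection()].
#' @param alpha_fdr FDR threshold for the `significant` flag (default 0.05).
#' @return data.frame sorted by FDR then p: `term`, `k`, `K`, `n`, `N`, `p`,
#'   `fdr`, `significant`, plus a `hits` column with the overlapping genes
#'   (comma-separated).
#' @export
enrich <- function(query, collection, alpha_fdr = 0.05) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  query <- unique(query)
  outside <- setdiff(query, collection$universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, collection$universe)
  }
  if (!length(query)) stop("empty query after intersection with universe")
  N <- length(collection$universe)
  n <- length(query)
  rows <- lapply(names(collection$sets), function(nm) {
    term <- intersect(collection$sets[[nm]], collection$universe)
    hits <- intersect(query, term)
    data.frame(term = nm, k = length(hits), K = length(term), n = n, N = N,
               p = hypergeometric_p(length(hits), length(term), n, N),
               hits = paste(sort(hits), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- adjust_pvalues(out$p, "bh")
  out$significant <- out$fdr < alpha_fdr
  out <- out[order(out$fdr, out$p, out$term),
             c("term", "k", "K", "n", "N", "p", "fdr", "significant", "hits")]
  rownames(out) <- NULL
  out
}
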