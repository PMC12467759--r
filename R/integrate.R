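#' Integrated DEG-and-DCE gene set
#'
#' Intersects the replicated DEG list with the genes participating in
#' differential co-expression, keeping provenance: every member was called by
#' both analyses, and carries its DE direction.
#'
#' @param common_degs data.frame from [intersect_deg()] (columns `gene`,
#'   `direction_a`) or a character vector of gene symbols.
#' @param dce_genes character vector of DCE-participating genes
#'   (e.g. [genes_from_pairs()] output).
#' @return data.frame `gene`, `from_deg`, `from_dce`, `direction` (NA when
#'   the DEG input carried no directions), sorted by gene.
#' @export
deg_dce_overlap <- function(common_degs, dce_genes) {
  if (is.data.frame(common_degs)) {
    genes <- common_degs$gene
    dirs <- if ("direction_a" %in% names(common_degs)) {
      common_degs$direction_a
    } else if ("direction" %in% names(common_degs)) {
      common_degs$direction
    } else {
      rep(NA_character_, length(genes))
    }
  } else {
    genes <- common_degs
    dirs <- rep(NA_character_, length(genes))
  }
  keep <- genes %in% dce_genes
  out <- data.frame(gene = genes[keep],
                    from_deg = rep(TRUE, sum(keep)),
                    from_dce = rep(TRUE, sum(keep)),
                    direction = dirs[keep], stringsAsFactors = FALSE)
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Terms significant in both datasets' enrichment results
#'
#' @param terms_a,terms_b data.frames from [enrich()] (their significant rows
#'   are used) or character vectors of term IDs.
#' @return when both inputs carry FDRs, a data.frame `term`, `fdr_a`, `fdr_b`
#'   sorted by the larger of the two FDRs (ascending); otherwise a sorted
#'   character vector of common terms.
#' @export
intersect_enriched_terms <- function(terms_a, terms_b) {
  pick <- function(x) {
    if (is.data.frame(x)) x[x$significant, c("term", "fdr")] else
      data.frame(term = x, fdr = NA_real_, stringsAsFactors = FALSE)
  }
  a <- pick(terms_a)
  b <- pick(terms_b)
  m <- merge(a, b, by = "term", suffixes = c("_a", "_b"))
  if (all(is.na(m$fdr_a)) && all(is.na(m$fdr_b))) {
    return(sort(m$term))
  }
  m <- m[order(pmax(m$fdr_a, m$fdr_b), m$term), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Export ranked up/down gene signatures as GRP files
#'
#' Writes the top-k upregulated and top-k downregulated genes (by ascending
#' raw p-value; ties broken by gene symbol) to plain-text GRP files, one
#' symbol per line — the input format of connectivity-map style tools, which
#' accept at most 150 genes per list.
#'
#' @param degs data.frame from [run_deg()] (needs `gene`, `p`, `direction`).
#' @param out_prefix path prefix; files `<prefix>_up.grp` and
#'   `<prefix>_down.grp` are written.
#' @param top_k maximum genes per list (default 150). If fewer are available,
#'   all are written with a warning.
#' @return invisibly, `list(up = <genes>, down = <genes>)`.
#' @export
export_grp <- function(degs, out_prefix, top_k = 150L) {
  take <- function(dir) {
    d <- degs[degs$direction == dir, , drop = FALSE]
    d <- d[order(d$p, d$gene), , drop = FALSE]
    if (nrow(d) < top_k) {
      warning("only ", nrow(d), " ", dir, " gene(s) available (asked for ",
              top_k, ")")
    }
    utils::head(d$gene, top_k)
  }
  up <- take("UP")
  down <- take("DOWN")
  writeLines(up, paste0(out_prefix, "_up.grp"))
  writeLines(down, paste0(out_prefix, "_down.grp"))
  invisible(list(up = up, down = down))
}
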