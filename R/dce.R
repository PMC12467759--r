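#' Variance filter
#'
#' Selects the top fraction of genes by expression variance, computed across
#' all samples pooled (both groups together) with the unbiased n-1
#' denominator. The number kept is `ceiling(fraction * n_genes)`; ties at the
#' cutoff are broken by gene symbol (ascending).
#'
#' @param ds an `ExpressionDataset`.
#' @param fraction fraction of genes to keep, in (0, 1]; default 0.25.
#' @return list with `selected` (gene symbols), `variance` (named, all genes)
#'   and `fraction`.
#' @export
variance_filter <- function(ds, fraction = 0.25) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  v <- apply(ds$values, 1L, stats::var)
  if (all(v == 0)) stop("all genes have zero variance")
  count <- ceiling(fraction * length(v))
  ord <- order(-v, names(v))
  list(selected = sort(names(v)[ord[seq_len(count)]]),
       variance = v, fraction = fraction)
}

#' Fisher z-transformation of a correlation
#'
#' z = atanh(r) = 0.5 * log((1 + r) / (1 - r)), the variance-stabilising
#' transform. Correlations with |r| >= 1 - 1e-7 are clamped to that boundary
#' (flagged via the `"clamped"` attribute) so degenerate perfect correlations
#' never produce infinities.
#'
#' @param r numeric vector of Pearson correlations, |r| <= 1.
#' @return numeric vector of z values, with attribute `clamped` (logical
#'   vector) when any input was clamped.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1, na.rm = TRUE)) stop("|r| must be <= 1")
  lim <- 1 - 1e-7
  clamped <- abs(r) > lim
  r[clamped] <- sign(r[clamped]) * lim
  z <- atanh(r)
  if (any(clamped)) attr(z, "clamped") <- clamped
  z
}

#' Differential co-expression z statistic for one gene pair
#'
#' Tests whether a pair's Pearson correlation differs between two groups:
#' Z = (z1 - z2) / sqrt(1/(N1-3) + 1/(N2-3)) with z = atanh(r), referred to
#' the standard normal. The two-sided p-value is computed through the log
#' tail, so it stays accurate far below 1e-300 (the returned `log_p` carries
#' the natural-log p even when `p` underflows).
#'
#' @param r1,r2 group correlations (vectors allowed, recycled together).
#' @param N1,N2 group sample sizes; both must exceed 3.
#' @return list with `Z`, `p` (two-sided) and `log_p` (natural log of p).
#' @export
dce_z_statistic <- function(r1, N1, r2, N2) {
  if (any(N1 <= 3) || any(N2 <= 3)) {
    stop("group sizes must exceed 3 (z variance is 1/(N-3))")
  }
  Z <- (fisher_z(r1) - fisher_z(r2)) / sqrt(1 / (N1 - 3) + 1 / (N2 - 3))
  log_p <- stats::pnorm(abs(Z), lower.tail = FALSE, log.p = TRUE) + log(2)
  log_p <- pmin(log_p, 0)
  list(Z = as.numeric(Z), p = exp(log_p), log_p = log_p)
}

#' Per-pair Bonferroni threshold for pairwise testing
#'
#' @param alpha family-wise error rate.
#' @param n_genes_filtered number of genes entering pairwise testing (>= 2).
#' @return `alpha / choose(n_genes_filtered, 2)`.
#' @export
bonferroni_pair_threshold <- function(alpha, n_genes_filtered) {
  if (n_genes_filtered < 2) stop("need at least 2 genes")
  bonferroni_threshold(alpha, choose(n_genes_filtered, 2))
}

#' Differential co-expression analysis over all filtered gene pairs
#'
#' Applies the variance filter, drops genes with zero variance within either
#' group (their correlations are undefined; the count is reported via
#' `message()`), computes per-group Pearson correlation matrices, and tests
#' every pair with [dce_z_statistic()]. Multiple-testing adjustment uses the
#' full pair family choose(m, 2).
#'
#' @param ds an `ExpressionDataset` with more than 3 samples per group.
#' @param fraction variance-filter fraction (default 0.25).
#' @param method `"bonferroni"` or `"bh"` for the significance flag.
#' @param alpha significance level.
#' @return data.frame with one row per pair: `gene_a`, `gene_b` (canonical
#'   order), `pair_key`, `r_wt`, `r_mut`, `z_wt`, `z_mut`, `Z`, `N1`, `N2`,
#'   `p`, `log_p`, `p_bonf`, `p_bh`, `delta_direction` (`GAIN`/`LOSS`),
#'   `significant`.
#' @export
run_dce <- function(ds, fraction = 0.25, method = c("bonferroni", "bh"),
                    alpha = 0.05) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  method <- match.arg(method)
  wt <- ds$labels == "WT"
  mut <- ds$labels == "MUT"
  N1 <- sum(wt)
  N2 <- sum(mut)
  if (N1 <= 3 || N2 <= 3) stop("both groups need more than 3 samples")
  keep <- variance_filter(ds, fraction)$selected
  sub <- ds$values[keep, , drop = FALSE]
  v_wt <- apply(sub[, wt, drop = FALSE], 1L, stats::var)
  v_mut <- apply(sub[, mut, drop = FALSE], 1L, stats::var)
  degen <- v_wt == 0 | v_mut == 0
  if (any(degen)) {
    message(sum(degen), " gene(s) with zero within-group variance excluded")
    sub <- sub[!degen, , drop = FALSE]
  }
  m <- nrow(sub)
  if (m < 2) stop("fewer than 2 genes left for pairwise testing")
  sub <- sub[order(rownames(sub)), , drop = FALSE]
  r_wt <- stats::cor(t(sub[, wt, drop = FALSE]))
  r_mut <- stats::cor(t(sub[, mut, drop = FALSE]))
  ut <- which(upper.tri(r_wt), arr.ind = TRUE)
  g <- rownames(sub)
  r1 <- r_wt[ut]
  r2 <- r_mut[ut]
  zt <- dce_z_statistic(r1, N1, r2, N2)
  n_tests <- choose(m, 2)
  out <- data.frame(
    gene_a = g[ut[, 1L]],
    gene_b = g[ut[, 2L]],
    r_wt = r1, r_mut = r2,
    z_wt = as.numeric(fisher_z(r1)), z_mut = as.numeric(fisher_z(r2)),
    Z = zt$Z, N1 = N1, N2 = N2,
    p = zt$p, log_p = zt$log_p,
    p_bonf = adjust_pvalues(zt$p, "bonferroni", m = n_tests),
    p_bh = adjust_pvalues(zt$p, "bh", m = n_tests),
    delta_direction = ifelse(r2 >= r1, "GAIN", "LOSS"),
    stringsAsFactors = FALSE
  )
  out$pair_key <- pair_key(out$gene_a, out$gene_b)
  out$significant <- switch(method, bonferroni = out$p_bonf,
                            bh = out$p_bh) < alpha
  attr(out, "n_genes_tested") <- m
  attr(out, "method") <- method
  attr(out, "alpha") <- alpha
  out
}

#' Overlap of significant pairs between two datasets
#'
#' Matches significant pairs on canonical pair keys (so (X,Y) in one table
#' matches (Y,X) in the other) and reports both datasets' correlations and
#' p-values side by side.
#'
#' @param a,b data.frames from [run_dce()].
#' @return data.frame with the pair key, gene symbols, and `r_wt`, `r_mut`,
#'   `p` from both datasets (suffixes `_a`, `_b`).
#' @export
overlap_pairs <- function(a, b) {
  sa <- a[a$significant, c("pair_key", "gene_a", "gene_b", "r_wt", "r_mut", "p")]
  sb <- b[b$significant, c("pair_key", "r_wt", "r_mut", "p")]
  m <- merge(sa, sb, by = "pair_key", suffixes = c("_a", "_b"))
  m <- m[order(m$pair_key), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Direction-consistent replicated pairs under the relaxed criterion
#'
#' Keeps pairs whose co-expression change has the same sign in both datasets
#' and that are significant after multiple-testing correction in one dataset
#' while at least nominally significant (raw p < `nominal_alpha`) in the
#' other — the relaxed cross-dataset replication rule.
#'
#' @param a,b data.frames from [run_dce()] carrying `significant` flags and
#'   raw p-values.
#' @param nominal_alpha nominal significance level for the relaxed side
#'   (default 0.05).
#' @return data.frame of kept pairs with both datasets' statistics.
#' @export
direction_consistent_pairs <- function(a, b, nominal_alpha = 0.05) {
  cols <- c("pair_key", "gene_a", "gene_b", "r_wt", "r_mut", "p", "significant")
  m <- merge(a[, cols], b[, cols[-(2:3)]], by = "pair_key",
             suffixes = c("_a", "_b"))
  same_dir <- sign(m$r_mut_a - m$r_wt_a) == sign(m$r_mut_b - m$r_wt_b)
  relaxed <- (m$significant_a & m$p_b < nominal_alpha) |
    (m$significant_b & m$p_a < nominal_alpha)
  m <- m[same_dir & relaxed, , drop = FALSE]
  m <- m[order(m$pair_key), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Unique genes participating in a set of pairs
#'
#' @param pairs data.frame with `gene_a`, `gene_b` columns (e.g. significant
#'   rows of [run_dce()] output, or [overlap_pairs()] output).
#' @return sorted character vector of unique gene symbols.
#' @export
genes_from_pairs <- function(pairs) {
  if (!nrow(pairs)) return(character())
  sort(unique(c(pairs$gene_a, pairs$gene_b)))
}
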