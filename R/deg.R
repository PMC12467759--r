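#' Wilcoxon rank-sum test between two groups
#'
#' Two-sided rank-sum test comparing WT and MUT expression values of one gene.
#' The default mode is the normal approximation with mid-ranks for ties,
#' tie-corrected variance and (optionally) continuity correction — standard
#' practice at cohort scale. An exact enumeration mode over all
#' choose(n1+n2, n1) group labelings is available for small samples
#' (n1 + n2 <= 12) and serves as the reference for the approximation.
#'
#' @param x numeric values of the WT group.
#' @param y numeric values of the MUT group.
#' @param exact if `TRUE`, enumerate all labelings (requires
#'   `length(x) + length(y) <= 12`); two-sided p = min(1, 2 * min tail).
#' @param correct apply continuity correction in the normal approximation.
#' @return list with `W` (rank sum of the WT group), `p` (two-sided) and
#'   `degenerate` (`TRUE` when all pooled values are identical, in which case
#'   p = 1).
#' @export
wilcoxon_rank_sum <- function(x, y, exact = FALSE, correct = TRUE) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  W <- sum(r[seq_len(n1)])
  if (length(unique(pooled)) == 1L) {
    return(list(W = W, p = 1, degenerate = TRUE))
  }
  if (exact) {
    n <- length(pooled)
    if (n > 12) stop("exact enumeration limited to n1 + n2 <= 12")
    combos <- utils::combn(n, n1)
    sums <- colSums(matrix(r[combos], nrow = n1))
    lo <- mean(sums <= W)
    hi <- mean(sums >= W)
    p <- min(1, 2 * min(lo, hi))
    return(list(W = W, p = p, degenerate = FALSE))
  }
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = correct)
  )
  list(W = W, p = ht$p.value, degenerate = FALSE)
}

#' Multiple-testing adjustment with an explicit family size
#'
#' Bonferroni: min(1, p * m). Benjamini–Hochberg: the standard step-up with
#' enforced monotonicity, computed for family size `m` (useful when the family
#' is larger than the vector actually carried around).
#'
#' @param p numeric vector of raw p-values in [0, 1].
#' @param method `"bonferroni"` or `"bh"`.
#' @param m family size (defaults to `length(p)`; must be >= `length(p)`).
#' @return adjusted p-values in the input order.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh"), m = length(p)) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  if (m < length(p)) stop("family size m must be >= length(p)")
  stats::p.adjust(p, method = switch(method, bonferroni = "bonferroni", bh = "BH"),
                  n = m)
}

#' Per-test Bonferroni threshold
#'
#' @param alpha family-wise error rate in (0, 1).
#' @param m number of tests (>= 1).
#' @return `alpha / m`, the raw-p threshold equivalent to Bonferroni-adjusted
#'   significance at `alpha`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (m < 1) stop("m must be >= 1")
  alpha / m
}

#' Differential expression by Wilcoxon rank-sum test
#'
#' Tests every gene for an expression difference between MUT and WT samples,
#' adjusts for multiple testing over the full gene family, and calls a
#' direction from the group means (UP = higher in MUT). Both Bonferroni and BH
#' adjusted p-values are reported; the `significant` flag uses the requested
#' method at level `alpha`.
#'
#' @param ds an `ExpressionDataset`.
#' @param method `"bonferroni"` or `"bh"` for the significance call.
#' @param alpha significance level (default 0.05).
#' @param correct continuity correction flag passed to [wilcoxon_rank_sum()].
#' @return data.frame with one row per gene: `gene`, `W`, `p`, `p_bonf`,
#'   `p_bh`, `direction` (`UP`/`DOWN`/`NONE`), `mean_wt`, `mean_mut`,
#'   `significant`.
#' @export
run_deg <- function(ds, method = c("bonferroni", "bh"), alpha = 0.05,
                    correct = TRUE) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  method <- match.arg(method)
  wt <- ds$labels == "WT"
  mut <- ds$labels == "MUT"
  if (!any(wt) || !any(mut)) stop("both groups must be non-empty")
  res <- apply(ds$values, 1L, function(v) {
    ht <- wilcoxon_rank_sum(v[wt], v[mut], correct = correct)
    c(ht$W, ht$p)
  })
  mean_wt <- rowMeans(ds$values[, wt, drop = FALSE])
  mean_mut <- rowMeans(ds$values[, mut, drop = FALSE])
  p <- res[2L, ]
  out <- data.frame(
    gene = ds$genes,
    W = res[1L, ],
    p = p,
    p_bonf = adjust_pvalues(p, "bonferroni"),
    p_bh = adjust_pvalues(p, "bh"),
    direction = ifelse(mean_mut > mean_wt, "UP",
                       ifelse(mean_mut < mean_wt, "DOWN", "NONE")),
    mean_wt = mean_wt,
    mean_mut = mean_mut,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out$significant <- switch(method,
                            bonferroni = out$p_bonf,
                            bh = out$p_bh) < alpha
  attr(out, "method") <- method
  attr(out, "alpha") <- alpha
  out
}

#' Cross-dataset intersection of significant DEGs
#'
#' Keeps genes flagged significant in both result tables; with
#' `require_same_direction` (the replication rule used throughout this
#' workflow) the direction of change must also agree, and genes with direction
#' `NONE` are excluded.
#'
#' @param a,b data.frames from [run_deg()] (with `significant` flags).
#' @param require_same_direction logical.
#' @return data.frame `gene`, `direction_a`, `direction_b`.
#' @export
intersect_deg <- function(a, b, require_same_direction = TRUE) {
  sa <- a[a$significant, c("gene", "direction")]
  sb <- b[b$significant, c("gene", "direction")]
  m <- merge(sa, sb, by = "gene", suffixes = c("_a", "_b"))
  if (require_same_direction) {
    m <- m[m$direction_a == m$direction_b &
             m$direction_a != "NONE", , drop = FALSE]
  }
  m <- m[order(m$gene), , drop = FALSE]
  rownames(m) <- NULL
  m
}
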