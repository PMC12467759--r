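#' Canonical gene-pair key
#'
#' Pairs are always keyed with the lexicographically smaller symbol first, so
#' (A,B) and (B,A) refer to the same pair everywhere.
#'
#' @param a,b character vectors of gene symbols (recycled).
#' @return character vector of keys `"<min>|<max>"`.
#' @export
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

hash_string <- function(s) {
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  h
}

#' Simulation configuration
#'
#' Describes a two-group expression study with planted differentially
#' expressed (DE) genes and planted differentially co-expressed (DCE) gene
#' blocks. Two platforms (cohorts) may have different sample sizes; signal
#' placement is shared between platforms according to `shared_fraction`.
#'
#' @param seed integer master seed; all generation is a pure function of
#'   (seed, config, platform).
#' @param n_genes number of genes.
#' @param n_wt,n_mut per-platform group sizes; scalars or length-2 vectors
#'   (platform 1, platform 2). Must be >= 4 (the Fisher z test needs N > 3).
#' @param de_spec data.frame with columns `gene` (index) and `shift` (signed
#'   mean shift in units of `noise_sd`).
#' @param dce_spec list of blocks, each `list(genes = <indices>, r_wt, r_mut)`;
#'   within a block the group correlation matrix is exchangeable with the
#'   given off-diagonal. Blocks must be disjoint and |r| < 1.
#' @param shared_fraction fraction of planted signals common to both
#'   platforms (rounded count of each signal list).
#' @param marginal `"gaussian"` or `"lognormal"` (the Gaussian draw is
#'   exponentiated).
#' @param noise_sd positive marginal standard deviation.
#' @return a `SimulationConfig` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_genes = 200L,
                              n_wt = 93L,
                              n_mut = 415L,
                              de_spec = NULL,
                              dce_spec = NULL,
                              shared_fraction = 1,
                              marginal = c("gaussian", "lognormal"),
                              noise_sd = 1) {
  marginal <- match.arg(marginal)
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (shared_fraction < 0 || shared_fraction > 1) {
    stop("shared_fraction must lie in [0, 1]")
  }
  if (any(c(n_wt, n_mut) < 4)) stop("group sizes must be >= 4 (N - 3 > 0)")
  if (is.null(de_spec)) de_spec <- data.frame(gene = integer(), shift = numeric())
  de_spec <- as.data.frame(de_spec)
  if (nrow(de_spec) && (any(de_spec$gene < 1) || any(de_spec$gene > n_genes))) {
    stop("de_spec gene index out of range")
  }
  if (anyDuplicated(de_spec$gene)) stop("duplicate DE gene indices")
  if (is.null(dce_spec)) dce_spec <- list()
  all_block <- unlist(lapply(dce_spec, `[[`, "genes"))
  if (length(all_block)) {
    if (anyDuplicated(all_block)) stop("DCE blocks must be disjoint")
    if (any(all_block < 1) || any(all_block > n_genes)) {
      stop("dce_spec gene index out of range")
    }
  }
  for (b in dce_spec) {
    if (abs(b$r_wt) >= 1 || abs(b$r_mut) >= 1) stop("|r| must be < 1")
    if (length(b$genes) < 2) stop("DCE blocks need at least 2 genes")
  }
  structure(
    list(seed = as.integer(seed), n_genes = as.integer(n_genes),
         n_wt = as.integer(n_wt), n_mut = as.integer(n_mut),
         de_spec = de_spec, dce_spec = dce_spec,
         shared_fraction = shared_fraction, marginal = marginal,
         noise_sd = noise_sd),
    class = "SimulationConfig"
  )
}

#' Default two-cohort study configuration
#'
#' Emulates the study design this workflow targets, at desk scale: a large
#' cohort (93 WT / 415 MUT) and a small unbalanced cohort (14 WT / 166 MUT),
#' 2,000 genes, 50 planted DE genes at a 2-SD shift (alternating up/down, so
#' both directions are represented among the shared signals), and
#' 20 planted DCE pairs. Half of the DCE pairs sit inside the DE gene set so
#' that the integrated (DEG-and-DCE) gene set is non-empty by construction.
#' Correlation changes mirror the magnitudes observed in replicated real
#' pairs (e.g. 0.93 vs 0.75, 0.89 vs 0.05); half of all planted signals are
#' shared across platforms.
#'
#' @param seed integer master seed.
#' @param n_genes number of genes (default 2,000).
#' @return a `SimulationConfig`.
#' @export
default_simulation_config <- function(seed = 1L, n_genes = 2000L) {
  de <- data.frame(gene = 1:50, shift = rep(c(2, -2), 25))
  r_pairs <- list(
    c(0.93, 0.75), c(0.90, 0.00), c(0.95, 0.20), c(-0.80, 0.10),
    c(0.20, 0.85), c(0.85, -0.10), c(0.92, 0.30), c(-0.60, 0.40),
    c(0.88, 0.05), c(0.75, -0.35)
  )
  blocks <- vector("list", 20L)
  for (i in 1:10) { # pairs inside the DE gene set
    blocks[[i]] <- list(genes = c(2L * i - 1L, 2L * i),
                        r_wt = r_pairs[[i]][1], r_mut = r_pairs[[i]][2])
  }
  for (i in 1:10) { # pairs outside it
    blocks[[10L + i]] <- list(genes = c(49L + 2L * i, 50L + 2L * i),
                              r_wt = r_pairs[[i]][1], r_mut = r_pairs[[i]][2])
  }
  simulation_config(
    seed = seed, n_genes = n_genes,
    n_wt = c(93L, 14L), n_mut = c(415L, 166L),
    de_spec = de, dce_spec = blocks,
    shared_fraction = 0.5, marginal = "gaussian", noise_sd = 1
  )
}

gene_names <- function(n) sprintf("G%0*d", max(4L, nchar(n)), seq_len(n))

# exchangeable-correlation Cholesky for one block; errors if not PD
block_chol <- function(k, r) {
  sigma <- matrix(r, k, k)
  diag(sigma) <- 1
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) {
    stop("block correlation matrix not positive definite (k = ", k,
         ", r = ", r, ")")
  }
  ch
}

#' Simulate one platform's expression dataset
#'
#' Non-planted genes are i.i.d. Gaussian noise; each DCE block is drawn, per
#' group, from a multivariate normal with an exchangeable correlation matrix
#' at the block's group-specific off-diagonal; DE genes get their mean shift
#' (in SD units) added to the MUT group. With `marginal = "lognormal"` the
#' Gaussian draw is exponentiated. Generation is a pure function of
#' (seed, config, platform).
#'
#' @param cfg a [simulation_config()].
#' @param platform 1 or 2; selects the per-platform sample sizes.
#' @param platform_id label stored on the dataset (also feeds the RNG
#'   substream, so platforms have independent draws).
#' @return `list(dataset = ExpressionDataset, truth = list(de, dce))` where
#'   `truth$de` has columns gene/shift/direction and `truth$dce` has columns
#'   gene_a/gene_b/r_wt/r_mut/pair_key.
#' @export
simulate_dataset <- function(cfg, platform = 1L,
                             platform_id = paste0("P", platform)) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  i <- min(platform, length(cfg$n_wt))
  n_wt <- cfg$n_wt[i]
  n_mut <- cfg$n_mut[min(platform, length(cfg$n_mut))]
  n <- n_wt + n_mut
  set.seed(as.integer((as.numeric(cfg$seed) * 48271 +
                         hash_string(platform_id)) %% 2147483647))
  g <- cfg$n_genes
  vals <- matrix(stats::rnorm(g * n), g, n)
  wt_cols <- seq_len(n_wt)
  mut_cols <- n_wt + seq_len(n_mut)
  for (b in cfg$dce_spec) {
    k <- length(b$genes)
    vals[b$genes, wt_cols] <- t(matrix(stats::rnorm(n_wt * k), n_wt, k) %*%
                                  block_chol(k, b$r_wt))
    vals[b$genes, mut_cols] <- t(matrix(stats::rnorm(n_mut * k), n_mut, k) %*%
                                   block_chol(k, b$r_mut))
  }
  vals <- vals * cfg$noise_sd
  if (nrow(cfg$de_spec)) {
    vals[cfg$de_spec$gene, mut_cols] <-
      vals[cfg$de_spec$gene, mut_cols] + cfg$de_spec$shift * cfg$noise_sd
  }
  if (cfg$marginal == "lognormal") vals <- exp(vals)
  gn <- gene_names(g)
  rownames(vals) <- gn
  colnames(vals) <- sprintf("%s_S%03d", platform_id, seq_len(n))
  labels <- rep(c("WT", "MUT"), c(n_wt, n_mut))
  ds <- expression_dataset(vals, labels, platform_id = platform_id)
  de <- cfg$de_spec
  truth_de <- data.frame(
    gene = gn[de$gene],
    shift = de$shift,
    direction = ifelse(de$shift > 0, "UP", "DOWN"),
    stringsAsFactors = FALSE
  )
  truth_dce <- do.call(rbind, lapply(cfg$dce_spec, function(b) {
    idx <- t(utils::combn(sort(b$genes), 2L))
    data.frame(gene_a = gn[idx[, 1]], gene_b = gn[idx[, 2]],
               r_wt = b$r_wt, r_mut = b$r_mut, stringsAsFactors = FALSE)
  }))
  if (is.null(truth_dce)) {
    truth_dce <- data.frame(gene_a = character(), gene_b = character(),
                            r_wt = numeric(), r_mut = numeric())
  }
  truth_dce$pair_key <- pair_key(truth_dce$gene_a, truth_dce$gene_b)
  list(dataset = ds, truth = list(de = truth_de, dce = truth_dce))
}

# split a signal list into (shared, private-to-A) and relocate a disjoint
# private set for B onto unused gene indices
split_signals <- function(cfg) {
  n_de <- nrow(cfg$de_spec)
  n_blk <- length(cfg$dce_spec)
  sh_de <- round(cfg$shared_fraction * n_de)
  sh_blk <- round(cfg$shared_fraction * n_blk)
  used <- sort(unique(c(cfg$de_spec$gene,
                        unlist(lapply(cfg$dce_spec, `[[`, "genes")))))
  free <- setdiff(seq_len(cfg$n_genes), used)
  need <- (n_de - sh_de) +
    sum(vapply(cfg$dce_spec, function(b) length(b$genes), 0L)[
      seq_len(n_blk) > sh_blk])
  if (need > length(free)) {
    stop("not enough unplanted genes to host platform-private signals")
  }
  de_b <- cfg$de_spec
  take <- 0L
  if (n_de > sh_de) {
    priv <- (sh_de + 1L):n_de
    de_b$gene[priv] <- free[seq_along(priv)]
    take <- length(priv)
  }
  dce_b <- cfg$dce_spec
  if (n_blk > sh_blk) {
    for (j in (sh_blk + 1L):n_blk) {
      k <- length(dce_b[[j]]$genes)
      dce_b[[j]]$genes <- free[take + seq_len(k)]
      take <- take + k
    }
  }
  list(de_b = de_b, dce_b = dce_b)
}

#' Simulate a pair of platforms sharing part of their planted signal
#'
#' Platform 1 carries the configured signals; platform 2 carries the shared
#' fraction at the same gene positions (identical directions and r-values)
#' plus relocated platform-private signals on genes untouched in platform 1,
#' so private signals are disjoint between platforms.
#'
#' @param cfg a [simulation_config()] with `shared_fraction` set.
#' @return list with elements `a` and `b`, each as returned by
#'   [simulate_dataset()].
#' @export
simulate_pair_of_platforms <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  a <- simulate_dataset(cfg, platform = 1L, platform_id = "P1")
  moved <- split_signals(cfg)
  cfg_b <- cfg
  cfg_b$de_spec <- moved$de_b
  cfg_b$dce_spec <- moved$dce_b
  b <- simulate_dataset(cfg_b, platform = 2L, platform_id = "P2")
  list(a = a, b = b)
}

#' Sensitivity and false discovery proportion of a called set
#'
#' @param truth character vector of true item keys (gene symbols or pair
#'   keys from [pair_key()]).
#' @param called character vector of called items.
#' @return `c(sensitivity, fdp)` with sensitivity = |called ∩ truth| / |truth|
#'   and FDP = |called \ truth| / max(1, |called|).
#' @export
recovery_metrics <- function(truth, called) {
  truth <- unique(truth)
  called <- unique(called)
  sens <- if (length(truth)) length(intersect(called, truth)) / length(truth) else NA_real_
  fdp <- length(setdiff(called, truth)) / max(1L, length(called))
  c(sensitivity = sens, fdp = fdp)
}

#' Simulate a weighted interaction network with planted cliques
#'
#' Builds an edge list in which each supplied module is a clique of high-weight
#' edges, plus sparse random background edges among the remaining genes —
#' enough structure for the Markov clustering stage to have something real to
#' find in an end-to-end run.
#'
#' @param modules list of character vectors (genes forming cliques).
#' @param background character vector of additional genes.
#' @param n_background_edges number of random low-weight background edges.
#' @param clique_weight weight on within-module edges.
#' @param seed integer seed.
#' @return data.frame with columns `gene_a`, `gene_b`, `weight`.
#' @export
simulate_ppi_network <- function(modules, background = character(),
                                 n_background_edges = 2L * length(background),
                                 clique_weight = 0.9, seed = 1L) {
  set.seed(as.integer(seed))
  edges <- do.call(rbind, lapply(modules, function(m) {
    if (length(m) < 2) return(NULL)
    idx <- t(utils::combn(sort(m), 2L))
    data.frame(gene_a = idx[, 1], gene_b = idx[, 2], weight = clique_weight,
               stringsAsFactors = FALSE)
  }))
  pool <- unique(c(unlist(modules), background))
  if (n_background_edges > 0 && length(pool) >= 2) {
    bg <- data.frame(
      gene_a = sample(pool, n_background_edges, replace = TRUE),
      gene_b = sample(pool, n_background_edges, replace = TRUE),
      weight = stats::runif(n_background_edges, 0.15, 0.4),
      stringsAsFactors = FALSE
    )
    bg <- bg[bg$gene_a != bg$gene_b, , drop = FALSE]
    edges <- rbind(edges, bg)
  }
  if (is.null(edges)) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      weight = numeric()))
  }
  key <- pair_key(edges$gene_a, edges$gene_b)
  edges <- edges[!duplicated(key), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}
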