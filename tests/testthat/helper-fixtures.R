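# deterministic small dataset: g genes x (n_wt + n_mut) samples
make_ds <- function(g = 6, n_wt = 4, n_mut = 4, seed = 1, platform = "T") {
  set.seed(seed)
  vals <- matrix(rnorm(g * (n_wt + n_mut)), g,
                 dimnames = list(sprintf("G%02d", seq_len(g)),
                                 sprintf("%s_S%02d", platform, seq_len(n_wt + n_mut))))
  expression_dataset(vals, rep(c("WT", "MUT"), c(n_wt, n_mut)),
                     platform_id = platform)
}

# build a run_deg/run_dce-shaped record table by hand for rule tests
fake_deg <- function(genes, directions, significant = TRUE) {
  data.frame(gene = genes, W = 0, p = 0.001, p_bonf = 0.01, p_bh = 0.01,
             direction = directions, mean_wt = 0, mean_mut = 1,
             significant = significant, stringsAsFactors = FALSE)
}

fake_dce <- function(gene_a, gene_b, r_wt, r_mut, p, significant) {
  out <- data.frame(gene_a = gene_a, gene_b = gene_b, r_wt = r_wt,
                    r_mut = r_mut, Z = 0, N1 = 50, N2 = 50, p = p,
                    log_p = log(p), p_bonf = pmin(1, p * 10),
                    p_bh = pmin(1, p * 10),
                    delta_direction = ifelse(r_mut >= r_wt, "GAIN", "LOSS"),
                    significant = significant, stringsAsFactors = FALSE)
  out$pair_key <- pair_key(out$gene_a, out$gene_b)
  out
}

# two k-cliques with given weights, optional bridge between them
two_cliques <- function(k = 3, w = 0.9, bridge = NA) {
  a <- sprintf("A%d", seq_len(k))
  b <- sprintf("B%d", seq_len(k))
  el <- rbind(
    do.call(rbind, lapply(utils::combn(a, 2, simplify = FALSE),
                          function(p) data.frame(gene_a = p[1], gene_b = p[2],
                                                 weight = w))),
    do.call(rbind, lapply(utils::combn(b, 2, simplify = FALSE),
                          function(p) data.frame(gene_a = p[1], gene_b = p[2],
                                                 weight = w)))
  )
  if (!is.na(bridge)) {
    el <- rbind(el, data.frame(gene_a = a[k], gene_b = b[1], weight = bridge))
  }
  el
}
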