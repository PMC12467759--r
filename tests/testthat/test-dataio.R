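test_that("expression matrix write/read round trip is the identity", {
  ds <- make_ds(g = 20, n_wt = 5, n_mut = 5, seed = 3)
  mp <- withr::local_tempfile(fileext = ".tsv")
  lp <- withr::local_tempfile(fileext = ".tsv")
  write_expression(ds, mp, lp)
  back <- read_expression(mp, lp, platform_id = "T")
  expect_equal(back$values, ds$values)
  expect_equal(back$genes, ds$genes)
  expect_equal(as.character(back$labels), as.character(ds$labels))
})

test_that("read_expression validates its contract", {
  ds <- make_ds(g = 3, n_wt = 2, n_mut = 2)
  mp <- withr::local_tempfile(fileext = ".tsv")
  lp <- withr::local_tempfile(fileext = ".tsv")
  write_expression(ds, mp, lp)
  got <- read_expression(mp, lp)
  expect_equal(dim(got$values), c(3L, 4L))

  # sample missing from labels -> error
  lab <- read.delim(lp)
  write.table(lab[-1, ], lp, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_expression(mp, lp), "absent from labels")

  # unknown group label -> error
  lab$group[1] <- "HET"
  write.table(lab, lp, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_expression(mp, lp), "unknown group")
})

test_that("non-numeric rows are dropped with a warning", {
  mp <- withr::local_tempfile(fileext = ".tsv")
  lp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tS1\tS2", "G1\t1.5\t2.0", "G2\tlow\t3.1"), mp)
  writeLines(c("sample_id\tgroup", "S1\tWT", "S2\tMUT"), lp)
  expect_warning(ds <- read_expression(mp, lp), "non-numeric")
  expect_equal(ds$genes, "G1")
})

test_that("collapse_probes keeps the max-variance probe per gene", {
  vals <- rbind(
    PR1 = c(1, 2, 3, 4),    # var 5/3
    PR2 = c(0, 2, 4, 6),    # var 20/3 -> wins for GENE1
    PR3 = c(5, 5, 5, 6)
  )
  colnames(vals) <- paste0("S", 1:4)
  ds <- expression_dataset(vals, c("WT", "WT", "MUT", "MUT"))
  pm <- data.frame(probe_id = c("PR1", "PR2", "PR3"),
                   gene_symbol = c("GENE1", "GENE1", "GENE2"))
  out <- collapse_probes(ds, pm)
  expect_equal(sort(out$genes), c("GENE1", "GENE2"))
  expect_equal(unname(out$values["GENE1", ]), c(0, 2, 4, 6))
  expect_equal(out$samples, ds$samples)  # column order preserved
})

test_that("collapse_probes drops unmapped probes and is identity when 1:1", {
  ds <- make_ds(g = 4)
  pm <- data.frame(probe_id = ds$genes[1:3],
                   gene_symbol = paste0("SYM", 1:3))
  expect_message(out <- collapse_probes(ds, pm), "1 unmapped")
  expect_equal(length(out$genes), 3L)
  # all probes distinct genes -> values unchanged (up to row order)
  pm2 <- data.frame(probe_id = ds$genes, gene_symbol = ds$genes)
  out2 <- collapse_probes(ds, pm2)
  expect_equal(out2$values[ds$genes, ], ds$values)
  expect_lte(length(out2$genes), length(ds$genes))
  # a probe mapping to two genes is an error
  expect_error(probe_map(data.frame(probe_id = c("P1", "P1"),
                                    gene_symbol = c("A", "B"))),
               "more than one gene")
})

test_that("GMT parsing handles the standard format and rejects bad lines", {
  p <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc\tA\tB\tC", "S2\tdesc\tB\tD"), p)
  sets <- read_gmt(p)
  expect_equal(sets$S1, c("A", "B", "C"))
  expect_equal(sets$S2, c("B", "D"))
  writeLines(c("S1\tdesc"), p)
  expect_error(read_gmt(p), "line 1")
  # write/read round trip
  p2 <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(list(S1 = c("A", "B", "C"), S2 = c("B", "D")), p2)
  expect_equal(read_gmt(p2), list(S1 = c("A", "B", "C"), S2 = c("B", "D")))
})

test_that("edge lists enforce weights in (0,1] and drop self-edges", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_a\tgene_b\tweight", "A\tB\t0.9", "B\tC\t0"), p)
  expect_error(read_edge_list(p), "outside")
  writeLines(c("gene_a\tgene_b\tweight", "A\tB\t0.9", "C\tC\t0.5"), p)
  expect_warning(el <- read_edge_list(p), "self-edge")
  expect_equal(nrow(el), 1L)
})

test_that("record tables round trip at full precision", {
  p <- withr::local_tempfile(fileext = ".tsv")
  tab <- data.frame(gene = c("A", "B"), p = c(3.834915e-300, 0.049999999999),
                    Z = c(-37.1234567890123, 0.5))
  write_table(tab, p)
  back <- read_table(p)
  expect_equal(back$p, tab$p, tolerance = 1e-12)
  expect_equal(back$Z, tab$Z, tolerance = 1e-12)
  expect_equal(names(back), names(tab))
})
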