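#' Construct an expression dataset
#'
#' The central container for all downstream analyses: a gene-by-sample numeric
#' matrix with a binary group label (`MUT` vs `WT`, i.e. IDH mutation status)
#' per sample and a platform tag. Values are taken on the platform's native
#' scale (RSEM, log2 microarray intensity, ...); no transform is applied
#' internally, since all downstream statistics are rank- or correlation-based.
#'
#' @param values numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample IDs). All entries must be finite.
#' @param labels character or factor of per-sample groups, `"MUT"` or `"WT"`,
#'   either unnamed (aligned to `colnames(values)`) or named by sample ID.
#' @param platform_id short label for the platform/cohort.
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `platform_id`, `genes`, `samples`, `values` and `labels` (factor with
#'   levels `WT`, `MUT`, in that order, so "direction" always means change in
#'   the mutant group relative to wild type).
#' @export
expression_dataset <- function(values, labels, platform_id = "platform") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate gene symbols")
  if (anyDuplicated(colnames(values))) stop("duplicate sample IDs")
  if (!all(is.finite(values))) stop("all expression values must be finite")
  if (!is.null(names(labels))) {
    missing <- setdiff(colnames(values), names(labels))
    if (length(missing)) {
      stop("samples absent from labels: ", paste(missing, collapse = ", "))
    }
    labels <- labels[colnames(values)]
  } else if (length(labels) != ncol(values)) {
    stop("labels length does not match sample count")
  }
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("WT", "MUT"))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  labels <- factor(labels, levels = c("WT", "MUT"))
  if (any(table(labels) == 0)) stop("both groups (WT, MUT) must be non-empty")
  structure(
    list(
      platform_id = platform_id,
      genes = rownames(values),
      samples = colnames(values),
      values = values,
      labels = stats::setNames(labels, colnames(values))
    ),
    class = "ExpressionDataset"
  )
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf(
    "ExpressionDataset '%s': %d genes x %d samples (%d WT, %d MUT)\n",
    x$platform_id, length(x$genes), length(x$samples),
    sum(x$labels == "WT"), sum(x$labels == "MUT")
  ))
  invisible(x)
}

#' Read an expression matrix and its sample labels
#'
#' @param matrix_path TSV with a header row of sample IDs and one row per
#'   gene/probe; first column holds the gene/probe identifier.
#' @param labels_path TSV with columns `sample_id` and `group` (values `MUT`
#'   or `WT`).
#' @param platform_id platform tag stored on the dataset.
#' @return An [expression_dataset()]. Rows containing non-numeric entries are
#'   dropped with a warning.
#' @export
read_expression <- function(matrix_path, labels_path, platform_id = "platform") {
  mat <- data.table::fread(matrix_path, sep = "\t", header = TRUE,
                           colClasses = list(character = 1), data.table = FALSE)
  if (ncol(mat) < 2) stop("expression matrix needs an ID column plus samples")
  ids <- mat[[1]]
  if (anyDuplicated(ids)) stop("duplicate gene/probe IDs in ", matrix_path)
  vals <- as.matrix(mat[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    suppressWarnings(storage.mode(vals) <- "double")
  }
  bad_rows <- !stats::complete.cases(vals) | rowSums(!is.finite(vals)) > 0
  if (any(bad_rows)) {
    warning(sum(bad_rows), " row(s) with non-numeric entries dropped")
    vals <- vals[!bad_rows, , drop = FALSE]
    ids <- ids[!bad_rows]
  }
  if (!nrow(vals)) stop("no numeric rows left in ", matrix_path)
  rownames(vals) <- ids
  lab <- data.table::fread(labels_path, sep = "\t", header = TRUE,
                           data.table = FALSE)
  if (!all(c("sample_id", "group") %in% names(lab))) {
    stop("labels file must have columns sample_id and group")
  }
  if (anyDuplicated(lab$sample_id)) stop("duplicate sample IDs in labels")
  missing <- setdiff(colnames(vals), lab$sample_id)
  if (length(missing)) {
    stop("samples in matrix absent from labels: ", paste(missing, collapse = ", "))
  }
  expression_dataset(vals,
                     stats::setNames(lab$group, lab$sample_id),
                     platform_id = platform_id)
}

#' Write an expression dataset to matrix + labels TSVs
#'
#' Inverse of [read_expression()]; values are written at full precision so a
#' read/write round trip is the identity.
#'
#' @param ds an `ExpressionDataset`.
#' @param matrix_path,labels_path output TSV paths.
#' @export
write_expression <- function(ds, matrix_path, labels_path) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  out <- data.frame(gene = ds$genes, ds$values, check.names = FALSE)
  data.table::fwrite(out, matrix_path, sep = "\t")
  data.table::fwrite(
    data.frame(sample_id = ds$samples, group = as.character(ds$labels)),
    labels_path, sep = "\t"
  )
  invisible(c(matrix_path, labels_path))
}

#' Read a probe-to-gene mapping table
#'
#' @param path TSV with columns `probe_id` and `gene_symbol`; many probes may
#'   map to one gene, but a probe mapping to more than one gene is an error.
#' @return data.frame with columns `probe_id`, `gene_symbol`.
#' @export
read_probe_map <- function(path) {
  pm <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (!all(c("probe_id", "gene_symbol") %in% names(pm))) {
    stop("probe map must have columns probe_id and gene_symbol")
  }
  probe_map(pm)
}

#' Validate a probe map
#' @param pm data.frame with columns `probe_id`, `gene_symbol`.
#' @return the validated data.frame.
#' @export
probe_map <- function(pm) {
  pm <- as.data.frame(pm)[, c("probe_id", "gene_symbol")]
  if (anyDuplicated(pm$probe_id)) {
    dup <- unique(pm$probe_id[duplicated(pm$probe_id)])
    stop("probe(s) mapping to more than one gene: ", paste(dup, collapse = ", "))
  }
  pm
}

#' Collapse probe-level rows to gene level
#'
#' When several probes map to the same gene, the probe with the highest
#' variance across all samples is kept — the conventional rule, and the one
#' that interacts correctly with the downstream variance filter. Probes absent
#' from the map are dropped (count reported via `message()`).
#'
#' @param ds probe-level `ExpressionDataset`.
#' @param pm probe map ([probe_map()]).
#' @return gene-level `ExpressionDataset` with the same samples in the same
#'   order.
#' @export
collapse_probes <- function(ds, pm) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  pm <- probe_map(pm)
  idx <- match(ds$genes, pm$probe_id)
  unmapped <- sum(is.na(idx))
  if (unmapped) message(unmapped, " unmapped probe(s) dropped")
  keep <- which(!is.na(idx))
  if (!length(keep)) stop("no probes left after mapping")
  gene <- pm$gene_symbol[idx[keep]]
  vals <- ds$values[keep, , drop = FALSE]
  v <- apply(vals, 1L, stats::var)
  # within each gene keep the max-variance probe; ties broken by probe ID
  ord <- order(gene, -v, rownames(vals))
  first <- !duplicated(gene[ord])
  sel <- ord[first]
  out <- vals[sel, , drop = FALSE]
  rownames(out) <- gene[sel]
  out <- out[order(rownames(out)), , drop = FALSE]
  expression_dataset(out, ds$labels, platform_id = ds$platform_id)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' member genes.
#'
#' @param path GMT file path.
#' @return named list of character vectors (gene sets).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      stop("malformed GMT line ", i, ": fewer than 3 fields")
    }
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) stop("malformed GMT line ", i, ": empty set")
    if (f[[1]] %in% names(sets)) stop("duplicate set name at line ", i)
    sets[[f[[1]]]] <- members
  }
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a weighted undirected edge list
#'
#' @param path TSV with columns `gene_a`, `gene_b`, `weight`; weights must lie
#'   in (0, 1]. Self-edges are dropped with a warning.
#' @return data.frame with columns `gene_a`, `gene_b`, `weight`.
#' @export
read_edge_list <- function(path) {
  el <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (!all(c("gene_a", "gene_b", "weight") %in% names(el))) {
    stop("edge list must have columns gene_a, gene_b, weight")
  }
  bad <- which(!is.finite(el$weight) | el$weight <= 0 | el$weight > 1)
  if (length(bad)) {
    stop("edge weight outside (0,1] at data line(s): ",
         paste(bad, collapse = ", "))
  }
  self <- el$gene_a == el$gene_b
  if (any(self)) {
    warning(sum(self), " self-edge(s) dropped")
    el <- el[!self, , drop = FALSE]
  }
  el
}

#' Write a result table as TSV
#'
#' Stable column order, full-precision numerics (>= 15 significant digits), so
#' that read/write is the identity on record tables.
#'
#' @param records data.frame.
#' @param path output TSV path.
#' @export
write_table <- function(records, path) {
  data.table::fwrite(as.data.frame(records), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a result table written by [write_table()]
#' @param path TSV path.
#' @return data.frame.
#' @export
read_table <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
}
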