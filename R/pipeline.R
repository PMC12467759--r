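#' Run the full two-cohort workflow
#'
#' Executes the analysis stages in order — differential expression on each
#' dataset, same-direction cross-dataset intersection, differential
#' co-expression on each dataset, pair overlap and direction-consistent
#' replication, DEG-and-DCE integration, optional gene-set enrichment with
#' cross-dataset term intersection, optional Markov clustering on an
#' interaction network, optional cross-platform classification, and export of
#' ranked up/down signatures — writing every stage's table under
#' `config$out_dir` plus a JSON manifest recording inputs, parameters, row
#' counts, package version and seed. Failures in the optional stages
#' (enrichment, MCL, classification) are reported as warnings and do not
#' discard earlier outputs. With only one dataset configured, replication
#' stages are skipped with a warning.
#'
#' @param config a list, or path to a YAML file, with entries:
#'   \describe{
#'     \item{out_dir}{output directory (created if needed).}
#'     \item{seed}{integer seed (fold assignment etc.; default 1).}
#'     \item{dataset_a, dataset_b}{each either `list(dataset = <ExpressionDataset>)`
#'       or `list(matrix =, labels =, probe_map = NULL, platform_id =)` file
#'       paths. `dataset_b` may be `NULL`.}
#'     \item{alpha}{significance level for all stages (default 0.05).}
#'     \item{deg_method_a, deg_method_b}{`"bonferroni"` or `"bh"` per dataset
#'       (defaults: bonferroni for A, bh for B — the stringent-then-relaxed
#'       two-step used when the smaller cohort yields too few hits).}
#'     \item{dce_method_a, dce_method_b}{likewise for the pair tests.}
#'     \item{variance_fraction}{variance-filter fraction (default 0.25).}
#'     \item{nominal_alpha}{raw-p level for the relaxed replication rule
#'       (default 0.05).}
#'     \item{gmt}{optional named character vector/list of GMT paths, or a
#'       named list of gene-set lists.}
#'     \item{network}{optional edge-list path or data.frame for MCL.}
#'     \item{classify}{run the classification stage (default `TRUE` when two
#'       datasets are present).}
#'     \item{n_folds, protocol}{classification settings (defaults 10,
#'       `"refit"`).}
#'     \item{mcl_inflation}{MCL inflation (default 2).}
#'     \item{top_k}{signature size per direction for GRP export (default 150).}
#'   }
#' @return invisibly, the manifest list (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(seed = 1L, alpha = 0.05, deg_method_a = "bonferroni",
                   deg_method_b = "bh", dce_method_a = "bonferroni",
                   dce_method_b = "bh", variance_fraction = 0.25,
                   nominal_alpha = 0.05, gmt = NULL, network = NULL,
                   classify = TRUE, n_folds = 10L, protocol = "refit",
                   mcl_inflation = 2, top_k = 150L)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  if (config$alpha <= 0 || config$alpha >= 1) stop("alpha must lie in (0, 1)")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(as.integer(config$seed))

  load_ds <- function(entry, default_id) {
    if (is.null(entry)) return(NULL)
    ds <- if (!is.null(entry$dataset)) {
      entry$dataset
    } else {
      read_expression(entry$matrix, entry$labels,
                      platform_id = entry$platform_id %||% default_id)
    }
    if (!is.null(entry$probe_map)) {
      pm <- if (is.character(entry$probe_map)) read_probe_map(entry$probe_map)
            else probe_map(entry$probe_map)
      ds <- collapse_probes(ds, pm)
    }
    ds
  }
  ds_a <- load_ds(config$dataset_a, "A")
  ds_b <- load_ds(config$dataset_b, "B")
  if (is.null(ds_a)) stop("dataset_a is required")

  manifest <- list(package = "dicoex",
                   version = as.character(utils::packageVersion("dicoex")),
                   seed = config$seed,
                   parameters = config[setdiff(names(defaults), c("gmt", "network"))],
                   stages = list())
  out <- function(name) file.path(config$out_dir, name)
  record <- function(stage, files, rows) {
    manifest$stages[[stage]] <<- list(outputs = as.list(files),
                                      rows = as.list(rows))
  }

  # --- differential expression -------------------------------------------
  deg_a <- run_deg(ds_a, method = config$deg_method_a, alpha = config$alpha)
  write_table(deg_a, out("deg_a.tsv"))
  record("deg_a", "deg_a.tsv", nrow(deg_a))
  deg_b <- NULL
  if (!is.null(ds_b)) {
    deg_b <- run_deg(ds_b, method = config$deg_method_b, alpha = config$alpha)
    write_table(deg_b, out("deg_b.tsv"))
    record("deg_b", "deg_b.tsv", nrow(deg_b))
    deg_common <- intersect_deg(deg_a, deg_b, require_same_direction = TRUE)
    write_table(deg_common, out("deg_common.tsv"))
    record("deg_common", "deg_common.tsv", nrow(deg_common))
  } else {
    warning("dataset_b missing: replication stages skipped")
  }

  # --- differential co-expression ----------------------------------------
  dce_a <- run_dce(ds_a, fraction = config$variance_fraction,
                   method = config$dce_method_a, alpha = config$alpha)
  write_table(dce_a, out("dce_a.tsv"))
  record("dce_a", "dce_a.tsv", nrow(dce_a))
  if (!is.null(ds_b)) {
    dce_b <- run_dce(ds_b, fraction = config$variance_fraction,
                     method = config$dce_method_b, alpha = config$alpha)
    write_table(dce_b, out("dce_b.tsv"))
    record("dce_b", "dce_b.tsv", nrow(dce_b))
    dce_overlap <- overlap_pairs(dce_a, dce_b)
    write_table(dce_overlap, out("dce_overlap.tsv"))
    record("dce_overlap", "dce_overlap.tsv", nrow(dce_overlap))
    dce_consistent <- direction_consistent_pairs(dce_a, dce_b,
                                                 nominal_alpha = config$nominal_alpha)
    write_table(dce_consistent, out("dce_consistent.tsv"))
    record("dce_consistent", "dce_consistent.tsv", nrow(dce_consistent))
    genes_a <- genes_from_pairs(dce_a[dce_a$significant, ])
    genes_b <- genes_from_pairs(dce_b[dce_b$significant, ])
    dce_genes <- intersect(genes_a, genes_b)
    writeLines(dce_genes, out("dce_genes_common.txt"))
    record("dce_genes_common", "dce_genes_common.txt", length(dce_genes))

    # --- integration ------------------------------------------------------
    integrated <- deg_dce_overlap(deg_common, dce_genes)
    write_table(integrated, out("integrated_genes.tsv"))
    record("integrated", "integrated_genes.tsv", nrow(integrated))

    # --- enrichment (optional) -------------------------------------------
    if (!is.null(config$gmt)) {
      tryCatch({
        sets <- if (is.character(config$gmt) || all(vapply(config$gmt, is.character, TRUE) &
                                                    lengths(config$gmt) == 1L)) {
          lapply(config$gmt, read_gmt)
        } else {
          config$gmt
        }
        if (is.null(names(sets))) names(sets) <- paste0("collection", seq_along(sets))
        files <- character()
        rows <- integer()
        for (nm in names(sets)) {
          coll_a <- gene_set_collection(sets[[nm]], ds_a$genes)
          coll_b <- gene_set_collection(sets[[nm]], ds_b$genes)
          enr_a <- enrich(genes_a, coll_a, alpha_fdr = config$alpha)
          enr_b <- enrich(genes_b, coll_b, alpha_fdr = config$alpha)
          fa <- paste0("enrichment_dce_a_", nm, ".tsv")
          fb <- paste0("enrichment_dce_b_", nm, ".tsv")
          write_table(enr_a, out(fa))
          write_table(enr_b, out(fb))
          common_terms <- intersect_enriched_terms(enr_a, enr_b)
          fc <- paste0("enrichment_common_terms_", nm, ".tsv")
          write_table(as.data.frame(common_terms), out(fc))
          # enrichment of the replicated DEG list over the shared gene space
          coll_c <- gene_set_collection(sets[[nm]],
                                        intersect(ds_a$genes, ds_b$genes))
          enr_deg <- enrich(deg_common$gene, coll_c, alpha_fdr = config$alpha)
          fd <- paste0("enrichment_deg_common_", nm, ".tsv")
          write_table(enr_deg, out(fd))
          files <- c(files, fa, fb, fc, fd)
          rows <- c(rows, nrow(enr_a), nrow(enr_b),
                    NROW(common_terms), nrow(enr_deg))
        }
        record("enrichment", files, rows)
      }, error = function(e) warning("enrichment stage failed: ",
                                     conditionMessage(e)))
    }

    # --- MCL (optional) ---------------------------------------------------
    if (!is.null(config$network)) {
      tryCatch({
        net <- if (is.character(config$network)) read_edge_list(config$network)
               else config$network
        g <- induced_subgraph_genes(net, integrated$gene)
        res <- mcl_cluster(g, inflation = config$mcl_inflation)
        tab <- cluster_table(res)
        write_table(tab, out("clusters.tsv"))
        record("mcl", "clusters.tsv", nrow(tab))
      }, error = function(e) warning("MCL stage failed: ",
                                     conditionMessage(e)))
    }

    # --- classification (optional) ---------------------------------------
    if (isTRUE(config$classify)) {
      tryCatch({
        cand <- intersect(deg_a$gene[deg_a$significant], ds_b$genes)
        sel <- l1_select(ds_a, cand, n_folds = config$n_folds,
                         seed = config$seed)
        rep_ab <- cross_platform_eval(sel$selected, ds_a, ds_b,
                                      protocol = config$protocol)
        cand_b <- intersect(deg_b$gene[deg_b$significant], ds_a$genes)
        sel_b <- l1_select(ds_b, cand_b, n_folds = config$n_folds,
                           seed = config$seed)
        rep_ba <- cross_platform_eval(sel_b$selected, ds_b, ds_a,
                                      protocol = config$protocol)
        tab <- data.frame(
          direction = c("a_to_b", "b_to_a"),
          n_selected = c(length(sel$selected), length(sel_b$selected)),
          n_mapped = c(length(rep_ab$mapped), length(rep_ba$mapped)),
          cv_auc_source = c(sel$cv_auc, sel_b$cv_auc),
          auc_target = c(rep_ab$auc, rep_ba$auc)
        )
        write_table(tab, out("classifier_report.tsv"))
        record("classify", "classifier_report.tsv", nrow(tab))
      }, error = function(e) warning("classification stage failed: ",
                                     conditionMessage(e)))
    }

    # --- signature export -------------------------------------------------
    deg_rank <- deg_a[deg_a$gene %in% deg_common$gene, , drop = FALSE]
    grp <- suppressWarnings(
      export_grp(deg_rank, out("signature"), top_k = config$top_k)
    )
    record("grp_export", c("signature_up.grp", "signature_down.grp"),
           c(length(grp$up), length(grp$down)))
  }

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
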