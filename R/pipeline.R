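#' Run the full workflow from a configuration
#'
#' Orchestrates representative-cell construction, co-expression module
#' inference, module selection, regulatory-network inference with motif
#' filtering, and the drug overlay, writing every stage's tables plus a
#' machine-readable JSON run report. Each stage can equally be run in
#' isolation through its own function ([make_representative_cells],
#' [fit_gcn], [fit_grn], [map_drugs]); `run_pipeline` is their composition.
#'
#' @param config a named list or the path to a YAML file. Recognized
#'   entries: input paths (`counts`, `counts_fmt`, `metadata`, `tf_list`,
#'   `motif_ranks`, `motif_annotation`, `drug_table`), stage parameters
#'   (`group_column`, `n_subclusters`, `pca_dims`, `normalize`,
#'   `cor_method`, `network_type`, `power`, `min_module_size`, `merge_cut`,
#'   `rank_threshold_frac`, `nes_cut`, `top_per_tf`, `n_trees_max`,
#'   `seed`), and the module-selection rule (`module` for an explicit id,
#'   or `select_trait` for "largest absolute trait correlation with this
#'   trait").
#' @param out_dir output directory for stage tables and `report.json`.
#' @return the run report, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  report <- list(schema_version = "1.0",
                 package_version = as.character(utils::packageVersion("scgrnet")),
                 timestamp = format(Sys.time(), tz = "UTC"),
                 seed = seed, parameters = config, warnings = list())
  log_msg <- function(stage, msg) {
    message(sprintf("[%s] %s", stage, msg))
  }
  note_warnings <- function(stage, expr) {
    withCallingHandlers(expr, warning = function(w) {
      report$warnings[[length(report$warnings) + 1L]] <<-
        list(stage = stage, message = conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  fail <- function(stage, e) {
    stop(sprintf("pipeline aborted at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }

  # --- load -----------------------------------------------------------
  stage <- "load"
  expr <- tryCatch({
    x <- read_expression(config$counts, fmt = config$counts_fmt %||% "tsv",
                         counts = isTRUE(config$counts_are_integer %||% TRUE))
    if (!is.null(config$metadata)) {
      md <- read_metadata(config$metadata,
                          key_column = config$metadata_key %||% "cell_id")
      x <- sc_expr(x$values, x$gene_ids, x$cell_ids, metadata = md,
                   counts = x$counts)
    }
    x
  }, error = function(e) fail(stage, e))
  log_msg(stage, sprintf("%d cells x %d genes", nrow(expr$values),
                         ncol(expr$values)))
  if (isTRUE(config$normalize %||% TRUE) && isTRUE(expr$counts)) {
    expr <- note_warnings("normalize", normalize_counts(expr))
    log_msg("normalize", "library-size (counts per 1e4) + log1p applied")
  }

  # --- pseudocells ----------------------------------------------------
  stage <- "pseudocells"
  pc <- tryCatch(note_warnings(stage, make_representative_cells(
    expr, group_column = config$group_column %||% "cell_type",
    n_subclusters = config$n_subclusters,
    seed = seed, embedding_dims = config$pca_dims %||% 50L)),
    error = function(e) fail(stage, e))
  write_expression(pc$expr, file.path(out_dir, "representative_cells.tsv"))
  write_edge_table(pc$assignment, file.path(out_dir, "assignment.tsv"))
  report$pseudocells <- list(n_cells_in = nrow(expr$values),
                             n_representative = nrow(pc$expr$values),
                             n_subclusters = pc$n_subclusters)
  log_msg(stage, sprintf("%d representative cells", nrow(pc$expr$values)))

  # --- co-expression network -----------------------------------------
  stage <- "gcn"
  gcn <- tryCatch(note_warnings(stage, fit_gcn(
    pc$expr,
    method = config$cor_method %||% "bicor",
    network_type = config$network_type %||% "signed",
    power = config$power,
    min_module_size = config$min_module_size %||% 30,
    merge_cut = config$merge_cut %||% 0.25)),
    error = function(e) fail(stage, e))
  export_gcn(gcn, out_dir)
  labels <- gcn$modules$labels
  mod_ids <- sort(unique(labels[labels != 0]))
  report$gcn <- list(power = gcn$power, n_modules = length(mod_ids),
                     module_sizes = as.list(stats::setNames(
                       vapply(mod_ids, function(m) sum(labels == m),
                              integer(1)),
                       paste0("M", mod_ids))),
                     n_grey = sum(labels == 0),
                     scale_free_r2 = if (is.null(gcn$scale_free)) NA else
                       gcn$scale_free$r2)
  log_msg(stage, sprintf("power %d, %d modules", gcn$power, length(mod_ids)))

  # --- module selection ----------------------------------------------
  stage <- "module_selection"
  module_id <- config$module
  if (is.null(module_id)) {
    trait <- config$select_trait
    if (is.null(trait) || is.null(gcn$trait_cor)) {
      fail(stage, simpleError(
        "need 'module' or 'select_trait' (with metadata) in the config"))
    }
    tc <- gcn$trait_cor[startsWith(gcn$trait_cor$trait, trait), ]
    if (nrow(tc) == 0L) {
      fail(stage, simpleError(sprintf("trait '%s' not found", trait)))
    }
    best <- tc[which.max(abs(tc$rho)), ]
    module_id <- as.integer(sub("^ME", "", best$module))
    log_msg(stage, sprintf("module M%d selected (|rho| = %.3f with %s)",
                           module_id, abs(best$rho), best$trait))
  }
  module_genes <- names(labels)[labels == module_id]
  if (length(module_genes) == 0L) {
    fail(stage, simpleError(sprintf("module %s is empty", module_id)))
  }
  report$module_selection <- list(module = module_id,
                                  n_genes = length(module_genes))

  # --- regulatory network --------------------------------------------
  stage <- "grn"
  grn <- tryCatch({
    if (is.null(config$motif_ranks) || is.null(config$motif_annotation)) {
      stop("motif database paths missing from config")
    }
    tf_list <- read_tf_list(config$tf_list)
    db <- read_motif_db(config$motif_ranks, config$motif_annotation)
    note_warnings(stage, fit_grn(
      pc$expr, module_genes, tf_list, db, seed = seed,
      rank_threshold_frac = config$rank_threshold_frac %||% 0.05,
      nes_cut = config$nes_cut %||% 3.0,
      top_per_tf = config$top_per_tf %||% 50,
      n_trees_max = config$n_trees_max %||% 500))
  }, error = function(e) fail(stage, e))
  cand <- attr(grn, "candidates")
  write_edge_table(cand, file.path(out_dir, "candidates.tsv"))
  write_edge_table(attr(grn, "enrichment")$table,
                   file.path(out_dir, "motif_enrichment.tsv"))
  write_edge_table(grn$edges, file.path(out_dir, "grn.tsv"))
  report$grn <- list(n_tfs = length(unique(cand$tf)),
                     n_candidates = nrow(cand),
                     n_retained = nrow(grn$edges),
                     unannotated_tfs = grn$unannotated_tfs)
  log_msg(stage, sprintf("%d candidates -> %d motif-supported edges",
                         nrow(cand), nrow(grn$edges)))

  # --- drugs ----------------------------------------------------------
  stage <- "drugs"
  dm <- NULL
  if (!is.null(config$drug_table)) {
    dm <- tryCatch({
      tab <- read_drug_table(config$drug_table)
      net_genes <- unique(c(grn$edges$tf, grn$edges$target))
      if (length(net_genes) == 0L) net_genes <- module_genes
      note_warnings(stage, map_drugs(net_genes, tab))
    }, error = function(e) fail(stage, e))
    write_edge_table(dm$associations, file.path(out_dir, "drug_associations.tsv"))
    report$drugs <- list(n_drugs = dm$n_drugs,
                         n_targeted_genes = dm$n_targeted_genes,
                         provenance = dm$provenance)
    log_msg(stage, sprintf("%d drugs over %d targeted genes",
                           dm$n_drugs, dm$n_targeted_genes))
  }

  # --- combined graph -------------------------------------------------
  if (nrow(grn$edges) > 0L) {
    g <- build_combined_network(grn, dm)
    write_graphml(g, file.path(out_dir, "combined_network.graphml"))
  }
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(report)
}
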