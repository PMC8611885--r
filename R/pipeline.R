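# End-to-end orchestration: clinical labels -> pair catalog -> tumor-type
# classification -> per-pair (split / balance / select / train / evaluate)
# -> recapture -> enrichment and the weighted overlap null. All stage seeds
# derive from one master seed and are recorded in the run manifest, so a
# rerun with the same configuration is bit-identical.

#' Assemble a pipeline configuration
#'
#' Inputs may be in-memory objects (matrix / data.frame / `go_annotation`)
#' or file paths (expression TSV, clinical TSV, GMT, DAG edge TSV).
#'
#' @param expression samples x transcripts matrix, or a TSV path.
#' @param clinical clinical data.frame, or a TSV path.
#' @param annotation a `go_annotation`, or a GMT path.
#' @param dag DAG edge data.frame, or a TSV path (optional; needed only for
#'   semantic clustering).
#' @param out_dir output directory.
#' @param pair_filter a [pair_filter_config()].
#' @param smote a [smote_config()].
#' @param selection a [selection_config()].
#' @param tumor a [tumor_type_config()].
#' @param site_model a [site_model_config()].
#' @param null_sim a [null_sim_config()], or `NULL` to skip the simulation.
#' @param holdout_fraction per-pair held-out fraction of real samples.
#' @param seed master seed; stage seeds are derived from it.
#' @param cache if `TRUE` and a previous run of the identical configuration
#'   left a complete, hash-verified output set, the run is reused.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(expression, clinical, annotation = NULL,
                            dag = NULL, out_dir,
                            pair_filter = pair_filter_config(),
                            smote = smote_config(),
                            selection = selection_config(),
                            tumor = tumor_type_config(),
                            site_model = site_model_config(),
                            null_sim = null_sim_config(),
                            holdout_fraction = 0.3, seed = 1,
                            cache = FALSE) {
  structure(list(expression = expression, clinical = clinical,
                 annotation = annotation, dag = dag, out_dir = out_dir,
                 pair_filter = pair_filter, smote = smote,
                 selection = selection, tumor = tumor,
                 site_model = site_model, null_sim = null_sim,
                 holdout_fraction = holdout_fraction,
                 seed = as.integer(seed), cache = isTRUE(cache)),
            class = "pipeline_config")
}

.load_input <- function(x, loader) if (is.character(x)) loader(x) else x

# configuration fingerprint: everything that determines the outputs
.pipeline_fingerprint <- function(config, expression, clinical) {
  config_hash(list(
    stage_configs = config[c("pair_filter", "smote", "selection", "tumor",
                             "site_model", "null_sim", "holdout_fraction",
                             "seed")],
    expression_dim = dim(expression),
    expression_sum = sum(expression),
    clinical_rows = nrow(clinical)))
}

#' Run the full organotropism pipeline
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the run manifest (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  expression <- .load_input(config$expression, read_expression)
  clinical <- .load_input(config$clinical,
                          function(p) utils::read.delim(p, check.names = FALSE,
                                                        stringsAsFactors = FALSE))
  annotation <- if (!is.null(config$annotation))
    .load_input(config$annotation, read_gmt) else NULL
  dag <- if (!is.null(config$dag)) .load_input(config$dag, read_dag_edges)
         else if (!is.null(annotation)) annotation$dag else NULL

  fingerprint <- .pipeline_fingerprint(config, expression, clinical)
  manifest_path <- file.path(out_dir, "manifest.json")
  if (config$cache && file.exists(manifest_path)) {
    prev <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
    files <- file.path(out_dir, names(prev$files))
    if (identical(prev$fingerprint, as.character(fingerprint)) &&
        all(file.exists(files)) &&
        identical(unname(tools::md5sum(files)), unname(unlist(prev$files)))) {
      message("cache hit: reusing outputs in ", out_dir)
      return(invisible(prev))
    }
  }

  seed <- config$seed
  harmonized <- harmonize_sites(clinical)
  cancer_col <- .find_column(harmonized, .CANCER_COLUMNS)
  codes <- toupper(as.character(harmonized[[cancer_col]]))
  if (config$pair_filter$merge_coadread) codes <- merge_coadread_codes(codes)
  all_sites <- sort(unique(unlist(harmonized$.sites)))
  all_cancers <- sort(unique(codes))

  # stage 1: per-pair labels and the analyzable-pair catalog
  label_sets <- list()
  for (cc in all_cancers) for (ss in all_sites) {
    ls <- build_progression_labels(harmonized, cc, ss,
                                   merge_coadread = config$pair_filter$merge_coadread)
    label_sets[[paste(cc, ss, sep = "|")]] <- ls
  }
  catalog <- filter_pairs(label_sets, config$pair_filter)
  utils::write.table(attr(catalog, "all"), file.path(out_dir, "pair_catalog.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(catalog) == 0)
    warning("no (cancer, site) pair survives filtering; pair stages are empty")

  # stage 2: multiclass tumor-type classification
  id_col <- .find_column(harmonized, .ID_COLUMNS)
  ids <- as.character(harmonized[[id_col]])
  keep <- ids %in% rownames(expression)
  Xall <- expression[ids[keep], , drop = FALSE]
  yall <- codes[keep]
  tt_split <- withr::with_seed(seed + 1L, {
    test <- unlist(lapply(unique(yall), function(cl) {
      idx <- which(yall == cl)
      n_test <- min(max(1L, as.integer(round_half_away(0.3 * length(idx)))),
                    length(idx) - 1L)
      sample(idx, n_test)
    }))
    sort(test)
  })
  tt_model <- train_tumor_type(Xall[-tt_split, , drop = FALSE], yall[-tt_split],
                               config$tumor)
  tt_report <- evaluate_multiclass(tt_model, Xall[tt_split, , drop = FALSE],
                                   yall[tt_split])
  utils::write.table(tt_report$confusion,
                     file.path(out_dir, "tumor_type_confusion.tsv"),
                     sep = "\t", quote = FALSE)
  jsonlite::write_json(list(macro = as.list(tt_report$macro),
                            per_class = tt_report$per_class),
                       file.path(out_dir, "tumor_type_report.json"),
                       auto_unbox = TRUE, digits = NA)

  # stage 3: per-pair binary classification
  pair_results <- list()
  top_lists <- list()
  if (nrow(catalog) > 0) {
    for (r in seq_len(nrow(catalog))) {
      key <- paste(catalog$cancer[r], catalog$site[r], sep = "|")
      ls <- label_sets[[key]]
      labs <- ls$labels[names(ls$labels) %in% rownames(expression)]
      res <- tryCatch(
        run_pair_analysis(expression, labs,
                          smote_cfg = config$smote,
                          selection_cfg = config$selection,
                          model_cfg = config$site_model,
                          holdout_fraction = config$holdout_fraction,
                          seed = seed + 100L + r, pair = ls$pair),
        error = function(e) stop("pair stage failed for ", key, ": ",
                                 conditionMessage(e)))
      pair_results[[key]] <- res$report
      top_lists[[key]] <- res$candidates$top
      safe <- gsub("[^A-Za-z0-9]+", "_", key)
      writeLines(res$candidates$top,
                 file.path(out_dir, paste0("top_features_", safe, ".txt")))
      jsonlite::write_json(unclass(res$report),
                           file.path(out_dir, paste0("report_", safe, ".json")),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
    }
    agg <- aggregate_site_reports(pair_results)
    utils::write.table(agg, file.path(out_dir, "site_metrics_by_cancer.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # stage 4: recapture of selected features across pairs
  if (length(top_lists) >= 2) {
    rec <- recapture_tests(top_lists, background = colnames(expression))
    write_recapture(rec, file.path(out_dir, "recapture.tsv"))
  }

  # stage 5: enrichment, weighted overlap null, semantic clustering
  if (!is.null(annotation)) {
    sig_lists <- list()
    for (key in names(top_lists)) {
      enr <- suppressWarnings(go_overrepresentation(top_lists[[key]], annotation))
      safe <- gsub("[^A-Za-z0-9]+", "_", key)
      utils::write.table(enr, file.path(out_dir, paste0("enrichment_", safe, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      sig_lists[[key]] <- enr$term[enr$kept]
    }
    if (!is.null(config$null_sim)) {
      ns_cfg <- config$null_sim
      ns_cfg$seed <- as.integer(seed + 2L)
      null <- weighted_overlap_null(annotation, ns_cfg)
      utils::write.table(null$quantiles, file.path(out_dir, "overlap_null.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    shared <- unique(unlist(sig_lists))
    if (length(shared) >= 2 && !is.null(dag)) {
      sem <- go_semantic_clusters(shared, dag)
      utils::write.table(data.frame(term = names(sem$clusters),
                                    cluster = sem$clusters),
                         file.path(out_dir, "semantic_clusters.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  files <- setdiff(list.files(out_dir), "manifest.json")
  hashes <- tools::md5sum(file.path(out_dir, files))
  manifest <- list(package = "organotropism",
                   version = as.character(utils::packageVersion("organotropism")),
                   seed = seed, fingerprint = as.character(fingerprint),
                   n_pairs = nrow(catalog),
                   files = stats::setNames(as.list(unname(hashes)), files))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
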