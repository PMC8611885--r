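# Clinical annotation: harmonize free-text metastatic-site columns into
# per-(cancer, site) binary progression labels, and filter tumor-site pairs
# to those with enough annotated progression to model.

.SITE_COLUMNS <- c("metastatic tissue", "sites of metastases",
                   "metastatic tissue site")
.ID_COLUMNS <- c("sample_id", "patient_id", "case_id", "barcode", "id")
.CANCER_COLUMNS <- c("cancer_type", "cancer_code", "project", "project_id",
                     "type")

.norm_colname <- function(x) gsub("[._ ]+", " ", tolower(trimws(x)))

find_site_columns <- function(table) {
  hits <- names(table)[.norm_colname(names(table)) %in% .SITE_COLUMNS]
  hits
}

.find_column <- function(table, candidates) {
  hit <- names(table)[.norm_colname(names(table)) %in% .norm_colname(candidates)]
  if (length(hit) == 0) NULL else hit[1]
}

#' Canonicalize a metastatic-site string
#'
#' Trims, collapses internal whitespace and title-cases each word, so that
#' `" lung "`, `"lung"` and `"LUNG"` all become `"Lung"`. Idempotent.
#'
#' @param x character vector of site strings.
#' @return character vector of canonical site names.
#' @export
canonical_site <- function(x) {
  s <- tolower(gsub("\\s+", " ", trimws(x)))
  gsub("(^|[ -])([a-z])", "\\1\\U\\2", s, perl = TRUE)
}

#' Harmonize clinical metastatic-site annotation
#'
#' Recognizes the TCGA-style free-text columns `"metastatic tissue"`,
#' `"sites of metastases"` and `"metastatic tissue site"` (case, dot and
#' underscore variants accepted), splits multi-site cells on the declared
#' delimiter set, canonicalizes site strings, and flags rows whose
#' progression timing contains "synchronous". Synchronous rows are excluded
#' from metastatic labeling downstream because the clinical timeline of their
#' diagnosis is ambiguous. Harmonization is idempotent.
#'
#' @param table a clinical data.frame.
#' @param delimiters characters on which multi-site cells are split.
#' @param timing_pattern regex selecting progression-timing columns.
#' @return the input data.frame with two added columns: `.sites` (list column
#'   of canonical site names) and `.synchronous` (logical).
#' @export
harmonize_sites <- function(table, delimiters = c(";", ",", "|"),
                            timing_pattern = "timing|progression|synchronous") {
  site_cols <- find_site_columns(table)
  if (length(site_cols) == 0)
    stop("no recognized metastatic-site column; expected one of: ",
         paste(.SITE_COLUMNS, collapse = ", "))
  split_re <- paste0("[", paste(gsub("([|\\\\])", "\\\\\\1", delimiters),
                                collapse = ""), "]")
  sites <- lapply(seq_len(nrow(table)), function(r) {
    cells <- unlist(table[r, site_cols, drop = FALSE], use.names = FALSE)
    cells <- cells[!is.na(cells)]
    parts <- unlist(strsplit(as.character(cells), split_re), use.names = FALSE)
    parts <- canonical_site(parts)
    unique(parts[nzchar(parts)])
  })
  timing_cols <- setdiff(grep(timing_pattern, .norm_colname(names(table))),
                         match(site_cols, names(table)))
  synchronous <- rep(FALSE, nrow(table))
  for (j in timing_cols) {
    v <- as.character(table[[j]])
    synchronous <- synchronous | grepl("synchronous", v, ignore.case = TRUE)
  }
  table$.sites <- sites
  table$.synchronous <- synchronous
  table
}

#' Build binary progression labels for one (cancer, site) pair
#'
#' The positive class is tumors with a recorded metastasis at the tested
#' site; the negative class is tumors without one (including tumors that
#' metastasized elsewhere). Rows flagged synchronous contribute to neither
#' class. With `merge_coadread = TRUE` the code `"COADREAD"` pools the COAD
#' and READ cohorts, whose metastatic progressions overlap considerably.
#'
#' @param table a clinical data.frame (harmonized with [harmonize_sites()];
#'   harmonization is applied if missing).
#' @param cancer_code 4-letter project code, or `"COADREAD"`.
#' @param site site name (canonicalized internally).
#' @param merge_coadread pool COAD and READ under `"COADREAD"`.
#' @return object of class `progression_labels`: list with `pair`, `labels`
#'   (named 0/1 integer vector over retained sample IDs), `n_pos`, `n_total`.
#' @export
build_progression_labels <- function(table, cancer_code, site,
                                     merge_coadread = TRUE) {
  if (is.null(table$.sites)) table <- harmonize_sites(table)
  cancer_col <- .find_column(table, .CANCER_COLUMNS)
  if (is.null(cancer_col)) stop("no cancer-type column found; expected one of: ",
                                paste(.CANCER_COLUMNS, collapse = ", "))
  id_col <- .find_column(table, .ID_COLUMNS)
  ids <- if (is.null(id_col)) rownames(table) else as.character(table[[id_col]])

  codes <- toupper(as.character(table[[cancer_col]]))
  want <- toupper(cancer_code)
  match_rows <- if (merge_coadread && want == "COADREAD")
    codes %in% c("COAD", "READ", "COADREAD") else codes == want
  keep <- which(match_rows & !table$.synchronous)

  site_c <- canonical_site(site)
  labels <- vapply(table$.sites[keep], function(s) as.integer(site_c %in% s), 0L)
  names(labels) <- ids[keep]
  structure(list(pair = c(cancer = toupper(cancer_code), site = site_c),
                 labels = labels,
                 n_pos = sum(labels), n_total = length(labels)),
            class = "progression_labels")
}

#' @export
print.progression_labels <- function(x, ...) {
  cat(sprintf("Progression labels %s | %s: %d positive / %d total\n",
              x$pair[["cancer"]], x$pair[["site"]], x$n_pos, x$n_total))
  invisible(x)
}

#' Pair filtering thresholds
#'
#' Tumor-site pairs are analyzable when they have at least
#' `min_site_annotations` recorded progressions to the site and a total
#' cohort population strictly over `min_population` patients.
#'
#' @param min_site_annotations minimum positive count (inclusive).
#' @param min_population population threshold (exclusive: kept if
#'   `n_total > min_population`).
#' @param merge_coadread pool COAD and READ cohorts.
#' @return object of class `pair_filter_config`.
#' @export
pair_filter_config <- function(min_site_annotations = 8, min_population = 50,
                               merge_coadread = TRUE) {
  stopifnot(min_site_annotations >= 1, min_population >= 1)
  structure(list(min_site_annotations = min_site_annotations,
                 min_population = min_population,
                 merge_coadread = merge_coadread),
            class = "pair_filter_config")
}

#' Filter tumor-site pairs to those with enough annotated progression
#'
#' @param label_sets list of `progression_labels`.
#' @param cfg a [pair_filter_config()].
#' @return data.frame catalog of the retained pairs (cancer, site, n_pos,
#'   n_total), sorted by (cancer, site); the full catalog, with a `kept`
#'   column, is available as `attr(, "all")`.
#' @export
filter_pairs <- function(label_sets, cfg = pair_filter_config()) {
  stopifnot(inherits(cfg, "pair_filter_config"))
  cat_all <- do.call(rbind, lapply(label_sets, function(ls) {
    data.frame(cancer = ls$pair[["cancer"]], site = ls$pair[["site"]],
               n_pos = ls$n_pos, n_total = ls$n_total,
               stringsAsFactors = FALSE)
  }))
  if (is.null(cat_all))
    cat_all <- data.frame(cancer = character(), site = character(),
                          n_pos = integer(), n_total = integer())
  cat_all$kept <- cat_all$n_pos >= cfg$min_site_annotations &
    cat_all$n_total > cfg$min_population
  cat_all <- cat_all[order(cat_all$cancer, cat_all$site), , drop = FALSE]
  rownames(cat_all) <- NULL
  out <- cat_all[cat_all$kept, setdiff(names(cat_all), "kept"), drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all") <- cat_all
  out
}

#' Merge COAD and READ codes into COADREAD
#' @param codes character vector of project codes.
#' @return codes with COAD/READ replaced by COADREAD.
#' @export
merge_coadread_codes <- function(codes) {
  out <- toupper(as.character(codes))
  out[out %in% c("COAD", "READ")] <- "COADREAD"
  out
}
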