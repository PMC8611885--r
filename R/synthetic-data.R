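#' Configuration for a synthetic tumor cohort
#'
#' Describes a desk-scale cohort of primary-tumor transcriptomes with planted
#' tumor-type signatures and per-(cancer, site) tropism signatures. Expression
#' is modelled as negative-binomial counts with log-scale mean shifts, which
#' mimics the RNA-seq count matrices consumed by the downstream classifiers.
#'
#' @param n_cancer_types number of tumor types in the cohort.
#' @param samples_per_type primary tumors simulated per type.
#' @param n_transcripts width of the expression matrix. The human reference
#'   transcriptome used as a background elsewhere has 60,483 transcripts;
#'   unit-scale cohorts use far fewer.
#' @param sites metastatic site vocabulary (canonical names).
#' @param tropism_signature_size transcripts whose mean is shifted in samples
#'   that progress to a given site, per (cancer, site) pair.
#' @param effect_size standardized log-scale mean shift for tropism signature
#'   transcripts (multiples of the per-transcript noise SD).
#' @param positive_fraction fraction of each type's samples labeled as having
#'   metastasized to each site (drawn independently per site, so a sample may
#'   progress to several sites).
#' @param synchronous_fraction fraction of metastatic samples whose progression
#'   timing reads "synchronous"; these must be excluded from labeling
#'   downstream because the clinical ordering of diagnosis is ambiguous.
#' @param noise_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param seed integer seed; a fixed seed makes the cohort bit-reproducible.
#' @param cancer_codes optional character vector of 4-letter project codes; a
#'   default pool is used when `NULL`.
#' @param type_signature_size transcripts shifted per tumor type (what makes
#'   types separable for the multiclass stage).
#' @param type_effect_size standardized shift for type signature transcripts.
#' @param base_log_mean,base_log_sd log-normal hyperparameters for baseline
#'   transcript means.
#' @param signature_transcripts optional named list ("CODE|Site" ->
#'   transcript IDs) overriding the random choice of tropism signatures, e.g.
#'   to plant GO-coherent signatures.
#' @param messy_fraction fraction of clinical site strings written with
#'   case/whitespace variants, to exercise harmonization.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_cancer_types = 3, samples_per_type = 100,
                          n_transcripts = 2000,
                          sites = c("Bone", "Liver", "Lung", "Lymph Node"),
                          tropism_signature_size = 20, effect_size = 1.5,
                          positive_fraction = 0.15, synchronous_fraction = 0.1,
                          noise_dispersion = 0.3, seed = 1,
                          cancer_codes = NULL,
                          type_signature_size = 50, type_effect_size = 2,
                          base_log_mean = log(50), base_log_sd = 0.6,
                          signature_transcripts = NULL,
                          messy_fraction = 0.3) {
  stopifnot(n_cancer_types >= 1, samples_per_type >= 1, n_transcripts >= 1,
            length(sites) >= 1, tropism_signature_size >= 1,
            type_signature_size >= 0,
            positive_fraction > 0, positive_fraction < 1,
            synchronous_fraction >= 0, synchronous_fraction < 1,
            noise_dispersion > 0)
  if (is.null(cancer_codes)) {
    pool <- c("BRCA", "LUAD", "PRAD", "SKCM", "BLCA", "KIRC", "LIHC", "STAD",
              "HNSC", "PAAD", "SARC", "THCA", "ESCA", "KIRP", "LUSC", "CESC")
    if (n_cancer_types > length(pool))
      pool <- c(pool, sprintf("CT%02d", seq_len(n_cancer_types)))
    cancer_codes <- pool[seq_len(n_cancer_types)]
  }
  stopifnot(length(cancer_codes) == n_cancer_types, !anyDuplicated(cancer_codes))
  n_pairs <- n_cancer_types * length(sites)
  needed <- n_cancer_types * type_signature_size + n_pairs * tropism_signature_size
  if (needed > n_transcripts)
    stop("signature transcripts (", needed, ") exceed n_transcripts (",
         n_transcripts, "); signatures must be assignable without exhausting features")
  structure(list(n_cancer_types = n_cancer_types,
                 samples_per_type = samples_per_type,
                 n_transcripts = n_transcripts, sites = sites,
                 tropism_signature_size = tropism_signature_size,
                 effect_size = effect_size,
                 positive_fraction = positive_fraction,
                 synchronous_fraction = synchronous_fraction,
                 noise_dispersion = noise_dispersion, seed = as.integer(seed),
                 cancer_codes = cancer_codes,
                 type_signature_size = type_signature_size,
                 type_effect_size = type_effect_size,
                 base_log_mean = base_log_mean, base_log_sd = base_log_sd,
                 signature_transcripts = signature_transcripts,
                 messy_fraction = messy_fraction),
            class = "cohort_config")
}

# write a canonical site string with random case/whitespace noise
.vary_site <- function(site, messy) {
  if (!messy) return(site)
  switch(sample.int(3L, 1L),
         tolower(site),
         toupper(site),
         paste0(" ", site, " "))
}

#' Generate a synthetic cohort of tumor transcriptomes
#'
#' Draws a samples-by-transcripts count matrix from a negative-binomial model
#' with planted tumor-type and tropism signatures, plus a TCGA-style clinical
#' table (a "metastatic tissue" free-text column with messy site strings and
#' a progression-timing column containing "synchronous" rows) and a ground
#' truth record. The ground truth is intended for validation only and is never
#' consumed by the analysis pipeline itself.
#'
#' @param config a [cohort_config()].
#' @return an object of class `synthetic_cohort`: a list with `expression`
#'   (numeric matrix, samples x transcripts), `clinical` (data.frame),
#'   `truth` (list: per-pair signature IDs, per-pair positive sample IDs,
#'   per-type signature IDs, synchronous sample IDs) and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(config$seed, {
    n_types <- config$n_cancer_types
    n_per <- config$samples_per_type
    n_tx <- config$n_transcripts
    sites <- config$sites
    codes <- config$cancer_codes
    n_samples <- n_types * n_per

    transcripts <- sprintf("ENST%011d", seq_len(n_tx))
    sample_type <- rep(codes, each = n_per)
    sample_ids <- sprintf("%s-%04d", sample_type,
                          unlist(lapply(seq_len(n_types), function(i) seq_len(n_per))))

    log_mu <- stats::rnorm(n_tx, config$base_log_mean, config$base_log_sd)
    # per-transcript noise SD on the log scale under the NB model
    unit_sd <- sqrt(config$noise_dispersion + 1 / exp(log_mu))

    shuffled <- sample.int(n_tx)
    take <- function(k) {
      if (k == 0) return(integer(0))
      idx <- shuffled[seq_len(k)]
      shuffled <<- shuffled[-seq_len(k)]
      idx
    }
    type_sig <- stats::setNames(
      lapply(seq_len(n_types), function(i) take(config$type_signature_size)), codes)

    pair_keys <- as.vector(outer(codes, sites, function(a, b) paste(a, b, sep = "|")))
    if (!is.null(config$signature_transcripts)) {
      miss <- setdiff(names(config$signature_transcripts), pair_keys)
      if (length(miss)) stop("unknown pair keys in signature_transcripts: ",
                             paste(miss, collapse = ", "))
    }
    pair_sig <- stats::setNames(lapply(pair_keys, function(key) {
      if (!is.null(config$signature_transcripts) &&
          key %in% names(config$signature_transcripts)) {
        idx <- match(config$signature_transcripts[[key]], transcripts)
        if (anyNA(idx)) stop("signature_transcripts for ", key,
                             " contains unknown transcript IDs")
        idx
      } else take(config$tropism_signature_size)
    }), pair_keys)
    sig_sign <- lapply(pair_sig, function(idx)
      sample(c(-1, 1), length(idx), replace = TRUE))
    type_sign <- lapply(type_sig, function(idx)
      sample(c(-1, 1), length(idx), replace = TRUE))

    # positives per (cancer, site), independent across sites
    n_pos <- round_half_away(config$positive_fraction * n_per)
    positives <- stats::setNames(vector("list", length(pair_keys)), pair_keys)
    for (key in pair_keys) {
      code <- sub("\\|.*$", "", key)
      rows <- which(sample_type == code)
      positives[[key]] <- sort(sample(rows, n_pos))
    }

    L <- matrix(log_mu, nrow = n_samples, ncol = n_tx, byrow = TRUE)
    for (i in seq_len(n_types)) {
      rows <- which(sample_type == codes[i])
      idx <- type_sig[[i]]
      if (length(idx))
        L[rows, idx] <- L[rows, idx] +
          rep(config$type_effect_size * type_sign[[i]] * unit_sd[idx],
              each = length(rows))
    }
    for (key in pair_keys) {
      rows <- positives[[key]]
      idx <- pair_sig[[key]]
      L[rows, idx] <- L[rows, idx] +
        rep(config$effect_size * sig_sign[[key]] * unit_sd[idx],
            each = length(rows))
    }

    counts <- matrix(stats::rnbinom(n_samples * n_tx, mu = exp(L),
                                    size = 1 / config$noise_dispersion),
                     nrow = n_samples, ncol = n_tx,
                     dimnames = list(sample_ids, transcripts))

    # clinical table: per-sample site list, messy strings, synchronous rows
    sample_sites <- vector("list", n_samples)
    for (key in pair_keys) {
      site <- sub("^.*\\|", "", key)
      for (r in positives[[key]])
        sample_sites[[r]] <- c(sample_sites[[r]], site)
    }
    metastatic <- which(lengths(sample_sites) > 0)
    n_sync <- round_half_away(config$synchronous_fraction * length(metastatic))
    sync_rows <- if (n_sync > 0) sort(sample(metastatic, n_sync)) else integer(0)

    delims <- c("; ", " | ", ", ")
    site_cell <- vapply(seq_len(n_samples), function(r) {
      ss <- sample_sites[[r]]
      if (is.null(ss)) return("")
      messy <- stats::runif(length(ss)) < config$messy_fraction
      ss <- vapply(seq_along(ss), function(j) .vary_site(ss[j], messy[j]), "")
      if (length(ss) == 1) ss else paste(ss, collapse = sample(delims, 1))
    }, "")
    timing <- rep("", n_samples)
    timing[metastatic] <- "metachronous"
    timing[sync_rows] <- "synchronous"

    clinical <- data.frame(sample_id = sample_ids,
                           cancer_type = sample_type,
                           "metastatic tissue" = site_cell,
                           progression_timing = timing,
                           check.names = FALSE, stringsAsFactors = FALSE)

    truth <- list(
      signatures = lapply(pair_sig, function(idx) transcripts[idx]),
      type_signatures = lapply(type_sig, function(idx) transcripts[idx]),
      positives = lapply(positives, function(rows) sample_ids[rows]),
      synchronous_samples = sample_ids[sync_rows])

    structure(list(expression = counts, clinical = clinical, truth = truth,
                   config = config),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$expression), "samples x",
      ncol(x$expression), "transcripts\n")
  cat("Cancer types:", paste(x$config$cancer_codes, collapse = ", "), "\n")
  cat("Sites:", paste(x$config$sites, collapse = ", "), "\n")
  cat("Metastatic samples:", sum(nzchar(x$clinical[["metastatic tissue"]])),
      "(", length(x$truth$synchronous_samples), "synchronous )\n")
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes the expression matrix (samples as rows, transcript IDs as header),
#' the clinical table, and the ground-truth record. The ground truth goes to a
#' separate JSON file so the analysis pipeline never has to touch it.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if missing).
#' @return invisibly, the written file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expr_path <- file.path(dir, "expression.tsv")
  clin_path <- file.path(dir, "clinical.tsv")
  truth_path <- file.path(dir, "ground_truth.json")
  expr <- data.frame(sample_id = rownames(cohort$expression),
                     cohort$expression, check.names = FALSE)
  utils::write.table(expr, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$clinical, clin_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(cohort$truth, truth_path, auto_unbox = FALSE)
  invisible(c(expression = expr_path, clinical = clin_path, truth = truth_path))
}

#' Read an expression matrix written by [write_cohort()]
#' @param path TSV with a `sample_id` column and transcript columns.
#' @return numeric matrix, samples x transcripts.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Configuration for synthetic GO biological-process annotation
#'
#' @param n_terms number of GO terms.
#' @param term_size_range integer vector `c(min, max)`: transcripts per term.
#' @param multiplicity_skew mean number of *extra* term memberships per
#'   transcript beyond the guaranteed one; memberships are
#'   `1 + NegBin(mu = skew, size = 1)`, giving the long-tailed
#'   transcript-to-term multiplicity seen in real annotation. `0` makes every
#'   transcript map to exactly one term.
#' @param dag_depth depth of the generated is-a DAG below the root.
#' @param seed integer seed.
#' @return an object of class `go_config`.
#' @export
go_config <- function(n_terms = 50, term_size_range = c(10, 40),
                      multiplicity_skew = 1, dag_depth = 3, seed = 1) {
  stopifnot(n_terms >= 1, length(term_size_range) == 2,
            term_size_range[1] >= 1, term_size_range[2] >= term_size_range[1],
            multiplicity_skew >= 0, dag_depth >= 1)
  structure(list(n_terms = n_terms, term_size_range = as.integer(term_size_range),
                 multiplicity_skew = multiplicity_skew,
                 dag_depth = as.integer(dag_depth), seed = as.integer(seed)),
            class = "go_config")
}

#' Generate synthetic GO annotation and an is-a DAG
#'
#' Every transcript receives at least one term membership; the number of
#' memberships is long-tailed under `multiplicity_skew`, reproducing the fact
#' that transcript IDs map to multiple GO biological-process IDs. Terms are
#' arranged in a rooted acyclic is-a graph.
#'
#' @param config a [go_config()].
#' @param transcript_ids character vector of transcript IDs to annotate.
#' @return object of class `go_annotation`: list with `terms` (named list,
#'   term -> transcript IDs), `multiplicity` (named integer, per transcript),
#'   `dag` (data.frame child/parent), `root`, and `config`.
#' @export
generate_go_annotation <- function(config, transcript_ids) {
  stopifnot(inherits(config, "go_config"), length(transcript_ids) > 0)
  rng <- config$term_size_range
  if (rng[1] > length(transcript_ids))
    stop("term_size_range minimum (", rng[1],
         ") exceeds the number of transcripts (", length(transcript_ids), ")")
  withr::with_seed(config$seed, {
    n_tx <- length(transcript_ids)
    n_terms <- config$n_terms
    m <- 1L + stats::rnbinom(n_tx, size = 1, mu = config$multiplicity_skew)
    m <- pmin(m, n_terms)
    total <- sum(m)
    if (total < n_terms * rng[1])
      stop("too few term memberships (", total, ") to give every one of ",
           n_terms, " terms at least ", rng[1],
           " members; increase multiplicity_skew or transcripts")

    # target term sizes: min each, leftover spread up to max, overflow uniform
    sizes <- rep(rng[1], n_terms)
    leftover <- total - sum(sizes)
    caps <- rng[2] - rng[1]
    if (leftover > 0 && caps > 0) {
      slots <- rep(seq_len(n_terms), each = caps)
      grab <- min(leftover, length(slots))
      add <- tabulate(sample(slots, grab), nbins = n_terms)
      sizes <- sizes + add
      leftover <- leftover - grab
    }
    if (leftover > 0)
      sizes <- sizes + tabulate(sample.int(n_terms, leftover, replace = TRUE),
                                nbins = n_terms)

    # assign each transcript m_i distinct terms, weighted by remaining capacity
    capacity <- sizes
    members <- vector("list", n_terms)
    for (i in sample.int(n_tx)) {
      open <- which(capacity > 0)
      k <- min(m[i], length(open))
      pick <- if (k == length(open)) open
              else open[sample.int(length(open), k, prob = capacity[open])]
      for (t in pick) members[[t]] <- c(members[[t]], i)
      capacity[pick] <- capacity[pick] - 1L
      m[i] <- k
    }
    term_ids <- sprintf("GO:%07d", seq_len(n_terms))
    terms <- stats::setNames(lapply(members, function(ix) transcript_ids[sort(ix)]),
                             term_ids)

    # rooted is-a DAG: terms spread over dag_depth levels, parent in the
    # level above (root for level 1); edges run child -> parent
    root <- "GO:0000000"
    levels <- sort(rep_len(seq_len(config$dag_depth), n_terms))
    parent <- character(n_terms)
    for (i in seq_len(n_terms)) {
      above <- which(levels == levels[i] - 1L)
      parent[i] <- if (length(above) == 0) root
                   else term_ids[above[sample.int(length(above), 1)]]
    }
    dag <- data.frame(child = term_ids, parent = parent,
                      stringsAsFactors = FALSE)

    structure(list(terms = terms,
                   multiplicity = stats::setNames(m, transcript_ids),
                   dag = dag, root = root, config = config),
              class = "go_annotation")
  })
}

#' @export
print.go_annotation <- function(x, ...) {
  sz <- lengths(x$terms)
  cat("GO annotation:", length(x$terms), "terms over",
      length(x$multiplicity), "transcripts\n")
  cat("Term sizes:", min(sz), "-", max(sz),
      "| multiplicity 1 .. ", max(x$multiplicity), "\n")
  invisible(x)
}

#' Write annotation as a GMT file
#' @param annotation a `go_annotation` (or any named list of ID vectors).
#' @param path output file.
#' @export
write_gmt <- function(annotation, path) {
  terms <- if (inherits(annotation, "go_annotation")) annotation$terms else annotation
  lines <- vapply(names(terms), function(t)
    paste(c(t, "synthetic", terms[[t]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a GMT file into a `go_annotation`
#'
#' @param path GMT file (term, description, members...).
#' @param dag optional data.frame of child/parent edges (see
#'   [read_dag_edges()]).
#' @return a `go_annotation` (without a generator config).
#' @export
read_gmt <- function(path, dag = NULL) {
  terms <- fgsea::gmtPathways(path)
  mult <- table(unlist(terms, use.names = FALSE))
  structure(list(terms = terms,
                 multiplicity = stats::setNames(as.integer(mult), names(mult)),
                 dag = dag, root = if (!is.null(dag)) setdiff(dag$parent, dag$child)[1] else NA,
                 config = NULL),
            class = "go_annotation")
}

#' Write / read DAG edges as a two-column TSV (child, parent)
#' @param annotation a `go_annotation` with a `dag` element.
#' @param path file path.
#' @export
write_dag_edges <- function(annotation, path) {
  utils::write.table(annotation$dag, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_dag_edges
#' @export
read_dag_edges <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
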