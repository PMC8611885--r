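# GO biological-process overrepresentation on selected feature lists, a
# multiplicity-weighted simulation null for the overlap of two enriched
# GO-term lists, and semantic-similarity clustering of enriched terms.

#' Map transcripts to their GO terms
#'
#' Unannotated transcripts are dropped (their count is reported via a
#' message and the `n_dropped` attribute).
#'
#' @param transcripts character vector of transcript IDs.
#' @param annotation a `go_annotation`.
#' @return list with `per_transcript` (named list of term-ID vectors for the
#'   annotated transcripts) and `terms` (the aggregate union of term IDs).
#' @export
map_transcripts_to_go <- function(transcripts, annotation) {
  stopifnot(inherits(annotation, "go_annotation"))
  if (length(annotation$terms) == 0) stop("empty annotation")
  tx2terms <- split(rep(names(annotation$terms), lengths(annotation$terms)),
                    unlist(annotation$terms, use.names = FALSE))
  transcripts <- unique(transcripts)
  hit <- transcripts %in% names(tx2terms)
  if (any(!hit))
    message(sum(!hit), " of ", length(transcripts),
            " transcripts have no GO annotation and were dropped")
  per <- tx2terms[transcripts[hit]]
  out <- list(per_transcript = per,
              terms = unique(unlist(per, use.names = FALSE)))
  attr(out, "n_dropped") <- sum(!hit)
  out
}

#' GO overrepresentation test
#'
#' Per-term hypergeometric upper-tail test of the list's hits against the
#' annotated transcript universe, Bonferroni-corrected over all tested
#' terms; terms with `p_adj < alpha` are flagged as kept.
#'
#' @param gene_list character vector of transcript IDs.
#' @param annotation a `go_annotation`.
#' @param alpha significance level on the adjusted p-value (default 0.05).
#' @return data.frame (class `enrichment_result`): term, k (hits), K (term
#'   size), n (annotated list size), N (annotated universe size), p, p_adj,
#'   kept.
#' @export
go_overrepresentation <- function(gene_list, annotation, alpha = 0.05) {
  stopifnot(inherits(annotation, "go_annotation"))
  universe <- unique(unlist(annotation$terms, use.names = FALSE))
  N <- length(universe)
  lst <- intersect(unique(gene_list), universe)
  n <- length(lst)
  if (n == 0) {
    warning("no annotated transcripts in the list; empty enrichment result")
    out <- data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      p_adj = numeric(), kept = logical())
    class(out) <- c("enrichment_result", "data.frame")
    return(out)
  }
  K <- lengths(annotation$terms)
  k <- vapply(annotation$terms, function(members)
    length(intersect(members, lst)), 0L)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  p_adj <- bonferroni_adjust(p)
  out <- data.frame(term = names(annotation$terms), k = as.integer(k),
                    K = as.integer(K), n = n, N = N, p = p, p_adj = p_adj,
                    kept = p_adj < alpha, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out <- out[order(out$p, out$term), , drop = FALSE]
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Configuration for the weighted GO-overlap simulation null
#'
#' @param list_sizes transcript-list sizes simulated; all unordered pairs
#'   (with repetition) of these sizes are crossed, so 5 sizes give 15
#'   combinations.
#' @param reps replicates per size combination. The full-scale protocol is
#'   50,000 per combination (750,000 in total over 15 combinations); the
#'   default here is a desk-scale 500.
#' @param weighting `"inverse-multiplicity"` samples transcript `i` with
#'   weight proportional to `1/m_i`, prioritizing transcripts that map to
#'   few GO terms; `"uniform"` disables weighting.
#' @param alpha per-replicate enrichment significance threshold.
#' @param seed integer seed.
#' @return object of class `null_sim_config`.
#' @export
null_sim_config <- function(list_sizes = c(100, 200, 300, 400, 500),
                            reps = 500,
                            weighting = c("inverse-multiplicity", "uniform"),
                            alpha = 0.05, seed = 1) {
  weighting <- match.arg(weighting)
  stopifnot(all(list_sizes >= 1), reps >= 1, alpha > 0, alpha < 1)
  structure(list(list_sizes = as.integer(sort(list_sizes)),
                 reps = as.integer(reps), weighting = weighting,
                 alpha = alpha, seed = as.integer(seed)),
            class = "null_sim_config")
}

#' Simulate the null distribution of enriched-GO-list overlaps
#'
#' Per replicate, two transcript lists are drawn without replacement from
#' the annotated universe with sampling weight proportional to the inverse
#' of each transcript's GO multiplicity; a GO overrepresentation test is run
#' on each list and the overlap of their significant term lists is recorded.
#' Replicates with no significant terms contribute an overlap of zero.
#'
#' @param annotation a `go_annotation`.
#' @param cfg a [null_sim_config()].
#' @return object of class `overlap_null`: list with `overlaps` (named list
#'   of integer vectors per "sizeA|sizeB" combination), `quantiles`
#'   (data.frame with 50th, 95th, 99th percentiles per combination) and
#'   `config`.
#' @export
weighted_overlap_null <- function(annotation, cfg = null_sim_config()) {
  stopifnot(inherits(annotation, "go_annotation"),
            inherits(cfg, "null_sim_config"))
  universe <- unique(unlist(annotation$terms, use.names = FALSE))
  N <- length(universe)
  if (max(cfg$list_sizes) > N)
    stop("list size ", max(cfg$list_sizes), " exceeds the annotated universe (",
         N, " transcripts)")
  w <- if (cfg$weighting == "inverse-multiplicity") {
    m <- annotation$multiplicity[universe]
    m[is.na(m)] <- 1
    1 / as.numeric(m)
  } else rep(1, N)

  # sparse term x transcript membership for fast per-replicate hit counts
  term_ids <- names(annotation$terms)
  M <- Matrix::sparseMatrix(
    i = rep(seq_along(term_ids), lengths(annotation$terms)),
    j = match(unlist(annotation$terms, use.names = FALSE), universe),
    x = 1, dims = c(length(term_ids), N))
  K <- lengths(annotation$terms)
  n_terms <- length(term_ids)

  sig_terms <- function(idx) {
    ind <- numeric(N)
    ind[idx] <- 1
    k <- as.numeric(M %*% ind)
    p <- stats::phyper(k - 1, K, N - K, length(idx), lower.tail = FALSE)
    which(pmin(1, n_terms * p) < cfg$alpha)
  }

  sizes <- cfg$list_sizes
  combos <- list()
  for (i in seq_along(sizes))
    for (j in i:length(sizes))
      combos[[length(combos) + 1L]] <- c(sizes[i], sizes[j])
  overlaps <- withr::with_seed(cfg$seed, {
    lapply(combos, function(sz) {
      vapply(seq_len(cfg$reps), function(r) {
        la <- sample.int(N, sz[1], prob = w)
        lb <- sample.int(N, sz[2], prob = w)
        length(intersect(sig_terms(la), sig_terms(lb)))
      }, 0L)
    })
  })
  names(overlaps) <- vapply(combos, function(sz) paste(sz, collapse = "|"), "")
  qs <- do.call(rbind, lapply(names(overlaps), function(nm) {
    q <- stats::quantile(overlaps[[nm]], c(0.5, 0.95, 0.99))
    sz <- as.integer(strsplit(nm, "|", fixed = TRUE)[[1]])
    data.frame(size_a = sz[1], size_b = sz[2],
               q50 = q[[1]], q95 = q[[2]], q99 = q[[3]])
  }))
  structure(list(overlaps = overlaps, quantiles = qs, config = cfg),
            class = "overlap_null")
}

#' @export
print.overlap_null <- function(x, ...) {
  cat("Simulated overlap null:", length(x$overlaps), "size combinations x",
      x$config$reps, "replicates (", x$config$weighting, "weighting )\n")
  print(x$quantiles, row.names = FALSE)
  invisible(x)
}

# inclusive is-a ancestor sets for a vector of terms
.ancestor_sets <- function(term_ids, dag_edges) {
  g <- igraph::graph_from_data_frame(dag_edges[, c("child", "parent")],
                                     directed = TRUE)
  lapply(term_ids, function(t)
    names(igraph::subcomponent(g, t, mode = "out")))
}

#' Semantic-similarity clustering of GO terms
#'
#' Pairwise similarity is the Jaccard index of the terms' inclusive is-a
#' ancestor sets in the DAG (a graph-based semantic similarity). Clusters
#' are formed by recursive bipartition (average-linkage cut of the
#' dissimilarity into two) that stops once a cluster's mean off-diagonal
#' similarity reaches the threshold.
#'
#' @param term_ids character vector of GO term IDs.
#' @param dag_edges data.frame of child/parent is-a edges.
#' @param threshold within-cluster mean similarity at which splitting stops.
#' @return object of class `go_semsim`: list with `similarity` (symmetric
#'   matrix, unit diagonal), `clusters` (named integer), `excluded` (terms
#'   missing from the DAG) and `threshold`.
#' @export
go_semantic_clusters <- function(term_ids, dag_edges, threshold = 0.6) {
  term_ids <- unique(term_ids)
  nodes <- unique(c(dag_edges$child, dag_edges$parent))
  excluded <- setdiff(term_ids, nodes)
  if (length(excluded))
    message(length(excluded), " terms absent from the DAG were excluded")
  term_ids <- intersect(term_ids, nodes)
  if (length(term_ids) == 0) stop("no query terms present in the DAG")
  anc <- .ancestor_sets(term_ids, dag_edges)
  n <- length(term_ids)
  sim <- matrix(1, n, n, dimnames = list(term_ids, term_ids))
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      inter <- length(intersect(anc[[i]], anc[[j]]))
      uni <- length(union(anc[[i]], anc[[j]]))
      sim[i, j] <- sim[j, i] <- inter / uni
    }
  }
  clusters <- integer(n)
  names(clusters) <- term_ids
  next_id <- 0L
  assign_cluster <- function(idx) {
    next_id <<- next_id + 1L
    clusters[idx] <<- next_id
  }
  mean_offdiag <- function(idx) {
    if (length(idx) < 2) return(1)
    s <- sim[idx, idx]
    mean(s[lower.tri(s)])
  }
  recurse <- function(idx) {
    if (length(idx) <= 1 || mean_offdiag(idx) >= threshold) {
      assign_cluster(idx)
      return(invisible())
    }
    hc <- stats::hclust(stats::as.dist(1 - sim[idx, idx]), method = "average")
    grp <- stats::cutree(hc, k = 2)
    if (length(unique(grp)) < 2) { assign_cluster(idx); return(invisible()) }
    recurse(idx[grp == 1])
    recurse(idx[grp == 2])
  }
  recurse(seq_len(n))
  structure(list(similarity = sim, clusters = clusters, excluded = excluded,
                 threshold = threshold),
            class = "go_semsim")
}

#' @export
print.go_semsim <- function(x, ...) {
  cat("Semantic similarity over", nrow(x$similarity), "GO terms;",
      max(x$clusters), "clusters at threshold", x$threshold, "\n")
  invisible(x)
}
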