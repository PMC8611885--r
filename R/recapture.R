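# Fisher's exact tests for recapture of features across independently
# selected lists. Because every binary comparison starts from the same full
# transcriptome, that transcriptome is the background for all tests.

#' Fisher's exact test for the overlap of two feature lists
#'
#' Builds the 2x2 contingency table `a = |A intersect B|`, `b = |A \ B|`,
#' `c = |B \ A|`, `d = N - a - b - c` over a shared background of size `N`
#' and tests whether the overlap exceeds chance. The default one-sided
#' (enrichment) p-value is the hypergeometric upper tail
#' `P(X >= a)`; the odds ratio is `(a d)/(b c)`, reported as `Inf` when
#' `b c = 0` with overlap present (optionally Haldane-Anscombe corrected).
#'
#' @param list_a,list_b character vectors of feature IDs (deduplicated
#'   internally); both must be subsets of `background`.
#' @param background character vector of all background IDs.
#' @param alternative `"greater"` (enrichment, default) or `"two.sided"`.
#' @param haldane add 0.5 to every cell when computing the odds ratio.
#' @return object of class `overlap_test`: list with `table` (named counts
#'   a, b, c, d), `N`, `odds_ratio`, `p`, `alternative`.
#' @export
fisher_overlap <- function(list_a, list_b, background,
                           alternative = c("greater", "two.sided"),
                           haldane = FALSE) {
  alternative <- match.arg(alternative)
  background <- unique(background)
  list_a <- unique(list_a)
  list_b <- unique(list_b)
  bad <- setdiff(c(list_a, list_b), background)
  if (length(bad))
    stop("IDs absent from the background: ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) sprintf(" (and %d more)", length(bad) - 5))
  N <- length(background)
  a <- length(intersect(list_a, list_b))
  b <- length(list_a) - a
  cc <- length(list_b) - a
  d <- N - a - b - cc
  odds <- if (haldane) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
  } else if (b * cc == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * cc)
  if (a == 0 && !haldane) odds <- 0
  p <- if (alternative == "greater") {
    stats::phyper(a - 1, length(list_a), N - length(list_a), length(list_b),
                  lower.tail = FALSE)
  } else {
    m <- matrix(c(a, b, cc, d), 2, 2, byrow = TRUE)
    stats::fisher.test(m, alternative = "two.sided")$p.value
  }
  structure(list(table = c(a = a, b = b, c = cc, d = d), N = N,
                 odds_ratio = odds, p = p, alternative = alternative),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf("Overlap a=%d b=%d c=%d d=%d (N=%d)\n",
              x$table["a"], x$table["b"], x$table["c"], x$table["d"], x$N))
  cat(sprintf("odds ratio %s, p = %.4g (%s)\n",
              format(x$odds_ratio), x$p, x$alternative))
  invisible(x)
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p)` elementwise, where `m` is at least the number of
#' tests performed.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param m number of tests (defaults to `length(p_values)`).
#' @return adjusted p-values.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  if (m < length(p_values)) stop("m must be at least the number of tests")
  pmin(1, m * p_values)
}

#' All pairwise recapture tests over a set of feature lists
#'
#' Runs [fisher_overlap()] for every unordered pair of lists and applies a
#' Bonferroni correction across the tests performed.
#'
#' @param lists named list of character feature-ID vectors (e.g., the top
#'   selected features of each (cancer, site) classification).
#' @param background shared background IDs.
#' @param alternative passed to [fisher_overlap()].
#' @return data.frame: list_a, list_b, a, b, c, d, odds_ratio, p, p_adj.
#' @export
recapture_tests <- function(lists, background,
                            alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(length(lists) >= 2, !is.null(names(lists)))
  nm <- names(lists)
  pairs <- utils::combn(length(lists), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    ft <- fisher_overlap(lists[[i1]], lists[[i2]], background, alternative)
    data.frame(list_a = nm[i1], list_b = nm[i2],
               a = ft$table["a"], b = ft$table["b"], c = ft$table["c"],
               d = ft$table["d"], odds_ratio = ft$odds_ratio, p = ft$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adj <- bonferroni_adjust(out$p)
  out
}

#' Write a recapture table with an "Inf" sentinel for infinite odds ratios
#' @param tests data.frame from [recapture_tests()].
#' @param path output TSV.
#' @export
write_recapture <- function(tests, path) {
  tests$odds_ratio <- ifelse(is.infinite(tests$odds_ratio), "Inf",
                             format(tests$odds_ratio, digits = 6))
  utils::write.table(tests, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
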