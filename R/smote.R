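# Minority-class synthetic oversampling (SMOTE) with an 80%-of-majority
# stopping rule: the minority class is grown until its size equals the
# target fraction of the majority class, rounded to the closest integer.

#' SMOTE configuration
#'
#' @param k_neighbors number of minority-class nearest neighbors a synthetic
#'   sample's second parent is drawn from (SMOTE's classic default is 5).
#' @param target_fraction the minority class is oversampled until its count
#'   reaches `round(target_fraction * majority count)`; the default 0.8
#'   deliberately stops short of full balance as an overfit guard.
#' @param seed integer seed controlling template, neighbor and interpolation
#'   draws.
#' @return object of class `smote_config`.
#' @export
smote_config <- function(k_neighbors = 5, target_fraction = 0.8, seed = 1) {
  stopifnot(k_neighbors >= 1, target_fraction > 0, target_fraction <= 1)
  structure(list(k_neighbors = as.integer(k_neighbors),
                 target_fraction = target_fraction, seed = as.integer(seed)),
            class = "smote_config")
}

#' Interpolate a synthetic sample between two parents
#'
#' Returns the convex combination `x_i + u * (x_j - x_i)`; every coordinate
#' of the synthetic point lies on the segment between its parents.
#'
#' @param x_i,x_j numeric vectors of equal length (the two real parents).
#' @param u interpolation weight in `[0, 1]`.
#' @return numeric vector of the same length.
#' @export
smote_interpolate <- function(x_i, x_j, u) {
  if (length(x_i) != length(x_j))
    stop("parent dimension mismatch: ", length(x_i), " vs ", length(x_j))
  if (!is.numeric(u) || length(u) != 1 || u < 0 || u > 1)
    stop("u must be a single number in [0, 1]")
  x_i + u * (x_j - x_i)
}

#' Balance a binary dataset by SMOTE oversampling of the minority class
#'
#' Synthetic minority samples are convex combinations of a minority instance
#' and one of its `k` minority-class nearest neighbors (Euclidean distance,
#' ties broken by lower instance index; the neighbor is chosen uniformly at
#' random). Oversampling stops when the minority count reaches
#' `round(target_fraction * majority count)` (round half away from zero); if
#' the minority already meets the target, no synthetics are generated.
#'
#' @param X numeric matrix (instances x features), real samples only.
#' @param y binary labels (0/1, logical, or 2-level factor/character), length
#'   `nrow(X)`.
#' @param cfg a [smote_config()].
#' @return object of class `balanced_dataset`: list with `X` (real +
#'   synthetic rows), `y`, `is_synthetic`, `provenance` (data.frame:
#'   synthetic_id, parent_a, parent_b, u) and `config`.
#' @export
balance_dataset <- function(X, y, cfg = smote_config()) {
  stopifnot(inherits(cfg, "smote_config"))
  X <- as.matrix(X)
  y01 <- as_binary01(y)
  stopifnot(length(y01) == nrow(X))
  tab <- table(factor(y01, levels = c(0, 1)))
  if (any(tab == 0)) stop("both classes must be present")
  minority <- as.integer(names(tab)[which.min(tab)])
  min_idx <- which(y01 == minority)
  maj_n <- max(tab)
  min_n <- length(min_idx)

  target <- round_half_away(cfg$target_fraction * maj_n)
  n_syn <- max(0L, as.integer(target - min_n))

  ids <- rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))

  if (n_syn == 0L) {
    return(structure(list(X = X, y = y01,
                          is_synthetic = rep(FALSE, nrow(X)),
                          provenance = data.frame(synthetic_id = character(),
                                                  parent_a = character(),
                                                  parent_b = character(),
                                                  u = numeric()),
                          config = cfg),
                     class = "balanced_dataset"))
  }

  k <- cfg$k_neighbors
  if (min_n <= k) {
    k <- min_n - 1L
    warning("minority class has only ", min_n,
            " instances; reducing k_neighbors to ", k)
  }
  if (k < 1) stop("minority class too small for SMOTE (need at least 2 instances)")

  Xmin <- X[min_idx, , drop = FALSE]
  D <- as.matrix(stats::dist(Xmin))
  # k nearest minority neighbors per minority instance, ties by lower index
  knn <- t(vapply(seq_len(min_n), function(i) {
    ord <- order(D[i, ], seq_len(min_n))
    ord <- ord[ord != i]
    ord[seq_len(k)]
  }, integer(k)))
  if (k == 1) knn <- matrix(knn, ncol = 1)

  synth <- withr::with_seed(cfg$seed, {
    templates <- sample.int(min_n, n_syn, replace = TRUE)
    nbr_pick <- sample.int(k, n_syn, replace = TRUE)
    u <- stats::runif(n_syn)
    neighbors <- knn[cbind(templates, nbr_pick)]
    Xi <- Xmin[templates, , drop = FALSE]
    Xj <- Xmin[neighbors, , drop = FALSE]
    list(X = Xi + u * (Xj - Xi), templates = templates,
         neighbors = neighbors, u = u)
  })

  syn_ids <- sprintf("syn_%04d", seq_len(n_syn))
  rownames(synth$X) <- syn_ids
  provenance <- data.frame(synthetic_id = syn_ids,
                           parent_a = ids[min_idx[synth$templates]],
                           parent_b = ids[min_idx[synth$neighbors]],
                           u = synth$u, stringsAsFactors = FALSE)

  Xout <- rbind(X, synth$X)
  rownames(Xout) <- c(ids, syn_ids)
  yout <- c(y01, rep(minority, n_syn))
  names(yout) <- rownames(Xout)
  structure(list(X = Xout, y = yout,
                 is_synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, n_syn)),
                 provenance = provenance, config = cfg),
            class = "balanced_dataset")
}

#' @export
print.balanced_dataset <- function(x, ...) {
  tab <- table(x$y)
  cat("Balanced dataset:", nrow(x$X), "instances (",
      sum(x$is_synthetic), "synthetic )\n")
  cat("Class counts:", paste(names(tab), as.integer(tab), sep = "=",
                             collapse = ", "), "\n")
  invisible(x)
}
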