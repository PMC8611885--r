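# Blockwise consensus feature selection. The transcriptome is partitioned
# into contiguous blocks; each block is scored independently by five
# selectors (chi-square filter, recursive feature elimination under a linear
# logistic estimator, random-forest classifier and regressor importances,
# and L1-penalized logistic regression). Per-method support booleans are
# summed into a vote, features are ranked by (vote, score), colinear
# features are pruned greedily in rank order, and the top of each block is
# retained as the candidate set.

#' Consensus feature-selection configuration
#'
#' @param n_blocks number of contiguous feature blocks (100 splits a 60,483
#'   transcript feature space into blocks of roughly 600).
#' @param per_block_keep features retained per block after voting and
#'   colinearity pruning (50 per block over 100 blocks gives ~5000
#'   candidates).
#' @param keep_fraction if non-`NULL`, overrides `per_block_keep` with
#'   `round(keep_fraction * block size)` — the "top 10% per block" reading.
#' @param colinearity_r absolute Pearson correlation at or above which a
#'   lower-ranked feature is dropped as colinear.
#' @param export_top size of the globally ranked export list (the "top 1000"
#'   used for recapture and enrichment).
#' @param rfe_step fraction of remaining features eliminated per RFE round.
#' @param num_trees trees per random forest selector.
#' @param cv_folds if > 1, each selector is refitted leaving one fold out at
#'   a time and a method supports a feature only when it does so in a
#'   majority of folds.
#' @param seed integer seed (forest selectors are seeded per block).
#' @return object of class `selection_config`.
#' @export
selection_config <- function(n_blocks = 100, per_block_keep = 50,
                             keep_fraction = NULL, colinearity_r = 0.95,
                             export_top = 1000, rfe_step = 0.1,
                             num_trees = 100, cv_folds = 1, seed = 1) {
  stopifnot(n_blocks >= 1, per_block_keep >= 1,
            colinearity_r > 0, colinearity_r <= 1,
            export_top >= 1, rfe_step > 0, rfe_step < 1,
            num_trees >= 1, cv_folds >= 1)
  if (!is.null(keep_fraction))
    stopifnot(keep_fraction > 0, keep_fraction <= 1)
  structure(list(n_blocks = as.integer(n_blocks),
                 per_block_keep = as.integer(per_block_keep),
                 keep_fraction = keep_fraction,
                 colinearity_r = colinearity_r,
                 export_top = as.integer(export_top),
                 rfe_step = rfe_step, num_trees = as.integer(num_trees),
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed)),
            class = "selection_config")
}

#' Partition a feature space into contiguous, nearly equal blocks
#'
#' The first `n mod B` blocks get `ceiling(n / B)` features and the rest
#' `floor(n / B)`; blocks are disjoint, order-preserving and cover all
#' features.
#'
#' @param n_features total feature count.
#' @param n_blocks number of blocks (must not exceed `n_features`).
#' @return object of class `block_partition`: a list of integer index
#'   vectors.
#' @export
partition_blocks <- function(n_features, n_blocks) {
  stopifnot(n_features >= 1, n_blocks >= 1)
  if (n_blocks > n_features)
    stop("n_blocks (", n_blocks, ") exceeds n_features (", n_features, ")")
  base <- n_features %/% n_blocks
  extra <- n_features %% n_blocks
  sizes <- c(rep(base + 1L, extra), rep(base, n_blocks - extra))
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  blocks <- Map(seq.int, starts, ends)
  structure(blocks, class = "block_partition",
            n_features = n_features, n_blocks = n_blocks)
}

# top-k support by (score desc, index asc); returns logical vector
.top_k_support <- function(score, k) {
  p <- length(score)
  sup <- rep(FALSE, p)
  if (k > 0) sup[order(-score, seq_len(p))[seq_len(min(k, p))]] <- TRUE
  sup
}

#' Chi-square filter selection
#'
#' Features are min-max scaled to `[0, 1]` (the chi-square statistic needs
#' nonnegative input; constant features scale to all zeros and score 0) and
#' scored by the chi-square statistic between per-class feature mass and the
#' class marginal. The `k` highest-scoring features are supported, ties
#' broken by lower feature index.
#'
#' @param block_X numeric matrix (instances x block features).
#' @param y binary labels.
#' @param k number of features to support.
#' @return list with `support` (logical) and `score` (numeric).
#' @export
chi2_select <- function(block_X, y, k) {
  y01 <- as_binary01(y)
  if (length(unique(y01)) < 2) stop("single-class target")
  Xs <- minmax_scale(block_X)
  score <- rep(0, ncol(Xs))
  tot <- colSums(Xs)
  for (cls in c(0L, 1L)) {
    obs <- colSums(Xs[y01 == cls, , drop = FALSE])
    expd <- tot * mean(y01 == cls)
    ok <- expd > 0
    score[ok] <- score[ok] + (obs[ok] - expd[ok])^2 / expd[ok]
  }
  list(support = .top_k_support(score, k), score = score)
}

# ridge-logistic coefficient magnitudes used as the RFE ranking criterion;
# on non-convergence the regularization is increased once, then it errors
.logistic_coef <- function(X, y01, lambda = 1e-2) {
  fit_once <- function(lam) {
    fit <- glmnet::glmnet(X, y01, family = "binomial", alpha = 0,
                          lambda = lam, standardize = FALSE)
    as.numeric(fit$beta)
  }
  tryCatch(fit_once(lambda),
           error = function(e) {
             tryCatch(fit_once(lambda * 10),
                      error = function(e2)
                        stop("logistic estimator failed to converge: ",
                             conditionMessage(e2)))
           })
}

#' Recursive feature elimination under a linear logistic estimator
#'
#' Features are standardized and a regularized logistic model is refitted
#' repeatedly; each round the `step` fraction (at least one) of the
#' lowest-|coefficient| features is dropped until `n_keep` remain.
#'
#' @param block_X numeric matrix.
#' @param y binary labels.
#' @param n_keep number of surviving features.
#' @param step fraction of remaining features removed per round.
#' @return list with `support` (logical over block features) and `rounds`
#'   (elimination rounds performed).
#' @export
rfe_select <- function(block_X, y, n_keep, step = 0.1) {
  y01 <- as_binary01(y)
  if (length(unique(y01)) < 2) stop("two classes required")
  stopifnot(n_keep >= 1, step > 0, step < 1)
  p <- ncol(block_X)
  Xs <- standardize(block_X)
  keep <- seq_len(p)
  rounds <- 0L
  while (length(keep) > n_keep) {
    beta <- abs(.logistic_coef(Xs[, keep, drop = FALSE], y01))
    drop_n <- min(max(1L, as.integer(floor(step * length(keep)))),
                  length(keep) - n_keep)
    # remove the lowest-|coef| features; on ties the higher index goes first
    ord <- order(beta, -seq_along(keep))
    keep <- sort(keep[-ord[seq_len(drop_n)]])
    rounds <- rounds + 1L
  }
  sup <- rep(FALSE, p)
  sup[keep] <- TRUE
  list(support = sup, rounds = rounds)
}

#' Embedded feature selection (forest importances, L1 logistic)
#'
#' `rf_classifier` and `rf_regressor` rank features by impurity importance
#' of a seeded random forest (the regressor treats the 0/1 label as a
#' numeric target); `l1_logistic` ranks by |coefficient| of an L1-penalized
#' logistic model at the sparsest point on the regularization path with at
#' least `n_keep` active features. Support is the top `n_keep` by score,
#' ties broken by lower index; if every score is zero nothing is supported.
#'
#' @param block_X numeric matrix.
#' @param y binary labels.
#' @param method one of `"rf_classifier"`, `"rf_regressor"`, `"l1_logistic"`.
#' @param n_keep number of features to support.
#' @param seed forest seed.
#' @param num_trees trees per forest.
#' @return list with `support` and `score`.
#' @export
embedded_select <- function(block_X, y,
                            method = c("rf_classifier", "rf_regressor",
                                       "l1_logistic"),
                            n_keep, seed = 1, num_trees = 100) {
  method <- match.arg(method)
  y01 <- as_binary01(y)
  if (length(unique(y01)) < 2) stop("two classes required")
  p <- ncol(block_X)
  df <- as.data.frame(block_X)
  names(df) <- paste0("f", seq_len(p))
  score <- switch(method,
    rf_classifier = {
      fit <- ranger::ranger(x = df, y = factor(y01), num.trees = num_trees,
                            importance = "impurity", seed = seed,
                            num.threads = 1)
      unname(fit$variable.importance)
    },
    rf_regressor = {
      fit <- ranger::ranger(x = df, y = as.numeric(y01), num.trees = num_trees,
                            importance = "impurity", seed = seed,
                            num.threads = 1)
      unname(fit$variable.importance)
    },
    l1_logistic = {
      fit <- glmnet::glmnet(as.matrix(block_X), y01, family = "binomial",
                            alpha = 1)
      nz <- fit$df
      idx <- which(nz >= min(n_keep, p))[1]
      if (is.na(idx)) idx <- length(fit$lambda)
      abs(as.numeric(fit$beta[, idx]))
    })
  if (n_keep == 0) return(list(support = rep(FALSE, p), score = score))
  if (all(score == 0)) {
    warning("all-zero importances for ", method, "; supporting no features")
    return(list(support = rep(FALSE, p), score = score))
  }
  list(support = .top_k_support(score, n_keep), score = score)
}

.METHODS <- c("chi2_filter", "rfe_logistic", "rf_classifier", "rf_regressor",
              "l1_logistic")

# run the five selectors on one block, optionally over leave-one-fold-out
# refits with majority-fold support
score_block <- function(block_X, y, k, cfg, seed) {
  y01 <- as_binary01(y)
  p <- ncol(block_X)
  run_once <- function(rows) {
    Xb <- block_X[rows, , drop = FALSE]
    yb <- y01[rows]
    chi <- chi2_select(Xb, yb, k)
    rfe <- rfe_select(Xb, yb, n_keep = min(k, p), step = cfg$rfe_step)
    rfc <- embedded_select(Xb, yb, "rf_classifier", k, seed = seed,
                           num_trees = cfg$num_trees)
    rfr <- embedded_select(Xb, yb, "rf_regressor", k, seed = seed + 1L,
                           num_trees = cfg$num_trees)
    l1 <- suppressWarnings(embedded_select(Xb, yb, "l1_logistic", k))
    list(sup = cbind(chi2_filter = chi$support, rfe_logistic = rfe$support,
                     rf_classifier = rfc$support, rf_regressor = rfr$support,
                     l1_logistic = l1$support),
         sco = cbind(chi2_filter = chi$score, rfe_logistic = as.numeric(rfe$support),
                     rf_classifier = rfc$score, rf_regressor = rfr$score,
                     l1_logistic = l1$score))
  }
  n <- length(y01)
  if (cfg$cv_folds <= 1) {
    res <- run_once(seq_len(n))
    return(res)
  }
  folds <- make_stratified_folds(y01, cfg$cv_folds, seed)
  runs <- lapply(seq_len(cfg$cv_folds), function(f) run_once(which(folds != f)))
  sup_sum <- Reduce(`+`, lapply(runs, function(r) r$sup * 1L))
  sco_mean <- Reduce(`+`, lapply(runs, function(r) r$sco)) / cfg$cv_folds
  list(sup = sup_sum > cfg$cv_folds / 2, sco = sco_mean)
}

# deterministic stratified fold assignment
make_stratified_folds <- function(y01, k, seed) {
  folds <- integer(length(y01))
  withr::with_seed(seed, {
    for (cls in unique(y01)) {
      idx <- which(y01 == cls)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

#' Vote and rank features by consensus support
#'
#' The vote is the number of methods supporting the feature (0-5); features
#' are ranked by vote (descending), then by the mean of per-method scores
#' normalized to `[0, 1]` (descending), then by lower feature index.
#'
#' @param supports a support table: data.frame with columns `feature`,
#'   `idx`, five `sup_*` logicals and five `score_*` columns (as produced
#'   inside [select_candidates()], or built by hand).
#' @return the table with `vote` and `mean_score` columns, sorted in rank
#'   order.
#' @export
vote_and_rank <- function(supports) {
  sup_cols <- paste0("sup_", .METHODS)
  sco_cols <- paste0("score_", .METHODS)
  stopifnot(all(sup_cols %in% names(supports)))
  supports$vote <- rowSums(as.matrix(supports[, sup_cols]))
  norm <- sapply(sco_cols, function(cn) {
    v <- supports[[cn]]
    if (is.null(v)) return(rep(0, nrow(supports)))
    rng <- range(v)
    if (diff(rng) == 0) rep(0, length(v)) else (v - rng[1]) / diff(rng)
  })
  supports$mean_score <- rowMeans(as.matrix(norm))
  ord <- order(-supports$vote, -supports$mean_score, supports$idx)
  out <- supports[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy colinearity pruning in rank order
#'
#' Scans the ranked feature list and drops any feature whose absolute
#' Pearson correlation with an already-kept feature is at or above the
#' threshold, so higher-support features survive. Zero-variance features
#' have undefined correlation, treated as 0 (colinear with nothing).
#'
#' @param ranked character vector of feature names in rank order.
#' @param X numeric matrix containing those columns.
#' @param r_threshold absolute correlation threshold.
#' @return the retained feature names, still in rank order.
#' @export
drop_colinear <- function(ranked, X, r_threshold = 0.95) {
  stopifnot(length(ranked) >= 1, all(ranked %in% colnames(X)))
  kept <- character(0)
  for (f in ranked) {
    if (length(kept) == 0) { kept <- f; next }
    r <- suppressWarnings(stats::cor(X[, f], X[, kept, drop = FALSE]))
    r[is.na(r)] <- 0
    if (all(abs(r) < r_threshold)) kept <- c(kept, f)
  }
  kept
}

#' Blockwise consensus feature selection
#'
#' Partitions the feature space into blocks, scores each block with the
#' five selectors, votes and ranks, prunes colinear features greedily, and
#' retains the top `per_block_keep` features per block (all survivors, with
#' a logged shortfall, if pruning exhausts a block). Candidates from all
#' blocks are pooled and additionally ranked globally by (vote, normalized
#' score, index) to export the top `export_top` list.
#'
#' @param X numeric matrix (instances x features) with column names.
#' @param y binary labels.
#' @param cfg a [selection_config()].
#' @return object of class `candidate_set`: list with `candidates`
#'   (character, in block order), `top` (global top `export_top`), `support`
#'   (full support table), `partition`, `shortfall` (named integer) and
#'   `config`.
#' @export
select_candidates <- function(X, y, cfg = selection_config()) {
  stopifnot(inherits(cfg, "selection_config"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("feat_%05d", seq_len(ncol(X)))
  blocks <- partition_blocks(ncol(X), cfg$n_blocks)
  tables <- vector("list", length(blocks))
  kept_per_block <- vector("list", length(blocks))
  shortfall <- integer(0)
  for (b in seq_along(blocks)) {
    idx <- blocks[[b]]
    Xb <- X[, idx, drop = FALSE]
    keep_b <- if (!is.null(cfg$keep_fraction))
      max(1L, as.integer(round_half_away(cfg$keep_fraction * length(idx))))
    else min(cfg$per_block_keep, length(idx))
    res <- score_block(Xb, y, keep_b, cfg, seed = cfg$seed + b)
    tab <- data.frame(feature = colnames(Xb), idx = idx, block = b,
                      stringsAsFactors = FALSE)
    for (m in .METHODS) {
      tab[[paste0("sup_", m)]] <- res$sup[, m]
      tab[[paste0("score_", m)]] <- res$sco[, m]
    }
    tab <- vote_and_rank(tab)
    surv <- drop_colinear(tab$feature, Xb, cfg$colinearity_r)
    if (length(surv) < keep_b) {
      shortfall[as.character(b)] <- keep_b - length(surv)
      message("block ", b, ": colinearity pruning left ", length(surv),
              " of the requested ", keep_b, " features")
    }
    kept_per_block[[b]] <- utils::head(surv, keep_b)
    tables[[b]] <- tab
  }
  support <- do.call(rbind, tables)
  rownames(support) <- NULL
  candidates <- unlist(kept_per_block, use.names = FALSE)
  cand_tab <- support[support$feature %in% candidates, , drop = FALSE]
  ord <- order(-cand_tab$vote, -cand_tab$mean_score, cand_tab$idx)
  top <- utils::head(cand_tab$feature[ord], cfg$export_top)
  structure(list(candidates = candidates, top = top, support = support,
                 partition = blocks, shortfall = shortfall, config = cfg),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("Candidate feature set:", length(x$candidates), "candidates from",
      length(x$partition), "blocks; exported top", length(x$top), "\n")
  if (length(x$shortfall))
    cat("Blocks short after colinearity pruning:",
        paste(names(x$shortfall), collapse = ", "), "\n")
  invisible(x)
}

#' Write a support table / candidate lists to disk
#' @param candidate_set a `candidate_set`.
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
write_candidates <- function(candidate_set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- file.path(dir, "support_table.tsv")
  cp <- file.path(dir, "candidates.txt")
  tp <- file.path(dir, "top_features.txt")
  utils::write.table(candidate_set$support, sp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(candidate_set$candidates, cp)
  writeLines(candidate_set$top, tp)
  invisible(c(support = sp, candidates = cp, top = tp))
}
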