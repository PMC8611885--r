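test_that("block partition sizes follow division with remainder", {
  bp <- partition_blocks(60483, 100)
  sizes <- lengths(bp)
  expect_equal(sum(sizes), 60483)
  expect_equal(sum(sizes == 605), 83)
  expect_equal(sum(sizes == 604), 17)
  expect_equal(lengths(partition_blocks(10, 2)), c(5L, 5L))
  expect_equal(lengths(partition_blocks(7, 7)), rep(1L, 7))
  expect_error(partition_blocks(5, 6), "exceeds")
})

test_that("blocks are disjoint, order-preserving and cover all features", {
  for (s in 1:50) {
    withr::with_seed(s, {
      n <- sample(5:5000, 1)
      B <- sample(seq_len(n), 1)
    })
    bp <- partition_blocks(n, B)
    idx <- unlist(bp)
    expect_identical(idx, seq_len(n))          # coverage + order
    expect_lte(diff(range(lengths(bp))), 1)    # sizes differ by <= 1
  }
})

test_that("chi-square filter finds a label-identical feature among noise", {
  withr::with_seed(21, {
    y <- rep(c(0, 1), each = 20)
    X <- matrix(runif(40 * 6), 40, 6)
    X[, 4] <- y
  })
  res <- chi2_select(X, y, k = 1)
  expect_true(res$support[4])
  expect_equal(sum(res$support), 1)
  # brute-force chi-square on the 2x2 table for the binary feature: after
  # min-max scaling the class sums are the 'observed' masses
  Xs <- X
  obs <- c(sum(X[y == 0, 4]), sum(X[y == 1, 4]))
  expd <- sum(X[, 4]) * c(0.5, 0.5)
  expect_equal(res$score[4], sum((obs - expd)^2 / expd))
  # saturation and degenerate target
  expect_true(all(chi2_select(X, y, k = ncol(X))$support))
  expect_error(chi2_select(X, rep(1, 40), k = 1), "single-class")
  # constant feature scores zero and is never supported at small k
  Xc <- cbind(X, const = 5)
  resc <- chi2_select(Xc, y, k = 3)
  expect_equal(resc$score[7], 0)
  expect_false(resc$support[7])
})

test_that("RFE keeps a perfectly separating feature and counts rounds", {
  withr::with_seed(22, {
    y <- rep(c(0, 1), each = 25)
    X <- matrix(rnorm(50 * 5), 50, 5)
    X[, 2] <- y * 4 + rnorm(50, sd = 0.1)
  })
  res <- rfe_select(X, y, n_keep = 1, step = 0.1)
  expect_true(res$support[2])
  expect_equal(sum(res$support), 1)
  # n_keep = block size: no elimination at all
  res_all <- rfe_select(X, y, n_keep = 5)
  expect_true(all(res_all$support))
  expect_equal(res_all$rounds, 0L)
  # one-per-round schedule on 3 features takes exactly 2 rounds
  res3 <- rfe_select(X[, 1:3], y, n_keep = 1, step = 0.1)
  expect_equal(res3$rounds, 2L)
})

test_that("embedded selectors rank a planted linear signal first", {
  withr::with_seed(23, {
    y <- rep(c(0, 1), each = 30)
    X <- matrix(rnorm(60 * 8), 60, 8)
    X[, 5] <- y * 3 + rnorm(60, sd = 0.3)
  })
  for (m in c("rf_classifier", "rf_regressor", "l1_logistic")) {
    res <- embedded_select(X, y, m, n_keep = 1, seed = 2)
    expect_true(res$support[5], label = m)
  }
  # seeded forests are reproducible on pure noise
  withr::with_seed(24, Xn <- matrix(rnorm(40 * 10), 40, 10))
  yn <- rep(c(0, 1), each = 20)
  r1 <- embedded_select(Xn, yn, "rf_classifier", 3, seed = 7)
  r2 <- embedded_select(Xn, yn, "rf_classifier", 3, seed = 7)
  expect_identical(r1$support, r2$support)
  expect_identical(r1$score, r2$score)
  # n_keep = 0 supports nothing
  expect_equal(sum(embedded_select(Xn, yn, "rf_classifier", 0, seed = 1)$support), 0)
})

test_that("votes count supports and rank with the declared tie-breaks", {
  tab <- data.frame(feature = c("a", "b", "c"), idx = 1:3, block = 1)
  sup <- list(c(TRUE, TRUE, FALSE, TRUE, FALSE),   # a: vote 3
              c(TRUE, TRUE, TRUE, TRUE, TRUE),     # b: vote 5
              c(TRUE, TRUE, FALSE, TRUE, FALSE))   # c: vote 3
  methods <- c("chi2_filter", "rfe_logistic", "rf_classifier", "rf_regressor",
               "l1_logistic")
  for (j in seq_along(methods)) {
    tab[[paste0("sup_", methods[j])]] <- c(sup[[1]][j], sup[[2]][j], sup[[3]][j])
    tab[[paste0("score_", methods[j])]] <- c(1, 1, 1)  # equal scores
  }
  ranked <- vote_and_rank(tab)
  expect_equal(ranked$vote, c(5, 3, 3))
  expect_equal(ranked$feature, c("b", "a", "c"))  # 5 first, then index order
})

test_that("colinearity pruning drops duplicates and sign flips, keeps orthogonals", {
  withr::with_seed(25, {
    X <- matrix(rnorm(100 * 3), 100, 3)
    X <- cbind(X, dup = X[, 1], neg = -X[, 2])
    colnames(X) <- c("a", "b", "c", "dup", "neg")
  })
  kept <- drop_colinear(c("a", "b", "c", "dup", "neg"), X, 0.95)
  expect_equal(kept, c("a", "b", "c"))
  # orthogonal features all survive
  expect_equal(drop_colinear(c("a", "b", "c"), X, 0.95), c("a", "b", "c"))
  # rank order decides the survivor
  expect_equal(drop_colinear(c("dup", "a"), X, 0.95), "dup")
})

test_that("candidate counts follow the per-block arithmetic", {
  withr::with_seed(26, {
    X <- matrix(rnorm(60 * 10), 60, 10)
    colnames(X) <- sprintf("t%02d", 1:10)
    y <- rep(c(0, 1), each = 30)
  })
  cs <- select_candidates(X, y, selection_config(n_blocks = 2, per_block_keep = 3,
                                                 export_top = 4, seed = 1))
  expect_length(cs$candidates, 6)
  expect_length(cs$top, 4)
  expect_true(all(cs$top %in% cs$candidates))
  # per-block: 3 candidates from each contiguous half
  expect_equal(sum(cs$candidates %in% sprintf("t%02d", 1:5)), 3)
})

test_that("selection recovers a planted signature within the candidate set", {
  co <- small_cohort(seed = 31, effect_size = 2, samples_per_type = 80,
                     n_transcripts = 300, positive_fraction = 0.35)
  key <- names(co$truth$signatures)[1]
  sig <- co$truth$signatures[[key]]
  code <- sub("\\|.*", "", key)
  rows <- grepl(paste0("^", code), rownames(co$expression))
  y <- as.integer(rownames(co$expression)[rows] %in% co$truth$positives[[key]])
  names(y) <- rownames(co$expression)[rows]
  cs <- select_candidates(co$expression[rows, ], y,
                          selection_config(n_blocks = 3, per_block_keep = 25,
                                           export_top = 75, seed = 2))
  expect_gte(length(intersect(sig, cs$candidates)), 8)  # >= 80% of 10
})

test_that("within-block feature permutation does not change selected IDs", {
  withr::with_seed(27, {
    X <- matrix(rnorm(70 * 12), 70, 12)
    colnames(X) <- sprintf("g%02d", 1:12)
    y <- rep(c(0, 1), each = 35)
    X[, 3] <- y * 2 + rnorm(70, sd = 0.5)   # distinct scores, no index ties
    X[, 9] <- y * 1.5 + rnorm(70, sd = 0.5)
  })
  cfg <- selection_config(n_blocks = 2, per_block_keep = 2, export_top = 4,
                          seed = 5)
  base <- select_candidates(X, y, cfg)
  perm <- c(sample(1:6), sample(7:12))  # permute inside each block only
  withr::with_seed(28, perm <- c(sample(1:6), sample(7:12)))
  Xp <- X[, perm]
  permuted <- select_candidates(Xp, y, cfg)
  expect_setequal(base$candidates, permuted$candidates)
})

test_that("on pure noise, planted-feature recovery sits at chance", {
  withr::with_seed(29, {
    X <- matrix(rnorm(80 * 60), 80, 60)
    colnames(X) <- sprintf("n%02d", 1:60)
    y <- rep(c(0, 1), each = 40)
    fake_sig <- sample(colnames(X), 12)
  })
  cs <- select_candidates(X, y, selection_config(n_blocks = 2, per_block_keep = 15,
                                                 export_top = 30, seed = 3))
  hit <- length(intersect(fake_sig, cs$candidates))
  # chance rate: 30/60 candidates -> Binomial(12, 0.5), central 95% bounds
  expect_gte(hit, qbinom(0.025, 12, 0.5))
  expect_lte(hit, qbinom(0.975, 12, 0.5))
})
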