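test_that("transcripts map to their terms and aggregate by union", {
  ann <- tiny_annotation()
  mp <- map_transcripts_to_go(c("t3", "t7"), ann)
  expect_equal(sort(mp$per_transcript[["t3"]]), c("GO:0000001", "GO:0000002"))
  expect_equal(mp$per_transcript[["t7"]], "GO:0000003")
  expect_setequal(mp$terms, c("GO:0000001", "GO:0000002", "GO:0000003"))
  # unannotated transcripts are dropped and counted
  expect_message(mp2 <- map_transcripts_to_go(c("t1", "nope"), ann), "dropped")
  expect_equal(attr(mp2, "n_dropped"), 1)
  # disjoint transcripts: aggregate is the union of their term sets
  mp3 <- suppressMessages(map_transcripts_to_go(c("t1", "t7"), ann))
  expect_length(mp3$terms, 2)
})

test_that("hypergeometric enrichment p matches exact enumeration", {
  # hand-checkable case: N=20, K=5, n=4, k=3
  terms <- list(T1 = sprintf("g%02d", 1:5))
  universe <- sprintf("g%02d", 1:20)
  terms$T0 <- universe  # second term so the universe is complete
  ann <- structure(list(terms = terms,
                        multiplicity = stats::setNames(rep(1L, 20), universe),
                        dag = NULL, root = NA, config = NULL),
                   class = "go_annotation")
  res <- go_overrepresentation(c("g01", "g02", "g03", "g11"), ann)
  p_hand <- (choose(5, 3) * choose(15, 1) + choose(5, 4) * choose(15, 0)) /
    choose(20, 4)
  expect_equal(res$p[res$term == "T1"], p_hand)
  expect_equal(p_hand, 155 / 4845)
  # Bonferroni over the 2 tested terms
  expect_equal(res$p_adj, pmin(1, 2 * res$p))
  # k = 0 gives p = 1
  res0 <- go_overrepresentation(c("g11", "g12"), ann)
  expect_equal(res0$p[res0$term == "T1"], 1)

  # random small cases against the enumeration oracle
  for (s in 1:40) {
    withr::with_seed(s, {
      N <- sample(10:50, 1)
      uni <- sprintf("u%02d", seq_len(N))
      K <- sample(2:(N - 1), 1)
      n <- sample(1:(N - 1), 1)
      annr <- structure(list(terms = list(A = sample(uni, K), ALL = uni),
                             multiplicity = stats::setNames(rep(1L, N), uni),
                             dag = NULL, root = NA, config = NULL),
                        class = "go_annotation")
      lst <- sample(uni, n)
    })
    res <- go_overrepresentation(lst, annr)
    k <- length(intersect(lst, annr$terms$A))
    expect_equal(res$p[res$term == "A"], enum_upper_tail(k, K, n, N),
                 tolerance = 1e-12)
  }
})

test_that("a list with no annotated members warns and returns empty", {
  ann <- tiny_annotation()
  expect_warning(res <- go_overrepresentation(c("x", "y"), ann), "no annotated")
  expect_equal(nrow(res), 0)
})

test_that("inverse-multiplicity weighting favors sparsely annotated transcripts", {
  ids <- c(sprintf("a%02d", 1:30), sprintf("b%02d", 1:30))
  terms <- list(T1 = ids[1:30],                      # a* have m = 1
                T2 = ids[31:60], T3 = ids[31:60])    # b* have m = 2
  mult <- stats::setNames(c(rep(1L, 30), rep(2L, 30)), ids)
  w <- 1 / as.numeric(mult)
  draws <- withr::with_seed(8, {
    vapply(1:10000, function(i) sample(ids, 1, prob = w), "")
  })
  frac_a <- mean(grepl("^a", draws))
  # w=1 vs w=0.5 over equal group sizes -> 2/3 of draws from group a
  expect_equal(frac_a, 2 / 3, tolerance = 0.03)
})

test_that("uniform multiplicity makes weighted sampling uniform", {
  ids <- sprintf("t%03d", 1:500)
  ann <- structure(list(terms = list(A = ids[1:250], B = ids[251:500]),
                        multiplicity = stats::setNames(rep(1L, 500), ids),
                        dag = NULL, root = NA, config = NULL),
                   class = "go_annotation")
  nw <- weighted_overlap_null(ann, null_sim_config(list_sizes = c(20, 40),
                                                   reps = 30, seed = 2,
                                                   weighting = "inverse-multiplicity"))
  nu <- weighted_overlap_null(ann, null_sim_config(list_sizes = c(20, 40),
                                                   reps = 30, seed = 2,
                                                   weighting = "uniform"))
  # identical weights (all 1) and seed => identical draws and overlaps
  expect_identical(nw$overlaps, nu$overlaps)
})

test_that("the overlap null has the configured shape and bounded overlaps", {
  ids <- sprintf("t%03d", 1:400)
  ann <- generate_go_annotation(go_config(n_terms = 25, term_size_range = c(8, 30),
                                          multiplicity_skew = 1, seed = 6), ids)
  cfg <- null_sim_config(list_sizes = c(50, 100, 150), reps = 40, seed = 3)
  nl <- weighted_overlap_null(ann, cfg)
  expect_length(nl$overlaps, 6)   # 3 sizes -> 6 unordered combinations
  expect_true(all(vapply(nl$overlaps, length, 0L) == 40))
  expect_true(all(unlist(nl$overlaps) >= 0))
  expect_true(all(unlist(nl$overlaps) <= 25))
  expect_equal(nrow(nl$quantiles), 6)
  # oversized lists are rejected
  expect_error(weighted_overlap_null(ann, null_sim_config(list_sizes = 1000,
                                                          reps = 2)),
               "exceeds")
})

test_that("semantic similarity is a proper similarity with sensible values", {
  # toy DAG: root -> p1 -> {t1, t2}; root -> p2 -> {t3}
  dag <- data.frame(child = c("p1", "p2", "t1", "t2", "t3"),
                    parent = c("root", "root", "p1", "p1", "p2"))
  sem <- go_semantic_clusters(c("t1", "t2", "t3"), dag, threshold = 0.6)
  S <- sem$similarity
  expect_equal(diag(S), stats::setNames(rep(1, 3), c("t1", "t2", "t3")))
  expect_equal(S, t(S))
  # t1, t2 share {p1, root}: ancestors {t,p1,root} -> Jaccard 2/4
  expect_equal(S["t1", "t2"], 0.5)
  # t1, t3 share only the root: 1 / |union| = 1/5
  expect_equal(S["t1", "t3"], 1 / 5)
  # terms missing from the DAG are excluded with a message
  expect_message(go_semantic_clusters(c("t1", "GO:none"), dag), "excluded")
})

test_that("two planted term families recover exactly two clusters", {
  dag <- data.frame(
    child = c("famA", "famB", paste0("a", 1:4), paste0("b", 1:4)),
    parent = c("root", "root", rep("famA", 4), rep("famB", 4)))
  # within-family similarity is 0.5, cross-family 0.2; a 0.45 threshold
  # stops the bipartition exactly at the family level
  sem <- go_semantic_clusters(c(paste0("a", 1:4), paste0("b", 1:4)), dag,
                              threshold = 0.45)
  cl <- sem$clusters
  expect_equal(length(unique(cl)), 2)
  expect_length(unique(cl[paste0("a", 1:4)]), 1)
  expect_length(unique(cl[paste0("b", 1:4)]), 1)
  expect_false(cl[["a1"]] == cl[["b1"]])
})
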