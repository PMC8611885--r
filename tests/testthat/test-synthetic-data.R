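test_that("a fixed seed reproduces the cohort bit-for-bit", {
  a <- small_cohort(seed = 7)
  b <- small_cohort(seed = 7)
  expect_identical(a$expression, b$expression)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth, b$truth)
  c2 <- small_cohort(seed = 8)
  expect_false(identical(a$expression, c2$expression))
})

test_that("cohort dimensions and label fractions match the configuration", {
  cfg <- cohort_config(n_cancer_types = 3, samples_per_type = 100,
                       n_transcripts = 2000, seed = 2)
  co <- generate_cohort(cfg)
  expect_equal(dim(co$expression), c(300, 2000))
  expect_equal(nrow(co$clinical), 300)
  expect_true(all(co$expression >= 0))
  # marginal positive counts match the configured fraction within rounding
  for (key in names(co$truth$positives))
    expect_equal(length(co$truth$positives[[key]]),
                 round(cfg$positive_fraction * cfg$samples_per_type))
  # synchronous rows at the configured fraction of metastatic rows
  n_met <- sum(nzchar(co$clinical[["metastatic tissue"]]))
  expect_equal(length(co$truth$synchronous_samples),
               round(cfg$synchronous_fraction * n_met))
})

test_that("positive samples carry the planted signature shift", {
  co <- small_cohort(seed = 5, effect_size = 2)
  key <- names(co$truth$signatures)[1]
  sig <- co$truth$signatures[[key]]
  pos <- co$truth$positives[[key]]
  code <- sub("\\|.*", "", key)
  same_type <- grepl(paste0("^", code), rownames(co$expression))
  neg <- setdiff(rownames(co$expression)[same_type], pos)
  lp <- log1p(co$expression[pos, sig, drop = FALSE])
  ln <- log1p(co$expression[neg, sig, drop = FALSE])
  d <- abs(colMeans(lp) - colMeans(ln)) / apply(log1p(co$expression[same_type, sig]), 2, sd)
  expect_gt(mean(d), 1)  # strong standardized separation on signature transcripts
})

test_that("effect_size 0 leaves signature transcripts at background level", {
  co <- small_cohort(seed = 5, effect_size = 0)
  key <- names(co$truth$signatures)[1]
  sig <- co$truth$signatures[[key]]
  pos <- co$truth$positives[[key]]
  code <- sub("\\|.*", "", key)
  same_type <- grepl(paste0("^", code), rownames(co$expression))
  neg <- setdiff(rownames(co$expression)[same_type], pos)
  d <- abs(colMeans(log1p(co$expression[pos, sig, drop = FALSE])) -
           colMeans(log1p(co$expression[neg, sig, drop = FALSE]))) /
    apply(log1p(co$expression[same_type, sig]), 2, sd)
  expect_lt(mean(d), 0.5)
})

test_that("signature allocation is rejected when it would exhaust the features", {
  expect_error(cohort_config(n_cancer_types = 4, n_transcripts = 100,
                             tropism_signature_size = 30,
                             type_signature_size = 0),
               "exhausting")
})

test_that("cohort round-trips through its on-disk representation", {
  co <- small_cohort(seed = 9, n_transcripts = 120, samples_per_type = 15)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  X <- read_expression(file.path(dir, "expression.tsv"))
  expect_equal(X, co$expression)
})

test_that("GO annotation respects multiplicity and size contracts", {
  ids <- sprintf("tx%04d", 1:2000)
  ann <- generate_go_annotation(go_config(n_terms = 50, term_size_range = c(10, 40),
                                          multiplicity_skew = 1, seed = 4), ids)
  expect_true(all(lengths(ann$terms) >= 10))
  expect_true(all(ann$multiplicity >= 1))
  # non-degenerate multiplicity: singletons and multi-mappers both present
  expect_true(any(ann$multiplicity == 1) && any(ann$multiplicity > 1))
  # every annotated transcript maps to at least one term
  expect_setequal(unique(unlist(ann$terms)), ids)
  # fixed seed => identical annotation
  ann2 <- generate_go_annotation(go_config(n_terms = 50, term_size_range = c(10, 40),
                                           multiplicity_skew = 1, seed = 4), ids)
  expect_identical(ann$terms, ann2$terms)
})

test_that("zero multiplicity skew degenerates to one term per transcript", {
  ids <- sprintf("tx%03d", 1:400)
  ann <- generate_go_annotation(go_config(n_terms = 20, term_size_range = c(5, 30),
                                          multiplicity_skew = 0, seed = 1), ids)
  expect_true(all(ann$multiplicity == 1))
  expect_equal(sum(lengths(ann$terms)), 400)
})

test_that("the generated DAG is rooted and acyclic", {
  ids <- sprintf("tx%03d", 1:300)
  ann <- generate_go_annotation(go_config(n_terms = 30, dag_depth = 4, seed = 2,
                                          term_size_range = c(5, 20)), ids)
  g <- igraph::graph_from_data_frame(ann$dag)
  expect_true(igraph::is_dag(g))
  # every term reaches the root
  root_reach <- igraph::subcomponent(g, ann$root, mode = "in")
  expect_setequal(names(root_reach), c(ann$root, names(ann$terms)))
})

test_that("GMT and DAG files round-trip", {
  ids <- sprintf("tx%03d", 1:200)
  ann <- generate_go_annotation(go_config(n_terms = 10, term_size_range = c(5, 30),
                                          seed = 3), ids)
  gmt <- withr::local_tempfile(fileext = ".gmt")
  dagf <- withr::local_tempfile(fileext = ".tsv")
  write_gmt(ann, gmt)
  write_dag_edges(ann, dagf)
  back <- read_gmt(gmt, dag = read_dag_edges(dagf))
  expect_equal(back$terms, ann$terms)
  expect_equal(back$multiplicity[names(ann$multiplicity)], ann$multiplicity)
  expect_equal(back$dag, ann$dag)
})

test_that("impossible term sizes are rejected", {
  expect_error(generate_go_annotation(go_config(term_size_range = c(50, 60)),
                                      sprintf("t%d", 1:20)),
               "exceeds the number of transcripts")
})
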