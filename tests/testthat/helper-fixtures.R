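# Shared fixtures, all built in code at test time.

# a small two-type cohort with a strong planted tropism signature
small_cohort <- function(seed = 3, effect_size = 2, n_transcripts = 400,
                         samples_per_type = 60, positive_fraction = 0.3,
                         sites = c("Liver", "Lung"), ...) {
  generate_cohort(cohort_config(
    n_cancer_types = 2, samples_per_type = samples_per_type,
    n_transcripts = n_transcripts, sites = sites,
    tropism_signature_size = 10, effect_size = effect_size,
    positive_fraction = positive_fraction, synchronous_fraction = 0.05,
    type_signature_size = 20, seed = seed, ...))
}

# toy clinical table exercising messy strings, multi-site cells and
# synchronous rows
toy_clinical <- function() {
  data.frame(
    sample_id = sprintf("S%02d", 1:10),
    cancer_type = c(rep("BRCA", 6), rep("COAD", 2), rep("READ", 2)),
    "metastatic tissue" = c(" Lung ", "lung", "Liver; Lung", "BONE", "",
                            "Liver", "Liver", "", "liver", ""),
    progression_timing = c("", "", "", "", "", "synchronous",
                           "", "", "metachronous", ""),
    check.names = FALSE, stringsAsFactors = FALSE)
}

# deterministic separable binary data: two Gaussian clouds (imbalanced by
# default so SMOTE has work to do)
separable_binary <- function(n_per = 30, p = 8, shift = 3, seed = 11,
                             n0 = n_per * 2, n1 = n_per) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n0 * p), n0, p),
               matrix(rnorm(n1 * p, mean = shift), n1, p))
    rownames(X) <- sprintf("s%03d", seq_len(n0 + n1))
    colnames(X) <- sprintf("f%02d", seq_len(p))
    list(X = X, y = rep(c(0L, 1L), c(n0, n1)))
  })
}

# tiny hand-built GO annotation over named transcripts
tiny_annotation <- function() {
  terms <- list(
    "GO:0000001" = c("t1", "t2", "t3", "t4"),
    "GO:0000002" = c("t3", "t4", "t5", "t6"),
    "GO:0000003" = c("t7", "t8"))
  mult <- table(unlist(terms))
  structure(list(terms = terms,
                 multiplicity = stats::setNames(as.integer(mult), names(mult)),
                 dag = data.frame(child = names(terms),
                                  parent = "GO:0000000",
                                  stringsAsFactors = FALSE),
                 root = "GO:0000000", config = NULL),
            class = "go_annotation")
}

# exact hypergeometric upper tail by direct enumeration (independent oracle)
enum_upper_tail <- function(a, nA, nB, N) {
  ks <- max(a, 0):min(nA, nB)
  sum(choose(nA, ks) * choose(N - nA, nB - ks)) / choose(N, nB)
}
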