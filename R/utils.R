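# Internal helpers shared across modules.

# round-half-away-from-zero; base round() uses banker's rounding, which would
# make the 80%-of-majority target drift on .5 boundaries
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# per-column min-max scaling to [0, 1]; zero-range columns map to all zeros
minmax_scale <- function(X) {
  X <- as.matrix(X)
  lo <- apply(X, 2, min)
  hi <- apply(X, 2, max)
  span <- hi - lo
  Xs <- sweep(X, 2, lo, "-")
  Xs <- sweep(Xs, 2, ifelse(span == 0, 1, span), "/")
  if (any(span == 0)) Xs[, span == 0] <- 0
  Xs
}

# standardize columns; zero-variance columns become all zeros
standardize <- function(X) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  Xs <- sweep(X, 2, mu, "-")
  Xs <- sweep(Xs, 2, ifelse(sdv == 0, 1, sdv), "/")
  if (any(sdv == 0)) Xs[, sdv == 0] <- 0
  Xs
}

# coerce a binary label vector to 0/1 integer, preserving names
as_binary01 <- function(y) {
  nm <- names(y)
  if (is.factor(y)) y <- as.character(y)
  if (is.logical(y)) y <- as.integer(y)
  if (is.character(y)) {
    lv <- sort(unique(y))
    if (length(lv) > 2L) stop("labels must be binary")
    y <- as.integer(y == lv[length(lv)])
  }
  if (!all(y %in% c(0, 1))) {
    lv <- sort(unique(y))
    if (length(lv) > 2L) stop("labels must be binary")
    y <- as.integer(y == lv[length(lv)])
  }
  y <- as.integer(y)
  names(y) <- nm
  y
}

# md5 of an in-memory object via a canonical JSON serialization
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                           force = TRUE)), f)
  unname(tools::md5sum(f))
}
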