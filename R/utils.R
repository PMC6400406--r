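# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is restored afterwards. seed = NULL runs unseeded.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stopf("`%s` must be a single number in [%s, %s]", name,
          format(lower), format(upper))
  }
  invisible(x)
}

# Pairwise squared Euclidean distances between rows of a and rows of b.
cross_dist2 <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

# Indices of the k smallest entries per row of a distance matrix,
# optionally excluding the diagonal (self).
row_knn <- function(d, k, exclude_self = FALSE) {
  n <- nrow(d)
  t(vapply(seq_len(n), function(i) {
    v <- d[i, ]
    if (exclude_self) v[i] <- Inf
    order(v)[seq_len(k)]
  }, integer(k)))
}
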