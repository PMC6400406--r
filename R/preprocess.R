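#' k-nearest-neighbor smoothing of UMI counts
#'
#' Reduces technical noise by summing, for every cell, the raw expression
#' profiles of the cell and its `k` nearest neighbors — neighbors that
#' are transcriptionally similar and likely of the same type. Distances
#' are Euclidean in the first `n_pcs` principal components of
#' median-normalized, square-root-stabilized counts; a seeded uniform
#' jitter of total amplitude `dither` times each component's range is
#' added before the neighbor search (it never alters the summed
#' profiles). The summed matrix is rescaled by one global factor so its
#' grand total equals that of the input.
#'
#' @param counts A [count_matrix()] of raw UMIs.
#' @param k Number of neighbors to sum (default 10); `k = 0` returns the
#'   input unchanged.
#' @param n_pcs Number of principal components for the neighbor search
#'   (default 10).
#' @param dither Jitter amplitude as a fraction of each component's range
#'   (default 0.05).
#' @param seed Seed for the jitter.
#' @return A [count_matrix()] with `smoothed = TRUE` (entries are
#'   nonnegative reals after the global rescaling).
#' @export
knn_smooth <- function(counts, k = 10, n_pcs = 10, dither = 0.05,
                       seed = NULL) {
  stopifnot(inherits(counts, "CountMatrix"))
  n <- length(counts$cells)
  assert_scalar_number(k, "k", 0)
  if (k >= n) stopf("k (%d) must be smaller than the number of cells (%d)",
                    k, n)
  if (k == 0) return(counts)
  raw <- counts$counts
  totals <- Matrix::colSums(raw)
  med <- median(totals)
  fac <- ifelse(totals > 0, med / totals, 1)
  st <- sqrt(as.matrix(raw) %*% Matrix::Diagonal(x = fac))
  st <- as.matrix(st)
  emb <- run_pca(expression_matrix(st, genes = counts$genes,
                                   cells = counts$cells,
                                   transform_tag = "raw"),
                 n_components = min(n_pcs, n - 1L, nrow(st)))
  coords <- emb$coordinates
  if (dither > 0) {
    rng <- apply(coords, 2, function(v) diff(range(v)))
    coords <- with_seed(seed, {
      coords + matrix(runif(length(coords), -0.5, 0.5), nrow(coords)) *
        rep(dither * rng, each = nrow(coords))
    })
  }
  d <- as.matrix(dist(coords))
  nn <- row_knn(d, k, exclude_self = TRUE)
  s <- Matrix::sparseMatrix(
    i = c(seq_len(n), as.vector(t(nn))),
    j = c(seq_len(n), rep(seq_len(n), each = k)),
    x = 1, dims = c(n, n)
  )
  sm <- raw %*% s
  sm <- sm * (sum(totals) / sum(sm))
  count_matrix(sm, genes = counts$genes, cells = counts$cells,
               batch = counts$batch, smoothed = TRUE)
}

#' Library-size size factors
#'
#' @param counts A [count_matrix()].
#' @return Per-cell positive factors rescaled to mean 1.
#' @export
library_size_factors <- function(counts) {
  stopifnot(inherits(counts, "CountMatrix"))
  totals <- Matrix::colSums(counts$counts)
  if (any(totals <= 0)) stopf("cells with zero total count present")
  sf <- totals / mean(totals)
  names(sf) <- counts$cells
  class(sf) <- c("SizeFactors", class(sf))
  sf
}

#' Pool-and-deconvolve size factors
#'
#' Estimates per-cell size factors by summing cells into overlapping
#' pools, comparing each pooled profile with the average profile, and
#' deconvolving the resulting linear system — robust to the zero
#' inflation that defeats per-cell ratio estimators. Backed by
#' `scran::calculateSumFactors`. When there are fewer cells than the
#' smallest pool the system is under-determined and the estimator falls
#' back to library-size factors with a message.
#'
#' @param counts A [count_matrix()] of (possibly smoothed) counts.
#' @param pool_sizes Integer pool sizes (default `c(21, 41, 61)`),
#'   clipped to the number of cells.
#' @param min_mean Minimum gene abundance passed to the estimator.
#' @return Per-cell positive factors rescaled to mean 1 (class
#'   `SizeFactors`).
#' @export
estimate_size_factors <- function(counts, pool_sizes = c(21, 41, 61),
                                  min_mean = 0.1) {
  stopifnot(inherits(counts, "CountMatrix"))
  n <- length(counts$cells)
  if (n < 2L) stopf("need at least 2 cells")
  if (n < min(pool_sizes)) {
    message("fewer cells than the smallest pool; using library-size factors")
    return(library_size_factors(counts))
  }
  sizes <- sort(unique(pmin(as.integer(pool_sizes), n)))
  sf <- scran::calculateSumFactors(as.matrix(counts$counts), sizes = sizes,
                                   positive = FALSE, min.mean = min_mean)
  if (any(sf <= 0)) {
    stopf(paste("deconvolution produced non-positive size factors;",
                "consider library_size_factors()"))
  }
  sf <- sf / mean(sf)
  names(sf) <- counts$cells
  class(sf) <- c("SizeFactors", class(sf))
  sf
}

#' Size-factor normalization
#'
#' Divides each cell's counts by its size factor.
#'
#' @param counts A [count_matrix()].
#' @param sf Size factors from [estimate_size_factors()] or
#'   [library_size_factors()].
#' @return An [expression_matrix()] with `transform_tag = "normalized"`.
#' @export
normalize_counts <- function(counts, sf) {
  stopifnot(inherits(counts, "CountMatrix"))
  if (length(sf) != length(counts$cells)) {
    stopf("size factors do not match cells")
  }
  if (any(sf <= 0)) stopf("size factors must be positive")
  v <- as.matrix(counts$counts %*% Matrix::Diagonal(x = 1 / as.numeric(sf)))
  expression_matrix(v, genes = counts$genes, cells = counts$cells,
                    transform_tag = "normalized")
}

#' Freeman-Tukey variance-stabilizing transform
#'
#' Applies `FT(x) = sqrt(x) + sqrt(x + 1)` element-wise; for counts this
#' approximately stabilizes the variance, and `FT(0) = 1`.
#'
#' @param x An [expression_matrix()] (or nonnegative matrix).
#' @return An [expression_matrix()] with `transform_tag =
#'   "freeman_tukey"`.
#' @export
freeman_tukey <- function(x) {
  if (inherits(x, "CountMatrix")) {
    x <- expression_matrix(as.matrix(x$counts), genes = x$genes,
                           cells = x$cells, transform_tag = "raw")
  }
  if (!inherits(x, "ExpressionMatrix")) {
    x <- expression_matrix(as.matrix(x), transform_tag = "raw")
  }
  if (any(x$values < 0)) stopf("Freeman-Tukey requires nonnegative values")
  expression_matrix(sqrt(x$values) + sqrt(x$values + 1), genes = x$genes,
                    cells = x$cells, transform_tag = "freeman_tukey")
}

# Robust (iteratively bisquare-reweighted) fit of the technical-noise
# trend CV2(mu) = a + b/mu.
fit_cv2_trend <- function(mu, cv2, iterations = 20) {
  w <- rep(1, length(mu))
  x <- 1 / mu
  fit <- NULL
  for (it in seq_len(iterations)) {
    fit <- stats::lm.wfit(cbind(1, x), cv2, w)
    r <- cv2 - cbind(1, x) %*% fit$coefficients
    s <- stats::mad(r)
    if (s <= 0) break
    u <- abs(r / (6 * s))
    w <- as.numeric(ifelse(u < 1, (1 - u^2)^2, 0))
    if (all(w == 0)) { w <- rep(1, length(mu)); break }
  }
  as.numeric(cbind(1, x) %*% fit$coefficients)
}

#' Highly variable gene selection
#'
#' Ranks genes by the ratio of their squared coefficient of variation to
#' a robustly fitted technical trend `CV2(mu) = a + b/mu`, and selects
#' the top `fraction` of eligible genes. Genes on the exclusion lists
#' (typically stress markers and ribosomal genes) are never selected.
#'
#' @param x An [expression_matrix()] of normalized counts.
#' @param fraction Fraction of eligible genes to select (default 0.05).
#' @param exclude Character vector of gene symbols excluded from
#'   selection (case-insensitive).
#' @param min_mean Minimum mean expression for eligibility (default 0,
#'   i.e. no filter).
#' @return An `HVGResult` data frame: `gene`, `mean`, `cv2`, `trend`,
#'   `hvg_score`, `eligible`, `selected`.
#' @export
select_hvg <- function(x, fraction = 0.05, exclude = character(),
                       min_mean = 0) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (length(x$cells) < 2L) stopf("need at least 2 cells")
  assert_scalar_number(fraction, "fraction", 1e-12, 1)
  mu <- rowMeans(x$values)
  v <- apply(x$values, 1, var)
  cv2 <- ifelse(mu > 0, v / mu^2, NA_real_)
  pool <- mu > 0 & !(toupper(x$genes) %in% toupper(exclude))
  eligible <- pool & mu > min_mean
  trend <- rep(NA_real_, length(mu))
  fit_on <- which(mu > 0)
  trend[fit_on] <- fit_cv2_trend(mu[fit_on], cv2[fit_on])
  trend <- pmax(trend, 1e-8)
  score <- cv2 / trend
  n_req <- ceiling(fraction * sum(pool))
  if (n_req > sum(eligible)) {
    warnf("fewer eligible genes (%d) than the %d requested; returning all",
          sum(eligible), n_req)
    n_req <- sum(eligible)
  }
  selected <- rep(FALSE, length(mu))
  ord <- order(ifelse(eligible, score, -Inf), decreasing = TRUE)
  selected[ord[seq_len(n_req)]] <- TRUE
  out <- data.frame(gene = x$genes, mean = mu, cv2 = cv2, trend = trend,
                    hvg_score = score, eligible = eligible,
                    selected = selected, stringsAsFactors = FALSE)
  class(out) <- c("HVGResult", "data.frame")
  out
}

#' Principal component analysis of cells
#'
#' Centered PCA of cells over a gene subset, deterministic up to
#' machine precision: each loading vector's sign is fixed by making its
#' largest-magnitude entry positive.
#'
#' @param x An [expression_matrix()].
#' @param n_components Number of components (default
#'   `min(10, cells - 1, genes)`).
#' @param genes Optional gene subset (character vector); default all.
#' @return An [embedding_matrix()] of cell scores (`kind = "pca"`), with
#'   attributes `loadings`, `var_explained`, and `center`.
#' @export
run_pca <- function(x, n_components = NULL, genes = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (!is.null(genes)) {
    keep <- x$genes %in% genes
    if (!any(keep)) stopf("empty gene subset")
    vals <- x$values[keep, , drop = FALSE]
  } else {
    vals <- x$values
  }
  xm <- t(vals)                       # cells x genes
  ctr <- colMeans(xm)
  xc <- sweep(xm, 2, ctr)
  max_rank <- min(dim(xc))
  if (is.null(n_components)) n_components <- min(10L, nrow(xc) - 1L, ncol(xc))
  if (n_components > max_rank) {
    stopf("n_components (%d) exceeds min(genes, cells) = %d",
          n_components, max_rank)
  }
  sv <- svd(xc, nu = n_components, nv = n_components)
  flip <- vapply(seq_len(n_components), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(sv$u, 2, sv$d[seq_len(n_components)] * flip, "*")
  loadings <- sweep(sv$v, 2, flip, "*")
  rownames(scores) <- x$cells
  colnames(scores) <- paste0("PC", seq_len(n_components))
  emb <- embedding_matrix(scores, cells = x$cells, kind = "pca")
  attr(emb, "loadings") <- loadings
  attr(emb, "var_explained") <- sv$d^2 / sum(sv$d^2)
  attr(emb, "center") <- ctr
  emb
}
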