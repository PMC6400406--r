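# Small in-code fixtures shared across test files.

# A tiny deterministic count matrix with named genes/cells.
tiny_counts <- function() {
  m <- matrix(c(5L, 0L, 2L,
                0L, 3L, 1L,
                4L, 0L, 0L,
                1L, 2L, 6L), nrow = 4, byrow = TRUE)
  count_matrix(m, genes = c("A", "B", "C", "D"),
               cells = c("c1", "c2", "c3"))
}

# Well-separated Gaussian blob embedding with labels.
blob_embedding <- function(n_per = 50, centers = rbind(c(0, 0), c(8, 8)),
                           sd = 0.5, seed = 1, prefix = "c") {
  set.seed(seed)
  k <- nrow(centers)
  xm <- do.call(rbind, lapply(seq_len(k), function(i) {
    matrix(rnorm(n_per * 2, sd = sd), n_per, 2) +
      matrix(centers[i, ], n_per, 2, byrow = TRUE)
  }))
  cells <- paste0(prefix, seq_len(k * n_per))
  list(embedding = embedding_matrix(xm, cells = cells),
       labels = stats::setNames(rep(seq_len(k), each = n_per), cells))
}

# Brute-force threshold-sweep ROC area (trapezoidal), the independent
# oracle for the rank-formula AUROC.
sweep_auroc <- function(v, pos) {
  thr <- sort(unique(v))
  # classifier: "in COI" iff value > t; sweep t from above max to below min
  cuts <- c(max(v) + 1, thr - .Machine$double.eps^0.5, min(v) - 1)
  tpr <- vapply(cuts, function(t) mean(v[pos] > t), numeric(1))
  fpr <- vapply(cuts, function(t) mean(v[!pos] > t), numeric(1))
  ord <- order(fpr, tpr)
  fpr <- fpr[ord]; tpr <- tpr[ord]
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# Adjusted Rand index (independent of mclust, small-n safe).
ari <- function(a, b) {
  tab <- table(a, b)
  s <- function(x) sum(choose(x, 2))
  sij <- s(as.vector(tab)); si <- s(rowSums(tab)); sj <- s(colSums(tab))
  n2 <- choose(sum(tab), 2)
  exp_idx <- si * sj / n2
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}
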