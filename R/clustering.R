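#' Correlation distance between cells
#'
#' `d(i, j) = 1 - r(i, j)` where `r` is the Pearson correlation of the
#' two cells' expression profiles over a gene subset (typically the
#' highly variable genes).
#'
#' @param x An [expression_matrix()].
#' @param genes Optional gene subset; default all genes.
#' @return A symmetric cells x cells matrix with zero diagonal, entries
#'   in `[0, 2]`.
#' @export
correlation_distance <- function(x, genes = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  vals <- if (is.null(genes)) x$values else {
    keep <- x$genes %in% genes
    if (sum(keep) < 2L) stopf("need at least 2 genes")
    x$values[keep, , drop = FALSE]
  }
  sds <- apply(vals, 2, sd)
  if (any(sds == 0)) {
    stopf("zero-variance cell(s): %s",
          paste(head(x$cells[sds == 0], 3), collapse = ", "))
  }
  d <- 1 - cor(vals)
  d[d < 0] <- 0
  diag(d) <- 0
  dimnames(d) <- list(x$cells, x$cells)
  d
}

#' Ward hierarchical clustering
#'
#' Agglomerative clustering with Ward's minimum-variance linkage
#' (Lance-Williams update on squared dissimilarities, `hclust` method
#' `"ward.D2"`) on a precomputed distance matrix.
#'
#' @param d A symmetric distance matrix (e.g. from
#'   [correlation_distance()]) or a `dist` object.
#' @param method `hclust` linkage (default `"ward.D2"`).
#' @return An `hclust` dendrogram.
#' @export
ward_cluster <- function(d, method = "ward.D2") {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (!isSymmetric(unname(d), tol = 1e-8)) {
      stopf("distance matrix must be symmetric")
    }
    d <- as.dist(d)
  }
  hclust(d, method = method)
}

#' Cut a dendrogram into clusters
#'
#' Cuts either at a height or into a requested number of clusters;
#' exactly one criterion must be given. Labels are renumbered by cluster
#' size, largest first.
#'
#' @param dend An `hclust` object from [ward_cluster()].
#' @param height Cut height (all merges above it are undone).
#' @param n_clusters Desired number of clusters.
#' @return A `ClusterAssignment`: list with `labels` (named integer
#'   vector), `dendrogram`, `n_clusters`, and `merge_map` (identity at
#'   this stage).
#' @export
cut_dendrogram <- function(dend, height = NULL, n_clusters = NULL) {
  stopifnot(inherits(dend, "hclust"))
  if (is.null(height) == is.null(n_clusters)) {
    stopf("give exactly one of `height` or `n_clusters`")
  }
  raw <- if (!is.null(height)) cutree(dend, h = height) else
    cutree(dend, k = n_clusters)
  sizes <- sort(table(raw), decreasing = TRUE)
  remap <- stats::setNames(seq_along(sizes), names(sizes))
  labels <- unname(remap[as.character(raw)])
  names(labels) <- dend$labels %||% names(raw) %||% seq_along(raw)
  structure(
    list(labels = labels, dendrogram = dend,
         n_clusters = length(sizes),
         merge_map = stats::setNames(as.character(seq_along(sizes)),
                                     seq_along(sizes))),
    class = "ClusterAssignment"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ClusterAssignment <- function(x, ...) {
  cat(sprintf("ClusterAssignment: %d cells in %d clusters\n",
              length(x$labels), x$n_clusters))
  print(table(x$labels))
  invisible(x)
}

#' Per-cluster expression profiles
#'
#' Averages (typically Freeman-Tukey transformed) expression over all
#' cells of each cluster and Z-standardizes each gene across clusters.
#' Genes with zero standard deviation across clusters get an all-zero
#' standardized row and are flagged.
#'
#' @param x An [expression_matrix()].
#' @param assign A `ClusterAssignment` (or a label vector matching the
#'   cells).
#' @param genes Optional gene subset.
#' @return A `ClusterProfile`: list with `means` (clusters x genes),
#'   `z` (standardized), `constant_genes` (flag vector).
#' @export
cluster_profile <- function(x, assign, genes = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  labels <- cluster_labels(assign, x$cells)
  vals <- if (is.null(genes)) x$values else {
    keep <- x$genes %in% genes
    if (!any(keep)) stopf("empty gene subset")
    x$values[keep, , drop = FALSE]
  }
  lev <- sort(unique(labels))
  if (any(table(labels) == 0)) stopf("empty cluster")
  means <- matrix(0, length(lev), nrow(vals),
                  dimnames = list(as.character(lev), rownames(vals)))
  for (i in seq_along(lev)) {
    means[i, ] <- rowMeans(vals[, labels == lev[i], drop = FALSE])
  }
  gsd <- apply(means, 2, sd)
  constant <- is.na(gsd) | gsd == 0
  z <- means
  if (length(lev) > 1L) {
    z <- scale(means)
    z[, constant] <- 0
  } else {
    z[] <- 0
    constant[] <- TRUE
  }
  structure(list(means = means, z = z, constant_genes = constant),
            class = "ClusterProfile")
}

# Resolve a ClusterAssignment or plain vector to labels ordered by cells.
cluster_labels <- function(assign, cells) {
  labels <- if (inherits(assign, "ClusterAssignment")) assign$labels else
    assign
  if (!is.null(names(labels)) && all(cells %in% names(labels))) {
    labels <- labels[cells]
  } else if (length(labels) != length(cells)) {
    stopf("cluster labels do not cover all cells")
  }
  unname(labels)
}

#' Merge clusters
#'
#' Applies an explicit merge map (a named vector `old label -> new
#' label`), or, in auto mode, iteratively merges the pair of clusters
#' whose mean literature-marker profiles have the highest Pearson
#' correlation above `auto_threshold` — a reproducible surrogate for the
#' manual marker-similarity merging of over-cut dendrograms.
#'
#' @param assign A `ClusterAssignment`.
#' @param profiles A `ClusterProfile` computed on literature-marker genes
#'   (required for auto mode) or the [expression_matrix()] to compute it
#'   from.
#' @param merge_map Named character vector mapping original labels to
#'   merged labels; labels absent from the map are kept.
#' @param auto_threshold Correlation threshold for auto mode.
#' @param genes Gene subset used when `profiles` is an expression matrix.
#' @return A new `ClusterAssignment` with updated `labels`, `merge_map`,
#'   and merge history.
#' @export
merge_clusters <- function(assign, profiles = NULL, merge_map = NULL,
                           auto_threshold = NULL, genes = NULL) {
  stopifnot(inherits(assign, "ClusterAssignment"))
  if (is.null(merge_map) == is.null(auto_threshold)) {
    stopf("give exactly one of `merge_map` or `auto_threshold`")
  }
  labels <- assign$labels
  history <- list()
  if (!is.null(merge_map)) {
    unknown <- setdiff(names(merge_map), as.character(unique(labels)))
    if (length(unknown)) {
      stopf("merge_map references unknown labels: %s",
            paste(unknown, collapse = ", "))
    }
    new <- as.character(labels)
    hit <- new %in% names(merge_map)
    new[hit] <- merge_map[new[hit]]
    full_map <- stats::setNames(as.character(unique(labels)),
                                unique(labels))
    full_map[names(merge_map)] <- merge_map
    out_labels <- stats::setNames(new, names(labels))
    history <- list(merge_map)
  } else {
    if (inherits(profiles, "ExpressionMatrix")) {
      profiles <- cluster_profile(profiles, assign, genes = genes)
    }
    if (!inherits(profiles, "ClusterProfile")) {
      stopf("auto mode needs cluster profiles")
    }
    means <- profiles$means
    cur <- stats::setNames(rownames(means), rownames(means))
    repeat {
      if (nrow(means) < 2L) break
      rmat <- cor(t(means))
      diag(rmat) <- -Inf
      best <- which(rmat == max(rmat), arr.ind = TRUE)[1, ]
      if (rmat[best[1], best[2]] <= auto_threshold) break
      a <- rownames(means)[best[1]]; b <- rownames(means)[best[2]]
      history[[length(history) + 1L]] <-
        c(from = b, to = a, r = rmat[best[1], best[2]])
      na <- sum(cur == a); nb <- sum(cur == b)
      # size-weighted profile of the merged cluster
      sizes <- table(labels)
      wa <- sizes[names(cur)[cur == a]]; wb <- sizes[names(cur)[cur == b]]
      means[best[1], ] <- (sum(wa) * means[best[1], ] +
                             sum(wb) * means[best[2], ]) / (sum(wa) + sum(wb))
      means <- means[-best[2], , drop = FALSE]
      cur[cur == b] <- a
    }
    out_labels <- stats::setNames(unname(cur[as.character(labels)]),
                                  names(labels))
    full_map <- cur
  }
  structure(
    list(labels = out_labels, dendrogram = assign$dendrogram,
         n_clusters = length(unique(out_labels)),
         merge_map = full_map, history = history),
    class = "ClusterAssignment"
  )
}
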