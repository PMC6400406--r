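#' Mutual-nearest-neighbor batch correction
#'
#' A pair-and-shift correction in a common principal-component basis:
#' batches are merged in order of decreasing size; for each query batch,
#' mutual k-nearest-neighbor pairs against the growing reference are
#' found (Euclidean distance), each pair contributes a correction vector
#' (reference minus query), and every query cell is shifted by a
#' Gaussian-kernel-weighted average of pair corrections (bandwidth
#' `sigma` in query space). Reference-batch coordinates are never
#' changed. This is a deliberately simplified scheme sharing the mutual
#' -pair contract of the full published MNN algorithm (which additionally
#' cosine-normalizes and adjusts variance along the batch vector).
#'
#' The correction is estimated in two stages. First, the constant
#' component of the batch effect — a translation, the dominant term of a
#' batch offset — is estimated as the mean of all pair difference
#' vectors and the pair-and-shift update is iterated until it stalls
#' (with a large offset, mutual pairs form preferentially between the
#' facing edges of the clouds and a single pass under-corrects).
#' Second, one local pass shifts each query cell by a Gaussian-kernel-
#' weighted average of pair corrections (bandwidth `sigma` in query
#' space), capturing position-dependent offsets.
#'
#' @param batches List of [embedding_matrix()] objects in a common PC
#'   basis (computed on the pooled data).
#' @param k Neighbors per side for the mutual-pair search (default 20).
#' @param sigma Kernel bandwidth of the local pass; default 0.1 times the
#'   RMS pairwise distance within the reference batch.
#' @param max_iter Maximum global pair-and-shift iterations per query
#'   batch (default 20); iteration stops when the shift falls below 1e-3
#'   of the first shift.
#' @return A `CorrectedSpace`: list with `coordinates` (all cells,
#'   corrected), `cells`, `batch`, and `mnn_pairs` (data frame of
#'   reference/query cell names, from the final pair search).
#' @export
mnn_correct <- function(batches, k = 20, sigma = NULL, max_iter = 20) {
  stopifnot(is.list(batches), length(batches) >= 1L)
  for (b in batches) stopifnot(inherits(b, "EmbeddingMatrix"))
  if (is.null(names(batches))) {
    names(batches) <- paste0("batch", seq_along(batches))
  }
  ord <- order(vapply(batches, function(b) nrow(b$coordinates), numeric(1)),
               decreasing = TRUE)
  batches <- batches[ord]
  ref <- batches[[1]]$coordinates
  ref_cells <- batches[[1]]$cells
  batch_lab <- rep(names(batches)[1], nrow(ref))
  pairs <- list()
  if (is.null(sigma)) {
    n <- nrow(ref)
    sub <- if (n > 500) sample(n, 500) else seq_len(n)
    sigma <- 0.1 * sqrt(mean(dist(ref[sub, , drop = FALSE])^2))
  }
  find_pairs <- function(ref, corrected) {
    d2 <- cross_dist2(ref, corrected)        # ref x query
    kr <- min(k, ncol(d2))                   # query neighbors of a ref cell
    kq <- min(k, nrow(d2))                   # ref neighbors of a query cell
    nn_of_ref <- row_knn(d2, kr)             # ref -> query indices
    nn_of_qry <- row_knn(t(d2), kq)          # query -> ref indices
    in_ref_nn <- matrix(FALSE, nrow(d2), ncol(d2))
    in_ref_nn[cbind(rep(seq_len(nrow(d2)), each = kr),
                    as.vector(t(nn_of_ref)))] <- TRUE
    pr <- do.call(rbind, lapply(seq_len(ncol(d2)), function(j) {
      ri <- nn_of_qry[j, in_ref_nn[nn_of_qry[j, ], j]]
      if (length(ri)) cbind(ref = ri, query = j) else NULL
    }))
    if (is.null(pr) || nrow(pr) == 0L) {
      stopf("no mutual nearest-neighbor pairs found; try a larger k")
    }
    pr
  }
  for (bi in seq_along(batches)[-1]) {
    qry <- batches[[bi]]$coordinates
    corrected <- qry
    first_shift <- NULL
    # stage 1: iterated global translation from the pair means
    for (it in seq_len(max_iter)) {
      pr <- find_pairs(ref, corrected)
      gshift <- colMeans(ref[pr[, "ref"], , drop = FALSE] -
                           corrected[pr[, "query"], , drop = FALSE])
      corrected <- sweep(corrected, 2, gshift, "+")
      ms <- sqrt(sum(gshift^2))
      if (is.null(first_shift)) first_shift <- ms
      if (ms <= 1e-3 * first_shift) break
    }
    # stage 2: one local kernel-weighted pass. Weights are measured to
    # the pair midpoint: the mutual-pair relation is symmetric between
    # two identical clouds, so opposite pair vectors share a midpoint and
    # cancel exactly -- identical batches are not moved at all.
    pr <- find_pairs(ref, corrected)
    corr_vec <- ref[pr[, "ref"], , drop = FALSE] -
      corrected[pr[, "query"], , drop = FALSE]
    mid <- (ref[pr[, "ref"], , drop = FALSE] +
              corrected[pr[, "query"], , drop = FALSE]) / 2
    dq2 <- cross_dist2(corrected, mid)
    w <- exp(-dq2 / (2 * sigma^2))
    wsum <- rowSums(w)
    # cells with negligible kernel mass fall back to the nearest pair
    far <- wsum < 1e-12
    if (any(far)) {
      nearest <- apply(dq2[far, , drop = FALSE], 1, which.min)
      w[far, ] <- 0
      w[cbind(which(far), nearest)] <- 1
      wsum <- rowSums(w)
    }
    corrected <- corrected + (w %*% corr_vec) / wsum
    # report the mutual pairs of the final corrected geometry
    pr <- find_pairs(ref, corrected)
    pairs[[length(pairs) + 1L]] <- data.frame(
      reference = ref_cells[pr[, "ref"]],
      query = batches[[bi]]$cells[pr[, "query"]],
      query_batch = names(batches)[bi], stringsAsFactors = FALSE)
    ref <- rbind(ref, corrected)
    ref_cells <- c(ref_cells, batches[[bi]]$cells)
    batch_lab <- c(batch_lab, rep(names(batches)[bi], nrow(qry)))
  }
  structure(list(cells = ref_cells, coordinates = ref, batch = batch_lab,
                 mnn_pairs = if (length(pairs)) do.call(rbind, pairs) else
                   NULL,
                 sigma = sigma),
            class = "CorrectedSpace")
}

#' k-nearest-neighbor cell-type transfer
#'
#' Assigns each query cell the most common type among its `k` nearest
#' labeled reference cells in (batch-corrected) embedding space; ties
#' are broken by the smallest mean distance among the tied classes.
#'
#' @param space A `CorrectedSpace` from [mnn_correct()] or an
#'   [embedding_matrix()] holding reference and query cells.
#' @param reference_labels Named vector of types for the reference cells.
#' @param query_cells Cells to classify; default: all cells without a
#'   reference label.
#' @param k Number of neighbors (default 20).
#' @return Named character vector of transferred labels.
#' @export
knn_classify <- function(space, reference_labels, query_cells = NULL,
                         k = 20) {
  coords <- if (inherits(space, "CorrectedSpace")) space$coordinates else
    space$coordinates
  cells <- if (inherits(space, "CorrectedSpace")) space$cells else
    space$cells
  rownames(coords) <- cells
  ref_cells <- intersect(cells, names(reference_labels))
  if (length(ref_cells) == 0L) stopf("no labeled reference cells in space")
  if (k > length(ref_cells)) {
    stopf("k (%d) exceeds the number of reference cells (%d)", k,
          length(ref_cells))
  }
  if (is.null(query_cells)) query_cells <- setdiff(cells, ref_cells)
  d2 <- cross_dist2(coords[query_cells, , drop = FALSE],
                    coords[ref_cells, , drop = FALSE])
  lab <- as.character(reference_labels[ref_cells])
  out <- vapply(seq_along(query_cells), function(i) {
    nn <- order(d2[i, ])[seq_len(k)]
    votes <- table(lab[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1L) return(top)
    md <- vapply(top, function(cl) mean(d2[i, nn[lab[nn] == cl]]),
                 numeric(1))
    top[which.min(md)]
  }, character(1))
  stats::setNames(out, query_cells)
}

#' Negative binomial differential expression with a detection-rate
#' covariate
#'
#' Models raw counts per gene with a negative binomial generalized
#' linear model whose design contains the group factor and the centered
#' cellular detection rate (each cell's fraction of detected genes) —
#' absorbing the depth-driven component of single-cell expression
#' differences. Backed by edgeR: TMM normalization, trended dispersion
#' estimation, and either the likelihood-ratio test (default) or the
#' quasi-likelihood F-test. For more than two groups every pairwise
#' contrast is tested. P-values are Benjamini-Hochberg adjusted within
#' each contrast.
#'
#' @param counts A [count_matrix()] of raw (unsmoothed) counts or a
#'   numeric matrix.
#' @param groups Factor/vector of group labels, one per cell.
#' @param detection_covariate Include the cellular detection rate
#'   (default `TRUE`).
#' @param test `"lrt"` (likelihood-ratio test, default) or `"qlf"`
#'   (quasi-likelihood F-test).
#' @return A `DEResult`: list with `table` (long data frame: `contrast`,
#'   `gene`, `l2fc`, `p`, `fdr`), `detection` (per-gene detection rate
#'   per group), and `skipped` (all-zero genes).
#' @export
differential_expression <- function(counts, groups,
                                    detection_covariate = TRUE,
                                    test = c("lrt", "qlf")) {
  test <- match.arg(test)
  m <- if (inherits(counts, "CountMatrix")) as.matrix(counts$counts) else
    as.matrix(counts)
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stopf("need at least 2 groups")
  if (any(table(groups) < 2L)) stopf("every group needs at least 2 cells")
  nonzero <- rowSums(m) > 0
  skipped <- rownames(m)[!nonzero]
  m <- m[nonzero, , drop = FALSE]
  cdr <- scale(colMeans(m > 0))
  y <- edgeR::DGEList(counts = m, group = groups)
  y <- edgeR::calcNormFactors(y)
  design <- if (detection_covariate) {
    model.matrix(~ cdr + groups)
  } else {
    model.matrix(~groups)
  }
  y <- edgeR::estimateDisp(y, design)
  lev <- levels(groups)
  contrasts <- utils::combn(lev, 2, simplify = FALSE)
  fit <- if (test == "qlf") edgeR::glmQLFit(y, design) else
    edgeR::glmFit(y, design)
  run_contrast <- function(a, b) {
    # coefficient of b relative to a; with >2 levels use a contrast vector
    cvec <- rep(0, ncol(design))
    names(cvec) <- colnames(design)
    ca <- paste0("groups", a); cb <- paste0("groups", b)
    if (cb %in% names(cvec)) cvec[cb] <- 1
    if (ca %in% names(cvec)) cvec[ca] <- -1
    res <- if (test == "qlf") edgeR::glmQLFTest(fit, contrast = cvec) else
      edgeR::glmLRT(fit, contrast = cvec)
    tt <- edgeR::topTags(res, n = Inf, sort.by = "none")$table
    data.frame(contrast = paste(b, "vs", a), gene = rownames(tt),
               l2fc = tt$logFC, p = tt$PValue, fdr = tt$FDR,
               stringsAsFactors = FALSE, row.names = NULL)
  }
  tab <- do.call(rbind, lapply(contrasts, function(pr) {
    run_contrast(pr[1], pr[2])
  }))
  detection <- vapply(lev, function(g) {
    rowMeans(m[, groups == g, drop = FALSE] > 0)
  }, numeric(nrow(m)))
  structure(list(table = tab, detection = detection, skipped = skipped,
                 test = test),
            class = "DEResult")
}

#' Filter differential-expression results by fold change and FDR
#'
#' Returns the genes with `|L2FC| > log2(min_fold)` (strict) and
#' `FDR < max_fdr` (strict) in **any** contrast.
#'
#' @param de A `DEResult` from [differential_expression()].
#' @param min_fold Minimum fold change (default 2).
#' @param max_fdr FDR ceiling (default 0.05).
#' @return Character vector of gene symbols.
#' @export
fold_change_filter <- function(de, min_fold = 2, max_fdr = 0.05) {
  stopifnot(inherits(de, "DEResult"))
  tab <- de$table
  if (is.null(tab) || nrow(tab) == 0L) return(character(0))
  hit <- abs(tab$l2fc) > log2(min_fold) & tab$fdr < max_fdr
  sort(unique(tab$gene[hit]))
}
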