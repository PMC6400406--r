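#' Single-gene AUROC for cluster membership
#'
#' For a gene, the cluster of interest (COI) is the cluster with the
#' highest mean expression. A binary expression-threshold classifier for
#' COI membership, swept over all thresholds, traces an ROC curve; its
#' area is computed here by the rank (Mann-Whitney) formula with
#' midranks for ties, which is identical to the threshold sweep.
#'
#' @param x An [expression_matrix()] (Freeman-Tukey transformed in the
#'   standard workflow; AUROC is invariant to monotone transforms).
#' @param assign A `ClusterAssignment` or label vector.
#' @param gene Gene symbol.
#' @return A list with `coi` and `auroc`.
#' @export
gene_auroc <- function(x, assign, gene) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  labels <- cluster_labels(assign, x$cells)
  if (length(unique(labels)) < 2L) stopf("need at least 2 clusters")
  i <- match(gene, x$genes)
  if (is.na(i)) stopf("gene '%s' not in matrix", gene)
  v <- x$values[i, ]
  mns <- tapply(v, labels, mean)
  coi <- names(mns)[which.max(mns)]
  list(coi = coi, auroc = rank_auroc(v, labels == coi))
}

# AUROC by the rank formula with midranks; `pos` is the logical COI mask.
rank_auroc <- function(v, pos) {
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stopf("both classes must be non-empty")
  r <- rank(v)                      # midranks
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Four-criterion AUROC marker selection
#'
#' A gene is a marker candidate for its cluster of interest (COI) iff
#' (1) its AUROC exceeds `auroc_min`, (2) it is detected in at least
#' `detect_min` of COI cells, (3) its mean expression in the COI is at
#' least `mean_min`, and (4) at most `outside_max` of the cells outside
#' the COI (pooled) express it above the COI's 25th expression
#' percentile. Per cluster, candidates are ranked by AUROC (ties broken
#' by detection fraction, COI mean, then gene name) and the top `top_k`
#' are selected.
#'
#' @param x An [expression_matrix()], Freeman-Tukey transformed. With
#'   this transform a zero count maps to 1, so detection defaults to
#'   `value > 1`; for other tags detection is `value > 0`.
#' @param assign Final (merged) cluster labels.
#' @param auroc_min AUROC threshold, strict (default 0.8).
#' @param detect_min COI detection fraction, non-strict (default 0.80).
#' @param mean_min COI mean expression, non-strict (default 1.5).
#' @param outside_max Maximum pooled fraction of non-COI cells with
#'   expression strictly above the COI 25th percentile, non-strict
#'   (default 0.25).
#' @param top_k Markers retained per cluster (default 4).
#' @return A `MarkerRecord` data frame with one row per gene: `gene`,
#'   `coi`, `auroc`, `detect_frac_coi`, `mean_coi`, `sig_frac_outside`,
#'   the four `pass_*` flags, `candidate`, `selected`, `rank_in_coi`.
#' @export
select_markers <- function(x, assign, auroc_min = 0.8, detect_min = 0.80,
                           mean_min = 1.5, outside_max = 0.25, top_k = 4) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  labels <- cluster_labels(assign, x$cells)
  if (length(unique(labels)) < 2L) stopf("need at least 2 clusters")
  lev <- sort(unique(labels))
  detect_floor <- if (x$transform_tag == "freeman_tukey") 1 else 0
  vals <- x$values
  # cluster means for every gene at once
  cm <- vapply(lev, function(k) rowMeans(vals[, labels == k, drop = FALSE]),
               numeric(nrow(vals)))
  coi_idx <- max.col(cm, ties.method = "first")
  coi <- as.character(lev[coi_idx])
  n_genes <- nrow(vals)
  auroc <- numeric(n_genes)
  detect_frac <- numeric(n_genes)
  q25 <- numeric(n_genes)
  sig_out <- numeric(n_genes)
  for (g in seq_len(n_genes)) {
    inc <- labels == lev[coi_idx[g]]
    v <- vals[g, ]
    auroc[g] <- rank_auroc(v, inc)
    detect_frac[g] <- mean(v[inc] > detect_floor)
    q25[g] <- quantile(v[inc], 0.25, names = FALSE)
    sig_out[g] <- mean(v[!inc] > q25[g])
  }
  mean_coi <- cm[cbind(seq_len(n_genes), coi_idx)]
  pass1 <- auroc > auroc_min
  pass2 <- detect_frac >= detect_min
  pass3 <- mean_coi >= mean_min
  pass4 <- sig_out <= outside_max
  candidate <- pass1 & pass2 & pass3 & pass4
  rec <- data.frame(
    gene = x$genes, coi = coi, auroc = auroc,
    detect_frac_coi = detect_frac, mean_coi = mean_coi,
    coi_q25 = q25, sig_frac_outside = sig_out,
    pass_auroc = pass1, pass_detection = pass2, pass_mean = pass3,
    pass_outside = pass4, candidate = candidate,
    selected = FALSE, rank_in_coi = NA_integer_,
    stringsAsFactors = FALSE
  )
  for (k in lev) {
    idx <- which(rec$candidate & rec$coi == as.character(k))
    if (length(idx) == 0L) next
    ord <- idx[order(-rec$auroc[idx], -rec$detect_frac_coi[idx],
                     -rec$mean_coi[idx], rec$gene[idx])]
    rec$rank_in_coi[ord] <- seq_along(ord)
    rec$selected[ord[seq_len(min(top_k, length(ord)))]] <- TRUE
  }
  class(rec) <- c("MarkerRecord", "data.frame")
  rec
}

#' Per-cluster proliferation score
#'
#' For each proliferation marker, cluster means are Z-standardized
#' across clusters; the score of a cluster is the mean of those Z values
#' over the marker list. Constant genes contribute 0.
#'
#' @param x An [expression_matrix()].
#' @param assign Cluster labels.
#' @param markers Character vector of proliferation marker symbols
#'   (default: the built-in list).
#' @return Named numeric vector of per-cluster scores.
#' @export
proliferation_score <- function(x, assign,
                                markers = gene_list(default_gene_lists(),
                                                    "proliferation_markers")) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  present <- match_gene_list(x$genes, markers, "proliferation markers")
  if (length(present) == 0L) stopf("no proliferation marker genes found")
  prof <- cluster_profile(x, assign, genes = present)
  colMeans(t(prof$z))
}

#' Train a LASSO multinomial cell-type classifier
#'
#' Fits an L1-penalized multinomial logistic regression of cell type on
#' the most highly variable genes; the shrinkage parameter is chosen by
#' cross-validated deviance. Genes with any nonzero weight form the
#' classifier gene set.
#'
#' @param x An [expression_matrix()] of training cells.
#' @param labels Cell-type labels (one per training cell).
#' @param n_hvg Number of most variable genes used (default 500); if
#'   `genes` is given it is used verbatim instead.
#' @param genes Optional explicit training gene set.
#' @param folds Cross-validation folds (default 20); reduced with a
#'   warning when the smallest class is smaller.
#' @param exclude Genes never used (e.g. stress and ribosomal lists).
#' @param seed Seed for the fold assignment.
#' @return A `ClassifierModel`: list with the `glmnet` fit, chosen
#'   `lambda`, `classifier_genes`, and `classes`.
#' @export
train_id_classifier <- function(x, labels, n_hvg = 500, genes = NULL,
                                folds = 20, exclude = character(),
                                seed = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  labels <- as.character(cluster_labels(labels, x$cells))
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stopf("need at least 2 classes")
  min_class <- min(table(labels))
  if (folds > min_class) {
    warnf("reducing folds from %d to smallest class size %d", folds,
          min_class)
    folds <- max(3L, min_class)
  }
  if (is.null(genes)) {
    hvg <- select_hvg(x, fraction = 1, exclude = exclude)
    ord <- order(hvg$hvg_score, decreasing = TRUE)
    ord <- ord[hvg$eligible[ord]]
    genes <- hvg$gene[head(ord, n_hvg)]
  }
  keep <- x$genes %in% genes
  xm <- t(x$values[keep, , drop = FALSE])
  cv <- with_seed(seed, {
    glmnet::cv.glmnet(xm, factor(labels, levels = classes),
                      family = "multinomial", alpha = 1, nfolds = folds,
                      type.measure = "deviance")
  })
  cf <- coef(cv, s = "lambda.min")
  nz <- unique(unlist(lapply(cf, function(b) {
    rn <- rownames(b)[which(as.matrix(b) != 0)]
    setdiff(rn, "(Intercept)")
  })))
  structure(list(fit = cv, lambda = cv$lambda.min,
                 genes = colnames(xm), classifier_genes = nz,
                 classes = classes, folds = folds),
            class = "ClassifierModel")
}

#' Predict cell-type identity scores
#'
#' Applies a trained classifier; each cell is assigned to the type with
#' the highest class probability (its identity score).
#'
#' @param model A `ClassifierModel` from [train_id_classifier()].
#' @param x An [expression_matrix()] of test cells. Model genes missing
#'   from the matrix are imputed as 0 with a warning.
#' @return An `IdScoreResult` data frame: `cell`, `assigned_type`,
#'   `id_score`, plus one probability column per class; probabilities
#'   sum to 1 per cell.
#' @export
predict_id_scores <- function(model, x) {
  stopifnot(inherits(model, "ClassifierModel"),
            inherits(x, "ExpressionMatrix"))
  idx <- match(model$genes, x$genes)
  if (anyNA(idx)) {
    warnf("%d model genes missing from test matrix; imputed as 0",
          sum(is.na(idx)))
  }
  xm <- matrix(0, nrow = length(x$cells), ncol = length(model$genes),
               dimnames = list(x$cells, model$genes))
  ok <- !is.na(idx)
  xm[, ok] <- t(x$values[idx[ok], , drop = FALSE])
  p <- predict(model$fit, newx = xm, s = "lambda.min", type = "response")
  p <- p[, , 1]
  if (is.null(dim(p))) p <- matrix(p, nrow = 1, dimnames = list(
    x$cells, model$classes))
  assigned <- colnames(p)[max.col(p, ties.method = "first")]
  out <- data.frame(cell = x$cells, assigned_type = assigned,
                    id_score = apply(p, 1, max), p,
                    check.names = FALSE, stringsAsFactors = FALSE)
  class(out) <- c("IdScoreResult", "data.frame")
  out
}
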