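make_expr <- function(values, labels) {
  x <- expression_matrix(values, transform_tag = "freeman_tukey")
  list(x = x, labels = stats::setNames(labels, colnames(values)))
}

test_that("AUROC identities: perfect separation and all-ties", {
  vals <- rbind(perfect = c(5, 6, 7, 1, 1, 1) + 1,
                flat = rep(2, 6))
  colnames(vals) <- paste0("c", 1:6)
  f <- make_expr(vals, rep(c("A", "B"), each = 3))
  expect_equal(gene_auroc(f$x, f$labels, "perfect")$auroc, 1)
  expect_equal(gene_auroc(f$x, f$labels, "perfect")$coi, "A")
  expect_equal(gene_auroc(f$x, f$labels, "flat")$auroc, 0.5)
})

test_that("rank-formula AUROC equals the threshold-sweep oracle", {
  vals <- rbind(toy = c(3, 5, 4, 1, 2, 3))
  colnames(vals) <- paste0("c", 1:6)
  f <- make_expr(vals, rep(c("A", "B"), each = 3))
  got <- gene_auroc(f$x, f$labels, "toy")$auroc
  expect_equal(got, sweep_auroc(c(3, 5, 4, 1, 2, 3),
                                rep(c(TRUE, FALSE), each = 3)))
  # random small instances with heavy ties
  set.seed(41)
  for (i in 1:50) {
    n <- sample(6:30, 1)
    v <- sample(0:5, n, replace = TRUE)
    pos <- rep(FALSE, n)
    pos[sample(n, sample(2:(n - 2), 1))] <- TRUE
    a1 <- (sum(rank(v)[pos]) - sum(pos) * (sum(pos) + 1) / 2) /
      (sum(pos) * sum(!pos))
    expect_equal(a1, sweep_auroc(v, pos), tolerance = 1e-12)
  }
})

test_that("the four selection criteria use the stated strictness", {
  # gene at AUROC exactly 0.8: 4+1 vs 5 design -> not a candidate
  set.seed(42)
  n <- 40
  labels <- rep(c("A", "B"), each = n / 2)
  vals <- matrix(2, 2, n, dimnames = list(c("edge", "good"),
                                          paste0("c", 1:n)))
  # construct 'edge' with AUROC exactly 0.8: 12 clean wins and 8 full
  # ties against 20 opposite cells gives (12*20 + 8*20/2) / 400 = 0.8
  vals["edge", ] <- c(rep(3, 12), rep(1, 8), rep(1, 20))
  pos <- labels == "A"
  a <- (sum(rank(vals["edge", ])[pos]) - 20 * 21 / 2) / 400
  stopifnot(abs(a - 0.8) < 1e-12)    # construction check, not the test
  vals["good", ] <- c(rnorm(20, 10, 0.5), rnorm(20, 2, 0.5))
  f <- make_expr(vals, labels)
  rec <- select_markers(f$x, f$labels, mean_min = 1.5)
  expect_false(rec$candidate[rec$gene == "edge"])
  expect_false(rec$pass_auroc[rec$gene == "edge"])
  expect_true(rec$selected[rec$gene == "good"])
})

test_that("at most top_k candidates are selected, ranked by AUROC", {
  set.seed(43)
  n <- 60
  labels <- rep(c("A", "B"), each = n / 2)
  sep <- c(9, 8.5, 8, 7.5, 7, 6.5)   # six clean candidates for cluster A
  vals <- t(vapply(sep, function(s) {
    c(rnorm(30, s, 0.3), rnorm(30, 1.2, 0.3))
  }, numeric(n)))
  vals <- pmax(vals, 1.01)
  dimnames(vals) <- list(paste0("m", 1:6), paste0("c", 1:n))
  f <- make_expr(vals, labels)
  rec <- select_markers(f$x, f$labels, top_k = 4)
  cand_a <- rec[rec$candidate & rec$coi == "A", ]
  expect_gte(nrow(cand_a), 5)
  sel <- rec[rec$selected & rec$coi == "A", ]
  expect_equal(nrow(sel), 4)
  # the four highest AUROCs were taken
  expect_true(min(sel$auroc) >= max(cand_a$auroc[!cand_a$gene %in%
                                                   sel$gene]))
  # audited flags: every selected gene passes all four criteria
  expect_true(all(sel$pass_auroc & sel$pass_detection & sel$pass_mean &
                    sel$pass_outside))
  expect_true(all(sel$rank_in_coi <= 4))
})

test_that("planted markers are recovered on synthetic clusters", {
  sim <- generate_counts(count_sim_spec(n_clusters = 5,
                                        cells_per_cluster = 80,
                                        marker_fold = 8, seed = 44))
  ft <- freeman_tukey(normalize_counts(sim$counts,
                                       library_size_factors(sim$counts)))
  labels <- stats::setNames(sim$truth$cells$cluster, sim$truth$cells$cell)
  rec <- select_markers(ft, labels)
  sel <- rec$gene[rec$selected]
  expect_equal(length(sel), 20)                 # 5 clusters x top 4
  expect_true(all(grepl("^MRK", sel)))          # all planted
  # never more than top_k per cluster
  expect_true(all(table(rec$coi[rec$selected]) <= 4))
})

test_that("proliferation scores standardize across clusters", {
  set.seed(45)
  pro <- default_gene_lists()$proliferation_markers
  n <- 120
  labels <- stats::setNames(rep(1:3, each = n / 3), paste0("c", 1:n))
  vals <- matrix(rnorm((length(pro) + 5) * n, 2, 0.2),
                 length(pro) + 5, n,
                 dimnames = list(c(pro, paste0("g", 1:5)), names(labels)))
  # plant a proliferating cluster by inflating the marker genes
  vals[pro, labels == 2] <- vals[pro, labels == 2, drop = FALSE] + 3
  x <- expression_matrix(vals, transform_tag = "freeman_tukey")
  sc <- proliferation_score(x, labels)
  expect_equal(names(which.max(sc)), "2")
  expect_lt(abs(mean(sc)), 1e-8)   # Z-scores average to zero
  # a constant gene contributes nothing; scores still centered
  vals[pro[1], ] <- 1
  sc2 <- proliferation_score(expression_matrix(
    vals, transform_tag = "freeman_tukey"), labels)
  expect_lt(abs(mean(sc2)), 1e-8)
  # warns about markers absent from the matrix
  expect_warning(
    proliferation_score(x, labels, markers = c(pro, "NOTAGENE")),
    "not present")
})

test_that("the LASSO classifier separates blobs and collapses under a
           label permutation", {
  set.seed(46)
  n <- 180; g <- 50
  labels <- rep(c("A", "B", "C"), each = n / 3)
  vals <- matrix(rnorm(g * n), g, n)
  vals[1:3, labels == "A"] <- vals[1:3, labels == "A"] + 4
  vals[4:6, labels == "B"] <- vals[4:6, labels == "B"] + 4
  vals <- vals - min(vals)
  dimnames(vals) <- list(paste0("g", 1:g), paste0("c", 1:n))
  train <- seq_len(n) %% 3 != 0
  x_tr <- expression_matrix(vals[, train], transform_tag = "normalized")
  x_te <- expression_matrix(vals[, !train], transform_tag = "normalized")
  mdl <- train_id_classifier(x_tr, stats::setNames(labels[train],
                                                   colnames(vals)[train]),
                             n_hvg = g, folds = 5, seed = 1)
  pred <- predict_id_scores(mdl, x_te)
  expect_equal(mean(pred$assigned_type == labels[!train]), 1)
  expect_true(all(abs(rowSums(pred[, mdl$classes]) - 1) < 1e-8))
  expect_true(all(mdl$classifier_genes %in% mdl$genes))
  # nonzero-gene count grows as the penalty relaxes along the path
  nz <- mdl$fit$nzero
  expect_lte(nz[1], tail(nz, 1))
  # shuffled labels give chance-level held-out accuracy
  sh <- sample(labels[train])
  # a label permutation has no signal; glmnet may warn about convergence
  mdl0 <- suppressWarnings(
    train_id_classifier(x_tr, stats::setNames(sh, colnames(vals)[train]),
                        n_hvg = g, folds = 5, seed = 2))
  p0 <- predict_id_scores(mdl0, x_te)
  acc0 <- mean(p0$assigned_type == labels[!train])
  expect_lt(acc0, 1 / 3 + 3 * sqrt((1 / 3) * (2 / 3) / nrow(p0)))
})
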