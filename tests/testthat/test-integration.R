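test_that("a single batch passes through unchanged", {
  b <- blob_embedding(n_per = 40, seed = 51)
  cs <- mnn_correct(list(only = b$embedding))
  expect_identical(cs$coordinates, b$embedding$coordinates)
})

test_that("a constant batch offset is removed and pairs are mutual", {
  set.seed(52)
  n <- 200; p <- 10
  a <- matrix(rnorm(n * p), n, p)
  v <- rnorm(p, 1.5, 1)
  b <- a + matrix(v, n, p, byrow = TRUE)
  ea <- embedding_matrix(a, cells = paste0("a", 1:n))
  eb <- embedding_matrix(b, cells = paste0("b", 1:n))
  cs <- mnn_correct(list(ref = ea, qry = eb), k = 20)
  # reference coordinates bit-identical
  expect_equal(unname(cs$coordinates[1:n, ]), a)
  delta <- colMeans(cs$coordinates[cs$batch == "qry", ]) - colMeans(a)
  expect_lt(sqrt(sum(delta^2)), 0.05 * sqrt(sum(v^2)))
  # every reported pair is mutual under brute-force kNN recomputation
  corrected <- cs$coordinates[cs$batch == "qry", ]
  d2 <- outer(rowSums(a^2), rowSums(corrected^2), "+") -
    2 * tcrossprod(a, corrected)
  pr <- cs$mnn_pairs
  ri <- match(pr$reference, paste0("a", 1:n))
  qi <- match(pr$query, paste0("b", 1:n))
  for (i in sample(nrow(pr), 25)) {
    expect_true(qi[i] %in% order(d2[ri[i], ])[1:20])
    expect_true(ri[i] %in% order(d2[, qi[i]])[1:20])
  }
  expect_error(mnn_correct(list(ref = ea, qry = eb), k = 0), "larger k")
})

test_that("identical batches are moved by at most numerical noise", {
  set.seed(53)
  a <- matrix(rnorm(100 * 5), 100, 5)
  cs <- mnn_correct(list(r = embedding_matrix(a, cells = paste0("a", 1:100)),
                         q = embedding_matrix(a, cells = paste0("b", 1:100))),
                    k = 5)
  moved <- sqrt(rowSums((cs$coordinates[101:200, ] - a)^2))
  expect_lt(max(moved), 1e-8)
})

test_that("kNN label transfer votes and breaks ties by distance", {
  coords <- rbind(c(0, 0), c(0, 1), c(2, 0), c(2, 1), c(0.2, 0.5))
  cells <- c("r1", "r2", "r3", "r4", "q")
  emb <- embedding_matrix(coords, cells = cells)
  labs <- c(r1 = "A", r2 = "A", r3 = "B", r4 = "B")
  # k = 1 with a coincident reference cell
  emb2 <- embedding_matrix(rbind(coords[1:4, ], c(0, 0)), cells = cells)
  expect_equal(unname(knn_classify(emb2, labs, k = 1)), "A")
  # 2 vs 2 tie at k = 4: A cells are nearer on average
  expect_equal(unname(knn_classify(emb, labs, k = 4)), "A")
  # majority: 15 of 20 neighbors labeled A
  set.seed(54)
  ref <- rbind(matrix(rnorm(30, 0, 0.1), 15, 2),
               matrix(rnorm(10, 0.3, 0.1), 5, 2),
               matrix(rnorm(40, 20, 0.1), 20, 2))
  cells <- c(paste0("a", 1:20), paste0("far", 1:20))
  labs2 <- stats::setNames(c(rep("A", 15), rep("B", 5), rep("B", 20)),
                           cells)
  emb3 <- embedding_matrix(rbind(ref, c(0.1, 0.1)),
                           cells = c(cells, "q"))
  expect_equal(unname(knn_classify(emb3, labs2, k = 20)), "A")
  # invariance to reference permutation
  perm <- sample(names(labs2))
  expect_equal(knn_classify(emb3, labs2[perm], k = 20),
               knn_classify(emb3, labs2, k = 20))
  expect_error(knn_classify(emb3, labs2, k = 100), "exceeds")
})

test_that("cross-batch label transfer is accurate on planted types", {
  set.seed(55)
  n <- 200; p <- 10
  a <- rbind(matrix(rnorm(n / 2 * p), n / 2, p),
             matrix(rnorm(n / 2 * p, 6), n / 2, p))
  v <- rnorm(p, 1.5, 1)
  b <- a + matrix(v, n, p, byrow = TRUE)
  cs <- mnn_correct(list(ref = embedding_matrix(a, cells = paste0("a", 1:n)),
                         qry = embedding_matrix(b, cells = paste0("b", 1:n))),
                    k = 20)
  labs <- stats::setNames(rep(c("X", "Y"), each = n / 2), paste0("a", 1:n))
  pred <- knn_classify(cs, labs, k = 20)
  truth <- stats::setNames(rep(c("X", "Y"), each = n / 2), paste0("b", 1:n))
  expect_gte(mean(pred[names(truth)] == truth), 0.95)
})

test_that("differential expression recovers planted folds with the right
           sign", {
  set.seed(56)
  g <- 400; n <- 60
  mu <- rep(8, g)
  m <- matrix(rnbinom(g * n, size = 10, mu = mu), g, n,
              dimnames = list(paste0("g", 1:g), paste0("c", 1:n)))
  up <- 1:20; dn <- 21:40
  m[up, 31:60] <- rnbinom(20 * 30, size = 10, mu = 32)
  m[dn, 31:60] <- rnbinom(20 * 30, size = 10, mu = 2)
  de <- differential_expression(count_matrix(m), rep(c("A", "B"), each = 30))
  tab <- de$table
  expect_true(all(tab$fdr >= tab$p))
  hits <- fold_change_filter(de, min_fold = 2, max_fdr = 0.05)
  called_up <- tab$gene[tab$l2fc > 0 & tab$gene %in% hits]
  called_dn <- tab$gene[tab$l2fc < 0 & tab$gene %in% hits]
  expect_gte(mean(paste0("g", up) %in% called_up), 0.9)
  expect_gte(mean(paste0("g", dn) %in% called_dn), 0.9)
  # detection rates are per-group fractions of nonzero cells
  expect_equal(unname(de$detection["g21", "B"]), mean(m[21, 31:60] > 0))
})

test_that("fold-change filtering is strict at its boundaries", {
  de <- structure(list(table = data.frame(
    contrast = "B vs A",
    gene = c("exact", "above", "high_fdr"),
    l2fc = c(1.0, 1.01, 5),
    p = c(1e-4, 1e-4, 0.2),
    fdr = c(1e-3, 1e-3, 0.2))), class = "DEResult")
  expect_identical(fold_change_filter(de, min_fold = 2, max_fdr = 0.05),
                   "above")
  empty <- structure(list(table = de$table[0, ]), class = "DEResult")
  expect_identical(fold_change_filter(empty), character(0))
  expect_true(all(fold_change_filter(de, 1.1, 1) %in% de$table$gene))
})
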