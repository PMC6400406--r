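#' Learn a principal tree over an embedding
#'
#' A lightweight principal-tree estimator: seeded k-means places
#' `n_nodes` centroids in the embedding, the centroids are joined by
#' their Euclidean minimum spanning tree, and every cell is projected
#' onto the nearest point of any tree edge. This shares the contract of
#' reversed-graph-embedding trajectory learners (tree + projection +
#' geodesic pseudotime) at a fraction of their complexity; see the
#' methods vignette for what that simplification implies.
#'
#' @param embedding An [embedding_matrix()] (typically PCA of the
#'   Freeman-Tukey expression of trajectory cells).
#' @param n_nodes Number of tree nodes; default
#'   `max(10, ceiling(n_cells / 100))`.
#' @param seed Seed for k-means.
#' @return A `PrincipalTree`: list with `nodes` (coordinates), `edges`
#'   (two-column matrix), `edge_length`, and per-cell `projection`
#'   (`edge`, `offset` along the edge from its first node, `coords`,
#'   `dist`).
#' @export
learn_tree <- function(embedding, n_nodes = NULL, seed = NULL) {
  stopifnot(inherits(embedding, "EmbeddingMatrix"))
  xm <- embedding$coordinates
  n <- nrow(xm)
  if (is.null(n_nodes)) n_nodes <- max(10L, ceiling(n / 100))
  if (n_nodes < 2L) stopf("n_nodes must be at least 2")
  if (n_nodes > n) stopf("n_nodes exceeds the number of cells")
  km <- with_seed(seed, kmeans(xm, centers = n_nodes, nstart = 10,
                               iter.max = 100))
  nodes <- km$centers
  nd <- as.matrix(dist(nodes))
  g <- igraph::graph_from_adjacency_matrix(nd, mode = "undirected",
                                           weighted = TRUE)
  mst <- igraph::mst(g)
  edges <- igraph::as_edgelist(mst, names = FALSE)
  # project every cell onto the nearest edge segment
  proj_edge <- integer(n); proj_off <- numeric(n); proj_d2 <- rep(Inf, n)
  proj_xy <- matrix(0, n, ncol(xm))
  for (e in seq_len(nrow(edges))) {
    a <- nodes[edges[e, 1], ]; b <- nodes[edges[e, 2], ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 == 0) rep(0, n) else
      pmin(pmax((sweep(xm, 2, a) %*% ab) / len2, 0), 1)
    p <- sweep(outer(as.numeric(t), ab), 2, a, "+")
    d2 <- rowSums((xm - p)^2)
    better <- d2 < proj_d2
    proj_edge[better] <- e
    proj_off[better] <- t[better] * sqrt(len2)
    proj_d2[better] <- d2[better]
    proj_xy[better, ] <- p[better, , drop = FALSE]
  }
  edge_length <- sqrt(rowSums((nodes[edges[, 1], , drop = FALSE] -
                                 nodes[edges[, 2], , drop = FALSE])^2))
  if (!igraph::is_connected(mst) || igraph::gsize(mst) != n_nodes - 1L) {
    stopf("internal error: principal tree is not a spanning tree")
  }
  structure(
    list(nodes = nodes, edges = edges, edge_length = edge_length,
         graph = mst, cells = embedding$cells,
         projection = data.frame(edge = proj_edge, offset = proj_off,
                                 dist = sqrt(proj_d2)),
         projection_coords = proj_xy),
    class = "PrincipalTree"
  )
}

# Geodesic distance from a root node to every cell's projection point.
geodesic_from <- function(tree, root_node) {
  node_d <- igraph::distances(tree$graph, v = root_node,
                              weights = igraph::E(tree$graph)$weight)[1, ]
  e <- tree$edges[tree$projection$edge, , drop = FALSE]
  off <- tree$projection$offset
  len <- tree$edge_length[tree$projection$edge]
  pmin(node_d[e[, 1]] + off, node_d[e[, 2]] + (len - off))
}

#' Pseudotime along a principal tree
#'
#' Pseudotime is the geodesic arc length along the tree from the root to
#' each cell's projection point. The root may be given as a node index
#' or as a cluster label (with `assign`), resolved to the tree node
#' nearest that cluster's centroid — mirroring the practice of rooting
#' the trajectory at the earliest progenitor state (e.g. the pretubular
#' aggregate).
#'
#' @param tree A `PrincipalTree` from [learn_tree()].
#' @param root Node index, or cluster label when `assign` is given.
#' @param assign Cluster labels of the embedded cells (needed for a
#'   cluster root).
#' @param embedding The embedding used to learn the tree (needed for a
#'   cluster root).
#' @return A `PseudotimeResult` data frame: `cell`, `pseudotime`,
#'   `branch` (id of the maximal tree segment between branch points
#'   carrying the cell's edge), with attributes `root_node` and
#'   `branch_points`.
#' @export
compute_pseudotime <- function(tree, root, assign = NULL, embedding = NULL) {
  stopifnot(inherits(tree, "PrincipalTree"))
  if (is.numeric(root) && length(root) == 1L && root == round(root) &&
      root >= 1 && root <= nrow(tree$nodes)) {
    root_node <- as.integer(root)
  } else {
    if (is.null(assign) || is.null(embedding)) {
      stopf("a cluster root needs `assign` and `embedding`")
    }
    labels <- cluster_labels(assign, tree$cells)
    if (!root %in% labels) stopf("root cluster '%s' not found", root)
    centroid <- colMeans(embedding$coordinates[labels == root, ,
                                               drop = FALSE])
    root_node <- which.min(colSums((t(tree$nodes) - centroid)^2))
  }
  pt <- geodesic_from(tree, root_node)
  # branches: connected runs of edges after removing branch points
  deg <- igraph::degree(tree$graph)
  branch_points <- which(deg >= 3L)
  line <- igraph::make_line_graph(tree$graph)
  # two edges belong to the same branch iff their shared node has degree 2
  el <- tree$edges
  keep <- vapply(seq_len(igraph::gsize(line)), function(i) {
    ends <- igraph::ends(line, i)
    shared <- intersect(el[ends[1], ], el[ends[2], ])
    all(deg[shared] == 2L)
  }, logical(1))
  line2 <- igraph::subgraph_from_edges(line, which(keep),
                                       delete.vertices = FALSE)
  branch_of_edge <- igraph::components(line2)$membership
  out <- data.frame(cell = tree$cells, pseudotime = pt,
                    branch = branch_of_edge[tree$projection$edge],
                    stringsAsFactors = FALSE)
  class(out) <- c("PseudotimeResult", "data.frame")
  attr(out, "root_node") <- root_node
  attr(out, "branch_points") <- branch_points
  out
}

#' Summarize pseudotime by cluster
#'
#' @param res A `PseudotimeResult`.
#' @param assign Cluster labels covering the cells.
#' @return Data frame with per-cluster `n`, quartiles, and `median`,
#'   ordered by median pseudotime.
#' @export
pseudotime_by_cluster <- function(res, assign) {
  stopifnot(inherits(res, "PseudotimeResult"))
  labels <- cluster_labels(assign, res$cell)
  lev <- unique(labels)
  out <- do.call(rbind, lapply(lev, function(k) {
    v <- res$pseudotime[labels == k]
    if (length(v) == 0L) return(NULL)
    data.frame(cluster = as.character(k), n = length(v),
               q25 = quantile(v, 0.25, names = FALSE),
               median = median(v),
               q75 = quantile(v, 0.75, names = FALSE),
               stringsAsFactors = FALSE)
  }))
  out[order(out$median), , drop = FALSE]
}
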