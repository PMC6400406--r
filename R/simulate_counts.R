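#' Specification for synthetic UMI count data
#'
#' Defines a negative-binomial count simulation with planted cluster
#' structure, marker genes, mitochondrial / stress / hemoglobin
#' contamination, optional batch effects, and an optional branching
#' developmental trajectory. The negative binomial is parameterized so
#' that `variance = mu + dispersion * mu^2`.
#'
#' Defaults emulate a droplet scRNA-seq experiment on fetal kidney at
#' desk scale: ~1,200 cells in 8 types, 2,000 genes with log-normal
#' baseline means averaging 1.5 UMI (an expected ~3,000 UMI per cell),
#' 8-fold exclusive markers, and contamination planted at twice the QC
#' thresholds in the designated stressed / red-blood-cell subsets
#' (mitochondrial 20% vs the 10% threshold, stress 10% vs 5%, hemoglobin
#' 2% vs 1%), with low background fractions elsewhere.
#'
#' @param n_clusters Number of planted cell types.
#' @param cells_per_cluster Cells per type.
#' @param n_genes Total genes, including marker and contamination-list
#'   genes.
#' @param markers_per_cluster Exclusive marker genes planted per cluster.
#' @param marker_fold Mean fold elevation of a marker in its cluster.
#' @param baseline_mean Average baseline mean UMI per gene per cell.
#' @param dispersion NB dispersion phi (`variance = mu + phi * mu^2`);
#'   0 gives Poisson counts.
#' @param mito_fraction,stress_fraction,hemoglobin_fraction Expected
#'   expression fractions planted in the designated stressed (mito and
#'   stress lists) and red-blood-cell (hemoglobin list) subsets.
#' @param background_fractions Named numeric: expected mitochondrial,
#'   stress, and hemoglobin fractions in ordinary cells.
#' @param n_stressed,n_rbc,n_low_count Sizes of the designated subsets;
#'   `NULL` uses 5%, 1%, and 2% of cells respectively.
#' @param low_count_factor Depth multiplier for designated low-count
#'   cells (expected total well below the 2,000-UMI retention threshold).
#' @param batch_offsets Optional numeric vector of per-batch effect
#'   strengths (one per batch; e.g. `c(0, 0.3)` for two batches). Cells
#'   are assigned to batches evenly within each cluster and batch `b`
#'   multiplies every gene mean by `exp(strength_b * z_g)` for a fixed
#'   standard-normal gene loading `z_g`.
#' @param trajectory Optional list describing a latent trajectory; see
#'   [generate_trajectory_counts()].
#' @param seed Integer seed; the same spec and seed give bit-identical
#'   output.
#' @return An object of class `CountSimSpec`.
#' @export
count_sim_spec <- function(n_clusters = 8, cells_per_cluster = 150,
                           n_genes = 2000, markers_per_cluster = 5,
                           marker_fold = 8, baseline_mean = 1.5,
                           dispersion = 0.1,
                           mito_fraction = 0.20, stress_fraction = 0.10,
                           hemoglobin_fraction = 0.02,
                           background_fractions = c(mitochondrial = 0.03,
                                                    stress_markers = 0.015,
                                                    hemoglobin = 0.001),
                           n_stressed = NULL, n_rbc = NULL, n_low_count = NULL,
                           low_count_factor = 0.3,
                           batch_offsets = NULL, trajectory = NULL,
                           seed = 1) {
  assert_scalar_number(n_clusters, "n_clusters", 1)
  assert_scalar_number(cells_per_cluster, "cells_per_cluster", 2)
  assert_scalar_number(n_genes, "n_genes", 10)
  assert_scalar_number(marker_fold, "marker_fold", lower = 1 + 1e-9)
  assert_scalar_number(baseline_mean, "baseline_mean", lower = 1e-12)
  assert_scalar_number(dispersion, "dispersion", lower = 0)
  for (f in c(mito_fraction, stress_fraction, hemoglobin_fraction,
              background_fractions)) {
    if (f < 0 || f >= 1) stopf("expression fractions must lie in [0, 1)")
  }
  n_cells <- n_clusters * cells_per_cluster
  if (is.null(n_stressed)) n_stressed <- round(0.05 * n_cells)
  if (is.null(n_rbc)) n_rbc <- max(5, round(0.01 * n_cells))
  if (is.null(n_low_count)) n_low_count <- round(0.02 * n_cells)
  registry <- default_gene_lists()
  n_list_genes <- length(registry$mitochondrial) +
    length(registry$stress_markers) + length(registry$hemoglobin)
  if (markers_per_cluster * n_clusters + n_list_genes > n_genes) {
    stopf("n_genes (%d) too small for %d planted markers plus %d list genes",
          n_genes, markers_per_cluster * n_clusters, n_list_genes)
  }
  structure(
    list(n_clusters = n_clusters, cells_per_cluster = cells_per_cluster,
         n_genes = n_genes, markers_per_cluster = markers_per_cluster,
         marker_fold = marker_fold, baseline_mean = baseline_mean,
         dispersion = dispersion, mito_fraction = mito_fraction,
         stress_fraction = stress_fraction,
         hemoglobin_fraction = hemoglobin_fraction,
         background_fractions = background_fractions,
         n_stressed = n_stressed, n_rbc = n_rbc, n_low_count = n_low_count,
         low_count_factor = low_count_factor,
         batch_offsets = batch_offsets, trajectory = trajectory,
         seed = seed),
    class = "CountSimSpec"
  )
}

# Draw NB counts with variance = mu + phi mu^2 (Poisson when phi = 0).
rnb <- function(mu, phi) {
  n <- length(mu)
  if (phi <= 0) return(rpois(n, mu))
  rnbinom(n, size = 1 / phi, mu = mu)
}

#' Generate a synthetic clustered count matrix with recorded ground truth
#'
#' Counts are independent negative binomials with cluster-specific means:
#' each cluster carries `markers_per_cluster` exclusive genes elevated by
#' `marker_fold`; mitochondrial, stress, and hemoglobin genes carry low
#' background fractions in ordinary cells and the planted elevated
#' fractions in the designated stressed / red-blood-cell subsets.
#' Contamination counts in designated cells are drawn as Poisson (the
#' contaminating material is technical and not subject to the biological
#' overdispersion), so the planted fractions are exceeded in expectation
#' with high probability at the 2x threshold margins used here.
#'
#' @param spec A [count_sim_spec()].
#' @return A list with `counts` (a [count_matrix()], batch labels set if
#'   batches were requested) and `truth`, a ground-truth list with
#'   per-cell `cluster`, `batch`, `designation`, per-gene `role`,
#'   `marker_cluster`, `fold`, and the generating parameters.
#' @export
generate_counts <- function(spec) {
  stopifnot(inherits(spec, "CountSimSpec"))
  with_seed(spec$seed, generate_counts_impl(spec))
}

generate_counts_impl <- function(spec) {
  registry <- default_gene_lists()
  mito <- registry$mitochondrial
  stress <- registry$stress_markers
  hb <- registry$hemoglobin
  list_genes <- c(mito, stress, hb)
  K <- spec$n_clusters
  n_mark <- spec$markers_per_cluster * K
  n_base <- spec$n_genes - n_mark - length(list_genes)
  marker_genes <- sprintf("MRK%02d_%d", rep(seq_len(K), each = spec$markers_per_cluster),
                          rep(seq_len(spec$markers_per_cluster), K))
  base_genes <- sprintf("GENE%05d", seq_len(n_base))
  genes <- c(marker_genes, base_genes, list_genes)

  n_cells <- K * spec$cells_per_cluster
  cells <- sprintf("cell%05d", seq_len(n_cells))
  cluster <- rep(seq_len(K), each = spec$cells_per_cluster)

  # Baseline means: markers flat at baseline_mean, other genes log-normal
  # around baseline_mean (sdlog 0.7) so the CV^2-mean trend is estimable.
  sdlog <- 0.7
  base_mu <- c(rep(spec$baseline_mean, n_mark),
               stats::rlnorm(n_base, log(spec$baseline_mean) - sdlog^2 / 2,
                             sdlog))

  # genes x clusters expected means for non-list genes
  M <- matrix(base_mu, nrow = n_mark + n_base, ncol = K)
  for (k in seq_len(K)) {
    idx <- (k - 1) * spec$markers_per_cluster + seq_len(spec$markers_per_cluster)
    M[idx, k] <- M[idx, k] * spec$marker_fold
  }

  # List-gene means per cluster chosen so the expected list fractions of
  # the cell total equal the background fractions.
  bg <- spec$background_fractions
  f_tot <- sum(bg)
  w_mito <- stats::rlnorm(length(mito), 0, 0.3); w_mito <- w_mito / sum(w_mito)
  w_str <- stats::rlnorm(length(stress), 0, 0.3); w_str <- w_str / sum(w_str)
  w_hb <- stats::rlnorm(length(hb), 0, 0.3); w_hb <- w_hb / sum(w_hb)
  Mlist <- matrix(0, nrow = length(list_genes), ncol = K)
  for (k in seq_len(K)) {
    total_k <- sum(M[, k]) / (1 - f_tot)
    Mlist[, k] <- c(bg[["mitochondrial"]] * total_k * w_mito,
                    bg[["stress_markers"]] * total_k * w_str,
                    bg[["hemoglobin"]] * total_k * w_hb)
  }
  Mfull <- rbind(M, Mlist)
  rownames(Mfull) <- genes

  # Per-cell mean matrix
  mu_cell <- Mfull[, cluster, drop = FALSE]

  # Designated cells: stressed, red blood, low count (disjoint)
  designation <- rep("normal", n_cells)
  pick <- sample(n_cells, spec$n_stressed + spec$n_rbc + spec$n_low_count)
  i_str <- pick[seq_len(spec$n_stressed)]
  i_rbc <- pick[spec$n_stressed + seq_len(spec$n_rbc)]
  i_low <- pick[spec$n_stressed + spec$n_rbc + seq_len(spec$n_low_count)]
  designation[i_str] <- "stressed"
  designation[i_rbc] <- "red_blood_cell"
  designation[i_low] <- "low_count"

  idx_mito <- match(mito, genes)
  idx_str <- match(stress, genes)
  idx_hb <- match(hb, genes)
  idx_other <- setdiff(seq_along(genes), c(idx_mito, idx_str, idx_hb))
  reallocate <- function(mu, f_new) {
    # f_new: named fractions for the three lists; others rescaled so the
    # expected cell total is preserved.
    total <- sum(mu)
    f_old_other <- sum(mu[idx_other]) / total
    mu[idx_mito] <- f_new[["mitochondrial"]] * total * w_mito
    mu[idx_str] <- f_new[["stress_markers"]] * total * w_str
    mu[idx_hb] <- f_new[["hemoglobin"]] * total * w_hb
    f_new_other <- 1 - sum(f_new)
    mu[idx_other] <- mu[idx_other] * f_new_other / f_old_other
    mu
  }
  for (i in i_str) {
    f <- c(mitochondrial = spec$mito_fraction,
           stress_markers = spec$stress_fraction,
           hemoglobin = spec$background_fractions[["hemoglobin"]])
    mu_cell[, i] <- reallocate(mu_cell[, i], f)
  }
  for (i in i_rbc) {
    f <- c(mitochondrial = spec$background_fractions[["mitochondrial"]],
           stress_markers = spec$background_fractions[["stress_markers"]],
           hemoglobin = spec$hemoglobin_fraction)
    mu_cell[, i] <- reallocate(mu_cell[, i], f)
  }
  mu_cell[, i_low] <- mu_cell[, i_low, drop = FALSE] * spec$low_count_factor

  # Batch effects: multiplicative log-normal gene factors.
  batch <- NULL
  batch_loading <- NULL
  if (!is.null(spec$batch_offsets)) {
    n_batch <- length(spec$batch_offsets)
    batch <- ((seq_len(n_cells) - 1L) %% n_batch) + 1L  # within-cluster split
    batch_loading <- stats::rnorm(length(genes))
    for (b in seq_len(n_batch)) {
      fac <- exp(spec$batch_offsets[b] * batch_loading)
      mu_cell[, batch == b] <- mu_cell[, batch == b, drop = FALSE] * fac
    }
    batch <- paste0("batch", batch)
  }

  counts <- matrix(rnb(as.vector(mu_cell), spec$dispersion),
                   nrow = length(genes), ncol = n_cells)
  # Contamination in designated cells is Poisson around the planted mean.
  idx_lists <- c(idx_mito, idx_str, idx_hb)
  for (i in c(i_str, i_rbc)) {
    counts[idx_lists, i] <- rpois(length(idx_lists), mu_cell[idx_lists, i])
  }
  rownames(counts) <- genes
  colnames(counts) <- cells

  role <- c(rep("marker", n_mark), rep("baseline", n_base),
            rep("mitochondrial", length(mito)),
            rep("stress", length(stress)), rep("hemoglobin", length(hb)))
  marker_cluster <- c(rep(seq_len(K), each = spec$markers_per_cluster),
                      rep(NA_integer_, length(genes) - n_mark))
  truth <- list(
    cells = data.frame(cell = cells, cluster = cluster,
                       batch = if (is.null(batch)) NA_character_ else batch,
                       designation = designation,
                       stringsAsFactors = FALSE),
    genes = data.frame(gene = genes, role = role,
                       marker_cluster = marker_cluster,
                       fold = ifelse(role == "marker", spec$marker_fold, 1),
                       base_mean = Mfull[, 1],
                       stringsAsFactors = FALSE),
    cluster_means = Mfull,
    batch_loading = batch_loading,
    spec = spec
  )
  list(counts = count_matrix(counts, genes = genes, cells = cells,
                             batch = batch),
       truth = truth)
}

#' Describe a planted trajectory topology
#'
#' @param topology `"linear"` or `"Y"`, or an integer parent vector
#'   `p` where segment `s` descends from segment `p[s]` (`0` = root);
#'   parents must precede children (`p[s] < s`), which rules out cycles.
#' @param n_segments Number of segments for `"linear"` topology.
#' @param cells_per_segment Cells placed uniformly along each segment.
#' @param dynamic_genes_per_segment Genes upregulated along each segment
#'   (and kept high in its descendants).
#' @param n_time_genes Genes whose mean increases monotonically with
#'   depth along every path (fold `marker_fold` from root to the deepest
#'   node).
#' @return A list suitable for the `trajectory` field of
#'   [count_sim_spec()].
#' @export
trajectory_spec <- function(topology = "linear", n_segments = 3,
                            cells_per_segment = 200,
                            dynamic_genes_per_segment = 30,
                            n_time_genes = 20) {
  if (is.character(topology)) {
    topology <- switch(match.arg(topology, c("linear", "Y")),
                       linear = c(0L, seq_len(n_segments - 1L)),
                       Y = c(0L, 1L, 1L))
  }
  topology <- as.integer(topology)
  if (any(topology >= seq_along(topology)) || any(topology < 0L)) {
    stopf("branch topology must be acyclic: parent index must precede child")
  }
  list(topology = topology, cells_per_segment = cells_per_segment,
       dynamic_genes_per_segment = dynamic_genes_per_segment,
       n_time_genes = n_time_genes)
}

#' Generate counts along a planted developmental trajectory
#'
#' Gene means vary piecewise-linearly with a latent time coordinate:
#' each segment interpolates between the expression profile of its start
#' and end node; segment-specific gene sets ramp up along their segment
#' and stay high in descendants, and a set of "time genes" increases
#' monotonically with depth. Contamination-list genes carry background
#' fractions only (no designated stressed cells).
#'
#' @param spec A [count_sim_spec()] whose `trajectory` field is set (see
#'   [trajectory_spec()]).
#' @return A list with `counts` and `truth`; `truth$cells` records the
#'   true `segment`, within-segment position `u`, and `latent_time`
#'   (= depth of the segment start + `u`), and `truth$topology` the
#'   parent vector.
#' @export
generate_trajectory_counts <- function(spec) {
  stopifnot(inherits(spec, "CountSimSpec"))
  if (is.null(spec$trajectory)) stopf("spec$trajectory must be set")
  with_seed(spec$seed, generate_trajectory_impl(spec))
}

generate_trajectory_impl <- function(spec) {
  tr <- spec$trajectory
  topo <- tr$topology
  S <- length(topo)
  registry <- default_gene_lists()
  list_genes <- c(registry$mitochondrial, registry$stress_markers,
                  registry$hemoglobin)
  n_dyn <- tr$dynamic_genes_per_segment * S
  n_time <- tr$n_time_genes
  n_base <- spec$n_genes - n_dyn - n_time - length(list_genes)
  if (n_base < 0) stopf("n_genes too small for the trajectory gene sets")
  dyn_genes <- sprintf("DYN%02d_%d", rep(seq_len(S), each = tr$dynamic_genes_per_segment),
                       rep(seq_len(tr$dynamic_genes_per_segment), S))
  time_genes <- sprintf("TIME%03d", seq_len(n_time))
  base_genes <- sprintf("GENE%05d", seq_len(n_base))
  genes <- c(dyn_genes, time_genes, base_genes, list_genes)
  n_nonlist <- n_dyn + n_time + n_base

  # depth of the start node of each segment (root has depth 0)
  depth_start <- integer(S)
  for (s in seq_len(S)) {
    depth_start[s] <- if (topo[s] == 0L) 0L else depth_start[topo[s]] + 1L
  }
  max_depth <- max(depth_start) + 1L

  sdlog <- 0.7
  base_mu <- c(rep(spec$baseline_mean, n_dyn + n_time),
               stats::rlnorm(n_base, log(spec$baseline_mean) - sdlog^2 / 2,
                             sdlog))

  # Node profiles over non-list genes: node 0 = baseline; end node of
  # segment s = profile of its start node with segment-s dynamic genes at
  # fold, and time genes at fold^(depth/max_depth).
  node_profile <- vector("list", S + 1L)
  node_profile[[1]] <- base_mu
  idx_time <- n_dyn + seq_len(n_time)
  for (s in seq_len(S)) {
    start <- node_profile[[topo[s] + 1L]]
    prof <- start
    idx_dyn <- (s - 1L) * tr$dynamic_genes_per_segment +
      seq_len(tr$dynamic_genes_per_segment)
    prof[idx_dyn] <- base_mu[idx_dyn] * spec$marker_fold
    d_end <- depth_start[s] + 1L
    prof[idx_time] <- base_mu[idx_time] * spec$marker_fold^(d_end / max_depth)
    node_profile[[s + 1L]] <- prof
  }

  n_cells <- S * tr$cells_per_segment
  cells <- sprintf("cell%05d", seq_len(n_cells))
  segment <- rep(seq_len(S), each = tr$cells_per_segment)
  u <- runif(n_cells)
  mu_cell <- matrix(0, nrow = n_nonlist, ncol = n_cells)
  for (i in seq_len(n_cells)) {
    s <- segment[i]
    mu_cell[, i] <- (1 - u[i]) * node_profile[[topo[s] + 1L]][seq_len(n_nonlist)] +
      u[i] * node_profile[[s + 1L]][seq_len(n_nonlist)]
  }

  bg <- spec$background_fractions
  f_tot <- sum(bg)
  w <- stats::rlnorm(length(list_genes), 0, 0.3)
  parts <- rep(c(bg[["mitochondrial"]], bg[["stress_markers"]],
                 bg[["hemoglobin"]]),
               c(length(registry$mitochondrial),
                 length(registry$stress_markers),
                 length(registry$hemoglobin)))
  grp <- rep(1:3, c(length(registry$mitochondrial),
                    length(registry$stress_markers),
                    length(registry$hemoglobin)))
  w <- w / ave(w, grp, FUN = sum)
  totals <- colSums(mu_cell) / (1 - f_tot)
  mu_list <- outer(parts * w, totals)
  mu_all <- rbind(mu_cell, mu_list)
  rownames(mu_all) <- genes

  counts <- matrix(rnb(as.vector(mu_all), spec$dispersion),
                   nrow = length(genes), ncol = n_cells,
                   dimnames = list(genes, cells))

  role <- c(rep("dynamic", n_dyn), rep("time", n_time),
            rep("baseline", n_base), rep("list", length(list_genes)))
  truth <- list(
    cells = data.frame(cell = cells, segment = segment, u = u,
                       latent_time = depth_start[segment] + u,
                       stringsAsFactors = FALSE),
    genes = data.frame(gene = genes, role = role,
                       segment = c(rep(seq_len(S),
                                       each = tr$dynamic_genes_per_segment),
                                   rep(NA_integer_,
                                       length(genes) - n_dyn)),
                       stringsAsFactors = FALSE),
    topology = topo,
    spec = spec
  )
  list(counts = count_matrix(counts, genes = genes, cells = cells),
       truth = truth)
}
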