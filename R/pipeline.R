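#' Run the standard single-sample analysis pipeline
#'
#' Chains the transcriptomic stages with their standard defaults:
#' cell QC and filtering, k-nearest-neighbor smoothing, pool
#' size-factor normalization, Freeman-Tukey transformation, highly
#' variable gene selection (excluding stress markers and ribosomal
#' genes), correlation-distance Ward clustering, and four-criterion
#' AUROC marker selection.
#'
#' @param counts A [count_matrix()] of raw UMIs.
#' @param n_clusters Number of clusters to cut the dendrogram into.
#' @param registry Gene lists used by QC and the HVG exclusions.
#' @param smooth_k Smoothing neighbors (default 10).
#' @param hvg_fraction HVG fraction (default 0.05).
#' @param min_umi,max_mito,max_stress,max_hb QC thresholds; see
#'   [filter_cells()].
#' @param top_k Markers per cluster (default 4).
#' @param seed Seed for the smoothing jitter.
#' @return A list with elements `qc`, `filter`, `smoothed`,
#'   `size_factors`, `normalized`, `ft`, `hvg`, `dendrogram`,
#'   `clusters`, and `markers`.
#' @export
run_kidney_pipeline <- function(counts, n_clusters,
                                registry = default_gene_lists(),
                                smooth_k = 10, hvg_fraction = 0.05,
                                min_umi = 2000, max_mito = 0.10,
                                max_stress = 0.05, max_hb = 0.01,
                                top_k = 4, seed = 1) {
  qc <- compute_cell_qc(counts, registry)
  filt <- filter_cells(counts, qc, min_umi = min_umi, max_mito = max_mito,
                       max_stress = max_stress, max_hb = max_hb)
  sm <- knn_smooth(filt$retained, k = smooth_k, seed = seed)
  sf <- estimate_size_factors(sm)
  norm <- normalize_counts(sm, sf)
  ft <- freeman_tukey(norm)
  exclude <- c(gene_list(registry, "stress_markers"),
               gene_list(registry, "ribosomal"))
  hvg <- select_hvg(norm, fraction = hvg_fraction, exclude = exclude)
  d <- correlation_distance(ft, genes = hvg$gene[hvg$selected])
  dend <- ward_cluster(d)
  clusters <- cut_dendrogram(dend, n_clusters = n_clusters)
  markers <- select_markers(ft, clusters, top_k = top_k)
  list(qc = qc, filter = filt, smoothed = sm, size_factors = sf,
       normalized = norm, ft = ft, hvg = hvg, dendrogram = dend,
       clusters = clusters, markers = markers)
}
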