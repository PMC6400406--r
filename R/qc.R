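#' Per-cell quality-control metrics
#'
#' Computes, for every cell, the total UMI count and the fractions of
#' expression coming from the mitochondrial, stress-marker, and
#' hemoglobin gene lists. Fractions use the cell's full unfiltered UMI
#' total as denominator; a zero-total cell has all fractions defined as
#' 0 and is destined for the low-count class.
#'
#' @param counts A [count_matrix()] of raw UMIs.
#' @param registry A [gene_list_registry()] providing `mitochondrial`,
#'   `stress_markers`, and `hemoglobin` lists.
#' @return A `CellQCReport` data frame with one row per cell: `cell`,
#'   `total_umi`, `mito_fraction`, `stress_fraction`,
#'   `hemoglobin_fraction`.
#' @export
compute_cell_qc <- function(counts, registry = default_gene_lists()) {
  stopifnot(inherits(counts, "CountMatrix"))
  mito <- match_gene_list(counts$genes, gene_list(registry, "mitochondrial"),
                          "mitochondrial list")
  stress <- match_gene_list(counts$genes, gene_list(registry, "stress_markers"),
                            "stress list")
  hb <- match_gene_list(counts$genes, gene_list(registry, "hemoglobin"),
                        "hemoglobin list")
  m <- counts$counts
  total <- Matrix::colSums(m)
  list_sum <- function(g) {
    if (length(g) == 0L) return(rep(0, ncol(m)))
    Matrix::colSums(m[g, , drop = FALSE])
  }
  safe_frac <- function(s) ifelse(total > 0, s / pmax(total, 1), 0)
  out <- data.frame(
    cell = counts$cells,
    total_umi = total,
    mito_fraction = safe_frac(list_sum(mito)),
    stress_fraction = safe_frac(list_sum(stress)),
    hemoglobin_fraction = safe_frac(list_sum(hb)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("CellQCReport", "data.frame")
  out
}

#' Partition cells by the QC removal rules
#'
#' Applies the cell-removal rules: cells with fewer than `min_umi`
#' transcripts are removed as low-count; of the remainder, cells with
#' more than `max_mito` of their expression from mitochondrial genes
#' *or* more than `max_stress` from stress markers are removed as
#' stressed; of the remainder, cells with more than `max_hb` of their
#' expression from hemoglobin genes are removed as red blood cells. All
#' inequalities are strict, and the precedence low-count > stressed >
#' red-blood-cell gives each cell exactly one flag.
#'
#' @param counts The [count_matrix()] the report was computed on.
#' @param qc A `CellQCReport` from [compute_cell_qc()].
#' @param min_umi Retention threshold on total UMI (default 2000; cells
#'   with `total < min_umi` are removed).
#' @param max_mito,max_stress,max_hb Fraction thresholds (defaults 0.10,
#'   0.05, 0.01; cells strictly above are removed).
#' @return A list with `retained` (a [count_matrix()] of retained cells),
#'   `flags` (per-cell flag, one of `retained`, `low_count`, `stressed`,
#'   `red_blood_cell`), and `summary` (class counts; they sum to the
#'   input cell count).
#' @export
filter_cells <- function(counts, qc, min_umi = 2000, max_mito = 0.10,
                         max_stress = 0.05, max_hb = 0.01) {
  stopifnot(inherits(counts, "CountMatrix"), inherits(qc, "CellQCReport"))
  if (!identical(qc$cell, counts$cells)) {
    stopf("QC report does not match the count matrix cells")
  }
  assert_scalar_number(min_umi, "min_umi", 0)
  assert_scalar_number(max_mito, "max_mito", 0, 1)
  assert_scalar_number(max_stress, "max_stress", 0, 1)
  assert_scalar_number(max_hb, "max_hb", 0, 1)
  flag <- rep("retained", nrow(qc))
  flag[qc$hemoglobin_fraction > max_hb] <- "red_blood_cell"
  flag[qc$mito_fraction > max_mito | qc$stress_fraction > max_stress] <-
    "stressed"
  flag[qc$total_umi < min_umi] <- "low_count"
  keep <- flag == "retained"
  retained <- count_matrix(counts$counts[, keep, drop = FALSE],
                           genes = counts$genes,
                           cells = counts$cells[keep],
                           batch = if (is.null(counts$batch)) NULL else
                             counts$batch[keep],
                           smoothed = counts$smoothed)
  summary <- c(retained = sum(keep),
               low_count = sum(flag == "low_count"),
               stressed = sum(flag == "stressed"),
               red_blood_cell = sum(flag == "red_blood_cell"))
  list(retained = retained,
       flags = stats::setNames(flag, qc$cell),
       summary = summary)
}
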