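#' One-sided Fisher enrichment of a gene set in DE genes
#'
#' Tests whether a disease gene list is over-represented among
#' differentially expressed genes within a gene universe. The one-sided
#' (greater) p-value is the hypergeometric upper tail
#' `P(X >= observed overlap)`; genes outside the universe are dropped
#' with a warning.
#'
#' @param de_genes Character vector of DE gene symbols.
#' @param disease_genes Character vector (e.g. a GWAS trait list).
#' @param universe All genes eligible for either set (typically all genes
#'   detected in the expression matrix).
#' @return An `EnrichmentResult`: list with the 2x2 `table` (counts
#'   `de_in_list`, `de_not_list`, `list_not_de`, `neither`), `odds_ratio`
#'   (`Inf` flagged when a margin cell is 0), `p_value`, and
#'   `universe_size`.
#' @export
fisher_enrichment <- function(de_genes, disease_genes, universe) {
  universe <- unique(toupper(universe))
  if (length(universe) == 0L) stopf("empty gene universe")
  de_genes <- unique(toupper(de_genes))
  disease_genes <- unique(toupper(disease_genes))
  drop_de <- setdiff(de_genes, universe)
  drop_dis <- setdiff(disease_genes, universe)
  if (length(drop_de)) {
    warnf("%d DE genes outside the universe dropped", length(drop_de))
  }
  if (length(drop_dis)) {
    warnf("%d disease genes outside the universe dropped", length(drop_dis))
  }
  de_genes <- intersect(de_genes, universe)
  disease_genes <- intersect(disease_genes, universe)
  n11 <- length(intersect(de_genes, disease_genes))
  n12 <- length(de_genes) - n11
  n21 <- length(disease_genes) - n11
  n22 <- length(universe) - n11 - n12 - n21
  # hypergeometric upper tail P(X >= n11)
  p <- phyper(n11 - 1, length(disease_genes),
              length(universe) - length(disease_genes),
              length(de_genes), lower.tail = FALSE)
  or <- if (n12 == 0L || n21 == 0L) {
    if (n11 == 0L) NA_real_ else Inf
  } else {
    (n11 * n22) / (n12 * n21)
  }
  structure(list(table = c(de_in_list = n11, de_not_list = n12,
                           list_not_de = n21, neither = n22),
                 odds_ratio = or, p_value = p,
                 universe_size = length(universe)),
            class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf(paste0("EnrichmentResult: overlap %d of %d DE genes vs ",
                     "%d list genes (universe %d)\n"),
              x$table[["de_in_list"]],
              x$table[["de_in_list"]] + x$table[["de_not_list"]],
              x$table[["de_in_list"]] + x$table[["list_not_de"]],
              x$universe_size))
  cat(sprintf("one-sided p = %.3g, odds ratio = %.3g\n", x$p_value,
              x$odds_ratio))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: the adjusted value of the
#' i-th smallest p is `min over j >= i of p_(j) * m / j`, capped at 1.
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}
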