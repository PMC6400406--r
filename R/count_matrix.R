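#' Construct a UMI count matrix
#'
#' A `CountMatrix` holds a genes x cells matrix of unique molecular
#' identifier (UMI) counts, the raw substrate of every transcriptomic
#' analysis stage. Counts must be nonnegative and, unless the matrix is
#' the output of neighborhood smoothing, integral.
#'
#' @param counts Numeric matrix (genes x cells), dense or `Matrix` sparse.
#' @param genes Character vector of gene symbols (row names). Defaults to
#'   `rownames(counts)`.
#' @param cells Character vector of cell barcodes (column names). Defaults
#'   to `colnames(counts)`.
#' @param batch Optional per-cell batch label (length = number of cells).
#' @param smoothed Logical; `TRUE` for matrices produced by
#'   [knn_smooth()], whose entries are nonnegative reals rather than
#'   integers.
#' @return An object of class `CountMatrix` with fields `genes`, `cells`,
#'   `counts` (a `dgCMatrix`), and optional `batch`.
#' @examples
#' m <- matrix(c(5L, 0L, 0L, 0L, 0L, 2L), nrow = 3)
#' cm <- count_matrix(m, genes = c("A", "B", "C"), cells = c("c1", "c2"))
#' Matrix::colSums(cm$counts)
#' @export
count_matrix <- function(counts, genes = rownames(counts),
                         cells = colnames(counts), batch = NULL,
                         smoothed = FALSE) {
  if (is.null(genes) || is.null(cells)) {
    stopf("gene and cell names are required")
  }
  genes <- as.character(genes)
  cells <- as.character(cells)
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (nrow(counts) != length(genes)) {
    stopf("dimension mismatch: %d matrix rows but %d gene symbols",
          nrow(counts), length(genes))
  }
  if (ncol(counts) != length(cells)) {
    stopf("dimension mismatch: %d matrix columns but %d cell barcodes",
          ncol(counts), length(cells))
  }
  if (anyDuplicated(genes)) {
    stopf("duplicate gene symbols: %s",
          paste(unique(genes[duplicated(genes)])[1:3], collapse = ", "))
  }
  if (anyDuplicated(cells)) {
    stopf("duplicate cell barcodes: %s",
          paste(unique(cells[duplicated(cells)])[1:3], collapse = ", "))
  }
  v <- counts@x
  if (any(!is.finite(v)) || any(v < 0)) {
    stopf("counts must be finite and nonnegative")
  }
  if (!smoothed && any(v != floor(v))) {
    bad <- which(v != floor(v))[1]
    stopf("non-integer count %g found in matrix", v[bad])
  }
  if (!is.null(batch)) {
    if (length(batch) != length(cells)) {
      stopf("`batch` must have one label per cell")
    }
    batch <- as.character(batch)
  }
  dimnames(counts) <- list(genes, cells)
  structure(
    list(genes = genes, cells = cells, counts = counts, batch = batch,
         smoothed = smoothed),
    class = "CountMatrix"
  )
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d genes x %d cells (%s; %d nonzero)\n",
              length(x$genes), length(x$cells),
              if (isTRUE(x$smoothed)) "smoothed" else "raw UMI",
              length(x$counts@x)))
  if (!is.null(x$batch)) {
    cat("batches:", paste(names(table(x$batch)), table(x$batch),
                          sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' Construct an expression matrix
#'
#' An `ExpressionMatrix` holds real-valued genes x cells expression
#' values together with a tag recording which transform produced them.
#'
#' @param values Numeric genes x cells matrix.
#' @param genes,cells Row / column identifiers; default to dimnames.
#' @param transform_tag One of `"raw"`, `"normalized"`,
#'   `"freeman_tukey"`, `"log1p"`.
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, genes = rownames(values),
                              cells = colnames(values),
                              transform_tag = c("raw", "normalized",
                                                "freeman_tukey", "log1p")) {
  transform_tag <- match.arg(transform_tag)
  values <- as.matrix(values)
  if (is.null(genes) || is.null(cells)) stopf("gene and cell names required")
  if (nrow(values) != length(genes) || ncol(values) != length(cells)) {
    stopf("dimension mismatch between values and gene/cell names")
  }
  if (any(!is.finite(values))) stopf("expression values must be finite")
  dimnames(values) <- list(genes, cells)
  structure(
    list(genes = as.character(genes), cells = as.character(cells),
         values = values, transform_tag = transform_tag),
    class = "ExpressionMatrix"
  )
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d cells (%s)\n",
              length(x$genes), length(x$cells), x$transform_tag))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Construct a low-dimensional embedding of cells
#'
#' @param coordinates Numeric cells x components matrix.
#' @param cells Cell barcodes; default `rownames(coordinates)`.
#' @param kind One of `"pca"`, `"corrected_pca"`, `"tsne"`.
#' @return An object of class `EmbeddingMatrix`.
#' @export
embedding_matrix <- function(coordinates, cells = rownames(coordinates),
                             kind = c("pca", "corrected_pca", "tsne")) {
  kind <- match.arg(kind)
  coordinates <- as.matrix(coordinates)
  if (is.null(cells)) stopf("cell names required")
  if (nrow(coordinates) != length(cells)) {
    stopf("coordinates/cells dimension mismatch")
  }
  if (ncol(coordinates) < 1L) stopf("need at least one component")
  if (any(!is.finite(coordinates))) stopf("coordinates must be finite")
  rownames(coordinates) <- cells
  structure(list(cells = as.character(cells), coordinates = coordinates,
                 kind = kind),
            class = "EmbeddingMatrix")
}

#' @export
print.EmbeddingMatrix <- function(x, ...) {
  cat(sprintf("EmbeddingMatrix: %d cells x %d components (%s)\n",
              nrow(x$coordinates), ncol(x$coordinates), x$kind))
  invisible(x)
}

# Coerce a CountMatrix / ExpressionMatrix / plain matrix to a dense
# genes x cells base matrix.
as_dense <- function(x) {
  if (inherits(x, "CountMatrix")) return(as.matrix(x$counts))
  if (inherits(x, "ExpressionMatrix")) return(x$values)
  as.matrix(x)
}
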