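#' Read a UMI count matrix from disk
#'
#' Reads either a MatrixMarket sparse triplet file (the canonical
#' interchange format: genes are rows, cells are columns, 1-based indices
#' on disk) accompanied by `genes.tsv` and `barcodes.tsv`, or a dense CSV
#' with gene symbols in the first column and cell barcodes as header.
#'
#' @param path Path to the `.mtx` file or the CSV file.
#' @param format `"mtx"` or `"csv"`; guessed from the file extension when
#'   missing.
#' @param genes_file,barcodes_file For MTX input, paths to the gene and
#'   barcode annotation files; default to `genes.tsv` / `barcodes.tsv`
#'   next to the matrix.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path, format = NULL,
                              genes_file = NULL, barcodes_file = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (is.null(format)) {
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "csv"
  }
  format <- match.arg(format, c("mtx", "csv"))
  if (format == "mtx") {
    m <- tryCatch(Matrix::readMM(path),
                  error = function(e) stopf("malformed MTX header in %s: %s",
                                            path, conditionMessage(e)))
    if (is.null(genes_file)) genes_file <- file.path(dirname(path), "genes.tsv")
    if (is.null(barcodes_file)) {
      barcodes_file <- file.path(dirname(path), "barcodes.tsv")
    }
    if (!file.exists(genes_file)) stopf("gene file not found: %s", genes_file)
    if (!file.exists(barcodes_file)) {
      stopf("barcode file not found: %s", barcodes_file)
    }
    genes <- read.delim(genes_file, header = FALSE,
                        stringsAsFactors = FALSE)[[1]]
    cells <- read.delim(barcodes_file, header = FALSE,
                        stringsAsFactors = FALSE)[[1]]
    if (nrow(m) != length(genes)) {
      stopf("dimension mismatch: MTX declares %d rows but %s has %d symbols",
            nrow(m), genes_file, length(genes))
    }
    if (ncol(m) != length(cells)) {
      stopf("dimension mismatch: MTX declares %d columns but %s has %d barcodes",
            ncol(m), barcodes_file, length(cells))
    }
    count_matrix(m, genes = genes, cells = cells)
  } else {
    df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    genes <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    count_matrix(m, genes = genes, cells = colnames(df)[-1])
  }
}

#' Write a UMI count matrix to disk
#'
#' @param x A [count_matrix()].
#' @param path For `format = "mtx"`, the output directory (writes
#'   `matrix.mtx`, `genes.tsv`, `barcodes.tsv`); for `"csv"`, the output
#'   file.
#' @param format `"mtx"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path, format = c("mtx", "csv")) {
  stopifnot(inherits(x, "CountMatrix"))
  format <- match.arg(format)
  if (format == "mtx") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(x$counts, file.path(path, "matrix.mtx"))
    writeLines(x$genes, file.path(path, "genes.tsv"))
    writeLines(x$cells, file.path(path, "barcodes.tsv"))
  } else {
    df <- data.frame(gene = x$genes, as.matrix(x$counts),
                     check.names = FALSE)
    colnames(df) <- c("gene", x$cells)
    write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Curated gene-list registry
#'
#' Named lists of gene symbols (mitochondrial, stress markers,
#' hemoglobin, ribosomal, literature markers, proliferation markers,
#' disease GWAS lists) drive the QC filters, HVG exclusions, and scores.
#' Symbols are matched case-insensitively and stored uppercase.
#'
#' @param lists Named list of character vectors of gene symbols.
#' @return An object of class `GeneListRegistry`.
#' @export
gene_list_registry <- function(lists) {
  if (is.null(names(lists)) || any(names(lists) == "")) {
    stopf("all gene lists must be named")
  }
  lists <- lapply(lists, function(v) unique(toupper(as.character(v))))
  structure(lists, class = "GeneListRegistry")
}

#' @export
print.GeneListRegistry <- function(x, ...) {
  cat("GeneListRegistry:\n")
  for (nm in names(x)) cat(sprintf("  %-20s %d genes\n", nm, length(x[[nm]])))
  invisible(x)
}

#' Look up a gene list in a registry
#'
#' @param registry A [gene_list_registry()].
#' @param name List name, e.g. `"mitochondrial"`.
#' @return Character vector of uppercase gene symbols.
#' @export
gene_list <- function(registry, name) {
  stopifnot(inherits(registry, "GeneListRegistry"))
  if (!name %in% names(registry)) {
    stopf("unknown gene list '%s' (available: %s)", name,
          paste(names(registry), collapse = ", "))
  }
  out <- registry[[name]]
  if (length(out) == 0L) stopf("gene list '%s' is empty", name)
  out
}

# Match a gene list against the genes present in a matrix; warns about
# absent symbols (a dataset may simply lack a gene) and returns the
# intersection, preserving matrix naming.
match_gene_list <- function(genes, list_genes, list_name = "gene list") {
  hit <- toupper(genes) %in% toupper(list_genes)
  n_missing <- length(list_genes) - sum(hit)
  if (n_missing > 0L && sum(hit) > 0L) {
    warnf("%d of %d symbols in %s not present in the matrix",
          n_missing, length(list_genes), list_name)
  }
  genes[hit]
}

#' Read gene lists from a CSV or YAML file
#'
#' CSV input needs a list-name column and a symbol column (named `list`
#' and `gene`, or the first two columns). YAML input maps list names to
#' symbol arrays. Symbols are deduplicated and uppercased.
#'
#' @param path Path to the file.
#' @return A [gene_list_registry()].
#' @export
read_gene_lists <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    lists <- yaml::read_yaml(path)
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE)
    cols <- if (all(c("list", "gene") %in% names(df))) {
      df[, c("list", "gene")]
    } else {
      df[, 1:2]
    }
    lists <- split(as.character(cols[[2]]), cols[[1]])
  }
  gene_list_registry(lists)
}

#' Write gene lists to a CSV file
#'
#' @param registry A [gene_list_registry()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_gene_lists <- function(registry, path) {
  stopifnot(inherits(registry, "GeneListRegistry"))
  df <- do.call(rbind, lapply(names(registry), function(nm) {
    data.frame(list = nm, gene = registry[[nm]], stringsAsFactors = FALSE)
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Built-in gene lists for the fetal kidney workflow
#'
#' Returns a registry with the 13 protein-coding mitochondrial genes and
#' the three hemoglobin genes used by the cell filters, a representative
#' set of dissociation-stress immediate-early and heat-shock genes, a
#' representative proliferation marker set, and ribosomal gene symbols.
#' The stress and proliferation lists here are compact representative
#' subsets suitable for synthetic data; analyses of real data should load
#' the full curated lists with [read_gene_lists()].
#'
#' @return A [gene_list_registry()].
#' @export
default_gene_lists <- function() {
  gene_list_registry(list(
    mitochondrial = c("MT-ND1", "MT-ND2", "MT-CO1", "MT-CO2", "MT-ATP8",
                      "MT-ATP6", "MT-CO3", "MT-ND3", "MT-ND4L", "MT-ND4",
                      "MT-ND5", "MT-ND6", "MT-CYB"),
    hemoglobin = c("HBB", "HBA1", "HBA2"),
    stress_markers = c("FOS", "FOSB", "JUN", "JUNB", "JUND", "EGR1", "ATF3",
                       "HSPA1A", "HSPA1B", "HSPA8", "DNAJB1", "ZFP36",
                       "IER2", "IER3", "NR4A1", "DUSP1", "SOCS3", "KLF6",
                       "BTG2", "CYR61"),
    ribosomal = c(paste0("RPS", 1:15), paste0("RPL", 1:15)),
    proliferation_markers = c("MKI67", "CCNB1", "CCNB2", "CDK1", "TOP2A",
                              "BUB1", "PLK1", "AURKA", "UBE2C", "CENPF")
  ))
}

#' Read or write polyline / polygon annotations
#'
#' Annotations (ROI polygons, tubule contours, cross-sections) are stored
#' as JSON: a list of named polylines, each an object with `row` and
#' `col` arrays of 0-based pixel-center coordinates.
#'
#' @param path JSON file path.
#' @return A named list of matrices with columns `row`, `col`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(p) cbind(row = as.numeric(p$row),
                                col = as.numeric(p$col)))
}

#' @rdname read_annotations
#' @param annotations Named list of matrices/data frames with columns
#'   `row`, `col`.
#' @export
write_annotations <- function(annotations, path) {
  out <- lapply(annotations, function(p) {
    p <- as.matrix(p)
    list(row = unname(p[, "row"]), col = unname(p[, "col"]))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write single-channel TIFF images
#'
#' Images are real matrices indexed `[row, col]`. On write, values are
#' stored as 32-bit float samples; intensities should be scaled to
#' `[0, 1]` beforehand (see `scale`).
#'
#' @param path TIFF file path.
#' @return `read_image`: a numeric matrix.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img
}

#' @rdname read_image
#' @param image Numeric matrix.
#' @param scale Logical; divide by the image maximum before writing
#'   (default `TRUE`). The scale factor is not stored.
#' @export
write_image <- function(image, path, scale = TRUE) {
  image <- as.matrix(image)
  if (scale && max(image) > 0) image <- image / max(image)
  image[image < 0] <- 0
  image[image > 1] <- 1
  tiff::writeTIFF(image, path, bits.per.sample = 32L)
  invisible(path)
}
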