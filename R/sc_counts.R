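# A light container for a sparse gene-by-cell count matrix with per-gene
# category flags. Gene categories follow human nomenclature: mitochondrial
# genes are named "MT-*", cytosolic ribosomal genes "RPL*"/"RPS*" (both
# case-insensitive). Mitochondrial-ribosomal MRP* genes match neither.

#' Construct a gene-by-cell counts object
#'
#' Wraps a sparse (or dense) gene-by-cell matrix with row names as gene
#' symbols, deriving mitochondrial and ribosomal flags from the names.
#'
#' @param counts A matrix or `Matrix::sparseMatrix` with genes as rows
#'   (row names required) and cells as columns.
#' @param cell_class Optional character vector of planted per-cell quality
#'   classes (kept as ground truth by the synthetic generator).
#' @return An object of class `sc_counts` with elements `counts` (a
#'   `dgCMatrix`), `genes` (tibble: `gene`, `is_mito`, `is_ribo`) and `cells`
#'   (tibble: `cell_id`, optional `class`).
#' @export
sc_counts <- function(counts, cell_class = NULL) {
  if (is.null(rownames(counts)) && nrow(counts) > 0) {
    abort("`counts` must have gene symbols as row names.")
  }
  m <- Matrix::Matrix(counts, sparse = TRUE)
  m <- as(as(m, "CsparseMatrix"), "generalMatrix")
  genes <- tibble(
    gene = rownames(m),
    is_mito = grepl("^MT-", rownames(m), ignore.case = TRUE),
    is_ribo = grepl("^RP[LS]", rownames(m), ignore.case = TRUE)
  )
  cell_id <- colnames(m) %||% as.character(seq_len(ncol(m)))
  cells <- tibble(cell_id = cell_id)
  if (!is.null(cell_class)) {
    if (length(cell_class) != ncol(m)) {
      abort(sprintf("`cell_class` has length %d but the matrix has %d cells.",
                    length(cell_class), ncol(m)))
    }
    cells$class <- cell_class
  }
  structure(list(counts = m, genes = genes, cells = cells),
            class = "sc_counts")
}

#' @export
print.sc_counts <- function(x, ...) {
  cat(sprintf(
    "<sc_counts> %d genes x %d cells (%d mitochondrial, %d ribosomal genes)\n",
    nrow(x$counts), ncol(x$counts), sum(x$genes$is_mito), sum(x$genes$is_ribo)
  ))
  invisible(x)
}

#' @export
dim.sc_counts <- function(x) dim(x$counts)

# Accept either an sc_counts or a bare named matrix in the QC verbs.
as_sc_counts <- function(x) {
  if (inherits(x, "sc_counts")) x else sc_counts(x)
}
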