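# Readers and writers for the plain-text formats the pipeline touches:
# TSV/CSV cell tables, Matrix Market counts with genes/barcodes sidecars,
# and YAML configurations.

default_bindings <- function() {
  list(cell_id = "cell_id", sample_id = "sample_id",
       condition = "condition", cluster = "cluster")
}

#' Read a cell-level table from delimited text
#'
#' Reads a TSV (or CSV) with a header, validates that the bound columns are
#' present, and renames them to the package's canonical names (`cell_id`,
#' `sample_id`, `condition`, `cluster`) so external atlases with their own
#' metadata headers can be analysed without editing files. Unbound columns
#' are preserved as-is. An empty file yields an empty table.
#'
#' @param path File path.
#' @param bindings Named list mapping canonical names to the file's column
#'   names; bindings set to `NULL` are not required (e.g. tables without a
#'   cluster column).
#' @param delim Field delimiter (default tab; use `","` for CSV).
#' @return A tibble.
#' @export
read_cell_table <- function(path, bindings = default_bindings(),
                            delim = "\t") {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (file.size(path) == 0) {
    out <- tibble::tibble()
    for (nm in names(bindings)) out[[nm]] <- character()
    return(out)
  }
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  bindings <- bindings[!vapply(bindings, is.null, logical(1))]
  missing <- setdiff(unlist(bindings), names(tab))
  if (length(missing) > 0) {
    abort(sprintf("Bound column%s not found in %s: %s",
                  if (length(missing) > 1) "s" else "", path,
                  paste(missing, collapse = ", ")))
  }
  for (canon in names(bindings)) {
    names(tab)[names(tab) == bindings[[canon]]] <- canon
  }
  if ("cell_id" %in% names(tab) && anyDuplicated(tab$cell_id)) {
    abort(sprintf("Duplicate cell ids in %s (e.g. %s).", path,
                  tab$cell_id[anyDuplicated(tab$cell_id)][1]))
  }
  tab
}

#' Write a cell-level table as TSV
#'
#' @param cells A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  readr::write_tsv(as_tibble(cells), path, progress = FALSE)
  invisible(path)
}

#' Read sparse counts in Matrix Market format with sidecars
#'
#' Expects the conventional triplet layout: a coordinate-format `.mtx` file,
#' a genes file (first column = gene symbol) and a barcodes file, one entry
#' per line, matching the matrix dimensions.
#'
#' @param mtx,genes,barcodes File paths.
#' @return An [sc_counts] object.
#' @export
read_count_matrix <- function(mtx, genes, barcodes) {
  m <- as(Matrix::readMM(mtx), "CsparseMatrix")
  gtab <- readr::read_tsv(genes, col_names = FALSE, show_col_types = FALSE,
                          progress = FALSE)
  gene_names <- as.character(gtab[[1]])
  bc <- readr::read_tsv(barcodes, col_names = FALSE, show_col_types = FALSE,
                        progress = FALSE)[[1]]
  if (length(gene_names) != nrow(m)) {
    abort(sprintf("Gene sidecar has %d entries but the matrix has %d rows.",
                  length(gene_names), nrow(m)))
  }
  if (length(bc) != ncol(m)) {
    abort(sprintf("Barcode sidecar has %d entries but the matrix has %d columns.",
                  length(bc), ncol(m)))
  }
  dimnames(m) <- list(gene_names, as.character(bc))
  sc_counts(m)
}

#' Write sparse counts as Matrix Market plus genes/barcodes sidecars
#'
#' @param counts An [sc_counts] object or a gene-by-cell matrix with
#'   dimnames.
#' @param dir Output directory (created if needed); files `matrix.mtx`,
#'   `genes.tsv`, `barcodes.tsv` are written inside it.
#' @return The three paths, invisibly.
#' @export
write_count_matrix <- function(counts, dir) {
  x <- as_sc_counts(counts)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("matrix.mtx", "genes.tsv", "barcodes.tsv"))
  Matrix::writeMM(x$counts, paths[1])
  writeLines(x$genes$gene, paths[2])
  writeLines(x$cells$cell_id, paths[3])
  invisible(paths)
}

#' Read an analysis configuration from YAML
#'
#' Parses the pipeline configuration (see [run_pipeline()]) and normalises
#' it: the simulation block becomes a [composition_spec()] (plus optional
#' [gene_model()]), QC thresholds a [qc_thresholds()], and stratification
#' rules [stratification_rule()] objects (the names `creatinine`, `egfr`,
#' `age`, `sex` select the built-ins).
#'
#' @param path YAML file path.
#' @return An `analysis_config` list.
#' @export
read_analysis_config <- function(path) {
  raw <- yaml::read_yaml(path)
  analysis_config(
    seed = raw$seed %||% 1L,
    simulate = raw$simulate,
    qc = raw$qc,
    stratify = raw$stratify,
    dpa = raw$dpa,
    cells_path = raw$cells_path,
    out_dir = raw$out_dir,
    quiet = isTRUE(raw$quiet)
  )
}

#' Assemble an analysis configuration
#'
#' @param seed Master seed; all stage seeds derive from it via
#'   [child_seed()].
#' @param simulate `NULL`, or a list accepted by [composition_spec()]
#'   (optionally with a `gene_model` sub-list and a logical
#'   `clinical`, default `TRUE`), or a ready `composition_spec`.
#' @param qc `NULL`/`FALSE` to skip, `TRUE` or a list of
#'   [qc_thresholds()] arguments (plus optional logical
#'   `drop_ribosomal`, default `TRUE`).
#' @param stratify Character vector of built-in rule names and/or a list of
#'   [stratification_rule()] objects.
#' @param dpa A list of [dpa_test()] arguments (`w`, `iterations`, `alpha`,
#'   `group_col`, ...).
#' @param cells_path Optional path of an existing cell table (instead of
#'   simulation).
#' @param out_dir Output directory for [run_pipeline()].
#' @param quiet Suppress progress messages.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(seed = 1L, simulate = NULL, qc = NULL,
                            stratify = NULL, dpa = list(),
                            cells_path = NULL, out_dir = NULL,
                            quiet = FALSE) {
  if (is.null(simulate) && is.null(cells_path)) {
    abort("Provide either a `simulate` block or a `cells_path`.")
  }
  structure(
    list(seed = as.integer(seed), simulate = simulate, qc = qc,
         stratify = stratify, dpa = dpa, cells_path = cells_path,
         out_dir = out_dir, quiet = quiet),
    class = "analysis_config"
  )
}

#' Write an analysis configuration as YAML
#'
#' Round-trips through [read_analysis_config()]; only plain-list
#' configurations (as read from YAML) serialise losslessly.
#'
#' @param config An `analysis_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_analysis_config <- function(config, path) {
  plain <- unclass(config)
  plain$quiet <- isTRUE(plain$quiet)
  yaml::write_yaml(plain, path)
  invisible(path)
}
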