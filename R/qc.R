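# Per-cell QC metrics, threshold filtering, ribosomal-gene removal and the
# expressed-gene background rule.

#' QC filtering thresholds
#'
#' A cell is retained iff `n_features > min_features` AND
#' `n_counts < max_counts` AND `pct_mito < max_mito_pct`. All three
#' inequalities are strict, so boundary cells (exactly 200 features, exactly
#' 12,000 counts, exactly 30% mitochondrial) are removed.
#'
#' @param min_features Detected-gene floor (default 200, exclusive).
#' @param max_counts Total-count ceiling (default 12,000, exclusive).
#' @param max_mito_pct Mitochondrial percentage ceiling (default 30, exclusive).
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_features = 200, max_counts = 12000,
                          max_mito_pct = 30) {
  check_scalar_number(min_features, "min_features", lower = 0)
  check_scalar_number(max_counts, "max_counts", lower = min_features,
                      lower_open = TRUE)
  check_scalar_number(max_mito_pct, "max_mito_pct", lower = 0, upper = 100)
  structure(list(min_features = min_features, max_counts = max_counts,
                 max_mito_pct = max_mito_pct),
            class = "qc_thresholds")
}

#' @export
print.qc_thresholds <- function(x, ...) {
  cat(sprintf(
    "<qc_thresholds> keep iff n_features > %g & n_counts < %g & pct_mito < %g\n",
    x$min_features, x$max_counts, x$max_mito_pct
  ))
  invisible(x)
}

#' Compute per-cell QC metrics from a count matrix
#'
#' For each cell: `n_counts` (total counts), `n_features` (genes with a
#' non-zero count) and `pct_mito` (100 x mitochondrial counts / total counts;
#' defined as 0 for cells with zero total counts, so an empty cell cannot be
#' rescued by the mitochondrial rule — it fails the feature floor anyway).
#' Metrics are computed on the matrix as given; apply
#' [remove_ribosomal_genes()] afterwards if ribosome-free downstream input is
#' wanted with metrics still reflecting the raw matrix.
#'
#' @param counts An [sc_counts] object or a gene-by-cell matrix with gene
#'   symbols as row names.
#' @return A tibble with columns `cell_id`, `n_counts`, `n_features`,
#'   `pct_mito` (plus `class` when the matrix carries planted classes).
#' @export
#' @examples
#' m <- matrix(c(5, 5, 0, 0, 3, 1), nrow = 3,
#'             dimnames = list(c("MT-ND1", "ACTB", "RPL3"), c("c1", "c2")))
#' compute_qc_metrics(m)
compute_qc_metrics <- function(counts) {
  x <- as_sc_counts(counts)
  m <- x$counts
  if (ncol(m) == 0) {
    out <- tibble(cell_id = character(), n_counts = numeric(),
                  n_features = integer(), pct_mito = numeric())
    return(out)
  }
  total <- Matrix::colSums(m)
  feats <- Matrix::colSums(m > 0)
  mito <- if (any(x$genes$is_mito)) {
    Matrix::colSums(m[x$genes$is_mito, , drop = FALSE])
  } else {
    rep(0, ncol(m))
  }
  out <- tibble(
    cell_id = x$cells$cell_id,
    n_counts = as.numeric(unname(total)),
    n_features = as.integer(unname(feats)),
    pct_mito = unname(ifelse(total > 0, 100 * mito / total, 0))
  )
  if ("class" %in% names(x$cells)) out$class <- x$cells$class
  out
}

#' Filter cells on QC metrics
#'
#' Applies the strict-inequality retention rule of [qc_thresholds()] to a
#' cell table carrying QC metric columns. The removal report (counts per
#' rule, overlaps between rules, and totals) is attached as the
#' `"qc_removal"` attribute and retrievable with [qc_removal_report()].
#' Filtering is idempotent: filtering an already-filtered table removes
#' nothing.
#'
#' @param cells A data frame with columns `n_features`, `n_counts`,
#'   `pct_mito` (as from [compute_qc_metrics()], possibly joined to more
#'   metadata).
#' @param thresholds A [qc_thresholds()].
#' @return The retained rows of `cells`, with the removal report attached.
#' @export
filter_cells <- function(cells, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  check_columns(cells, c("n_features", "n_counts", "pct_mito"), "cell table")
  fail_features <- !(cells$n_features > thresholds$min_features)
  fail_counts <- !(cells$n_counts < thresholds$max_counts)
  fail_mito <- !(cells$pct_mito < thresholds$max_mito_pct)
  keep <- !(fail_features | fail_counts | fail_mito)
  fails <- cbind(low_features = fail_features, high_counts = fail_counts,
                 high_mito = fail_mito)
  overlap <- as_tibble(as.data.frame(table(
    low_features = fail_features, high_counts = fail_counts,
    high_mito = fail_mito
  )))
  names(overlap)[4] <- "n_cells"
  overlap <- overlap[overlap$n_cells > 0, , drop = FALSE]
  report <- list(
    n_input = nrow(cells),
    n_retained = sum(keep),
    n_removed = sum(!keep),
    per_rule = tibble(
      rule = colnames(fails),
      threshold = c(thresholds$min_features, thresholds$max_counts,
                    thresholds$max_mito_pct),
      n_removed = as.integer(colSums(fails))
    ),
    overlap = overlap
  )
  out <- cells[keep, , drop = FALSE]
  attr(out, "qc_removal") <- report
  out
}

#' Retrieve the removal report attached by [filter_cells()]
#'
#' @param cells The table returned by [filter_cells()].
#' @return A list with `n_input`, `n_retained`, `n_removed`, the per-rule
#'   removal counts, and the overlap table of failure patterns.
#' @export
qc_removal_report <- function(cells) {
  rep <- attr(cells, "qc_removal")
  if (is.null(rep)) abort("No removal report: was this table filtered?")
  rep
}

#' Drop ribosomal genes from a count matrix
#'
#' Removes genes whose names begin with `RPL` or `RPS` (case-insensitive);
#' these dominate library composition and distort downstream clustering.
#' Mitochondrial-ribosomal `MRP*` genes are kept. Cells and the counts of
#' remaining genes are unchanged.
#'
#' @param counts An [sc_counts] object or gene-by-cell matrix with row names.
#' @return The same type of object without ribosomal genes.
#' @export
remove_ribosomal_genes <- function(counts) {
  x <- as_sc_counts(counts)
  keep <- !x$genes$is_ribo
  m <- x$counts[keep, , drop = FALSE]
  if (is.null(rownames(m))) rownames(m) <- character(nrow(m))
  out <- sc_counts(m, cell_class = x$cells[["class"]])
  if (inherits(counts, "sc_counts")) out else out$counts
}

#' Per-group expressed-gene background sets
#'
#' A gene counts as expressed in a group when it has a non-zero value in at
#' least `min_fraction` of the group's cells (inclusive threshold: non-zero
#' in exactly 10% of cells qualifies at the default).
#'
#' @param counts An [sc_counts] object or gene-by-cell matrix.
#' @param groups Per-cell group labels (e.g. cell types), length = number of
#'   cells. An empty group (possible with factor levels) yields no rows and a
#'   warning.
#' @param min_fraction Inclusive expression threshold in \[0, 1\]
#'   (default 0.1).
#' @return A tibble with columns `group`, `gene`, `n_nonzero`, `n_cells`,
#'   `fraction`, one row per (group, expressed gene).
#' @export
expressed_genes <- function(counts, groups, min_fraction = 0.1) {
  x <- as_sc_counts(counts)
  m <- x$counts
  if (length(groups) != ncol(m)) {
    abort(sprintf("`groups` has length %d but the matrix has %d cells.",
                  length(groups), ncol(m)))
  }
  check_scalar_number(min_fraction, "min_fraction", lower = 0, upper = 1)
  groups <- as.factor(groups)
  out <- list()
  for (g in levels(groups)) {
    idx <- which(groups == g)
    if (length(idx) == 0) {
      warn(sprintf("Group '%s' has no cells; its expressed set is empty.", g))
      next
    }
    nz <- Matrix::rowSums(m[, idx, drop = FALSE] > 0)
    frac <- nz / length(idx)
    sel <- frac >= min_fraction
    if (any(sel)) {
      out[[g]] <- tibble(group = g, gene = rownames(m)[sel],
                         n_nonzero = as.integer(unname(nz[sel])),
                         n_cells = length(idx),
                         fraction = unname(frac[sel]))
    }
  }
  if (length(out) == 0) {
    return(tibble(group = character(), gene = character(),
                  n_nonzero = integer(), n_cells = integer(),
                  fraction = numeric()))
  }
  bind_rows(out)
}
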