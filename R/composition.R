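# Cluster-by-group proportion tables, the per-cluster difference statistic,
# and clinical stratification of samples into comparison groups.

#' Cluster proportions per group
#'
#' Pools cells within each group and computes, for every cluster, its share
#' of the group's cells. Clusters absent from a group get proportion 0, so
#' every group's proportions sum to 1 exactly over the common cluster set.
#' For per-sample diagnostic proportions, pass the sample column as
#' `group_col`.
#'
#' @param cells A data frame with one row per cell.
#' @param group_col Name of the grouping column (default `"condition"`).
#' @param cluster_col Name of the cluster-label column (default `"cluster"`).
#' @return A tibble of class `proportion_table` with columns `cluster`,
#'   `group`, `n_cells`, `proportion`.
#' @export
#' @examples
#' cells <- tibble::tibble(
#'   condition = rep(c("A", "B"), c(100, 100)),
#'   cluster = c(rep(c("x", "y"), c(30, 70)), rep(c("x", "y"), c(50, 50)))
#' )
#' cluster_proportions(cells)
cluster_proportions <- function(cells, group_col = "condition",
                                cluster_col = "cluster") {
  check_columns(cells, c(group_col, cluster_col), "cell table")
  if (nrow(cells) == 0) abort("The cell table is empty.")
  g <- cells[[group_col]]
  cl <- cells[[cluster_col]]
  if (anyNA(g) || anyNA(cl)) {
    abort("Every cell needs non-missing group and cluster labels.")
  }
  g <- as.factor(g)
  empty_groups <- levels(g)[tabulate(g, nlevels(g)) == 0]
  if (length(empty_groups) > 0) {
    abort(sprintf("Group%s with zero cells: %s",
                  if (length(empty_groups) > 1) "s" else "",
                  paste(empty_groups, collapse = ", ")))
  }
  cl <- as.factor(cl)
  unused <- levels(cl)[tabulate(cl, nlevels(cl)) == 0]
  if (length(unused) > 0) {
    warn(sprintf("Dropping cluster level%s with zero cells in every group: %s",
                 if (length(unused) > 1) "s" else "",
                 paste(unused, collapse = ", ")))
    cl <- droplevels(cl)
  }
  counts <- table(cluster = cl, group = g)
  props <- sweep(counts, 2, colSums(counts), "/")
  out <- as_tibble(as.data.frame(counts, stringsAsFactors = FALSE))
  names(out)[3] <- "n_cells"
  out$proportion <- as.vector(props)
  out <- arrange(out, .data$group, .data$cluster)
  structure(out, class = c("proportion_table", class(out)),
            groups = levels(g), clusters = levels(cl))
}

#' Per-cluster proportion-difference statistic
#'
#' For each cluster c, the statistic is T_c = p_c(test) - p_c(reference),
#' the difference between the cluster's share of cells in the test group and
#' in the reference group. Because both columns sum to 1, the statistics sum
#' to 0.
#'
#' @param props A [cluster_proportions()] table.
#' @param reference,test Group labels to compare; default to the first and
#'   second group present.
#' @return A tibble with columns `cluster`, `n_ref`, `n_test`, `prop_ref`,
#'   `prop_test`, `statistic`.
#' @export
proportion_difference <- function(props, reference = NULL, test = NULL) {
  groups <- attr(props, "groups") %||% unique(props$group)
  reference <- reference %||% groups[1]
  test <- test %||% setdiff(groups, reference)[1]
  for (gname in c(reference, test)) {
    if (!gname %in% groups) {
      abort(sprintf("Unknown group '%s' (available: %s).", gname,
                    paste(groups, collapse = ", ")))
    }
  }
  ref <- props[props$group == reference, ]
  tst <- props[props$group == test, ]
  ref <- ref[order(ref$cluster), ]
  tst <- tst[order(tst$cluster), ]
  tibble(
    cluster = ref$cluster,
    n_ref = ref$n_cells,
    n_test = tst$n_cells,
    prop_ref = ref$proportion,
    prop_test = tst$proportion,
    statistic = tst$proportion - ref$proportion
  )
}

#' Define a clinical stratification rule
#'
#' Splits samples into ordered strata of a numeric covariate at one or more
#' thresholds, or groups them by a categorical covariate as-is. For each
#' threshold, `boundary` records which side a value exactly equal to the
#' threshold joins: `"upper"` assigns equality to the stratum above the
#' threshold, `"lower"` to the stratum below.
#'
#' @param covariate Covariate column name in the clinical table.
#' @param kind `"threshold"` (ordered numeric strata) or `"category"`.
#' @param thresholds Strictly increasing numeric cut points (threshold kind).
#' @param labels Stratum labels, one more than the number of thresholds
#'   (threshold kind), ordered from lowest to highest stratum.
#' @param boundary `"upper"` or `"lower"` per threshold (recycled).
#' @return An object of class `stratification_rule`.
#' @export
#' @seealso [rule_creatinine()], [rule_egfr()], [rule_age()], [rule_sex()]
stratification_rule <- function(covariate, kind = c("threshold", "category"),
                                thresholds = numeric(), labels = character(),
                                boundary = "upper") {
  kind <- match.arg(kind)
  if (kind == "threshold") {
    if (length(thresholds) < 1 || is.unsorted(thresholds, strictly = TRUE)) {
      abort("`thresholds` must be strictly increasing and non-empty.")
    }
    if (length(labels) != length(thresholds) + 1) {
      abort("Need exactly one label per stratum (thresholds + 1).")
    }
    boundary <- rep(boundary, length.out = length(thresholds))
    if (!all(boundary %in% c("upper", "lower"))) {
      abort("`boundary` entries must be 'upper' or 'lower'.")
    }
  }
  structure(list(covariate = covariate, kind = kind,
                 thresholds = thresholds, labels = as.character(labels),
                 boundary = boundary),
            class = "stratification_rule")
}

#' Built-in clinical stratification rules
#'
#' Conventions for the kidney-function covariates: serum creatinine splits at
#' 140 uM with equality assigned to the `"impaired"` (upper) side; eGFR
#' splits at 60 mL/min/1.73m2 with equality assigned to the `"normal"`
#' (upper) side; age splits into young (< 30), adult (30-60, inclusive at
#' both ends) and elderly (> 60); sex is taken as given. Boundary
#' conventions are configurable through [stratification_rule()].
#'
#' @return A [stratification_rule()].
#' @export
rule_creatinine <- function() {
  stratification_rule("creatinine", "threshold", thresholds = 140,
                      labels = c("normal", "impaired"), boundary = "upper")
}

#' @rdname rule_creatinine
#' @export
rule_egfr <- function() {
  stratification_rule("egfr", "threshold", thresholds = 60,
                      labels = c("impaired", "normal"), boundary = "upper")
}

#' @rdname rule_creatinine
#' @export
rule_age <- function() {
  stratification_rule("age", "threshold", thresholds = c(30, 60),
                      labels = c("young", "adult", "elderly"),
                      boundary = c("upper", "lower"))
}

#' @rdname rule_creatinine
#' @export
rule_sex <- function() {
  stratification_rule("sex", "category")
}

#' Apply a stratification rule to covariate values
#'
#' @param rule A [stratification_rule()].
#' @param values Covariate values.
#' @return A character vector of stratum labels.
#' @export
#' @examples
#' apply_stratification_rule(rule_creatinine(), c(139.9, 140, 140.1))
apply_stratification_rule <- function(rule, values) {
  stopifnot(inherits(rule, "stratification_rule"))
  if (rule$kind == "category") {
    return(as.character(values))
  }
  if (anyNA(values)) abort("Covariate values must be non-missing.")
  idx <- rep(1L, length(values))
  for (j in seq_along(rule$thresholds)) {
    t <- rule$thresholds[j]
    above <- values > t | (values == t & rule$boundary[j] == "upper")
    idx <- idx + above
  }
  rule$labels[idx]
}

#' Stratify cells by a clinical covariate of their sample
#'
#' Assigns each sample to a stratum via `rule` applied to the clinical table,
#' then gives every cell its sample's stratum in a new column, producing the
#' two-group (or multi-group) labels used by downstream proportion tests.
#'
#' @param cells A cell table with a `sample_id` column.
#' @param clinical A per-sample covariate table (`sample_id` + covariates),
#'   as from [simulate_clinical()].
#' @param rule A [stratification_rule()].
#' @param group_col Name of the new column (default `"<covariate>_group"`).
#' @return `cells` with the stratum column added.
#' @export
stratify <- function(cells, clinical, rule,
                     group_col = paste0(rule$covariate, "_group")) {
  stopifnot(inherits(rule, "stratification_rule"))
  check_columns(cells, "sample_id", "cell table")
  check_columns(clinical, c("sample_id", rule$covariate), "clinical table")
  missing_samp <- setdiff(unique(cells$sample_id), clinical$sample_id)
  vals <- clinical[[rule$covariate]]
  bad <- clinical$sample_id[is.na(vals)]
  missing_samp <- union(missing_samp, intersect(bad, cells$sample_id))
  if (length(missing_samp) > 0) {
    abort(sprintf("Covariate '%s' missing for sample%s: %s", rule$covariate,
                  if (length(missing_samp) > 1) "s" else "",
                  paste(sort(missing_samp), collapse = ", ")))
  }
  strata <- tibble(
    sample_id = clinical$sample_id,
    stratum = apply_stratification_rule(rule, vals)
  )
  names(strata)[2] <- group_col
  out <- left_join(as_tibble(cells), strata, by = "sample_id")
  out
}
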