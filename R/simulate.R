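# Synthetic cohort generator: planted cluster compositions, sparse counts
# with QC structure, and clinical covariates correlated with condition.

#' Specify a synthetic cell-composition scenario
#'
#' Describes a two-or-more-condition cohort as a Dirichlet-multinomial
#' hierarchy: each condition has a cluster composition obtained by multiplying
#' a shared baseline simplex by per-condition effect multipliers and
#' renormalising; each sample draws its own composition from a Dirichlet
#' centred on its condition's composition (concentration controls
#' between-sample overdispersion), and cells draw cluster labels
#' multinomially from the sample composition.
#'
#' The first condition is the reference: its multipliers are fixed to 1.
#' A multiplier of exactly 0 removes the cluster from that condition.
#'
#' @param cluster_names Character vector of cluster labels.
#' @param baseline_proportions Numeric simplex over clusters (sums to 1
#'   within 1e-12).
#' @param effect_multipliers Per-condition non-negative multipliers: a named
#'   list mapping each non-reference condition to a numeric vector over
#'   clusters, or a single numeric vector when there are exactly two
#'   conditions. `NULL` means no planted shift (all ones).
#' @param conditions Character vector of condition labels; the first is the
#'   reference (default `c("normal", "CKD")`).
#' @param n_samples_per_condition Integer vector, one entry per condition
#'   (default `c(42, 23)`, the cohort split the generator emulates).
#' @param cells_per_sample A single positive integer, or a length-2 range
#'   `c(min, max)` from which each sample's cell count is drawn uniformly.
#'   Zero is allowed and yields an empty table.
#' @param dirichlet_concentration Positive scalar; larger values mean samples
#'   track their condition composition more tightly (default 200, moderate
#'   overdispersion).
#' @param seed Integer master seed stored with the scenario.
#' @return An object of class `composition_spec`.
#' @export
#' @examples
#' spec <- composition_spec(
#'   cluster_names = c("NK", "Tnaive", "Mono"),
#'   baseline_proportions = c(0.2, 0.3, 0.5),
#'   effect_multipliers = c(0.3, 2, 1)
#' )
#' spec
composition_spec <- function(cluster_names,
                             baseline_proportions,
                             effect_multipliers = NULL,
                             conditions = c("normal", "CKD"),
                             n_samples_per_condition = c(42L, 23L),
                             cells_per_sample = 500L,
                             dirichlet_concentration = 200,
                             seed = 1L) {
  cluster_names <- as.character(cluster_names)
  k <- length(cluster_names)
  if (k < 1 || anyDuplicated(cluster_names)) {
    abort("`cluster_names` must be a non-empty vector of unique labels.")
  }
  if (length(baseline_proportions) != k) {
    abort("`baseline_proportions` must have one entry per cluster.")
  }
  if (any(baseline_proportions < 0) ||
      abs(sum(baseline_proportions) - 1) > 1e-12) {
    abort("`baseline_proportions` must be non-negative and sum to 1 within 1e-12.")
  }
  conditions <- as.character(conditions)
  if (length(conditions) < 2 || anyDuplicated(conditions)) {
    abort("`conditions` must contain at least two unique labels.")
  }
  if (length(n_samples_per_condition) != length(conditions) ||
      any(n_samples_per_condition < 1)) {
    abort("`n_samples_per_condition` needs one positive entry per condition.")
  }
  mult <- matrix(1, nrow = k, ncol = length(conditions),
                 dimnames = list(cluster_names, conditions))
  if (!is.null(effect_multipliers)) {
    if (is.numeric(effect_multipliers) && length(conditions) == 2) {
      effect_multipliers <- setNames(list(effect_multipliers), conditions[2])
    }
    if (!is.list(effect_multipliers) ||
        !all(names(effect_multipliers) %in% conditions[-1])) {
      abort("`effect_multipliers` must name non-reference conditions only.")
    }
    for (cond in names(effect_multipliers)) {
      m <- effect_multipliers[[cond]]
      if (length(m) != k || any(m < 0) || any(!is.finite(m))) {
        abort("Effect multipliers must be finite, non-negative, one per cluster.")
      }
      mult[, cond] <- m
    }
  }
  if (length(cells_per_sample) == 1) {
    cells_per_sample <- rep(cells_per_sample, 2)
  }
  if (length(cells_per_sample) != 2 || any(cells_per_sample < 0) ||
      cells_per_sample[1] > cells_per_sample[2]) {
    abort("`cells_per_sample` must be a count or an increasing range c(min, max).")
  }
  check_scalar_number(dirichlet_concentration, "dirichlet_concentration",
                      lower = 0, lower_open = TRUE)
  structure(
    list(
      cluster_names = cluster_names,
      baseline_proportions = as.numeric(baseline_proportions),
      effect_multipliers = mult,
      conditions = conditions,
      n_samples_per_condition = as.integer(n_samples_per_condition),
      cells_per_sample = as.integer(cells_per_sample),
      dirichlet_concentration = dirichlet_concentration,
      seed = as.integer(seed)
    ),
    class = "composition_spec"
  )
}

#' @export
print.composition_spec <- function(x, ...) {
  cat("<composition_spec>\n")
  cat("  clusters:   ", paste(x$cluster_names, collapse = ", "), "\n")
  cat("  conditions: ",
      paste(sprintf("%s (n=%d)", x$conditions, x$n_samples_per_condition),
            collapse = ", "), "\n")
  cat("  cells/sample:", paste(unique(x$cells_per_sample), collapse = "-"),
      " concentration:", x$dirichlet_concentration, " seed:", x$seed, "\n")
  print(round(condition_proportions(x), 4))
  invisible(x)
}

#' Planted per-condition cluster compositions
#'
#' Baseline proportions multiplied by each condition's effect multipliers and
#' renormalised to the simplex.
#'
#' @param spec A [composition_spec()].
#' @return A cluster-by-condition matrix whose columns sum to 1.
#' @export
condition_proportions <- function(spec) {
  stopifnot(inherits(spec, "composition_spec"))
  p <- spec$baseline_proportions * spec$effect_multipliers
  sweep(p, 2, colSums(p), "/")
}

#' Simulate a cell-level table from a composition scenario
#'
#' Draws, for every sample, a composition from a Dirichlet centred on its
#' condition's planted composition, then cluster labels multinomially for the
#' sample's cells. The output is the cell table consumed by the proportion
#' and differential-proportion stages: one row per cell with `cell_id`,
#' `sample_id`, `condition` and `cluster`.
#'
#' @param spec A [composition_spec()].
#' @param seed Integer seed; defaults to `child_seed(spec$seed, "cells")`.
#' @return A tibble with one row per cell.
#' @export
#' @examples
#' spec <- composition_spec(c("A", "B"), c(0.4, 0.6),
#'                          n_samples_per_condition = c(3, 2),
#'                          cells_per_sample = 50)
#' cells <- simulate_cell_table(spec)
#' dplyr::count(cells, condition, cluster)
simulate_cell_table <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "composition_spec"))
  seed <- seed %||% child_seed(spec$seed, "cells")
  cond_props <- condition_proportions(spec)
  k <- length(spec$cluster_names)
  with_seed(seed, {
    rows <- list()
    for (ci in seq_along(spec$conditions)) {
      cond <- spec$conditions[ci]
      n_samp <- spec$n_samples_per_condition[ci]
      alpha <- spec$dirichlet_concentration * cond_props[, ci]
      for (si in seq_len(n_samp)) {
        sample_id <- sprintf("%s_s%02d", cond, si)
        n_cells <- if (spec$cells_per_sample[1] == spec$cells_per_sample[2]) {
          spec$cells_per_sample[1]
        } else {
          sample(spec$cells_per_sample[1]:spec$cells_per_sample[2], 1)
        }
        if (n_cells == 0) next
        props <- rdirichlet1(alpha)
        counts <- as.vector(rmultinom(1, n_cells, props))
        rows[[length(rows) + 1]] <- tibble(
          sample_id = sample_id,
          condition = cond,
          cluster = rep(spec$cluster_names, counts)
        )
      }
    }
    out <- if (length(rows) == 0) {
      tibble(sample_id = character(), condition = character(),
             cluster = character())
    } else {
      bind_rows(rows)
    }
    out$cell_id <- if (nrow(out) > 0) {
      paste0(out$sample_id, "_c", stats::ave(seq_len(nrow(out)), out$sample_id,
                                             FUN = seq_along))
    } else {
      character()
    }
    out[, c("cell_id", "sample_id", "condition", "cluster")]
  })
}

#' Specify the gene-level generative model for synthetic counts
#'
#' Counts are generated as negative binomial per-cell totals allocated
#' multinomially across genes; the mitochondrial share of each cell's total is
#' binomially thinned toward its class's target fraction. Cells belong to one
#' of two classes: `healthy`, and `low_quality` cells whose expected totals
#' sit below the detected-gene floor used by QC filtering (damaged or empty
#' droplets).
#'
#' Gene names follow human nomenclature conventions consumed by the QC stage:
#' mitochondrial genes are prefixed `MT-`, ribosomal genes `RPL`/`RPS`.
#'
#' @param n_genes Total number of genes (> 0).
#' @param mito_gene_count,ribo_gene_count Numbers of mitochondrial and
#'   ribosomal genes; their sum must not exceed `n_genes`.
#' @param mean_counts_per_cell Expected total counts of a healthy cell.
#' @param dispersion Negative binomial size parameter for cell totals
#'   (smaller = more overdispersed).
#' @param target_mito_fraction Named fractions in \[0, 1\] per cell class
#'   (`healthy`, `low_quality`): expected mitochondrial share of counts.
#' @param lowquality_cell_fraction Fraction of cells in \[0, 1\] planted as
#'   low quality.
#' @param lowquality_mean_counts Expected total counts of a low-quality cell;
#'   the default (60) puts the expected detected-gene count near 50, well
#'   under a 200-feature floor.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(n_genes = 1000L,
                       mito_gene_count = 13L,
                       ribo_gene_count = 80L,
                       mean_counts_per_cell = 3000,
                       dispersion = 2,
                       target_mito_fraction = c(healthy = 0.05,
                                                low_quality = 0.4),
                       lowquality_cell_fraction = 0.1,
                       lowquality_mean_counts = 60) {
  check_scalar_number(n_genes, "n_genes", lower = 1)
  if (mito_gene_count + ribo_gene_count > n_genes) {
    abort("mito_gene_count + ribo_gene_count must not exceed n_genes.")
  }
  check_scalar_number(mean_counts_per_cell, "mean_counts_per_cell",
                      lower = 0, lower_open = TRUE)
  check_scalar_number(dispersion, "dispersion", lower = 0, lower_open = TRUE)
  if (!all(c("healthy", "low_quality") %in% names(target_mito_fraction))) {
    abort("`target_mito_fraction` must name classes 'healthy' and 'low_quality'.")
  }
  if (any(target_mito_fraction < 0) || any(target_mito_fraction > 1)) {
    abort("`target_mito_fraction` values must lie in [0, 1].")
  }
  check_scalar_number(lowquality_cell_fraction, "lowquality_cell_fraction",
                      lower = 0, upper = 1)
  check_scalar_number(lowquality_mean_counts, "lowquality_mean_counts",
                      lower = 0, lower_open = TRUE)
  structure(
    list(
      n_genes = as.integer(n_genes),
      mito_gene_count = as.integer(mito_gene_count),
      ribo_gene_count = as.integer(ribo_gene_count),
      mean_counts_per_cell = mean_counts_per_cell,
      dispersion = dispersion,
      target_mito_fraction = target_mito_fraction,
      lowquality_cell_fraction = lowquality_cell_fraction,
      lowquality_mean_counts = lowquality_mean_counts
    ),
    class = "gene_model"
  )
}

gene_names_for <- function(model) {
  n_other <- model$n_genes - model$mito_gene_count - model$ribo_gene_count
  mito <- if (model$mito_gene_count > 0) {
    sprintf("MT-G%d", seq_len(model$mito_gene_count))
  } else character()
  ribo <- if (model$ribo_gene_count > 0) {
    prefix <- rep(c("RPL", "RPS"), length.out = model$ribo_gene_count)
    sprintf("%s%d", prefix, seq_len(model$ribo_gene_count))
  } else character()
  other <- if (n_other > 0) sprintf("GENE%04d", seq_len(n_other)) else character()
  c(mito, ribo, other)
}

#' Simulate a sparse gene-by-cell count matrix
#'
#' For each cell: a negative binomial total (class-specific mean), a binomial
#' thinning of that total into mitochondrial vs nuclear counts at the class's
#' target mitochondrial fraction, then multinomial allocation over the genes
#' of each compartment with fixed lognormal gene weights.
#'
#' @param cells A cell table (one row per cell with a `cell_id` column), as
#'   from [simulate_cell_table()]. May have zero rows.
#' @param model A [gene_model()].
#' @param seed Integer seed (required for reproducibility; default 1).
#' @return An [sc_counts] object: sparse counts plus gene flags and the
#'   planted per-cell class (ground truth for QC tests).
#' @export
simulate_count_matrix <- function(cells, model = gene_model(), seed = 1L) {
  stopifnot(inherits(model, "gene_model"))
  check_columns(cells, "cell_id", "cell table")
  genes <- gene_names_for(model)
  is_mito <- grepl("^MT-", genes, ignore.case = TRUE)
  n_cells <- nrow(cells)
  if (n_cells == 0) {
    m <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(model$n_genes, 0))
    rownames(m) <- genes
    return(sc_counts(m, cell_class = character()))
  }
  with_seed(seed, {
    class <- ifelse(
      runif(n_cells) < model$lowquality_cell_fraction, "low_quality", "healthy"
    )
    mu <- ifelse(class == "low_quality",
                 model$lowquality_mean_counts, model$mean_counts_per_cell)
    totals <- rnbinom(n_cells, size = model$dispersion, mu = mu)
    mito_frac <- model$target_mito_fraction[class]
    mito_totals <- rbinom(n_cells, totals, mito_frac)
    # fixed relative expression levels per gene within each compartment
    w_mito <- rlnorm(sum(is_mito), 0, 1)
    w_nuc <- rlnorm(sum(!is_mito), 0, 1)
    ii <- vector("list", n_cells)
    xx <- vector("list", n_cells)
    mito_idx <- which(is_mito)
    nuc_idx <- which(!is_mito)
    for (ci in seq_len(n_cells)) {
      cnt <- numeric(0)
      idx <- integer(0)
      if (mito_totals[ci] > 0 && length(mito_idx) > 0) {
        cm <- as.vector(rmultinom(1, mito_totals[ci], w_mito))
        keep <- cm > 0
        idx <- c(idx, mito_idx[keep])
        cnt <- c(cnt, cm[keep])
      }
      nuc <- totals[ci] - mito_totals[ci]
      if (nuc > 0 && length(nuc_idx) > 0) {
        cn <- as.vector(rmultinom(1, nuc, w_nuc))
        keep <- cn > 0
        idx <- c(idx, nuc_idx[keep])
        cnt <- c(cnt, cn[keep])
      }
      ii[[ci]] <- idx
      xx[[ci]] <- cnt
    }
    jj <- rep(seq_len(n_cells), lengths(ii))
    m <- Matrix::sparseMatrix(
      i = unlist(ii), j = jj, x = unlist(xx),
      dims = c(model$n_genes, n_cells),
      dimnames = list(genes, cells$cell_id)
    )
    sc_counts(m, cell_class = class)
  })
}

#' Specify per-condition clinical covariate distributions
#'
#' Families supported: `"lognormal"` (location = log median, scale = sdlog)
#' and `"normal"` (optionally truncated). Zero scale collapses a covariate to
#' its condition's central value exactly. Defaults are chosen only to
#' straddle the clinical decision thresholds used for stratification
#' (creatinine 140 uM, eGFR 60 mL/min/1.73m2); they are not estimates of any
#' real cohort.
#'
#' @param creatinine,egfr,age Lists with `family`, per-condition `location`
#'   and `scale` (recycled across conditions if scalar), and optional
#'   `lower`/`upper` truncation bounds for the normal family.
#' @param sex_probabilities Named probabilities summing to 1.
#' @return An object of class `clinical_model`.
#' @export
clinical_model <- function(
    creatinine = list(family = "lognormal",
                      location = c(log(80), log(250)),
                      scale = c(0.30, 0.35)),
    egfr = list(family = "normal", location = c(90, 35),
                scale = c(15, 15), lower = 0),
    age = list(family = "normal", location = 55, scale = 15,
               lower = 18, upper = 95),
    sex_probabilities = c(female = 0.5, male = 0.5)) {
  for (cov in list(creatinine = creatinine, egfr = egfr, age = age)) {
    if (!cov$family %in% c("lognormal", "normal")) {
      abort(sprintf("Unknown distribution family '%s'.", cov$family))
    }
    if (any(cov$scale < 0)) abort("Distribution scales must be >= 0.")
  }
  if (abs(sum(sex_probabilities) - 1) > 1e-8 || any(sex_probabilities < 0)) {
    abort("`sex_probabilities` must be non-negative and sum to 1.")
  }
  structure(
    list(creatinine = creatinine, egfr = egfr, age = age,
         sex_probabilities = sex_probabilities),
    class = "clinical_model"
  )
}

draw_covariate <- function(cov, cond_index, n) {
  loc <- rep(cov$location, length.out = max(cond_index))[cond_index]
  sc <- rep(cov$scale, length.out = max(cond_index))[cond_index]
  lower <- cov$lower %||% -Inf
  upper <- cov$upper %||% Inf
  out <- numeric(n)
  if (cov$family == "lognormal") {
    out <- ifelse(sc == 0, exp(loc), rlnorm(n, loc, sc))
  } else {
    for (i in seq_len(n)) {
      out[i] <- rnorm_truncated(1, loc[i], sc[i], lower, upper)
    }
  }
  out
}

#' Simulate per-sample clinical covariates
#'
#' One row per sample: serum creatinine (uM), eGFR (mL/min/1.73m2), age
#' (years) and sex, drawn from the condition-specific distributions of a
#' [clinical_model()]. Under the default model, case samples tend above the
#' 140 uM creatinine threshold and below the 60 eGFR threshold, controls the
#' reverse.
#'
#' @param samples A data frame with `sample_id` and `condition` columns (a
#'   cell table works: distinct sample rows are taken), or a character vector
#'   of sample ids together with `conditions`.
#' @param model A [clinical_model()].
#' @param seed Integer seed.
#' @param conditions Character vector of per-sample conditions, only when
#'   `samples` is a bare vector of ids.
#' @param reference Condition label treated as control (it receives the
#'   first location/scale of each covariate distribution); defaults to the
#'   first condition encountered in the table.
#' @return A tibble with columns `sample_id`, `condition`, `creatinine`,
#'   `egfr`, `age`, `sex`.
#' @export
simulate_clinical <- function(samples, model = clinical_model(), seed = 1L,
                              conditions = NULL, reference = NULL) {
  if (is.data.frame(samples)) {
    check_columns(samples, c("sample_id", "condition"), "sample table")
    tab <- distinct(samples, .data$sample_id, .data$condition)
  } else {
    if (is.null(conditions) || length(conditions) != length(samples)) {
      abort("`conditions` must accompany a bare vector of sample ids.")
    }
    tab <- tibble(sample_id = as.character(samples),
                  condition = as.character(conditions))
  }
  if (anyDuplicated(tab$sample_id)) {
    abort("Sample ids map to more than one condition.")
  }
  # reference (control) defaults to the first condition encountered, which
  # for generator output is the cohort's first (control) condition
  levels <- unique(c(reference %||% character(), unique(tab$condition)))
  ci <- match(tab$condition, levels)
  n <- nrow(tab)
  if (n == 0) {
    return(tibble(sample_id = character(), condition = character(),
                  creatinine = numeric(), egfr = numeric(),
                  age = numeric(), sex = character()))
  }
  with_seed(seed, {
    tab$creatinine <- draw_covariate(model$creatinine, ci, n)
    tab$egfr <- draw_covariate(model$egfr, ci, n)
    tab$age <- draw_covariate(model$age, pmin(ci, length(model$age$location)), n)
    tab$sex <- sample(names(model$sex_probabilities), n, replace = TRUE,
                      prob = model$sex_probabilities)
    as_tibble(tab)
  })
}
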