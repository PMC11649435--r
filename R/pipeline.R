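# End-to-end orchestration: simulate (or read) -> QC -> stratify ->
# proportions -> DPA, with per-stage TSV outputs and a JSON run manifest.

pipeline_log <- function(quiet, ...) {
  if (!quiet) message(sprintf(...))
}

stage_guard <- function(stage, out_dir, quiet, expr) {
  tryCatch(expr, error = function(e) {
    marker <- file.path(out_dir, "FAILED")
    writeLines(sprintf("stage: %s\nerror: %s", stage, conditionMessage(e)),
               marker)
    abort(sprintf("[%s] %s", stage, conditionMessage(e)))
  })
}

#' Run the full compositional-analysis pipeline
#'
#' Executes the enabled stages in order — simulate (or read) the cell table,
#' simulate counts and clinical covariates, QC-filter, stratify, compute
#' cluster proportions, run the differential proportion analysis — writing
#' each stage's table as TSV into `out_dir` together with a JSON manifest
#' recording seeds, versions and the cell-count ledger (cells before/after
#' every stage, and each QC rule's removals). All randomness derives from
#' the single master seed via [child_seed()], so runs with equal seeds
#' produce byte-identical outputs.
#'
#' @param config An [analysis_config()] (or path to its YAML form).
#' @param out_dir Output directory; overrides `config$out_dir`.
#' @return Invisibly, a list with the output directory, the per-stage
#'   objects (`cells`, `counts`, `clinical`, `proportions`, `dpa`) and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_analysis_config(config)
  stopifnot(inherits(config, "analysis_config"))
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) abort("An output directory is required.")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  quiet <- isTRUE(config$quiet)
  ledger <- list()
  files <- character()

  # --- cells -----------------------------------------------------------
  cells <- stage_guard("cells", out_dir, quiet, {
    if (!is.null(config$cells_path)) {
      pipeline_log(quiet, "reading cells from %s", config$cells_path)
      read_cell_table(config$cells_path)
    } else {
      spec <- config$simulate
      if (!inherits(spec, "composition_spec")) {
        args <- spec[setdiff(names(spec), c("gene_model", "clinical"))]
        args$seed <- config$seed
        spec <- do.call(composition_spec, args)
      }
      simulate_cell_table(spec, seed = child_seed(config$seed, "cells"))
    }
  })
  ledger$cells_input <- nrow(cells)
  write_cell_table(cells, file.path(out_dir, "cells.tsv"))
  files <- c(files, "cells.tsv")
  pipeline_log(quiet, "cell table: %d cells, %d samples", nrow(cells),
               length(unique(cells$sample_id)))

  # --- counts + QC -----------------------------------------------------
  counts <- NULL
  qc_cfg <- config$qc
  gm_cfg <- if (is.list(config$simulate)) config$simulate$gene_model else NULL
  if (!is.null(gm_cfg)) {
    counts <- stage_guard("counts", out_dir, quiet, {
      gm <- if (inherits(gm_cfg, "gene_model")) gm_cfg else {
        do.call(gene_model, gm_cfg)
      }
      simulate_count_matrix(cells, gm, seed = child_seed(config$seed, "counts"))
    })
    write_count_matrix(counts, file.path(out_dir, "counts"))
    files <- c(files, "counts/matrix.mtx", "counts/genes.tsv",
               "counts/barcodes.tsv")
  }
  qc_enabled <- !is.null(qc_cfg) && !isFALSE(qc_cfg) &&
    !(is.list(qc_cfg) && isFALSE(qc_cfg$enabled))
  ledger$cells_before_qc <- nrow(cells)
  if (qc_enabled) {
    cells <- stage_guard("qc", out_dir, quiet, {
      thr_args <- if (is.list(qc_cfg)) {
        qc_cfg[intersect(names(qc_cfg),
                         c("min_features", "max_counts", "max_mito_pct"))]
      } else list()
      thr <- do.call(qc_thresholds, thr_args)
      metrics_present <- all(c("n_features", "n_counts", "pct_mito") %in%
                               names(cells))
      if (!metrics_present) {
        if (is.null(counts)) {
          abort("QC requested but neither metrics columns nor counts are available.")
        }
        metrics <- compute_qc_metrics(counts)
        cells <- left_join(cells, metrics, by = "cell_id")
      }
      readr::write_tsv(
        select(cells, all_of(c("cell_id", "n_counts", "n_features",
                               "pct_mito"))),
        file.path(out_dir, "qc_metrics.tsv"), progress = FALSE
      )
      filtered <- filter_cells(cells, thr)
      rep <- qc_removal_report(filtered)
      readr::write_tsv(rep$per_rule, file.path(out_dir, "qc_removals.tsv"),
                       progress = FALSE)
      pipeline_log(quiet, "QC: %d -> %d cells (%s)", rep$n_input,
                   rep$n_retained,
                   paste(sprintf("%s: %d", rep$per_rule$rule,
                                 rep$per_rule$n_removed), collapse = ", "))
      ledger$qc_removals <- setNames(as.list(rep$per_rule$n_removed),
                                     rep$per_rule$rule)
      files <- c(files, "qc_metrics.tsv", "qc_removals.tsv")
      filtered
    })
    if (!is.null(counts)) {
      counts <- remove_ribosomal_genes(counts)
    }
  }
  ledger$cells_after_qc <- nrow(cells)
  if (qc_enabled) {
    write_cell_table(cells, file.path(out_dir, "cells_filtered.tsv"))
    files <- c(files, "cells_filtered.tsv")
  }

  # --- clinical + stratification --------------------------------------
  clinical <- NULL
  if (is.list(config$simulate) && !isFALSE(config$simulate$clinical)) {
    clinical <- stage_guard("clinical", out_dir, quiet, {
      ref_cond <- if (is.list(config$simulate)) {
        config$simulate$conditions[1] %||% NULL
      } else NULL
      simulate_clinical(cells, seed = child_seed(config$seed, "clinical"),
                        reference = ref_cond)
    })
    write_cell_table(clinical, file.path(out_dir, "clinical.tsv"))
    files <- c(files, "clinical.tsv")
  }
  if (!is.null(config$stratify) && !is.null(clinical)) {
    cells <- stage_guard("stratify", out_dir, quiet, {
      rules <- config$stratify
      if (is.character(rules)) {
        builtin <- list(creatinine = rule_creatinine, egfr = rule_egfr,
                        age = rule_age, sex = rule_sex)
        unknown <- setdiff(rules, names(builtin))
        if (length(unknown) > 0) {
          abort(sprintf("Unknown built-in rule(s): %s",
                        paste(unknown, collapse = ", ")))
        }
        rules <- lapply(rules, function(r) builtin[[r]]())
      }
      for (rule in rules) cells <- stratify(cells, clinical, rule)
      cells
    })
    write_cell_table(cells, file.path(out_dir, "cells_stratified.tsv"))
    files <- c(files, "cells_stratified.tsv")
  }

  # --- proportions -----------------------------------------------------
  group_col <- config$dpa$group_col %||% "condition"
  props <- stage_guard("proportions", out_dir, quiet, {
    cluster_proportions(cells, group_col = group_col)
  })
  readr::write_tsv(props, file.path(out_dir, "proportions.tsv"),
                   progress = FALSE)
  files <- c(files, "proportions.tsv")

  # --- dpa -------------------------------------------------------------
  dpa <- stage_guard("dpa", out_dir, quiet, {
    args <- config$dpa %||% list()
    args$cells <- cells
    args$group_col <- group_col
    args$seed <- args$seed %||% child_seed(config$seed, "dpa")
    do.call(dpa_test, args)
  })
  readr::write_tsv(tidy(dpa), file.path(out_dir, "dpa.tsv"), progress = FALSE)
  files <- c(files, "dpa.tsv")
  pipeline_log(quiet, "DPA: %d/%d clusters significant at alpha = %g",
               sum(tidy(dpa)$significant), dpa$n_clusters, dpa$alpha)

  # --- manifest --------------------------------------------------------
  manifest <- list(
    package = "cellprop",
    version = as.character(utils::packageVersion("cellprop")),
    master_seed = config$seed,
    stage_seeds = list(cells = child_seed(config$seed, "cells"),
                       counts = child_seed(config$seed, "counts"),
                       clinical = child_seed(config$seed, "clinical"),
                       dpa = child_seed(config$seed, "dpa")),
    cell_counts = ledger,
    dpa = list(w = dpa$w, iterations = dpa$iterations, alpha = dpa$alpha,
               groups = as.list(dpa$groups),
               n_significant = sum(tidy(dpa)$significant)),
    files = files
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(out_dir = out_dir, cells = cells, counts = counts,
                 clinical = clinical, proportions = props, dpa = dpa,
                 manifest = manifest))
}
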