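# Synthetic cohort generator: planted compositions, counts, clinical
# covariates, determinism.

test_that("study-scale scenario yields 65 samples with a 42/23 split", {
  spec <- composition_spec(
    cluster_names = c("a", "b"), baseline_proportions = c(0.4, 0.6),
    n_samples_per_condition = c(42, 23), cells_per_sample = 20
  )
  cells <- simulate_cell_table(spec)
  samples <- dplyr::distinct(cells, sample_id, condition)
  expect_equal(nrow(samples), 65)
  expect_equal(sum(samples$condition == "normal"), 42)
  expect_equal(sum(samples$condition == "CKD"), 23)
  expect_equal(nrow(cells), 65 * 20)
})

test_that("zero planted effect leaves pooled compositions equal within noise", {
  spec <- composition_spec(
    cluster_names = paste0("c", 1:4),
    baseline_proportions = c(0.1, 0.2, 0.3, 0.4),
    n_samples_per_condition = c(10, 10), cells_per_sample = 1000,
    dirichlet_concentration = 1e8, seed = 11
  )
  cells <- simulate_cell_table(spec)
  d <- proportion_difference(cluster_proportions(cells))
  # 3 binomial SE of the difference at n = 10,000 per condition
  se <- sqrt(2 * c(0.1, 0.2, 0.3, 0.4) * c(0.9, 0.8, 0.7, 0.6) / 10000)
  expect_true(all(abs(d$statistic) <= 3 * se))
})

test_that("a zero multiplier removes the cluster from that condition", {
  spec <- composition_spec(
    cluster_names = c("gone", "kept"), baseline_proportions = c(0.5, 0.5),
    effect_multipliers = c(0, 1),
    n_samples_per_condition = c(3, 3), cells_per_sample = 200, seed = 2
  )
  cells <- simulate_cell_table(spec)
  case <- cells[cells$condition == "CKD", ]
  expect_gt(nrow(case), 0)
  expect_false(any(case$cluster == "gone"))
  expect_true(any(cells$cluster[cells$condition == "normal"] == "gone"))
})

test_that("empirical composition converges to the planted composition", {
  base <- c(0.15, 0.35, 0.5)
  spec <- composition_spec(
    cluster_names = c("a", "b", "c"), baseline_proportions = base,
    effect_multipliers = c(2, 1, 0.5),
    n_samples_per_condition = c(100, 100), cells_per_sample = 1000,
    dirichlet_concentration = 1e8, seed = 21
  )
  cells <- simulate_cell_table(spec)
  planted <- condition_proportions(spec)
  pr <- cluster_proportions(cells)
  for (cond in colnames(planted)) {
    got <- pr$proportion[pr$group == cond][order(pr$cluster[pr$group == cond])]
    p <- planted[order(rownames(planted)), cond]
    se <- sqrt(p * (1 - p) / 1e5)
    expect_true(all(abs(got - p) <= 3 * se + 1e-4))
  }
})

test_that("equal seeds reproduce byte-identical tables, different seeds differ", {
  spec <- composition_spec(c("a", "b"), c(0.3, 0.7),
                           n_samples_per_condition = c(4, 4),
                           cells_per_sample = 100, seed = 5)
  t1 <- simulate_cell_table(spec)
  t2 <- simulate_cell_table(spec)
  t3 <- simulate_cell_table(spec, seed = 999)
  expect_identical(t1, t2)
  expect_false(identical(t1$cluster, t3$cluster))
})

test_that("infinite-concentration limit recovers multinomial-only variance", {
  p1 <- 0.3
  n_cells <- 200
  spec_inf <- composition_spec(
    c("a", "b"), c(p1, 1 - p1), n_samples_per_condition = c(300, 2),
    cells_per_sample = n_cells, dirichlet_concentration = 1e9, seed = 31
  )
  cells <- simulate_cell_table(spec_inf)
  per_sample <- dplyr::summarise(
    dplyr::group_by(cells[cells$condition == "normal", ], sample_id),
    p = mean(cluster == "a"), .groups = "drop"
  )
  v_emp <- var(per_sample$p)
  v_multinomial <- p1 * (1 - p1) / n_cells
  expect_gt(v_emp / v_multinomial, 0.7)
  expect_lt(v_emp / v_multinomial, 1.35)

  # moderate concentration must show the Dirichlet-multinomial inflation
  a <- 50
  spec_od <- composition_spec(
    c("a", "b"), c(p1, 1 - p1), n_samples_per_condition = c(300, 2),
    cells_per_sample = n_cells, dirichlet_concentration = a, seed = 32
  )
  cells_od <- simulate_cell_table(spec_od)
  per_sample_od <- dplyr::summarise(
    dplyr::group_by(cells_od[cells_od$condition == "normal", ], sample_id),
    p = mean(cluster == "a"), .groups = "drop"
  )
  v_expected <- p1 * (1 - p1) / n_cells * (n_cells + a) / (1 + a)
  expect_gt(var(per_sample_od$p) / v_expected, 0.7)
  expect_lt(var(per_sample_od$p) / v_expected, 1.35)
})

test_that("invalid composition specs are rejected", {
  expect_error(composition_spec(c("a", "b"), c(0.5, 0.6)), "sum to 1")
  expect_error(composition_spec(c("a", "b"), c(0.5, 0.5),
                                effect_multipliers = c(-1, 1)),
               "non-negative")
  expect_error(composition_spec(c("a", "a"), c(0.5, 0.5)), "unique")
})

test_that("zero cells per sample yields an empty, well-formed table", {
  spec <- composition_spec(c("a", "b"), c(0.5, 0.5),
                           n_samples_per_condition = c(2, 2),
                           cells_per_sample = 0)
  cells <- simulate_cell_table(spec)
  expect_equal(nrow(cells), 0)
  expect_named(cells, c("cell_id", "sample_id", "condition", "cluster"))
})

test_that("binomial thinning hits the target mitochondrial fraction", {
  cells <- tibble::tibble(cell_id = sprintf("c%d", 1:1000))
  model <- gene_model(n_genes = 200, mito_gene_count = 10,
                      target_mito_fraction = c(healthy = 0.5,
                                               low_quality = 0.5),
                      lowquality_cell_fraction = 0)
  sc <- simulate_count_matrix(cells, model, seed = 3)
  total <- Matrix::colSums(sc$counts)
  mito <- Matrix::colSums(sc$counts[sc$genes$is_mito, ])
  expect_lt(abs(mean(100 * mito / total) - 50), 2)
})

test_that("zero cells give a zero-column matrix with the gene list intact", {
  model <- gene_model(n_genes = 50, mito_gene_count = 5, ribo_gene_count = 5)
  sc <- simulate_count_matrix(tibble::tibble(cell_id = character()), model)
  expect_equal(dim(sc), c(50, 0))
  expect_equal(nrow(sc$genes), 50)
  expect_equal(sum(sc$genes$is_mito), 5)
})

test_that("planted low-quality cells fall under the detected-gene floor", {
  cells <- tibble::tibble(cell_id = sprintf("c%d", 1:500))
  model <- gene_model(n_genes = 1000, lowquality_cell_fraction = 1,
                      lowquality_mean_counts = 60)
  sc <- simulate_count_matrix(cells, model, seed = 4)
  n_features <- Matrix::colSums(sc$counts > 0)
  expect_gte(mean(n_features <= 200), 0.95)
})

test_that("default clinical model straddles the creatinine threshold", {
  samples <- tibble::tibble(
    sample_id = sprintf("s%04d", 1:2000),
    condition = rep(c("normal", "CKD"), each = 1000)
  )
  clin <- simulate_clinical(samples, seed = 8)
  case <- clin[clin$condition == "CKD", ]
  ctrl <- clin[clin$condition == "normal", ]
  expect_gte(mean(case$creatinine > 140), 0.90)
  expect_gte(mean(ctrl$creatinine < 140), 0.90)
  expect_gte(mean(case$egfr < 60), 0.90)
  expect_gte(mean(ctrl$egfr >= 60), 0.90)
  expect_true(all(clin$egfr >= 0))
})

test_that("zero-variance clinical model collapses to the condition centres", {
  model <- clinical_model(
    creatinine = list(family = "lognormal", location = c(log(80), log(250)),
                      scale = c(0, 0)),
    egfr = list(family = "normal", location = c(90, 35), scale = c(0, 0),
                lower = 0)
  )
  samples <- tibble::tibble(sample_id = c("s1", "s2"),
                            condition = c("normal", "CKD"))
  clin <- simulate_clinical(samples, model, seed = 1)
  expect_equal(clin$creatinine, c(80, 250))
  expect_equal(clin$egfr, c(90, 35))
})

test_that("unknown distribution families are rejected at model build", {
  expect_error(
    clinical_model(creatinine = list(family = "cauchy", location = 1,
                                     scale = 1)),
    "Unknown distribution family"
  )
})
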