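# Proportion tables, the difference statistic and clinical stratification.

test_that("cluster proportions match hand computation", {
  pr <- cluster_proportions(toy_two_groups())
  expect_equal(pr$proportion[pr$group == "A" & pr$cluster == "x"], 0.3)
  expect_equal(pr$proportion[pr$group == "A" & pr$cluster == "y"], 0.7)
  expect_equal(pr$proportion[pr$group == "B" & pr$cluster == "x"], 0.5)
  expect_equal(pr$n_cells[pr$group == "B" & pr$cluster == "y"], 50)
})

test_that("a single cluster has proportion 1 in every group", {
  cells <- tibble::tibble(condition = c("A", "A", "B"), cluster = "only")
  pr <- cluster_proportions(cells)
  expect_true(all(pr$proportion == 1))
})

test_that("per-sample proportion columns each sum to 1", {
  spec <- composition_spec(paste0("c", 1:3), c(0.2, 0.3, 0.5),
                           n_samples_per_condition = c(5, 5),
                           cells_per_sample = 50, seed = 3)
  cells <- simulate_cell_table(spec)
  per_sample <- cluster_proportions(cells, group_col = "sample_id")
  sums <- tapply(per_sample$proportion, per_sample$group, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("clusters absent from one group get proportion zero", {
  cells <- tibble::tibble(condition = c("A", "A", "B"),
                          cluster = c("x", "y", "x"))
  pr <- cluster_proportions(cells)
  expect_equal(pr$proportion[pr$group == "B" & pr$cluster == "y"], 0)
  sums <- tapply(pr$proportion, pr$group, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("zero-cell groups error by name, unused clusters drop with warning", {
  cells <- tibble::tibble(
    condition = factor(c("A", "A"), levels = c("A", "B")),
    cluster = c("x", "y")
  )
  expect_error(cluster_proportions(cells), "B")
  cells2 <- tibble::tibble(
    condition = c("A", "B"),
    cluster = factor(c("x", "x"), levels = c("x", "ghost"))
  )
  expect_warning(pr <- cluster_proportions(cells2), "ghost")
  expect_false("ghost" %in% pr$cluster)
})

test_that("proportion differences match hand computation and sum to zero", {
  d <- proportion_difference(cluster_proportions(toy_two_groups()),
                             reference = "A", test = "B")
  expect_equal(d$statistic[d$cluster == "x"], 0.2)
  expect_equal(d$statistic[d$cluster == "y"], -0.2)
  expect_lt(abs(sum(d$statistic)), 1e-12)

  same <- tibble::tibble(condition = rep(c("A", "B"), each = 10),
                         cluster = rep(c("x", "y"), 10))
  d0 <- proportion_difference(cluster_proportions(same))
  expect_true(all(d0$statistic == 0))
})

test_that("statistics sum to zero for arbitrary random tables", {
  withr::with_seed(99, {
    for (i in 1:20) {
      k <- sample(2:8, 1)
      cells <- tibble::tibble(
        condition = sample(c("A", "B"), 200, replace = TRUE),
        cluster = sample(paste0("c", 1:k), 200, replace = TRUE)
      )
      d <- proportion_difference(cluster_proportions(cells))
      expect_lt(abs(sum(d$statistic)), 1e-12)
    }
  })
})

test_that("unknown comparison groups are rejected", {
  pr <- cluster_proportions(toy_two_groups())
  expect_error(proportion_difference(pr, reference = "Z"), "Unknown group")
})

test_that("clinical threshold rules honour the documented boundary sides", {
  expect_equal(
    apply_stratification_rule(rule_creatinine(), c(139.9, 140, 140.1)),
    c("normal", "impaired", "impaired")
  )
  expect_equal(
    apply_stratification_rule(rule_egfr(), c(59.9, 60, 60.1)),
    c("impaired", "normal", "normal")
  )
  expect_equal(
    apply_stratification_rule(rule_age(), c(29.9, 30, 45, 60, 60.1)),
    c("young", "adult", "adult", "adult", "elderly")
  )
  expect_equal(apply_stratification_rule(rule_sex(), c("f", "m")),
               c("f", "m"))
})

test_that("cells inherit their sample's stratum", {
  cells <- tibble::tibble(
    cell_id = sprintf("c%d", 1:6),
    sample_id = rep(c("s1", "s2", "s3"), each = 2),
    cluster = "x"
  )
  clinical <- tibble::tibble(sample_id = c("s1", "s2", "s3"),
                             creatinine = c(100, 140, 300))
  out <- stratify(cells, clinical, rule_creatinine())
  expect_equal(out$creatinine_group,
               rep(c("normal", "impaired", "impaired"), each = 2))
})

test_that("missing covariates error with the offending samples listed", {
  cells <- tibble::tibble(sample_id = c("s1", "s2"), cluster = "x")
  clinical <- tibble::tibble(sample_id = "s1", creatinine = 100)
  expect_error(stratify(cells, clinical, rule_creatinine()), "s2")
  clinical2 <- tibble::tibble(sample_id = c("s1", "s2"),
                              creatinine = c(100, NA))
  expect_error(stratify(cells, clinical2, rule_creatinine()), "s2")
})

test_that("degenerate stratification leaves one group and DPA refuses", {
  cells <- tibble::tibble(
    sample_id = rep(c("s1", "s2"), each = 10),
    cluster = rep(c("x", "y"), 10)
  )
  clinical <- tibble::tibble(sample_id = c("s1", "s2"),
                             creatinine = c(200, 300))
  strat <- stratify(cells, clinical, rule_creatinine())
  expect_equal(unique(strat$creatinine_group), "impaired")
  expect_error(dpa_test(strat, group_col = "creatinine_group",
                        iterations = 10),
               "exactly two groups")
})

test_that("proportions after stratification ignore cell and sample order", {
  spec <- composition_spec(paste0("c", 1:3), c(0.2, 0.3, 0.5),
                           n_samples_per_condition = c(6, 6),
                           cells_per_sample = 40, seed = 13)
  cells <- simulate_cell_table(spec)
  clinical <- simulate_clinical(cells, seed = 13)
  strat <- stratify(cells, clinical, rule_egfr())
  shuffled <- strat[withr::with_seed(1, sample(nrow(strat))), ]
  pr1 <- cluster_proportions(strat, group_col = "egfr_group")
  pr2 <- cluster_proportions(shuffled, group_col = "egfr_group")
  expect_equal(as.data.frame(pr1), as.data.frame(pr2))
})

test_that("a planted shift puts the largest expected |T| on that cluster", {
  stats <- matrix(0, nrow = 200, ncol = 5)
  for (r in 1:200) {
    spec <- composition_spec(
      paste0("c", 1:5), c(0.2, 0.2, 0.2, 0.2, 0.2),
      effect_multipliers = c(0.4, 1, 1, 1, 1),
      n_samples_per_condition = c(2, 2), cells_per_sample = 250,
      dirichlet_concentration = 1e8, seed = 1000 + r
    )
    cells <- simulate_cell_table(spec)
    d <- proportion_difference(cluster_proportions(cells))
    stats[r, ] <- abs(d$statistic[order(d$cluster)])
  }
  expect_equal(which.max(colMeans(stats)), 1L)
})

test_that("stratification rules validate their structure", {
  expect_error(stratification_rule("x", "threshold", thresholds = c(2, 1),
                                   labels = c("a", "b", "c")),
               "strictly increasing")
  expect_error(stratification_rule("x", "threshold", thresholds = 1,
                                   labels = c("a", "b", "c")),
               "one label per stratum")
})
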