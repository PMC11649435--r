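# Shared fixtures and independent oracles, built in code at test time.

# Tiny hand-checkable count matrix: one mitochondrial, one ribosomal and one
# plain gene over two cells.
toy_matrix <- function() {
  m <- matrix(c(5, 5, 0,
                0, 3, 1), nrow = 3,
              dimnames = list(c("MT-ND1", "ACTB", "RPL3"), c("c1", "c2")))
  m
}

# A two-group cell table with known pooled compositions:
# group A 30/70, group B 50/50 over clusters x/y.
toy_two_groups <- function() {
  tibble::tibble(
    condition = rep(c("A", "B"), each = 100),
    cluster = c(rep(c("x", "y"), c(30, 70)), rep(c("x", "y"), c(50, 50)))
  )
}

# Independent row-wise QC oracle: loops over cells applying each rule
# separately, no vectorised reuse of the implementation under test.
oracle_filter <- function(metrics, min_features = 200, max_counts = 12000,
                          max_mito_pct = 30) {
  keep <- logical(nrow(metrics))
  for (i in seq_len(nrow(metrics))) {
    row <- metrics[i, ]
    ok1 <- row$n_features > min_features
    ok2 <- row$n_counts < max_counts
    ok3 <- row$pct_mito < max_mito_pct
    keep[i] <- isTRUE(ok1 && ok2 && ok3)
  }
  metrics[keep, , drop = FALSE]
}

# Metrics fixture with planted failing sets and exact boundary cells.
# Returns the table plus the planted keep/fail truth per cell.
planted_metrics_fixture <- function(n = 1000, seed = 42) {
  withr::with_seed(seed, {
    status <- sample(c("pass", "low_features", "high_counts", "high_mito",
                       "boundary_features", "boundary_counts",
                       "boundary_mito"),
                     n, replace = TRUE,
                     prob = c(0.55, 0.15, 0.1, 0.1, 0.04, 0.03, 0.03))
    tab <- tibble::tibble(
      cell_id = sprintf("cell%04d", seq_len(n)),
      status = status,
      n_features = dplyr::case_when(
        status == "low_features" ~ sample(0:200, n, replace = TRUE),
        status == "boundary_features" ~ 200L,
        TRUE ~ sample(201:4000, n, replace = TRUE)
      ),
      n_counts = dplyr::case_when(
        status == "high_counts" ~ sample(12000:50000, n, replace = TRUE),
        status == "boundary_counts" ~ 12000L,
        TRUE ~ sample(500:11999, n, replace = TRUE)
      ) |> as.numeric(),
      pct_mito = dplyr::case_when(
        status == "high_mito" ~ runif(n, 30, 100),
        status == "boundary_mito" ~ 30,
        TRUE ~ runif(n, 0, 29.9)
      )
    )
    tab$n_counts <- pmax(tab$n_counts, tab$n_features)
    tab
  })
}

# A balanced two-group table with an independent multinomial null:
# every cell's cluster drawn iid from equal probabilities.
null_cells <- function(n_per_group = 1000, k = 5) {
  tibble::tibble(
    condition = rep(c("g1", "g2"), each = n_per_group),
    cluster = sample(letters[seq_len(k)], 2 * n_per_group, replace = TRUE)
  )
}

# Planted-contraction scenario used by the power checks: cluster "c1" drops
# from proportion 0.10 in the reference to 0.02 in the test group; the
# remaining mass is spread over four other clusters.
contraction_spec <- function(cells_per_sample = 1000, n_samples = c(3, 3),
                             concentration = 1e8) {
  base <- c(0.10, 0.225, 0.225, 0.225, 0.225)
  # solve for the multiplier giving renormalised test proportion 0.02
  mult1 <- (0.02 / 0.10) * (1 - 0.10) / (1 - 0.02)
  composition_spec(
    cluster_names = paste0("c", 1:5),
    baseline_proportions = base,
    effect_multipliers = c(mult1, 1, 1, 1, 1),
    n_samples_per_condition = n_samples,
    cells_per_sample = cells_per_sample,
    dirichlet_concentration = concentration
  )
}
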