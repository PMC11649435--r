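# Differential proportion analysis (DPA): a permutation test for shifts in
# cluster proportions between two conditions. The null distribution is built
# by repeatedly shuffling the cluster labels of a random fraction w of cells
# (pooled across both groups) and recomputing the per-cluster proportion
# difference; empirical p-values use the add-one estimator and are Bonferroni
# corrected across clusters.

#' Permute cluster labels for a fraction of cells
#'
#' One null iteration of the DPA permutation scheme: ceiling(w * N) cells are
#' chosen uniformly at random without replacement from the pooled dataset and
#' their cluster labels are shuffled uniformly among the chosen subset
#' (`mode = "shuffle"`, the default, which preserves the global label
#' multiset exactly), or replaced by independent draws from the global label
#' frequencies (`mode = "resample"`). Group labels are untouched. Uses the
#' current RNG stream; seed management belongs to the caller.
#'
#' @param labels Vector of per-cell cluster labels (length >= 2).
#' @param w Fraction of cells in (0, 1] whose labels are permuted.
#' @param mode `"shuffle"` or `"resample"`.
#' @return The permuted label vector.
#' @export
#' @examples
#' set.seed(1)
#' permute_labels_once(rep(c("a", "b"), 5), w = 0.5)
permute_labels_once <- function(labels, w, mode = c("shuffle", "resample")) {
  mode <- match.arg(mode)
  n <- length(labels)
  if (n < 2) abort("Need at least 2 cells to permute.")
  check_scalar_number(w, "w", lower = 0, upper = 1, lower_open = TRUE)
  m <- ceiling(w * n)
  idx <- sample.int(n, m)
  if (mode == "shuffle") {
    labels[idx] <- labels[idx][sample.int(m)]
  } else {
    labels[idx] <- sample(labels, m, replace = TRUE)
  }
  labels
}

dpa_two_groups <- function(cells, group_col, reference, test) {
  g <- as.character(cells[[group_col]])
  if (anyNA(g)) abort("Every cell needs a non-missing group label.")
  groups <- unique(g) # order of first appearance
  if (length(groups) != 2) {
    abort(sprintf("DPA needs exactly two groups; found %d (%s).",
                  length(groups), paste(groups, collapse = ", ")))
  }
  reference <- reference %||% groups[1]
  test <- test %||% setdiff(groups, reference)
  if (!reference %in% groups || !test %in% groups || reference == test) {
    abort("`reference` and `test` must name the two distinct groups present.")
  }
  list(g = g, reference = reference, test = test)
}

#' Differential proportion analysis between two conditions
#'
#' For each cluster the observed statistic is the difference in pooled
#' proportions between test and reference groups. A null distribution is
#' generated by `iterations` partial label shuffles ([permute_labels_once()]
#' with fraction `w`); the two-sided empirical p-value for cluster c is
#' `(1 + #\{b : |T*_c(b)| >= |T_c|\}) / (iterations + 1)` (add-one
#' estimator, ties counted as exceedances), then Bonferroni-adjusted across
#' the clusters tested. Clusters with fewer than `min_cluster_cells` cells in
#' total are reported but flagged unreliable.
#'
#' @param cells A cell table with one row per cell.
#' @param group_col,cluster_col Column names for the two-level condition and
#'   the cluster label.
#' @param reference,test Which group is the reference (defaults: order of
#'   first appearance in the table).
#' @param w Fraction of cells whose labels are permuted per iteration
#'   (default 0.1).
#' @param iterations Number of permutation iterations B (default 1000; use
#'   1e5 for publication-grade p-values).
#' @param alpha Significance level applied to the Bonferroni-adjusted p
#'   (default 0.05).
#' @param seed Integer seed for the permutation stream (`NULL` uses the
#'   current stream).
#' @param sided `"two"` (default; contraction and expansion both count) or
#'   `"greater"` (one-sided, test minus reference).
#' @param mode Permutation scheme, see [permute_labels_once()].
#' @param min_cluster_cells Reliability floor on total cells per cluster
#'   (default 5).
#' @return An object of class `dpa_result`; see [tidy.dpa_result()].
#' @export
#' @examples
#' spec <- composition_spec(c("A", "B", "C"), c(0.2, 0.3, 0.5),
#'                          effect_multipliers = c(0.2, 1, 1),
#'                          n_samples_per_condition = c(4, 4),
#'                          cells_per_sample = 200)
#' cells <- simulate_cell_table(spec, seed = 7)
#' dpa_test(cells, iterations = 200, seed = 7)
dpa_test <- function(cells, group_col = "condition", cluster_col = "cluster",
                     reference = NULL, test = NULL, w = 0.1,
                     iterations = 1000L, alpha = 0.05, seed = NULL,
                     sided = c("two", "greater"),
                     mode = c("shuffle", "resample"),
                     min_cluster_cells = 5L) {
  sided <- match.arg(sided)
  mode <- match.arg(mode)
  check_columns(cells, c(group_col, cluster_col), "cell table")
  check_scalar_number(w, "w", lower = 0, upper = 1, lower_open = TRUE)
  check_scalar_number(iterations, "iterations", lower = 1)
  check_scalar_number(alpha, "alpha", lower = 0, upper = 1,
                      lower_open = TRUE, upper_open = TRUE)
  gg <- dpa_two_groups(cells, group_col, reference, test)

  # observed statistics through the proportion machinery
  props <- cluster_proportions(cells, group_col, cluster_col)
  obs <- proportion_difference(props, gg$reference, gg$test)

  cl <- factor(as.character(cells[[cluster_col]]), levels = obs$cluster)
  lab <- as.integer(cl)
  k <- nlevels(cl)
  n <- length(lab)
  is_test <- gg$g == gg$test
  n_ref <- sum(!is_test)
  n_test <- sum(is_test)
  tot <- tabulate(lab, k)
  t_obs <- obs$statistic
  crit <- if (sided == "two") abs(t_obs) else t_obs
  m <- ceiling(w * n)
  b_total <- as.integer(iterations)

  exceed <- integer(k)
  run_perms <- function() {
    perm <- lab
    for (b in seq_len(b_total)) {
      idx <- sample.int(n, m)
      if (mode == "shuffle") {
        perm[idx] <- lab[idx][sample.int(m)]
        cnt2 <- tabulate(perm[is_test], k)
        tstar <- cnt2 / n_test - (tot - cnt2) / n_ref
      } else {
        perm[idx] <- lab[sample.int(n, m, replace = TRUE)]
        cnt2 <- tabulate(perm[is_test], k)
        cnt1 <- tabulate(perm[!is_test], k)
        tstar <- cnt2 / n_test - cnt1 / n_ref
      }
      stat <- if (sided == "two") abs(tstar) else tstar
      exceed <<- exceed + (stat >= crit - 1e-12)
      perm[idx] <- lab[idx]
    }
  }
  with_seed(seed, run_perms())

  p_emp <- (1 + exceed) / (b_total + 1)
  p_bonf <- bonferroni_adjust(p_emp, k)
  result <- mutate(
    obs,
    p_empirical = p_emp,
    p_bonferroni = p_bonf,
    significant = p_bonf < alpha,
    reliable = (.data$n_ref + .data$n_test) >= min_cluster_cells
  )
  structure(
    list(
      result = result,
      groups = c(reference = gg$reference, test = gg$test),
      group_sizes = c(reference = n_ref, test = n_test),
      w = w, iterations = b_total, alpha = alpha,
      seed = seed, sided = sided, mode = mode,
      n_cells = n, n_clusters = k,
      subset_size = m
    ),
    class = "dpa_result"
  )
}

#' Bonferroni adjustment of p-values
#'
#' Each p-value is multiplied by the number of tests `k` and capped at 1.
#'
#' @param p Numeric p-values in (0, 1].
#' @param k Number of tests; must be at least `length(p)`.
#' @return Adjusted p-values, elementwise `min(1, k * p)`.
#' @export
#' @examples
#' bonferroni_adjust(0.004, k = 8)
bonferroni_adjust <- function(p, k = length(p)) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    abort("p-values must lie in (0, 1].")
  }
  if (k < length(p)) abort("`k` must be at least the number of p-values.")
  pmin(1, k * p)
}

#' Exact null distribution of the DPA statistic on small instances
#'
#' Enumerates every outcome of one permutation iteration — each size-m subset
#' of cells (m = ceiling(w * N)) times each of the m! uniform shuffles of the
#' subset's labels — and collapses the per-cluster statistic values into an
#' exact probability mass function. Serves as an oracle for the Monte Carlo
#' p-values of [dpa_test()]: the exact two-sided p for cluster c is
#' P(|T*_c| >= |T_c|) under this law.
#'
#' @inheritParams dpa_test
#' @param max_outcomes Enumeration guard: refuse instances with more than
#'   this many (subset, shuffle) outcomes (default 1e6).
#' @return An object of class `dpa_exact`: a per-cluster table with the
#'   observed statistic and exact two-sided p, plus the full per-cluster mass
#'   functions in `$distribution`.
#' @export
#' @examples
#' cells <- tibble::tibble(
#'   condition = rep(c("ref", "case"), each = 3),
#'   cluster = c("a", "a", "b", "a", "b", "b")
#' )
#' exact_null_distribution(cells, w = 1)
exact_null_distribution <- function(cells, group_col = "condition",
                                    cluster_col = "cluster",
                                    reference = NULL, test = NULL, w = 1,
                                    sided = c("two", "greater"),
                                    max_outcomes = 1e6) {
  sided <- match.arg(sided)
  check_columns(cells, c(group_col, cluster_col), "cell table")
  check_scalar_number(w, "w", lower = 0, upper = 1, lower_open = TRUE)
  gg <- dpa_two_groups(cells, group_col, reference, test)
  props <- cluster_proportions(cells, group_col, cluster_col)
  obs <- proportion_difference(props, gg$reference, gg$test)
  cl <- factor(as.character(cells[[cluster_col]]), levels = obs$cluster)
  lab <- as.integer(cl)
  k <- nlevels(cl)
  n <- length(lab)
  m <- ceiling(w * n)
  n_subsets <- choose(n, m)
  n_outcomes <- n_subsets * factorial(m)
  if (n_outcomes > max_outcomes) {
    abort(sprintf(
      "Instance too large for exact enumeration: %.0f outcomes exceed the %.0f guard.",
      n_outcomes, max_outcomes
    ))
  }
  is_test <- gg$g == gg$test
  n_ref <- sum(!is_test)
  n_test <- sum(is_test)
  tot <- tabulate(lab, k)
  perms <- perm_matrix(m)
  subsets <- combn(n, m)
  p_outcome <- 1 / (ncol(subsets) * nrow(perms))
  vals <- matrix(0, nrow = ncol(subsets) * nrow(perms), ncol = k)
  row <- 0L
  perm <- lab
  for (s in seq_len(ncol(subsets))) {
    idx <- subsets[, s]
    labS <- lab[idx]
    for (p in seq_len(nrow(perms))) {
      perm[idx] <- labS[perms[p, ]]
      cnt2 <- tabulate(perm[is_test], k)
      row <- row + 1L
      vals[row, ] <- cnt2 / n_test - (tot - cnt2) / n_ref
    }
    perm[idx] <- labS
  }
  distribution <- purrr::map(seq_len(k), function(c_i) {
    v <- round(vals[, c_i], 12)
    agg <- tapply(rep(p_outcome, length(v)), v, sum)
    tibble(statistic = as.numeric(names(agg)), prob = as.numeric(agg))
  })
  names(distribution) <- obs$cluster
  p_exact <- vapply(seq_len(k), function(c_i) {
    v <- vals[, c_i]
    if (sided == "two") {
      sum((abs(v) >= abs(obs$statistic[c_i]) - 1e-12) * p_outcome)
    } else {
      sum((v >= obs$statistic[c_i] - 1e-12) * p_outcome)
    }
  }, numeric(1))
  p_exact <- pmin(p_exact, 1) # guard against accumulated rounding
  structure(
    list(
      result = mutate(obs, p_exact = p_exact),
      distribution = distribution,
      groups = c(reference = gg$reference, test = gg$test),
      w = w, subset_size = m, n_outcomes = n_outcomes, sided = sided
    ),
    class = "dpa_exact"
  )
}

# All permutations of 1..m as rows (m <= 9 under the enumeration guard).
perm_matrix <- function(m) {
  if (m == 1) return(matrix(1L, 1, 1))
  sub <- perm_matrix(m - 1L)
  out <- vector("list", m)
  for (i in seq_len(m)) {
    rest <- sub + (sub >= i)
    out[[i]] <- cbind(rep(i, nrow(sub)), rest)
  }
  do.call(rbind, out)
}

#' @export
print.dpa_result <- function(x, ...) {
  cat(sprintf(
    "Differential proportion analysis: %s (n=%d) vs %s (n=%d)\n",
    x$groups["test"], x$group_sizes["test"],
    x$groups["reference"], x$group_sizes["reference"]
  ))
  cat(sprintf(
    "  w = %g (%d of %d labels shuffled/iteration), B = %d, %s-sided, alpha = %g\n",
    x$w, x$subset_size, x$n_cells, x$iterations, x$sided, x$alpha
  ))
  print(x$result, ...)
  invisible(x)
}

#' @export
print.dpa_exact <- function(x, ...) {
  cat(sprintf(
    "Exact DPA null (w = %g, %d cells shuffled, %.0f outcomes enumerated)\n",
    x$w, x$subset_size, x$n_outcomes
  ))
  print(x$result, ...)
  invisible(x)
}

#' Tidy a DPA result
#'
#' @param x A [dpa_test()] result.
#' @param ... Unused.
#' @return A tibble with one row per cluster: group cell counts and
#'   proportions, the proportion-difference statistic, the empirical and
#'   Bonferroni-adjusted p-values, the significance flag at the configured
#'   alpha, and the small-cluster reliability flag.
#' @method tidy dpa_result
#' @export
tidy.dpa_result <- function(x, ...) {
  x$result
}

#' One-row summary of a DPA run
#'
#' @param x A [dpa_test()] result.
#' @param ... Unused.
#' @return A tibble with the test configuration and the number of
#'   significant clusters.
#' @method glance dpa_result
#' @export
glance.dpa_result <- function(x, ...) {
  tibble(
    n_cells = x$n_cells, n_clusters = x$n_clusters,
    reference = unname(x$groups["reference"]), test = unname(x$groups["test"]),
    w = x$w, iterations = x$iterations, alpha = x$alpha,
    sided = x$sided, mode = x$mode,
    n_significant = sum(x$result$significant),
    min_p_empirical = min(x$result$p_empirical)
  )
}

#' @method tidy dpa_exact
#' @export
tidy.dpa_exact <- function(x, ...) x$result
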