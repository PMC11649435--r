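# Internal helpers shared across modules.

#' Derive a stage-specific child seed from a master seed
#'
#' All randomness in the package flows from a single master seed; each
#' pipeline stage uses a child seed obtained by a fixed, documented offset so
#' that stages are individually reproducible and mutually independent of
#' execution order. Offsets: cells = 1, counts = 2, clinical = 3, dpa = 4.
#' The result is kept below 2^31 - 1.
#'
#' @param master Integer master seed.
#' @param stage One of `"cells"`, `"counts"`, `"clinical"`, `"dpa"`.
#' @return An integer seed.
#' @export
#' @examples
#' child_seed(1, "cells")
child_seed <- function(master, stage = c("cells", "counts", "clinical", "dpa")) {
  stage <- match.arg(stage)
  offsets <- c(cells = 1L, counts = 2L, clinical = 3L, dpa = 4L)
  master <- as.integer(master)
  if (is.na(master)) abort("`master` must be a finite integer seed.")
  (abs(master) %% 1000000000L) + 1000L * offsets[[stage]]
}

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
# A NULL seed uses (and advances) the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Require columns in a data frame, with an error that names what is missing.
check_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column%s: %s",
      what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                lower_open = FALSE, upper_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  ok_lower <- if (lower_open) x > lower else x >= lower
  ok_upper <- if (upper_open) x < upper else x <= upper
  if (!ok_lower || !ok_upper) {
    abort(sprintf(
      "`%s` must be in %s%s, %s%s (got %g).", name,
      if (lower_open) "(" else "[", format(lower),
      format(upper), if (upper_open) ")" else "]", x
    ))
  }
  invisible(x)
}

# Sample one Dirichlet vector; zero concentrations yield exact zeros.
rdirichlet1 <- function(alpha) {
  g <- numeric(length(alpha))
  pos <- alpha > 0
  g[pos] <- rgamma(sum(pos), shape = alpha[pos], rate = 1)
  s <- sum(g)
  if (s == 0) {
    abort("Dirichlet draw degenerate: all concentrations are zero.")
  }
  g / s
}

# Exact inverse-CDF sampling from a normal truncated to [lower, upper].
rnorm_truncated <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) {
    return(rep(pmin(pmax(mean, lower), upper), n))
  }
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}
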