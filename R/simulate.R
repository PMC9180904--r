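#' Sample a cohort table from a correlation structure
#'
#' Draws `n` subjects through a Gaussian copula: latent multivariate normal
#' variates with Pearson correlation \eqn{2\sin(\pi\rho_S/6)} (the exact
#' latent correlation whose population Spearman equals the target), mapped
#' through the probability integral transform to each variable's declared
#' marginal. Because every marginal quantile function is monotone, the
#' population Spearman correlation of the output equals `target_spearman`.
#'
#' @param structure A [correlation_structure()].
#' @param n Number of subjects (>= 4).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @param group Optional group label stored in a leading `group` column.
#' @return A tibble with `n` rows: a `group` column (if requested) followed
#'   by one numeric column per panel variable.
#' @examples
#' cs <- correlation_structure(default_panel(), diag(30))
#' tab <- sample_group(cs, n = 20, seed = 7, group = "NTN")
#' @export
sample_group <- function(structure, n, seed, group = NULL) {
  stopifnot(inherits(structure, "correlation_structure"))
  if (n < 4) stop("n must be at least 4", call. = FALSE)
  panel <- structure$panel
  sigma <- structure$latent_pearson
  # clip tiny negative eigenvalues from numerical noise; construction already
  # rejected materially non-PSD targets
  z <- withr::with_seed(as.integer(seed), {
    MASS::mvrnorm(n = n, mu = rep(0, nrow(panel)), Sigma = sigma, tol = 1e-6)
  })
  u <- stats::pnorm(z)
  cols <- lapply(seq_len(nrow(panel)), function(j) {
    marginal_quantile(panel$marginal[[j]], u[, j])
  })
  names(cols) <- panel$name
  out <- tibble::as_tibble(cols)
  if (!is.null(group)) {
    out <- dplyr::bind_cols(tibble::tibble(group = rep(group, n)), out)
  }
  out
}

#' Inject missing values completely at random
#'
#' Sets each non-grouping cell to `NA` independently with probability
#' `rate`, redrawing any column's missingness pattern until at least 4
#' observed values remain (pairwise correlation needs >= 4 complete pairs).
#'
#' @param table Cohort tibble (a `group` column, if present, is untouched).
#' @param rate Missingness probability in \[0, 1).
#' @param seed Integer seed.
#' @return The table with `NA`s injected.
#' @export
inject_missing <- function(table, rate, seed) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)", call. = FALSE)
  if (rate == 0) return(table)
  vars <- setdiff(names(table), "group")
  n <- nrow(table)
  withr::with_seed(as.integer(seed), {
    for (v in vars) {
      repeat {
        miss <- stats::runif(n) < rate
        if (sum(!miss) >= 4) break
      }
      table[[v]][miss] <- NA
    }
  })
  table
}

#' Generate the two cohort tables of a scenario
#'
#' Samples both groups of a [scenario_config()] with disjoint sub-seeds
#' derived deterministically from the master seed (an LCG step,
#' `(1103515245 * seed + 12345 + i) mod (2^31 - 1)`, with `i` indexing the
#' group and the missingness stream), then applies MCAR missingness if the
#' scenario requests it.
#'
#' @param config A `scenario_config`.
#' @return A named list of two tibbles (names = group names), each carrying
#'   its `group` column; identical configs produce identical tables.
#' @examples
#' study <- make_two_group_study(default_scenario(seed = 1))
#' sapply(study, nrow)
#' @export
make_two_group_study <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  tabs <- list()
  for (i in 1:2) {
    g <- config[[c("group_a", "group_b")[i]]]
    tab <- sample_group(g$structure, g$n, seed = derive_subseed(config$seed, i),
                        group = g$name)
    if (config$missing_rate > 0) {
      tab <- inject_missing(tab, config$missing_rate,
                            seed = derive_subseed(config$seed, i + 2L))
    }
    tabs[[g$name]] <- tab
  }
  tabs
}

#' Write / read a cohort table as CSV
#'
#' The CSV contract is a header row of variable names plus one metadata
#' column `group`; synthetic and user-supplied cohorts share it.
#'
#' @param table Cohort tibble.
#' @param path File path.
#' @return `write_cohort_csv()` returns `path` invisibly; `read_cohort_csv()`
#'   returns a tibble.
#' @export
write_cohort_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
}
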