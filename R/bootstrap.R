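#' Parametric bootstrap for variance components and powered fractions
#'
#' Simulates `n_boot` full datasets from the fitted hierarchical Gaussian
#' model — analyte shifts redrawn from N(0, fitted v_d), per-sample biology
#' and per-observation noise at each analyte's fitted (truncated) variances —
#' under the ORIGINAL replication design (same samples, same per-cell
#' replicate counts), re-estimates every quantity on each, and records the
#' draws. This yields percentile confidence intervals for v_d, the
#' analyte-averaged components, and (when `sif_grid` is supplied) the
#' percentage of analytes powered at each inflation factor.
#'
#' Analyte-level means are re-randomized in every replicate (analytes are
#' exchangeable under the model) rather than conditioned on the fitted
#' a^(k); this choice is recorded in the result metadata.
#'
#' @param decomposition a `variance_decomposition` from [decompose_all()].
#' @param profile the matching `repeatability_profile`.
#' @param table the original [replicate_table()] (supplies the design).
#' @param n_boot number of bootstrap replicates (>= 1).
#' @param seed RNG seed; results are reproducible given (seed, n_boot).
#' @param sif_grid optional SIF values at which to re-compute the powered
#'   percentage on every draw.
#' @return class `bootstrap_result`: list with `draws` (data.frame, one row
#'   per replicate: `v_d`, `v_b_bar`, `v_e_bar`, and one `pct_powered_<sif>`
#'   column per grid value), `n_boot`, `seed`, `sif_grid`, and
#'   `redraw_analyte_means = TRUE`.
#' @export
parametric_bootstrap <- function(decomposition, profile, table,
                                 n_boot = 1000L, seed = 1L, sif_grid = NULL) {
  stopifnot(inherits(decomposition, "variance_decomposition"),
            inherits(profile, "repeatability_profile"),
            inherits(table, "replicate_table"))
  if (n_boot < 1L) .err("iccpower_parameter_error", "n_boot must be >= 1")
  ids <- profile$analyte_id
  if (!identical(sort(ids), sort(names(decomposition$v_b)))) {
    .err("iccpower_parameter_error",
         "profile and decomposition cover different analytes")
  }
  d <- table$data[analyte_id %in% ids]
  cells <- d[, .(n = .N), by = .(analyte_id, sample_id)]
  # the design is uniform when every analyte shares the same (sample, n) cells
  pattern <- cells[order(sample_id), paste(sample_id, n, collapse = ";"),
                   by = analyte_id]
  uniform <- length(unique(pattern$V1)) == 1L

  p <- length(ids)
  v_b <- decomposition$v_b[ids]
  v_e <- decomposition$v_e[ids]
  v_d <- decomposition$v_d
  mu <- decomposition$mu_hat
  if (!is.finite(v_d)) {
    .err("iccpower_parameter_error",
         "fitted v_d is unavailable; need >= 2 estimable analytes")
  }

  set.seed(seed)
  draw_names <- c("v_d", "v_b_bar", "v_e_bar",
                  if (length(sif_grid)) paste0("pct_powered_", sif_grid))
  draws <- matrix(NA_real_, nrow = n_boot, ncol = length(draw_names),
                  dimnames = list(NULL, draw_names))

  if (uniform) {
    rep_counts <- cells[analyte_id == ids[1L]][order(sample_id), n]
    for (b in seq_len(n_boot)) {
      a <- stats::rnorm(p, 0, sqrt(v_d))
      sim <- .sim_matrix(p, rep_counts, mu, a, v_b, v_e)
      est <- .anova_matrix(sim$Y, sim$sample_idx)
      draws[b, ] <- .boot_summaries(est$v_b_raw, est$v_e, est$mean, est$n_i,
                                    sif_grid)
    }
  } else {
    # general path: simulate on the original long layout per replicate
    d_design <- d[, .(analyte_id, sample_id)]
    cell_key <- cells[, .(analyte_id, sample_id)]
    v_b_cell <- v_b[cell_key$analyte_id]
    v_e_obs <- v_e[d_design$analyte_id]
    cell_of_row <- cells[d_design, on = c("analyte_id", "sample_id"),
                         which = TRUE]
    a_index <- match(d_design$analyte_id, ids)
    for (b in seq_len(n_boot)) {
      a <- stats::rnorm(p, 0, sqrt(v_d))
      b_cell <- stats::rnorm(nrow(cell_key), 0, sqrt(v_b_cell))
      y <- mu + a[a_index] + b_cell[cell_of_row] +
        stats::rnorm(nrow(d_design), 0, sqrt(v_e_obs))
      sim_tab <- replicate_table(data.frame(
        analyte_id = d_design$analyte_id, sample_id = d_design$sample_id,
        replicate_id = d$replicate_id, value = y))
      fit <- decompose_all(sim_tab)
      dec <- fit$decomposition
      sv <- mapply(.grand_mean_sampling_var, dec$v_b, dec$v_e,
                   split(cells$n, cells$analyte_id)[names(dec$v_b)])
      draws[b, ] <- c(estimate_dynamic_range(dec$mu_analyte, sv),
                      dec$v_b_bar, dec$v_e_bar,
                      if (length(sif_grid)) {
                        vapply(sif_grid,
                               function(s) fraction_powered(fit$profile$R, s),
                               numeric(1))
                      })
    }
  }

  structure(list(draws = as.data.frame(draws), n_boot = as.integer(n_boot),
                 seed = as.integer(seed), sif_grid = sif_grid,
                 redraw_analyte_means = TRUE),
            class = "bootstrap_result")
}

# Summaries recomputed on each bootstrap draw (matrix fast path).
.boot_summaries <- function(v_b_raw, v_e, means, n_i, sif_grid) {
  v_b_t <- pmax(v_b_raw, 0)
  sv <- (sum(n_i^2) * v_b_t + sum(n_i) * v_e) / sum(n_i)^2
  v_d_hat <- max(stats::var(means) - mean(sv), 0)
  out <- c(v_d_hat, mean(v_b_t), mean(v_e))
  if (length(sif_grid)) {
    R <- ifelse(v_b_t + v_e == 0, 0, v_b_t / (v_b_t + v_e))
    out <- c(out, vapply(sif_grid, function(s) 100 * mean(s * R > 1),
                         numeric(1)))
  }
  out
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("bootstrap_result: %d replicates (seed %d)\n", x$n_boot, x$seed))
  invisible(x)
}

#' Percentile confidence interval from bootstrap draws
#'
#' Empirical percentile interval: the (1-level)/2 and 1-(1-level)/2
#' quantiles of the draws, with linear interpolation (the default type-7
#' definition).
#'
#' @param draws numeric vector of bootstrap re-estimates.
#' @param level coverage level in (0, 1).
#' @return named numeric vector `c(lower, upper)`.
#' @examples
#' ci_percentile(1:100, 0.95)  # c(3.475, 97.525)
#' @export
ci_percentile <- function(draws, level = 0.95) {
  if (length(draws) == 0L) .err("iccpower_parameter_error", "no draws supplied")
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    .err("iccpower_parameter_error", "level must be strictly inside (0, 1)")
  }
  q <- stats::quantile(draws, c((1 - level) / 2, 1 - (1 - level) / 2),
                       names = FALSE, type = 7)
  c(lower = q[1], upper = q[2])
}

#' Bootstrap bands for the powered-percentage curve
#'
#' Per-SIF percentile intervals of the percentage of analytes powered,
#' extracted from a [parametric_bootstrap()] run that was given the same
#' grid.
#'
#' @param result a `bootstrap_result` containing per-SIF draws.
#' @param sif_grid the SIF grid (must match the one bootstrapped).
#' @param level coverage level.
#' @return a data.frame with columns `sif`, `lower`, `upper` (percentages).
#' @export
powered_fraction_bands <- function(result, sif_grid, level = 0.95) {
  stopifnot(inherits(result, "bootstrap_result"))
  cols <- paste0("pct_powered_", sif_grid)
  if (!all(cols %in% names(result$draws))) {
    .err("iccpower_parameter_error",
         "requested sif_grid was not bootstrapped in this result")
  }
  ci <- vapply(cols, function(cn) ci_percentile(result$draws[[cn]], level),
               numeric(2))
  data.frame(sif = sif_grid, lower = ci[1, ], upper = ci[2, ],
             row.names = NULL)
}
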