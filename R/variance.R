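#' Closed-form ANOVA decomposition for one analyte
#'
#' Method-of-moments estimation of the one-way random-effects model for a
#' single analyte: sample i contributes n_i technical replicates y_ij around
#' its own biological level. The estimators are the classical unbalanced
#' ANOVA ones: v_e is the within-sample mean square
#' MSW = sum_ij (y_ij - ybar_i)^2 / (N - I), and v_b is
#' (MSB - MSW) / n0' with MSB = sum_i n_i (ybar_i - ybar)^2 / (I - 1) and
#' n0' = (N - sum_i n_i^2 / N) / (I - 1). The biological-variance estimate is
#' returned UNTRUNCATED (it can be negative when sample means are more
#' homogeneous than the replicate noise predicts); apply
#' [truncate_negative()] before computing repeatability.
#'
#' @param cells a list of numeric vectors, one per biological sample, each
#'   holding that sample's replicate measurements for this analyte.
#' @return a list with `v_b_hat` (untruncated), `v_e_hat`, `mean` (the grand
#'   mean over all observations), and the degrees-of-freedom bookkeeping
#'   (`n_samples`, `n_obs`).
#' @examples
#' anova_decompose(list(A = c(1.0, 1.2), B = c(2.0, 2.2), C = 3.1))
#' @export
anova_decompose <- function(cells) {
  if (!is.list(cells)) cells <- as.list(cells)
  values <- unlist(cells, use.names = FALSE)
  if (any(!is.finite(values))) {
    .err("iccpower_data_error", "non-finite measurement values")
  }
  n_i <- lengths(cells)
  I <- length(cells)
  N <- sum(n_i)
  if (I < 2L) .err("iccpower_design_error", "need >= 2 biological samples")
  if (N - I < 1L) {
    .err("iccpower_design_error",
         "need at least one sample with >= 2 replicates (N - I >= 1)")
  }
  means <- vapply(cells, mean, numeric(1))
  grand <- sum(values) / N
  ssw <- sum((values - rep(means, n_i))^2)
  ssb <- sum(n_i * (means - grand)^2)
  msw <- ssw / (N - I)
  msb <- ssb / (I - 1)
  n0p <- (N - sum(n_i^2) / N) / (I - 1)
  list(v_b_hat = (msb - msw) / n0p, v_e_hat = msw, mean = grand,
       n_samples = I, n_obs = N)
}

#' Set a negative variance estimate to zero
#'
#' Method-of-moments variance estimates can be negative although the
#' estimand is non-negative; truncating at zero introduces an upward bias but
#' reduces mean-squared error.
#'
#' @param v a finite variance estimate.
#' @return `max(v, 0)`.
#' @export
truncate_negative <- function(v) {
  if (!is.numeric(v) || any(!is.finite(v))) {
    .err("iccpower_data_error", "variance estimate must be finite")
  }
  pmax(v, 0)
}

#' Repeatability (intraclass correlation coefficient)
#'
#' The proportion of total observed variance at an analyte attributable to
#' biological sources: R = v_b / (v_b + v_e). R = 1 means the analyte is
#' measured perfectly (no experimental noise); R near 0 means measurements
#' are dominated by experimental variability. When both components are zero
#' there is no information at the analyte and R is defined as 0 (the
#' conservative choice for design: such analytes are never powered).
#'
#' @param v_b non-negative biological signal variance.
#' @param v_e non-negative experimental noise variance.
#' @return repeatability in `[0, 1]`; vectorized over its arguments.
#' @export
repeatability <- function(v_b, v_e) {
  if (any(v_b < 0) || any(v_e < 0)) {
    .err("iccpower_domain_error",
         "negative variance: apply truncate_negative() before repeatability()")
  }
  tot <- v_b + v_e
  r <- ifelse(tot == 0, 0, v_b / tot)
  as.numeric(r)
}

#' Repeatability coefficient on the measurement scale
#'
#' The 95% one-sided upper bound for the absolute difference between a pair
#' of replicate readings on the same sample: 1.96 * sqrt(2 * v_e). Unlike the
#' ICC this is on the same scale as the instrument, which aids clinical
#' interpretation but ignores biological variation.
#'
#' @param v_e non-negative experimental noise variance.
#' @return the coefficient, in measurement units.
#' @export
ba_repeatability_coefficient <- function(v_e) {
  if (any(!is.finite(v_e)) || any(v_e < 0)) {
    .err("iccpower_domain_error", "v_e must be finite and >= 0")
  }
  1.96 * sqrt(2 * v_e)
}

#' Dynamic-range variance across analytes
#'
#' The dynamic-range variance v_d is the variance of true mean concentration
#' across analytes — the spread that inflates the inter-replicate sample
#' correlation regardless of assay precision. It is estimated as the sample
#' variance (denominator p - 1) of the per-analyte grand means, minus the
#' average sampling variance of those means (each mean is itself noisy under
#' its analyte's design), truncated at zero.
#'
#' @param analyte_means per-analyte grand means.
#' @param mean_sampling_var per-analyte sampling variances of those means;
#'   scalar 0 (default) for exact/noise-free means.
#' @return the estimated v_d (>= 0).
#' @export
estimate_dynamic_range <- function(analyte_means, mean_sampling_var = 0) {
  if (length(analyte_means) < 2L) {
    .err("iccpower_design_error", "need >= 2 analytes to estimate dynamic range")
  }
  truncate_negative(stats::var(analyte_means) - mean(mean_sampling_var))
}

# Sampling variance of an analyte's grand mean under its own design:
# ybar = mu_k + (1/N) sum_i n_i b_i + (1/N) sum_ij e_ij
.grand_mean_sampling_var <- function(v_b, v_e, n_i) {
  N <- sum(n_i)
  sum(n_i^2) * v_b / N^2 + v_e / N
}

#' Estimate all variance components and repeatabilities of a pilot dataset
#'
#' Fits the one-way random-effects model to every analyte by closed-form
#' ANOVA ([anova_decompose()]), truncates negative biological-variance
#' estimates at zero, computes per-analyte repeatability, and estimates the
#' dynamic-range variance across analytes. Analytes whose design is
#' inestimable (fewer than 2 samples with data, or no replicated sample) are
#' excluded with a recorded reason rather than failing the whole run.
#'
#' @param table a [replicate_table()].
#' @return a list with components:
#' \describe{
#'   \item{decomposition}{class `variance_decomposition`: `v_d`, named
#'     per-analyte `v_b` and `v_e` (post-truncation), their analyte-averages
#'     `v_b_bar` and `v_e_bar`, per-analyte `v_b_raw` (pre-truncation),
#'     per-analyte means `mu_analyte`, global mean `mu_hat`, and `excluded`
#'     (named character vector of exclusion reasons).}
#'   \item{profile}{class `repeatability_profile`: per-analyte `R`,
#'     `mean_concentration`, and CI columns (NA until a bootstrap fills
#'     them).}
#' }
#' @export
decompose_all <- function(table) {
  stopifnot(inherits(table, "replicate_table"))
  d <- table$data
  cells <- d[, .(n = .N, m = mean(value),
                 ss = sum((value - mean(value))^2)),
             by = .(analyte_id, sample_id)]
  per_analyte <- cells[, {
    N <- sum(n); I <- .N
    grand <- sum(n * m) / N
    if (I < 2L) {
      list(ok = FALSE, reason = "fewer than 2 samples with data",
           v_b_raw = NA_real_, v_e = NA_real_, mean = grand, sv = NA_real_)
    } else if (N - I < 1L) {
      list(ok = FALSE, reason = "no replicated sample",
           v_b_raw = NA_real_, v_e = NA_real_, mean = grand, sv = NA_real_)
    } else {
      msw <- sum(ss) / (N - I)
      msb <- sum(n * (m - grand)^2) / (I - 1)
      n0p <- (N - sum(n^2) / N) / (I - 1)
      v_b_raw <- (msb - msw) / n0p
      v_b <- max(v_b_raw, 0)
      list(ok = TRUE, reason = NA_character_, v_b_raw = v_b_raw, v_e = msw,
           mean = grand,
           sv = .grand_mean_sampling_var(v_b, msw, n))
    }
  }, by = analyte_id]

  if (!any(per_analyte$ok)) {
    .err("iccpower_design_error", "no analyte has an estimable design")
  }
  excl <- per_analyte[ok == FALSE]
  for (i in seq_len(nrow(excl))) {
    .log_msg("WARN", "analyte ", excl$analyte_id[i], " excluded: ", excl$reason[i])
  }
  est <- per_analyte[ok == TRUE]
  v_b <- stats::setNames(truncate_negative(est$v_b_raw), est$analyte_id)
  v_e <- stats::setNames(est$v_e, est$analyte_id)
  v_d <- if (nrow(est) >= 2L) {
    estimate_dynamic_range(est$mean, est$sv)
  } else {
    NA_real_
  }
  decomposition <- structure(list(
    v_d = v_d,
    v_b = v_b,
    v_e = v_e,
    v_b_raw = stats::setNames(est$v_b_raw, est$analyte_id),
    v_b_bar = mean(v_b),
    v_e_bar = mean(v_e),
    mu_analyte = stats::setNames(est$mean, est$analyte_id),
    mu_hat = mean(d$value),
    excluded = stats::setNames(excl$reason, excl$analyte_id)
  ), class = "variance_decomposition")
  profile <- structure(list(
    analyte_id = est$analyte_id,
    R = repeatability(v_b, v_e),
    mean_concentration = est$mean,
    ci_lower = rep(NA_real_, nrow(est)),
    ci_upper = rep(NA_real_, nrow(est))
  ), class = "repeatability_profile")
  list(decomposition = decomposition, profile = profile)
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat(sprintf(
    "variance_decomposition: %d analytes\n  v_d = %.4g, v_b_bar = %.4g, v_e_bar = %.4g (excluded: %d)\n",
    length(x$v_b), x$v_d, x$v_b_bar, x$v_e_bar, length(x$excluded)))
  invisible(x)
}

#' @export
print.repeatability_profile <- function(x, ...) {
  cat(sprintf("repeatability_profile: %d analytes, median R = %.3f (IQR %.3f-%.3f)\n",
              length(x$R), stats::median(x$R),
              stats::quantile(x$R, .25), stats::quantile(x$R, .75)))
  invisible(x)
}

#' Convert a repeatability profile to a data.frame
#'
#' @param x a `repeatability_profile`.
#' @param ... unused.
#' @return a data.frame with one row per analyte.
#' @export
as.data.frame.repeatability_profile <- function(x, ...) {
  data.frame(analyte_id = x$analyte_id, R = x$R,
             mean_concentration = x$mean_concentration,
             ci_lower = x$ci_lower, ci_upper = x$ci_upper,
             stringsAsFactors = FALSE)
}
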