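#' Exact power of the balanced two-sample t-test
#'
#' Power of the two-sided, equal-variance two-sample t-test with m = n/2
#' subjects per group against a standardized mean difference, computed from
#' the noncentral t distribution: noncentrality delta * sqrt(m / 2) on
#' n - 2 degrees of freedom. When a repeatability `R < 1` is supplied, the
#' effect is attenuated to delta * sqrt(R) first, because measurement noise
#' inflates the per-subject variance from v_b to v_b + v_e (see
#' [effective_effect()]).
#'
#' @param n_total total sample size (even, >= 4; balanced groups).
#' @param delta standardized effect size, |mu_T - mu_C| / sqrt(v_b).
#' @param alpha two-sided significance level.
#' @param R repeatability of the analyte; 1 is a perfect instrument.
#' @return the power, a probability.
#' @examples
#' achieved_power(34, 1, 0.05)          # ~0.807
#' achieved_power(136, 1, 0.05, 0.25)   # SIF = 4 compensates R = 0.25
#' @export
achieved_power <- function(n_total, delta, alpha = 0.05, R = 1) {
  .check_number(n_total, "n_total", lower = 4)
  if (n_total %% 2 != 0) .err("iccpower_parameter_error", "n_total must be even")
  .check_number(delta, "delta", lower = 0)
  .check_number(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1) .err("iccpower_parameter_error", "alpha must be in (0,1)")
  m <- n_total / 2
  ncp <- effective_effect(delta, R) * sqrt(m / 2)
  df <- n_total - 2
  tcrit <- stats::qt(1 - alpha / 2, df)
  1 - stats::pt(tcrit, df, ncp) + stats::pt(-tcrit, df, ncp)
}

#' Baseline sample size for a perfect instrument
#'
#' Smallest even total sample size n0 = 2m such that the balanced two-sided
#' two-sample t-test attains the target power at significance level `alpha`
#' against standardized effect `delta`, assuming a noise-free instrument
#' (repeatability 1). This is the n0 that the sample size inflation factor
#' multiplies.
#'
#' @param delta standardized effect size (> 0), in units of the biological
#'   standard deviation.
#' @param alpha two-sided significance level.
#' @param power_target required power, in (0, 1).
#' @param cap search cap on n0 (guards against unattainable requests).
#' @return the even total sample size n0.
#' @examples
#' base_sample_size(1, 0.05, 0.80)  # 34, i.e. 17 per group
#' @export
base_sample_size <- function(delta, alpha = 0.05, power_target = 0.80,
                             cap = 1e7) {
  .check_number(delta, "delta")
  if (delta <= 0) .err("iccpower_parameter_error", "delta must be > 0")
  if (alpha <= 0 || alpha >= 1) .err("iccpower_parameter_error", "alpha must be in (0,1)")
  if (power_target <= 0 || power_target >= 1) {
    .err("iccpower_parameter_error", "power_target must be in (0,1)")
  }
  m <- 2L
  while (achieved_power(2 * m, delta, alpha) < power_target) {
    m <- m + 1L
    if (2 * m > cap) {
      .err("iccpower_parameter_error",
           sprintf("required sample size exceeds cap %g", cap))
    }
  }
  2L * m
}

#' Sample size inflation threshold of an analyte
#'
#' An analyte with repeatability R is powered once the sample size inflation
#' factor exceeds 1/R — the variance inflation factor by which measurement
#' noise multiplies the variance relevant to detecting a group difference.
#' R = 0 (no biological signal detected) maps to `Inf`: such an analyte is
#' never powered at any finite inflation.
#'
#' @param R repeatability in `[0, 1]`.
#' @return the threshold 1/R (`Inf` at R = 0); vectorized.
#' @export
sif_threshold <- function(R) {
  if (any(!is.finite(R)) || any(R < 0) || any(R > 1)) {
    .err("iccpower_domain_error", "R must lie in [0, 1]")
  }
  ifelse(R == 0, Inf, 1 / R)
}

#' Percentage of analytes powered at a given inflation factor
#'
#' An analyte counts as powered when `sif > 1/R` (strict inequality:
#' boundary analytes are unpowered, and R = 0 is never powered).
#'
#' @param R_values repeatabilities, each in `[0, 1]`.
#' @param sif sample size inflation factor (>= 1).
#' @return percentage in `[0, 100]`.
#' @export
fraction_powered <- function(R_values, sif) {
  if (length(R_values) == 0L) {
    .err("iccpower_parameter_error", "R_values must be non-empty")
  }
  if (any(!is.finite(R_values)) || any(R_values < 0) || any(R_values > 1)) {
    .err("iccpower_domain_error", "all R values must lie in [0, 1]")
  }
  .check_number(sif, "sif", lower = 1)
  100 * mean(sif > sif_threshold(R_values))
}

#' Inflate the baseline sample size by a SIF
#'
#' n = SIF x n0, rounded up to the nearest even integer so the two groups
#' stay balanced.
#'
#' @param n0 baseline (perfect-instrument) total sample size, even, positive.
#' @param sif inflation factor (>= 1).
#' @return the adjusted even total sample size.
#' @examples
#' adjusted_sample_size(34, 4)    # 136
#' adjusted_sample_size(34, 1.1)  # 38
#' @export
adjusted_sample_size <- function(n0, sif) {
  .check_number(n0, "n0", lower = 2)
  if (n0 %% 2 != 0) .err("iccpower_parameter_error", "n0 must be even")
  .check_number(sif, "sif", lower = 1)
  2 * ceiling(sif * n0 / 2)
}

#' Bonferroni-adjusted per-test significance level
#'
#' When tests are performed at each of `n_tests` analytes, dividing alpha by
#' the number of tests controls the family-wise error rate.
#'
#' @param alpha nominal family-wise level.
#' @param n_tests number of analytes tested (>= 1).
#' @return the per-test level alpha / n_tests.
#' @export
bonferroni_alpha <- function(alpha, n_tests) {
  if (alpha <= 0 || alpha >= 1) .err("iccpower_parameter_error", "alpha must be in (0,1)")
  if (!is.numeric(n_tests) || length(n_tests) != 1L || !is.finite(n_tests) ||
      n_tests < 1) {
    .err("iccpower_parameter_error", "n_tests must be >= 1")
  }
  alpha / n_tests
}

#' Attenuated effect size on the measured scale
#'
#' Measurement noise inflates the per-subject variance from v_b to
#' v_b + v_e, so the standardized effect observable in the data shrinks from
#' delta to delta * sqrt(R).
#'
#' @param delta standardized biological effect (>= 0).
#' @param R repeatability in `[0, 1]`.
#' @return the observable standardized effect.
#' @export
effective_effect <- function(delta, R) {
  .check_number(delta, "delta", lower = 0)
  .check_number(R, "R", lower = 0, upper = 1)
  delta * sqrt(R)
}

#' Monte-Carlo power of the balanced two-sample t-test under measurement noise
#'
#' Simulates balanced two-group experiments in which each subject's
#' measurement is its biological level (variance `v_b`, group means differing
#' by `delta * sqrt(v_b)`) plus independent measurement error (variance
#' `v_e`), applies the two-sided pooled-variance t-test at level `alpha`, and
#' returns the rejection rate. Used to verify the inflation rule by
#' simulation, independently of the noncentral-t formula in
#' [achieved_power()].
#'
#' @param n_per_group subjects per group.
#' @param delta standardized biological effect.
#' @param alpha significance level.
#' @param v_b,v_e biological and noise variance per subject.
#' @param n_sim number of simulated experiments.
#' @param seed RNG seed.
#' @return empirical power (rejection proportion).
#' @export
mc_power_two_sample <- function(n_per_group, delta, alpha = 0.05,
                                v_b = 1, v_e = 0, n_sim = 1e5, seed = 1L) {
  .check_number(n_per_group, "n_per_group", lower = 2)
  .check_number(v_b, "v_b", lower = 0)
  .check_number(v_e, "v_e", lower = 0)
  set.seed(seed)
  m <- as.integer(n_per_group)
  sd_obs <- sqrt(v_b + v_e)
  shift <- delta * sqrt(v_b)
  tcrit <- stats::qt(1 - alpha / 2, df = 2 * m - 2)
  chunk <- max(1L, as.integer(floor(2e7 / (2 * m))))
  rejected <- 0L
  done <- 0L
  while (done < n_sim) {
    b <- min(chunk, n_sim - done)
    xt <- matrix(stats::rnorm(m * b, mean = shift, sd = sd_obs), nrow = m)
    xc <- matrix(stats::rnorm(m * b, mean = 0, sd = sd_obs), nrow = m)
    mt <- colMeans(xt); mc <- colMeans(xc)
    sst <- colSums(xt^2) - m * mt^2
    ssc <- colSums(xc^2) - m * mc^2
    pooled <- (sst + ssc) / (2 * m - 2)
    tstat <- (mt - mc) / sqrt(pooled * 2 / m)
    rejected <- rejected + sum(abs(tstat) > tcrit)
    done <- done + b
  }
  rejected / n_sim
}

#' Table of percentage of analytes powered across SIF values
#'
#' The design-planning report: for each candidate inflation factor, the
#' percentage of the assay's analytes whose repeatability clears the 1/R
#' threshold, optionally with bootstrap confidence bands and the adjusted
#' total sample size implied by a baseline n0.
#'
#' @param profile a `repeatability_profile` from [decompose_all()].
#' @param sif_grid inflation factors to tabulate (each >= 1).
#' @param bands optional data.frame with columns `sif`, `lower`, `upper` from
#'   [powered_fraction_bands()].
#' @param n0 optional baseline sample size; adds an `n_adjusted` column.
#' @return a data.frame with columns `sif`, `pct_powered`, optional
#'   `lower`/`upper`, optional `n_adjusted`.
#' @export
power_table <- function(profile, sif_grid, bands = NULL, n0 = NULL) {
  stopifnot(inherits(profile, "repeatability_profile"))
  if (length(profile$R) == 0L) {
    .err("iccpower_parameter_error", "profile is empty")
  }
  if (length(sif_grid) == 0L) {
    .err("iccpower_parameter_error", "sif_grid is empty")
  }
  out <- data.frame(
    sif = sif_grid,
    pct_powered = vapply(sif_grid, function(s) fraction_powered(profile$R, s),
                         numeric(1))
  )
  if (!is.null(bands)) {
    if (!identical(as.numeric(bands$sif), as.numeric(sif_grid))) {
      .err("iccpower_parameter_error", "bands grid does not match sif_grid")
    }
    out$lower <- bands$lower
    out$upper <- bands$upper
  }
  if (!is.null(n0)) {
    out$n_adjusted <- vapply(sif_grid, function(s) adjusted_sample_size(n0, s),
                             numeric(1))
  }
  out
}
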