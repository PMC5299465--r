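#' Distribution laws for per-analyte variances
#'
#' Per-analyte biological and noise variances can be held constant across
#' analytes (useful for parameter-recovery checks) or drawn from a log-normal
#' law to emulate the wide spread of repeatabilities seen on real assays.
#' `law_lognormal()` is parameterized by the desired mean on the variance
#' scale and the log-scale sd, so `law_lognormal(mean = 0.05, sdlog = 1)`
#' draws variances averaging 0.05.
#'
#' @param value constant variance (>= 0).
#' @return a law object consumed by [simulation_config()].
#' @export
law_constant <- function(value) {
  .check_number(value, "value", lower = 0)
  structure(list(dist = "constant", value = value), class = "iccpower_law")
}

#' @rdname law_constant
#' @param mean desired mean of the drawn variances (> 0).
#' @param sdlog log-scale standard deviation (>= 0).
#' @export
law_lognormal <- function(mean, sdlog) {
  .check_number(mean, "mean", lower = 0)
  .check_number(sdlog, "sdlog", lower = 0)
  if (mean <= 0) .err("iccpower_parameter_error", "lognormal mean must be > 0")
  structure(list(dist = "lognormal", meanlog = log(mean) - sdlog^2 / 2,
                 sdlog = sdlog), class = "iccpower_law")
}

.draw_law <- function(law, p) {
  if (is.numeric(law) && length(law) == 1L) law <- law_constant(law)
  if (!inherits(law, "iccpower_law")) {
    .err("iccpower_parameter_error",
         "variance law must be a number, law_constant() or law_lognormal()")
  }
  switch(law$dist,
         constant = rep(law$value, p),
         lognormal = stats::rlnorm(p, law$meanlog, law$sdlog))
}

#' Configuration of a synthetic technical-replicate pilot
#'
#' Describes a dataset generated from the hierarchical Gaussian model
#' y_ij^(k) = mu + a^(k) + b_i^(k) + e_ij^(k): analyte level shifts a^(k)
#' with dynamic-range variance `v_d`, per-sample biological deviations with
#' variance v_b^(k), and per-observation noise with variance v_e^(k). By
#' default the first `n_replicated` samples receive 2 technical replicates
#' and the remainder 1, matching the usual pilot design in which only a
#' subset of samples is run in duplicate.
#'
#' @param p number of analytes (>= 1).
#' @param n_samples number of biological samples.
#' @param n_replicated number of samples given 2 replicates (<= n_samples);
#'   default: all of them.
#' @param replicate_counts optional explicit per-sample replicate counts
#'   (length `n_samples`), overriding `n_replicated`.
#' @param mu global mean log-concentration.
#' @param v_d dynamic-range variance (>= 0).
#' @param v_b_law per-analyte biological variance: a number (constant) or a
#'   law from [law_constant()] / [law_lognormal()].
#' @param v_e_law per-analyte noise variance, same forms.
#' @param noise_link optional function of the analyte's mean concentration
#'   (mu + a^(k)) returning a non-negative multiplier applied to v_e^(k);
#'   use a decreasing link to emulate low-concentration analytes being
#'   noisier.
#' @param seed RNG seed; generation is a pure function of (config, seed).
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(p, n_samples, n_replicated = n_samples,
                              replicate_counts = NULL, mu = 0, v_d = 1,
                              v_b_law = 0.05, v_e_law = 0.05,
                              noise_link = NULL, seed = 1L) {
  .check_number(p, "p", lower = 1)
  .check_number(n_samples, "n_samples", lower = 1)
  .check_number(n_replicated, "n_replicated", lower = 0, upper = n_samples)
  .check_number(v_d, "v_d", lower = 0)
  if (!is.null(replicate_counts)) {
    if (length(replicate_counts) != n_samples || any(replicate_counts < 1)) {
      .err("iccpower_parameter_error",
           "replicate_counts must have one entry >= 1 per sample")
    }
  }
  if (!is.null(noise_link) && !is.function(noise_link)) {
    .err("iccpower_parameter_error", "noise_link must be a function or NULL")
  }
  structure(list(p = as.integer(p), n_samples = as.integer(n_samples),
                 n_replicated = as.integer(n_replicated),
                 replicate_counts = replicate_counts, mu = mu, v_d = v_d,
                 v_b_law = v_b_law, v_e_law = v_e_law,
                 noise_link = noise_link, seed = as.integer(seed)),
            class = "simulation_config")
}

# Matrix-form simulation core: returns the p x N observation matrix plus the
# column -> sample index map. Used by simulate_dataset() and by the
# parametric bootstrap (where it is the hot loop).
.sim_matrix <- function(p, rep_counts, mu, a, v_b, v_e) {
  I <- length(rep_counts)
  N <- sum(rep_counts)
  sample_idx <- rep.int(seq_len(I), rep_counts)
  B <- matrix(stats::rnorm(p * I), nrow = p) * sqrt(v_b)
  E <- matrix(stats::rnorm(p * N), nrow = p) * sqrt(v_e)
  Y <- mu + a + B[, sample_idx, drop = FALSE] + E
  list(Y = Y, sample_idx = sample_idx)
}

# Matrix-form unbalanced one-way ANOVA across all analytes at once.
# Y: p x N; sample_idx: length-N integer map to samples 1..I.
.anova_matrix <- function(Y, sample_idx) {
  n_i <- tabulate(sample_idx)
  I <- length(n_i)
  N <- length(sample_idx)
  G <- outer(seq_len(I), sample_idx, "==") * 1 # I x N indicator
  S <- Y %*% t(G)                              # p x I per-sample sums
  Ssq_over_n <- sweep(S^2, 2, n_i, "/")
  grand <- rowSums(Y) / N
  ssw <- rowSums(Y^2) - rowSums(Ssq_over_n)
  ssb <- rowSums(Ssq_over_n) - N * grand^2
  msw <- ssw / (N - I)
  msb <- ssb / (I - 1)
  n0p <- (N - sum(n_i^2) / N) / (I - 1)
  list(v_b_raw = (msb - msw) / n0p, v_e = msw, mean = grand, n_i = n_i)
}

#' Simulate a technical-replicate pilot dataset
#'
#' Draws a dataset from the hierarchical Gaussian model described in
#' [simulation_config()] and returns it as a [replicate_table()] together
#' with the generating truth (analyte shifts and per-analyte variances), so
#' that estimator behaviour can be checked against known values.
#'
#' @param config a [simulation_config()].
#' @return a list with `table` (a [replicate_table()]) and `truth` (list with
#'   `a`, `v_b`, `v_e`, `mu`, `v_d`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  p <- config$p
  a <- stats::rnorm(p, 0, sqrt(config$v_d))
  v_b <- .draw_law(config$v_b_law, p)
  v_e <- .draw_law(config$v_e_law, p)
  if (!is.null(config$noise_link)) {
    mult <- config$noise_link(config$mu + a)
    if (any(!is.finite(mult)) || any(mult < 0)) {
      .err("iccpower_parameter_error",
           "noise_link must return finite non-negative multipliers")
    }
    v_e <- v_e * mult
  }
  rep_counts <- config$replicate_counts
  if (is.null(rep_counts)) {
    rep_counts <- c(rep(2L, config$n_replicated),
                    rep(1L, config$n_samples - config$n_replicated))
  }
  sim <- .sim_matrix(p, rep_counts, config$mu, a, v_b, v_e)

  analyte_ids <- sprintf("A%05d", seq_len(p))
  sample_ids <- sprintf("S%04d", seq_len(config$n_samples))
  rep_within <- sequence(rep_counts)
  long <- data.table::data.table(
    analyte_id = rep(analyte_ids, times = length(sim$sample_idx)),
    sample_id = rep(sample_ids[sim$sample_idx], each = p),
    replicate_id = rep(rep_within, each = p),
    value = as.vector(sim$Y)
  )
  truth <- list(a = stats::setNames(a, analyte_ids),
                v_b = stats::setNames(v_b, analyte_ids),
                v_e = stats::setNames(v_e, analyte_ids),
                mu = config$mu, v_d = config$v_d)
  list(table = replicate_table(long), truth = truth)
}

#' Minimal demonstration of the dynamic-range confound
#'
#' Generates the pedagogical three-analyte example: one biological sample
#' measured in two technical replicates on three analytes whose mean
#' concentrations span a wide dynamic range, while biological signal and
#' experimental noise are comparable in size. The replicate scatter across
#' the three analytes then shows near-perfect correlation even though the
#' assay is, per analyte, quite noisy — which is exactly why r misleads.
#'
#' @param seed RNG seed.
#' @param v_d dynamic-range variance (wide by default).
#' @param v_b,v_e biological and noise variances (comparable by default).
#' @param p number of analytes (3 for the classic picture).
#' @return a list with `table` (a [replicate_table()]) and `truth`.
#' @export
simulate_confound_demo <- function(seed = 1L, v_d = 9, v_b = 0.05,
                                   v_e = 0.05, p = 3L) {
  cfg <- simulation_config(p = p, n_samples = 1L, n_replicated = 1L,
                           mu = 10, v_d = v_d, v_b_law = v_b, v_e_law = v_e,
                           seed = seed)
  simulate_dataset(cfg)
}
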