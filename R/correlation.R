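#' Inter-replicate sample correlation across analytes
#'
#' The correlation commonly reported from replicate scatterplots: for one
#' biological sample measured twice, the Pearson correlation across analytes
#' between the two replicate vectors. Despite its popularity this is NOT a
#' measure of assay precision — as the number of analytes grows it converges
#' to (v_d + v_b_bar) / (v_d + v_b_bar + v_e_bar), so a wide dynamic range
#' v_d drives r toward 1 regardless of how noisy the instrument is (see
#' [asymptotic_correlation()]).
#'
#' @param table a [replicate_table()].
#' @param sample_id which biological sample to use; default: the first sample
#'   (in sorted order) with two replicates on at least 3 analytes.
#' @param replicate_pair integer pair of replicate indices, default `c(1, 2)`.
#' @return the Pearson correlation, computed over analytes where both
#'   replicates are non-missing.
#' @export
replicate_correlation <- function(table, sample_id = NULL,
                                  replicate_pair = c(1L, 2L)) {
  v <- .replicate_pair_vectors(table, sample_id, replicate_pair)
  stats::cor(v$x, v$y)
}

# Extract the two replicate vectors (one entry per complete analyte) for a
# sample; shared by the correlation, convergence and scatterplot code.
.replicate_pair_vectors <- function(table, sample_id = NULL,
                                    replicate_pair = c(1L, 2L)) {
  stopifnot(inherits(table, "replicate_table"), length(replicate_pair) == 2L)
  d <- table$data
  if (is.null(sample_id)) {
    counts <- d[replicate_id %in% replicate_pair,
                .(n_complete = sum(.N == 2L)),
                by = .(sample_id, analyte_id)][
                  , .(n_complete = sum(n_complete)), by = sample_id]
    ok <- counts[n_complete >= 3L][order(sample_id)]
    if (nrow(ok) == 0L) {
      .err("iccpower_data_error",
           "no sample has both replicates on >= 3 analytes")
    }
    sample_id <- ok$sample_id[1L]
  }
  sid <- sample_id
  sub <- d[sample_id == sid & replicate_id %in% replicate_pair]
  wide <- data.table::dcast(sub, analyte_id ~ replicate_id, value.var = "value")
  keep <- stats::complete.cases(wide)
  wide <- wide[keep]
  if (nrow(wide) < 3L) {
    .err("iccpower_data_error",
         sprintf("sample '%s' has both replicates on only %d analytes (need >= 3)",
                 sample_id, nrow(wide)))
  }
  list(x = wide[[2L]], y = wide[[3L]], analyte_id = wide$analyte_id,
       sample_id = sample_id)
}

#' Large-p limit of the inter-replicate correlation
#'
#' Under the variance-components model, as the number of analytes grows the
#' inter-replicate sample correlation converges in probability to
#' (v_d + v_b_bar) / (v_d + v_b_bar + v_e_bar). The dynamic-range variance
#' v_d therefore confounds r as a precision measure: holding signal and
#' noise fixed, a wider dynamic range alone pushes r toward 1.
#'
#' @param v_d dynamic-range variance (>= 0).
#' @param v_b_bar analyte-averaged biological signal variance (>= 0).
#' @param v_e_bar analyte-averaged experimental noise variance (>= 0).
#' @return the limiting correlation in `[0, 1]`.
#' @examples
#' asymptotic_correlation(8.17, 0.04, 0.01) # 0.999 to three decimals
#' @export
asymptotic_correlation <- function(v_d, v_b_bar, v_e_bar) {
  .check_number(v_d, "v_d", lower = 0, class = "iccpower_domain_error")
  .check_number(v_b_bar, "v_b_bar", lower = 0, class = "iccpower_domain_error")
  .check_number(v_e_bar, "v_e_bar", lower = 0, class = "iccpower_domain_error")
  tot <- v_d + v_b_bar + v_e_bar
  if (tot == 0) {
    .err("iccpower_domain_error", "all variance components are zero")
  }
  (v_d + v_b_bar) / tot
}

#' Finite-p convergence of the inter-replicate correlation
#'
#' Resampling study of how quickly r stabilizes as the number of analytes
#' grows: for each subset size p in `p_grid`, draws analyte subsets without
#' replacement, recomputes r on each, and records the mean and spread,
#' together with r on the full analyte set.
#'
#' @param table a [replicate_table()].
#' @param sample_id,replicate_pair as in [replicate_correlation()].
#' @param p_grid strictly increasing subset sizes, each at most the number of
#'   complete analytes.
#' @param n_resamples subsets drawn per grid point (>= 1).
#' @param seed RNG seed for the subset draws.
#' @return class `convergence_curve`: a data.frame with columns `p`,
#'   `r_mean`, `r_sd`, plus attributes `r_full`, `n_resamples`, `seed`.
#' @export
convergence_curve <- function(table, sample_id = NULL,
                              replicate_pair = c(1L, 2L),
                              p_grid, n_resamples = 200L, seed = 1L) {
  if (n_resamples < 1L) .err("iccpower_parameter_error", "n_resamples must be >= 1")
  if (is.unsorted(p_grid, strictly = TRUE)) {
    .err("iccpower_parameter_error", "p_grid must be strictly increasing")
  }
  v <- .replicate_pair_vectors(table, sample_id, replicate_pair)
  p_full <- length(v$x)
  if (max(p_grid) > p_full) {
    .err("iccpower_parameter_error",
         sprintf("max(p_grid) = %d exceeds the %d complete analytes",
                 max(p_grid), p_full))
  }
  if (min(p_grid) < 3L) .err("iccpower_parameter_error", "subset sizes must be >= 3")
  r_full <- stats::cor(v$x, v$y)
  set.seed(seed)
  rows <- lapply(p_grid, function(p) {
    rs <- vapply(seq_len(n_resamples), function(b) {
      idx <- sample.int(p_full, p)
      stats::cor(v$x[idx], v$y[idx])
    }, numeric(1))
    c(r_mean = mean(rs), r_sd = stats::sd(rs),
      mean_abs_rel_dev = mean(abs(rs - r_full)) / abs(r_full))
  })
  out <- data.frame(p = p_grid, do.call(rbind, rows))
  structure(out, class = c("convergence_curve", "data.frame"),
            r_full = r_full, n_resamples = n_resamples, seed = seed,
            sample_id = v$sample_id)
}
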