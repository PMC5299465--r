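#' Technical-replicate pilot data
#'
#' A `replicate_table` holds measured log-concentrations indexed by
#' (analyte, biological sample, technical replicate). It is the input to all
#' estimation in the package: one value per aliquot measurement, in long
#' format. Missing values are dropped at construction; replicate indices are
#' re-assigned to 1..n within each (analyte, sample) cell, since replicate
#' identity carries no meaning beyond grouping (replicates are exchangeable
#' within a sample under the variance-components model).
#'
#' @param data a data.frame with columns `analyte_id`, `sample_id`,
#'   `replicate_id`, `value`. `value` must be numeric (log-scale
#'   concentrations); rows with missing `value` are dropped.
#' @return an object of class `replicate_table` wrapping a `data.table` in
#'   the same four columns, keyed by (analyte_id, sample_id, replicate_id).
#' @examples
#' df <- expand.grid(analyte_id = c("a1", "a2"), sample_id = c("s1", "s2"),
#'                   replicate_id = 1:2)
#' df$value <- rnorm(nrow(df))
#' tab <- replicate_table(df)
#' @export
replicate_table <- function(data) {
  required <- c("analyte_id", "sample_id", "replicate_id", "value")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    .err("iccpower_format_error",
         paste0("missing required columns: ", paste(missing_cols, collapse = ", ")))
  }
  dt <- data.table::as.data.table(data)[, required, with = FALSE]
  if (!is.numeric(dt$value)) {
    .err("iccpower_parse_error", "`value` column must be numeric")
  }
  dt[, `:=`(analyte_id = as.character(analyte_id),
            sample_id  = as.character(sample_id))]
  dt <- dt[is.finite(value)]
  if (nrow(dt) == 0L) .err("iccpower_data_error", "no non-missing observations")
  if (anyDuplicated(dt, by = c("analyte_id", "sample_id", "replicate_id"))) {
    .err("iccpower_format_error",
         "duplicate (analyte_id, sample_id, replicate_id) keys")
  }
  # re-index replicates 1..n_i within each cell, no gaps
  data.table::setorder(dt, analyte_id, sample_id, replicate_id)
  dt[, replicate_id := seq_len(.N), by = .(analyte_id, sample_id)]
  if (length(unique(dt$analyte_id)) < 1L) {
    .err("iccpower_design_error", "at least 1 analyte is required")
  }
  structure(list(data = dt), class = "replicate_table")
}

#' @export
print.replicate_table <- function(x, ...) {
  d <- x$data
  cat(sprintf("replicate_table: %d analytes x %d samples, %d observations\n",
              length(unique(d$analyte_id)), length(unique(d$sample_id)),
              nrow(d)))
  invisible(x)
}

#' Read a technical-replicate pilot dataset from disk
#'
#' Supports two layouts. `long`: one row per observation with columns
#' analyte_id, sample_id, replicate_id, value (names remappable through
#' `column_map`, a named character vector `c(standard = "file_column")`).
#' `wide`: one row per analyte; the first column (default name `analyte_id`)
#' holds analyte identifiers and each remaining measurement column is mapped
#' to a (sample, replicate) pair through `column_map`, a data.frame with
#' columns `column`, `sample_id`, `replicate_id`.
#'
#' @param path path to a TSV or CSV file (delimiter inferred from extension;
#'   `.csv` is comma-separated, anything else tab-separated).
#' @param layout `"long"` or `"wide"`.
#' @param column_map layout-dependent column mapping (see Details); optional
#'   for `long`, required for `wide`.
#' @param log_transform `"none"` (values are already log-scale, the default)
#'   or `"log2"` (values are raw concentrations, strictly positive, and are
#'   log2-transformed on ingestion).
#' @return a [replicate_table()].
#' @export
read_replicate_table <- function(path, layout = c("long", "wide"),
                                 column_map = NULL,
                                 log_transform = c("none", "log2")) {
  layout <- match.arg(layout)
  log_transform <- match.arg(log_transform)
  if (!file.exists(path)) .err("iccpower_io_error", paste0("file not found: ", path))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- data.table::fread(path, sep = sep, header = TRUE, data.table = TRUE)

  if (layout == "long") {
    std <- c("analyte_id", "sample_id", "replicate_id", "value")
    if (!is.null(column_map)) {
      for (nm in intersect(std, names(column_map))) {
        if (!column_map[[nm]] %in% names(raw)) {
          .err("iccpower_format_error",
               sprintf("mapped column '%s' not found in file", column_map[[nm]]))
        }
        data.table::setnames(raw, column_map[[nm]], nm)
      }
    }
    missing_cols <- setdiff(std, names(raw))
    if (length(missing_cols)) {
      .err("iccpower_format_error",
           paste0("missing required columns: ", paste(missing_cols, collapse = ", ")))
    }
    long <- raw[, .(analyte_id, sample_id, replicate_id, value)]
  } else {
    if (is.null(column_map)) {
      .err("iccpower_format_error", "wide layout requires a column_map")
    }
    cm <- data.table::as.data.table(column_map)
    need <- c("column", "sample_id", "replicate_id")
    if (!all(need %in% names(cm))) {
      .err("iccpower_format_error",
           "wide column_map needs columns: column, sample_id, replicate_id")
    }
    id_col <- setdiff(names(raw), cm$column)
    if (length(id_col) != 1L) {
      .err("iccpower_format_error",
           "wide layout must have exactly one unmapped analyte-identifier column")
    }
    missing_cols <- setdiff(cm$column, names(raw))
    if (length(missing_cols)) {
      .err("iccpower_format_error",
           paste0("mapped columns absent from file: ",
                  paste(missing_cols, collapse = ", ")))
    }
    raw[, (cm$column) := lapply(.SD, as.numeric), .SDcols = cm$column]
    long <- data.table::melt(raw, id.vars = id_col, measure.vars = cm$column,
                             variable.name = "column", value.name = "value",
                             variable.factor = FALSE)
    data.table::setnames(long, id_col, "analyte_id")
    long <- merge(long, cm, by = "column")[
      , .(analyte_id, sample_id, replicate_id, value)]
  }

  if (!is.numeric(long$value)) {
    .err("iccpower_parse_error", "non-numeric values in measurement column")
  }
  if (log_transform == "log2") {
    bad <- is.finite(long$value) & long$value <= 0
    if (any(bad)) {
      .err("iccpower_domain_error",
           sprintf("log2 transform requires strictly positive values; %d are <= 0",
                   sum(bad)))
    }
    long[, value := log2(value)]
  }
  replicate_table(long)
}

#' Summarize the replication design of a pilot dataset
#'
#' Counts samples, analytes, and how many samples carry technical replication
#' (at least 2 replicates on at least 1 analyte), in the style of a
#' "number of samples (number replicated)" report. Estimating the
#' within-sample (experimental noise) variance requires at least one
#' replicated sample; with only one, estimation is still possible but
#' imprecise, and the summary carries a warning flag.
#'
#' @param table a [replicate_table()].
#' @return an object of class `design_summary` with fields `n_samples`,
#'   `n_replicated`, `n_analytes`, `replicate_counts` (per-sample maximum
#'   replicate count histogram, as a named integer vector), and
#'   `warn_few_replicated`.
#' @export
validate_design <- function(table) {
  stopifnot(inherits(table, "replicate_table"))
  d <- table$data
  per_cell <- d[, .(n = .N), by = .(analyte_id, sample_id)]
  per_sample <- per_cell[, .(max_rep = max(n)), by = sample_id]
  n_samples <- nrow(per_sample)
  n_replicated <- sum(per_sample$max_rep >= 2L)
  if (n_replicated == 0L) {
    .err("iccpower_design_error",
         "no sample has >= 2 technical replicates: within-sample variance is inestimable")
  }
  warn_flag <- n_replicated < 2L
  if (warn_flag) {
    warning("only one replicated sample: noise-variance estimates will be imprecise",
            call. = FALSE)
  }
  counts <- table(per_sample$max_rep)
  structure(list(
    n_samples = n_samples,
    n_replicated = n_replicated,
    n_analytes = length(unique(d$analyte_id)),
    replicate_counts = stats::setNames(as.integer(counts), names(counts)),
    warn_few_replicated = warn_flag
  ), class = "design_summary")
}

#' @export
print.design_summary <- function(x, ...) {
  cat(sprintf("design_summary: %d analytes; %d samples (%d replicated)\n",
              x$n_analytes, x$n_samples, x$n_replicated))
  invisible(x)
}

#' Write per-analyte estimates and the global variance summary to disk
#'
#' Writes a tab-separated file with one row per analyte (analyte_id, mean
#' log2 concentration, biological and noise variance, repeatability and its
#' confidence bounds) plus a companion summary file carrying the global
#' components: dynamic-range variance v_d, the analyte-averaged v_b and v_e,
#' and the global mean.
#'
#' @param profile a `repeatability_profile` from [decompose_all()].
#' @param decomposition a `variance_decomposition` from [decompose_all()].
#' @param path output TSV path for the per-analyte table.
#' @param summary_path output TSV path for the global summary; defaults to
#'   `<path without extension>_summary.tsv`.
#' @return invisibly, the two paths written.
#' @export
write_estimates <- function(profile, decomposition, path,
                            summary_path = paste0(
                              tools::file_path_sans_ext(path), "_summary.tsv")) {
  stopifnot(inherits(profile, "repeatability_profile"),
            inherits(decomposition, "variance_decomposition"))
  out <- data.table::data.table(
    analyte_id = profile$analyte_id,
    mean_log2_concentration = profile$mean_concentration,
    v_b = decomposition$v_b[profile$analyte_id],
    v_e = decomposition$v_e[profile$analyte_id],
    R = profile$R,
    ci_lower = profile$ci_lower,
    ci_upper = profile$ci_upper
  )
  ok <- tryCatch({
    data.table::fwrite(out, path, sep = "\t", na = "NA")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) .err("iccpower_io_error", paste0("cannot write to ", path))
  summ <- data.table::data.table(
    quantity = c("v_d", "v_b_bar", "v_e_bar", "mu_hat", "n_analytes"),
    value = c(decomposition$v_d, decomposition$v_b_bar, decomposition$v_e_bar,
              decomposition$mu_hat, length(profile$analyte_id))
  )
  data.table::fwrite(summ, summary_path, sep = "\t")
  invisible(c(path, summary_path))
}

#' Read back a per-analyte estimates file written by [write_estimates()]
#'
#' @param path the per-analyte TSV.
#' @return a data.table with the columns written by [write_estimates()].
#' @export
read_estimates <- function(path) {
  if (!file.exists(path)) .err("iccpower_io_error", paste0("file not found: ", path))
  data.table::fread(path, sep = "\t")
}

#' Write a replicate table to a long-format TSV
#'
#' @param table a [replicate_table()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_replicate_table <- function(table, path) {
  stopifnot(inherits(table, "replicate_table"))
  data.table::fwrite(table$data, path, sep = "\t")
  invisible(path)
}
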