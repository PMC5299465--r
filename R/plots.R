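#' Kernel-weighted running quantiles
#'
#' Smooth quantile curves of y as a function of x: at each point of an even
#' grid spanning the range of x, observations are weighted by a Gaussian
#' kernel (scale = `bandwidth`) in x, and weighted empirical quantiles of y
#' are computed with linear interpolation. Used to draw the median and
#' quartile bands of repeatability as a smooth function of concentration.
#'
#' @param x concentrations (length >= 10).
#' @param y repeatabilities (same length).
#' @param quantiles probabilities, default quartiles `c(0.25, 0.5, 0.75)`.
#' @param bandwidth kernel scale in x units; default `diff(range(x)) / 10`.
#' @param n_grid number of grid points.
#' @return class `smoothed_quantiles`: a data.frame with column `grid` and
#'   one column `q<percent>` per requested quantile, plus a `bandwidth`
#'   attribute. Curves for increasing probabilities are pointwise ordered.
#' @export
running_quantiles <- function(x, y, quantiles = c(0.25, 0.5, 0.75),
                              bandwidth = diff(range(x)) / 10,
                              n_grid = 100L) {
  if (length(x) != length(y)) {
    .err("iccpower_parameter_error", "x and y must have equal length")
  }
  if (length(x) < 10L) {
    .err("iccpower_parameter_error", "need >= 10 points to smooth")
  }
  .check_number(bandwidth, "bandwidth")
  if (bandwidth <= 0) .err("iccpower_parameter_error", "bandwidth must be > 0")
  if (any(quantiles <= 0) || any(quantiles >= 1)) {
    .err("iccpower_parameter_error", "quantiles must be inside (0, 1)")
  }
  ord <- order(y)
  y_sorted <- y[ord]
  x_sorted <- x[ord]
  grid <- seq(min(x), max(x), length.out = n_grid)
  qmat <- t(vapply(grid, function(g) {
    w <- stats::dnorm(x_sorted, mean = g, sd = bandwidth)
    w <- w / sum(w)
    cw <- cumsum(w) - w / 2
    stats::approx(cw, y_sorted, xout = quantiles, rule = 2, ties = "ordered")$y
  }, numeric(length(quantiles))))
  out <- data.frame(grid = grid, qmat)
  names(out)[-1L] <- paste0("q", round(100 * quantiles))
  structure(out, class = c("smoothed_quantiles", "data.frame"),
            bandwidth = bandwidth, quantiles = quantiles)
}

.open_device <- function(file, width = 7, height = 6) {
  ext <- tolower(tools::file_ext(file))
  switch(ext,
         svg = grDevices::svg(file, width = width, height = height),
         png = grDevices::png(file, width = width * 100, height = height * 100,
                              res = 100),
         pdf = grDevices::pdf(file, width = width, height = height),
         .err("iccpower_parameter_error",
              paste0("unsupported figure format: .", ext)))
}

.write_figure <- function(plot, file, width = 7, height = 6) {
  ok <- tryCatch({
    .open_device(file, width, height)
    print(plot)
    grDevices::dev.off()
    TRUE
  }, error = function(e) {
    try(grDevices::dev.off(), silent = TRUE)
    if (inherits(e, "iccpower_error")) stop(e)
    FALSE
  })
  if (!ok) .err("iccpower_io_error", paste0("could not write figure to ", file))
  invisible(file)
}

.sidecar <- function(file, suffix) {
  paste0(tools::file_path_sans_ext(file), ".", suffix, ".tsv")
}

#' Repeatability-versus-concentration diagnostic figure
#'
#' One point per analyte (estimated repeatability against mean measured log2
#' concentration), overlaid with kernel-smoothed median and quartile curves,
#' and marginal histograms of both axes. Every plotted layer is also written
#' to machine-readable TSV sidecars (`*.points.tsv`, `*.quantiles.tsv`) so
#' the figure's content can be checked without parsing the image.
#'
#' @param profile a `repeatability_profile` from [decompose_all()].
#' @param file output figure path (`.svg`, `.png`, or `.pdf`).
#' @param bandwidth smoother bandwidth; default concentration range / 10.
#' @param bins_r histogram bins for repeatability (on `[0, 1]`).
#' @return invisibly, a character vector of all files written.
#' @export
plot_repeatability_vs_concentration <- function(profile, file,
                                                bandwidth = NULL,
                                                bins_r = 30L) {
  stopifnot(inherits(profile, "repeatability_profile"))
  pts <- as.data.frame(profile)
  if (nrow(pts) < 1L) .err("iccpower_parameter_error", "profile is empty")
  smooth <- NULL
  if (nrow(pts) >= 10L && diff(range(pts$mean_concentration)) > 0) {
    if (is.null(bandwidth)) {
      bandwidth <- diff(range(pts$mean_concentration)) / 10
    }
    smooth <- running_quantiles(pts$mean_concentration, pts$R,
                                bandwidth = bandwidth)
  }

  scatter <- ggplot2::ggplot(pts,
      ggplot2::aes(x = mean_concentration, y = R)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "mean measured log2 concentration",
                  y = "repeatability R") +
    ggplot2::theme_bw()
  if (!is.null(smooth)) {
    scatter <- scatter +
      ggplot2::geom_line(data = smooth, ggplot2::aes(x = grid, y = q50),
                         colour = "red", linewidth = 0.8) +
      ggplot2::geom_line(data = smooth, ggplot2::aes(x = grid, y = q25),
                         colour = "red", linetype = "dashed") +
      ggplot2::geom_line(data = smooth, ggplot2::aes(x = grid, y = q75),
                         colour = "red", linetype = "dashed")
  }
  top <- ggplot2::ggplot(pts, ggplot2::aes(x = mean_concentration)) +
    ggplot2::geom_histogram(bins = max(grDevices::nclass.FD(pts$mean_concentration), 1L),
                            fill = "grey60") +
    ggplot2::theme_void()
  right <- ggplot2::ggplot(pts, ggplot2::aes(x = R)) +
    ggplot2::geom_histogram(bins = bins_r, boundary = 0, fill = "grey60") +
    ggplot2::coord_flip(xlim = c(0, 1)) +
    ggplot2::theme_void()
  fig <- top + patchwork::plot_spacer() + scatter + right +
    patchwork::plot_layout(ncol = 2, widths = c(4, 1), heights = c(1, 4))

  .write_figure(fig, file)
  points_file <- .sidecar(file, "points")
  data.table::fwrite(pts, points_file, sep = "\t")
  written <- c(file, points_file)
  if (!is.null(smooth)) {
    quant_file <- .sidecar(file, "quantiles")
    data.table::fwrite(as.data.frame(smooth), quant_file, sep = "\t")
    written <- c(written, quant_file)
  }
  invisible(written)
}

#' Percentage-of-analytes-powered curve
#'
#' Line plot of the percentage of analytes powered against the sample size
#' inflation factor, with an optional shaded bootstrap confidence band.
#' The plotted curve is written to a `*.curve.tsv` sidecar.
#'
#' @param plan a data.frame from [power_table()] (columns `sif`,
#'   `pct_powered`, optional `lower`/`upper`).
#' @param file output figure path.
#' @return invisibly, the files written.
#' @export
plot_powered_vs_sif <- function(plan, file) {
  if (!is.data.frame(plan) || nrow(plan) == 0L ||
      !all(c("sif", "pct_powered") %in% names(plan))) {
    .err("iccpower_parameter_error", "plan must be a non-empty power_table()")
  }
  g <- ggplot2::ggplot(plan, ggplot2::aes(x = sif, y = pct_powered))
  if (all(c("lower", "upper") %in% names(plan))) {
    g <- g + ggplot2::geom_ribbon(ggplot2::aes(ymin = lower, ymax = upper),
                                  fill = "grey70", alpha = 0.6)
  }
  g <- g + ggplot2::geom_line(linewidth = 0.9) +
    ggplot2::coord_cartesian(xlim = c(1, max(plan$sif)), ylim = c(0, 100)) +
    ggplot2::labs(x = "sample size inflation factor (SIF)",
                  y = "% analytes powered") +
    ggplot2::theme_bw()
  .write_figure(g, file, width = 6, height = 5)
  curve_file <- .sidecar(file, "curve")
  data.table::fwrite(plan, curve_file, sep = "\t")
  invisible(c(file, curve_file))
}

#' Replicate scatterplot (the panel not to trust)
#'
#' The conventional precision display: measured log-concentrations of two
#' technical replicates of one sample plotted against each other, one point
#' per analyte, with the x = y guide line and the sample correlation r
#' annotated. Provided as the pedagogical counterpoint: r is confounded with
#' dynamic range and says little about per-analyte precision. Points go to a
#' `*.points.tsv` sidecar.
#'
#' @param table a [replicate_table()].
#' @param sample_id,replicate_pair as in [replicate_correlation()].
#' @param file output figure path.
#' @return invisibly, the files written; the annotated r is attached as the
#'   `r` attribute.
#' @export
plot_replicate_scatter <- function(table, sample_id = NULL,
                                   replicate_pair = c(1L, 2L), file) {
  v <- .replicate_pair_vectors(table, sample_id, replicate_pair)
  r <- stats::cor(v$x, v$y)
  pts <- data.frame(analyte_id = v$analyte_id, replicate_1 = v$x,
                    replicate_2 = v$y)
  g <- ggplot2::ggplot(pts, ggplot2::aes(x = replicate_1, y = replicate_2)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::annotate("text", x = min(pts$replicate_1), y = max(pts$replicate_2),
                      hjust = 0, label = sprintf("r = %.3f", r)) +
    ggplot2::labs(x = "replicate 1 (log concentration)",
                  y = "replicate 2 (log concentration)",
                  title = paste0("sample ", v$sample_id)) +
    ggplot2::theme_bw()
  .write_figure(g, file, width = 5.5, height = 5.5)
  points_file <- .sidecar(file, "points")
  data.table::fwrite(pts, points_file, sep = "\t")
  out <- c(file, points_file)
  attr(out, "r") <- r
  invisible(out)
}
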