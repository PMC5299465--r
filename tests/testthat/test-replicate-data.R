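test_that("long ingestion validates, re-indexes replicates, and counts observations", {
  df <- tiny_long()
  tab <- replicate_table(df)
  expect_s3_class(tab, "replicate_table")
  expect_equal(nrow(tab$data), 12L)

  # gaps in replicate indices are closed; missing values dropped per cell
  df2 <- df
  df2$replicate_id[df2$analyte_id == "a1" & df2$sample_id == "s1"] <- c(3L, 7L)
  df2$value[df2$analyte_id == "a2" & df2$sample_id == "s2" &
              df2$replicate_id == 1] <- NA
  tab2 <- replicate_table(df2)
  expect_equal(nrow(tab2$data), 11L)
  reps <- tab2$data[analyte_id == "a1" & sample_id == "s1", replicate_id]
  expect_equal(reps, 1:2)
  reps2 <- tab2$data[analyte_id == "a2" & sample_id == "s2", replicate_id]
  expect_equal(reps2, 1L)

  expect_error(replicate_table(df[, -4]), "missing required columns")
  expect_error(replicate_table(rbind(df, df[1, ])), "duplicate")
})

test_that("long and wide files of the same data ingest identically", {
  df <- tiny_long()
  long_path <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, long_path, sep = "\t", row.names = FALSE, quote = FALSE)

  # wide layout: one row per analyte, one column per (sample, replicate)
  obs_cols <- with(df, paste0(sample_id, "_r", replicate_id))
  wide <- data.frame(analyte_id = unique(df$analyte_id))
  cmap <- unique(data.frame(column = obs_cols, sample_id = df$sample_id,
                            replicate_id = df$replicate_id))
  for (i in seq_len(nrow(cmap))) {
    sel <- df$sample_id == cmap$sample_id[i] &
      df$replicate_id == cmap$replicate_id[i]
    wide[[cmap$column[i]]] <- df$value[sel][match(wide$analyte_id,
                                                  df$analyte_id[sel])]
  }
  wide_path <- withr::local_tempfile(fileext = ".tsv")
  write.table(wide, wide_path, sep = "\t", row.names = FALSE, quote = FALSE)

  tab_long <- read_replicate_table(long_path, layout = "long")
  tab_wide <- read_replicate_table(wide_path, layout = "wide",
                                   column_map = cmap)
  expect_equal(
    as.data.frame(tab_long$data[order(analyte_id, sample_id, replicate_id)]),
    as.data.frame(tab_wide$data[order(analyte_id, sample_id, replicate_id)]))
})

test_that("log2 ingestion transforms positive values and rejects non-positive ones", {
  df <- tiny_long()
  df$value <- 2^df$value
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  tab <- read_replicate_table(path, log_transform = "log2")
  expect_equal(sort(tab$data$value), sort(log2(df$value)))

  df$value[3] <- 0
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_replicate_table(path, log_transform = "log2"),
               class = "iccpower_domain_error")
})

test_that("write-then-read of a replicate table is lossless", {
  sim <- known_pilot(p = 10, n_samples = 8, n_replicated = 5, seed = 11)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_replicate_table(sim$table, path)
  back <- read_replicate_table(path, layout = "long")
  expect_equal(as.data.frame(back$data), as.data.frame(sim$table$data))
})

test_that("design summaries count samples and replicated samples", {
  sim_a <- known_pilot(p = 5, n_samples = 69, n_replicated = 69, seed = 2)
  des_a <- validate_design(sim_a$table)
  expect_equal(des_a$n_samples, 69L)
  expect_equal(des_a$n_replicated, 69L)
  expect_equal(des_a$n_analytes, 5L)
  expect_false(des_a$warn_few_replicated)

  sim_b <- known_pilot(p = 5, n_samples = 76, n_replicated = 15, seed = 3)
  des_b <- validate_design(sim_b$table)
  expect_equal(des_b$n_samples, 76L)
  expect_equal(des_b$n_replicated, 15L)
  expect_equal(unname(des_b$replicate_counts[c("1", "2")]), c(61L, 15L))

  # no replication at all: within-sample variance is inestimable
  sim_none <- known_pilot(p = 5, n_samples = 10, n_replicated = 0, seed = 4)
  expect_error(validate_design(sim_none$table),
               class = "iccpower_design_error")

  # a single replicated sample estimates, but with a warning flag
  sim_one <- known_pilot(p = 5, n_samples = 10, n_replicated = 1, seed = 5)
  expect_warning(des_one <- validate_design(sim_one$table),
                 "only one replicated sample")
  expect_true(des_one$warn_few_replicated)
})

test_that("estimates files round-trip at full precision, including empty profiles", {
  sim <- known_pilot(p = 6, n_samples = 20, n_replicated = 20, seed = 8)
  fit <- decompose_all(sim$table)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_estimates(fit$profile, fit$decomposition, path)
  back <- read_estimates(path)
  expect_equal(nrow(back), 6L)
  expect_equal(back$R, fit$profile$R)
  expect_equal(back$v_e, unname(fit$decomposition$v_e[back$analyte_id]))
  expect_equal(back$mean_log2_concentration, fit$profile$mean_concentration)

  summ <- read_estimates(paste0(tools::file_path_sans_ext(path),
                                "_summary.tsv"))
  expect_equal(summ$value[summ$quantity == "v_d"], fit$decomposition$v_d)

  # degenerate: empty profile writes a header-only table
  empty_profile <- structure(list(analyte_id = character(), R = numeric(),
                                  mean_concentration = numeric(),
                                  ci_lower = numeric(), ci_upper = numeric()),
                             class = "repeatability_profile")
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_estimates(empty_profile, fit$decomposition, path2)
  expect_equal(nrow(read_estimates(path2)), 0L)
  expect_equal(length(readLines(path2)), 1L)
})
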