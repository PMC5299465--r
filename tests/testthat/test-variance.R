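test_that("anova_decompose reproduces the worked unbalanced example", {
  est <- anova_decompose(list(A = c(1.0, 1.2), B = c(2.0, 2.2), C = 3.1))
  expect_equal(est$v_e_hat, 0.02)
  expect_equal(est$v_b_hat, 0.8625)
  expect_equal(est$mean, 1.9)
  expect_equal(repeatability(truncate_negative(est$v_b_hat), est$v_e_hat),
               0.8625 / (0.8625 + 0.02))
})

test_that("anova_decompose matches an independent aov() oracle on random unbalanced designs", {
  set.seed(42)
  for (i in 1:25) {
    cells <- random_cells(n_samples = sample(3:12, 1))
    est <- anova_decompose(cells)
    ora <- oracle_anova(cells)
    expect_equal(est$v_e_hat, ora$v_e_hat, tolerance = 1e-10)
    expect_equal(est$v_b_hat, ora$v_b_hat, tolerance = 1e-10)
    expect_equal(est$mean, ora$mean, tolerance = 1e-12)
  }
})

test_that("anova_decompose handles degenerate inputs as designed", {
  # identical replicates within samples: zero noise
  est <- anova_decompose(list(c(1, 1), c(2, 2), c(5, 5, 5)))
  expect_equal(est$v_e_hat, 0)
  # identical sample means with within-sample spread: negative v_b before truncation
  est2 <- anova_decompose(list(c(0.9, 1.1), c(0.8, 1.2), c(1.0, 1.0)))
  expect_lt(est2$v_b_hat, 0)
  expect_equal(truncate_negative(est2$v_b_hat), 0)
  # preconditions
  expect_error(anova_decompose(list(c(1, 2))), class = "iccpower_design_error")
  expect_error(anova_decompose(list(1, 2, 3)), class = "iccpower_design_error")
  expect_error(anova_decompose(list(c(1, NA), c(2, 3))),
               class = "iccpower_data_error")
})

test_that("truncation and repeatability obey their defining identities", {
  expect_equal(truncate_negative(-0.013), 0)
  expect_equal(truncate_negative(0.5), 0.5)
  expect_equal(truncate_negative(0), 0)
  expect_error(truncate_negative(NaN), class = "iccpower_data_error")

  expect_equal(repeatability(0.3, 0), 1)
  expect_equal(repeatability(0, 0.3), 0)
  expect_equal(repeatability(0, 0), 0)
  expect_equal(repeatability(0.8625, 0.02), 0.97734, tolerance = 1e-4)
  expect_error(repeatability(-0.1, 0.2), class = "iccpower_domain_error")

  # monotone in v_b (increasing) and v_e (decreasing)
  vb_grid <- seq(0.01, 2, length.out = 40)
  expect_true(all(diff(repeatability(vb_grid, 0.5)) > 0))
  ve_grid <- seq(0.01, 2, length.out = 40)
  expect_true(all(diff(repeatability(0.5, ve_grid)) < 0))
})

test_that("repeatability coefficient on the measurement scale is 1.96*sqrt(2 v_e)", {
  expect_equal(ba_repeatability_coefficient(0.5), 1.96)
  expect_equal(ba_repeatability_coefficient(0), 0)
  expect_equal(ba_repeatability_coefficient(0.06), 0.6791, tolerance = 1e-3)
  expect_error(ba_repeatability_coefficient(-1), class = "iccpower_domain_error")
})

test_that("dynamic-range estimator: spread of means minus their sampling variance", {
  expect_equal(estimate_dynamic_range(c(3, 3, 3, 3)), 0)
  expect_equal(estimate_dynamic_range(c(0, 2)), 2)
  expect_equal(estimate_dynamic_range(c(0, 2), mean_sampling_var = 0.5), 1.5)
  # truncated at zero when sampling noise explains all the spread
  expect_equal(estimate_dynamic_range(c(0, 0.1), mean_sampling_var = 1), 0)
  expect_error(estimate_dynamic_range(3), class = "iccpower_design_error")
})

test_that("decompose_all recovers known simulation components", {
  # zero noise everywhere: every analyte measured perfectly
  sim0 <- known_pilot(p = 40, n_samples = 30, n_replicated = 30,
                      v_d = 2, v_b = 0.05, v_e = 0, seed = 21)
  fit0 <- decompose_all(sim0$table)
  expect_true(all(fit0$profile$R == 1))
  expect_true(all(fit0$decomposition$v_e == 0))

  # v_b = v_e: repeatabilities center on 1/2, v_d recovered
  sim <- known_pilot(p = 500, n_samples = 200, n_replicated = 200,
                     v_d = 2, v_b = 0.05, v_e = 0.05, seed = 22)
  fit <- decompose_all(sim$table)
  expect_lt(abs(mean(fit$profile$R) - 0.5), 0.05)
  expect_lt(abs(fit$decomposition$v_d - 2), 0.3)
  expect_lt(abs(fit$decomposition$v_b_bar - 0.05) / 0.05, 0.10)
  expect_lt(abs(fit$decomposition$v_e_bar - 0.05) / 0.05, 0.10)
  # exact identities of the container
  expect_equal(fit$decomposition$v_b_bar, mean(fit$decomposition$v_b))
  expect_equal(fit$decomposition$v_e_bar, mean(fit$decomposition$v_e))
  expect_true(all(fit$decomposition$v_b >= 0))
  expect_true(all(fit$decomposition$v_e >= 0))
})

test_that("truncation induces non-negative bias in v_b when the true signal is zero", {
  sim <- known_pilot(p = 400, n_samples = 50, n_replicated = 50,
                     v_d = 1, v_b = 0, v_e = 0.05, seed = 23)
  fit <- decompose_all(sim$table)
  expect_gt(mean(fit$decomposition$v_b), 0)
  # while roughly half the raw estimates fall below zero
  expect_gt(mean(fit$decomposition$v_b_raw < 0), 0.3)
})

test_that("inestimable analytes are excluded with a reason, not fatal", {
  sim <- known_pilot(p = 4, n_samples = 20, n_replicated = 20, seed = 24)
  d <- as.data.frame(sim$table$data)
  # strip analyte A00001 down to a single sample: inestimable
  d <- d[!(d$analyte_id == "A00001" & d$sample_id != "S0001"), ]
  fit <- decompose_all(replicate_table(d))
  expect_named(fit$decomposition$excluded, "A00001")
  expect_equal(length(fit$profile$R), 3L)

  # if every analyte is inestimable the decomposition fails as a whole
  d2 <- as.data.frame(sim$table$data)
  d2 <- d2[d2$sample_id == "S0001", ]
  expect_error(decompose_all(replicate_table(d2)),
               class = "iccpower_design_error")
})
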