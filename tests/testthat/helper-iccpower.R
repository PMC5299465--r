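# Shared fixture builders and independent oracles.

# Small deterministic long-format dataset: 3 analytes x 2 samples x 2 reps.
tiny_long <- function() {
  g <- expand.grid(analyte_id = c("a1", "a2", "a3"),
                   sample_id = c("s1", "s2"),
                   replicate_id = 1:2, stringsAsFactors = FALSE)
  g <- g[order(g$analyte_id, g$sample_id, g$replicate_id), ]
  g$value <- seq(0.5, by = 0.25, length.out = nrow(g))
  rownames(g) <- NULL
  g
}

# Independent one-way ANOVA oracle: mean squares from stats::aov, then the
# same method-of-moments map to variance components.
oracle_anova <- function(cells) {
  df <- data.frame(
    y = unlist(cells, use.names = FALSE),
    g = factor(rep(seq_along(cells), lengths(cells))))
  ms <- summary(stats::aov(y ~ g, data = df))[[1]][["Mean Sq"]]
  n_i <- lengths(cells)
  N <- sum(n_i)
  I <- length(cells)
  n0p <- (N - sum(n_i^2) / N) / (I - 1)
  list(v_b_hat = (ms[1] - ms[2]) / n0p, v_e_hat = ms[2],
       mean = mean(df$y))
}

# Random unbalanced instance for estimator cross-checks.
random_cells <- function(n_samples, max_rep = 4L) {
  n_i <- sample(1:max_rep, n_samples, replace = TRUE)
  if (all(n_i == 1L)) n_i[1L] <- 2L
  lapply(n_i, function(n) rnorm(n, mean = rnorm(1, 0, 2), sd = 0.5))
}

# A pilot with known constant components, all-duplicate design.
known_pilot <- function(p = 200, n_samples = 100, n_replicated = 50,
                        v_d = 2, v_b = 0.05, v_e = 0.05, seed = 1) {
  simulate_dataset(simulation_config(
    p = p, n_samples = n_samples, n_replicated = n_replicated, mu = 5,
    v_d = v_d, v_b_law = v_b, v_e_law = v_e, seed = seed))
}
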