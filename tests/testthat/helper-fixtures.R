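# Small deterministic fixtures for classifier and GA tests.

# perfectly separable table: one informative feature with a wide gap
separable_table <- function(n_subj = 8, d = 3) {
  X <- matrix(rnorm(2 * n_subj * d, sd = 0.1), 2 * n_subj, d)
  cond <- rep(c("A", "B"), n_subj)
  X[cond == "B", 1] <- X[cond == "B", 1] + 10
  feature_table(X, cond, rep(sprintf("S%02d", seq_len(n_subj)), each = 2),
                metric_name = "toy")
}

# label-independent features (pure noise)
noise_table <- function(n_subj = 8, d = 3) {
  feature_table(matrix(rnorm(2 * n_subj * d), 2 * n_subj, d),
                rep(c("A", "B"), n_subj),
                rep(sprintf("S%02d", seq_len(n_subj)), each = 2),
                metric_name = "noise")
}

# tiny planted feature-mode cohort for fast GA end-to-end tests
tiny_planted <- function(seed, d = 12, n_subjects = 8, planted = 3,
                         effect = 2) {
  simulate_cohort(synth_config(d = d, n_subjects = n_subjects,
                               planted = planted, effect = effect,
                               mode = "feature"), seed = seed)
}

fast_grid <- function() hyper_grid(cost = c(1, 64), gamma = c(0.01, 0.25))
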