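# Small panels built in code, shared across test files.

# a fully explicit 2-subject, 3-visit panel
tiny_panel <- function() {
  longitudinal_panel(data.frame(
    id = rep(1:2, each = 3),
    t = rep(1:3, 2),
    X = c(0, 1, 1, 1, 0, 1),
    Y = c(0.5, 1.2, -0.3, 2.0, 0.7, 1.1)))
}

# deterministic numeric panel with n subjects, T visits (no randomness)
grid_panel <- function(n = 4, T_v = 2) {
  k <- seq_len(n * T_v)
  longitudinal_panel(data.frame(
    id = rep(seq_len(n), each = T_v),
    t = rep(seq_len(T_v), n),
    X = rep(c(0, 1), length.out = n * T_v),
    Y = round(sin(k) * 2 + k / (n * T_v), 6)))
}

# forge a weight_models object with stated per-row probabilities
forged_weight_models <- function(den_prob, num_prob = NULL) {
  structure(list(denominator = NULL, denominator_prob = den_prob,
                 numerator = NULL, numerator_prob = num_prob,
                 denominator_spec = model_spec(exposure_lags = 1,
                                               outcome_lags = 1),
                 numerator_spec = if (!is.null(num_prob))
                   model_spec(exposure_lags = 1)),
            class = "weight_models")
}

# cached expensive computations for the acceptance suite
.acceptance_cache <- new.env(parent = emptyenv())

acceptance_grid <- function() {
  if (is.null(.acceptance_cache$grid)) {
    .acceptance_cache$grid <- run_estimator_grid(
      dgp_params(scenario = 1), nsim = 1000, seed = 20260923)
  }
  .acceptance_cache$grid
}

grid_cell <- function(g, estimator, working) {
  g[g$estimator == estimator & g$working == working, ]
}

# three-sigma Monte-Carlo band half-width for a grid cell's bias
mc3 <- function(cell) 3 * cell$empirical_sd / sqrt(cell$nsim)
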