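test_that("null propensity model: scores track the marginal exposure rate", {
  # exposure independent of everything: gammaX = gammaY = gammaU = 0
  p <- dgp_params(n = 1500, gammaX = 0, gammaY = 0, gammaU = 0)
  pan <- generate_panel(p, seed = 71)
  ps <- fit_propensity(pan)
  z <- coef(ps$fit)[c("X_lag1", "Y_lag1")] /
    robust_se(ps$fit)[c("X_lag1", "Y_lag1")]
  expect_lt(max(abs(z)), 3)
  expect_lt(abs(mean(ps$scores) - mean(pan$X)), 0.01)
})

test_that("propensity model recovers the generating exposure coefficients", {
  # gammaU = 0: the pooled logistic is exactly the generating model, so
  # the coefficients must be recovered; with a random effect the pooled
  # model is marginal and recovery is only approximate
  p <- dgp_params(n = 6000, gammaU = 0)
  pan <- generate_panel(p, seed = 72)
  ps <- fit_propensity(pan)
  est <- coef(ps$fit)
  se <- robust_se(ps$fit)
  expect_lt(abs(est[["X_lag1"]] - p$gammaX), 3 * se[["X_lag1"]])
  expect_lt(abs(est[["Y_lag1"]] - p$gammaY), 3 * se[["Y_lag1"]])
})

test_that("degenerate constant exposure cannot be fitted", {
  df <- data.frame(id = rep(1:10, each = 3), t = rep(1:3, 10),
                   X = 1, Y = rnorm(30))
  pan <- longitudinal_panel(df)
  expect_error(suppressWarnings(fit_propensity(pan)))
})

test_that("the reported effect is the named current-exposure coefficient", {
  pan <- generate_panel(dgp_params(n = 120), seed = 73)
  fit <- fit_scmm(pan, model_spec(exposure_lags = 0:1, outcome_lags = 1,
                                  include_propensity = TRUE))
  expect_identical(unname(fit$effect["estimate"]),
                   unname(coef(fit$gee)[["X_lag0"]]))
  expect_true("PS" %in% names(coef(fit$gee)))
  expect_equal(fit$effect[["lower"]],
               fit$effect[["estimate"]] - 1.96 * fit$effect[["robust.se"]])
})

test_that("no confounding: the crude estimate is unbiased", {
  # all confounding paths off: exposure purely random
  p <- dgp_params(n = 8000, gammaX = 0, gammaY = 0, gammaU = 0)
  pan <- generate_panel(p, seed = 74)
  fit <- fit_scmm(pan, model_spec(exposure_lags = 0))
  expect_lt(abs(fit$effect[["estimate"]] - p$alphaX),
            3 * fit$effect[["robust.se"]])
})

test_that("double robustness holds when exactly one model is correct", {
  p <- dgp_params(n = 20000)
  pan <- generate_panel(p, seed = 75)
  se_scale <- 0.09 * sqrt(200 / 20000)   # SCMM SE at n = 200 scaled down

  # (a) outcome model badly misspecified (current exposure only), but the
  # propensity model conditions on the true exposure predictors
  fit_a <- fit_scmm(pan, model_spec(exposure_lags = 0,
                                    include_propensity = TRUE))
  expect_lt(abs(fit_a$effect[["estimate"]] - p$alphaX), 3 * se_scale + 0.01)

  # (b) outcome model correct, propensity model misses the prior exposure
  # (a misspecification that is not collinear with the outcome regressors)
  fit_b <- fit_scmm(pan, model_spec(exposure_lags = 0:1, outcome_lags = 1,
                                    include_propensity = TRUE),
                    propensity_spec = model_spec(exposure_lags = integer(),
                                                 outcome_lags = 1))
  expect_lt(abs(fit_b$effect[["estimate"]] - p$alphaX), 3 * se_scale + 0.01)

  # for contrast: both models missing the outcome history is biased
  fit_c <- fit_scmm(pan, model_spec(exposure_lags = 0,
                                    include_propensity = TRUE),
                    propensity_spec = model_spec(exposure_lags = 1))
  expect_gt(fit_c$effect[["estimate"]] - p$alphaX, 0.05)
})

test_that("exposure-covariate interactions add the matching score interaction", {
  pan <- generate_panel(dgp_params(n = 100), seed = 76)
  spec <- model_spec(exposure_lags = 0:1, outcome_lags = 1,
                     include_propensity = TRUE,
                     interactions = list(c("X_lag0", "Y_lag1")))
  fit <- fit_scmm(pan, spec)
  nms <- names(coef(fit$gee))
  expect_true("X_lag0:Y_lag1" %in% nms)
  expect_true("PS:Y_lag1" %in% nms)
})

test_that("continuous exposures use a linear conditional-mean score", {
  set.seed(78)
  n <- 300; T_v <- 4
  df <- data.frame(id = rep(seq_len(n), each = T_v),
                   t = rep(seq_len(T_v), n))
  X <- matrix(0, n, T_v + 1); Y <- matrix(0, n, T_v + 1)
  for (t in 1:T_v) {
    X[, t + 1] <- 0.4 * X[, t] + 0.2 * Y[, t] + rnorm(n, 0, 0.8)
    Y[, t + 1] <- 0.5 * X[, t + 1] + rnorm(n)
  }
  df$X <- as.vector(t(X[, -1])); df$Y <- as.vector(t(Y[, -1]))
  pan <- longitudinal_panel(df, exposure_type = "continuous")
  ps <- fit_propensity(pan)
  # scores are pooled linear fitted means of X_t given the past
  d <- build_design(pan, model_spec(exposure_lags = 1, outcome_lags = 1),
                    response = "exposure")
  ols <- lm.fit(d$x, d$y)
  expect_equal(ps$scores, unname(ols$fitted.values), tolerance = 1e-8)
  # score adjustment replaces the raw history (a linear score alongside
  # all of its own predictors would be exactly collinear) and recovers
  # the short-term effect
  fit <- fit_scmm(pan, model_spec(exposure_lags = 0,
                                  include_propensity = TRUE))
  expect_lt(abs(fit$effect[["estimate"]] - 0.5),
            3 * fit$effect[["robust.se"]])
})

test_that("logistic SCMM fits a binary outcome", {
  p <- dgp_params(n = 300)
  pan0 <- generate_panel(p, seed = 77)
  df <- as.data.frame(pan0)
  df$Y <- as.numeric(df$Y > 0)
  pan <- longitudinal_panel(df)
  fit <- fit_scmm(pan, model_spec(exposure_lags = 0:1, outcome_lags = 1),
                  family = "binomial")
  expect_true(fit$gee$converged)
  expect_gt(fit$effect[["estimate"]], 0)   # positive short-term effect
})
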