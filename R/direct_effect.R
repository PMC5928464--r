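# Step-1/step-3 design construction shared by the R path and the
# compiled bootstrap core. Step 1 regresses Y_t on all exposure lags
# 0..T-1 and outcome lags 1..T-1 (zero-padded); step 3 regresses X_{t-1}
# (visits t = 2..T) on the deeper history X lags 2..T-1, Y lags 2..T-1,
# plus the predicted outcomes.
.step1_spec <- function(T_v) {
  model_spec(exposure_lags = 0:(T_v - 1L), outcome_lags = 1:(T_v - 1L))
}

.step3_design <- function(panel) {
  n <- n_subjects(panel); T_v <- n_visits(panel)
  Xm <- .panel_matrix(panel, "X")
  Ym <- .panel_matrix(panel, "Y")
  keep <- rep(seq_len(T_v) >= 2L, times = n)       # visits 2..T, subject-major
  resp <- as.vector(t(.lag_column(Xm, 1L, T_v)))[keep]   # X_{t-1}
  deeper <- 2:(T_v - 1L)
  cols <- list("(Intercept)" = rep(1, sum(keep)))
  for (l in deeper) {
    cols[[paste0("X_lag", l)]] <- as.vector(t(.lag_column(Xm, l, T_v)))[keep]
  }
  for (l in deeper) {
    cols[[paste0("Y_lag", l)]] <- as.vector(t(.lag_column(Ym, l, T_v)))[keep]
  }
  x <- do.call(cbind, cols)
  list(y = resp, x = x, id = panel$id[keep], keep = keep)
}

#' Step 1: SCMM of the outcome on the full measured history
#'
#' Fits the linear SCMM of `Y_t` on exposure lags `0..T-1` and outcome
#' lags `1..T-1` (zero-padded before baseline), pooled over visits with
#' an independence GEE. This model is used to infer the short-term effect
#' of `X_t` and to construct reference-exposure predictions.
#'
#' @param panel a [longitudinal_panel()] with at least 3 visits.
#' @param control a [gee_control()].
#' @return an `"scmm_fit"`.
#' @export
fit_step1 <- function(panel, control = gee_control()) {
  stopifnot(inherits(panel, "longitudinal_panel"))
  if (n_visits(panel) < 3L) stop("the direct-effect test requires T >= 3")
  fit_scmm(panel, .step1_spec(n_visits(panel)), working = "independence",
           family = "gaussian", control = control)
}

#' Step 2: predicted outcomes under a reference current exposure
#'
#' Evaluates the step-1 fit at every subject-visit row with the current
#' exposure (lag 0 only) set to `reference` and all other regressors at
#' their observed values: with the linear model this is the fitted value
#' minus `betaX1 * (X_t - reference)`.
#'
#' @param step1 an `"scmm_fit"` from [fit_step1()].
#' @param panel the panel it was fitted to.
#' @param reference the exposure value substituted for `X_t` (default 0).
#' @return numeric vector of predictions aligned to panel rows.
#' @export
predict_zero_exposure <- function(step1, panel, reference = 0) {
  stopifnot(inherits(step1, "scmm_fit"))
  bX0 <- coef(step1)[["X_lag0"]]
  step1$gee$fitted - bX0 * (panel$X - reference)
}

#' Step 3: pooled logistic regression of prior exposure on predictions
#'
#' Regresses `X_{t-1}` (over visits `t = 2..T` combined) on the deeper
#' exposure and outcome history (lags 2 and beyond, zero-padded) and the
#' predicted outcomes `yhat`. The coefficient of `yhat` is the test
#' statistic: under the null of no long-term direct effect it converges
#' to zero.
#'
#' @param panel a [longitudinal_panel()].
#' @param yhat predictions from [predict_zero_exposure()], aligned to
#'   panel rows.
#' @param control a [gee_control()].
#' @return list with `delta` (the `yhat` coefficient) and the pooled
#'   logistic `fit`.
#' @export
fit_step3 <- function(panel, yhat, control = gee_control()) {
  stopifnot(inherits(panel, "longitudinal_panel"),
            length(yhat) == nrow(panel))
  d <- .step3_design(panel)
  x <- cbind(d$x, Yhat = yhat[d$keep])
  fit <- fit_pooled_logistic(d$y, x, d$id, control = control)
  list(delta = coef(fit)[["Yhat"]], fit = fit)
}

#' Test for long-term direct effects of past exposures
#'
#' Tests whether the previous exposure `X_{t-1}` directly affects the
#' subsequent outcome `Y_t` other than through the current exposure
#' `X_t`. The three-step statistic fits the full-history SCMM
#' ([fit_step1()]), predicts outcomes with the current exposure forced to
#' `reference` ([predict_zero_exposure()]), and takes the coefficient
#' `delta` of those predictions in a pooled logistic regression of
#' `X_{t-1}` on the deeper history ([fit_step3()]). Because the
#' predictions are estimated, analytic standard errors are too small;
#' inference uses a cluster bootstrap that resamples whole subject
#' trajectories with replacement and re-runs all three steps on each
#' resample.
#'
#' The 95% confidence interval is the 2.5th-97.5th percentile range of
#' the bootstrap estimates. The primary p-value is the fraction of
#' bootstrap estimates lying more than `|delta|` from 0; the conventional
#' recentred bootstrap p-value (fraction with `|delta* - delta| >=
#' |delta|`) is reported alongside. Resamples whose refit fails
#' (singular design or non-converged logistic) are dropped from the
#' percentile computation and counted.
#'
#' @param panel a [longitudinal_panel()] with at least 3 visits.
#' @param B number of bootstrap resamples.
#' @param seed optional integer seed for the resampling.
#' @param reference exposure value forced in step 2 (the test can probe
#'   direct effects at reference levels other than 0).
#' @param control a [gee_control()].
#' @return an object of class `"direct_effect_test"`: `delta_hat`,
#'   `bootstrap_estimates` (length `B`, `NA` where the refit failed),
#'   `ci_lower`, `ci_upper`, `p_value`, `p_value_recentered`, `n_failed`,
#'   `B`, `seed`, `reference`, `reject` (CI excludes 0).
#' @examples
#' pan <- generate_panel(dgp_params(scenario = 1, n = 100), seed = 6)
#' direct_effect_test(pan, B = 50, seed = 1)
#' @export
direct_effect_test <- function(panel, B = 1000, seed = NULL, reference = 0,
                               control = gee_control()) {
  stopifnot(inherits(panel, "longitudinal_panel"), B >= 1)
  if (n_visits(panel) < 3L) stop("the direct-effect test requires T >= 3")
  n <- n_subjects(panel); T_v <- n_visits(panel)

  step1 <- fit_step1(panel, control = control)
  yhat <- predict_zero_exposure(step1, panel, reference = reference)
  step3 <- fit_step3(panel, yhat, control = control)
  delta_hat <- step3$delta

  d1 <- build_design(panel, .step1_spec(T_v))
  d3 <- .step3_design(panel)
  if (!is.null(seed)) set.seed(seed)
  idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = n, ncol = B)
  res <- boot_direct_effect_cpp(d1$x, d1$y,
                                x0_col = which(colnames(d1$x) == "X_lag0") - 1L,
                                ref = reference,
                                M3 = d3$x, y3 = d3$y,
                                idx = idx, T = T_v)
  est <- res[, 1]
  est[res[, 2] == 0] <- NA_real_
  n_failed <- sum(is.na(est))
  if (n_failed > 0.05 * B) {
    warning(n_failed, " of ", B, " bootstrap refits failed (",
            round(100 * n_failed / B, 1), "%); percentile interval may be unreliable")
  }
  ok <- est[!is.na(est)]
  ci <- quantile(ok, c(0.025, 0.975), names = FALSE)
  p_val <- mean(abs(ok) > abs(delta_hat))
  p_rec <- mean(abs(ok - delta_hat) >= abs(delta_hat))
  structure(list(delta_hat = delta_hat, bootstrap_estimates = est,
                 ci_lower = ci[1], ci_upper = ci[2],
                 p_value = p_val, p_value_recentered = p_rec,
                 n_failed = n_failed, B = B, seed = seed,
                 reference = reference,
                 reject = ci[1] > 0 || ci[2] < 0,
                 step1 = step1, step3 = step3),
            class = "direct_effect_test")
}

#' @export
print.direct_effect_test <- function(x, ...) {
  cat("Test for a long-term direct effect of X_{t-1} on Y_t\n")
  cat(sprintf("delta = %.4f, 95%% bootstrap percentile CI (%.4f, %.4f), B = %d\n",
              x$delta_hat, x$ci_lower, x$ci_upper, x$B))
  cat(sprintf("p-value (distance-from-zero rule) = %.4g; recentred = %.4g\n",
              x$p_value, x$p_value_recentered))
  if (x$n_failed > 0) cat("failed bootstrap refits:", x$n_failed, "\n")
  cat(if (x$reject) "CI excludes 0: evidence of a long-term direct effect\n"
      else "CI includes 0: no evidence of a long-term direct effect\n")
  invisible(x)
}
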