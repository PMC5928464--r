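#' Estimator labels for the comparison grid
#'
#' SCMM variants i-iv regress `Y_t` on, respectively, `X_t`;
#' `X_t + Y_{t-1}`; `X_t + X_{t-1}`; `X_t + X_{t-1} + Y_{t-1}`; the
#' `scmm_ps_*` versions add the estimated propensity score. MSM form 1
#' is the short-term form (`x_t` only), form 2 adds `x_{t-1}`; each is
#' fitted with unstabilized, stabilized, and percentile-truncated
#' stabilized weights (`_t1`, `_t5`, `_t10`, `_t20`).
#'
#' @return character vector of valid estimator labels.
#' @export
estimator_labels <- function() {
  c(paste0("scmm_", c("i", "ii", "iii", "iv")),
    paste0("scmm_ps_", c("i", "ii", "iii", "iv")),
    paste0("msm_", rep(1:2, times = 6), "_",
           rep(c("unstab", "stab", "stab_t1", "stab_t5", "stab_t10",
                 "stab_t20"), each = 2)))
}

.scmm_spec_for <- function(label) {
  ps <- grepl("_ps_", label)
  roman <- sub(".*_(i+v?|iv)$", "\\1", label)
  switch(roman,
         i = model_spec(exposure_lags = 0, include_propensity = ps),
         ii = model_spec(exposure_lags = 0, outcome_lags = 1,
                         include_propensity = ps),
         iii = model_spec(exposure_lags = 0:1, include_propensity = ps),
         iv = model_spec(exposure_lags = 0:1, outcome_lags = 1,
                         include_propensity = ps),
         stop("unknown SCMM variant: ", label))
}

# fit every requested estimator on one panel; returns named estimates
.fit_all_estimators <- function(panel, estimators, workings, control) {
  out <- c()
  ps_scores <- NULL
  wm <- NULL
  weight_sets <- list()
  need_ps <- any(grepl("^scmm_ps_", estimators))
  need_w <- any(grepl("^msm_", estimators))
  if (need_ps) {
    ps_scores <- fit_propensity(panel)$scores
  }
  if (need_w) {
    wm <- fit_weight_models(panel)
    for (lab in unique(sub("^msm_[12]_", "", grep("^msm_", estimators,
                                                  value = TRUE)))) {
      weight_sets[[lab]] <- switch(lab,
        unstab = compute_weights(panel, wm, "unstabilized"),
        stab = compute_weights(panel, wm, "stabilized"),
        stab_t1 = compute_weights(panel, wm, "stabilized", truncation_p = 1),
        stab_t5 = compute_weights(panel, wm, "stabilized", truncation_p = 5),
        stab_t10 = compute_weights(panel, wm, "stabilized", truncation_p = 10),
        stab_t20 = compute_weights(panel, wm, "stabilized", truncation_p = 20),
        stop("unknown weight kind: ", lab))
    }
  }
  for (est in estimators) {
    for (wk in workings) {
      val <- tryCatch({
        if (grepl("^scmm", est)) {
          spec <- .scmm_spec_for(est)
          if (spec$include_propensity) {
            d <- build_design(panel, spec, propensity = ps_scores)
          } else {
            d <- build_design(panel, spec)
          }
          fit <- fit_gee(d$y, d$x, d$id, family = "gaussian", working = wk,
                         control = control)
          coef(fit)[["X_lag0"]]
        } else {
          form <- if (grepl("^msm_1_", est)) "short_term" else "current_plus_lag1"
          wlab <- sub("^msm_[12]_", "", est)
          fit <- fit_msm(panel, form = form, weights = weight_sets[[wlab]],
                         working = wk, force = TRUE, control = control)
          fit$effect[["estimate"]]
        }
      }, error = function(e) NA_real_)
      out[paste(est, wk, sep = ".")] <- val
    }
  }
  out
}

#' Compare estimators of the short-term effect across simulated panels
#'
#' Generates `nsim` panels from `params`, fits every requested estimator
#' and working correlation to each panel (the same panels are shared
#' across estimators, a paired design that sharpens contrasts), and
#' summarizes each cell by its bias against the true short-term effect,
#' the normal-approximation Monte-Carlo 95% interval for the bias, and
#' the empirical standard deviation of the estimates.
#'
#' @param params a [dgp_params()].
#' @param nsim number of simulation replicates.
#' @param estimators subset of [estimator_labels()] (default: all).
#' @param workings working correlations to fit (default both).
#' @param seed optional root seed; replicate seeds are drawn from it so
#'   results are reproducible.
#' @param control a [gee_control()].
#' @return a data.frame of class `"estimator_grid"` with one row per
#'   estimator-working cell: `estimator`, `working`, `nsim`, `n_fail`,
#'   `bias`, `mc_lower`, `mc_upper`, `empirical_sd`. The per-replicate
#'   estimates are attached as attribute `"estimates"` for audit.
#' @examples
#' g <- run_estimator_grid(dgp_params(n = 50), nsim = 5,
#'                         estimators = c("scmm_i", "scmm_iv"),
#'                         workings = "independence", seed = 1)
#' g
#' @export
run_estimator_grid <- function(params, nsim = 1000,
                               estimators = estimator_labels(),
                               workings = c("independence", "unstructured"),
                               seed = NULL, control = gee_control()) {
  stopifnot(inherits(params, "dgp_params"))
  bad <- setdiff(estimators, estimator_labels())
  if (length(bad)) stop("unknown estimator label(s): ", paste(bad, collapse = ", "))
  workings <- match.arg(workings, several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, nsim)
  rows <- vector("list", nsim)
  for (r in seq_len(nsim)) {
    panel <- generate_panel(params, seed = rep_seeds[r])
    rows[[r]] <- suppressWarnings(
      .fit_all_estimators(panel, estimators, workings, control))
  }
  est_mat <- do.call(rbind, rows)
  truth <- params$alphaX
  cells <- colnames(est_mat)
  summ <- lapply(cells, function(cl) {
    v <- est_mat[, cl]
    ok <- v[!is.na(v)]
    m <- length(ok)
    bias <- mean(ok) - truth
    sdv <- if (m > 1) sd(ok) else NA_real_
    half <- if (m > 1) 1.96 * sdv / sqrt(m) else NA_real_
    parts <- strsplit(cl, ".", fixed = TRUE)[[1]]
    data.frame(estimator = parts[1], working = parts[2], nsim = m,
               n_fail = sum(is.na(v)), bias = bias,
               mc_lower = bias - half, mc_upper = bias + half,
               empirical_sd = sdv)
  })
  out <- do.call(rbind, summ)
  rownames(out) <- NULL
  attr(out, "estimates") <- est_mat
  attr(out, "true_effect") <- truth
  attr(out, "seed") <- seed
  class(out) <- c("estimator_grid", "data.frame")
  out
}

#' @export
print.estimator_grid <- function(x, digits = 4, ...) {
  cat(sprintf("Estimator comparison over %d replicates (true short-term effect %g)\n",
              max(x$nsim + x$n_fail), attr(x, "true_effect")))
  print.data.frame(cbind(x[, c("estimator", "working", "nsim", "n_fail")],
                         round(x[, c("bias", "mc_lower", "mc_upper",
                                     "empirical_sd")], digits)), ...)
  invisible(x)
}

#' Calibration of the long-term direct-effect test
#'
#' Runs the full bootstrap test on `nsim` independently generated panels
#' and reports the rejection rate (the fraction of 95% percentile
#' intervals excluding 0), together with the mean and standard deviation
#' of the test statistic across replicates. Under scenario 2 (no lagged
#' direct effect) the rejection rate estimates the type-I error; under
#' scenario 1 it estimates power.
#'
#' @param params a [dgp_params()].
#' @param nsim number of simulated panels.
#' @param B bootstrap resamples per panel.
#' @param seed optional root seed (controls both panel generation and
#'   resampling, via per-replicate derived seeds).
#' @return an object of class `"calibration_result"`: `rejection_rate`,
#'   `mean_delta`, `sd_delta`, `nsim`, `B`, `n_failed_refits`, and the
#'   per-replicate table `replicates`.
#' @examples
#' run_test_calibration(dgp_params(scenario = 2, n = 60), nsim = 3, B = 30,
#'                      seed = 1)
#' @export
run_test_calibration <- function(params, nsim = 1000, B = 1000, seed = NULL) {
  stopifnot(inherits(params, "dgp_params"))
  if (!is.null(seed)) set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1L, 2 * nsim), ncol = 2)
  res <- vector("list", nsim)
  for (r in seq_len(nsim)) {
    panel <- generate_panel(params, seed = seeds[r, 1])
    tst <- suppressWarnings(
      direct_effect_test(panel, B = B, seed = seeds[r, 2]))
    res[[r]] <- data.frame(delta = tst$delta_hat, ci_lower = tst$ci_lower,
                           ci_upper = tst$ci_upper, reject = tst$reject,
                           n_failed = tst$n_failed)
  }
  tab <- do.call(rbind, res)
  structure(list(rejection_rate = mean(tab$reject),
                 mean_delta = mean(tab$delta), sd_delta = sd(tab$delta),
                 nsim = nsim, B = B, scenario = params$scenario,
                 n_failed_refits = sum(tab$n_failed),
                 seed = seed, replicates = tab),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Direct-effect test calibration (scenario %d): %d panels x %d resamples\n",
              x$scenario, x$nsim, x$B))
  cat(sprintf("rejection rate = %.3f; mean delta = %.3f (SD %.3f)\n",
              x$rejection_rate, x$mean_delta, x$sd_delta))
  if (x$n_failed_refits > 0)
    cat("total failed bootstrap refits:", x$n_failed_refits, "\n")
  invisible(x)
}
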