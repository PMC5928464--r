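#' Fit the exposure models behind inverse-probability weights
#'
#' Pooled logistic regressions for the probability of the observed
#' exposure at each visit: a denominator model conditioning on the
#' measured confounder history (default: prior exposure and prior
#' outcome) and, for stabilized weights, a numerator model conditioning
#' on a subset treated as baseline-like (default: prior exposure only).
#' Per-row probabilities are of the observed exposure value (`p` when
#' `X_t = 1`, `1 - p` when `X_t = 0`).
#'
#' @param panel a [longitudinal_panel()] with binary exposure.
#' @param denominator_spec a [model_spec()] of denominator predictors.
#' @param numerator_spec a [model_spec()] of numerator predictors, or
#'   `NULL` for unstabilized weights only.
#' @return an object of class `"weight_models"` with the fitted models
#'   and per-row observed-exposure probabilities.
#' @export
fit_weight_models <- function(panel,
                              denominator_spec = model_spec(exposure_lags = 1,
                                                            outcome_lags = 1),
                              numerator_spec = model_spec(exposure_lags = 1)) {
  stopifnot(inherits(panel, "longitudinal_panel"))
  if (exposure_type(panel) != "binary") {
    stop("inverse-probability weights for a continuous exposure are not ",
         "supported: conditional-density weight models are too sensitive ",
         "to tail misspecification to be reliable")
  }
  prob_of_observed <- function(spec) {
    d <- build_design(panel, spec, response = "exposure")
    fit <- fit_pooled_logistic(d$y, d$x, d$id)
    p_obs <- ifelse(d$y == 1, fit$fitted, 1 - fit$fitted)
    if (any(p_obs < 1e-3)) {
      warning("positivity concern: ", sum(p_obs < 1e-3), " observation(s) ",
              "with probability of the observed exposure below 0.001")
    }
    list(fit = fit, p_obs = p_obs)
  }
  den <- prob_of_observed(denominator_spec)
  num <- if (!is.null(numerator_spec)) prob_of_observed(numerator_spec)
  structure(list(denominator = den$fit, denominator_prob = den$p_obs,
                 numerator = num$fit, numerator_prob = num$p_obs,
                 denominator_spec = denominator_spec,
                 numerator_spec = numerator_spec),
            class = "weight_models")
}

#' Cumulative inverse-probability-of-treatment weights
#'
#' Builds per-row cumulative weights from fitted exposure models: the
#' unstabilized weight at visit `t` is the inverse of the running product
#' of denominator probabilities over visits `1..t`; the stabilized weight
#' multiplies this by the running product of numerator probabilities.
#' Truncation at level `p` (percent) replaces weights below the `p`-th
#' percentile of the pooled weight distribution by that percentile value,
#' and symmetrically above the `(100 - p)`-th percentile (percentiles over
#' all subject-visit rows, linear-interpolation definition).
#'
#' @param panel the [longitudinal_panel()] the models were fitted to.
#' @param models a [fit_weight_models()] result.
#' @param kind `"unstabilized"` or `"stabilized"`.
#' @param truncation_p truncation percentage (0 = none; the run used for
#'   comparison truncates at 1, 5, 10 or 20).
#' @return an object of class `"ipw_weights"`: per-row `weights`,
#'   component cumulative products, `kind` and `truncation_p`.
#' @examples
#' pan <- generate_panel(dgp_params(n = 100), seed = 5)
#' wm <- fit_weight_models(pan)
#' w <- compute_weights(pan, wm, kind = "stabilized")
#' summary(w$weights)
#' @export
compute_weights <- function(panel, models,
                            kind = c("stabilized", "unstabilized"),
                            truncation_p = 0) {
  stopifnot(inherits(panel, "longitudinal_panel"),
            inherits(models, "weight_models"))
  kind <- match.arg(kind)
  stopifnot(truncation_p >= 0, truncation_p < 50)
  n <- n_subjects(panel); T_v <- n_visits(panel)

  cum_prod <- function(p, what) {
    if (any(p <= 0)) {
      bad <- which(p <= 0)[1]
      stop("zero ", what, " probability at subject ", panel$id[bad],
           ", visit ", panel$t[bad])
    }
    m <- matrix(p, nrow = T_v)           # visits x subjects (subject-major rows)
    as.vector(apply(m, 2, cumprod))
  }
  cum_den <- cum_prod(models$denominator_prob, "denominator")
  w <- 1 / cum_den
  cum_num <- NULL
  if (kind == "stabilized") {
    if (is.null(models$numerator_prob)) {
      stop("stabilized weights require a numerator model")
    }
    cum_num <- cum_prod(models$numerator_prob, "numerator")
    w <- cum_num / cum_den
  }
  raw <- w
  if (truncation_p > 0) {
    lo <- quantile(w, truncation_p / 100)
    hi <- quantile(w, 1 - truncation_p / 100)
    w <- pmin(pmax(w, lo), hi)
  }
  structure(list(weights = w, untruncated = raw,
                 cumulative_denominator = cum_den,
                 cumulative_numerator = cum_num,
                 kind = if (truncation_p > 0) "truncated" else kind,
                 base_kind = kind, truncation_p = truncation_p,
                 numerator_spec = models$numerator_spec,
                 denominator_spec = models$denominator_spec,
                 id = panel$id, t = panel$t),
            class = "ipw_weights")
}

#' @export
print.ipw_weights <- function(x, ...) {
  cat(sprintf("IPW weights: %s%s\n", x$base_kind,
              if (x$truncation_p > 0)
                sprintf(", truncated at %g%%/%g%%", x$truncation_p,
                        100 - x$truncation_p) else ""))
  by_t <- split(x$weights, x$t)
  tab <- t(vapply(by_t, function(v)
    c(min = min(v), mean = mean(v), max = max(v)), numeric(3)))
  print(round(tab, 4))
  invisible(x)
}

#' Fit a marginal structural model by weighted GEE
#'
#' Fits the MSM mean model for the counterfactual outcome under the
#' observed exposure path, weighting each subject-visit row by its
#' cumulative inverse-probability weight. Two forms are supported:
#' `"short_term"` (`E(Y^x_t) = w0* + wX1* x_t`) and `"current_plus_lag1"`
#' (`E(Y^xbar_t) = w0 + wX1 x_t + wX2 x_{t-1}`). An independence working
#' correlation is recommended: with outcome-dependent exposure, a
#' non-diagonal working correlation lets a subject's other visits enter
#' each visit's estimating contribution and biases the fit (GEE bias) —
#' which an MSM, unlike an SCMM, cannot repair by adjusting for outcome
#' history. The unstructured option is provided to reproduce that bias.
#'
#' The short-term form leaves confounding by prior exposure entirely to
#' the weights, so it requires unstabilized weights or stabilized weights
#' whose numerator excludes prior exposure; the invalid pairing errors
#' unless `force = TRUE`.
#'
#' @param panel a [longitudinal_panel()].
#' @param form `"current_plus_lag1"` or `"short_term"`.
#' @param weights an [compute_weights()] result (or `NULL` for an
#'   unweighted fit of the same mean model).
#' @param working working correlation.
#' @param force allow the invalid short-term/stabilized pairing.
#' @param control a [gee_control()].
#' @return an object of class `"msm_fit"` with the weighted `gee` fit and
#'   the current-exposure `effect` row.
#' @export
fit_msm <- function(panel, form = c("current_plus_lag1", "short_term"),
                    weights = NULL,
                    working = c("independence", "unstructured"),
                    force = FALSE, control = gee_control()) {
  stopifnot(inherits(panel, "longitudinal_panel"))
  form <- match.arg(form)
  working <- match.arg(working)
  w <- NULL
  if (!is.null(weights)) {
    stopifnot(inherits(weights, "ipw_weights"))
    w <- weights$weights
    if (form == "short_term" && weights$base_kind == "stabilized" && !force) {
      ns <- weights$numerator_spec
      # pairing is invalid whenever the numerator conditions on prior exposure
      if (!is.null(ns) && 1L %in% ns$exposure_lags) {
        stop("the short-term MSM form requires confounding by prior exposure ",
             "to live in the weights: use unstabilized weights or a numerator ",
             "without X_{t-1} (or force = TRUE to reproduce the biased fit)")
      }
    }
  }
  spec <- if (form == "current_plus_lag1") {
    model_spec(exposure_lags = 0:1)
  } else {
    model_spec(exposure_lags = 0)
  }
  d <- build_design(panel, spec, response = "outcome")
  gee <- fit_gee(d$y, d$x, d$id, family = "gaussian", working = working,
                 weights = w, control = control)
  est <- coef(gee)[["X_lag0"]]
  se <- robust_se(gee)[["X_lag0"]]
  structure(list(gee = gee, form = form,
                 effect = c(estimate = est, robust.se = se,
                            lower = est - 1.96 * se, upper = est + 1.96 * se),
                 weights = weights, working = working),
            class = "msm_fit")
}

#' @export
print.msm_fit <- function(x, ...) {
  cat(sprintf("MSM (%s form, %s working correlation, %s weights)\n",
              x$form, x$working,
              if (is.null(x$weights)) "no" else x$weights$kind))
  cat(sprintf("Short-term effect (X_lag0): %.4f (robust SE %.4f)\n",
              x$effect["estimate"], x$effect["robust.se"]))
  print(round(rbind(estimate = coef(x$gee), robust.se = robust_se(x$gee)), 4))
  invisible(x)
}

#' @export
coef.msm_fit <- function(object, ...) coef(object$gee)
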