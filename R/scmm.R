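#' Fit a pooled propensity-score model
#'
#' The propensity score at visit `t` is the probability of the observed
#' exposure level given the measured past,
#' `PS_t = Pr(X_t = 1 | X_{t-1}..., Y_{t-1}..., L_t...)` for a binary
#' exposure, fitted by logistic regression pooled across all visits; for
#' a continuous exposure the score is the pooled linear-model fitted
#' conditional mean `E(X_t | past)`. Predictors must exclude the current
#' exposure and current outcome.
#'
#' @param panel a [longitudinal_panel()].
#' @param predictor_spec a [model_spec()] describing the predictors
#'   (exposure lags must start at 1; covariate lag 0 is allowed since
#'   `L_t` precedes `X_t` in the assumed within-visit ordering is not
#'   modeled — the default simulation carries no covariates).
#' @return an object of class `"propensity_fit"` with the pooled model
#'   (`fit`, a `"gee_fit"`), per-row `scores` aligned to panel rows, and
#'   the exposure type.
#' @examples
#' pan <- generate_panel(dgp_params(n = 100), seed = 3)
#' ps <- fit_propensity(pan, model_spec(exposure_lags = 1, outcome_lags = 1))
#' range(ps$scores)
#' @export
fit_propensity <- function(panel,
                           predictor_spec = model_spec(exposure_lags = 1,
                                                       outcome_lags = 1)) {
  stopifnot(inherits(panel, "longitudinal_panel"))
  binary <- exposure_type(panel) == "binary"
  if (binary && length(unique(panel$X)) < 2L) {
    stop("exposure is constant (X = ", panel$X[1],
         " everywhere): the propensity model is degenerate")
  }
  d <- build_design(panel, predictor_spec, response = "exposure")
  fit <- if (binary) {
    fit_pooled_logistic(d$y, d$x, d$id)
  } else {
    fit_gee(d$y, d$x, d$id, family = "gaussian", working = "independence")
  }
  scores <- fit$fitted
  if (binary) {
    extreme <- scores < 1e-6 | scores > 1 - 1e-6
    if (any(extreme)) {
      rows <- paste0("(", d$id[extreme], ",t=", d$t[extreme], ")")
      warning("positivity concern: fitted propensity within 1e-6 of 0/1 at ",
              sum(extreme), " row(s): ",
              paste(utils::head(rows, 5), collapse = " "),
              if (sum(extreme) > 5) " ...")
    }
  }
  structure(list(fit = fit, scores = scores,
                 exposure_type = exposure_type(panel),
                 predictor_spec = predictor_spec),
            class = "propensity_fit")
}

#' @export
print.propensity_fit <- function(x, ...) {
  cat("Pooled propensity model (", x$exposure_type, " exposure)\n", sep = "")
  print(round(rbind(estimate = coef(x$fit), robust.se = robust_se(x$fit)), 4))
  cat("Score range:", paste(format(range(x$scores), digits = 4),
                            collapse = " - "), "\n")
  invisible(x)
}

#' Fit a sequential conditional mean model
#'
#' Regresses the outcome at each visit on the current exposure plus the
#' requested exposure, outcome and covariate histories (and optionally
#' the estimated propensity score), pooled over visits and fitted by GEE.
#' With a correctly specified conditional mean, the coefficient of the
#' current exposure (`X_lag0`) is the conditional short-term (total)
#' causal effect of `X_t` on `Y_t`; lagged-exposure coefficients estimate
#' long-term direct effects conditional on the included history. In
#' linear models, adding the propensity score makes this coefficient
#' doubly robust: consistent when either the outcome regression or the
#' propensity model is correct.
#'
#' When `spec$include_propensity` is `TRUE` the score is estimated once
#' on the full panel by [fit_propensity()] and then treated as a fixed
#' regressor (no variance correction for its estimation); every
#' covariate-by-exposure interaction automatically gains the matching
#' covariate-by-score interaction.
#'
#' @param panel a [longitudinal_panel()].
#' @param spec a [model_spec()] for the outcome regression.
#' @param working working correlation for the GEE.
#' @param family `"gaussian"` for a continuous outcome (identity link) or
#'   `"binomial"` for a binary outcome (logistic SCMM).
#' @param propensity_spec predictors of the propensity model (used only
#'   when `spec$include_propensity`).
#' @param control a [gee_control()].
#' @return object of class `"scmm_fit"`: the underlying `gee` fit, the
#'   current-exposure `effect` row (estimate, robust SE, Wald 95% CI),
#'   and the propensity fit if any.
#' @examples
#' pan <- generate_panel(dgp_params(n = 150), seed = 4)
#' fit_scmm(pan, model_spec(exposure_lags = 0:1, outcome_lags = 1))
#' @export
fit_scmm <- function(panel, spec,
                     working = c("independence", "unstructured"),
                     family = c("gaussian", "binomial"),
                     propensity_spec = model_spec(exposure_lags = 1,
                                                  outcome_lags = 1),
                     control = gee_control()) {
  stopifnot(inherits(panel, "longitudinal_panel"), inherits(spec, "model_spec"))
  working <- match.arg(working)
  family <- match.arg(family)
  propensity <- NULL
  ps_fit <- NULL
  if (spec$include_propensity) {
    ps_fit <- fit_propensity(panel, propensity_spec)
    propensity <- ps_fit$scores
  }
  d <- build_design(panel, spec, response = "outcome",
                    propensity = propensity)
  gee <- fit_gee(d$y, d$x, d$id, family = family, working = working,
                 control = control)
  if (!("X_lag0" %in% names(coef(gee)))) {
    stop("the SCMM must include the current exposure (lag 0)")
  }
  est <- coef(gee)[["X_lag0"]]
  se <- robust_se(gee)[["X_lag0"]]
  effect <- c(estimate = est, robust.se = se,
              lower = est - 1.96 * se, upper = est + 1.96 * se)
  structure(list(gee = gee, effect = effect, spec = spec,
                 propensity = ps_fit, working = working, family = family),
            class = "scmm_fit")
}

#' @export
print.scmm_fit <- function(x, ...) {
  cat(sprintf("SCMM (%s link, %s working correlation)\n",
              if (x$family == "gaussian") "identity" else "logit", x$working))
  cat(sprintf("Short-term effect of X_t (X_lag0): %.4f (robust SE %.4f, 95%% CI %.4f to %.4f)\n",
              x$effect["estimate"], x$effect["robust.se"],
              x$effect["lower"], x$effect["upper"]))
  cat("Coefficients:\n")
  print(round(rbind(estimate = coef(x$gee), robust.se = robust_se(x$gee)), 4))
  invisible(x)
}

#' @export
coef.scmm_fit <- function(object, ...) coef(object$gee)
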