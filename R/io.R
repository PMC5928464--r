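#' Serialize fitted objects and simulation summaries
#'
#' Writes results to disk with stable field names: JSON (default) for
#' model fits and test results, CSV for estimator-comparison grids.
#' Numeric values are written at 12 significant digits; every file
#' carries the package version, and a seed when the object records one.
#'
#' @param x a `"gee_fit"`, `"scmm_fit"`, `"msm_fit"`,
#'   `"direct_effect_test"`, `"calibration_result"` or
#'   `"estimator_grid"`.
#' @param path output file path.
#' @param format `"json"` or `"csv"` (grids only).
#' @return invisibly, `path`.
#' @export
write_results <- function(x, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    if (!inherits(x, "estimator_grid") && !is.data.frame(x)) {
      stop("CSV output supports estimator grids and data frames")
    }
    utils::write.csv(as.data.frame(x), path, row.names = FALSE)
    return(invisible(path))
  }
  payload <- results_payload(x)
  payload$package_version <- as.character(utils::packageVersion("seqcausal"))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = 12,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Flatten a fitted object to a serializable list
#'
#' @param x a supported fitted object (see [write_results()]).
#' @return a named list of plain vectors and scalars.
#' @export
results_payload <- function(x) {
  coef_block <- function(fit) {
    list(coefficients = as.list(coef(fit)),
         robust_se = as.list(robust_se(fit)),
         dispersion = fit$dispersion,
         n_clusters = fit$n_clusters,
         converged = fit$converged,
         working = fit$working, family = fit$family)
  }
  if (inherits(x, "gee_fit")) return(coef_block(x))
  if (inherits(x, "scmm_fit")) {
    return(list(effect = as.list(x$effect), model = coef_block(x$gee),
                propensity = if (!is.null(x$propensity))
                  as.list(coef(x$propensity$fit))))
  }
  if (inherits(x, "msm_fit")) {
    return(list(effect = as.list(x$effect), form = x$form,
                weight_kind = if (!is.null(x$weights)) x$weights$kind,
                truncation_p = if (!is.null(x$weights)) x$weights$truncation_p,
                model = coef_block(x$gee)))
  }
  if (inherits(x, "direct_effect_test")) {
    return(list(delta_hat = x$delta_hat, ci_lower = x$ci_lower,
                ci_upper = x$ci_upper, p_value = x$p_value,
                p_value_recentered = x$p_value_recentered,
                B = x$B, n_failed = x$n_failed, seed = x$seed,
                exposure_reference = x$reference, reject = x$reject,
                bootstrap_estimates = x$bootstrap_estimates))
  }
  if (inherits(x, "calibration_result")) {
    return(list(rejection_rate = x$rejection_rate,
                mean_delta = x$mean_delta, sd_delta = x$sd_delta,
                nsim = x$nsim, B = x$B, scenario = x$scenario,
                n_failed_refits = x$n_failed_refits, seed = x$seed))
  }
  if (inherits(x, "estimator_grid")) {
    return(list(true_effect = attr(x, "true_effect"),
                seed = attr(x, "seed"),
                cells = as.data.frame(x)))
  }
  stop("no serializer for class ", paste(class(x), collapse = "/"))
}

#' Key-value text report of a GEE fit
#'
#' One `key = value` line per quantity: each coefficient with its robust
#' standard error and Wald 95% interval, plus fit metadata.
#'
#' @param fit a `"gee_fit"`.
#' @param path optional file; when `NULL` the lines are returned.
#' @return character vector of report lines, invisibly when written.
#' @export
gee_report <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "gee_fit"))
  est <- coef(fit); se <- robust_se(fit)
  fmt <- function(v) formatC(v, digits = 12, format = "g")
  lines <- c(
    paste0("family = ", fit$family),
    paste0("working = ", fit$working),
    paste0("n_clusters = ", fit$n_clusters),
    paste0("converged = ", fit$converged),
    unlist(lapply(names(est), function(nm) c(
      paste0("coef.", nm, " = ", fmt(est[[nm]])),
      paste0("se.", nm, " = ", fmt(se[[nm]])),
      paste0("ci95.", nm, " = ", fmt(est[[nm]] - 1.96 * se[[nm]]), " ",
             fmt(est[[nm]] + 1.96 * se[[nm]]))))))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
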