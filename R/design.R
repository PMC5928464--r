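#' Specify the regressors of a sequential conditional mean model
#'
#' A model specification lists which lags of the exposure, outcome and
#' covariates enter the regression for the outcome at visit `t`, whether
#' the estimated propensity score is added, and which interaction terms
#' are included. Lag 0 is the current measurement; outcome lag 0 is
#' forbidden (the response cannot be its own regressor).
#'
#' References to visits `t <= 0` follow the `padding` rule: `"zero"`
#' (default) substitutes 0, matching the generative convention that
#' exposures and outcomes are zero before baseline, and retains all `T`
#' visits; `"drop"` removes visits at which any requested lag is
#' undefined.
#'
#' @param exposure_lags non-negative integers (0 = current exposure).
#' @param outcome_lags positive integers.
#' @param covariate_lags named list of non-negative integer vectors, one
#'   entry per covariate.
#' @param include_propensity logical; add the fitted propensity score as a
#'   regressor.
#' @param interactions list of 2-element character vectors naming design
#'   columns to interact (e.g. `c("X_lag0", "Y_lag1")`); a covariate or
#'   lagged-outcome interaction with the current exposure automatically
#'   adds the matching propensity-score interaction when
#'   `include_propensity` is `TRUE`.
#' @param padding `"zero"` or `"drop"`.
#' @return an object of class `"model_spec"`.
#' @examples
#' model_spec(exposure_lags = 0:1, outcome_lags = 1)
#' @export
model_spec <- function(exposure_lags = 0, outcome_lags = integer(),
                       covariate_lags = list(), include_propensity = FALSE,
                       interactions = list(), padding = c("zero", "drop")) {
  padding <- match.arg(padding)
  exposure_lags <- sort(unique(as.integer(exposure_lags)))
  outcome_lags <- sort(unique(as.integer(outcome_lags)))
  if (any(exposure_lags < 0)) stop("exposure lags must be >= 0")
  if (length(outcome_lags) && any(outcome_lags < 1)) {
    stop("outcome lag 0 is forbidden: the response cannot be a regressor")
  }
  if (length(covariate_lags)) {
    if (is.null(names(covariate_lags)) || any(!nzchar(names(covariate_lags)))) {
      stop("'covariate_lags' must be a named list")
    }
    covariate_lags <- lapply(covariate_lags, function(l) {
      l <- sort(unique(as.integer(l)))
      if (any(l < 0)) stop("covariate lags must be >= 0")
      l
    })
  }
  main_terms <- c(paste0("X_lag", exposure_lags),
                  if (length(outcome_lags)) paste0("Y_lag", outcome_lags),
                  unlist(lapply(names(covariate_lags), function(nm)
                    paste0(nm, "_lag", covariate_lags[[nm]]))),
                  if (include_propensity) "PS")
  for (ia in interactions) {
    if (length(ia) != 2L || !is.character(ia)) {
      stop("each interaction must be a character vector of two term names")
    }
    unknown <- setdiff(ia, main_terms)
    if (length(unknown)) {
      stop("interaction references term(s) not in the specification: ",
           paste(unknown, collapse = ", "))
    }
  }
  structure(list(exposure_lags = exposure_lags, outcome_lags = outcome_lags,
                 covariate_lags = covariate_lags,
                 include_propensity = include_propensity,
                 interactions = interactions, padding = padding),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Model specification\n")
  cat("  exposure lags: ", paste(x$exposure_lags, collapse = ", "), "\n")
  if (length(x$outcome_lags))
    cat("  outcome lags:  ", paste(x$outcome_lags, collapse = ", "), "\n")
  for (nm in names(x$covariate_lags))
    cat("  ", nm, " lags: ", paste(x$covariate_lags[[nm]], collapse = ", "), "\n")
  if (x$include_propensity) cat("  + propensity score\n")
  for (ia in x$interactions) cat("  interaction: ", paste(ia, collapse = " x "), "\n")
  cat("  padding for t <= 0:", x$padding, "\n")
  invisible(x)
}

# lagged column of a visit-major (n x T+1, col 1 = t0) matrix, zero-padded
.lag_column <- function(mat, lag, T_v) {
  n <- nrow(mat)
  vals <- matrix(0, n, T_v)
  for (t in seq_len(T_v)) {
    if (t - lag >= 1) vals[, t] <- mat[, t - lag + 1]
    # t - lag <= 0 stays at the pre-baseline value 0
  }
  vals
}

#' Build a lagged regression design from a panel
#'
#' Materializes the lagged regressor columns requested by a
#' [model_spec()], aligned to `(subject, t)` rows in canonical subject-
#' major order. Column names follow the `term_lagK` convention
#' (`X_lag0`, `Y_lag1`, `L1_lag0`, `PS`, `X_lag0:Y_lag1`, ...), so
#' downstream coefficient extraction is by name.
#'
#' @param panel a [longitudinal_panel()].
#' @param spec a [model_spec()].
#' @param response `"outcome"` (default) regresses `Y_t`; `"exposure"`
#'   regresses `X_t` (used by propensity and weight models, whose
#'   predictors must then exclude lag-0 terms).
#' @param propensity optional numeric vector of fitted propensity scores
#'   aligned to panel rows, required when `spec$include_propensity`.
#' @return a list of class `"panel_design"` with elements `y` (response),
#'   `x` (model matrix including intercept), `id`, `t`, and `retained`
#'   (logical index of panel rows kept under the padding rule).
#' @export
build_design <- function(panel, spec, response = c("outcome", "exposure"),
                         propensity = NULL) {
  stopifnot(inherits(panel, "longitudinal_panel"), inherits(spec, "model_spec"))
  response <- match.arg(response)
  n <- n_subjects(panel); T_v <- n_visits(panel)
  max_lag <- max(c(spec$exposure_lags, spec$outcome_lags,
                   unlist(spec$covariate_lags), 0L))
  if (max_lag > T_v - 1L) {
    stop("largest lag (", max_lag, ") exceeds T - 1 = ", T_v - 1L)
  }
  if (response == "exposure" &&
      (0L %in% spec$exposure_lags ||
       any(vapply(spec$covariate_lags, function(l) 0L %in% l, logical(1))))) {
    stop("exposure-model predictors must exclude current (lag-0) terms")
  }

  Xm <- .panel_matrix(panel, "X")
  Ym <- .panel_matrix(panel, "Y")
  cols <- list()
  for (l in spec$exposure_lags) {
    cols[[paste0("X_lag", l)]] <- .lag_column(Xm, l, T_v)
  }
  for (l in spec$outcome_lags) {
    cols[[paste0("Y_lag", l)]] <- .lag_column(Ym, l, T_v)
  }
  for (nm in names(spec$covariate_lags)) {
    Lm <- .panel_matrix(panel, nm)
    for (l in spec$covariate_lags[[nm]]) {
      cols[[paste0(nm, "_lag", l)]] <- .lag_column(Lm, l, T_v)
    }
  }
  if (spec$include_propensity) {
    if (is.null(propensity)) {
      stop("spec includes the propensity score but none was supplied")
    }
    stopifnot(length(propensity) == nrow(panel))
    cols[["PS"]] <- t(matrix(propensity, T_v, n))  # subject-major to n x T
  }

  # flatten visit-major n x T blocks to subject-major row order
  flat <- vapply(cols, function(m) as.vector(t(m)), numeric(n * T_v))
  x <- cbind("(Intercept)" = 1, flat)

  for (ia in spec$interactions) {
    x <- cbind(x, x[, ia[1]] * x[, ia[2]])
    colnames(x)[ncol(x)] <- paste(ia, collapse = ":")
    # a current-exposure interaction requires the matching propensity-score
    # interaction so the doubly robust adjustment stays coherent
    if (spec$include_propensity && "X_lag0" %in% ia) {
      other <- setdiff(ia, "X_lag0")
      ps_name <- paste("PS", other, sep = ":")
      if (length(other) == 1L && !(ps_name %in% colnames(x))) {
        x <- cbind(x, x[, "PS"] * x[, other])
        colnames(x)[ncol(x)] <- ps_name
      }
    }
  }

  y <- if (response == "outcome") panel$Y else panel$X
  retained <- rep(TRUE, n * T_v)
  if (spec$padding == "drop" && max_lag > 0) {
    retained <- panel$t > max_lag
    x <- x[retained, , drop = FALSE]
    y <- y[retained]
  }
  structure(list(y = y, x = x, id = panel$id[retained], t = panel$t[retained],
                 retained = retained),
            class = "panel_design")
}
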