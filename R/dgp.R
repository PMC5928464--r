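#' Parameters of the synthetic longitudinal data-generating process
#'
#' Subjects carry two independent Gaussian random effects, `UX` acting on
#' the exposure process and `UY` on the outcome process. With pre-baseline
#' values fixed at `X0 = Y0 = 0`, visits `t = 1..T` evolve as
#' \deqn{X_t \sim Bernoulli(expit(\gamma_0 + \gamma_X X_{t-1} +
#'   \gamma_Y Y_{t-1} + \gamma_U U_X)),}
#' \deqn{Y_t = \alpha_0 + \alpha_X X_t + \alpha_{Xlag} X_{t-1} + U_Y +
#'   \epsilon_t, \quad \epsilon_t \sim N(0, \sigma_\epsilon^2).}
#' Prior outcomes confound the exposure-outcome association (through
#' `UY`), and prior exposure both persists (`gamma_X`, `gamma_U`) and, in
#' scenario 1, directly affects the next outcome (`alpha_Xlag`). Scenario
#' 2 removes the lagged direct effect (`alpha_Xlag = 0`), the null of the
#' long-term direct-effect test. Outcome serial dependence flows only
#' through `UY` and the exposure path; there is no `Y_{t-1} -> Y_t` arrow.
#'
#' @param scenario 1 (lagged direct effect present) or 2 (absent).
#' @param n number of subjects.
#' @param n_visits visits per subject (`T`).
#' @param gamma0,gammaX,gammaY,gammaU exposure-model coefficients
#'   (intercept, prior exposure, prior outcome, exposure random effect).
#' @param alpha0,alphaX,alphaXlag outcome-model coefficients (intercept,
#'   current exposure = the true short-term effect, prior exposure = the
#'   long-term direct effect). `alphaXlag` is forced to 0 for scenario 2.
#' @param sigma_UY,sigma_UX,sigma_eps standard deviations of the outcome
#'   random effect, exposure random effect, and outcome noise.
#' @return an object of class `"dgp_params"`.
#' @examples
#' dgp_params(scenario = 2)$alphaXlag  # 0 by construction
#' @export
dgp_params <- function(scenario = 1, n = 200, n_visits = 5,
                       gamma0 = -0.5, gammaX = 1.2, gammaY = 0.2,
                       gammaU = 0.3,
                       alpha0 = 0, alphaX = 0.5, alphaXlag = 0.8,
                       sigma_UY = 0.9, sigma_UX = 1, sigma_eps = 1) {
  stopifnot(scenario %in% c(1, 2), n >= 2, n_visits >= 2,
            sigma_UY >= 0, sigma_UX >= 0, sigma_eps >= 0)
  if (scenario == 2) alphaXlag <- 0
  structure(list(scenario = scenario, n = as.integer(n),
                 n_visits = as.integer(n_visits),
                 gamma0 = gamma0, gammaX = gammaX, gammaY = gammaY,
                 gammaU = gammaU, alpha0 = alpha0, alphaX = alphaX,
                 alphaXlag = alphaXlag, sigma_UY = sigma_UY,
                 sigma_UX = sigma_UX, sigma_eps = sigma_eps),
            class = "dgp_params")
}

#' @export
print.dgp_params <- function(x, ...) {
  cat(sprintf("DGP parameters (scenario %d): n=%d, T=%d\n",
              x$scenario, x$n, x$n_visits))
  cat(sprintf("  exposure:  logit P(X_t=1) = %.3g %+.3g X_{t-1} %+.3g Y_{t-1} %+.3g U_X\n",
              x$gamma0, x$gammaX, x$gammaY, x$gammaU))
  cat(sprintf("  outcome:   Y_t = %.3g %+.3g X_t %+.3g X_{t-1} + U_Y + eps\n",
              x$alpha0, x$alphaX, x$alphaXlag))
  cat(sprintf("  sd(U_Y)=%.3g, sd(U_X)=%.3g, sd(eps)=%.3g\n",
              x$sigma_UY, x$sigma_UX, x$sigma_eps))
  invisible(x)
}

# simulate visit-major trajectories; optionally force the exposure at one
# visit (intervene_t / intervene_x), sharing random-effect and noise draws
# through the current RNG state
.simulate_traj <- function(params, n, intervene_t = NULL, intervene_x = NULL,
                           U = NULL) {
  T_v <- params$n_visits
  if (is.null(U)) {
    U <- list(UX = rnorm(n, 0, params$sigma_UX),
              UY = rnorm(n, 0, params$sigma_UY),
              eps = matrix(rnorm(n * T_v, 0, params$sigma_eps), n, T_v),
              u01 = matrix(stats::runif(n * T_v), n, T_v))
  }
  X <- matrix(0, n, T_v + 1L)  # column 1 = pre-baseline t = 0
  Y <- matrix(0, n, T_v + 1L)
  for (t in seq_len(T_v)) {
    pr <- plogis(params$gamma0 + params$gammaX * X[, t] +
                 params$gammaY * Y[, t] + params$gammaU * U$UX)
    X[, t + 1L] <- as.numeric(U$u01[, t] < pr)
    if (!is.null(intervene_t) && t == intervene_t) X[, t + 1L] <- intervene_x
    Y[, t + 1L] <- params$alpha0 + params$alphaX * X[, t + 1L] +
      params$alphaXlag * X[, t] + U$UY + U$eps[, t]
  }
  list(X = X, Y = Y, U = U)
}

#' Generate a synthetic longitudinal panel
#'
#' Draws a balanced panel from the process described in [dgp_params()].
#' The same `seed` always yields the identical panel.
#'
#' @param params a [dgp_params()].
#' @param seed optional integer seed.
#' @return a [longitudinal_panel()] with `n` subjects and `T` visits.
#' @export
generate_panel <- function(params, seed = NULL) {
  stopifnot(inherits(params, "dgp_params"))
  if (!is.null(seed)) set.seed(seed)
  sim <- .simulate_traj(params, params$n)
  T_v <- params$n_visits
  df <- data.frame(
    id = rep(seq_len(params$n), each = T_v),
    t = rep(seq_len(T_v), times = params$n),
    X = as.vector(t(sim$X[, -1L, drop = FALSE])),
    Y = as.vector(t(sim$Y[, -1L, drop = FALSE])))
  panel <- longitudinal_panel(df)
  # latent draws kept for structural diagnostics (not part of the data)
  attr(panel, "random_effects") <- data.frame(id = seq_len(params$n),
                                              UX = sim$U$UX, UY = sim$U$UY)
  attr(panel, "dgp_params") <- params
  panel
}

#' True causal effects under the generative process
#'
#' The short-term effect of `X_t` on `Y_t` is `alphaX` exactly (the
#' outcome model is linear). Total effects of lagged exposures `X_{t-a}`
#' on `Y_t` (direct plus the part mediated through intermediate
#' exposures) are computed by forced-exposure simulation: paired
#' counterfactual trajectories are drawn with the exposure at visit
#' `T - a` set to 1 versus 0 (sharing all random draws), downstream
#' variables regenerated, and the mean difference in `Y_T` taken.
#'
#' @param params a [dgp_params()].
#' @param lags non-negative integers `a`; `a = 0` is the short-term
#'   effect.
#' @param nsim_mc Monte-Carlo sample size for the forced-exposure
#'   simulation.
#' @param seed optional integer seed.
#' @return named numeric vector of total effects, one per lag.
#' @export
true_effects <- function(params, lags = 0:1, nsim_mc = 1e5, seed = NULL) {
  stopifnot(inherits(params, "dgp_params"))
  if (!is.null(seed)) set.seed(seed)
  T_v <- params$n_visits
  out <- numeric(length(lags))
  names(out) <- paste0("lag", lags)
  for (k in seq_along(lags)) {
    a <- lags[k]
    if (a == 0) { out[k] <- params$alphaX; next }
    if (a >= T_v) stop("lag must be smaller than the number of visits")
    t_int <- T_v - a
    base <- .simulate_traj(params, nsim_mc)  # draws shared U
    s1 <- .simulate_traj(params, nsim_mc, intervene_t = t_int,
                         intervene_x = 1, U = base$U)
    s0 <- .simulate_traj(params, nsim_mc, intervene_t = t_int,
                         intervene_x = 0, U = base$U)
    out[k] <- mean(s1$Y[, T_v + 1L] - s0$Y[, T_v + 1L])
  }
  out
}
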