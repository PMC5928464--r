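#' Control parameters for the GEE solver
#'
#' @param tol convergence tolerance on the maximum absolute coefficient
#'   change between iterations.
#' @param maxit maximum number of iterations.
#' @return a list of class `"gee_control"`.
#' @export
gee_control <- function(tol = 1e-8, maxit = 100L) {
  stopifnot(tol > 0, maxit >= 1)
  structure(list(tol = tol, maxit = as.integer(maxit)), class = "gee_control")
}

#' Solve weighted generalized estimating equations on a balanced panel
#'
#' Estimates regression coefficients `beta` solving
#' \deqn{\sum_i D_i^T V_i^{-1} W_i (y_i - \mu_i(\beta)) = 0,}
#' where `D_i` is the derivative of the cluster mean, `V_i = A_i^{1/2} R
#' A_i^{1/2} \phi` the working covariance built from the working
#' correlation `R`, and `W_i` a diagonal matrix of observation weights
#' (the inverse-probability weights of an MSM fit, or 1). Supported mean
#' models are the identity link with Gaussian variance and the logit link
#' with Bernoulli variance; supported working correlations are
#' independence and unstructured. Clusters must be balanced (every
#' cluster the same size, rows ordered by visit within cluster).
#'
#' The solver alternates moment estimation of the dispersion and (for the
#' unstructured case) the working correlation with Fisher-scoring
#' coefficient updates, until the largest absolute coefficient change
#' falls below `control$tol`. Standard errors come from the cluster-robust
#' sandwich `B^{-1} M B^{-T}` with bread `B = sum D'V^{-1}WD` and meat
#' `M = sum D'V^{-1}W rr' WV^{-1}D`.
#'
#' @param y response vector.
#' @param x model matrix (including intercept), full column rank.
#' @param id cluster labels, same length as `y`.
#' @param family `"gaussian"` (identity link) or `"binomial"` (logit).
#' @param working `"independence"` or `"unstructured"`.
#' @param weights non-negative observation weights (default 1).
#' @param control a [gee_control()].
#' @return an object of class `"gee_fit"`: named `coefficients`,
#'   `sandwich_cov`, `naive_cov`, `working_correlation`, `dispersion`,
#'   `n_clusters`, `cluster_size`, `iterations`, `converged`, plus
#'   residuals and fitted values.
#' @examples
#' pan <- generate_panel(dgp_params(scenario = 1, n = 50), seed = 2)
#' d <- build_design(pan, model_spec(exposure_lags = 0:1, outcome_lags = 1))
#' fit_gee(d$y, d$x, d$id)
#' @export
fit_gee <- function(y, x, id,
                    family = c("gaussian", "binomial"),
                    working = c("independence", "unstructured"),
                    weights = NULL, control = gee_control()) {
  family <- match.arg(family)
  working <- match.arg(working)
  x <- as.matrix(x)
  N <- length(y)
  stopifnot(nrow(x) == N, length(id) == N)
  if (is.null(weights)) weights <- rep(1, N)
  if (length(weights) != N || any(!is.finite(weights)) || any(weights < 0)) {
    stop("weights must be finite, non-negative, and aligned to rows")
  }
  p <- ncol(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("b", seq_len(p) - 1L)

  # canonical subject-major contiguous ordering (stable within cluster)
  ord <- order(match(id, unique(id)))
  y <- y[ord]; x <- x[ord, , drop = FALSE]
  id <- id[ord]; weights <- weights[ord]
  sizes <- table(factor(id, levels = unique(id)))
  n <- length(sizes)
  if (n < 2L) stop("at least 2 clusters are required")
  T_v <- as.integer(sizes[1L])
  if (any(sizes != T_v)) stop("clusters must be balanced (equal sizes)")
  if (qr(x)$rank < p) stop("design matrix is rank deficient")
  if (family == "binomial" && !all(y %in% c(0, 1))) {
    stop("binomial family requires a 0/1 response")
  }

  vis <- lapply(seq_len(T_v), function(s) seq(s, N, by = T_v))
  Xs <- lapply(vis, function(ix) x[ix, , drop = FALSE])
  ys <- lapply(vis, function(ix) y[ix])
  ws <- lapply(vis, function(ix) weights[ix])

  beta <- if (family == "gaussian") {
    lm.wfit(x, y, weights + (weights == 0) * 0)$coefficients
  } else {
    rep(0, p)
  }
  beta[is.na(beta)] <- 0
  R <- diag(T_v)
  phi <- 1
  converged <- FALSE
  iter <- 0L

  repeat {
    iter <- iter + 1L
    eta <- drop(x %*% beta)
    if (family == "gaussian") {
      mu <- eta; a <- rep(1, N)
    } else {
      mu <- plogis(eta); a <- pmax(mu * (1 - mu), 1e-10)
    }
    r <- y - mu
    e <- r / sqrt(a)
    phi <- sum(weights * e^2) / max(sum(weights) - p, 1)

    if (working == "unstructured") {
      Em <- matrix(e, nrow = T_v)   # T x n, columns are clusters
      Wm <- matrix(weights, nrow = T_v)
      R <- unstructured_correlation(t(Em), t(Wm))
    }
    Rinv <- solve(R)

    sq_a <- sqrt(a)
    Gs <- lapply(seq_len(T_v), function(s) {
      if (family == "gaussian") Xs[[s]] else Xs[[s]] * sq_a[vis[[s]]]
    })
    rts <- lapply(seq_len(T_v), function(s) r[vis[[s]]] / sq_a[vis[[s]]])

    J <- matrix(0, p, p); U <- numeric(p)
    for (s in seq_len(T_v)) {
      for (t2 in seq_len(T_v)) {
        rst <- Rinv[s, t2]
        if (rst == 0) next
        J <- J + rst * crossprod(Gs[[s]], ws[[t2]] * Gs[[t2]])
        U <- U + rst * drop(crossprod(Gs[[s]], ws[[t2]] * rts[[t2]]))
      }
    }
    delta <- solve(J, U)
    beta <- beta + delta
    if (max(abs(delta)) < control$tol) { converged <- TRUE; break }
    if (iter >= control$maxit) break
  }
  if (!converged) {
    warning("GEE did not converge in ", control$maxit,
            " iterations (max coefficient change ",
            format(max(abs(delta)), digits = 3), ")")
  }

  # final quantities at the returned beta
  eta <- drop(x %*% beta)
  if (family == "gaussian") {
    mu <- eta; a <- rep(1, N)
  } else {
    mu <- plogis(eta); a <- pmax(mu * (1 - mu), 1e-10)
  }
  r <- y - mu
  e <- r / sqrt(a)
  phi <- sum(weights * e^2) / max(sum(weights) - p, 1)
  sq_a <- sqrt(a)
  Gs <- lapply(seq_len(T_v), function(s) {
    if (family == "gaussian") Xs[[s]] else Xs[[s]] * sq_a[vis[[s]]]
  })
  Rinv <- solve(R)
  J <- matrix(0, p, p)
  Gmat <- matrix(0, n, p)
  for (s in seq_len(T_v)) {
    cs <- numeric(n)
    for (t2 in seq_len(T_v)) {
      rst <- Rinv[s, t2]
      if (rst == 0) next
      wt_rt <- ws[[t2]] * r[vis[[t2]]] / sq_a[vis[[t2]]]
      cs <- cs + rst * wt_rt
      J <- J + rst * crossprod(Gs[[s]], ws[[t2]] * Gs[[t2]])
    }
    Gmat <- Gmat + Gs[[s]] * cs
  }
  bread_inv <- solve(J)
  meat <- crossprod(Gmat)
  sandwich <- bread_inv %*% meat %*% t(bread_inv)
  sandwich <- (sandwich + t(sandwich)) / 2
  naive <- phi * bread_inv

  if (family == "binomial") {
    sds <- apply(x, 2, stats::sd)
    sds[sds == 0] <- 1
    if (any(abs(beta * sds) > 20)) {
      warning("possible separation: standardized coefficient(s) exceed 20 (",
              paste(colnames(x)[abs(beta * sds) > 20], collapse = ", "), ")")
    }
  }

  nm <- colnames(x)
  dimnames(sandwich) <- dimnames(naive) <- list(nm, nm)
  structure(list(coefficients = setNames(drop(beta), nm),
                 sandwich_cov = sandwich, naive_cov = naive,
                 working_correlation = R, dispersion = phi,
                 n_clusters = n, cluster_size = T_v,
                 iterations = iter, converged = converged,
                 family = family, working = working,
                 fitted = mu, residuals = r, weights = weights),
            class = "gee_fit")
}

#' Moment estimator of an unstructured working correlation
#'
#' Entry `(s, t)` is the weighted average across clusters of the products
#' of standardized residuals at visits `s` and `t` (cluster contribution
#' weighted by the geometric mean of the two observation weights), scaled
#' afterwards to a unit diagonal.
#'
#' @param resid_mat `n x T` matrix of standardized residuals, one row per
#'   cluster.
#' @param weight_mat optional `n x T` matrix of observation weights.
#' @return a symmetric `T x T` correlation matrix with unit diagonal.
#' @export
unstructured_correlation <- function(resid_mat, weight_mat = NULL) {
  resid_mat <- as.matrix(resid_mat)
  n <- nrow(resid_mat); T_v <- ncol(resid_mat)
  if (is.null(weight_mat)) weight_mat <- matrix(1, n, T_v)
  stopifnot(all(dim(weight_mat) == dim(resid_mat)))
  if (n <= T_v) {
    warning("only ", n, " clusters for a ", T_v, "x", T_v,
            " correlation: estimate may be unstable")
  }
  sw <- sqrt(weight_mat)
  num <- crossprod(sw * resid_mat)       # (s,t): sum_i sqrt(w_is w_it) e_is e_it
  den <- crossprod(sw)                   # (s,t): sum_i sqrt(w_is w_it)
  C <- num / den
  d <- sqrt(diag(C))
  R <- C / tcrossprod(d)
  diag(R) <- 1
  (R + t(R)) / 2
}

#' Pooled logistic regression across visits with cluster-robust variance
#'
#' Maximum-likelihood logistic regression fitted to all subject-visit
#' rows combined (equivalently, a logit-link GEE with independence
#' working correlation), with the sandwich covariance clustered by
#' subject. This is the fitter behind propensity-score and
#' exposure-weight models.
#'
#' @inheritParams fit_gee
#' @return a `"gee_fit"`.
#' @export
fit_pooled_logistic <- function(y, x, id, weights = NULL,
                                control = gee_control()) {
  fit_gee(y, x, id, family = "binomial", working = "independence",
          weights = weights, control = control)
}

#' @export
coef.gee_fit <- function(object, ...) object$coefficients

#' @export
vcov.gee_fit <- function(object, type = c("robust", "naive"), ...) {
  switch(match.arg(type), robust = object$sandwich_cov,
         naive = object$naive_cov)
}

#' Robust standard errors of a GEE fit
#' @param object a `"gee_fit"`.
#' @return named vector of cluster-robust (sandwich) standard errors.
#' @export
robust_se <- function(object) sqrt(diag(object$sandwich_cov))

#' @export
print.gee_fit <- function(x, ...) {
  cat(sprintf("GEE fit: %s family, %s working correlation\n",
              x$family, x$working))
  cat(sprintf("%d clusters x %d observations; %d iterations (%s)\n",
              x$n_clusters, x$cluster_size, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  print(round(rbind(estimate = x$coefficients,
                    robust.se = robust_se(x)), 4))
  invisible(x)
}

#' @export
summary.gee_fit <- function(object, level = 0.95, ...) {
  est <- object$coefficients
  se <- robust_se(object)
  zq <- stats::qnorm(1 - (1 - level) / 2)
  tab <- cbind(estimate = est, robust.se = se, z = est / se,
               p.value = 2 * pnorm(-abs(est / se)),
               lower = est - zq * se, upper = est + zq * se)
  structure(list(coefficients = tab, dispersion = object$dispersion,
                 working_correlation = object$working_correlation,
                 n_clusters = object$n_clusters,
                 converged = object$converged, level = level),
            class = "summary.gee_fit")
}

#' @export
print.summary.gee_fit <- function(x, ...) {
  cat(sprintf("Coefficients (robust SE, %d clusters):\n", x$n_clusters))
  print(round(x$coefficients, 4))
  cat("Dispersion:", format(x$dispersion, digits = 4), "\n")
  invisible(x)
}
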