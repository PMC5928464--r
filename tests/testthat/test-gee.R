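test_that("identity-link independence GEE with unit weights is OLS", {
  pan <- generate_panel(dgp_params(n = 40), seed = 11)
  d <- build_design(pan, model_spec(exposure_lags = 0:1, outcome_lags = 1))
  fit <- fit_gee(d$y, d$x, d$id)
  ols <- lm.fit(d$x, d$y)$coefficients
  expect_lt(max(abs(coef(fit) - ols)), 1e-10)
  expect_true(fit$converged)
  expect_equal(fit$working_correlation, diag(5))
})

test_that("rescaling all weights by a constant leaves coefficients unchanged", {
  pan <- generate_panel(dgp_params(n = 30), seed = 12)
  d <- build_design(pan, model_spec(exposure_lags = 0:1))
  w <- runif(nrow(d$x), 0.5, 2)
  f1 <- fit_gee(d$y, d$x, d$id, weights = w)
  f2 <- fit_gee(d$y, d$x, d$id, weights = 7.3 * w)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-12)
  db <- build_design(pan, model_spec(exposure_lags = 1, outcome_lags = 1),
                     response = "exposure")
  f3 <- fit_gee(db$y, db$x, db$id, family = "binomial",
                working = "unstructured", weights = w)
  f4 <- fit_gee(db$y, db$x, db$id, family = "binomial",
                working = "unstructured", weights = 7.3 * w)
  expect_equal(coef(f3), coef(f4), tolerance = 1e-8)
})

test_that("unstructured-GEE coefficients solve the estimating equations", {
  skip_if_not_installed("pracma")
  pan <- grid_panel(n = 4, T_v = 2)
  d <- build_design(pan, model_spec(exposure_lags = 0, outcome_lags = 1))
  fit <- fit_gee(d$y, d$x, d$id, working = "unstructured")
  R <- fit$working_correlation
  Rinv <- solve(R)
  # estimating function at the converged working correlation, computed
  # independently cluster by cluster
  ee <- function(beta) {
    g <- numeric(ncol(d$x))
    for (i in unique(d$id)) {
      rows <- which(d$id == i)
      Xi <- d$x[rows, , drop = FALSE]
      ri <- d$y[rows] - drop(Xi %*% beta)
      g <- g + drop(t(Xi) %*% Rinv %*% ri)
    }
    g
  }
  expect_lt(max(abs(ee(coef(fit)))), 1e-6)
  root <- pracma::fsolve(ee, coef(fit) * 0 + 0.1)$x
  expect_equal(unname(coef(fit)), unname(root), tolerance = 1e-6)
})

test_that("unstructured correlation matches hand-computed moments", {
  # 3 clusters, T = 2, residuals listed by hand
  e <- rbind(c(1.0, 0.5), c(-0.5, 1.0), c(0.2, -0.4))
  R <- suppressWarnings(unstructured_correlation(e))
  num <- sum(e[, 1] * e[, 2]) / 3
  hand <- num / sqrt(mean(e[, 1]^2) * mean(e[, 2]^2))
  expect_equal(R[1, 2], hand)
  expect_equal(diag(R), c(1, 1))
  expect_equal(R, t(R))

  # residuals identical across visits => perfect correlation
  e2 <- cbind(c(1, -2, 0.5, 3), c(1, -2, 0.5, 3))
  expect_equal(suppressWarnings(unstructured_correlation(e2))[1, 2], 1)

  # independent standard-normal residuals: off-diagonals near 0
  set.seed(99)
  n <- 5000
  e3 <- matrix(rnorm(n * 3), n, 3)
  R3 <- unstructured_correlation(e3)
  expect_lt(max(abs(R3[upper.tri(R3)])), 3 / sqrt(n))
})

test_that("sandwich reduces to HC0 when every cluster has one observation", {
  skip_if_not_installed("sandwich")
  set.seed(21)
  n <- 60
  x <- cbind(1, rnorm(n), runif(n))
  colnames(x) <- c("(Intercept)", "x1", "x2")
  y <- drop(x %*% c(1, 2, -1)) + rnorm(n) * (1 + abs(x[, 2]))
  fit <- fit_gee(y, x, id = seq_len(n))
  lmfit <- lm(y ~ x1 + x2, data = data.frame(y = y, x1 = x[, 2], x2 = x[, 3]))
  hc0 <- sandwich::vcovHC(lmfit, type = "HC0")
  expect_equal(unname(fit$sandwich_cov), unname(hc0), tolerance = 1e-8)
})

test_that("sandwich matches term-by-term summation and is PSD", {
  pan <- grid_panel(n = 3, T_v = 2)
  d <- build_design(pan, model_spec(exposure_lags = 0))
  fit <- fit_gee(d$y, d$x, d$id)
  # direct arithmetic: bread and meat summed cluster by cluster
  B <- matrix(0, 2, 2); M <- matrix(0, 2, 2)
  for (i in unique(d$id)) {
    rows <- which(d$id == i)
    Xi <- d$x[rows, , drop = FALSE]
    ri <- d$y[rows] - drop(Xi %*% coef(fit))
    B <- B + t(Xi) %*% Xi
    gi <- t(Xi) %*% ri
    M <- M + gi %*% t(gi)
  }
  hand <- solve(B) %*% M %*% solve(B)
  expect_equal(unname(fit$sandwich_cov), unname(hand), tolerance = 1e-10)
  expect_true(all(eigen(fit$sandwich_cov, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-12))
  # permuting cluster order leaves the matrix unchanged
  perm <- order(rep(c(2, 3, 1), each = 2))
  f2 <- fit_gee(d$y[perm], d$x[perm, ], d$id[perm])
  expect_equal(f2$sandwich_cov, fit$sandwich_cov, tolerance = 1e-12)
})

test_that("sandwich variance shrinks like 1/n_clusters on replicated data", {
  pan <- generate_panel(dgp_params(n = 25), seed = 31)
  d <- build_design(pan, model_spec(exposure_lags = 0:1))
  f1 <- fit_gee(d$y, d$x, d$id)
  k <- 4
  f4 <- fit_gee(rep(d$y, k), d$x[rep(seq_along(d$y), k), ],
                rep(seq_len(25 * k), each = 5))
  expect_equal(unname(f4$sandwich_cov), unname(f1$sandwich_cov) / k,
               tolerance = 1e-8)
})

test_that("pooled logistic equals ML logistic with cluster-robust SE", {
  pan <- generate_panel(dgp_params(n = 80), seed = 41)
  d <- build_design(pan, model_spec(exposure_lags = 1, outcome_lags = 1),
                    response = "exposure")
  fit <- fit_pooled_logistic(d$y, d$x, d$id)
  ref <- glm.fit(d$x, d$y, family = binomial())
  expect_lt(max(abs(coef(fit) - ref$coefficients)), 1e-8)

  # intercept-only model: closed form logit of the sample proportion
  f0 <- fit_pooled_logistic(d$y, matrix(1, length(d$y), 1,
                                        dimnames = list(NULL, "(Intercept)")),
                            d$id)
  expect_equal(unname(coef(f0)), qlogis(mean(d$y)), tolerance = 1e-8)
})

test_that("pooled logistic matches direct likelihood maximization", {
  # 6-row hand fixture, 3 clusters
  x <- cbind("(Intercept)" = 1, z = c(-1.2, 0.4, 1.5, -0.3, 0.8, 2.0))
  y <- c(0, 1, 1, 0, 0, 1)   # overlapping groups, no separation
  id <- rep(1:3, each = 2)
  fit <- fit_pooled_logistic(y, x, id)
  nll <- function(b) -sum(y * (x %*% b) - log(1 + exp(x %*% b)))
  opt <- optim(c(0, 0), nll, method = "BFGS", control = list(reltol = 1e-14))
  expect_equal(unname(coef(fit)), opt$par, tolerance = 1e-5)
})

test_that("null logistic model recovers zero slopes within Monte-Carlo error", {
  set.seed(51)
  n <- 2000
  x <- cbind("(Intercept)" = 1, a = rnorm(n), b = runif(n))
  y <- rbinom(n, 1, 0.4)                      # independent of predictors
  fit <- fit_pooled_logistic(y, x, rep(1:(n / 2), each = 2))
  z <- coef(fit)[c("a", "b")] / robust_se(fit)[c("a", "b")]
  expect_lt(max(abs(z)), 3)
})

test_that("degenerate and ill-posed problems are diagnosed", {
  pan <- grid_panel(n = 3, T_v = 2)
  d <- build_design(pan, model_spec(exposure_lags = 0))
  xx <- cbind(d$x, dup = d$x[, "X_lag0"])
  expect_error(fit_gee(d$y, xx, d$id), "rank deficient")
  expect_error(fit_gee(d$y, d$x, rep(1, 6)), "at least 2 clusters")
  expect_error(fit_gee(d$y, d$x, d$id, weights = rep(-1, 6)), "weights")
  expect_error(fit_gee(d$y[c(1:5)], d$x[1:5, ], d$id[1:5]), "balanced")
  # separation: perfectly separating predictor triggers a warning
  sep_x <- cbind("(Intercept)" = 1, z = c(-2, -1, -1.5, 1, 2, 1.5))
  sep_y <- c(0, 0, 0, 1, 1, 1)
  warns <- capture_warnings(fit_pooled_logistic(sep_y, sep_x, rep(1:3, each = 2)))
  expect_true(any(grepl("separation", warns)))
})

test_that("unstructured and independence agree for a correct linear mean", {
  # large panel, correctly specified mean: the two workings estimate the
  # same parameter; their difference should be well inside sampling noise
  pan <- generate_panel(dgp_params(n = 3000), seed = 61)
  d <- build_design(pan, model_spec(exposure_lags = 0:1, outcome_lags = 1))
  fi <- fit_gee(d$y, d$x, d$id, working = "independence")
  fu <- fit_gee(d$y, d$x, d$id, working = "unstructured")
  se <- robust_se(fi)[["X_lag0"]]
  expect_lt(abs(coef(fi)[["X_lag0"]] - coef(fu)[["X_lag0"]]), 3 * se)
  # unstructured working correlation is a valid correlation matrix
  R <- fu$working_correlation
  expect_equal(diag(R), rep(1, 5))
  expect_true(all(abs(R) <= 1 + 1e-12))
  expect_equal(R, t(R))
})
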