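test_that("OLS reproduces exact linear data and rejects bad designs", {
  x <- 1:20
  X <- cbind(1, x)
  y <- 3 - 2 * x
  f <- ols_fit(X, y)
  expect_equal(unname(f$beta), c(3, -2), tolerance = 1e-10)
  expect_equal(f$r_squared, 1)
  expect_equal(max(abs(f$residuals)), 0, tolerance = 1e-10)
  expect_error(ols_fit(cbind(1, x, 2 * x), y), "rank-deficient")
  expect_error(ols_fit(cbind(1, 1:2), 1:2), "more observations")
})

test_that("OLS slope vanishes when the response is orthogonal to the centred design", {
  x <- c(-2, -1, 0, 1, 2)
  y <- c(1, -2, 2, -2, 1)  # sum(y) = 0 and sum(x * y) = 0
  f <- ols_fit(cbind(1, x), y)
  expect_equal(unname(f$beta), c(0, 0), tolerance = 1e-12)
})

test_that("OLS matches the longhand normal-equations solution", {
  set.seed(40)
  X <- cbind(1, rnorm(25), runif(25))
  y <- rnorm(25)
  f <- ols_fit(X, y)
  beta_ne <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(unname(f$beta), as.numeric(beta_ne), tolerance = 1e-10)
  expect_equal(f$mae, sum(abs(y - X %*% beta_ne)) / 25, tolerance = 1e-10)
})

test_that("with no spatial process the SLM collapses to OLS", {
  set.seed(41)
  n <- 200
  w <- knn_weights(cbind(runif(n), runif(n)) * 1e4, k = 8)
  X <- cbind(1, rnorm(n))
  y <- as.numeric(X %*% c(5, -2)) + rnorm(n, 0, 0.5)
  fit <- slm_fit_ml(X, y, w)
  expect_lt(abs(fit$rho), 2 * fit$rho_se)
  expect_equal(unname(fit$beta), unname(ols_fit(X, y)$beta), tolerance = 0.05)
})

test_that("concentrated ML agrees with a dense grid search over rho", {
  for (seed in c(50, 51)) {
    set.seed(seed)
    xy <- as.matrix(expand.grid(1:7, 1:7)) * 1000
    w <- knn_weights(xy, k = 8)
    X <- cbind(1, runif(49), runif(49))
    y <- slm_dgp(X, w, c(8, -4, -1), rho = 0.45, sigma = 0.6, seed = seed)
    fit <- slm_fit_ml(X, y, w)
    Wd <- as.matrix(w$W)
    grid <- oracle_slm_grid_search(X, y, Wd, seq(-0.90, 0.99, by = 0.01))
    expect_lt(abs(fit$rho - grid$rho), 0.011)
    # beta at the ML rho equals the dense generalized solution at that rho
    expect_equal(unname(fit$beta),
                 as.numeric(oracle_beta_at_rho(X, y, Wd, fit$rho)),
                 tolerance = 1e-8)
  }
})

test_that("LU and eigenvalue log-determinant backends give the same fit", {
  set.seed(52)
  xy <- as.matrix(expand.grid(1:8, 1:8)) * 1000
  w <- knn_weights(xy, k = 8)
  X <- cbind(1, runif(64))
  y <- slm_dgp(X, w, c(6, -3), rho = 0.5, sigma = 0.5, seed = 52)
  f_lu <- slm_fit_ml(X, y, w, method = "lu")
  f_ei <- slm_fit_ml(X, y, w, method = "eigen")
  expect_equal(f_lu$rho, f_ei$rho, tolerance = 1e-6)
  expect_equal(f_lu$beta, f_ei$beta, tolerance = 1e-6)
})

test_that("the fitted SLM log-likelihood dominates OLS (its rho = 0 submodel)", {
  for (seed in 60:63) {
    set.seed(seed)
    n <- 100
    w <- knn_weights(cbind(runif(n), runif(n)), k = 6)
    X <- cbind(1, rnorm(n))
    y <- rnorm(n, as.numeric(X %*% c(2, 1)), 1)
    fit <- slm_fit_ml(X, y, w)
    expect_gte(fit$loglik, fit$loglik_ols - 1e-8)
  }
})

test_that("reduced-form prediction honours closed forms and the dense inverse", {
  xy <- as.matrix(expand.grid(1:3, 1:3)) * 1000
  w <- knn_weights(xy, k = 8)
  m <- structure(list(beta = c(intercept = 10), rho = 0.5,
                      feature_names = "intercept"), class = "slm_model")
  expect_equal(slm_predict(m, cbind(rep(1, 9)), w), rep(20, 9),
               tolerance = 1e-10)

  set.seed(53)
  w8 <- knn_weights(cbind(runif(8), runif(8)), k = 3)
  X <- cbind(1, rnorm(8))
  m2 <- structure(list(beta = c(1, -2), rho = 0.6), class = "slm_model")
  dense <- solve(diag(8) - 0.6 * as.matrix(w8$W)) %*% (X %*% c(1, -2))
  expect_equal(slm_predict(m2, X, w8), as.numeric(dense), tolerance = 1e-10)

  m0 <- structure(list(beta = c(1, -2), rho = 0), class = "slm_model")
  expect_equal(slm_predict(m0, X, w8), as.numeric(X %*% c(1, -2)),
               tolerance = 1e-12)
})

test_that("prediction clipping is applied and reported", {
  xy <- as.matrix(expand.grid(1:3, 1:3)) * 1000
  w <- knn_weights(xy, k = 8)
  m <- structure(list(beta = c(intercept = 100), rho = 0.5), class = "slm_model")
  expect_message(p <- slm_predict(m, cbind(rep(1, 9)), w, clip = c(0, 92)),
                 "clipped 9")
  expect_true(all(p == 92))
})

test_that("cross-validation is near-perfect on noiseless data and useless on noise", {
  sc <- synthetic_city(synthetic_config(n_rows = 14, n_cols = 14, seed = 70,
                                        dgp_sigma = 0))
  g <- sc$grid[!sc$grid$is_water, ]
  X <- cbind(intercept = 1, ndvi = g$ndvi, d_w = g$d_w)
  cv <- kfold_cv(X, g$days_day, sc$w, n_folds = 4, seed = 1)
  slm_rows <- cv$folds[cv$folds$model == "slm", ]
  expect_true(all(slm_rows$r2_test > 0.99))

  set.seed(71)
  y_perm <- sample(g$days_day)
  cv0 <- kfold_cv(X, y_perm, sc$w, n_folds = 4, seed = 1)
  expect_lt(mean(cv0$folds$r2_test[cv0$folds$model == "slm"]), 0.2)
})

test_that("fold MAE equals a hand summation and coefficients average over folds", {
  sc <- synthetic_city(synthetic_config(n_rows = 12, n_cols = 12, seed = 72))
  g <- sc$grid[!sc$grid$is_water, ]
  X <- cbind(intercept = 1, ndvi = g$ndvi, d_w = g$d_w)
  y <- g$days_day
  n <- nrow(X)
  cv <- kfold_cv(X, y, sc$w, n_folds = 3, seed = 9)

  # reconstruct fold 1 with the same deterministic assignment
  set.seed(9)
  fold <- sample(rep(1:3, length.out = n))
  tr <- fold != 1
  fit <- slm_fit_ml(X[tr, ], y[tr], greenheat:::restrict_weights(sc$w, tr),
                    feature_names = colnames(X))
  pred <- slm_predict(fit, X, sc$w)
  mae_hand <- sum(abs(y[!tr] - pred[!tr])) / sum(!tr)
  got <- cv$folds$mae_test[cv$folds$model == "slm" & cv$folds$fold == 1]
  expect_equal(got, mae_hand, tolerance = 1e-10)

  # averaged coefficients are the arithmetic mean of per-fold estimates
  betas <- sapply(1:3, function(f) {
    tr <- fold != f
    slm_fit_ml(X[tr, ], y[tr], greenheat:::restrict_weights(sc$w, tr))$beta
  })
  expect_equal(unname(cv$beta_avg), unname(rowMeans(betas)), tolerance = 1e-10)
})

test_that("estimation bias shrinks as the city grows", {
  bias_at <- function(n_side, seeds) {
    est <- sapply(seeds, function(s) {
      sc <- synthetic_city(synthetic_config(n_rows = n_side, n_cols = n_side,
                                            seed = s))
      fit_exceedance_slm(sc$grid, "days_day", w = sc$w)$beta["ndvi"]
    })
    abs(mean(est) - (-4.7))
  }
  b_small <- bias_at(10, 1:4)
  b_large <- bias_at(40, 1:4)
  expect_lt(b_large, b_small + 0.05)
})

test_that("with spatial dependence the SLM out-predicts OLS out of sample", {
  sc <- synthetic_city(synthetic_config(n_rows = 20, n_cols = 20, seed = 73,
                                        dgp_rho = 0.5))
  g <- sc$grid[!sc$grid$is_water, ]
  X <- cbind(intercept = 1, ndvi = g$ndvi, d_w = g$d_w)
  cv <- kfold_cv(X, g$days_day, sc$w, n_folds = 5, seed = 2, ols = TRUE)
  r2 <- tapply(cv$folds$r2_test, cv$folds$model, mean)
  expect_gt(r2["slm"], r2["ols"])
})

test_that("tidy and glance expose the fitted model in broom shape", {
  sc <- tiny_city(seed = 74, n = 10)
  fit <- fit_exceedance_slm(sc$grid, "days_day", w = sc$w)
  td <- tidy(fit)
  expect_identical(td$term, c("intercept", "ndvi", "d_w", "rho"))
  expect_true(all(is.finite(td$estimate)))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_gt(gl$sigma2, 0)
})
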