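#' Ordinary least squares baseline
#'
#' Plain linear regression used as the non-spatial comparator for the
#' spatial lag model. Solved by QR via [stats::lm.fit()].
#'
#' @param X Design matrix including an intercept column.
#' @param y Response vector.
#' @return List with `beta`, `fitted`, `residuals`, `sigma2` (ML variant,
#'   SSE/n), `r_squared`, `mae` and `loglik` (Gaussian log-likelihood at
#'   the ML variance).
#' @export
ols_fit <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p) abort("ols_fit: need more observations than parameters")
  if (qr(X)$rank < p) abort("ols_fit: design matrix is rank-deficient")
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  res <- fit$residuals
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  sigma2 <- sse / n
  list(beta = beta,
       fitted = fit$fitted.values,
       residuals = res,
       sigma2 = sigma2,
       r_squared = 1 - sse / sst,
       mae = mean(abs(res)),
       loglik = -(n / 2) * (log(2 * pi * sigma2) + 1))
}

# log|I - rho W| for a sparse row-standardized W.
# method "lu": sparse LU factorization at each rho (no dense matrix).
# method "eigen": one dense eigendecomposition of W, then
#   sum log|1 - rho lambda_i| per rho; only sensible for n <= ~2000.
make_logdet <- function(W, method = c("lu", "eigen")) {
  method <- match.arg(method)
  n <- nrow(W)
  if (method == "eigen") {
    if (n > 2000) abort("eigen log-determinant limited to n <= 2000")
    ev <- eigen(as.matrix(W), only.values = TRUE)$values
    function(rho) sum(log(Mod(1 - rho * ev)))
  } else {
    I_n <- Diagonal(n)
    function(rho) {
      d <- Matrix::determinant(I_n - rho * W, logarithm = TRUE)
      as.numeric(d$modulus)
    }
  }
}

#' Maximum-likelihood fit of the spatial lag model
#'
#' Fits y = rho W y + X beta + eps (eps iid Gaussian) by maximizing the
#' log-likelihood concentrated over the spatial autoregressive parameter
#' rho: for each candidate rho, beta(rho) and sigma2(rho) come from OLS of
#' the spatially filtered response (I - rho W) y on X, and the objective
#'
#'   ll(rho) = -(n/2) log(2 pi sigma2(rho)) + log|I - rho W| - n/2
#'
#' is maximized by scalar optimization over `interval`. The
#' log-determinant uses a sparse LU factorization per candidate rho by
#' default (`method = "lu"`); `method = "eigen"` precomputes the dense
#' eigenvalues of W once (n <= 2000 only).
#'
#' @param X Design matrix including an intercept column, one row per pixel
#'   in weight order.
#' @param y Response vector (mean warm-season exceedance days).
#' @param w A `spatial_weights` object (row-standardized).
#' @param interval Search interval for rho, strictly inside (-1, 1) for a
#'   row-standardized W (default `c(-0.99, 0.99)`).
#' @param method Log-determinant backend, `"lu"` or `"eigen"`.
#' @param feature_names Optional column labels for `X`.
#' @return An object of class `slm_model`: list with `beta`, `rho`,
#'   `sigma2`, `loglik`, `loglik_ols`, `beta_se` (OLS-style SEs at the
#'   fitted rho), `rho_se` (from the numerical curvature of the
#'   concentrated likelihood), `n`, `feature_names`, `converged` (FALSE
#'   when the optimizer lands on the interval boundary) and `fitted`
#'   (reduced-form predictions (I - rho W)^{-1} X beta).
#' @export
slm_fit_ml <- function(X, y, w, interval = c(-0.99, 0.99),
                       method = c("lu", "eigen"), feature_names = NULL) {
  method <- match.arg(method)
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(y) == n, w$n == n)
  if (!all(is.finite(y))) abort("slm_fit_ml: response must be finite")
  if (is.null(feature_names)) {
    feature_names <- colnames(X) %||% paste0("x", seq_len(ncol(X)) - 1L)
  }

  W <- w$W
  Wy <- as.numeric(W %*% y)
  f_o <- stats::lm.fit(X, y)
  f_l <- stats::lm.fit(X, Wy)
  e_o <- f_o$residuals
  e_l <- f_l$residuals

  logdet <- make_logdet(W, method)
  conc_ll <- function(rho) {
    e <- e_o - rho * e_l
    s2 <- sum(e^2) / n
    -(n / 2) * log(2 * pi * s2) + logdet(rho) - n / 2
  }

  opt <- optimize(conc_ll, interval = interval, maximum = TRUE,
                  tol = .Machine$double.eps^0.5)
  rho <- opt$maximum
  converged <- (rho - interval[1] > 1e-4) && (interval[2] - rho > 1e-4)
  if (!converged) {
    warn(sprintf("slm_fit_ml: rho estimate %.4f is at the search boundary; flagged non-converged",
                 rho))
  }

  beta <- f_o$coefficients - rho * f_l$coefficients
  e <- e_o - rho * e_l
  sigma2 <- sum(e^2) / n
  loglik <- opt$objective

  # basic asymptotic SEs: OLS-style for beta at fixed rho, numerical
  # curvature of the concentrated likelihood for rho
  XtX_inv <- chol2inv(chol(crossprod(X)))
  beta_se <- sqrt(sigma2 * diag(XtX_inv))
  h <- 1e-4
  d2 <- (conc_ll(rho + h) - 2 * loglik + conc_ll(rho - h)) / h^2
  rho_se <- if (is.finite(d2) && d2 < 0) sqrt(-1 / d2) else NA_real_

  fitted <- as.numeric(Matrix::solve(Diagonal(n) - rho * W, X %*% beta))

  structure(list(beta = stats::setNames(as.numeric(beta), feature_names),
                 rho = rho, sigma2 = sigma2, loglik = loglik,
                 loglik_ols = -(n / 2) * (log(2 * pi * sum(e_o^2) / n) + 1),
                 beta_se = stats::setNames(beta_se, feature_names),
                 rho_se = rho_se, n = n,
                 feature_names = feature_names,
                 converged = converged, fitted = fitted,
                 method = method),
            class = "slm_model")
}

#' @export
print.slm_model <- function(x, ...) {
  cat("# spatial lag model (ML, concentrated likelihood)\n")
  cat(sprintf("  n = %d, rho = %.4f, sigma2 = %.4f, logLik = %.2f\n",
              x$n, x$rho, x$sigma2, x$loglik))
  print(round(x$beta, 4))
  invisible(x)
}

#' Reduced-form prediction from a fitted spatial lag model
#'
#' Solves (I - rho W) yhat = X beta by a sparse linear solve; the spatial
#' multiplier propagates each pixel's features to its neighbours'
#' predictions. Optionally clips to the physical range of exceedance
#' counts.
#'
#' @param model An `slm_model`.
#' @param X_new Design matrix aligned with `w`'s pixel ordering.
#' @param w A `spatial_weights` object.
#' @param clip Optional `c(lo, hi)`; out-of-range predictions are clipped
#'   and the count reported via a message.
#' @param verbose Report the number of clipped predictions (default TRUE;
#'   iterative callers such as the scenario solver silence it).
#' @return Numeric vector of predictions.
#' @export
slm_predict <- function(model, X_new, w, clip = NULL, verbose = TRUE) {
  X_new <- as.matrix(X_new)
  stopifnot(nrow(X_new) == w$n, ncol(X_new) == length(model$beta))
  n <- w$n
  yhat <- as.numeric(Matrix::solve(Diagonal(n) - model$rho * w$W,
                                   X_new %*% model$beta))
  if (!is.null(clip)) {
    n_clip <- sum(yhat < clip[1] | yhat > clip[2])
    if (n_clip > 0 && verbose) {
      inform(sprintf("slm_predict: clipped %d prediction(s) to [%g, %g]",
                     n_clip, clip[1], clip[2]))
    }
    yhat <- pmin(pmax(yhat, clip[1]), clip[2])
  }
  yhat
}

#' k-fold cross-validation of the spatial lag model
#'
#' Pixels are partitioned into folds at random (deterministic given
#' `seed`). For each fold the model is fitted on the training pixels with
#' W restricted to the training subgraph (rows re-standardized), and all
#' pixels are then predicted by the reduced form on the full W with the
#' training coefficients — held-out responses never enter the prediction.
#' Train and test R-squared (1 - SSE/SST on the evaluation set) and MAE
#' are reported per fold, together with the arithmetic mean of the
#' per-fold coefficient estimates, which downstream scenario analysis
#' uses as its working coefficients.
#'
#' @inheritParams slm_fit_ml
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @param ols Also cross-validate the OLS baseline on the same folds
#'   (default TRUE).
#' @return An object of class `cv_report`: list with `folds` (tibble of
#'   per-fold metrics), `beta_avg`, `rho_avg`, `n_folds`, `seed`.
#' @export
kfold_cv <- function(X, y, w, n_folds = 5, seed = 1L,
                     interval = c(-0.99, 0.99), method = c("lu", "eigen"),
                     feature_names = NULL, ols = TRUE) {
  method <- match.arg(method)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n_folds < 2) abort("kfold_cv: need at least 2 folds")
  set.seed(seed)
  fold <- sample(rep(seq_len(n_folds), length.out = n))
  if (min(table(fold)) <= ncol(X)) {
    abort("kfold_cv: a fold has fewer pixels than model features")
  }

  r2 <- function(obs, pred) 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)

  rows <- vector("list", n_folds)
  betas <- matrix(NA_real_, n_folds, ncol(X))
  rhos <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    te <- !tr
    w_tr <- restrict_weights(w, tr)
    fit <- slm_fit_ml(X[tr, , drop = FALSE], y[tr], w_tr,
                      interval = interval, method = method,
                      feature_names = feature_names)
    pred_all <- slm_predict(fit, X, w)
    betas[f, ] <- fit$beta
    rhos[f] <- fit$rho
    row <- tibble::tibble(
      fold = f, model = "slm",
      r2_train = r2(y[tr], pred_all[tr]),
      r2_test = r2(y[te], pred_all[te]),
      mae_train = mean(abs(y[tr] - pred_all[tr])),
      mae_test = mean(abs(y[te] - pred_all[te])),
      rho = fit$rho)
    if (ols) {
      ofit <- ols_fit(X[tr, , drop = FALSE], y[tr])
      opred <- as.numeric(X %*% ofit$beta)
      row <- dplyr::bind_rows(row, tibble::tibble(
        fold = f, model = "ols",
        r2_train = r2(y[tr], opred[tr]),
        r2_test = r2(y[te], opred[te]),
        mae_train = mean(abs(y[tr] - opred[tr])),
        mae_test = mean(abs(y[te] - opred[te])),
        rho = NA_real_))
    }
    rows[[f]] <- row
  }

  fn <- feature_names %||% colnames(X) %||% paste0("x", seq_len(ncol(X)) - 1L)
  structure(list(folds = dplyr::bind_rows(rows),
                 beta_avg = stats::setNames(colMeans(betas), fn),
                 rho_avg = mean(rhos),
                 n_folds = n_folds, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("# %d-fold spatial-lag cross-validation\n", x$n_folds))
  slm <- x$folds[x$folds$model == "slm", ]
  cat(sprintf("  mean test R2 = %.3f, mean test MAE = %.3f days\n",
              mean(slm$r2_test), mean(slm$mae_test)))
  cat("  fold-averaged coefficients:\n")
  print(round(c(x$beta_avg, rho = x$rho_avg), 4))
  invisible(x)
}

# ---- data-frame front end -------------------------------------------------

# Pixels that enter the regression: land pixels with observed NDVI and
# finite responses. Missing-NDVI exclusions are reported, not imputed.
model_pixels <- function(grid, response) {
  ok <- !grid$is_water & !is.na(grid$ndvi) & is.finite(grid[[response]])
  n_na_ndvi <- sum(!grid$is_water & is.na(grid$ndvi))
  if (n_na_ndvi > 0) {
    inform(sprintf("excluding %d land pixel(s) with missing NDVI from the fit",
                   n_na_ndvi))
  }
  ok
}

# Design matrix over the selected pixels; d_w is dropped automatically
# for cities without water.
slm_design <- function(grid, rows, use_dw = NULL) {
  if (is.null(use_dw)) use_dw <- !isTRUE(city_meta(grid)$dw_excluded)
  if (use_dw) {
    cbind(intercept = 1, ndvi = grid$ndvi[rows], d_w = grid$d_w[rows])
  } else {
    cbind(intercept = 1, ndvi = grid$ndvi[rows])
  }
}

#' Fit the exceedance spatial lag model to a city grid
#'
#' Data-frame front end to [slm_fit_ml()]: takes a `city_grid`, selects
#' the modelling pixels (land, observed NDVI, finite response), builds the
#' (intercept, NDVI, d_w) design — dropping d_w for cities without water —
#' constructs 8-nearest-neighbour weights over those pixels unless a
#' `spatial_weights` object is supplied, and fits by concentrated-likelihood
#' maximum likelihood.
#'
#' @param grid A `city_grid` with exceedance counts filled in.
#' @param response `"days_day"` or `"days_night"`.
#' @param w Optional `spatial_weights` over the modelling pixels.
#' @param k Neighbours for the weights when `w` is NULL.
#' @param ... Passed to [slm_fit_ml()].
#' @return An `slm_model` with an extra `pixels` element (the pixel ids
#'   used, in order).
#' @export
fit_exceedance_slm <- function(grid, response = c("days_day", "days_night"),
                               w = NULL, k = 8, ...) {
  response <- match.arg(response)
  rows <- model_pixels(grid, response)
  X <- slm_design(grid, rows)
  if (is.null(w)) w <- knn_weights(cbind(grid$x, grid$y)[rows, ], k = k)
  fit <- slm_fit_ml(X, grid[[response]][rows], w,
                    feature_names = colnames(X), ...)
  fit$pixels <- grid$pixel_id[rows]
  fit$response <- response
  fit
}

# ---- broom-style tidiers --------------------------------------------------

#' Tidy a fitted spatial lag model
#'
#' @param x An `slm_model`.
#' @param ... Unused.
#' @return One row per term (including `rho`) with `estimate` and
#'   `std.error`.
#' @export
tidy.slm_model <- function(x, ...) {
  tibble::tibble(term = c(x$feature_names, "rho"),
                 estimate = c(unname(x$beta), x$rho),
                 std.error = c(unname(x$beta_se), x$rho_se))
}

#' @rdname tidy.slm_model
#' @export
glance.slm_model <- function(x, ...) {
  tibble::tibble(n = x$n, rho = x$rho, sigma2 = x$sigma2,
                 logLik = x$loglik, logLik_ols = x$loglik_ols,
                 converged = x$converged)
}

#' Tidy a cross-validation report
#'
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return The per-fold metric tibble.
#' @export
tidy.cv_report <- function(x, ...) x$folds

#' @rdname tidy.cv_report
#' @export
glance.cv_report <- function(x, ...) {
  slm <- x$folds[x$folds$model == "slm", ]
  tibble::tibble(n_folds = x$n_folds,
                 r2_test_mean = mean(slm$r2_test),
                 mae_test_mean = mean(slm$mae_test),
                 rho_avg = x$rho_avg)
}
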