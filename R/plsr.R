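#' NIPALS partial least squares regression core
#'
#' Univariate-response NIPALS with X (and y) deflation. `X` and `y` are
#' expected already centered/scaled; the algorithm extracts up to `ncomp`
#' latent variables, each defined by a unit-norm weight vector
#' `w = X'y / ||X'y||`, scores `t = Xw`, loadings `p = X't/t't`,
#' `q = y't/t't`, followed by rank-one deflation `X <- X - t p'`,
#' `y <- y - q t`. Regression coefficients for every truncation level
#' 1..ncomp are accumulated through the standard recurrence
#' `r_a = w_a - sum_(j<a) r_j (p_j' w_a)`, `B_a = sum_(j<=a) r_j q_j`.
#'
#' Extraction stops early if X is fully deflated (weight norm ~ 0).
#'
#' @param X Centered/scaled predictor matrix (n x p).
#' @param y Centered/scaled response vector.
#' @param ncomp Maximum number of latent variables.
#' @return List with `weights` (p x a), `x_loadings` (p x a), `y_loadings`
#'   (length a), `scores` (n x a), `coefficients` (p x a; column a holds the
#'   coefficient vector of the a-component model) and `ncomp` (the number
#'   actually extracted).
#' @export
nipals_pls <- function(X, y, ncomp) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  p <- ncol(X)
  ncomp <- min(ncomp, n - 1L, p)
  W <- P <- B <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  Q <- numeric(ncomp)
  Rm <- matrix(0, p, ncomp)
  a <- 0L
  Xd <- X
  yd <- y
  while (a < ncomp) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t <- drop(Xd %*% w)
    tt <- sum(t^2)
    if (tt < 1e-24) break
    pl <- drop(crossprod(Xd, t)) / tt
    q <- sum(yd * t) / tt
    Xd <- Xd - tcrossprod(t, pl)
    yd <- yd - q * t
    a <- a + 1L
    W[, a] <- w
    P[, a] <- pl
    Q[a] <- q
    Tm[, a] <- t
    r <- w
    if (a > 1L) {
      for (j in seq_len(a - 1L)) r <- r - Rm[, j] * sum(P[, j] * w)
    }
    Rm[, a] <- r
    B[, a] <- if (a == 1L) r * q else B[, a - 1L] + r * q
  }
  idx <- seq_len(a)
  list(weights = W[, idx, drop = FALSE], x_loadings = P[, idx, drop = FALSE],
       y_loadings = Q[idx], scores = Tm[, idx, drop = FALSE],
       coefficients = B[, idx, drop = FALSE], ncomp = a)
}

#' Fit a PLSR calibration with cross-validated latent-variable selection
#'
#' Predictors and response are zero-centered and scaled to unit variance;
#' during cross-validation the scaling statistics are re-estimated on each
#' fold complement so no held-out information leaks into the fit. For each
#' candidate number of latent variables a in 1..max_lv the pooled k-fold
#' RMSE_CV is computed in original trait units; the selected model is the
#' one with the lowest RMSE_CV (ties go to the smaller a), refitted on all
#' training data.
#'
#' @param X Training [spectra_matrix] (or plain matrix).
#' @param y Training trait values.
#' @param max_lv Maximum latent variables considered (default 25); silently
#'   capped by the fold-wise rank bound `min(n - ceiling(n/k) - 1, p)` with
#'   a warning when the cap bites.
#' @param cv A [cv_spec].
#' @return Object of class `plsr_model`: standardizers, NIPALS factors,
#'   `coef_by_lv` (p x max_lv), `selected_n_lv`, `rmse_cv_by_lv`,
#'   `fitted` (training predictions at the selected size), `wavelengths`.
#' @export
fit_plsr <- function(X, y, max_lv = 25, cv = cv_spec()) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  stopifnot(length(y) == n)
  if (stats::sd(y) == 0) stop("zero-variance response", call. = FALSE)
  if (n < cv$k) stop("fewer samples than CV folds", call. = FALSE)
  rank_bound <- min(n - ceiling(n / cv$k) - 1L, ncol(X))
  if (max_lv > rank_bound) {
    warning("max_lv reduced from ", max_lv, " to rank bound ", rank_bound)
    max_lv <- rank_bound
  }
  fitter <- function(Xtr, ytr) {
    xs <- fit_standardizer(Xtr)
    ys <- fit_standardizer(ytr)
    fit <- nipals_pls(apply_standardizer(xs, Xtr),
                      apply_standardizer(ys, ytr), max_lv)
    list(xs = xs, ys = ys, fit = fit)
  }
  predictor <- function(f, Xh) {
    Z <- apply_standardizer(f$xs, Xh)
    pred <- Z %*% f$fit$coefficients   # one column per LV count available
    if (ncol(pred) < max_lv) {         # rank-exhausted fold: repeat last
      pred <- pred[, c(seq_len(ncol(pred)),
                       rep(ncol(pred), max_lv - ncol(pred))), drop = FALSE]
    }
    f$ys$mean + f$ys$sd * pred          # scalar y stats broadcast per column
  }
  rmse_cv <- cross_validate(fitter, predictor, X, y, cv)
  selected <- which.min(rmse_cv)       # first minimum = smallest n_LV
  full <- fitter(X, y)
  fitted_std <- drop(apply_standardizer(full$xs, X) %*%
                       full$fit$coefficients[, min(selected, full$fit$ncomp)])
  structure(
    list(x_standardizer = full$xs, y_standardizer = full$ys,
         weights = full$fit$weights, x_loadings = full$fit$x_loadings,
         y_loadings = full$fit$y_loadings, scores = full$fit$scores,
         coef_by_lv = full$fit$coefficients,
         selected_n_lv = as.integer(selected),
         rmse_cv_by_lv = rmse_cv,
         fitted = invert_standardizer(full$ys, fitted_std),
         wavelengths = suppressWarnings(as.numeric(colnames(X))), cv = cv),
    class = "plsr_model")
}

#' Predict traits from new spectra with a fitted PLSR model
#'
#' Applies the training standardization to the new spectra, the regression
#' coefficients of the selected (or requested) latent-variable count, and
#' inverts the response scaling.
#'
#' @param model A `plsr_model`.
#' @param X_new Matrix of new spectra on the model's wavelength grid.
#' @param n_lv Latent-variable count to use (default: the CV-selected one).
#' @return Numeric vector of predictions in original trait units.
#' @export
predict_plsr <- function(model, X_new, n_lv = model$selected_n_lv) {
  X_new <- as_column_row_matrix(X_new, length(model$x_standardizer$mean))
  check_model_grid(model$wavelengths, colnames(X_new))
  n_lv <- min(n_lv, ncol(model$coef_by_lv))
  Z <- apply_standardizer(model$x_standardizer, X_new)
  invert_standardizer(model$y_standardizer,
                      drop(Z %*% model$coef_by_lv[, n_lv]))
}

#' @export
predict.plsr_model <- function(object, newdata, ...) {
  predict_plsr(object, newdata, ...)
}

as_column_row_matrix <- function(X, p) {
  if (is.null(dim(X))) {
    if (length(X) != p) stop("grid mismatch: expected ", p, " bands", call. = FALSE)
    matrix(X, nrow = 1L)
  } else as.matrix(X)
}

check_model_grid <- function(model_wl, new_names) {
  if (is.null(new_names) || anyNA(model_wl)) return(invisible(TRUE))
  new_wl <- suppressWarnings(as.numeric(new_names))
  if (anyNA(new_wl)) return(invisible(TRUE))
  if (length(new_wl) != length(model_wl) ||
      any(abs(new_wl - model_wl) > 1e-9)) {
    stop("grid mismatch: new spectra are not on the model's wavelength grid",
         call. = FALSE)
  }
  invisible(TRUE)
}
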