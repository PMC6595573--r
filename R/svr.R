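#' Fit a linear epsilon-insensitive SVR calibration with cross-validated C
#'
#' The model is fitted in standardized space (predictors and response
#' zero-centered / unit-variance, statistics re-estimated per CV fold). The
#' bias term is carried as an extra constant feature appended to the
#' standardized design, so the solver works on box constraints only; the
#' epsilon-insensitive dual is minimized by randomized dual coordinate
#' descent (compiled), stopping at a relative duality gap of `tol` or after
#' `max_passes` sweeps. For each C in `c_grid` the pooled k-fold RMSE_CV is
#' computed in original trait units; the C with the lowest RMSE_CV wins
#' (ties go to the smaller C) and the model is refitted on all training
#' data.
#'
#' A constant response is accepted as a degenerate case: the model then has
#' a zero coefficient vector and predicts the training mean.
#'
#' @param X Training [spectra_matrix] (or plain matrix).
#' @param y Training trait values.
#' @param c_grid Candidate cost values, all > 0
#'   (default `c(0.01, 0.1, 1, 10, 100)`).
#' @param epsilon Insensitivity half-width in standardized response units
#'   (default 0.1).
#' @param cv A [cv_spec].
#' @param tol Relative duality-gap tolerance (default 1e-6).
#' @param max_passes Sweep cap (default 10000); hitting it is recorded in
#'   the model metadata as a convergence warning.
#' @return Object of class `svr_model`: standardizers, `coefficients`
#'   (standardized space), `intercept`, selected `C`, `epsilon`,
#'   `rmse_cv_by_c`, convergence metadata, `fitted`, `wavelengths`.
#' @export
fit_svr <- function(X, y, c_grid = c(0.01, 0.1, 1, 10, 100), epsilon = 0.1,
                    cv = cv_spec(), tol = 1e-6, max_passes = 10000L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  stopifnot(length(y) == n, epsilon > 0)
  if (any(c_grid <= 0)) stop("config error: C values must be positive", call. = FALSE)
  if (stats::sd(y) == 0) {                 # degenerate: constant response
    xs <- fit_standardizer(X)
    return(structure(
      list(x_standardizer = xs,
           y_standardizer = structure(list(mean = mean(y), sd = 1,
                                           fitted_on = n),
                                      class = "standardizer"),
           coefficients = numeric(ncol(X)), intercept = 0,
           C = c_grid[1L], epsilon = epsilon,
           rmse_cv_by_c = rep(0, length(c_grid)), converged = TRUE,
           duality_gap = 0, passes = 0L,
           fitted = rep(mean(y), n),
           wavelengths = suppressWarnings(as.numeric(colnames(X))), cv = cv),
      class = "svr_model"))
  }
  if (n < cv$k) stop("fewer samples than CV folds", call. = FALSE)
  solver_seed <- (cv$seed + 1664525L) %% 2147483647L
  solve_one <- function(Xtr, ytr, C) {
    xs <- fit_standardizer(Xtr)
    ys <- fit_standardizer(ytr)
    Z <- cbind(apply_standardizer(xs, Xtr), 1)   # bias feature
    svr_dcd(Z, apply_standardizer(ys, ytr), C, epsilon, tol,
            as.integer(max_passes), as.integer(solver_seed))
  }
  rmse_cv <- vapply(c_grid, function(C) {
    fitter <- function(Xtr, ytr) {
      xs <- fit_standardizer(Xtr)
      ys <- fit_standardizer(ytr)
      sol <- solve_one(Xtr, ytr, C)
      list(xs = xs, ys = ys, w = sol$weights)
    }
    predictor <- function(f, Xh) {
      Z <- cbind(apply_standardizer(f$xs, Xh), 1)
      invert_standardizer(f$ys, drop(Z %*% f$w))
    }
    cross_validate(fitter, predictor, X, y, cv)
  }, numeric(1L))
  best <- which.min(rmse_cv)               # first minimum = smallest C
  xs <- fit_standardizer(X)
  ys <- fit_standardizer(y)
  sol <- solve_one(X, y, c_grid[best])
  if (!sol$converged) {
    warning("SVR solver hit the sweep cap (duality gap ",
            format(sol$duality_gap, digits = 3), ")")
  }
  p <- ncol(X)
  fitted_std <- drop(cbind(apply_standardizer(xs, X), 1) %*% sol$weights)
  structure(
    list(x_standardizer = xs, y_standardizer = ys,
         coefficients = sol$weights[seq_len(p)],
         intercept = sol$weights[p + 1L],
         C = c_grid[best], epsilon = epsilon,
         rmse_cv_by_c = stats::setNames(rmse_cv, c_grid),
         converged = sol$converged, duality_gap = sol$duality_gap,
         passes = sol$passes,
         fitted = invert_standardizer(ys, fitted_std),
         wavelengths = suppressWarnings(as.numeric(colnames(X))), cv = cv),
    class = "svr_model")
}

#' Predict traits from new spectra with a fitted SVR model
#'
#' @param model An `svr_model`.
#' @param X_new Matrix of new spectra on the model's wavelength grid.
#' @return Numeric vector of predictions in original trait units.
#' @export
predict_svr <- function(model, X_new) {
  X_new <- as_column_row_matrix(X_new, length(model$x_standardizer$mean))
  check_model_grid(model$wavelengths, colnames(X_new))
  Z <- apply_standardizer(model$x_standardizer, X_new)
  invert_standardizer(model$y_standardizer,
                      drop(Z %*% model$coefficients) + model$intercept)
}

#' @export
predict.svr_model <- function(object, newdata, ...) predict_svr(object, newdata)
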