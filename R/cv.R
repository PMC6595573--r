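#' Cross-validation specification
#'
#' Random-segment k-fold CV: a seeded permutation of the training indices is
#' cut into k near-equal segments (sizes differ by at most one).
#'
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the fold permutation.
#' @return List of class `cv_spec`.
#' @export
cv_spec <- function(k = 10, seed = 1L) {
  stopifnot(k >= 2)
  structure(list(k = as.integer(k), seed = as.integer(seed)),
            class = "cv_spec")
}

#' Build the fold assignment for n samples
#'
#' @param n Number of samples; must be >= `cv$k`.
#' @param cv A [cv_spec].
#' @return Integer vector of length n with fold ids in 1..k; fold sizes
#'   differ by at most one and the assignment is reproducible from the seed.
#' @export
make_folds <- function(n, cv) {
  stopifnot(inherits(cv, "cv_spec"))
  if (cv$k > n) stop("k exceeds the number of samples", call. = FALSE)
  sizes <- rep(n %/% cv$k, cv$k)
  extra <- n %% cv$k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  perm <- with_seed(cv$seed, sample.int(n))
  folds <- integer(n)
  folds[perm] <- rep.int(seq_len(cv$k), sizes)
  folds
}

#' Pooled cross-validated RMSE over a hyperparameter grid
#'
#' For each fold, `fitter(X_train, y_train)` is fitted on the fold
#' complement (any standardization must happen inside `fitter`, so scaling
#' statistics are re-estimated per fold) and `predictor(fit, X_heldout)`
#' must return a matrix of predictions with one column per candidate
#' hyperparameter value, in original trait units. The RMSE per candidate is
#' pooled over all held-out residuals, i.e.
#' `sqrt(mean over all n held-out samples of squared error)` -- not the
#' mean of per-fold RMSEs.
#'
#' @param fitter Function `(X, y) -> fit` trained per fold.
#' @param predictor Function `(fit, X) -> n x n_candidates matrix`.
#' @param X Predictor matrix. @param y Response vector.
#' @param cv A [cv_spec].
#' @return Numeric vector of pooled RMSE_CV values, one per candidate.
#' @export
cross_validate <- function(fitter, predictor, X, y, cv) {
  n <- nrow(X)
  stopifnot(length(y) == n)
  folds <- make_folds(n, cv)
  sq_err <- NULL
  for (f in seq_len(cv$k)) {
    hold <- folds == f
    fit <- fitter(X[!hold, , drop = FALSE], y[!hold])
    pred <- predictor(fit, X[hold, , drop = FALSE])
    pred <- as.matrix(pred)
    err2 <- (pred - y[hold])^2
    sq_err <- if (is.null(sq_err)) err2 else rbind(sq_err, err2)
  }
  sqrt(colMeans(sq_err))
}
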