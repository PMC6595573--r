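#' Seeded random train/test split
#'
#' Disjoint exhaustive partition of the sample ids via a seeded
#' permutation; the training set gets `round(train_fraction * n)` ids.
#'
#' @param sample_ids Character vector of sample ids.
#' @param train_fraction Fraction assigned to training (default 0.6).
#' @param seed Integer seed.
#' @return List with `train` and `test` id vectors.
#' @export
train_test_split <- function(sample_ids, train_fraction = 0.6, seed = 1L) {
  n <- length(sample_ids)
  if (n < 2L) stop("need at least 2 samples to split", call. = FALSE)
  stopifnot(train_fraction > 0, train_fraction < 1)
  n_train <- round(train_fraction * n)
  n_train <- min(max(n_train, 1L), n - 1L)
  perm <- with_seed(seed, sample.int(n))
  list(train = sample_ids[perm[seq_len(n_train)]],
       test = sample_ids[perm[(n_train + 1L):n]])
}

#' Root mean squared error
#'
#' `sqrt(mean((predicted - measured)^2))` with the 1/N convention.
#'
#' @param measured,predicted Equal-length nonempty numeric vectors.
#' @return RMSE in trait units.
#' @export
rmse <- function(measured, predicted) {
  check_pair(measured, predicted)
  sqrt(mean((predicted - measured)^2))
}

#' Mean absolute percent error, normalized by the mean of the measured values
#'
#' `100 * mean(|predicted - measured|) / mean(measured)`. Note this is the
#' mean absolute error relative to the overall measured mean, not the
#' textbook per-sample MAPE `mean(|error_i / measured_i|)`; the two
#' definitions collide in name but differ numerically.
#'
#' @param measured,predicted Equal-length nonempty numeric vectors;
#'   `mean(measured)` must be nonzero.
#' @return MAPE in percent.
#' @export
mape <- function(measured, predicted) {
  check_pair(measured, predicted)
  ybar <- mean(measured)
  if (ybar == 0) stop("domain error: mean of measured values is zero", call. = FALSE)
  100 * mean(abs(predicted - measured)) / ybar
}

#' Ratio of performance to deviation
#'
#' `sd(measured) / rmse(measured, predicted)`, with the sample (n-1)
#' standard deviation of the measured (test) values. Perfect predictions
#' give `Inf`.
#'
#' @param measured,predicted Equal-length numeric vectors; >= 2 measured
#'   values with positive variance.
#' @return RPD (dimensionless; `Inf` when RMSE is 0).
#' @export
rpd <- function(measured, predicted) {
  check_pair(measured, predicted)
  if (length(measured) < 2L) stop("need >= 2 values for RPD", call. = FALSE)
  sdv <- stats::sd(measured)
  if (sdv == 0) stop("domain error: constant measured vector (SD = 0)", call. = FALSE)
  e <- rmse(measured, predicted)
  if (e == 0) Inf else sdv / e
}

#' Four-tier RPD quality grading
#'
#' Excellent for RPD > 3.5 (usable for quantitative prediction with high
#' confidence), Very Good for 2.5 < RPD <= 3.5, Good for 1.5 < RPD <= 2.5
#' (qualitative screening), Fair otherwise (needs improvement). Exact
#' boundary values fall into the lower tier, following the strict
#' inequalities of the grading scheme.
#'
#' @param x Positive RPD value(s); vectorized.
#' @return Ordered factor with levels Fair < Good < VeryGood < Excellent.
#' @export
classify_rpd <- function(x) {
  if (any(x <= 0, na.rm = TRUE)) stop("RPD must be positive", call. = FALSE)
  lv <- c("Fair", "Good", "VeryGood", "Excellent")
  out <- ifelse(x > 3.5, "Excellent",
                ifelse(x > 2.5, "VeryGood",
                       ifelse(x > 1.5, "Good", "Fair")))
  factor(out, levels = lv, ordered = TRUE)
}

#' Coefficient of determination of measured vs estimated values
#'
#' Primary definition: squared Pearson correlation between measured and
#' predicted (affine-invariant, the usual quantity quoted with
#' measured-vs-estimated scatterplots in chemometrics). The
#' `1 - SSres/SStot` variant is available via `r_squared_ss()` and is
#' co-reported in [evaluate_predictions()].
#'
#' @param measured,predicted Equal-length numeric vectors (>= 2 pairs);
#'   measured must have positive variance.
#' @return R-squared.
#' @export
r_squared <- function(measured, predicted) {
  check_pair(measured, predicted)
  if (length(measured) < 2L || stats::sd(measured) == 0) {
    stop("measured values must have positive variance", call. = FALSE)
  }
  if (stats::sd(predicted) == 0) return(0)
  stats::cor(measured, predicted)^2
}

#' @rdname r_squared
#' @export
r_squared_ss <- function(measured, predicted) {
  check_pair(measured, predicted)
  sstot <- sum((measured - mean(measured))^2)
  if (sstot == 0) stop("measured values must have positive variance", call. = FALSE)
  1 - sum((measured - predicted)^2) / sstot
}

check_pair <- function(measured, predicted) {
  if (length(measured) == 0L) stop("empty input", call. = FALSE)
  if (length(measured) != length(predicted)) {
    stop("length mismatch between measured and predicted", call. = FALSE)
  }
  invisible(TRUE)
}

#' Full evaluation report for one trait on one data split
#'
#' @param measured,predicted Test-set measured and predicted trait values.
#' @param trait Trait name recorded in the report.
#' @return List of class `eval_report`: `trait`, `n_test`, `r2` (squared
#'   correlation), `r2_ss` (1 - SSres/SStot), `rmse`, `mape_pct`, `rpd`,
#'   `rpd_infinite` flag and `category`.
#' @export
evaluate_predictions <- function(measured, predicted, trait = "trait") {
  rp <- rpd(measured, predicted)
  structure(
    list(trait = trait, n_test = length(measured),
         r2 = r_squared(measured, predicted),
         r2_ss = r_squared_ss(measured, predicted),
         rmse = rmse(measured, predicted),
         mape_pct = mape(measured, predicted),
         rpd = rp, rpd_infinite = is.infinite(rp),
         category = as.character(classify_rpd(min(rp, .Machine$double.xmax)))),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval> %s (n=%d): R2 %.3f | RMSE %.4g | MAPE %.2f%% | RPD %.2f (%s)\n",
    x$trait, x$n_test, x$r2, x$rmse, x$mape_pct, x$rpd, x$category))
  invisible(x)
}

#' PCA scores of a spectra matrix
#'
#' Column-centered singular value decomposition (via [stats::prcomp()],
#' no variance scaling). Used to visualise group structure in the processed
#' spectra (score plots) and to quantify how much spectral variance the
#' leading components carry.
#'
#' @param X A [spectra_matrix] or numeric matrix.
#' @param n_components Number of components, <= min(n - 1, p).
#' @return List with `scores` (n x n_components) and `explained_variance`
#'   (fractions of total variance, non-increasing, summing to <= 1).
#' @export
pca_scores <- function(X, n_components = 2) {
  X <- as.matrix(X)
  if (n_components > min(nrow(X) - 1L, ncol(X))) {
    stop("n_components exceeds min(n - 1, p)", call. = FALSE)
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  frac <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(n_components), drop = FALSE],
       explained_variance = frac[seq_len(n_components)])
}
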