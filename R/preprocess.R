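#' Preprocessing configuration
#'
#' Defaults follow common practice for contact-probe leaf spectra: drop the
#' noisy 350-450 nm edge, Savitzky-Golay smooth with window 5 / order 2,
#' then decimate to a 5-nm grid.
#'
#' @param trim_min_nm,trim_max_nm Retained wavelength range (nm).
#' @param sg_window Savitzky-Golay window length (odd, >= 3).
#' @param sg_polyorder Savitzky-Golay polynomial order (< window).
#' @param downsample_step_nm Decimation step (nm).
#' @return List of class `preprocess_config`.
#' @export
preprocess_config <- function(trim_min_nm = 450, trim_max_nm = 2500,
                              sg_window = 5, sg_polyorder = 2,
                              downsample_step_nm = 5) {
  stopifnot(trim_min_nm < trim_max_nm, downsample_step_nm > 0)
  check_sg_params(sg_window, sg_polyorder)
  structure(list(trim_min_nm = trim_min_nm, trim_max_nm = trim_max_nm,
                 sg_window = as.integer(sg_window),
                 sg_polyorder = as.integer(sg_polyorder),
                 downsample_step_nm = downsample_step_nm),
            class = "preprocess_config")
}

check_sg_params <- function(window, polyorder) {
  if (window %% 2 != 1 || window < 3) {
    stop("config error: sg window must be odd and >= 3", call. = FALSE)
  }
  if (polyorder >= window) {
    stop("config error: sg polynomial order must be < window", call. = FALSE)
  }
  invisible(TRUE)
}

#' Trim a spectra matrix to a wavelength range
#'
#' @param spectra A [spectra_matrix].
#' @param lo,hi Range bounds in nm; bands with `lo <= lambda <= hi` are
#'   retained in order.
#' @return A [spectra_matrix].
#' @export
trim_spectra <- function(spectra, lo, hi) {
  wl <- wavelengths(spectra)
  keep <- wl >= lo & wl <= hi
  if (!any(keep)) {
    stop(sprintf("empty selection: no bands in [%g, %g] nm", lo, hi),
         call. = FALSE)
  }
  spectra[, keep, drop = FALSE]
}

#' Savitzky-Golay smoothing of each spectrum
#'
#' Each band is replaced by the center value of a local least-squares
#' polynomial fit over the moving window (delegated to
#' [signal::sgolayfilt()]). The first and last `(window-1)/2` bands are
#' produced by the asymmetric-window rows of the projection matrix, i.e. a
#' polynomial fit over the first/last full window evaluated off-center, so
#' the output has the same length as the input.
#'
#' @param spectra A [spectra_matrix].
#' @param window Odd window length (bands).
#' @param polyorder Polynomial order, < window.
#' @return A [spectra_matrix] of identical shape.
#' @export
savitzky_golay <- function(spectra, window = 5, polyorder = 2) {
  check_sg_params(window, polyorder)
  if (window >= ncol(spectra)) {
    stop("config error: sg window must be smaller than the number of bands",
         call. = FALSE)
  }
  sm <- t(apply(unclass(spectra), 1,
                signal::sgolayfilt, p = polyorder, n = window))
  spectra_matrix(sm, wavelengths(spectra), rownames(spectra))
}

#' Downsample a spectra matrix by band selection
#'
#' Keeps the (already smoothed) values at wavelengths `anchor, anchor+step,
#' ...`; decimation, not block averaging.
#'
#' @param spectra A [spectra_matrix].
#' @param step_nm Step between retained bands (nm).
#' @param anchor_nm First retained wavelength; must be on the grid.
#'   Defaults to the first wavelength of `spectra`.
#' @return A [spectra_matrix].
#' @export
downsample_spectra <- function(spectra, step_nm = 5,
                               anchor_nm = wavelengths(spectra)[1L]) {
  wl <- wavelengths(spectra)
  if (!any(abs(wl - anchor_nm) < 1e-9)) {
    stop(sprintf("anchor %g nm is not on the wavelength grid", anchor_nm),
         call. = FALSE)
  }
  off <- (wl - anchor_nm) / step_nm
  keep <- wl >= anchor_nm & abs(off - round(off)) < 1e-9
  spectra[, keep, drop = FALSE]
}

#' Standardizer: column-wise zero-center / unit-variance scaling
#'
#' `fit_standardizer()` records per-column means and sample standard
#' deviations (n-1 denominator) of the training data;
#' `apply_standardizer()` and `invert_standardizer()` are an exact inverse
#' pair. In the calibration pipeline the standardizer is always fitted on
#' the training split only and reused on the test split.
#'
#' @param X Numeric matrix (or vector, treated as one column) with >= 2
#'   rows and no zero-variance column.
#' @return `fit_standardizer()`: list of class `standardizer` with `mean`,
#'   `sd`, `fitted_on`; the apply/invert functions return an object shaped
#'   like their input.
#' @export
fit_standardizer <- function(X) {
  X <- as_column_matrix(X)
  if (nrow(X) < 2L) stop("need >= 2 rows to fit a standardizer", call. = FALSE)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  if (any(sdv <= 0)) {
    bad <- colnames(X)[which(sdv <= 0)]
    if (is.null(bad)) bad <- which(sdv <= 0)
    stop("zero-variance column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(mean = mu, sd = sdv, fitted_on = nrow(X)),
            class = "standardizer")
}

#' @rdname fit_standardizer
#' @param std A fitted `standardizer`.
#' @export
apply_standardizer <- function(std, X) {
  vec <- is.null(dim(X))
  X <- as_column_matrix(X)
  check_standardizer_columns(std, X)
  out <- sweep(sweep(X, 2, std$mean, `-`), 2, std$sd, `/`)
  if (vec) drop(out) else out
}

#' @rdname fit_standardizer
#' @export
invert_standardizer <- function(std, X) {
  vec <- is.null(dim(X))
  X <- as_column_matrix(X)
  check_standardizer_columns(std, X)
  out <- sweep(sweep(X, 2, std$sd, `*`), 2, std$mean, `+`)
  if (vec) drop(out) else out
}

as_column_matrix <- function(X) {
  if (is.null(dim(X))) matrix(as.numeric(X), ncol = 1L) else as.matrix(X)
}

check_standardizer_columns <- function(std, X) {
  if (ncol(X) != length(std$mean)) {
    stop("column mismatch: standardizer was fitted on ", length(std$mean),
         " column(s), got ", ncol(X), call. = FALSE)
  }
  fit_names <- names(std$mean)
  if (!is.null(fit_names) && !is.null(colnames(X)) &&
      !identical(colnames(X), fit_names)) {
    stop("column mismatch: column names differ from the fitted columns",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Full preprocessing pipeline: trim, smooth, downsample
#'
#' @param spectra A [spectra_matrix] of replicate-averaged raw spectra.
#' @param config A [preprocess_config].
#' @return A model-ready [spectra_matrix] (standardization is left to the
#'   model fitters, which must compute it on the training split).
#' @export
preprocess_spectra <- function(spectra, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  x <- trim_spectra(spectra, config$trim_min_nm, config$trim_max_nm)
  x <- savitzky_golay(x, config$sg_window, config$sg_polyorder)
  downsample_spectra(x, config$downsample_step_nm, wavelengths(x)[1L])
}
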