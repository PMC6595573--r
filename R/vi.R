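#' Normalized-difference vegetation index definition
#'
#' All indices here take the normalized-difference form
#' `(R_B1 - R_B2) / (R_B1 + R_B2)` on reflectance at two named bands.
#'
#' @param name Index name.
#' @param band1_nm,band2_nm The two band centers in nm (B1 and B2 of the
#'   formula); must differ.
#' @return List of class `vi_definition`.
#' @export
vi_definition <- function(name, band1_nm, band2_nm) {
  if (band1_nm == band2_nm) stop("the two bands must differ", call. = FALSE)
  structure(list(name = name, band1_nm = band1_nm, band2_nm = band2_nm),
            class = "vi_definition")
}

#' @export
print.vi_definition <- function(x, ...) {
  cat(sprintf("<vi> %s = (R%g - R%g)/(R%g + R%g)\n", x$name,
              x$band1_nm, x$band2_nm, x$band1_nm, x$band2_nm))
  invisible(x)
}

#' The three built-in narrow-band indices
#'
#' GNDVI `(R800 - R550)/(R800 + R550)` (green, chlorophyll-sensitive),
#' RENDVI `(R750 - R705)/(R750 + R705)` (red edge), and NDWI
#' `(R860 - R1240)/(R860 + R1240)` (leaf water). GNDVI and RENDVI are
#' NIR-band-first; NDWI keeps its literature orientation with the shorter
#' band first.
#'
#' @return Named list of [vi_definition]s.
#' @export
builtin_vis <- function() {
  list(GNDVI  = vi_definition("GNDVI", 800, 550),
       RENDVI = vi_definition("RENDVI", 750, 705),
       NDWI   = vi_definition("NDWI", 860, 1240))
}

#' Compute a vegetation index for every sample
#'
#' Both bands must sit exactly on the grid (no interpolation). Samples
#' where the reflectance sum `R_B1 + R_B2` is not positive get `NA` and a
#' warning.
#'
#' @param spectra A [spectra_matrix].
#' @param definition A [vi_definition].
#' @return Numeric vector of index values, one per sample; values lie in
#'   (-1, 1) whenever both reflectances are positive.
#' @export
compute_vi <- function(spectra, definition) {
  wl <- wavelengths(spectra)
  idx <- function(band) {
    j <- which(abs(wl - band) < 1e-9)
    if (length(j) != 1L) {
      below <- suppressWarnings(max(wl[wl < band]))
      above <- suppressWarnings(min(wl[wl > band]))
      stop(sprintf("band %g nm is not on the grid (nearest available: %s)",
                   band, paste(c(below[is.finite(below)],
                                 above[is.finite(above)]), collapse = " and ")),
           call. = FALSE)
    }
    j
  }
  b1 <- spectra[, idx(definition$band1_nm)]
  b2 <- spectra[, idx(definition$band2_nm)]
  s <- b1 + b2
  out <- (b1 - b2) / s
  bad <- s <= 0
  if (any(bad)) {
    warning(sum(bad), " sample(s) with non-positive reflectance sum flagged NA")
    out[bad] <- NA_real_
  }
  unname(drop(out))
}

#' Linear + quadratic calibration of a trait on an index
#'
#' Ordinary least squares of the trait on `[1, v, v^2]` via [stats::lm()].
#'
#' @param index_values Per-sample index values (>= 3 non-missing).
#' @param trait_values Matching trait values with positive variance.
#' @param definition Optional [vi_definition] stored with the model.
#' @return Object of class `vi_model` with `intercept`, `linear_coef`,
#'   `quadratic_coef` and the underlying `lm` fit.
#' @export
fit_vi_model <- function(index_values, trait_values, definition = NULL) {
  ok <- stats::complete.cases(index_values, trait_values)
  v <- index_values[ok]
  tr <- trait_values[ok]
  if (length(v) < 3L) stop("need at least 3 samples", call. = FALSE)
  if (stats::sd(tr) == 0) stop("zero-variance trait", call. = FALSE)
  if (stats::sd(v) == 0) stop("collinear design: constant index", call. = FALSE)
  fit <- stats::lm(tr ~ v + I(v^2))
  cf <- stats::coef(fit)
  if (any(!is.finite(cf))) stop("non-finite coefficients", call. = FALSE)
  structure(list(definition = definition, intercept = unname(cf[1L]),
                 linear_coef = unname(cf[2L]), quadratic_coef = unname(cf[3L]),
                 lm_fit = fit),
            class = "vi_model")
}

#' Predict a trait from index values with a fitted VI model
#'
#' @param model A `vi_model`.
#' @param index_values New index values.
#' @return Predicted trait values (evaluates the quadratic).
#' @export
predict_vi_model <- function(model, index_values) {
  model$intercept + model$linear_coef * index_values +
    model$quadratic_coef * index_values^2
}

#' @export
predict.vi_model <- function(object, newdata, ...) {
  predict_vi_model(object, newdata)
}

#' Exhaustive two-band normalized-difference search
#'
#' Evaluates every unordered band pair of the (processed) grid, computing
#' the Pearson correlation between the normalized difference
#' `(R_long - R_short)/(R_long + R_short)` and the trait on the training
#' samples, and returns the pair with the highest `|r|`. Ties are broken in
#' favour of the lexicographically smallest (short band, long band) pair.
#' Because ND is antisymmetric under band swap, searching unordered pairs
#' loses nothing.
#'
#' Band selection must be done on the training split only; evaluate the
#' winning index on held-out data.
#'
#' @param spectra Training [spectra_matrix] (the 5-nm processed grid is the
#'   intended input; 411 bands give 84,255 pairs).
#' @param trait_values Training trait values with positive variance.
#' @param keep_matrix Also return the full band-pair `|r|` matrix?
#' @return List of class `band_search_result`: `best_definition` (a
#'   [vi_definition], band1 = longer band), `train_correlation` (signed r of
#'   the winning pair), `n_pairs_evaluated`, and optionally `abs_r_matrix`.
#' @export
exhaustive_band_search <- function(spectra, trait_values, keep_matrix = FALSE) {
  wl <- wavelengths(spectra)
  p <- length(wl)
  if (p < 2L) stop("need at least 2 bands", call. = FALSE)
  if (stats::sd(trait_values) == 0) stop("zero-variance trait", call. = FALSE)
  stopifnot(nrow(spectra) == length(trait_values))
  X <- unclass(spectra)
  best_abs <- -Inf
  best <- NULL
  rmat <- if (keep_matrix) matrix(NA_real_, p, p, dimnames = list(wl, wl))
  for (i in seq_len(p - 1L)) {
    longer <- X[, (i + 1L):p, drop = FALSE]
    nd <- (longer - X[, i]) / (longer + X[, i])
    r <- unname(suppressWarnings(drop(stats::cor(nd, trait_values))))
    r[!is.finite(r)] <- 0
    if (keep_matrix) {
      rmat[i, (i + 1L):p] <- abs(r)
      rmat[(i + 1L):p, i] <- abs(r)
    }
    j <- which.max(abs(r))                 # first max = smallest long band
    if (abs(r[j]) > best_abs) {
      best_abs <- abs(r[j])
      best <- list(short = wl[i], long = wl[i + j], r = r[j])
    }
  }
  structure(
    list(best_definition = vi_definition(
           sprintf("ND_%g_%g", best$long, best$short), best$long, best$short),
         train_correlation = best$r,
         n_pairs_evaluated = p * (p - 1L) / 2L,
         abs_r_matrix = rmat),
    class = "band_search_result")
}

#' @export
print.band_search_result <- function(x, ...) {
  cat(sprintf("<band_search> best pair %g/%g nm, train r = %.4f (%d pairs)\n",
              x$best_definition$band2_nm, x$best_definition$band1_nm,
              x$train_correlation, x$n_pairs_evaluated))
  invisible(x)
}
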