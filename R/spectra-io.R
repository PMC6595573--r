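#' Single leaf reflectance scan
#'
#' A `leaf_spectrum` holds one reflectance scan on a strictly increasing
#' wavelength grid in nm. Raw instrument scans live on the 1-nm integer grid
#' 350..2500 (2151 points), but the class accepts any strictly increasing
#' grid so that trimmed/downsampled spectra can be represented too.
#'
#' @param wavelengths_nm Numeric vector of wavelengths in nm, strictly
#'   increasing.
#' @param reflectance Numeric vector of reflectance fractions, same length as
#'   `wavelengths_nm`, finite and >= 0.
#' @param sample_id Character scalar identifying the plant.
#' @param replicate_label Character scalar identifying the scan within the
#'   plant (e.g. `"leaf2_tip"`).
#' @return An object of class `leaf_spectrum`.
#' @export
leaf_spectrum <- function(wavelengths_nm, reflectance, sample_id,
                          replicate_label = "") {
  wavelengths_nm <- as.numeric(wavelengths_nm)
  reflectance <- as.numeric(reflectance)
  if (length(wavelengths_nm) != length(reflectance)) {
    stop("wavelengths_nm and reflectance must have equal length", call. = FALSE)
  }
  if (length(wavelengths_nm) < 1L) stop("empty spectrum", call. = FALSE)
  if (any(diff(wavelengths_nm) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(reflectance)) || any(reflectance < 0)) {
    stop("reflectance values must be finite and >= 0", call. = FALSE)
  }
  structure(
    list(wavelengths_nm = wavelengths_nm, reflectance = reflectance,
         sample_id = as.character(sample_id),
         replicate_label = as.character(replicate_label)),
    class = "leaf_spectrum"
  )
}

#' @export
print.leaf_spectrum <- function(x, ...) {
  cat(sprintf("<leaf_spectrum> %s [%s]  %d bands (%g-%g nm)\n",
              x$sample_id, x$replicate_label, length(x$wavelengths_nm),
              min(x$wavelengths_nm), max(x$wavelengths_nm)))
  invisible(x)
}

#' Sample-by-band reflectance matrix
#'
#' The matrix form of replicate-averaged spectra: one row per sample, one
#' column per wavelength. Wavelengths are stored as numeric column names;
#' sample ids as row names.
#'
#' @param values Numeric matrix, n_samples x n_bands, no missing values.
#' @param wavelengths_nm Numeric vector of band centers (nm), strictly
#'   increasing, length `ncol(values)`.
#' @param sample_ids Character vector of unique sample ids, length
#'   `nrow(values)`.
#' @return A numeric matrix of class `spectra_matrix` with `dimnames`
#'   `list(sample_ids, wavelengths_nm)`.
#' @export
spectra_matrix <- function(values, wavelengths_nm, sample_ids) {
  values <- as.matrix(values)
  wavelengths_nm <- as.numeric(wavelengths_nm)
  sample_ids <- as.character(sample_ids)
  if (nrow(values) != length(sample_ids)) {
    stop("row count must equal length(sample_ids)", call. = FALSE)
  }
  if (ncol(values) != length(wavelengths_nm)) {
    stop("column count must equal length(wavelengths_nm)", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) stop("sample ids must be unique", call. = FALSE)
  if (any(diff(wavelengths_nm) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(values))) stop("missing/non-finite values", call. = FALSE)
  dimnames(values) <- list(sample_ids, format(wavelengths_nm, trim = TRUE,
                                              scientific = FALSE))
  class(values) <- c("spectra_matrix", "matrix", "array")
  values
}

#' Wavelength grid of a spectra matrix
#' @param x A `spectra_matrix`.
#' @return Numeric vector of band centers in nm.
#' @export
wavelengths <- function(x) as.numeric(colnames(x))

#' @export
print.spectra_matrix <- function(x, ...) {
  wl <- wavelengths(x)
  cat(sprintf("<spectra_matrix> %d samples x %d bands (%g-%g nm)\n",
              nrow(x), ncol(x), min(wl), max(wl)))
  invisible(x)
}

# keep the class through matrix-shaped subsetting (base drop semantics)
#' @export
`[.spectra_matrix` <- function(x, i, j, ..., drop = TRUE) {
  out <- NextMethod()
  if (is.matrix(out)) class(out) <- c("spectra_matrix", "matrix", "array")
  out
}

#' Read a wide spectra CSV
#'
#' Expected layout: a header row naming an id column, a replicate column, and
#' then one numeric wavelength column per band (nm). One data row per scan.
#'
#' @param path Path to the CSV file.
#' @param layout Only `"wide"` is supported.
#' @return List of [leaf_spectrum] objects, wavelength columns sorted
#'   ascending regardless of file order.
#' @export
read_spectra_csv <- function(path, layout = "wide") {
  layout <- match.arg(layout, "wide")
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 3L) {
    stop("format error: need id, replicate and wavelength columns", call. = FALSE)
  }
  hdr <- names(df)
  wl_names <- hdr[-(1:2)]
  wl <- suppressWarnings(as.numeric(wl_names))
  if (any(is.na(wl))) {
    stop("format error: non-numeric wavelength column(s): ",
         paste(wl_names[is.na(wl)], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(wl)) {
    stop("format error: duplicate wavelength column(s): ",
         paste(unique(wl[duplicated(wl)]), collapse = ", "), call. = FALSE)
  }
  ord <- order(wl)
  wl <- wl[ord]
  vals <- df[, -(1:2), drop = FALSE][, ord, drop = FALSE]
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    r <- suppressWarnings(as.numeric(vals[i, ]))
    if (anyNA(r)) {
      bad <- which(is.na(r))[1L]
      stop(sprintf("parse error: non-numeric reflectance at row %d, column \"%s\"",
                   i, format(wl[bad], trim = TRUE)), call. = FALSE)
    }
    out[[i]] <- leaf_spectrum(wl, r, df[i, 1L], df[i, 2L])
  }
  out
}

#' Write scans to a wide spectra CSV
#'
#' Values are written with 17 significant digits so that a write/read cycle
#' reproduces the doubles exactly.
#'
#' @param scans List of [leaf_spectrum] sharing one wavelength grid.
#' @param path Output path.
#' @param id_col,rep_col Header names for the id and replicate columns.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(scans, path, id_col = "sample_id",
                              rep_col = "replicate") {
  stopifnot(length(scans) >= 1L)
  wl <- scans[[1L]]$wavelengths_nm
  for (s in scans) {
    if (!identical(s$wavelengths_nm, wl)) {
      stop("grid error: scan ", s$sample_id, "/", s$replicate_label,
           " is not on the shared wavelength grid", call. = FALSE)
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(id_col, rep_col, format(wl, trim = TRUE,
                                             scientific = FALSE)),
                   collapse = ","), con)
  for (s in scans) {
    writeLines(paste(c(s$sample_id, s$replicate_label,
                       sprintf("%.17g", s$reflectance)), collapse = ","), con)
  }
  invisible(path)
}

#' Write / read a spectra matrix as CSV
#'
#' Row-per-sample layout with a `sample_id` column followed by one column per
#' band. Full-precision round trip.
#'
#' @param x A [spectra_matrix].
#' @param path File path.
#' @return `write_spectra_matrix_csv()` returns `path` invisibly;
#'   `read_spectra_matrix_csv()` returns a [spectra_matrix].
#' @export
write_spectra_matrix_csv <- function(x, path) {
  wl <- wavelengths(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("sample_id", format(wl, trim = TRUE, scientific = FALSE)),
                   collapse = ","), con)
  for (i in seq_len(nrow(x))) {
    writeLines(paste(c(rownames(x)[i], sprintf("%.17g", x[i, ])),
                     collapse = ","), con)
  }
  invisible(path)
}

#' @rdname write_spectra_matrix_csv
#' @export
read_spectra_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  wl <- as.numeric(names(df)[-1L])
  if (anyNA(wl)) stop("format error: non-numeric wavelength columns", call. = FALSE)
  spectra_matrix(as.matrix(df[, -1L, drop = FALSE]), wl, df[[1L]])
}

#' Read / write a trait table CSV
#'
#' Header `sample_id` followed by any subset of the trait columns
#' CHL (umol/m2), LWC (%), SLA (m2/kg), N, P, K (%) and the optional lab
#' fields FW, DW (g) and LA (m2).
#'
#' @param path File path.
#' @param traits Data frame with a `sample_id` column.
#' @return `read_traits_csv()` returns a data frame; `write_traits_csv()`
#'   returns `path` invisibly.
#' @export
read_traits_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"sample_id" %in% names(df)) {
    stop("format error: traits CSV must have a sample_id column", call. = FALSE)
  }
  df$sample_id <- as.character(df$sample_id)
  validate_trait_table(df)
  df
}

#' @rdname read_traits_csv
#' @export
write_traits_csv <- function(traits, path) {
  utils::write.csv(traits, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# range checks shared by the reader and the generator
validate_trait_table <- function(df) {
  chk <- function(cond, msg) if (!all(cond, na.rm = TRUE)) stop(msg, call. = FALSE)
  if ("LWC" %in% names(df)) chk(df$LWC >= 0 & df$LWC <= 100, "LWC outside [0, 100]")
  if ("SLA" %in% names(df)) chk(df$SLA > 0, "SLA must be > 0")
  for (nm in c("N", "P", "K")) {
    if (nm %in% names(df)) chk(df[[nm]] >= 0, paste(nm, "must be >= 0"))
  }
  if (all(c("FW", "DW") %in% names(df))) chk(df$DW <= df$FW, "DW exceeds FW")
  invisible(df)
}

#' Average replicate scans into a sample-by-band matrix
#'
#' Each plant is scanned several times (by default nine: three leaves times
#' tip/middle/base); the scans are averaged band-wise to give one spectrum
#' per plant. All scans of a plant are treated symmetrically.
#'
#' @param scans List of [leaf_spectrum] on one shared grid.
#' @param group_key Function mapping a `leaf_spectrum` to its grouping id
#'   (default: the `sample_id` field).
#' @param verbose Report group sizes via `message()`.
#' @return A [spectra_matrix] with one row per distinct id, rows ordered by
#'   first appearance in `scans`.
#' @export
average_replicates <- function(scans, group_key = function(s) s$sample_id,
                               verbose = FALSE) {
  if (length(scans) == 0L) stop("no scans to average", call. = FALSE)
  wl <- scans[[1L]]$wavelengths_nm
  for (s in scans) {
    if (!identical(s$wavelengths_nm, wl)) {
      stop("grid error: scan ", s$sample_id, "/", s$replicate_label,
           " has a mismatched wavelength grid", call. = FALSE)
    }
  }
  ids <- vapply(scans, group_key, character(1L))
  uids <- unique(ids)
  vals <- matrix(0, nrow = length(uids), ncol = length(wl))
  sizes <- integer(length(uids))
  for (k in seq_along(uids)) {
    sel <- which(ids == uids[k])
    sizes[k] <- length(sel)
    m <- do.call(rbind, lapply(scans[sel], function(s) s$reflectance))
    vals[k, ] <- colMeans(m)
  }
  if (verbose) {
    message("averaged ", length(scans), " scans into ", length(uids),
            " samples (group sizes: ",
            paste(sprintf("%s=%d", uids, sizes), collapse = ", "), ")")
  }
  spectra_matrix(vals, wl, uids)
}

#' Derive leaf water content and specific leaf area from lab measurements
#'
#' LWC (%) = (FW - DW)/FW x 100; SLA (m2/kg) = LA / DW, with DW converted
#' from grams to kilograms so SLA comes out in m2/kg. Vectorized.
#'
#' @param FW Fresh weight in g, > 0.
#' @param DW Dry weight in g, > 0 and <= FW.
#' @param LA Leaf area in m2, > 0.
#' @return Data frame with columns `LWC` (%) and `SLA` (m2/kg).
#' @export
derive_traits <- function(FW, DW, LA) {
  if (length(FW) != length(DW) || length(FW) != length(LA)) {
    stop("FW, DW, LA must have equal length", call. = FALSE)
  }
  if (any(FW <= 0) || any(DW <= 0) || any(LA <= 0)) {
    stop("domain error: FW, DW and LA must all be positive", call. = FALSE)
  }
  if (any(DW > FW)) stop("domain error: DW exceeds FW", call. = FALSE)
  data.frame(LWC = (FW - DW) / FW * 100, SLA = LA / (DW / 1000))
}
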