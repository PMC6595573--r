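# Shared fixture builders; everything is generated in code at test time.

# small synthetic study for fast end-to-end tests
small_config <- function(n = 8, seed = 101, ...) {
  synthetic_config(n_samples_per_group = n, seed = seed, ...)
}

# deterministic toy spectra matrix on an arbitrary grid
toy_matrix <- function(n = 5, wl = seq(450, 2500, by = 5), seed = 1) {
  vals <- with_test_seed(seed, matrix(runif(n * length(wl), 0.05, 0.6),
                                      nrow = n))
  spectra_matrix(vals, wl, sprintf("s%02d", seq_len(n)))
}

# a few scans on the full raw grid, mildly structured
toy_scans <- function(n_samples = 2, reps = 3, seed = 2) {
  wl <- 350:2500
  with_test_seed(seed, {
    out <- list()
    for (i in seq_len(n_samples)) {
      base <- 0.2 + 0.2 * stats::plogis((wl - 715) / 16) + runif(1, -0.02, 0.02)
      for (r in seq_len(reps)) {
        out[[length(out) + 1L]] <- leaf_spectrum(
          wl, pmax(base + rnorm(length(wl), 0, 0.002), 0.001),
          sprintf("plant%02d", i), sprintf("rep%d", r))
      }
    }
    out
  })
}

with_test_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# write a small wide spectra CSV by hand (header control for format tests)
write_raw_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}
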