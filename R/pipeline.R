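#' Derive a stage seed from the master run seed
#'
#' One master seed deterministically derives the per-stage seeds
#' (simulation, split, CV folds, solver) through a fixed counter scheme, so
#' individual stages can be rerun in isolation and whole runs are
#' bit-reproducible.
#'
#' @param master Integer master seed.
#' @param stage Integer stage counter (1 = simulation, 2 = split,
#'   3 = CV folds, 4 = solver).
#' @return An integer seed below 2^31.
#' @export
derive_seed <- function(master, stage) {
  as.integer((as.numeric(master) + 104729 * as.numeric(stage)) %% 2147483647)
}

#' Configuration of a full calibration run
#'
#' @param synthetic A [synthetic_config] (synthetic mode), or `NULL` to
#'   read data from `spectra_path`/`traits_path`.
#' @param spectra_path,traits_path Wide spectra CSV of raw scans and traits
#'   CSV (ignored in synthetic mode).
#' @param preprocess A [preprocess_config].
#' @param methods Subset of `c("plsr", "svr", "vi", "band_search")`.
#' @param traits Subset of `c("CHL", "LWC", "SLA", "N", "P", "K")`.
#' @param train_fraction Training fraction of the single shared split
#'   (default 0.6).
#' @param k CV folds (default 10).
#' @param max_lv PLSR latent-variable cap (default 25).
#' @param c_grid SVR cost grid (default `c(0.01, 0.1, 1, 10, 100)`).
#' @param epsilon SVR insensitivity width in standardized units.
#' @param seed Master run seed.
#' @param out_dir Output directory (created if needed).
#' @return List of class `run_config`.
#' @export
run_config <- function(synthetic = synthetic_config(),
                       spectra_path = NULL, traits_path = NULL,
                       preprocess = preprocess_config(),
                       methods = c("plsr", "svr", "vi", "band_search"),
                       traits = c("CHL", "LWC", "SLA", "N", "P", "K"),
                       train_fraction = 0.6, k = 10, max_lv = 25,
                       c_grid = c(0.01, 0.1, 1, 10, 100), epsilon = 0.1,
                       seed = 1L, out_dir = tempfile("leafspec_run_")) {
  methods <- match.arg(methods, c("plsr", "svr", "vi", "band_search"),
                       several.ok = TRUE)
  traits <- match.arg(traits, trait_names(), several.ok = TRUE)
  if (length(traits) == 0L) stop("traits must be nonempty", call. = FALSE)
  if (is.null(synthetic)) {
    if (is.null(spectra_path) || !file.exists(spectra_path) ||
        is.null(traits_path) || !file.exists(traits_path)) {
      stop("without synthetic mode, spectra_path and traits_path must exist",
           call. = FALSE)
    }
  }
  structure(list(synthetic = synthetic, spectra_path = spectra_path,
                 traits_path = traits_path, preprocess = preprocess,
                 methods = methods, traits = traits,
                 train_fraction = train_fraction, k = as.integer(k),
                 max_lv = as.integer(max_lv), c_grid = c_grid,
                 epsilon = epsilon, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full spectra-to-trait calibration pipeline
#'
#' Orchestrates simulate (or load) -> replicate averaging -> preprocessing
#' -> one shared train/test split -> per-trait model fitting (PLSR, SVR,
#' built-in VIs, exhaustive band search) -> evaluation. The split is
#' computed once and shared by all methods and traits; every fitted
#' parameter and selected band is derived from the training split only.
#' Writes one JSON evaluation report per (trait, method), a band-search
#' CSV, the resolved configuration and a log into `config$out_dir`.
#' Repeated runs with the same config and seed are bit-identical in all
#' numeric outputs.
#'
#' @param config A [run_config].
#' @return The output directory, invisibly; its `manifest` attribute lists
#'   the per-(trait, method) report files, and `results` holds the parsed
#'   in-memory reports.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "log.txt")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)

  sim_seed <- derive_seed(config$seed, 1)
  split_seed <- derive_seed(config$seed, 2)
  cv_seed <- derive_seed(config$seed, 3)

  if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    syn$seed <- sim_seed
    logf("stage simulate: %d samples/group x %d groups, seed %d",
         syn$n_samples_per_group, length(syn$groups), sim_seed)
    ds <- generate_dataset(syn)
    scans <- ds$scans
    traits_df <- ds$traits
  } else {
    logf("stage load: %s / %s", config$spectra_path, config$traits_path)
    scans <- read_spectra_csv(config$spectra_path)
    traits_df <- read_traits_csv(config$traits_path)
  }

  mat <- average_replicates(scans)
  logf("stage average: %d scans -> %d samples x %d bands",
       length(scans), nrow(mat), ncol(mat))
  proc <- preprocess_spectra(mat, config$preprocess)
  logf("stage preprocess: %d bands retained (%g-%g nm)",
       ncol(proc), min(wavelengths(proc)), max(wavelengths(proc)))

  ids <- rownames(proc)
  traits_df <- traits_df[match(ids, traits_df$sample_id), , drop = FALSE]
  split <- train_test_split(ids, config$train_fraction, split_seed)
  tr_idx <- ids %in% split$train
  logf("stage split: %d train / %d test (seed %d)",
       sum(tr_idx), sum(!tr_idx), split_seed)
  Xtr <- proc[tr_idx, , drop = FALSE]
  Xte <- proc[!tr_idx, , drop = FALSE]
  cv <- cv_spec(config$k, cv_seed)

  manifest <- character(0)
  results <- list()
  for (trait in config$traits) {
    ytr <- traits_df[[trait]][tr_idx]
    yte <- traits_df[[trait]][!tr_idx]
    for (method in config$methods) {
      rep_obj <- switch(
        method,
        plsr = {
          m <- fit_plsr(Xtr, ytr, max_lv = config$max_lv, cv = cv)
          ev <- evaluate_predictions(yte, predict_plsr(m, Xte), trait)
          c(unclass(ev), list(method = "plsr", n_lv = m$selected_n_lv,
                              calibration_r2 = r_squared(ytr, m$fitted),
                              calibration_rmse = rmse(ytr, m$fitted)))
        },
        svr = {
          m <- withCallingHandlers(
            fit_svr(Xtr, ytr, c_grid = config$c_grid,
                    epsilon = config$epsilon, cv = cv),
            warning = function(w) {       # solver cap noted in the log
              logf("stage %s/svr: %s", trait, conditionMessage(w))
              invokeRestart("muffleWarning")
            })
          ev <- evaluate_predictions(yte, predict_svr(m, Xte), trait)
          c(unclass(ev), list(method = "svr", C = m$C,
                              calibration_r2 = r_squared(ytr, m$fitted),
                              calibration_rmse = rmse(ytr, m$fitted)))
        },
        vi = {
          per_vi <- lapply(builtin_vis(), function(d) {
            vtr <- compute_vi(Xtr, d)
            vte <- compute_vi(Xte, d)
            m <- fit_vi_model(vtr, ytr, d)
            ev <- evaluate_predictions(yte, predict_vi_model(m, vte), trait)
            c(unclass(ev), list(index = d$name, band1_nm = d$band1_nm,
                                band2_nm = d$band2_nm))
          })
          best <- which.max(vapply(per_vi, `[[`, numeric(1L), "r2"))
          list(trait = trait, method = "vi", indices = per_vi,
               best_index = per_vi[[best]]$index,
               best_test_r2 = per_vi[[best]]$r2)
        },
        band_search = {
          bs <- exhaustive_band_search(Xtr, ytr)
          vtr <- compute_vi(Xtr, bs$best_definition)
          vte <- compute_vi(Xte, bs$best_definition)
          m <- fit_vi_model(vtr, ytr, bs$best_definition)
          ev <- evaluate_predictions(yte, predict_vi_model(m, vte), trait)
          c(unclass(ev),
            list(method = "band_search",
                 band1_nm = bs$best_definition$band1_nm,
                 band2_nm = bs$best_definition$band2_nm,
                 train_correlation = bs$train_correlation,
                 n_pairs_evaluated = bs$n_pairs_evaluated))
        })
      fname <- sprintf("eval_%s_%s.json", trait, method)
      jsonlite::write_json(rep_obj, file.path(config$out_dir, fname),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      manifest <- c(manifest, fname)
      results[[paste(trait, method, sep = ".")]] <- rep_obj
      logf("stage %s/%s: written %s", trait, method, fname)
    }
  }

  if ("band_search" %in% config$methods) {
    bs_rows <- do.call(rbind, lapply(config$traits, function(trait) {
      r <- results[[paste(trait, "band_search", sep = ".")]]
      data.frame(trait = trait, band1_nm = r$band1_nm, band2_nm = r$band2_nm,
                 train_r = r$train_correlation, test_r2 = r$r2, rpd = r$rpd)
    }))
    utils::write.csv(bs_rows, file.path(config$out_dir, "band_search.csv"),
                     row.names = FALSE)
  }

  resolved <- config
  resolved$out_dir <- NULL
  jsonlite::write_json(resolved_config_list(resolved),
                       file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  out <- config$out_dir
  attr(out, "manifest") <- manifest
  attr(out, "results") <- results
  invisible(out)
}

# flatten the config into JSON-friendly scalars/arrays
resolved_config_list <- function(config) {
  syn <- config$synthetic
  list(
    seed = config$seed, train_fraction = config$train_fraction,
    k = config$k, max_lv = config$max_lv, c_grid = config$c_grid,
    epsilon = config$epsilon, methods = config$methods,
    traits = config$traits,
    preprocess = unclass(config$preprocess),
    synthetic = if (!is.null(syn)) {
      list(n_samples_per_group = syn$n_samples_per_group,
           groups = syn$groups, seed = syn$seed,
           replicates_per_sample = syn$replicates_per_sample,
           noise_sd_main = syn$noise_sd_main,
           noise_sd_vis_edge = syn$noise_sd_vis_edge)
    })
}
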