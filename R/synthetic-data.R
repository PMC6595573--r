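#' Configuration for the synthetic leaf-spectrum generator
#'
#' The generator emulates the structure a leaf spectroscopy calibration
#' study relies on: 350-2500 nm reflectance at 1 nm with low VIS reflectance
#' from photosynthetic pigments, a logistic red edge near 700-750 nm, an NIR
#' plateau, water-absorption minima at 970/1240/1450/1900 nm, dry-matter
#' features in the 2000-2400 nm region, elevated instrument noise below
#' 450 nm; six correlated traits (CHL-N positive, CHL-SLA negative, LWC-SLA
#' positive, LWC-K positive, N-P positive); three environment groups with
#' group shifts in CHL and N (greenhouse highest, N-deprived field lowest);
#' and nine replicate scans per plant.
#'
#' Absorption features are shifted-truncated Gaussian dips in reflectance
#' space; each dip's depth saturates in its driving trait
#' (`depth = strength * s / (0.25 + 0.75 s)` with `s = value / reference`),
#' a Beer-Lambert-like saturation that makes two-band indices mildly
#' nonlinear in the trait. Per-sample structural nuisance (baseline, plateau
#' and red-edge-position jitter) mimics genotype-to-genotype leaf structure
#' variation that whole-spectrum models can correct for but two-band indices
#' cannot.
#'
#' @param n_samples_per_group Plants per environment group (>= 1).
#' @param groups Group labels.
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the config including this seed.
#' @param trait_means Matrix (group x trait) of group mean trait values.
#' @param trait_sds Named vector of within-group trait standard deviations.
#' @param trait_correlation 6x6 within-group trait correlation matrix
#'   (symmetric, unit diagonal, positive semi-definite).
#' @param absorption_features Data frame with columns `center_nm`,
#'   `width_nm`, `trait`, `strength` (dip depth at the trait's reference
#'   value, in reflectance units).
#' @param trait_refs Named vector of reference trait values used to scale
#'   dip depths.
#' @param continuum List of continuum parameters: `vis_base`, `nir_plateau`,
#'   `red_edge_nm`, `red_edge_width_nm`, `swir_decline`, `sla_plateau_coef`,
#'   `chl_red_edge_shift_nm`.
#' @param nuisance_sds List of per-sample structural jitter sds:
#'   `vis_base`, `nir_plateau`, `red_edge_nm`, and the per-scan
#'   multiplicative `scan_gain`.
#' @param noise_sd_vis_edge Per-band noise sd (reflectance units) for bands
#'   below 450 nm.
#' @param noise_sd_main Per-band noise sd elsewhere.
#' @param replicates_per_sample Scans per plant (default 9 = 3 leaves x 3
#'   positions).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples_per_group = 150,
                             groups = c("FieldMinusN", "FieldPlusN", "Greenhouse"),
                             seed = 1L,
                             trait_means = default_trait_means(groups),
                             trait_sds = c(CHL = 90, LWC = 3, SLA = 2.8,
                                           N = 0.4, P = 0.06, K = 0.35),
                             trait_correlation = default_trait_correlation(),
                             absorption_features = default_absorption_features(),
                             trait_refs = c(CHL = 450, LWC = 80, SLA = 19.5,
                                            N = 2.9, P = 0.33, K = 2.1),
                             continuum = list(vis_base = 0.20,
                                              nir_plateau = 0.48,
                                              red_edge_nm = 715,
                                              red_edge_width_nm = 16,
                                              swir_decline = 0.10,
                                              sla_plateau_coef = 0.08,
                                              chl_red_edge_shift_nm = 5),
                             nuisance_sds = list(vis_base = 0.006,
                                                 nir_plateau = 0.012,
                                                 red_edge_nm = 1.0,
                                                 scan_gain = 0.012),
                             noise_sd_vis_edge = 0.012,
                             noise_sd_main = 0.0025,
                             replicates_per_sample = 9L) {
  traits <- trait_names()
  stopifnot(n_samples_per_group >= 1, replicates_per_sample >= 1,
            noise_sd_vis_edge >= 0, noise_sd_main >= 0)
  trait_means <- as.matrix(trait_means)
  stopifnot(identical(colnames(trait_means), traits),
            nrow(trait_means) == length(groups))
  rownames(trait_means) <- groups
  stopifnot(identical(names(trait_sds), traits), all(trait_sds >= 0))
  R <- as.matrix(trait_correlation)
  if (!isTRUE(all.equal(R, t(R))) || any(abs(diag(R) - 1) > 1e-12)) {
    stop("config error: trait_correlation must be symmetric with unit diagonal",
         call. = FALSE)
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("config error: trait_correlation is not positive semi-definite",
         call. = FALSE)
  }
  stopifnot(all(absorption_features$width_nm > 0),
            all(absorption_features$trait %in% traits))
  structure(
    list(n_samples_per_group = as.integer(n_samples_per_group),
         groups = groups, seed = as.integer(seed),
         trait_means = trait_means, trait_sds = trait_sds,
         trait_correlation = R,
         absorption_features = absorption_features,
         trait_refs = trait_refs, continuum = continuum,
         nuisance_sds = nuisance_sds,
         noise_sd_vis_edge = noise_sd_vis_edge,
         noise_sd_main = noise_sd_main,
         replicates_per_sample = as.integer(replicates_per_sample)),
    class = "synthetic_config"
  )
}

trait_names <- function() c("CHL", "LWC", "SLA", "N", "P", "K")

#' @rdname synthetic_config
#' @export
default_trait_means <- function(groups = c("FieldMinusN", "FieldPlusN",
                                           "Greenhouse")) {
  m <- rbind(FieldMinusN = c(350, 78, 21.0, 2.2, 0.28, 1.90),
             FieldPlusN  = c(450, 80, 19.5, 2.9, 0.33, 2.10),
             Greenhouse  = c(550, 82, 18.0, 3.4, 0.36, 2.25))
  colnames(m) <- trait_names()
  m[groups, , drop = FALSE]
}

#' @rdname synthetic_config
#' @export
default_trait_correlation <- function() {
  tr <- trait_names()
  R <- diag(6)
  dimnames(R) <- list(tr, tr)
  set_r <- function(a, b, v) {
    R[a, b] <<- v
    R[b, a] <<- v
  }
  set_r("CHL", "N", 0.70)
  set_r("CHL", "SLA", -0.40)
  set_r("LWC", "SLA", 0.40)
  set_r("LWC", "K", 0.50)
  set_r("N", "P", 0.60)
  R
}

#' @rdname synthetic_config
#' @export
default_absorption_features <- function() {
  data.frame(
    center_nm = c(430, 550, 660, 970, 1240, 1450, 1900, 2100, 2300, 2350, 2170),
    width_nm  = c( 45,  70,  45,  45,   55,   80,   95,   60,   70,   50,   45),
    trait     = c("CHL", "CHL", "CHL", "LWC", "LWC", "LWC", "LWC",
                  "N", "N", "P", "K"),
    strength  = c(0.10, 0.05, 0.13, 0.04, 0.07, 0.26, 0.32,
                  0.025, 0.018, 0.002, 0.006),
    # per-sample relative sd of the dip depth (absorption path-length
    # variability unrelated to the driving trait)
    depth_jitter_sd = c(0.01, 0.01, 0.01, 0.02, 0.02, 0.02, 0.02,
                        0.06, 0.06, 0.08, 0.03),
    stringsAsFactors = FALSE
  )
}

#' Draw correlated trait tables for the configured environment groups
#'
#' Per group, traits are drawn from a multivariate Gaussian with the
#' configured group mean vector, per-trait sds and shared correlation
#' matrix (sampled through the Cholesky factor of the covariance), then
#' clipped to physical ranges: LWC to \[0, 100\], all other traits to >= 0.
#' Deterministic given `config$seed`.
#'
#' @param config A [synthetic_config].
#' @return Data frame: `sample_id`, `group`, and the six trait columns.
#' @export
generate_traits <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, generate_traits_impl(config))
}

generate_traits_impl <- function(config) {
  tr <- trait_names()
  S <- diag(config$trait_sds) %*% config$trait_correlation %*% diag(config$trait_sds)
  # chol() needs PD; add a whisker of ridge for exactly-singular configs
  L <- if (max(diag(S)) == 0) matrix(0, 6, 6) else
    chol(S + diag(1e-12 * max(diag(S)), 6))
  out <- vector("list", length(config$groups))
  for (g in seq_along(config$groups)) {
    n <- config$n_samples_per_group
    Z <- matrix(stats::rnorm(n * 6), n, 6)
    X <- Z %*% L
    X <- sweep(X, 2, config$trait_means[g, ], `+`)
    colnames(X) <- tr
    X[, "LWC"] <- pmin(pmax(X[, "LWC"], 0), 100)
    for (nm in setdiff(tr, "LWC")) X[, nm] <- pmax(X[, nm], 0)
    out[[g]] <- data.frame(
      sample_id = sprintf("%s_%03d", config$groups[g], seq_len(n)),
      group = config$groups[g], X, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  validate_trait_table(df)
  df
}

# dip depth saturates mildly in the scaled trait value; equals strength at
# s = 1 (Beer-Lambert-like: equal trait increments buy less extra depth)
dip_depth <- function(strength, s) strength * s / (0.5 + 0.5 * s)

# Gaussian dip truncated at 3 sigma and shifted to zero at the cutoff, so
# absorption features have compact support and the NIR plateau is untouched
# by VIS pigment features.
dip_profile <- function(wl, center, width) {
  z <- (wl - center) / width
  cutoff <- exp(-4.5)
  pmax(0, exp(-0.5 * z^2) - cutoff) / (1 - cutoff)
}

#' Deterministic reflectance curve for one trait vector
#'
#' Builds the noiseless 350-2500 nm reflectance for one plant: a smooth
#' continuum (low VIS shoulder, logistic red edge, NIR plateau, gentle SWIR
#' decline) minus trait-scaled absorption dips (pigments at 430/660 nm from
#' CHL; water at 970/1240/1450/1900 nm from LWC; dry matter in 2000-2400 nm
#' from N and weakly P and K), clamped to \[0.001, 1\]. With `nuisance` at
#' its default and `noise = FALSE` this is a pure function of the traits.
#'
#' @param trait_row One-row data frame (or named list) with the six traits.
#' @param config A [synthetic_config].
#' @param nuisance Per-sample structural perturbation, as drawn internally
#'   by [generate_dataset()]: list with `vis_base`, `nir_plateau` and
#'   `red_edge_nm` offsets and a `feature_gain` multiplier per absorption
#'   feature (path-length variability). Default: no perturbation.
#' @param noise Add per-band instrument noise (elevated below 450 nm)?
#' @param gain Multiplicative scan gain (within-leaf variability).
#' @param sample_id,replicate_label Passed to the returned [leaf_spectrum].
#' @return A [leaf_spectrum] on the 1-nm grid 350..2500 (2151 values).
#' @export
traits_to_spectrum <- function(trait_row, config,
                               nuisance = list(vis_base = 0, nir_plateau = 0,
                                               red_edge_nm = 0,
                                               feature_gain = NULL),
                               noise = FALSE, gain = 1,
                               sample_id = "synthetic",
                               replicate_label = "") {
  stopifnot(inherits(config, "synthetic_config"))
  wl <- 350:2500
  cn <- config$continuum
  s_sla <- trait_row[["SLA"]] / config$trait_refs[["SLA"]]
  s_chl <- trait_row[["CHL"]] / config$trait_refs[["CHL"]]
  vis_base <- cn$vis_base + nuisance$vis_base
  nir <- cn$nir_plateau - cn$sla_plateau_coef * (s_sla - 1) + nuisance$nir_plateau
  edge <- cn$red_edge_nm + cn$chl_red_edge_shift_nm * (s_chl - 1) +
    nuisance$red_edge_nm
  refl <- vis_base + (nir - vis_base) * stats::plogis((wl - edge) / cn$red_edge_width_nm) -
    cn$swir_decline * pmax(0, wl - 1300) / 1200
  fg <- nuisance$feature_gain
  if (is.null(fg)) fg <- rep(1, nrow(config$absorption_features))
  for (i in seq_len(nrow(config$absorption_features))) {
    f <- config$absorption_features[i, ]
    s <- trait_row[[f$trait]] / config$trait_refs[[f$trait]]
    refl <- refl - fg[i] * dip_depth(f$strength, s) *
      dip_profile(wl, f$center_nm, f$width_nm)
  }
  refl <- refl * gain
  if (noise) {
    sd_band <- ifelse(wl < 450, config$noise_sd_vis_edge, config$noise_sd_main)
    refl <- refl + stats::rnorm(length(wl), 0, sd_band)
  }
  refl <- pmin(pmax(refl, 0.001), 1)
  leaf_spectrum(wl, refl, sample_id, replicate_label)
}

#' Generate a full synthetic dataset: replicate scans plus trait table
#'
#' Draws the trait table, a per-sample structural nuisance (leaf structure
#' jitter shared by all scans of a plant), and then
#' `replicates_per_sample` scans per plant that differ only by a small
#' multiplicative gain and band noise. Fully reproducible from
#' `config$seed`.
#'
#' @param config A [synthetic_config].
#' @return List with `scans` (list of [leaf_spectrum]) and `traits`
#'   (data frame as from [generate_traits()]).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    traits <- generate_traits_impl(config)
    n <- nrow(traits)
    rep_labels <- replicate_labels(config$replicates_per_sample)
    scans <- vector("list", n * config$replicates_per_sample)
    k <- 0L
    for (i in seq_len(n)) {
      nu <- list(
        vis_base = stats::rnorm(1, 0, config$nuisance_sds$vis_base),
        nir_plateau = stats::rnorm(1, 0, config$nuisance_sds$nir_plateau),
        red_edge_nm = stats::rnorm(1, 0, config$nuisance_sds$red_edge_nm),
        feature_gain = 1 + stats::rnorm(
          nrow(config$absorption_features), 0,
          config$absorption_features$depth_jitter_sd))
      for (r in seq_len(config$replicates_per_sample)) {
        g <- stats::rnorm(1, 1, config$nuisance_sds$scan_gain)
        k <- k + 1L
        scans[[k]] <- traits_to_spectrum(
          traits[i, ], config, nuisance = nu, noise = TRUE, gain = g,
          sample_id = traits$sample_id[i], replicate_label = rep_labels[r])
      }
    }
    list(scans = scans, traits = traits)
  })
}

# leaf 2..4 (leaf 1 is the flag leaf) x tip/middle/base, recycled as needed
replicate_labels <- function(k) {
  lab <- as.vector(outer(c("tip", "middle", "base"), 2:4,
                         function(p, l) paste0("leaf", l, "_", p)))
  rep_len(lab, k)
}

# evaluate expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
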