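test_that("degenerate config collapses every sample to its group mean", {
  cfg <- small_config(n = 4, trait_sds = c(CHL = 0, LWC = 0, SLA = 0,
                                           N = 0, P = 0, K = 0))
  td <- generate_traits(cfg)
  for (g in cfg$groups) {
    rows <- td[td$group == g, c("CHL", "LWC", "SLA", "N", "P", "K")]
    expect_equal(unname(as.matrix(rows)),
                 matrix(cfg$trait_means[g, ], 4, 6, byrow = TRUE),
                 tolerance = 1e-9)
  }
})

test_that("within-group sample correlations track the configured matrix", {
  cfg <- synthetic_config(n_samples_per_group = 500, seed = 5)
  td <- generate_traits(cfg)
  one <- td[td$group == "FieldPlusN", c("CHL", "LWC", "SLA", "N", "P", "K")]
  cc <- stats::cor(one)
  R <- cfg$trait_correlation
  for (pair in list(c("CHL", "N"), c("CHL", "SLA"), c("LWC", "SLA"),
                    c("LWC", "K"), c("N", "P"))) {
    expect_equal(cc[pair[1], pair[2]], R[pair[1], pair[2]], tolerance = 0.1,
                 label = paste("cor", pair[1], pair[2]))
    expect_equal(sign(cc[pair[1], pair[2]]), sign(R[pair[1], pair[2]]))
  }
})

test_that("trait generation is seed-reproducible and validates its config", {
  cfg <- small_config(seed = 77)
  expect_identical(generate_traits(cfg), generate_traits(cfg))
  R <- default_trait_correlation()
  R["CHL", "SLA"] <- R["SLA", "CHL"] <- -0.99  # breaks PSD with the others
  expect_error(synthetic_config(trait_correlation = R), "positive semi-definite")
})

test_that("pigment and water features move reflectance the right way", {
  cfg <- small_config()
  base <- data.frame(CHL = 450, LWC = 80, SLA = 19.5, N = 2.9, P = 0.33, K = 2.1)
  hi <- lo <- base
  hi$CHL <- 560; lo$CHL <- 350
  s_hi <- traits_to_spectrum(hi, cfg)
  s_lo <- traits_to_spectrum(lo, cfg)
  wl <- s_hi$wavelengths_nm
  vis <- wl >= 450 & wl <= 700
  plateau <- wl >= 950 & wl <= 1050
  expect_lt(mean(s_hi$reflectance[vis]), mean(s_lo$reflectance[vis]))
  expect_lt(max(abs(s_hi$reflectance[plateau] - s_lo$reflectance[plateau])),
            1e-6)

  hi <- lo <- base
  hi$LWC <- 90; lo$LWC <- 70
  w_hi <- traits_to_spectrum(hi, cfg)
  w_lo <- traits_to_spectrum(lo, cfg)
  for (band in c(1450, 1900)) {
    j <- which(wl == band)
    expect_lt(w_hi$reflectance[j], w_lo$reflectance[j])
  }
})

test_that("noiseless spectra have water-absorption minima near 1450 and 1900 nm", {
  cfg <- small_config()
  s <- traits_to_spectrum(
    data.frame(CHL = 450, LWC = 80, SLA = 19.5, N = 2.9, P = 0.33, K = 2.1), cfg)
  wl <- s$wavelengths_nm
  for (ctr in c(1450, 1900)) {
    win <- which(abs(wl - ctr) <= 100)
    argmin <- wl[win][which.min(s$reflectance[win])]
    expect_lte(abs(argmin - ctr), 10)
  }
})

test_that("dataset generation has the right shape, support and determinism", {
  cfg <- small_config(n = 2, seed = 303)
  ds <- generate_dataset(cfg)
  expect_length(ds$scans, 2 * 3 * 9)
  expect_equal(nrow(ds$traits), 6L)
  for (s in ds$scans[c(1, 27, 54)]) {
    expect_length(s$reflectance, 2151L)
    expect_true(all(s$reflectance >= 0.001 & s$reflectance <= 1))
  }
  ds2 <- generate_dataset(cfg)
  expect_identical(ds$scans[[10]]$reflectance, ds2$scans[[10]]$reflectance)
  # a different seed redraws essentially every band
  ds3 <- generate_dataset(small_config(n = 2, seed = 304))
  frac_diff <- mean(ds$scans[[1]]$reflectance != ds3$scans[[1]]$reflectance)
  expect_gt(frac_diff, 0.99)
})

test_that("noise-free generation is a pure function of the traits", {
  cfg <- small_config()
  row <- data.frame(CHL = 500, LWC = 83, SLA = 18, N = 3.1, P = 0.35, K = 2.2)
  expect_identical(traits_to_spectrum(row, cfg)$reflectance,
                   traits_to_spectrum(row, cfg)$reflectance)
})

test_that("band 660 reflectance declines with chlorophyll across plants", {
  cfg <- small_config(n = 20, seed = 11)
  ds <- generate_dataset(cfg)
  mat <- average_replicates(ds$scans)
  r660 <- mat[, which(wavelengths(mat) == 660)]
  chl <- ds$traits$CHL[match(rownames(mat), ds$traits$sample_id)]
  expect_lt(unname(stats::coef(stats::lm(r660 ~ chl))[2]), 0)
})
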