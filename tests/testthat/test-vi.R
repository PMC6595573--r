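test_that("built-in index definitions use the canonical band pairs", {
  v <- builtin_vis()
  expect_setequal(c(v$GNDVI$band1_nm, v$GNDVI$band2_nm), c(550, 800))
  expect_setequal(c(v$RENDVI$band1_nm, v$RENDVI$band2_nm), c(705, 750))
  expect_setequal(c(v$NDWI$band1_nm, v$NDWI$band2_nm), c(860, 1240))
})

test_that("normalized-difference values follow the two-band formula", {
  wl <- c(550, 800, 860, 1240)
  m <- spectra_matrix(rbind(c(0.05, 0.45, 0.40, 0.40),
                            c(0.20, 0.60, 0.30, 0.30),
                            c(0.25, 0.25, 0.25, 0.25)),
                      wl, c("a", "b", "c"))
  gndvi <- compute_vi(m, builtin_vis()$GNDVI)
  expect_equal(gndvi[1], 0.8)                       # (0.45-0.05)/(0.45+0.05)
  expect_equal(gndvi[2], 0.5)                       # (0.6-0.2)/(0.6+0.2)
  expect_equal(compute_vi(m, builtin_vis()$NDWI)[1], 0)  # equal bands
  expect_equal(compute_vi(m, vi_definition("any", 800, 550))[3], 0)  # flat

  expect_error(compute_vi(toy_matrix(wl = seq(450, 2500, 5)),
                          vi_definition("x", 552, 700)),
               "552.*550 and 555")
  expect_error(vi_definition("bad", 700, 700), "must differ")
})

test_that("index values are antisymmetric under band swap", {
  m <- toy_matrix(n = 20, wl = seq(500, 900, 50), seed = 8)
  a <- compute_vi(m, vi_definition("ab", 600, 800))
  b <- compute_vi(m, vi_definition("ba", 800, 600))
  expect_equal(a, -b, tolerance = 1e-12)
})

test_that("VI regression recovers exact and random relationships", {
  v <- with_test_seed(3, runif(50, -0.2, 0.9))
  m_lin <- fit_vi_model(v, 2 + 3 * v)
  expect_equal(m_lin$intercept, 2, tolerance = 1e-8)
  expect_equal(m_lin$linear_coef, 3, tolerance = 1e-8)
  expect_equal(m_lin$quadratic_coef, 0, tolerance = 1e-8)
  expect_equal(predict_vi_model(m_lin, v), 2 + 3 * v, tolerance = 1e-8)

  m_quad <- fit_vi_model(v, v^2)
  expect_equal(m_quad$quadratic_coef, 1, tolerance = 1e-10)

  y <- with_test_seed(5, rnorm(50))
  m_rand <- fit_vi_model(v, y)
  X <- cbind(1, v, v^2)                      # normal-equations oracle
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(c(m_rand$intercept, m_rand$linear_coef, m_rand$quadratic_coef),
               drop(beta), tolerance = 1e-8, ignore_attr = TRUE)

  expect_error(fit_vi_model(c(0.1, 0.2), c(1, 2)), "at least 3")
  expect_error(fit_vi_model(rep(0.5, 10), rnorm(10)), "constant index")
  expect_error(fit_vi_model(runif(10), rep(1, 10)), "zero-variance trait")
})

test_that("band search finds a perfectly correlated constructed pair", {
  wl <- c(500, 600, 700)
  m <- toy_matrix(n = 30, wl = wl, seed = 12)
  trait <- drop((m[, 3] - m[, 1]) / (m[, 3] + m[, 1]))  # ND of bands 1 and 3
  res <- exhaustive_band_search(m, trait)
  expect_equal(sort(c(res$best_definition$band1_nm,
                      res$best_definition$band2_nm)), c(500, 700))
  expect_equal(abs(res$train_correlation), 1, tolerance = 1e-10)
  expect_equal(res$n_pairs_evaluated, 3L)
})

test_that("band search matches a naive double-loop oracle", {
  m <- toy_matrix(n = 30, wl = seq(500, 950, 50), seed = 21)  # 10 bands
  y <- with_test_seed(22, rnorm(30))
  res <- exhaustive_band_search(m, y, keep_matrix = TRUE)

  wl <- wavelengths(m)
  best <- list(r = 0)
  n_eval <- 0L
  for (i in seq_along(wl)) {
    for (j in seq_along(wl)) {
      if (j <= i) next
      nd <- drop((m[, j] - m[, i]) / (m[, j] + m[, i]))
      r <- stats::cor(nd, y)
      n_eval <- n_eval + 1L
      if (abs(r) > abs(best$r)) best <- list(short = wl[i], long = wl[j], r = r)
    }
  }
  expect_equal(res$best_definition$band1_nm, best$long)
  expect_equal(res$best_definition$band2_nm, best$short)
  expect_equal(res$train_correlation, best$r, tolerance = 1e-12)
  expect_equal(res$n_pairs_evaluated, n_eval)   # p(p-1)/2 evaluations
  expect_equal(res$abs_r_matrix[as.character(best$short),
                                as.character(best$long)],
               abs(best$r), tolerance = 1e-12)

  expect_error(exhaustive_band_search(m, rep(1, 30)), "zero-variance")
  expect_error(exhaustive_band_search(m[, 1, drop = FALSE], y), "2 bands")
})
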