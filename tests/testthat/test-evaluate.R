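test_that("train/test split is a seeded disjoint exhaustive partition", {
  ids <- sprintf("s%03d", 1:100)
  sp <- train_test_split(ids, 0.6, 7)
  expect_length(sp$train, 60L)
  expect_length(sp$test, 40L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_setequal(c(sp$train, sp$test), ids)
  expect_identical(train_test_split(ids, 0.6, 7), sp)

  sp5 <- train_test_split(letters[1:5], 0.6, 1)
  expect_length(sp5$train, 3L)
  expect_length(sp5$test, 2L)
  expect_error(train_test_split("a", 0.6, 1), "at least 2")
})

test_that("error metrics match hand-computed values", {
  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(3, 4), c(0, 0)), sqrt(12.5))
  expect_equal(rmse(2, 5), 3)
  expect_error(rmse(1:3, 1:2), "length mismatch")
  expect_error(rmse(numeric(0), numeric(0)), "empty")

  expect_equal(mape(c(1, 3), c(1, 3)), 0)
  expect_equal(mape(c(1, 3), c(2, 2)), 50)   # mean |err| = 1, mean y = 2
  expect_equal(mape(10, 11), 10)
  expect_error(mape(c(-1, 1), c(0, 0)), "mean of measured")
  # invariant under joint positive rescaling
  y <- c(2, 4, 9); p <- c(1, 5, 8)
  expect_equal(mape(10 * y, 10 * p), mape(y, p))
})

test_that("RPD is the measured SD over the RMSE", {
  expect_equal(rpd(c(1, 2, 3), c(1.5, 2.5, 3.5)), 1 / 0.5)  # sd 1, rmse 0.5
  expect_true(is.infinite(rpd(c(1, 2, 3), c(1, 2, 3))))
  expect_error(rpd(c(2, 2, 2), c(1, 2, 3)), "SD = 0")
  # two-path identity on random vectors
  with_test_seed(10, {
    for (i in 1:1000) {
      y <- rnorm(20)
      p <- y + rnorm(20)
      expect_equal(rpd(y, p) * rmse(y, p), sd(y), tolerance = 1e-10)
    }
  })
})

test_that("RPD grading uses the four published tiers with downward ties", {
  expect_equal(as.character(classify_rpd(4.12)), "Excellent")
  expect_equal(as.character(classify_rpd(2.63)), "VeryGood")
  expect_equal(as.character(classify_rpd(1.33)), "Fair")
  expect_equal(as.character(classify_rpd(c(3.5, 2.5, 1.5))),
               c("VeryGood", "Good", "Fair"))
  # monotone in the ordered factor
  grades <- classify_rpd(seq(0.5, 5, by = 0.1))
  expect_true(all(diff(as.integer(grades)) >= 0))
  expect_error(classify_rpd(-1), "positive")
})

test_that("R-squared definitions behave as documented", {
  y <- with_test_seed(14, rnorm(50))
  p <- with_test_seed(15, y + rnorm(50, 0, 0.5))
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, 3 + 2 * y), 1)          # affine invariance
  expect_equal(r_squared(y, p), cor(y, p)^2, tolerance = 1e-12)
  expect_equal(r_squared_ss(y, p),
               1 - sum((y - p)^2) / sum((y - mean(y))^2), tolerance = 1e-12)
  expect_lte(r_squared_ss(y, p), r_squared(y, p) + 1e-12)
  expect_error(r_squared(rep(1, 5), rnorm(5)), "variance")
})

test_that("evaluation reports are internally consistent", {
  y <- with_test_seed(16, rnorm(40, 10, 2))
  p <- y + rnorm(40, 0, 0.8)
  rep <- evaluate_predictions(y, p, "CHL")
  expect_equal(rep$n_test, 40L)
  expect_equal(rep$rpd * rep$rmse, sd(y), tolerance = 1e-10)
  expect_equal(rep$category, as.character(classify_rpd(rep$rpd)))
  expect_false(rep$rpd_infinite)
})

test_that("PCA scores and variance fractions match an eigen oracle", {
  X1 <- outer(1:10, c(1, 2, 3))                    # rank one
  expect_equal(pca_scores(X1, 1)$explained_variance, 1, tolerance = 1e-12)

  X <- with_test_seed(18, matrix(rnorm(30 * 6), 30, 6))
  out <- pca_scores(X, 4)
  expect_true(all(diff(out$explained_variance) <= 1e-12))
  expect_true(all(out$explained_variance >= 0 &
                    out$explained_variance <= 1))
  ev <- eigen(stats::cov(X), symmetric = TRUE)
  expect_equal(out$explained_variance, ev$values[1:4] / sum(ev$values),
               tolerance = 1e-10)
  Xc <- scale(X, scale = FALSE)
  for (j in 1:4) {
    oracle <- drop(Xc %*% ev$vectors[, j])
    expect_equal(abs(cor(out$scores[, j], oracle)), 1, tolerance = 1e-10)
  }
  expect_error(pca_scores(X, 10), "exceeds")
})
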