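test_that("one latent variable solves a rank-1 problem exactly", {
  x <- with_test_seed(1, matrix(rnorm(40), 40, 1, dimnames = list(NULL, "b1")))
  y <- drop(2 * x)
  m <- fit_plsr(x, y, max_lv = 1, cv = cv_spec(5, 3))
  expect_equal(m$selected_n_lv, 1L)
  expect_equal(m$fitted, y, tolerance = 1e-10)
  expect_equal(predict_plsr(m, x), y, tolerance = 1e-10)
})

test_that("full-rank PLSR reproduces ordinary least squares", {
  set.seed(42)
  X <- matrix(rnorm(60 * 5), 60, 5, dimnames = list(NULL, paste0("b", 1:5)))
  y <- drop(X %*% c(1, -2, 0.5, 3, -1)) + 4          # noiseless linear
  m <- fit_plsr(X, y, max_lv = 5, cv = cv_spec(10, 1))
  ols <- stats::lm(y ~ X)
  expect_equal(predict_plsr(m, X, n_lv = 5), unname(stats::fitted(ols)),
               tolerance = 1e-8)
  # also with a noisy response, where PLSR at full rank must equal OLS
  yn <- y + rnorm(60)
  mn <- fit_plsr(X, yn, max_lv = 5, cv = cv_spec(10, 1))
  olsn <- stats::lm(yn ~ X)
  expect_equal(predict_plsr(mn, X, n_lv = 5), unname(stats::fitted(olsn)),
               tolerance = 1e-8)
})

test_that("NIPALS factors are orthogonal with unit-norm weights", {
  set.seed(7)
  X <- scale(matrix(rnorm(50 * 20), 50, 20))
  y <- drop(scale(rnorm(50)))
  f <- nipals_pls(X, y, 8)
  G <- crossprod(f$scores)
  expect_equal(G - diag(diag(G)), matrix(0, f$ncomp, f$ncomp),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(unname(sqrt(colSums(f$weights^2))), rep(1, f$ncomp),
               tolerance = 1e-10)
})

test_that("training fit improves monotonically with more latent variables", {
  set.seed(9)
  X <- matrix(rnorm(40 * 10), 40, 10, dimnames = list(NULL, paste0("b", 1:10)))
  y <- rnorm(40)
  m <- fit_plsr(X, y, max_lv = 8, cv = cv_spec(5, 2))
  r2 <- vapply(seq_len(ncol(m$coef_by_lv)), function(a) {
    r_squared_ss(y, predict_plsr(m, X, n_lv = a))
  }, numeric(1))
  expect_true(all(diff(r2) > -1e-10))
})

test_that("PLSR recovers a known low-rank factor structure", {
  set.seed(31)
  n <- 120
  fac <- matrix(rnorm(n * 3), n, 3)
  load <- matrix(runif(3 * 40, -1, 1), 3, 40)
  X <- fac %*% load + matrix(rnorm(n * 40, 0, 0.05), n, 40)
  colnames(X) <- paste0("b", 1:40)
  y <- drop(fac %*% c(2, -1, 1)) + rnorm(n, 0, 0.2)
  hold <- seq_len(40)
  m <- fit_plsr(X[-hold, ], y[-hold], max_lv = 15, cv = cv_spec(10, 4))
  expect_gte(m$selected_n_lv, 2)
  expect_lte(m$selected_n_lv, 6)
  r2 <- r_squared(y[hold], predict_plsr(m, X[hold, ]))
  # 3-LV oracle on the same split
  oracle <- r_squared(y[hold], predict_plsr(m, X[hold, ], n_lv = 3))
  expect_gte(r2, oracle - 0.05)
})

test_that("prediction respects centering, batching and the grid contract", {
  set.seed(13)
  X <- matrix(rnorm(30 * 6), 30, 6, dimnames = list(NULL, paste0("b", 1:6)))
  y <- rnorm(30)
  m <- fit_plsr(X, y, max_lv = 4, cv = cv_spec(5, 5))
  # a sample at the training x-mean predicts the training y-mean
  expect_equal(unname(predict_plsr(m, colMeans(X))), mean(y), tolerance = 1e-10)
  # batch prediction equals looped per-sample prediction
  batch <- predict_plsr(m, X)
  looped <- vapply(seq_len(nrow(X)), function(i) predict_plsr(m, X[i, ]),
                   numeric(1))
  expect_equal(unname(batch), unname(looped), tolerance = 1e-12)
  expect_error(predict_plsr(m, X[, 1:3]), "grid mismatch|column mismatch")
  expect_error(fit_plsr(X, rep(1, 30), 4, cv_spec(5, 5)), "zero-variance")
  expect_warning(fit_plsr(X, y, max_lv = 20, cv = cv_spec(5, 5)), "rank bound")
})

test_that("fold assignment is balanced, exhaustive and seed-stable", {
  cv <- cv_spec(10, 42)
  f10 <- make_folds(10, cv)
  expect_equal(sort(unique(f10)), 1:10)
  expect_true(all(table(f10) == 1))          # leave-one-out

  f23 <- make_folds(23, cv)
  expect_equal(as.integer(sort(table(f23), decreasing = TRUE)),
               c(3L, 3L, 3L, 2L, 2L, 2L, 2L, 2L, 2L, 2L))
  expect_identical(make_folds(23, cv), f23)
  expect_error(make_folds(5, cv_spec(10, 1)), "exceeds")

  # a perfect model has zero pooled cross-validated RMSE
  X <- matrix(rnorm(20), 20, 1)
  y <- drop(X)
  r <- cross_validate(function(X, y) NULL,
                      function(fit, Xh) Xh, X, y, cv_spec(5, 1))
  expect_equal(r, 0)
})

test_that("linear SVR drives training residuals inside the epsilon tube", {
  set.seed(17)
  X <- matrix(rnorm(40 * 4), 40, 4, dimnames = list(NULL, paste0("b", 1:4)))
  y <- drop(X %*% c(1, 2, -1, 0.5)) + 3
  m <- fit_svr(X, y, c_grid = 100, epsilon = 0.1, cv = cv_spec(5, 6),
               tol = 1e-8)
  ys <- fit_standardizer(y)
  resid_std <- apply_standardizer(ys, y) - apply_standardizer(ys, predict_svr(m, X))
  expect_lte(max(abs(resid_std)), 0.1 + 1e-6)
  expect_true(m$converged)
})

test_that("a constant response yields the degenerate zero model", {
  X <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, paste0("b", 1:3)))
  m <- fit_svr(X, rep(5, 10), cv = cv_spec(5, 1))
  expect_equal(m$coefficients, rep(0, 3))
  expect_equal(m$intercept, 0)
  expect_equal(predict_svr(m, X), rep(5, 10))
})

test_that("the SVR dual solution matches a generic QP oracle", {
  set.seed(23)
  n <- 30; p <- 4; C <- 1; eps <- 0.1
  X <- matrix(rnorm(n * p), n, p)
  y <- drop(scale(X %*% rnorm(p) + rnorm(n, 0, 0.3)))
  Z <- cbind(scale(X), 1)                      # same augmented-bias problem
  mine <- leafspec:::svr_dcd(Z, y, C, eps, 1e-10, 200000L, 1L)
  expect_true(mine$converged)

  K <- tcrossprod(Z)
  H <- rbind(cbind(K, -K), cbind(-K, K)) + diag(1e-8, 2 * n)
  cc <- c(eps - y, eps + y)
  # box-only QP; the row constraint is made inactive (0 <= sum z <= 2nC)
  qp <- kernlab::ipop(c = cc, H = H, A = matrix(1, 1, 2 * n), b = 0,
                      l = rep(0, 2 * n), u = rep(C, 2 * n), r = 2 * n * C)
  z <- kernlab::primal(qp)
  beta <- z[1:n] - z[(n + 1):(2 * n)]
  obj_oracle <- -(0.5 * drop(beta %*% K %*% beta) - sum(y * beta) +
                    eps * sum(abs(beta)))
  expect_equal(mine$dual_objective, obj_oracle,
               tolerance = 1e-4 * max(1, abs(obj_oracle)))
})

test_that("SVR prediction batches correctly and honors the mean contract", {
  set.seed(19)
  X <- matrix(rnorm(30 * 4), 30, 4, dimnames = list(NULL, paste0("b", 1:4)))
  y <- drop(X %*% c(1, -1, 2, 0)) + rnorm(30, 0, 0.1)
  m <- fit_svr(X, y, c_grid = c(1, 10), cv = cv_spec(5, 8))
  batch <- predict_svr(m, X)
  looped <- vapply(seq_len(nrow(X)), function(i) predict_svr(m, X[i, ]),
                   numeric(1))
  expect_equal(unname(batch), unname(looped), tolerance = 1e-12)
  expect_error(fit_svr(X, y, c_grid = c(-1, 1), cv = cv_spec(5, 8)),
               "positive")
})
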