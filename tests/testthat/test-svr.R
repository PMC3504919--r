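make_regression <- function(n, seed = 1, noise = 0.05) {
  set.seed(seed)
  X <- matrix(runif(n * 12), n, 12)
  y <- sin(2 * pi * X[, 1]) + 0.5 * X[, 2] - X[, 3]^2 + rnorm(n, 0, noise)
  list(X = X, y = y)
}

test_that("min-max scaler maps features to [0,1] and inverts exactly", {
  X <- cbind(c(0, 5, 10), c(3, 3, 3), c(-1, 0, 2))
  sc <- fit_scaler(X)
  Xs <- scale_features(sc, X)
  expect_equal(Xs[, 1], c(0, 0.5, 1))
  expect_equal(Xs[, 2], c(0, 0, 0))  # constant feature
  set.seed(4)
  R <- matrix(rnorm(60), 20, 3)
  scr <- fit_scaler(R)
  expect_equal(unscale_features(scr, scale_features(scr, R)), R,
               tolerance = 1e-12)
  expect_error(scale_features(sc, matrix(1, 2, 5)), "scaler expects")
  expect_error(fit_scaler(matrix(numeric(0), 0, 3)), "empty")
})

test_that("nu selection is seeded, tie-broken to the smallest nu, and dominates nu = 1", {
  d <- make_regression(120, seed = 2)
  Xs <- scale_features(fit_scaler(d$X), d$X)
  s1 <- select_nu(Xs, d$y, seed = 42)
  s2 <- select_nu(Xs, d$y, seed = 42)
  expect_identical(s1, s2)
  expect_lte(min(s1$cv_mse), s1$cv_mse[["1.0"]])
  # duplicate-row degenerate set: identical CV error everywhere -> nu = 0.1
  Xd <- matrix(rep(runif(12), each = 40), 40, 12)
  sd_ <- select_nu(scale_features(fit_scaler(Xd), Xd), rep(0.4, 40))
  expect_equal(sd_$nu, 0.1)
  expect_error(select_nu(Xs[1:10, ], d$y[1:10]), "at least 20")
  expect_error(select_nu(Xs, d$y, grid = numeric(0)), "non-empty")
})

test_that("nu bounds the support-vector and margin-error fractions", {
  d <- make_regression(400, seed = 3)
  for (nu in c(0.3, 0.7)) {
    m <- fit_iqs_svr(d$X, d$y, "iqs", nu = nu)
    diag_ <- svr_margin_diagnostics(m, d$X, d$y)
    expect_gte(diag_$sv_fraction, nu - 0.02)
    expect_lte(diag_$margin_error_fraction, nu + 0.02)
  }
})

test_that("prediction is deterministic, permutation-equivariant and translation-equivariant", {
  d <- make_regression(150, seed = 6)
  m <- fit_iqs_svr(d$X, d$y, "iqs", nu = 0.5)
  Xnew <- make_regression(40, seed = 7)$X
  p <- predict(m, Xnew)
  expect_identical(p, predict(m, Xnew))
  perm <- sample(40)
  expect_identical(predict(m, Xnew[perm, ]), p[perm])
  m2 <- fit_iqs_svr(d$X, d$y + 3, "iqs", nu = 0.5)
  expect_equal(predict(m2, Xnew), p + 3, tolerance = 1e-6)
  expect_error(predict(m, Xnew[, 1:5]), "expects")
})

test_that("constant targets give constant predictions", {
  X <- make_regression(60, seed = 8)$X
  m <- fit_iqs_svr(X, rep(0.7, 60), "pc", nu = 0.3)
  expect_equal(predict(m, X), rep(0.7, 60), tolerance = 1e-6)
})

test_that("held-out accuracy recovers a smooth function of the features", {
  smooth_set <- function(n, seed) {
    set.seed(seed)
    X <- matrix(runif(n * 12), n, 12)
    y <- X[, 1] + X[, 2]^2 - X[, 3] + 0.5 * X[, 4] * X[, 5] +
      rnorm(n, 0, 0.05)
    list(X = X, y = y)
  }
  tr <- smooth_set(2000, seed = 10)
  te <- smooth_set(500, seed = 11)
  m <- fit_iqs_svr(tr$X, tr$y, "iqs", nu = 0.5)
  p <- predict(m, te$X)
  r2 <- 1 - mean((te$y - p)^2) / stats::var(te$y)
  expect_gte(r2, 0.8)
})

test_that("combining predicted Po and Pc applies the kappa arithmetic", {
  expect_equal(combine_po_pc(0.9, 0.36), 0.84375)
  expect_equal(combine_po_pc(0.4, 0.4), 0)
  expect_true(is.na(combine_po_pc(0.9, 1)))
  expect_equal(combine_po_pc(c(0.9, 0.5), c(0.36, 0.25)),
               c(0.84375, 1 / 3))
  expect_error(combine_po_pc(1:3 / 10, 1:2 / 10), "lengths differ")
})

test_that("serialized models reproduce their predictions through the kernel expansion", {
  d <- make_regression(100, seed = 12)
  m <- fit_iqs_svr(d$X, d$y, "po", nu = 0.4)
  path <- withr::local_tempfile(fileext = ".json")
  write_iqs_svr(m, path)
  m2 <- read_iqs_svr(path)
  expect_identical(m2$target_kind, "po")
  expect_equal(m2$nu, m$nu)
  Xnew <- make_regression(50, seed = 13)$X
  expect_equal(predict(m2, Xnew), predict(m, Xnew), tolerance = 1e-10)
  # fresh-handle prediction agrees with the explicit RBF expansion
  m_noh <- m; m_noh$svm <- NULL
  expect_equal(predict(m_noh, Xnew), predict(m, Xnew), tolerance = 1e-10)
})

test_that("training data with missing targets are rejected", {
  d <- make_regression(30, seed = 14)
  y <- d$y; y[5] <- NA
  expect_error(fit_iqs_svr(d$X, y, "iqs", nu = 0.5), "missing values")
})
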