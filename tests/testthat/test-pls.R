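test_that("a single latent factor is recovered exactly", {
  set.seed(61)
  # X built from one dominant direction: y is that direction's score, so a
  # single component must fit it exactly
  t1 <- rnorm(30)
  p1 <- rnorm(20)
  X <- tcrossprod(t1, p1)
  y <- 2 * t1 + 5
  m <- fit_pls(X, y, 1)
  r2 <- 1 - sum((m$fitted - y)^2) / sum((y - mean(y))^2)
  expect_gt(r2, 1 - 1e-8)
})

test_that("PLS2 reproduces PLS1 predictions on rank-adequate noiseless data", {
  set.seed(62)
  # rank-6 X and noiseless linear responses: with all 6 components both
  # modes interpolate the same exact solution
  scores <- matrix(rnorm(40 * 6), 40)
  X <- scores %*% matrix(rnorm(6 * 15), 6)
  B <- matrix(rnorm(30), 15)
  Y <- X %*% B
  m2 <- fit_pls(X, Y, 6, mode = "PLS2")
  for (j in 1:2) {
    m1 <- fit_pls(X, Y[, j, drop = FALSE], 6, mode = "PLS1")
    expect_lt(max(abs(m2$fitted[, j] - m1$fitted[, 1])), 1e-6)
    expect_lt(max(abs(m2$fitted[, j] - Y[, j])), 1e-6)
  }
})

test_that("regression coefficients reproduce the fitted values", {
  set.seed(63)
  X <- matrix(rnorm(25 * 12), 25)
  Y <- cbind(X %*% rnorm(12) + rnorm(25, 0, 0.1),
             X %*% rnorm(12) + rnorm(25, 0, 0.1))
  m <- fit_pls(X, Y, 4)
  manual <- sweep(sweep(X, 2, m$x_mean) %*% m$coef, 2, m$y_mean, `+`)
  expect_lt(max(abs(manual - m$fitted)), 1e-10)
})

test_that("predictions agree with an independent matrix-product oracle", {
  set.seed(64)
  X <- matrix(rnorm(30 * 10), 30)
  y <- X %*% rnorm(10) + rnorm(30, 0, 0.05)
  m <- fit_pls(X, y, 3)
  Xnew <- matrix(rnorm(5 * 10), 5)
  oracle <- sweep(Xnew, 2, m$x_mean) %*% m$coef + m$y_mean
  expect_equal(unname(predict(m, Xnew)), unname(oracle), tolerance = 1e-12)
})

test_that("prediction of the mean training spectrum is the mean response", {
  set.seed(65)
  X <- matrix(rnorm(20 * 8), 20)
  y <- X %*% rnorm(8)
  m <- fit_pls(X, y, 2)
  expect_equal(as.numeric(predict(m, matrix(m$x_mean, 1))),
               as.numeric(m$y_mean), tolerance = 1e-10)
})

test_that("component counts beyond the data rank are rejected", {
  set.seed(66)
  X <- matrix(rnorm(10 * 3), 10) %*% matrix(rnorm(3 * 20), 3) # rank 3
  y <- rnorm(10)
  expect_error(fit_pls(X, y, 25), "rank")
  expect_error(fit_pls(X, y, 8), "rank|exhausted")
})

test_that("our NIPALS agrees with mixOmics as an independent implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(67)
  X <- matrix(rnorm(30 * 15), 30,
              dimnames = list(NULL, paste0("v", 1:15)))
  Y <- cbind(X %*% rnorm(15) + rnorm(30, 0, 0.2),
             X %*% rnorm(15) + rnorm(30, 0, 0.2))
  m <- fit_pls(X, Y, 3, mode = "PLS2")
  ref <- mixOmics::pls(X, Y, ncomp = 3, scale = FALSE, mode = "regression")
  Xnew <- matrix(rnorm(6 * 15), 6,
                 dimnames = list(NULL, paste0("v", 1:15)))
  ours <- predict(m, Xnew)
  theirs <- predict(ref, Xnew)$predict[, , 3]
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-6)
})

test_that("leave-one-out predictions match a naive refit oracle", {
  set.seed(68)
  X <- matrix(rnorm(15 * 8), 15)
  Y <- X %*% rnorm(8) + rnorm(15, 0, 0.1)
  cv <- cross_validate(X, Y, 3)
  naive <- vapply(1:15, function(i) {
    m <- fit_pls(X[-i, ], Y[-i, , drop = FALSE], 3)
    predict(m, X[i, , drop = FALSE])[1, 1]
  }, numeric(1))
  expect_equal(unname(cv$predictions[, 1, 3]), naive, tolerance = 1e-10)
  expect_equal(nrow(cv$rmsecv), 3)
})

test_that("noiseless data reach ~zero RMSECV at the true rank", {
  set.seed(69)
  scores <- matrix(rnorm(20 * 2), 20)
  X <- scores %*% matrix(rnorm(2 * 30), 2)
  Y <- scores %*% c(1, -2)
  cv <- cross_validate(X, Y, 2)
  expect_lt(cv$rmsecv[2, 1], 1e-6)
})

test_that("excessive max_components is capped with a warning", {
  set.seed(70)
  X <- matrix(rnorm(8 * 20), 8)
  Y <- rnorm(8)
  expect_warning(cv <- cross_validate(X, Y, 10), "capped")
  expect_equal(nrow(cv$rmsecv), 6)
})

test_that("model serialization round-trips bit-identically", {
  set.seed(71)
  X <- matrix(rnorm(20 * 6), 20)
  Y <- cbind(s = X %*% rnorm(6), t = X %*% rnorm(6))
  m <- fit_pls(X, Y, 2, pretreatment = c("snv", "savgol[w=25,p=2,d=1]"),
               wavenumbers = seq(4000, 4020, by = 4))
  path <- withr::local_tempfile(fileext = ".json")
  write_pls_model(m, path)
  m2 <- read_pls_model(path)
  expect_identical(unname(m2$coef), unname(m$coef))
  expect_identical(as.numeric(m2$x_mean), as.numeric(m$x_mean))
  expect_identical(as.numeric(m2$y_mean), as.numeric(m$y_mean))
  expect_identical(m2$pretreatment, m$pretreatment)
  Xnew <- matrix(rnorm(3 * 6), 3)
  expect_identical(unname(predict(m, Xnew)), unname(predict(m2, Xnew)))
})
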