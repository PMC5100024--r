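test_that("range restriction keeps the inclusive window and is idempotent", {
  sp <- spectra_set(c(3500, 4000, 5000, 9500), matrix(rnorm(8), 2))
  r1 <- restrict_range(sp)
  expect_equal(r1$wavenumbers, c(4000, 5000))
  r2 <- restrict_range(r1)
  expect_equal(r2$absorbance, r1$absorbance)
  expect_error(restrict_range(sp, 10000, 11000), "range")
})

test_that("restriction count matches brute-force counting on the full grid", {
  grid <- seq(3300, 12000, by = 4)
  sp <- spectra_set(grid, matrix(rnorm(length(grid)), 1))
  r <- restrict_range(sp, 4000, 9000)
  expect_equal(length(r$wavenumbers), sum(grid >= 4000 & grid <= 9000))
})

test_that("SNV matches the hand-computed example and defining property", {
  sp <- spectra_set(1:3, matrix(c(1, 2, 3), 1))
  out <- snv(sp)
  expect_equal(as.numeric(out$absorbance), c(-1, 0, 1))
  sp2 <- spectra_set(1:50, matrix(rnorm(150), 3))
  out2 <- snv(sp2)$absorbance
  expect_lt(max(abs(rowMeans(out2))), 1e-10)
  expect_lt(max(abs(apply(out2, 1, sd) - 1)), 1e-10)
})

test_that("SNV is invariant to positive affine transforms of a spectrum", {
  x <- matrix(rnorm(80), 1)
  sp <- spectra_set(1:80, x)
  sp_aff <- spectra_set(1:80, 3.2 * x + 17)
  expect_equal(snv(sp)$absorbance, snv(sp_aff)$absorbance, tolerance = 1e-10)
})

test_that("SNV rejects constant spectra naming the sample", {
  sp <- spectra_set(1:4, rbind(rnorm(4), rep(2, 4)),
                    sample_ids = c("ok", "flatliner"))
  expect_error(snv(sp), "flatliner")
})

test_that("Savitzky-Golay derivatives are exact on polynomials", {
  grid <- seq(4000, 5000, by = 4)
  lin <- spectra_set(grid, matrix(3 * grid + 1, 1))
  d1 <- savgol_derivative(lin, window = 25, polyorder = 2, deriv = 1)
  expect_equal(as.numeric(d1$absorbance), rep(3, length(d1$wavenumbers)),
               tolerance = 1e-8)
  quad <- spectra_set(grid, matrix(grid^2, 1))
  d2 <- savgol_derivative(quad, window = 25, polyorder = 2, deriv = 1)
  expect_equal(as.numeric(d2$absorbance), 2 * d2$wavenumbers,
               tolerance = 1e-6)
})

test_that("Savitzky-Golay equals a per-window polynomial regression oracle", {
  grid <- seq(4000, 4400, by = 4)
  set.seed(77)
  x <- sin(grid / 50) + rnorm(length(grid), 0, 0.05)
  sp <- spectra_set(grid, matrix(x, 1))
  w <- 11L; p <- 2L; half <- 5L
  out <- savgol_derivative(sp, window = w, polyorder = p, deriv = 1)
  oracle <- vapply((half + 1):(length(grid) - half), function(i) {
    idx <- (i - half):(i + half)
    fit <- stats::lm(x[idx] ~ poly(grid[idx], p, raw = TRUE))
    b <- coef(fit)
    b[2] + 2 * b[3] * grid[i]
  }, numeric(1))
  expect_equal(as.numeric(out$absorbance), oracle, tolerance = 1e-8)
})

test_that("Savitzky-Golay drops half-window edges and guards its inputs", {
  grid <- seq(1, 100, by = 1)
  sp <- spectra_set(grid, matrix(rnorm(100), 1))
  out <- savgol_derivative(sp, window = 11, polyorder = 2, deriv = 1)
  expect_equal(length(out$wavenumbers), 100 - 10)
  expect_equal(out$wavenumbers[1], 6)
  irregular <- spectra_set(c(1, 2, 4, 8, 16, 32, 64), matrix(rnorm(7), 1))
  expect_error(savgol_derivative(irregular, window = 5, polyorder = 2),
               "uniform")
  expect_error(savgol_derivative(sp, window = 10), "odd")
  expect_error(savgol_derivative(sp, window = 11, polyorder = 2, deriv = 3),
               "deriv")
})
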