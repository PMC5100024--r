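test_that("rmse matches its definition and hand example", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 5)), sqrt(4 / 3))
  p <- c(0.3, 1.2, -0.5, 2); r <- c(0.1, 1.0, 0.0, 2.5)
  perm <- c(3, 1, 4, 2)
  expect_equal(rmse(p, r), rmse(p[perm], r[perm]))
  expect_error(rmse(numeric(0), numeric(0)), "empty")
})

test_that("the 2x RMSECV outlier rule flags strictly exceeding residuals", {
  cvp <- cbind(c(1.01, 1.05, 1.039))
  ref <- cbind(c(1, 1, 1))
  expect_equal(detect_outliers(cvp, ref, 0.02), 2L)
  expect_length(detect_outliers(ref, ref, 0.02), 0)
})

test_that("PLS2 outliers flag when either response exceeds its threshold", {
  set.seed(81)
  resid <- matrix(runif(40, 0, 0.01), 20)
  ref <- matrix(rnorm(40), 20)
  cvp <- ref + resid
  cvp[3, 1] <- ref[3, 1] + 0.05
  cvp[7, 2] <- ref[7, 2] - 0.06
  thr <- c(0.02, 0.02)
  got <- detect_outliers(cvp, ref, thr)
  # brute-force per-response check
  brute <- which(abs(cvp - ref)[, 1] > 2 * thr[1] |
                   abs(cvp - ref)[, 2] > 2 * thr[2])
  expect_equal(sort(got), sort(brute))
  expect_setequal(got, c(3L, 7L))
})

test_that("reference uncertainty is twice the mean within-sample SD", {
  tb <- data.frame(
    sample_id = rep(c("a", "b"), each = 3),
    value = c(1 - 0.01, 1, 1 + 0.01, 2 - 0.02, 2, 2 + 0.02)
  )
  expect_equal(reference_uncertainty(tb), 2 * mean(c(sd(c(0.99, 1, 1.01)),
                                                     sd(c(1.98, 2, 2.02)))))
  same <- data.frame(sample_id = rep(1:2, each = 3), value = rep(5, 6))
  expect_equal(reference_uncertainty(same), 0)
  one <- data.frame(sample_id = c(1, 1, 2), value = c(1, 2, 3))
  expect_warning(u <- reference_uncertainty(one), "excluded")
  expect_equal(u, 2 * sd(c(1, 2)))
})

test_that("simulated triplicates recover 2 * tau * c4 on average", {
  tau <- 0.05
  set.seed(82)
  tb <- data.frame(
    sample_id = rep(1:150, each = 3),
    value = rep(rnorm(150, 10, 1), each = 3) + rnorm(450, 0, tau)
  )
  c4 <- sqrt(2 / 2) * gamma(3 / 2) / gamma(1) # n = 3
  expect_lt(abs(reference_uncertainty(tb) - 2 * tau * c4) / (2 * tau * c4),
            0.1)
})

test_that("noiseless linear-mixture spectra calibrate essentially perfectly", {
  cs <- clean_spectra(n = 40, seed = 83, background = default_matrix_background())
  rep <- calibrate(cs$spectra, responses = "TNC", n_components = 3,
                   cal_size = 28)
  expect_gt(rep$statistics$r2_validation, 0.999)
  expect_equal(rep$n_calibration + rep$n_validation, 40)
  expect_true(all(rep$outliers %in% cs$spectra$sample_ids))
  expect_lte(length(rep$outliers), rep$n_calibration)
})

test_that("predicting with mismatched pretreatment or grid errors", {
  cs <- clean_spectra(n = 30, seed = 84, background = default_matrix_background())
  rep <- calibrate(cs$spectra, responses = "TNC", n_components = 3,
                   cal_size = 20)
  raw <- cs$spectra
  expect_error(predict(rep$model, raw), "pretreatment")
  pre_wrong <- snv(restrict_range(raw))
  expect_error(predict(rep$model, pre_wrong), "pretreatment")
  pre_right <- savgol_derivative(snv(restrict_range(raw)))
  expect_silent(predict(rep$model, pre_right))
})

test_that("the validation set influences nothing before final evaluation", {
  cs <- clean_spectra(n = 36, seed = 85, noise_sd = 1e-4,
                      wetchem_error_sd = 0.004,
                      background = default_matrix_background())
  rep1 <- calibrate(cs$spectra, responses = "TNC", n_components = 3,
                    cal_size = 24)
  sp2 <- cs$spectra
  # permute the wet chemistry of the validation samples only
  idx <- match(rep1$validation_ids, sp2$constituents$sample_id)
  perm <- withr::with_seed(1, sample(idx))
  sp2$constituents[idx, c("starch", "sucrose")] <-
    sp2$constituents[perm, c("starch", "sucrose")]
  rep2 <- calibrate(sp2, responses = "TNC", n_components = 3, cal_size = 24)
  expect_identical(rep1$model$coef, rep2$model$coef)
  expect_identical(rep1$model$x_mean, rep2$model$x_mean)
  expect_identical(rep1$outliers, rep2$outliers)
  # but the validation metrics do change
  expect_false(isTRUE(all.equal(rep1$statistics$r2_validation,
                                rep2$statistics$r2_validation)))
})

test_that("suggest_components finds the first local minimum", {
  expect_equal(suggest_components(c(5, 3, 4, 2, 6)), 2)
  expect_equal(suggest_components(c(5, 4, 3, 2, 1)), 5)
  expect_equal(suggest_components(c(1, 2, 3)), 1)
})
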