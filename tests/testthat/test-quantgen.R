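test_that("heritability draws are consistent arithmetic on the variance draws", {
  p <- tiny_panel(seed = 21)
  fit <- suppressWarnings(fit_single_trait(p$pheno, p$grm, spec = fast_spec(seed = 2)))
  d <- fit$draws
  expect_equal(d$h2, d$var_additive /
                 (d$var_additive + d$var_nonadditive + d$var_error),
               tolerance = 1e-12)
  # a fixed draw: variances 3, 1, 6 imply h2 = 0.3, H2 = 0.4
  expect_equal(3 / (3 + 1 + 6), 0.3)
  expect_equal((3 + 1) / (3 + 1 + 6), 0.4)
})

test_that("every draw satisfies the variance and heritability constraints", {
  p <- tiny_panel(seed = 22, line_cv_spread = 0.3)
  fit <- suppressWarnings(fit_single_trait(p$pheno, p$grm, spec = fast_spec(seed = 3)))
  d <- fit$draws
  expect_true(all(d$var_additive >= 0 & d$var_nonadditive >= 0 &
                    d$var_error >= 0))
  expect_true(all(d$h2 >= 0 & d$h2 <= d$H2 & d$H2 <= 1))
})

test_that("a line missing from the GRM is reported by name", {
  p <- tiny_panel(seed = 23)
  ph <- p$pheno
  ph$line[ph$line == "L001"] <- "GHOST"
  expect_error(fit_single_trait(ph, p$grm, spec = fast_spec()), "GHOST")
})

test_that("with K = I and no non-additive term the fit matches a one-way ANOVA
           variance decomposition", {
  n <- 80; reps <- 8
  set.seed(99)
  line_eff <- rnorm(n, 0, sqrt(0.5))
  y <- rep(line_eff, each = reps) + rnorm(n * reps, 0, sqrt(0.5))
  ph <- tibble::tibble(
    line = rep(sprintf("L%03d", 1:n), each = reps),
    replicate = rep(1:reps, n), trait = "T", value = 10 + y
  )
  Ki <- grm(diag(n), line_ids = sprintf("L%03d", 1:n))
  fit <- suppressWarnings(fit_single_trait(
    ph, Ki, spec = model_spec(nonadditive = FALSE, chains = 2,
                              warmup = 200, samples = 400, seed = 4)
  ))
  # ANOVA method-of-moments oracle for the intraclass correlation
  av <- anova(stats::lm(value ~ line, data = ph))
  msb <- av["line", "Mean Sq"]; msw <- av["Residuals", "Mean Sq"]
  sb <- (msb - msw) / reps
  icc <- sb / (sb + msw)
  expect_lt(abs(mean(fit$draws$h2) - icc), 0.08)
})

test_that("gaussian and student-t error families agree on gaussian data", {
  p <- tiny_panel(n_lines = 40, n_snps = 120, n_reps = 6, seed = 24)
  f_g <- suppressWarnings(fit_single_trait(
    p$pheno, p$grm, spec = model_spec(chains = 2, warmup = 200,
                                      samples = 400, seed = 5)
  ))
  f_t <- suppressWarnings(fit_single_trait(
    p$pheno, p$grm,
    spec = model_spec(error_family = "student_t", chains = 2,
                      warmup = 200, samples = 400, seed = 5)
  ))
  expect_lt(abs(mean(f_g$draws$h2) - mean(f_t$draws$h2)), 0.1)
  expect_true(all(f_t$draws$nu > 2))
})

test_that("line CV is the error scale over the absolute line mean", {
  p <- tiny_panel(seed = 25, line_cv_spread = 0.4)
  fit <- suppressWarnings(fit_single_trait(p$pheno, p$grm, spec = fast_spec(seed = 6)))
  # posterior-mean CV should be close to the ratio of posterior means for
  # stable line means far from zero
  approx_cv <- fit$lines$error_scale / abs(fit$lines$line_mean)
  expect_gt(cor(fit$lines$cv, approx_cv), 0.99)
})
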