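test_that("no genetic variance means no between-line genetic signal", {
  g <- simulate_genotypes(12, 30, seed = 2)
  cfg <- pheno_sim_config(var_additive = 0, var_nonadditive = 0,
                          var_error = 1, n_reps = 3)
  ph <- simulate_phenotypes(g, cfg, seed = 4)
  truth <- attr(ph, "truth")
  expect_equal(var(truth$additive + truth$nonadditive), 0)
})

test_that("perfect genetic correlation gives perfectly correlated additive values", {
  g <- simulate_genotypes(25, 60, seed = 3)
  cfg <- pheno_sim_config(traits = c("t1", "t2"), genetic_corr = 1,
                          var_nonadditive = 0, n_reps = 2)
  ph <- simulate_phenotypes(g, cfg, seed = 9)
  truth <- tidyr::pivot_wider(attr(ph, "truth")[c("line", "trait", "additive")],
                              names_from = "trait", values_from = "additive")
  expect_equal(cor(truth$t1, truth$t2), 1, tolerance = 1e-8)
})

test_that("realized additive variance targets the configured value", {
  # Monte-Carlo oracle: average realized var(a) over 20 seeds within 15%
  vars <- vapply(1:20, function(s) {
    g <- simulate_genotypes(200, 150, seed = s)
    ph <- simulate_phenotypes(
      g, pheno_sim_config(var_additive = 0.6, var_nonadditive = 0.1,
                          var_error = 0.3, n_reps = 2),
      seed = s + 500
    )
    var(attr(ph, "truth")$additive)
  }, numeric(1))
  expect_lt(abs(mean(vars) - 0.6) / 0.6, 0.15)
})

test_that("realized narrow-sense heritability tracks the config target", {
  h2 <- vapply(1:20, function(s) {
    g <- simulate_genotypes(150, 100, seed = s + 30)
    ph <- simulate_phenotypes(
      g, pheno_sim_config(var_additive = 0.5, var_nonadditive = 0.2,
                          var_error = 0.3, n_reps = 2),
      seed = s
    )
    tr <- attr(ph, "truth")
    va <- var(tr$additive)
    va / (va + var(tr$nonadditive) + mean(tr$error_scale^2))
  }, numeric(1))
  expect_lt(abs(mean(h2) - 0.5), 0.05)
})

test_that("student-t errors keep the configured variance", {
  g <- simulate_genotypes(50, 20, seed = 6)
  cfg <- pheno_sim_config(var_additive = 0, var_nonadditive = 0,
                          var_error = 2, n_reps = 200,
                          error_family = "student_t")
  ph <- simulate_phenotypes(g, cfg, seed = 13)
  expect_lt(abs(var(ph$value) - 2) / 2, 0.15)
})

test_that("replicate counts below 2 are rejected", {
  expect_error(pheno_sim_config(n_reps = 1), "n_reps")
})

test_that("simulation is deterministic given the seed", {
  g <- simulate_genotypes(10, 20, seed = 1)
  ph1 <- simulate_phenotypes(g, pheno_sim_config(n_reps = 3), seed = 5)
  ph2 <- simulate_phenotypes(g, pheno_sim_config(n_reps = 3), seed = 5)
  expect_identical(ph1$value, ph2$value)
})
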