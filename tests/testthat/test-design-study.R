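test_that("subsampling keeps exactly rs replicates per line", {
  p <- tiny_panel(n_lines = 6, n_reps = 20, seed = 41)
  sub <- subsample_replicates(p$pheno, 2, seed = 1)
  counts <- table(sub$line)
  expect_true(all(counts == 2))
})

test_that("subsampling at the full replicate count is a permutation", {
  p <- tiny_panel(n_lines = 5, n_reps = 4, seed = 42)
  sub <- subsample_replicates(p$pheno, 4, seed = 2)
  expect_setequal(
    paste(sub$line, sub$replicate, sub$value),
    paste(p$pheno$line, p$pheno$replicate, p$pheno$value)
  )
})

test_that("a line with too few replicates is reported by name", {
  p <- tiny_panel(n_lines = 4, n_reps = 3, seed = 43)
  short <- dplyr::filter(p$pheno, !(line == "L002" & replicate > 2))
  expect_error(subsample_replicates(short, 3), "L002")
})

test_that("within-line pairs are drawn uniformly", {
  ph <- tibble::tibble(line = "L1", replicate = 1:4, trait = "t",
                       value = rnorm(4))
  picks <- vapply(1:1000, function(s) {
    sub <- subsample_replicates(ph, 2, seed = s)
    paste(sort(sub$replicate), collapse = "-")
  }, character(1))
  freq <- table(picks) / 1000
  expect_length(freq, 6)
  # each unordered pair has probability 1/6; 3 binomial SEs
  se <- sqrt((1 / 6) * (5 / 6) / 1000)
  expect_true(all(abs(freq - 1 / 6) < 3 * se))
})

test_that("accuracy is the Pearson correlation with edge-case handling", {
  expect_equal(accuracy(c(1, 2, 3, 5), c(1, 2, 3, 5)), 1)
  expect_equal(accuracy(-c(1, 2, 3, 5), c(1, 2, 3, 5)), -1)
  expect_equal(accuracy(c(1, 2, 3, 5), c(1, 2, 3, 4)), 0.98270763, tolerance = 1e-6)
  expect_true(is.na(accuracy(c(1, 1, 1), c(1, 2, 3))))
  expect_error(accuracy(c(1, 2), c(1, 2)), "at least 3")
})

test_that("relative deviation follows its definition", {
  expect_equal(relative_deviation(0.45, 0.5), -0.1)
  expect_equal(relative_deviation(0.5, 0.5), 0)
  expect_equal(relative_deviation(0.66, 0.55), 0.2)
  expect_true(is.na(relative_deviation(1, 0)))
})

test_that("an identity-size design study reproduces the full fit", {
  p <- tiny_panel(n_lines = 20, n_snps = 80, n_reps = 6, seed = 44)
  st <- suppressWarnings(run_design_study(
    p$pheno, p$grm,
    spec = model_spec(chains = 2, warmup = 400, samples = 1200, seed = 1,
                      rhat_threshold = 1.2),
    config = design_study_config(replicate_sizes = 6, n_draws = 1,
                                 seed = 2, trait_pairs = list())
  ))
  acc <- dplyr::filter(st$results, metric == "accuracy",
                       parameter %in% c("line_mean", "gebv"))
  expect_true(all(acc$value > 0.98))
  dev <- dplyr::filter(st$results, metric == "relative_deviation",
                       parameter == "h2")
  expect_true(all(abs(dev$value) < 0.1))
})

test_that("design study results carry the declared tidy structure", {
  p <- tiny_panel(n_lines = 10, n_snps = 50, n_reps = 5, seed = 45)
  st <- suppressWarnings(run_design_study(
    p$pheno, p$grm,
    spec = model_spec(chains = 2, warmup = 100, samples = 200, seed = 1,
                      rhat_threshold = 2),
    config = design_study_config(replicate_sizes = c(2, 5), n_draws = 2,
                                 seed = 5, trait_pairs = list())
  ))
  expect_named(st$results,
               c("rs", "draw", "trait", "parameter", "metric", "value"))
  s <- tidy(st)
  expect_true(all(c("median", "q25", "q75") %in% names(s)))
  expect_setequal(unique(st$results$rs), c(2, 5))
})
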