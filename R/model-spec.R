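#' MCMC and prior settings for the hierarchical genetic model
#'
#' @param error_family `"gaussian"` or `"student_t"`. With Student-t errors
#'   the degrees of freedom are estimated (shifted-Exponential prior on
#'   `nu - 2`, keeping the variance finite).
#' @param nonadditive Include the i.i.d. non-additive line effect `d_i`
#'   (default `TRUE`). With `FALSE` the model reduces to additive + error and
#'   broad-sense equals narrow-sense heritability.
#' @param chains Number of MCMC chains (default 4).
#' @param warmup,samples Warmup (discarded) and retained iterations per chain.
#' @param seed Integer seed controlling all chains.
#' @param prior_scale Scale `A` of the weakly-informative priors on the
#'   standard deviations (half-t(3, A) on the genetic SDs, half-Normal(A) on
#'   the common error scale). Default `NULL` means `2 * sd(y)`, adapting the
#'   prior to the trait scale.
#' @param line_var_df Degrees of freedom `nu_h` of the scaled-inverse-chi2
#'   hierarchy that shrinks line-specific error variances towards the common
#'   scale; smaller values allow more dispersion heterogeneity (default 4).
#' @param rhat_threshold Convergence gate on split-R-hat; exceeding it raises
#'   a warning and flags the fit (default 1.05).
#' @return A `model_spec` list.
#' @export
model_spec <- function(error_family = c("gaussian", "student_t"),
                       nonadditive = TRUE, chains = 4L, warmup = 500L,
                       samples = 1000L, seed = 1L, prior_scale = NULL,
                       line_var_df = 4, rhat_threshold = 1.05) {
  error_family <- match.arg(error_family)
  assert_that(is_count(chains, 1L), "`chains` must be >= 1")
  assert_that(is_count(warmup, 0L), "`warmup` must be >= 0")
  assert_that(is_count(samples, 1L), "`samples` must be >= 1")
  structure(
    list(
      error_family = error_family, nonadditive = isTRUE(nonadditive),
      chains = as.integer(chains), warmup = as.integer(warmup),
      samples = as.integer(samples), seed = as.integer(seed),
      prior_scale = prior_scale, line_var_df = line_var_df,
      rhat_threshold = rhat_threshold
    ),
    class = "model_spec"
  )
}
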