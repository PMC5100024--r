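#' Configuration for the replicated-phenotype generator
#'
#' Describes the generative model behind a replicated greenhouse-style trial:
#' per line `i` and trait `t`, an additive genetic value built from SNP
#' effects, an i.i.d. non-additive line deviation, and replicate-level error
#' with optional line-specific scales, so that the narrow-sense heritability
#' targeted by the configuration is `var_additive / (var_additive +
#' var_nonadditive + var_error)`.
#'
#' @param traits Character vector of trait names (one or more).
#' @param n_reps Replicates per line (>= 2; the emulated study used 20).
#' @param mu Per-trait grand mean (recycled).
#' @param var_additive,var_nonadditive,var_error Per-trait variance components
#'   on the trait scale (recycled; all >= 0).
#' @param genetic_corr,env_corr Pairwise genetic / environmental correlation
#'   used for multi-trait generation: a scalar (exchangeable across trait
#'   pairs, `|rho| <= 1`) or a full trait correlation matrix for
#'   heterogeneous pairwise structure.
#' @param line_cv_spread Log-scale standard deviation of line-specific error
#'   scales; 0 gives homogeneous dispersion, larger values give each line a
#'   distinct true coefficient of variation.
#' @param error_family `"gaussian"` or `"student_t"`.
#' @param t_df Degrees of freedom for the Student-t error family (> 2 so the
#'   variance stays finite; default 4).
#' @return A `pheno_sim_config` list.
#' @export
pheno_sim_config <- function(traits = "STCH_HD", n_reps = 20L, mu = 10,
                             var_additive = 0.6, var_nonadditive = 0.1,
                             var_error = 0.3, genetic_corr = 0,
                             env_corr = 0, line_cv_spread = 0,
                             error_family = c("gaussian", "student_t"),
                             t_df = 4) {
  error_family <- match.arg(error_family)
  n_tr <- length(traits)
  assert_that(n_tr >= 1L, "at least one trait is required")
  assert_that(is_count(n_reps, 2L), "`n_reps` must be >= 2 (dispersion is unidentifiable otherwise)")
  rec <- function(x) rep_len(as.numeric(x), n_tr)
  va <- rec(var_additive); vd <- rec(var_nonadditive); ve <- rec(var_error)
  assert_that(all(c(va, vd, ve) >= 0), "variance components must be >= 0")
  assert_that(all(abs(genetic_corr) <= 1) && all(abs(env_corr) <= 1),
              "|genetic_corr| and |env_corr| must be <= 1")
  assert_that(is_number(line_cv_spread) && line_cv_spread >= 0,
              "`line_cv_spread` must be a non-negative number")
  assert_that(is_number(t_df) && t_df > 2, "`t_df` must be > 2")
  structure(
    list(
      traits = traits, n_reps = as.integer(n_reps), mu = rec(mu),
      var_additive = va, var_nonadditive = vd, var_error = ve,
      genetic_corr = genetic_corr, env_corr = env_corr,
      line_cv_spread = line_cv_spread, error_family = error_family,
      t_df = t_df
    ),
    class = "pheno_sim_config"
  )
}

# scalar rho -> exchangeable matrix; matrix rho -> validated as-is
make_corr <- function(k, rho, what) {
  if (is.matrix(rho)) {
    assert_that(nrow(rho) == k && ncol(rho) == k,
                sprintf("`%s` matrix must be %d x %d", what, k, k))
    assert_that(max(abs(rho - t(rho))) < 1e-10 && all(diag(rho) == 1),
                sprintf("`%s` must be a correlation matrix", what))
    return(rho)
  }
  m <- matrix(rho, k, k)
  diag(m) <- 1
  m
}

#' Simulate replicated phenotypes with genetic and environmental structure
#'
#' For each line `i`, trait `t` and replicate `r`:
#' `y_irt = mu_t + a_it + d_it + e_irt`, where the additive value
#' `a_it = sum_j z_ij beta_jt` is built from centered SNP dosages with effect
#' sizes scaled so the expected additive variance matches the configured
#' `var_additive` (`beta_j ~ N(0, var_additive / (2 * sum_j p_j (1 - p_j)))`,
#' the usual infinitesimal scaling), `d_it ~ N(0, var_nonadditive)` i.i.d.
#' across lines, and `e_irt` comes from the configured error family with a
#' line-specific scale `sigma_e * exp(line_cv_spread * z_i)` (log-normal around
#' the common scale). Across traits, the SNP effects and non-additive
#' deviations share correlation `genetic_corr` and the replicate errors share
#' correlation `env_corr`. Student-t errors are standardized to unit variance
#' before scaling so variance targets are met for either family.
#'
#' @param genotypes A [genotype_matrix] (required whenever `var_additive > 0`).
#' @param config A [pheno_sim_config].
#' @param seed Integer seed.
#' @return A tibble with columns `line`, `replicate`, `trait`, `value`
#'   (class `nsc_pheno`). The latent truth used to generate it is attached as
#'   `attr(, "truth")`: a tibble with per line x trait the additive value,
#'   non-additive deviation, error scale, true line mean and true CV.
#' @examples
#' g <- simulate_genotypes(20, 100, seed = 1)
#' ph <- simulate_phenotypes(g, pheno_sim_config(n_reps = 4), seed = 2)
#' head(ph)
#' @export
simulate_phenotypes <- function(genotypes, config = pheno_sim_config(),
                                seed = 1L) {
  assert_that(inherits(config, "pheno_sim_config"),
              "`config` must come from pheno_sim_config()")
  if (any(config$var_additive > 0)) {
    assert_that(inherits(genotypes, "genotype_matrix"),
                "genotypes are required when var_additive > 0")
  }
  n_tr <- length(config$traits)
  n_lines <- nrow(genotypes$dosages)
  line_ids <- genotypes$line_ids
  with_seed(seed, {
    # additive values from SNP effects with infinitesimal scaling
    Z <- center_dosages(genotypes)
    denom <- attr(Z, "denom") # 2 * sum p (1-p)
    Lg <- chol_psd(make_corr(n_tr, config$genetic_corr, "genetic_corr"))
    a <- matrix(0, n_lines, n_tr)
    if (denom > 0) {
      beta_std <- matrix(rnorm(ncol(Z) * n_tr), ncol(Z), n_tr) %*% Lg
      a_raw <- Z %*% beta_std / sqrt(denom) # unit additive variance per trait
      a <- sweep(a_raw, 2, sqrt(config$var_additive), `*`)
    }
    # non-additive line deviations, correlated across traits
    d <- matrix(rnorm(n_lines * n_tr), n_lines, n_tr) %*% Lg
    d <- sweep(d, 2, sqrt(config$var_nonadditive), `*`)
    # line-specific error scales (shared across traits up to the trait sigma)
    lam <- exp(config$line_cv_spread * rnorm(n_lines) -
                 config$line_cv_spread^2 / 2)
    scales <- outer(lam, sqrt(config$var_error)) # n_lines x n_tr
    # replicate errors
    Le <- chol_psd(make_corr(n_tr, config$env_corr, "env_corr"))
    n_obs <- n_lines * config$n_reps
    eps <- matrix(rnorm(n_obs * n_tr), n_obs, n_tr) %*% Le
    if (config$error_family == "student_t") {
      nu <- config$t_df
      w <- rgamma(n_obs, shape = nu / 2, rate = nu / 2)
      eps <- eps / sqrt(w) * sqrt((nu - 2) / nu) # unit-variance t
    }
    line_idx <- rep(seq_len(n_lines), each = config$n_reps)
    eps <- eps * scales[line_idx, , drop = FALSE]
    vals <- sweep(a + d, 2, config$mu, `+`)[line_idx, , drop = FALSE] + eps
    out <- tibble(
      line = rep(line_ids[line_idx], times = n_tr),
      replicate = rep(rep(seq_len(config$n_reps), n_lines), times = n_tr),
      trait = rep(config$traits, each = n_obs),
      value = as.vector(vals)
    )
    truth <- tibble(
      line = rep(line_ids, times = n_tr),
      trait = rep(config$traits, each = n_lines),
      additive = as.vector(a),
      nonadditive = as.vector(d),
      error_scale = as.vector(scales),
      line_mean = as.vector(sweep(a + d, 2, config$mu, `+`)),
      cv = as.vector(scales / abs(sweep(a + d, 2, config$mu, `+`)))
    )
    attr(out, "truth") <- truth
    class(out) <- c("nsc_pheno", class(out))
    out
  })
}

# column-center dosages at 2p (mean imputation for missing calls);
# attr "denom" carries 2 * sum_j p_j (1 - p_j) over polymorphic SNPs
center_dosages <- function(genotypes) {
  dos <- genotypes$dosages
  p <- colMeans(dos, na.rm = TRUE) / 2
  Z <- sweep(dos, 2, 2 * p)
  Z[is.na(Z)] <- 0
  poly <- p > 0 & p < 1
  structure(Z, denom = 2 * sum(p[poly] * (1 - p[poly])))
}

# Cholesky factor that tolerates the rho = +/-1 boundary
chol_psd <- function(m) {
  ev <- eigen(m, symmetric = TRUE)
  val <- pmax(ev$values, 0)
  t(ev$vectors %*% (t(ev$vectors) * sqrt(val)))
}
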