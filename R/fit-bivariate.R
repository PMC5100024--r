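#' Fit the bivariate genetic model for a trait pair
#'
#' Joint model for two traits measured on the same replicated lines:
#' \deqn{y_{irt} = \mu_t + a_{it} + \varepsilon_{irt}}
#' where the per-line additive pairs `(a_i1, a_i2)` follow a matrix-normal
#' prior with row covariance `K` (the GRM) and a free 2x2 genetic covariance
#' `Sigma_g`, and the replicate-level error pairs share a 2x2 environmental
#' covariance `Sigma_e` (optionally with a multivariate-t scale mixture for
#' `error_family = "student_t"`, df fixed at 4). The genetic correlation
#' `r_g = Sigma_g[1,2] / sqrt(Sigma_g[1,1] Sigma_g[2,2])` and environmental
#' correlation `r_e` are computed per draw, giving (lower, point, upper)
#' credible triplets in the layout of a pairwise correlation table.
#'
#' Covariance matrices get weakly-informative inverse-Wishart priors scaled
#' to the empirical between-line and within-line covariance of the data.
#'
#' @inheritParams fit_single_trait
#' @param traits Character vector of the two trait names; may be omitted when
#'   exactly two traits are present.
#' @return An `nsc_fit` object (class `nsc_fit_bivariate`): `draws` holds
#'   `r_g`, `r_e`, the per-trait genetic and environmental variances, and the
#'   means; `lines` holds per-line GEBVs for both traits.
#' @examples
#' g <- simulate_genotypes(15, 80, seed = 1)
#' cfg <- pheno_sim_config(traits = c("STCH_HD", "SUC_HD"), n_reps = 4,
#'                         genetic_corr = 0.5)
#' ph <- simulate_phenotypes(g, cfg, seed = 2)
#' fit <- fit_bivariate(ph, compute_grm(g),
#'   spec = model_spec(chains = 2, warmup = 50, samples = 100)
#' )
#' tidy(fit)
#' @export
fit_bivariate <- function(pheno, grm, traits = NULL, spec = model_spec()) {
  assert_that(inherits(grm, "grm"), "`grm` must be a grm object")
  assert_that(inherits(spec, "model_spec"), "`spec` must be a model_spec")
  pheno <- check_pheno(pheno)
  present <- unique(pheno$trait)
  if (is.null(traits)) {
    assert_that(length(present) == 2L,
                "`traits` must name the pair when != 2 traits are present")
    traits <- present
  }
  assert_that(length(traits) == 2L && all(traits %in% present),
              "`traits` must be two traits present in `pheno`")
  dat <- dplyr::filter(pheno, .data$trait %in% traits)
  lines_by_trait <- lapply(traits, function(tr) unique(dat$line[dat$trait == tr]))
  common <- intersect(lines_by_trait[[1]], lines_by_trait[[2]])
  if (length(common) == 0) abort("the two traits have disjoint line sets")
  miss <- setdiff(common, grm$line_ids)
  if (length(miss) > 0) {
    abort(sprintf("lines absent from the GRM: %s",
                  paste(miss, collapse = ", ")))
  }
  wide <- tidyr::pivot_wider(dat, id_cols = c("line", "replicate"),
                             names_from = "trait", values_from = "value")
  wide <- wide[stats::complete.cases(wide[traits]) & wide$line %in% common, ]
  lines <- grm$line_ids[grm$line_ids %in% wide$line]
  li <- match(wide$line, lines)
  Y <- as.matrix(wide[traits])
  n <- length(lines)
  K <- grm$K[lines, lines, drop = FALSE]

  res <- gibbs_bivariate(Y, li, n, K, spec)
  check_convergence(res, spec)

  lines_tbl <- tibble(
    line = lines,
    n_reps = tabulate(li, n),
    gebv_1 = res$line_sums$a1 / res$n_kept,
    gebv_2 = res$line_sums$a2 / res$n_kept
  )
  names(lines_tbl)[3:4] <- paste0("gebv_", traits)
  structure(
    list(
      trait = traits, draws = res$draws, lines = lines_tbl,
      diagnostics = res$diagnostics, spec = spec, n_obs = nrow(Y),
      converged = res$converged
    ),
    class = c("nsc_fit", "nsc_fit_bivariate")
  )
}

gibbs_bivariate <- function(Y, li, n, K, spec) {
  n_obs <- nrow(Y)
  student <- spec$error_family == "student_t"
  nu_t_fixed <- 4
  m0 <- colMeans(Y)
  sd_y <- pmax(apply(Y, 2, sd), 1e-6)
  V0 <- (10 * sd_y)^2

  eig <- eigen(K + diag(1e-8, n), symmetric = TRUE)
  Kinv <- eig$vectors %*% (t(eig$vectors) / pmax(eig$values, 1e-8))

  lm0 <- apply(Y, 2, function(v) rowsum(v, li)[, 1] / tabulate(li, n))
  Sb <- stats::cov(lm0)
  Sw <- stats::cov(Y - lm0[li, , drop = FALSE])
  # weakly-informative inverse-Wishart scales: light diagonal mass so the
  # posterior correlation is data-dominated even at small panel sizes
  nu0 <- 3
  S0g <- diag(pmax(diag(Sb), 1e-4 * sd_y^2) / 10, 2)
  S0e <- diag(pmax(diag(Sw), 1e-4 * sd_y^2) / 10, 2)

  total_iter <- spec$warmup + spec$samples
  scalar_names <- c("mu_1", "mu_2", "var_g_1", "var_g_2", "var_e_1",
                    "var_e_2", "r_g", "r_e")
  draws <- matrix(NA_real_, spec$chains * spec$samples, length(scalar_names),
                  dimnames = list(NULL, scalar_names))
  chain_id <- rep(seq_len(spec$chains), each = spec$samples)
  ls <- list(a1 = numeric(n), a2 = numeric(n))

  with_seed(derive_seed(spec$seed, "mcmc") + 1L, {
    for (ch in seq_len(spec$chains)) {
      mu <- m0 + rnorm(2, 0, 0.1 * sd_y)
      Sg <- Sb / 2 + diag(diag(Sb) / 4 + 1e-6, 2)
      Se <- Sw + diag(1e-6, 2)
      a <- matrix(0, n, 2)
      w <- rep(1, n_obs)
      for (it in seq_len(total_iter)) {
        Sei <- solve(Se)
        if (student) {
          R <- Y - rep(mu, each = n_obs) - a[li, , drop = FALSE]
          q <- rowSums((R %*% Sei) * R)
          w <- rgamma(n_obs, shape = (nu_t_fixed + 2) / 2,
                      rate = (nu_t_fixed + q) / 2)
        }
        # additive pairs: joint 2n-dimensional normal
        Wi <- rowsum(w, li)[, 1]
        S <- apply(Y - rep(mu, each = n_obs), 2,
                   function(v) rowsum(w * v, li)[, 1])
        U_lin <- as.vector(S %*% Sei) # stacked by trait blocks
        P <- kronecker(solve(Sg), Kinv) + kronecker(Sei, diag(Wi, n))
        Uc <- chol(P)
        m_a <- backsolve(Uc, forwardsolve(t(Uc), U_lin))
        av <- m_a + backsolve(Uc, rnorm(2 * n))
        a <- matrix(av, n, 2)
        # trait means
        E <- Y - a[li, , drop = FALSE]
        Pmu <- sum(w) * Sei + diag(1 / V0, 2)
        mmu <- solve(Pmu, Sei %*% colSums(w * E) + m0 / V0)
        mu <- as.vector(mmu + backsolve(chol(Pmu), rnorm(2)))
        # genetic covariance
        quad <- t(a) %*% Kinv %*% a
        Sg <- rinvwishart(nu0 + n, S0g + (quad + t(quad)) / 2)
        # environmental covariance
        R <- E - rep(mu, each = n_obs)
        Sr <- crossprod(R * sqrt(w))
        Se <- rinvwishart(nu0 + n_obs, S0e + (Sr + t(Sr)) / 2)
        if (it > spec$warmup) {
          k <- (ch - 1L) * spec$samples + (it - spec$warmup)
          draws[k, ] <- c(
            mu, diag(Sg), diag(Se),
            Sg[1, 2] / sqrt(Sg[1, 1] * Sg[2, 2]),
            Se[1, 2] / sqrt(Se[1, 1] * Se[2, 2])
          )
          ls$a1 <- ls$a1 + a[, 1]
          ls$a2 <- ls$a2 + a[, 2]
        }
      }
    }
  })

  diagnostics <- scalar_diagnostics(draws, chain_id, spec)
  draws_tbl <- tibble::add_column(
    as_tibble(as.data.frame(draws)),
    chain = chain_id,
    iter = rep(seq_len(spec$samples), spec$chains),
    .before = 1
  )
  list(
    draws = draws_tbl, line_sums = ls, n_kept = spec$chains * spec$samples,
    diagnostics = diagnostics,
    converged = all(diagnostics$rhat <= spec$rhat_threshold, na.rm = TRUE)
  )
}
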