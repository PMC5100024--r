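#' Fit the single-trait hierarchical genetic model
#'
#' Bayesian variance-component model for replicated phenotypes of inbred
#' lines with genomic relationship information:
#' \deqn{y_{ir} = \mu + a_i + d_i + \varepsilon_{ir}}
#' with additive values `a ~ MVN(0, s2_a K)`, non-additive line deviations
#' `d ~ MVN(0, s2_d I)`, and errors from a Gaussian or Student-t family with
#' line-specific variances `s2_e,i` drawn hierarchically around a common
#' scale (scaled-inverse-chi-square with `line_var_df` degrees of freedom).
#' Sampling is by a conjugate Gibbs sweep; Student-t errors use the standard
#' Gamma scale-mixture augmentation with the degrees of freedom updated by a
#' random-walk Metropolis step under a shifted-Exponential prior on `nu - 2`.
#'
#' Derived per draw: narrow-sense heritability
#' `h2 = s2_a / (s2_a + s2_d + mean_i(s2_e,i))`, broad-sense
#' `H2 = (s2_a + s2_d) / (s2_a + s2_d + mean_i(s2_e,i))`, per-line GEBV
#' (posterior draw of `a_i`), line mean (`mu + a_i + d_i`) and line CV
#' (`sigma_e,i / |line mean_i|`, flagged undefined when the line mean is
#' within 1e-8 of zero).
#'
#' @param pheno Long-format phenotype tibble (`line`, `replicate`, `trait`,
#'   `value`), e.g. from [simulate_phenotypes()] or [read_phenotypes()].
#' @param grm A [grm] covering every line in `pheno`.
#' @param trait Trait to fit; may be omitted when `pheno` holds one trait.
#' @param spec A [model_spec].
#' @return An `nsc_fit` object with elements `draws` (tibble: chain, iter and
#'   the scalar parameters), `lines` (tibble of per-line posterior summaries:
#'   GEBV, line mean, error scale, CV), `diagnostics` (split-R-hat and ESS per
#'   scalar), plus the call metadata. Methods: [summarize_posterior()],
#'   `tidy()`, `glance()`, `autoplot()`.
#' @examples
#' g <- simulate_genotypes(15, 80, seed = 1)
#' ph <- simulate_phenotypes(g, pheno_sim_config(n_reps = 4), seed = 2)
#' fit <- fit_single_trait(ph, compute_grm(g),
#'   spec = model_spec(chains = 2, warmup = 50, samples = 100)
#' )
#' glance(fit)
#' @export
fit_single_trait <- function(pheno, grm, trait = NULL, spec = model_spec()) {
  assert_that(inherits(grm, "grm"), "`grm` must be a grm object")
  assert_that(inherits(spec, "model_spec"), "`spec` must be a model_spec")
  pheno <- check_pheno(pheno)
  traits <- unique(pheno$trait)
  if (is.null(trait)) {
    assert_that(length(traits) == 1L,
                "`trait` must be given when multiple traits are present")
    trait <- traits
  }
  assert_that(trait %in% traits, sprintf("trait '%s' not present", trait))
  dat <- dplyr::filter(pheno, .data$trait == !!trait)
  miss <- setdiff(unique(dat$line), grm$line_ids)
  if (length(miss) > 0) {
    abort(sprintf("lines absent from the GRM: %s",
                  paste(miss, collapse = ", ")))
  }
  lines <- grm$line_ids[grm$line_ids %in% dat$line]
  li <- match(dat$line, lines)
  y <- dat$value
  n <- length(lines)
  reps <- tabulate(li, n)
  assert_that(any(reps >= 2L), "at least one line needs >= 2 replicates")
  K <- grm$K[lines, lines, drop = FALSE]

  res <- gibbs_single(y, li, n, K, spec)
  check_convergence(res, spec)

  lines_tbl <- tibble(
    line = lines,
    n_reps = reps,
    gebv = res$line_sums$a / res$n_kept,
    line_mean = res$line_sums$lm / res$n_kept,
    error_scale = res$line_sums$se / res$n_kept,
    cv = ifelse(res$line_sums$cv_n > 0,
                res$line_sums$cv / res$line_sums$cv_n, NA_real_)
  )
  structure(
    list(
      trait = trait, draws = res$draws, lines = lines_tbl,
      diagnostics = res$diagnostics, spec = spec, n_obs = length(y),
      converged = res$converged
    ),
    class = c("nsc_fit", "nsc_fit_single")
  )
}

check_pheno <- function(pheno) {
  assert_that(is.data.frame(pheno), "`pheno` must be a data frame")
  need <- c("line", "replicate", "trait", "value")
  missing_cols <- setdiff(need, names(pheno))
  assert_that(length(missing_cols) == 0,
              sprintf("phenotype table lacks column(s): %s",
                      paste(missing_cols, collapse = ", ")))
  as_tibble(pheno)
}

check_convergence <- function(res, spec) {
  bad <- res$diagnostics$rhat[is.finite(res$diagnostics$rhat)]
  if (length(bad) > 0 && max(bad) > spec$rhat_threshold) {
    warn(sprintf(
      "possible non-convergence: max split-R-hat %.3f > %.3f",
      max(bad), spec$rhat_threshold
    ))
  }
}

# ---- the Gibbs sampler -----------------------------------------------------

gibbs_single <- function(y, li, n, K, spec) {
  n_obs <- length(y)
  sd_y <- max(sd(y), 1e-6)
  A <- spec$prior_scale %||% (2 * sd_y)
  nu_t <- 3                # half-t df for genetic SD priors
  nu_h <- spec$line_var_df # line-variance hierarchy df
  m0 <- mean(y)
  V0 <- (10 * sd_y)^2
  student <- spec$error_family == "student_t"

  # eigen decomposition of K (jittered); used both for the generalized
  # inverse and for the blocked additive/non-additive decomposition
  eig <- eigen(K + diag(1e-8, n), symmetric = TRUE)
  lam <- pmax(eig$values, 1e-10)
  V <- eig$vectors
  Kinv <- V %*% (t(V) / lam)

  # moment-based starting decomposition
  lm0 <- rowsum(y, li)[, 1] / tabulate(li, n)
  vb <- max(var(lm0), 1e-4 * sd_y^2)
  vw <- max(mean((y - lm0[li])^2), 1e-4 * sd_y^2)

  total_iter <- spec$warmup + spec$samples
  scalar_names <- c("mu", "var_additive", "var_nonadditive", "var_error",
                    "h2", "H2", if (student) "nu")
  draws <- matrix(NA_real_, spec$chains * spec$samples, length(scalar_names),
                  dimnames = list(NULL, scalar_names))
  chain_id <- rep(seq_len(spec$chains), each = spec$samples)
  ls <- list(a = numeric(n), lm = numeric(n), se = numeric(n),
             cv = numeric(n), cv_n = numeric(n))

  with_seed(derive_seed(spec$seed, "mcmc"), {
    for (ch in seq_len(spec$chains)) {
      jit <- function(v) v * exp(rnorm(1, 0, 0.3))
      mu <- m0 + rnorm(1, 0, 0.1 * sd_y)
      s2a <- jit(vb / 2); s2d <- if (spec$nonadditive) jit(vb / 2) else 0
      s2e <- jit(vw); s2ei <- rep(s2e, n)
      a <- numeric(n); d <- numeric(n)
      xi_a <- 1; xi_d <- 1
      nu <- 4
      w <- rep(1, n_obs)
      for (it in seq_len(total_iter)) {
        # t-augmentation weights
        if (student) {
          r <- y - mu - a[li] - d[li]
          w <- rgamma(n_obs, shape = (nu + 1) / 2,
                      rate = (nu + r^2 / s2ei[li]) / 2)
        }
        tw <- w / s2ei[li]
        # joint blocked draw of (g, mu) with g = a + d the total line effect
        # (updating them separately mixes poorly: only their sum is
        # data-determined), followed by an exact decomposition of g into
        # additive and non-additive parts in the eigenbasis of K
        t_i <- rowsum(tw, li)[, 1]
        gvar <- if (spec$nonadditive) s2a * lam + s2d else s2a * lam
        P <- matrix(0, n + 1L, n + 1L)
        P[1:n, 1:n] <- V %*% (t(V) / gvar)
        diag(P)[1:n] <- diag(P)[1:n] + t_i
        P[1:n, n + 1L] <- t_i
        P[n + 1L, 1:n] <- t_i
        P[n + 1L, n + 1L] <- sum(tw) + 1 / V0
        u <- c(rowsum(tw * y, li)[, 1], sum(tw * y) + m0 / V0)
        U <- chol(P)
        x <- backsolve(U, forwardsolve(t(U), u) + rnorm(n + 1L))
        g <- x[1:n]
        mu <- x[n + 1L]
        if (spec$nonadditive) {
          gs <- crossprod(V, g)[, 1]
          # marginal Metropolis refresh of the variance split given g
          # (the latent split is integrated out analytically)
          vs <- update_var_split(s2a, s2d, gs, lam, nu_t, xi_a, xi_d)
          s2a <- vs[1]; s2d <- vs[2]
          prec <- 1 / (s2a * lam) + 1 / s2d
          as <- rnorm(n, (gs / s2d) / prec, sqrt(1 / prec))
          a <- as.vector(V %*% as)
          d <- g - a
        } else {
          a <- g
        }
        # genetic variance components: with the non-additive term present the
        # split was already refreshed by the marginal Metropolis move above
        # (conditioning on the realized split would re-tighten the coupling);
        # only the mixture hyper-parameters need conjugate refreshes there
        if (spec$nonadditive) {
          xi_a <- update_huang_wand_xi(s2a, nu_t, A)
          xi_d <- update_huang_wand_xi(s2d, nu_t, A)
        } else {
          quad_a <- sum(a * (Kinv %*% a))
          s2a <- 1 / rgamma(1, shape = (nu_t + n) / 2,
                            rate = nu_t / xi_a + quad_a / 2)
          xi_a <- update_huang_wand_xi(s2a, nu_t, A)
        }
        # line-specific error variances around the common scale
        r <- y - mu - a[li] - d[li]
        sse <- rowsum(w * r^2, li)[, 1]
        n_i <- tabulate(li, n)
        s2ei <- 1 / rgamma(n, shape = (nu_h + n_i) / 2,
                           rate = (nu_h * s2e + sse) / 2)
        # common error scale: half-Normal(A) prior on sigma_e, conjugate Gamma
        s2e <- rgamma(1, shape = 0.5 + n * nu_h / 2,
                      rate = 1 / (2 * A^2) + (nu_h / 2) * sum(1 / s2ei))
        # Student-t df: RW Metropolis on log(nu - 2)
        if (student) {
          nu <- update_t_df(nu, w)
        }
        if (it > spec$warmup) {
          k <- (ch - 1L) * spec$samples + (it - spec$warmup)
          s2e_bar <- mean(s2ei)
          tot <- s2a + s2d + s2e_bar
          row <- c(mu, s2a, s2d, s2e_bar, s2a / tot, (s2a + s2d) / tot,
                   if (student) nu)
          draws[k, ] <- row
          lm_i <- mu + a + d
          ls$a <- ls$a + a
          ls$lm <- ls$lm + lm_i
          ls$se <- ls$se + sqrt(s2ei)
          def <- abs(lm_i) >= 1e-8
          ls$cv[def] <- ls$cv[def] + sqrt(s2ei[def]) / abs(lm_i[def])
          ls$cv_n <- ls$cv_n + def
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

# Random-walk Metropolis on (log s2a, log s2d) targeting the marginal
# p(s2a, s2d | g) with the additive/non-additive split integrated out:
# g* ~ N(0, s2a * lam + s2d) per eigencomponent, times the conditional
# inverse-gamma priors of the Huang-Wand mixture.
update_var_split <- function(s2a, s2d, gs, lam, nu_t, xi_a, xi_d,
                             steps = 16L) {
  logpost <- function(va, vd) {
    v <- va * lam + vd
    -0.5 * sum(log(v) + gs^2 / v) -
      (nu_t / 2 + 1) * log(va) - (nu_t / xi_a) / va -
      (nu_t / 2 + 1) * log(vd) - (nu_t / xi_d) / vd +
      log(va) + log(vd) # Jacobian of the log transform
  }
  lp <- logpost(s2a, s2d)
  for (s in seq_len(steps)) {
    kind <- s %% 3L
    if (kind == 0L) {
      # joint rescale (moves the total)
      f <- exp(rnorm(1, 0, 0.3))
      ca <- s2a * f; cd <- s2d * f
    } else if (kind == 1L) {
      # trade variance between components: the weakly identified direction
      tot <- s2a + s2d
      phi <- stats::plogis(stats::qlogis(s2a / tot) + rnorm(1, 0, 1.2))
      ca <- tot * phi; cd <- tot * (1 - phi)
    } else {
      ca <- s2a * exp(rnorm(1, 0, 0.3))
      cd <- s2d * exp(rnorm(1, 0, 0.3))
    }
    # kinds 0/2 are symmetric random walks in (log va, log vd); the trade
    # move is a symmetric walk in logit(phi) at fixed total, whose Jacobian
    # correction log(phi (1 - phi)) is already carried by the log-va + log-vd
    # terms of `logpost` (the totals cancel in the ratio)
    lp_c <- logpost(ca, cd)
    if (log(runif(1)) < lp_c - lp) {
      s2a <- ca; s2d <- cd; lp <- lp_c
    }
  }
  c(s2a, s2d)
}

update_t_df <- function(nu, w, prior_rate = 0.1, prop_sd = 0.3) {
  loglik <- function(v) {
    length(w) * (v / 2 * log(v / 2) - lgamma(v / 2)) +
      (v / 2 - 1) * sum(log(w)) - v / 2 * sum(w)
  }
  lp <- function(v) loglik(v) - prior_rate * (v - 2) + log(v - 2)
  z <- log(nu - 2) + rnorm(1, 0, prop_sd)
  cand <- 2 + exp(z)
  if (log(runif(1)) < lp(cand) - lp(nu)) cand else nu
}

scalar_diagnostics <- function(draws, chain_id, spec) {
  purrr::map_dfr(colnames(draws), function(p) {
    m <- matrix(draws[, p], ncol = spec$chains)
    tibble(parameter = p, rhat = split_rhat(m), ess = ess_basic(m))
  })
}

#' @export
print.nsc_fit <- function(x, ...) {
  kind <- if (inherits(x, "nsc_fit_bivariate")) "bivariate" else "single-trait"
  cat(sprintf(
    "<nsc_fit> %s model, trait(s): %s\n  %d obs, %d lines, %d chains x %d draws (%s errors)\n",
    kind, paste(x$trait, collapse = " + "), x$n_obs, nrow(x$lines),
    x$spec$chains, x$spec$samples, x$spec$error_family
  ))
  if (!isTRUE(x$converged)) cat("  ! flagged: split-R-hat above threshold\n")
  print(summarize_posterior(x))
  invisible(x)
}
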