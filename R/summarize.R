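#' Summarize posterior draws
#'
#' Equal-tailed credible summaries per scalar parameter of a fitted model (or
#' of a raw draws table): posterior mean (point), lower/upper bounds at the
#' requested level, split-R-hat and effective sample size.
#'
#' @param posterior An `nsc_fit` object, or a tibble of draws with `chain` and
#'   `iter` columns followed by parameter columns.
#' @param level Credible level for the equal-tailed interval (default 0.9).
#' @return Tibble with columns `parameter`, `point`, `lower`, `upper`,
#'   `rhat`, `ess`.
#' @examples
#' d <- tibble::tibble(chain = rep(1:2, each = 50), iter = rep(1:50, 2),
#'                     theta = rnorm(100))
#' summarize_posterior(d)
#' @export
summarize_posterior <- function(posterior, level = 0.9) {
  assert_that(is_number(level) && level > 0 && level < 1,
              "`level` must be in (0, 1)")
  draws <- if (inherits(posterior, "nsc_fit")) posterior$draws else posterior
  assert_that(is.data.frame(draws) && nrow(draws) > 0, "no draws present")
  pars <- setdiff(names(draws), c("chain", "iter"))
  assert_that(length(pars) > 0, "no parameter columns present")
  chains <- if ("chain" %in% names(draws)) draws$chain else rep(1L, nrow(draws))
  purrr::map_dfr(pars, function(p) {
    x <- draws[[p]]
    ci <- cred_interval(x, level)
    m <- matrix(NA_real_, max(table(chains)), length(unique(chains)))
    for (j in seq_along(unique(chains))) {
      xj <- x[chains == unique(chains)[j]]
      m[seq_along(xj), j] <- xj
    }
    tibble(
      parameter = p, point = mean(x), lower = ci[1], upper = ci[2],
      rhat = split_rhat(m[stats::complete.cases(m), , drop = FALSE]),
      ess = ess_basic(m[stats::complete.cases(m), , drop = FALSE])
    )
  })
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy posterior summaries of a fitted genetic model
#'
#' @param x An `nsc_fit`.
#' @param level Credible level (default 0.9).
#' @param ... Unused.
#' @return One row per scalar parameter (see [summarize_posterior()]).
#' @method tidy nsc_fit
#' @export
tidy.nsc_fit <- function(x, level = 0.9, ...) {
  summarize_posterior(x, level = level)
}

#' One-row model overview for a fitted genetic model
#'
#' @param x An `nsc_fit`.
#' @param ... Unused.
#' @return Tibble with counts, point heritabilities or correlations, and the
#'   convergence flag.
#' @method glance nsc_fit
#' @export
glance.nsc_fit <- function(x, ...) {
  s <- summarize_posterior(x)
  pick <- function(p) if (p %in% s$parameter) s$point[s$parameter == p] else NA_real_
  tibble(
    traits = paste(x$trait, collapse = "+"),
    n_obs = x$n_obs, n_lines = nrow(x$lines),
    h2 = pick("h2"), H2 = pick("H2"),
    r_g = pick("r_g"), r_e = pick("r_e"),
    max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
    converged = x$converged
  )
}

#' Posterior interval plot for a fitted genetic model
#'
#' @param object An `nsc_fit`.
#' @param level Credible level (default 0.9).
#' @param ... Unused.
#' @return A ggplot of point estimates with credible intervals.
#' @method autoplot nsc_fit
#' @export
autoplot.nsc_fit <- function(object, level = 0.9, ...) {
  s <- summarize_posterior(object, level = level)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$point, y = .data$parameter)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lower,
                                          xmax = .data$upper)) +
    ggplot2::labs(
      x = sprintf("posterior point estimate (%d%% credible interval)",
                  round(100 * level)),
      y = NULL,
      title = paste("Posterior summaries:", paste(object$trait, collapse = " + "))
    ) +
    ggplot2::theme_minimal()
}

#' Correlation triplet table in the layout of a pairwise correlation matrix
#'
#' Formats bivariate fits as (upper / point / lower) credible triplets, the
#' conventional presentation for genetic and environmental correlations.
#'
#' @param fits A list of `nsc_fit_bivariate` objects.
#' @param which `"r_g"` or `"r_e"`.
#' @param level Credible level (default 0.9).
#' @return Tibble: `trait_1`, `trait_2`, `lower`, `point`, `upper`.
#' @export
correlation_triplets <- function(fits, which = c("r_g", "r_e"), level = 0.9) {
  which <- match.arg(which)
  if (inherits(fits, "nsc_fit")) fits <- list(fits)
  purrr::map_dfr(fits, function(f) {
    assert_that(inherits(f, "nsc_fit_bivariate"),
                "`fits` must contain bivariate fits")
    s <- summarize_posterior(f, level = level)
    row <- s[s$parameter == which, ]
    tibble(
      trait_1 = f$trait[1], trait_2 = f$trait[2],
      lower = row$lower, point = row$point, upper = row$upper
    )
  })
}
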