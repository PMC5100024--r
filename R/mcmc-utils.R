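# MCMC diagnostics: split-Rhat and a Geyer-style effective sample size.

# draws: iterations x chains matrix of one scalar parameter
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  if (n < 4L) return(NA_real_)
  half <- floor(n / 2)
  sub <- cbind(draws[seq_len(half), , drop = FALSE],
               draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, var)
  W <- mean(vars)
  B <- half * var(means)
  if (!is.finite(W) || W <= 0) {
    # constant chains: converged by construction
    return(if (isTRUE(all.equal(B, 0)) || !is.finite(B)) 1 else Inf)
  }
  var_plus <- (half - 1) / half * W + B / half
  sqrt(var_plus / W)
}

ess_basic <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  m <- ncol(draws)
  if (n < 4L) return(NA_real_)
  W <- mean(apply(draws, 2, var))
  if (!is.finite(W) || W <= 0) return(n * m)
  # chain-averaged autocorrelations, Geyer initial-positive-sequence truncation
  max_lag <- min(n - 2L, 200L)
  rho <- rowMeans(vapply(seq_len(m), function(j) {
    ac <- stats::acf(draws[, j], lag.max = max_lag, plot = FALSE,
                     demean = TRUE)$acf[-1]
    as.numeric(ac)
  }, numeric(max_lag)))
  s <- 0
  k <- 1L
  while (k < max_lag) {
    pair <- rho[k] + rho[k + 1L]
    if (!is.finite(pair) || pair <= 0) break
    s <- s + pair
    k <- k + 2L
  }
  max(min(n * m / (1 + 2 * s), n * m), 1)
}

# Sample Sigma ~ InverseWishart(df, S) (S the scale matrix of the density
# proportional to |Sigma|^{-(df + p + 1)/2} exp(-tr(S Sigma^{-1})/2)).
rinvwishart <- function(df, S) {
  p <- nrow(S)
  W <- rWishart(1L, df = df, Sigma = solve(S))[, , 1L]
  solve(W)
}

# Half-t(nu, A) prior on a standard deviation via the Huang-Wand
# inverse-gamma mixture: sigma2 | xi ~ IG(nu/2, nu/xi), xi ~ IG(1/2, 1/A^2).
# Conditionals used inside the Gibbs sweeps:
update_huang_wand_xi <- function(sigma2, nu, A) {
  1 / rgamma(1L, shape = (nu + 1) / 2, rate = nu / sigma2 + 1 / A^2)
}
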