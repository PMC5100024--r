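#' Restrict a spectra set to a wavenumber range
#'
#' Keeps grid points with `low <= wavenumber <= high` (order preserved); the
#' conventional working window for dried-plant NIR calibration is
#' 4000-9000 cm^-1.
#'
#' @param spectra A [spectra_set].
#' @param low,high Inclusive bounds (cm^-1).
#' @return The restricted `spectra_set` (pretreatment step recorded).
#' @examples
#' sp <- spectra_set(c(3500, 4000, 5000, 9500), matrix(1:8, 2))
#' restrict_range(sp)$wavenumbers
#' @export
restrict_range <- function(spectra, low = 4000, high = 9000) {
  assert_that(inherits(spectra, "spectra_set"), "`spectra` must be a spectra_set")
  keep <- spectra$wavenumbers >= low & spectra$wavenumbers <= high
  if (!any(keep)) abort("no wavenumbers fall inside the requested range")
  step <- sprintf("restrict[%g,%g]", low, high)
  pre <- spectra$pretreatment
  if (!identical(utils::tail(pre, 1), step)) pre <- c(pre, step)
  spectra_set(
    spectra$wavenumbers[keep],
    spectra$absorbance[, keep, drop = FALSE],
    sample_ids = spectra$sample_ids,
    constituents = spectra$constituents,
    pretreatment = pre
  )
}

#' Standard normal variate (SNV) scatter correction
#'
#' Each spectrum is independently centered to mean zero and scaled to unit
#' standard deviation (n-1 denominator), removing multiplicative scatter and
#' additive offset effects sample by sample.
#'
#' @param spectra A [spectra_set].
#' @return The SNV-corrected `spectra_set`.
#' @examples
#' sp <- spectra_set(1:3, matrix(c(1, 2, 3), 1))
#' snv(sp)$absorbance
#' @export
snv <- function(spectra) {
  assert_that(inherits(spectra, "spectra_set"), "`spectra` must be a spectra_set")
  A <- spectra$absorbance
  s <- apply(A, 1, sd)
  flat <- which(s == 0 | !is.finite(s))
  if (length(flat) > 0) {
    abort(sprintf("constant spectrum; SNV undefined for sample(s): %s",
                  paste(spectra$sample_ids[flat], collapse = ", ")))
  }
  A <- (A - rowMeans(A)) / s
  spectra_set(spectra$wavenumbers, A, sample_ids = spectra$sample_ids,
              constituents = spectra$constituents,
              pretreatment = c(spectra$pretreatment, "snv"))
}

#' Savitzky-Golay smoothing derivative
#'
#' Local least-squares polynomial filtering on a uniform grid (coefficients
#' from [signal::sgolay()]), returning the `deriv`-th derivative scaled by
#' the grid spacing. The half-window at each edge is dropped rather than
#' extrapolated, so the output grid shrinks by `window - 1` points.
#'
#' @param spectra A [spectra_set] on a uniformly spaced grid.
#' @param window Odd window length in points (default 25).
#' @param polyorder Polynomial order (default 2, must be < `window`).
#' @param deriv Derivative order (default 1, must be <= `polyorder`).
#' @return The filtered `spectra_set` on the trimmed grid.
#' @export
savgol_derivative <- function(spectra, window = 25L, polyorder = 2L,
                              deriv = 1L) {
  assert_that(inherits(spectra, "spectra_set"), "`spectra` must be a spectra_set")
  assert_that(is_count(window, 3L) && window %% 2 == 1,
              "`window` must be an odd integer >= 3")
  assert_that(window <= length(spectra$wavenumbers),
              "`window` exceeds the grid length")
  assert_that(is_count(polyorder, 0L) && polyorder < window,
              "`polyorder` must be < window")
  assert_that(is_count(deriv, 0L) && deriv <= polyorder,
              "`deriv` must be <= polyorder")
  h <- diff(spectra$wavenumbers)
  if (max(h) - min(h) > 1e-6 * mean(h)) {
    abort("Savitzky-Golay filtering requires a uniformly spaced grid")
  }
  spacing <- mean(h)
  fc <- signal::sgolay(p = polyorder, n = window, m = deriv, ts = spacing)
  half <- (window - 1L) / 2L
  # central-row coefficients give the interior (fully windowed) estimates
  centre <- fc[half + 1L, ]
  p <- length(spectra$wavenumbers)
  idx <- (half + 1L):(p - half)
  A <- spectra$absorbance
  out <- matrix(NA_real_, nrow(A), length(idx))
  for (k in seq_along(idx)) {
    cols <- (idx[k] - half):(idx[k] + half)
    out[, k] <- A[, cols, drop = FALSE] %*% centre
  }
  step <- sprintf("savgol[w=%d,p=%d,d=%d]", window, polyorder, deriv)
  spectra_set(spectra$wavenumbers[idx], out,
              sample_ids = spectra$sample_ids,
              constituents = spectra$constituents,
              pretreatment = c(spectra$pretreatment, step))
}
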