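#' Configuration for the synthetic FT-NIR spectra generator
#'
#' Spectra are generated as scatter- and baseline-corrupted linear mixtures
#' of pure-component absorption profiles on a fixed wavenumber grid:
#' \deqn{A_s(\lambda) = m_s \left( bg(\lambda) + \sum_c conc_{sc} \,
#'   pure_c(\lambda) \right) + b_{0s} + b_{1s} \lambda + noise}
#' with a log-normal multiplicative scatter term `m_s`, per-sample linear
#' baselines, i.i.d. Gaussian detector noise, and pure-component profiles
#' built from Gaussian bands. `bg` is a constant matrix background shared by
#' all samples — the dominant cell-wall absorbance of dried ground stem
#' tissue against which the constituent signal is a relative variation (this
#' is what makes per-spectrum SNV scaling informative rather than
#' destructive). Paired "wet-chemistry" values are the true concentrations
#' plus measurement error, optionally in technical triplicate for the
#' reference-uncertainty estimator.
#'
#' @param wavenumbers Grid (default 3300 to 12000 cm^-1 in 4 cm^-1 steps,
#'   FT-NIR-like density at desk scale).
#' @param bands Named list, one element per constituent, each a data frame
#'   with columns `center`, `width`, `height` of Gaussian bands (widths > 0).
#' @param background Band data frame (`center`, `width`, `height`) of the
#'   constant matrix component, or `NULL` to disable (pure linear mixture).
#' @param scatter_sdlog Log-SD of the multiplicative scatter term (0 disables).
#' @param baseline_offset_sd,baseline_slope_sd SDs of the per-sample baseline
#'   offset and slope (0 disables).
#' @param noise_sd Detector noise SD (>= 0).
#' @param wetchem_error_sd SD of the wet-chemistry measurement error.
#' @param wetchem_replicates Technical replicates per sample in the paired
#'   wet-chem table (default 1; use 3 for triplicates).
#' @return A `spectra_sim_config` list.
#' @export
spectra_sim_config <- function(wavenumbers = seq(3300, 12000, by = 4),
                               bands = default_nsc_bands(),
                               background = default_matrix_background(),
                               scatter_sdlog = 0.1,
                               baseline_offset_sd = 0.02,
                               baseline_slope_sd = 2e-6,
                               noise_sd = 1e-3,
                               wetchem_error_sd = 0.005,
                               wetchem_replicates = 1L) {
  assert_that(all(diff(wavenumbers) > 0), "grid must be strictly increasing")
  assert_that(is.list(bands) && length(bands) >= 1 &&
                !is.null(names(bands)), "`bands` must be a named list")
  for (b in bands) {
    assert_that(all(c("center", "width", "height") %in% names(b)),
                "each band set needs center, width, height")
    assert_that(all(b$width > 0), "band widths must be > 0")
  }
  assert_that(noise_sd >= 0, "`noise_sd` must be >= 0")
  if (!is.null(background)) {
    assert_that(all(c("center", "width", "height") %in% names(background)) &&
                  all(background$width > 0),
                "`background` needs center, width (> 0), height columns")
  }
  structure(
    list(
      wavenumbers = as.numeric(wavenumbers), bands = bands,
      background = background,
      scatter_sdlog = scatter_sdlog,
      baseline_offset_sd = baseline_offset_sd,
      baseline_slope_sd = baseline_slope_sd,
      noise_sd = noise_sd, wetchem_error_sd = wetchem_error_sd,
      wetchem_replicates = as.integer(wetchem_replicates)
    ),
    class = "spectra_sim_config"
  )
}

#' Default pure-component band sets for starch and sucrose
#'
#' Gaussian band positions loosely placed at carbohydrate O-H/C-H overtone
#' and combination regions inside the working 4000-9000 cm^-1 window (plus
#' flanking bands outside it), distinct enough between the two constituents
#' that a linear calibration can separate them.
#'
#' @return Named list of band data frames.
#' @export
default_nsc_bands <- function() {
  list(
    starch = data.frame(
      center = c(4300, 4750, 5200, 5800, 6900, 8300, 10200),
      width = c(120, 150, 180, 200, 250, 300, 400),
      height = c(1.0, 0.7, 0.9, 0.4, 0.6, 0.25, 0.1)
    ),
    sucrose = data.frame(
      center = c(4400, 4900, 5600, 6300, 7100, 8700, 11000),
      width = c(110, 140, 190, 220, 260, 320, 400),
      height = c(0.8, 1.0, 0.5, 0.7, 0.35, 0.2, 0.1)
    )
  )
}

#' Default matrix background bands
#'
#' Broad cell-wall-like absorbance envelope of dried ground stem tissue:
#' large smooth bands spanning the working window, amplitude well above the
#' constituent signal, identical for every sample.
#'
#' @return Band data frame (`center`, `width`, `height`).
#' @export
default_matrix_background <- function() {
  data.frame(
    center = c(4200, 4800, 5600, 6800, 8500, 10400),
    width = c(350, 420, 500, 600, 800, 900),
    height = c(4.5, 4.0, 3.5, 2.75, 1.75, 1.0)
  )
}

gaussian_band_profile <- function(wavenumbers, b) {
  rowSums(vapply(seq_len(nrow(b)), function(k) {
    b$height[k] * exp(-0.5 * ((wavenumbers - b$center[k]) / b$width[k])^2)
  }, numeric(length(wavenumbers))))
}

pure_profiles <- function(config) {
  vapply(config$bands, function(b) {
    gaussian_band_profile(config$wavenumbers, b)
  }, numeric(length(config$wavenumbers)))
}

#' Simulate FT-NIR-like spectra from constituent concentrations
#'
#' @param concentrations Matrix or data frame (samples x constituents,
#'   non-negative fractions w/w); column names must match the configured band
#'   sets.
#' @param config A [spectra_sim_config].
#' @param seed Integer seed.
#' @return A `spectra_set` whose `constituents` tibble holds the noisy paired
#'   wet-chemistry values (long over `replicate` when
#'   `wetchem_replicates > 1`). True concentrations are attached as
#'   `attr(, "truth")`.
#' @examples
#' conc <- cbind(starch = runif(5, 0, 0.4), sucrose = runif(5, 0, 0.2))
#' sp <- simulate_spectra(conc, seed = 1)
#' sp
#' @export
simulate_spectra <- function(concentrations, config = spectra_sim_config(),
                             seed = 1L) {
  assert_that(inherits(config, "spectra_sim_config"),
              "`config` must come from spectra_sim_config()")
  conc <- as.matrix(concentrations)
  assert_that(all(conc >= 0), "concentrations must be non-negative")
  if (is.null(colnames(conc))) {
    assert_that(ncol(conc) == length(config$bands),
                "constituent count does not match the configured band sets")
    colnames(conc) <- names(config$bands)
  }
  assert_that(setequal(colnames(conc), names(config$bands)),
              "constituent count/names do not match the configured band sets")
  conc <- conc[, names(config$bands), drop = FALSE]
  n <- nrow(conc)
  grid <- config$wavenumbers
  pure <- pure_profiles(config) # grid x constituents
  bg <- if (is.null(config$background)) {
    numeric(length(grid))
  } else {
    gaussian_band_profile(grid, config$background)
  }
  with_seed(seed, {
    clean <- conc %*% t(pure) + rep(1, n) %o% bg # samples x grid
    m <- if (config$scatter_sdlog > 0) {
      exp(rnorm(n, 0, config$scatter_sdlog))
    } else {
      rep(1, n)
    }
    b0 <- rnorm(n, 0, config$baseline_offset_sd)
    b1 <- rnorm(n, 0, config$baseline_slope_sd)
    A <- clean * m + outer(b0, rep(1, length(grid))) + outer(b1, grid)
    if (config$noise_sd > 0) {
      A <- A + matrix(rnorm(n * length(grid), 0, config$noise_sd),
                      n, length(grid))
    }
    ids <- sprintf("smp%03d", seq_len(n))
    wet <- tidyr::expand_grid(
      sample_id = ids,
      replicate = seq_len(config$wetchem_replicates)
    )
    true_tbl <- tibble::add_column(as_tibble(as.data.frame(conc)),
                                   sample_id = ids, .before = 1)
    wet <- dplyr::left_join(wet, true_tbl, by = "sample_id")
    for (cc in names(config$bands)) {
      wet[[cc]] <- pmax(
        wet[[cc]] + rnorm(nrow(wet), 0, config$wetchem_error_sd), 0
      )
    }
    out <- spectra_set(grid, A, sample_ids = ids, constituents = wet)
    attr(out, "truth") <- true_tbl
    out
  })
}
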