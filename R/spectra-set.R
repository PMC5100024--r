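#' Construct a spectra set
#'
#' Container for FT-NIR-like absorbance data: a strictly increasing
#' wavenumber grid (cm^-1), a samples x wavenumbers absorbance matrix, and
#' optionally paired wet-chemistry constituent values (fractions w/w).
#'
#' @param wavenumbers Strictly increasing numeric grid (cm^-1).
#' @param absorbance Matrix, samples in rows, one column per grid point.
#' @param sample_ids Optional sample identifiers.
#' @param constituents Optional tibble/data frame with `sample_id` plus
#'   constituent columns (e.g. `starch`, `sucrose`), fractions in `[0, 1]`.
#' @param pretreatment Character vector describing pretreatment steps already
#'   applied (used to guard model/prediction consistency).
#' @return A `spectra_set` object.
#' @export
spectra_set <- function(wavenumbers, absorbance, sample_ids = NULL,
                        constituents = NULL, pretreatment = character()) {
  assert_that(is.numeric(wavenumbers) && length(wavenumbers) >= 2,
              "`wavenumbers` must be a numeric grid")
  assert_that(all(diff(wavenumbers) > 0),
              "`wavenumbers` must be strictly increasing")
  absorbance <- as.matrix(absorbance)
  assert_that(ncol(absorbance) == length(wavenumbers),
              "`absorbance` must have one column per wavenumber")
  sample_ids <- sample_ids %||% rownames(absorbance) %||%
    sprintf("smp%03d", seq_len(nrow(absorbance)))
  rownames(absorbance) <- sample_ids
  if (!is.null(constituents)) {
    constituents <- as_tibble(constituents)
    assert_that("sample_id" %in% names(constituents),
                "`constituents` needs a sample_id column")
    num <- dplyr::select(constituents,
                         -dplyr::any_of(c("sample_id", "replicate")))
    assert_that(all(vapply(num, is.numeric, logical(1))),
                "constituent columns must be numeric")
    assert_that(all(as.matrix(num) >= 0 & as.matrix(num) <= 1, na.rm = TRUE),
                "constituent fractions must lie in [0, 1]")
  }
  structure(
    list(wavenumbers = as.numeric(wavenumbers), absorbance = absorbance,
         sample_ids = sample_ids, constituents = constituents,
         pretreatment = pretreatment),
    class = "spectra_set"
  )
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf(
    "<spectra_set> %d samples x %d wavenumbers (%.0f-%.0f cm^-1)%s\n",
    nrow(x$absorbance), length(x$wavenumbers),
    min(x$wavenumbers), max(x$wavenumbers),
    if (length(x$pretreatment) > 0) {
      paste0("; pretreated: ", paste(x$pretreatment, collapse = " -> "))
    } else ""
  ))
  if (!is.null(x$constituents)) {
    cat(sprintf("  paired constituents: %s\n",
                paste(setdiff(names(x$constituents), "sample_id"),
                      collapse = ", ")))
  }
  invisible(x)
}

#' @method as_tibble spectra_set
#' @export
as_tibble.spectra_set <- function(x, ...) {
  tidyr::pivot_longer(
    tibble::add_column(as_tibble(as.data.frame(x$absorbance),
                                 .name_repair = "minimal"),
                       sample_id = x$sample_ids, .before = 1),
    cols = -"sample_id", names_to = "wavenumber", values_to = "absorbance"
  ) |>
    dplyr::mutate(wavenumber = rep(x$wavenumbers, nrow(x$absorbance)))
}

#' TNC from its constituent fractions
#'
#' Total non-structural carbohydrate as the sum of starch and sucrose, the
#' operational definition used throughout the stem-NSC workflow.
#'
#' @param starch,sucrose Non-negative numeric vectors (percent or fraction,
#'   either scale — the sum is returned on the same scale).
#' @return `starch + sucrose`.
#' @examples
#' tnc(10, 6.7)
#' @export
tnc <- function(starch, sucrose) {
  assert_that(all(starch >= 0, na.rm = TRUE) && all(sucrose >= 0, na.rm = TRUE),
              "constituent values must be >= 0")
  starch + sucrose
}
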