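#' Root mean squared error
#'
#' `sqrt(mean((predicted - reference)^2))`, the generalized error used for
#' calibration (RMSEC), full cross-validation (RMSECV) and independent
#' prediction (RMSEP).
#'
#' @param predicted,reference Equal-length, non-empty numeric vectors.
#' @return Non-negative scalar.
#' @examples
#' rmse(c(1, 2, 3), c(1, 2, 5))
#' @export
rmse <- function(predicted, reference) {
  assert_that(length(predicted) > 0, "empty input")
  assert_that(length(predicted) == length(reference),
              "`predicted` and `reference` must have equal length")
  sqrt(mean((predicted - reference)^2))
}

# R^2 about the reference mean of the evaluated set (1 - SSE/SST);
# squared-Pearson variant switchable for comparison with other software.
r_squared <- function(predicted, reference, method = c("sse", "pearson")) {
  method <- match.arg(method)
  if (method == "pearson") return(cor(predicted, reference)^2)
  1 - sum((reference - predicted)^2) / sum((reference - mean(reference))^2)
}

#' Flag calibration outliers by the 2 x RMSECV rule
#'
#' A calibration sample is an outlier when the absolute difference between
#' its fully cross-validated prediction and the wet-chemistry reference
#' exceeds twice the RMSECV of the initial model. Single pass, no iteration.
#' For multi-response (PLS2) models a sample is flagged when either response
#' exceeds twice its own RMSECV.
#'
#' @param cv_predictions Matrix (samples x responses) of leave-one-out
#'   predictions from the initial model.
#' @param reference Matrix of reference values, same shape.
#' @param rmsecv_initial Per-response RMSECV of the initial model.
#' @param ids Sample identifiers (default row numbers).
#' @return Character (or integer) vector of flagged ids (possibly empty).
#' @examples
#' detect_outliers(cbind(c(1.01, 1.05, 1.039)), cbind(c(1, 1, 1)), 0.02)
#' @export
detect_outliers <- function(cv_predictions, reference, rmsecv_initial,
                            ids = NULL) {
  P <- as.matrix(cv_predictions)
  R <- as.matrix(reference)
  assert_that(all(dim(P) == dim(R)), "prediction/reference shape mismatch")
  assert_that(length(rmsecv_initial) == ncol(P),
              "one RMSECV per response is required")
  ids <- ids %||% rownames(P) %||% seq_len(nrow(P))
  resid <- abs(P - R)
  flag <- rowSums(sweep(resid, 2, 2 * rmsecv_initial, `>`)) > 0
  ids[flag]
}

#' Reference-method uncertainty from technical replicates
#'
#' Twice the average within-sample standard deviation (n-1 denominator) of
#' replicated wet-chemistry determinations — the uncertainty floor against
#' which RMSEP is judged.
#'
#' @param triplicate_table Data frame with `sample_id` and a numeric `value`
#'   column (or pass the constituent column name via `value_col`).
#' @param value_col Name of the value column (default `"value"`).
#' @return `2 * mean(within-sample SD)` over samples with >= 2 replicates;
#'   samples with fewer are excluded with a warning.
#' @examples
#' tb <- data.frame(sample_id = rep(1:2, each = 3), value = rnorm(6))
#' reference_uncertainty(tb)
#' @export
reference_uncertainty <- function(triplicate_table, value_col = "value") {
  assert_that(is.data.frame(triplicate_table) &&
                all(c("sample_id", value_col) %in% names(triplicate_table)),
              "need columns sample_id and the value column")
  sds <- dplyr::summarise(
    dplyr::group_by(triplicate_table, .data$sample_id),
    n = dplyr::n(), s = sd(.data[[value_col]]), .groups = "drop"
  )
  drop <- sum(sds$n < 2)
  if (drop > 0) {
    warn(sprintf("%d sample(s) with < 2 replicates excluded", drop))
  }
  keep <- sds$s[sds$n >= 2]
  assert_that(length(keep) > 0, "no sample has >= 2 technical replicates")
  2 * mean(keep)
}

#' Run the full NIR calibration workflow
#'
#' End-to-end pipeline for one PLS model: restrict the wavenumber range,
#' SNV scatter correction, Savitzky-Golay first derivative, Kennard-Stone
#' split into calibration and validation sets, initial PLS fit with full
#' (leave-one-out) cross-validation, single-pass outlier exclusion by the
#' 2 x RMSECV rule, refit without outliers, and final evaluation on the
#' untouched validation set. The validation samples influence nothing before
#' that last step.
#'
#' @param spectra A [spectra_set] with paired `constituents`.
#' @param responses Constituent column(s) to model: one name gives a PLS-1
#'   model, two or more a PLS-2 model. Use `"TNC"` to model starch + sucrose
#'   as their sum.
#' @param n_components Component count of the final (and initial) model.
#' @param cal_size Calibration-set size for the Kennard-Stone split.
#' @param range Wavenumber window, default `c(4000, 9000)` cm^-1.
#' @param window,polyorder,deriv Savitzky-Golay settings (default 25/2/1).
#' @param max_components Upper limit for the reported RMSECV/RMSEP curves
#'   (default `n_components + 5`).
#' @return A `calibration_report`: counts, component number, per-response R^2
#'   for calibration / cross-validation / independent validation, RMSEC /
#'   RMSECV / RMSEP, reference uncertainty (when replicated wet chemistry is
#'   available), outlier ids, the final `pls_model`, and the RMSEP-vs-
#'   components curve. Methods: `tidy()`, `glance()`, `autoplot()`.
#' @export
calibrate <- function(spectra, responses = "TNC", n_components = 8,
                      cal_size = NULL, range = c(4000, 9000),
                      window = 25L, polyorder = 2L, deriv = 1L,
                      max_components = n_components + 5L) {
  assert_that(inherits(spectra, "spectra_set"), "`spectra` must be a spectra_set")
  assert_that(!is.null(spectra$constituents),
              "`spectra` must carry paired constituent values")
  wet <- spectra$constituents
  if (identical(responses, "TNC") && !"TNC" %in% names(wet)) {
    assert_that(all(c("starch", "sucrose") %in% names(wet)),
                "TNC requires starch and sucrose columns")
    wet$TNC <- tnc(wet$starch, wet$sucrose)
  }
  assert_that(all(responses %in% names(wet)),
              "all `responses` must be constituent columns")
  # per-sample reference values (mean over technical replicates) and the
  # reference-method uncertainty from those replicates if present
  ref_unc <- NULL
  if ("replicate" %in% names(wet) && any(duplicated(wet$sample_id))) {
    ref_unc <- vapply(responses, function(rr) {
      reference_uncertainty(wet, value_col = rr)
    }, numeric(1))
  }
  refs <- dplyr::summarise(
    dplyr::group_by(wet, .data$sample_id),
    dplyr::across(dplyr::all_of(responses), ~ mean(.x, na.rm = TRUE)),
    .groups = "drop"
  )
  refs <- refs[match(spectra$sample_ids, refs$sample_id), ]
  Yall <- as.matrix(refs[responses])
  rownames(Yall) <- spectra$sample_ids

  pre <- savgol_derivative(
    snv(restrict_range(spectra, range[1], range[2])),
    window = window, polyorder = polyorder, deriv = deriv
  )
  n <- nrow(pre$absorbance)
  cal_size <- cal_size %||% round(0.7 * n)
  split <- kennard_stone(pre, cal_size)
  cal_idx <- match(split$selected, pre$sample_ids)
  val_idx <- match(split$remainder, pre$sample_ids)
  Xc <- pre$absorbance[cal_idx, , drop = FALSE]
  Yc <- Yall[cal_idx, , drop = FALSE]
  mode <- if (length(responses) == 1L) "PLS1" else "PLS2"

  max_components <- max(max_components, n_components)
  # initial model with full cross-validation; outlier pass
  cv0 <- cross_validate(Xc, Yc, max(n_components, 2L), mode = mode)
  rmsecv0 <- cv0$rmsecv[n_components, ]
  out_ids <- detect_outliers(
    matrix(cv0$predictions[, , n_components], nrow(Xc), ncol(Yc)),
    Yc, rmsecv0, ids = split$selected
  )
  keep <- !(split$selected %in% out_ids)

  Xf <- Xc[keep, , drop = FALSE]
  Yf <- Yc[keep, , drop = FALSE]
  model <- fit_pls(Xf, Yf, n_components, mode = mode,
                   pretreatment = pre$pretreatment,
                   wavenumbers = pre$wavenumbers)
  # curves only extend as far as the data's rank allows (exact-rank
  # synthetic spectra exhaust it early)
  max_eff <- n_components
  for (k in seq(max_components, n_components)) {
    ok <- tryCatch({fit_pls(Xf, Yf, k, mode = mode); TRUE},
                   error = function(e) FALSE)
    if (ok) { max_eff <- k; break }
  }
  cvf <- cross_validate(Xf, Yf, max_eff, mode = mode)
  fitted <- model$fitted
  # untouched validation set enters here only
  Xv <- pre$absorbance[val_idx, , drop = FALSE]
  Yv <- Yall[val_idx, , drop = FALSE]
  pred_v <- predict(model, Xv)
  rmsep_curve <- vapply(seq_len(max_eff), function(k) {
    mk <- fit_pls(Xf, Yf, k, mode = mode)
    vapply(seq_along(responses), function(j) {
      rmse(predict(mk, Xv)[, j], Yv[, j])
    }, numeric(1))
  }, numeric(length(responses)))
  rmsep_curve <- matrix(rmsep_curve, ncol = length(responses), byrow = TRUE,
                        dimnames = list(NULL, responses))

  per_resp <- purrr::map_dfr(seq_along(responses), function(j) {
    tibble(
      response = responses[j],
      r2_calibration = r_squared(fitted[, j], Yf[, j]),
      r2_cross_validation = r_squared(
        cvf$predictions[, j, n_components], Yf[, j]
      ),
      r2_validation = r_squared(pred_v[, j], Yv[, j]),
      rmsec = rmse(fitted[, j], Yf[, j]),
      rmsecv = rmse(cvf$predictions[, j, n_components], Yf[, j]),
      rmsep = rmse(pred_v[, j], Yv[, j]),
      reference_uncertainty = if (is.null(ref_unc)) NA_real_ else ref_unc[j]
    )
  })
  structure(
    list(
      mode = mode, responses = responses, n_components = n_components,
      n_calibration = length(cal_idx), n_validation = length(val_idx),
      outliers = out_ids, statistics = per_resp, model = model,
      rmsecv_initial = rmsecv0, rmsecv_curve = cvf$rmsecv,
      rmsep_curve = rmsep_curve,
      validation_ids = split$remainder,
      validation_predictions = pred_v, validation_reference = Yv
    ),
    class = "calibration_report"
  )
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf(
    "<calibration_report> %s, %d components\n  calibration n=%d (%d outliers removed), validation n=%d\n",
    x$mode, x$n_components, x$n_calibration, length(x$outliers),
    x$n_validation
  ))
  print(x$statistics)
  invisible(x)
}

#' Per-response statistics of a calibration report
#'
#' @param x A `calibration_report`.
#' @param ... Unused.
#' @return Tibble with one row per response: R^2 triplet, RMSEC/RMSECV/RMSEP
#'   and reference uncertainty.
#' @method tidy calibration_report
#' @export
tidy.calibration_report <- function(x, ...) x$statistics

#' One-row overview of a calibration report
#'
#' @param x A `calibration_report`.
#' @param ... Unused.
#' @return Tibble with counts and the component number.
#' @method glance calibration_report
#' @export
glance.calibration_report <- function(x, ...) {
  tibble(
    mode = x$mode, n_components = x$n_components,
    n_calibration = x$n_calibration, n_validation = x$n_validation,
    n_outliers = length(x$outliers)
  )
}

#' Predicted-vs-measured plot for the validation set
#'
#' @param object A `calibration_report`.
#' @param ... Unused.
#' @return A ggplot, one facet per response, with the 1:1 line.
#' @method autoplot calibration_report
#' @export
autoplot.calibration_report <- function(object, ...) {
  df <- purrr::map_dfr(seq_along(object$responses), function(j) {
    tibble(
      response = object$responses[j],
      measured = object$validation_reference[, j],
      predicted = object$validation_predictions[, j]
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$measured, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(ggplot2::vars(.data$response), scales = "free") +
    ggplot2::labs(x = "measured (wet chemistry)", y = "NIR predicted") +
    ggplot2::theme_minimal()
}

#' First-local-minimum helper for choosing the component count
#'
#' Returns the component count at the first local minimum of an RMSE curve
#' (the "inspect the curve" heuristic made explicit); falls back to the
#' global minimum when the curve is monotone.
#'
#' @param rmse_curve Numeric vector, RMSE per component count.
#' @return Integer component count.
#' @export
suggest_components <- function(rmse_curve) {
  assert_that(is.numeric(rmse_curve) && length(rmse_curve) >= 1,
              "`rmse_curve` must be a numeric vector")
  if (length(rmse_curve) >= 3) {
    for (k in 2:(length(rmse_curve) - 1)) {
      if (rmse_curve[k] < rmse_curve[k - 1] && rmse_curve[k] <= rmse_curve[k + 1]) {
        return(k)
      }
    }
  }
  which.min(rmse_curve)
}

#' Serialize a PLS model to a self-describing text file
#'
#' JSON with full double precision, so that a save/load round trip
#' reproduces the model bit-for-bit.
#'
#' @param model A `pls_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pls_model <- function(model, path) {
  assert_that(inherits(model, "pls_model"), "`model` must be a pls_model")
  payload <- model
  class(payload) <- NULL
  payload$fitted <- NULL
  payload$scores <- NULL
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

#' Read a serialized PLS model
#'
#' @param path File written by [write_pls_model()].
#' @return A `pls_model` (without training scores/fitted values).
#' @export
read_pls_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("weights", "x_loadings", "y_loadings", "coef", "rotation")) {
    raw[[nm]] <- as.matrix(raw[[nm]])
  }
  raw$x_mean <- as.numeric(raw$x_mean)
  raw$y_mean <- as.numeric(raw$y_mean)
  raw$wavenumbers <- if (is.null(raw$wavenumbers)) NULL else
    as.numeric(raw$wavenumbers)
  structure(raw, class = "pls_model")
}
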