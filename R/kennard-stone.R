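#' Kennard-Stone calibration/validation split
#'
#' Deterministic maximin sample selection in (pretreated) spectral space:
#' the pair at maximum Euclidean distance seeds the selection, then each step
#' adds the candidate whose minimum distance to the already-selected set is
#' largest. Ties are broken by the lowest sample index, making the split
#' fully reproducible.
#'
#' @param spectra A [spectra_set], or a numeric matrix (samples x variables).
#' @param n_select Number of samples for the calibration set
#'   (`2 <= n_select < n_samples`).
#' @return List with `selected` and `remainder` (sample ids, or row indices
#'   for matrix input).
#' @examples
#' m <- matrix(c(0, 1, 2, 10), ncol = 1)
#' kennard_stone(m, 3)$selected
#' @export
kennard_stone <- function(spectra, n_select) {
  X <- if (inherits(spectra, "spectra_set")) spectra$absorbance else as.matrix(spectra)
  ids <- if (inherits(spectra, "spectra_set")) spectra$sample_ids else
    (rownames(X) %||% seq_len(nrow(X)))
  n <- nrow(X)
  assert_that(is_count(n_select, 2L) && n_select < n,
              "`n_select` must satisfy 2 <= n_select < n_samples")
  D <- as.matrix(dist(X))
  sel <- integer(n_select)
  # seed pair: maximum pairwise distance, lowest indices on ties
  mx <- max(D)
  hit <- which(D == mx, arr.ind = TRUE)
  hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
  hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
  sel[1:2] <- hit[1, ]
  mind <- pmin(D[, sel[1]], D[, sel[2]])
  mind[sel[1:2]] <- -Inf
  if (n_select > 2) {
    for (k in 3:n_select) {
      cand <- which(mind == max(mind))[1] # lowest index on ties
      sel[k] <- cand
      mind <- pmin(mind, D[, cand])
      mind[cand] <- -Inf
    }
  }
  list(selected = ids[sel], remainder = ids[-sel])
}
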