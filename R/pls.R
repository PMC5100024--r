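#' Fit a PLS regression model (NIPALS)
#'
#' Mean-centered NIPALS partial least squares. `mode = "PLS1"` takes a single
#' response (e.g. TNC); `mode = "PLS2"` models several responses (e.g. starch
#' and sucrose) as one multivariate model. Exposes scores, weights, loadings
#' and the final regression coefficients `B` such that prediction is the
#' affine map `Y_hat = Y_mean + (x - X_mean) B`.
#'
#' @param X Numeric matrix (samples x variables), already pretreated.
#' @param Y Numeric vector/1-column matrix (PLS1) or 2+ column matrix (PLS2).
#' @param n_components Number of latent components (>= 1, <= rank of the
#'   centered `X`).
#' @param mode `"PLS1"` or `"PLS2"` (defaults to match `ncol(Y)`).
#' @param pretreatment Optional character vector recording the pretreatment
#'   pipeline of `X`; enforced at prediction time.
#' @param wavenumbers Optional grid of `X`'s columns; enforced at prediction
#'   time.
#' @return A `pls_model`: list with `mode`, `n_components`, `x_mean`,
#'   `y_mean`, `weights` (W), `x_loadings` (P), `y_loadings` (Q), `scores`
#'   (T), `coef` (B), `fitted`, `train_ids`, `pretreatment`, `wavenumbers`.
#' @examples
#' X <- matrix(rnorm(100), 20)
#' y <- X %*% rnorm(5)
#' m <- fit_pls(X, y, 2)
#' glance(m)
#' @export
fit_pls <- function(X, Y, n_components, mode = NULL, pretreatment = NULL,
                    wavenumbers = NULL) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  assert_that(nrow(X) == nrow(Y), "X and Y must have matching rows")
  mode <- mode %||% (if (ncol(Y) == 1L) "PLS1" else "PLS2")
  assert_that(mode %in% c("PLS1", "PLS2"), "`mode` must be PLS1 or PLS2")
  if (mode == "PLS1") {
    assert_that(ncol(Y) == 1L, "PLS1 requires a single response")
  }
  assert_that(is_count(n_components, 1L), "`n_components` must be >= 1")
  x_mean <- colMeans(X)
  y_mean <- colMeans(Y)
  Xc <- sweep(X, 2, x_mean)
  Yc <- sweep(Y, 2, y_mean)
  if (n_components > min(nrow(X) - 1L, ncol(X))) {
    abort(sprintf("n_components (%d) exceeds the rank of centered X",
                  n_components))
  }
  p <- ncol(X); q <- ncol(Y); a <- n_components
  x_scale <- sum(Xc^2)
  W <- matrix(0, p, a); P <- matrix(0, p, a)
  Q <- matrix(0, q, a); TT <- matrix(0, nrow(X), a)
  Xd <- Xc; Yd <- Yc
  for (k in seq_len(a)) {
    if (sum(Xd^2) <= 1e-14 * max(x_scale, 1e-300)) {
      abort(sprintf("n_components (%d) exceeds the rank of centered X", a))
    }
    if (q == 1L) {
      w <- crossprod(Xd, Yd)[, 1]
      nrm <- sqrt(sum(w^2))
      if (nrm <= 1e-300) {
        abort(sprintf(
          "response is exhausted before %d components; reduce n_components", a
        ))
      }
      w <- w / nrm
      tt <- Xd %*% w
    } else {
      u <- Yd[, which.max(apply(Yd, 2, var))]
      for (iter in 1:500) {
        w <- crossprod(Xd, u)[, 1]
        w <- w / sqrt(sum(w^2))
        tt <- Xd %*% w
        qv <- crossprod(Yd, tt)[, 1] / sum(tt^2)
        u_new <- Yd %*% qv / sum(qv^2)
        if (max(abs(u_new - u)) < 1e-12 * max(abs(u_new), 1e-300)) {
          u <- u_new
          break
        }
        u <- u_new
      }
    }
    tsq <- sum(tt^2)
    if (!is.finite(tsq) || tsq <= 1e-12 * x_scale / nrow(X)) {
      abort(sprintf("n_components (%d) exceeds the rank of centered X", a))
    }
    pv <- crossprod(Xd, tt)[, 1] / tsq
    qv <- crossprod(Yd, tt)[, 1] / tsq
    W[, k] <- w; P[, k] <- pv; Q[, k] <- qv; TT[, k] <- tt
    Xd <- Xd - tcrossprod(tt, pv)
    Yd <- Yd - tcrossprod(tt, qv)
  }
  R <- W %*% solve(crossprod(P, W)) # X-rotation: T = Xc R
  B <- R %*% t(Q)
  fitted <- sweep(Xc %*% B, 2, y_mean, `+`)
  colnames(fitted) <- colnames(Y)
  structure(
    list(
      mode = mode, n_components = a, x_mean = x_mean, y_mean = y_mean,
      weights = W, x_loadings = P, y_loadings = Q, scores = TT,
      rotation = R, coef = B, fitted = fitted,
      responses = colnames(Y) %||% paste0("y", seq_len(q)),
      train_ids = rownames(X), pretreatment = pretreatment,
      wavenumbers = wavenumbers
    ),
    class = "pls_model"
  )
}

#' Predict constituent values from spectra with a fitted PLS model
#'
#' Affine prediction `Y_hat = Y_mean + (x - X_mean) B`. When the model
#' records a pretreatment descriptor or a wavenumber grid, the new spectra
#' must match both; a mismatch is an error, never a silent recalculation.
#'
#' @param object A `pls_model`.
#' @param spectra A [spectra_set] pretreated identically to the training
#'   spectra, or a bare numeric matrix.
#' @param ... Unused.
#' @return Matrix of predictions (samples x responses).
#' @export
predict.pls_model <- function(object, spectra, ...) {
  if (inherits(spectra, "spectra_set")) {
    if (!is.null(object$pretreatment) &&
        !identical(spectra$pretreatment, object$pretreatment)) {
      abort(sprintf(
        "pretreatment mismatch: model expects '%s', spectra carry '%s'",
        paste(object$pretreatment, collapse = " -> "),
        paste(spectra$pretreatment, collapse = " -> ")
      ))
    }
    if (!is.null(object$wavenumbers) &&
        !isTRUE(all.equal(spectra$wavenumbers, object$wavenumbers))) {
      abort("wavenumber grid mismatch between model and spectra")
    }
    X <- spectra$absorbance
  } else {
    X <- as.matrix(spectra)
  }
  assert_that(ncol(X) == length(object$x_mean),
              "spectra have the wrong number of variables")
  out <- sweep(sweep(X, 2, object$x_mean) %*% object$coef, 2,
               object$y_mean, `+`)
  colnames(out) <- object$responses
  out
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %s, %d components, %d responses (%s)\n",
              x$mode, x$n_components, length(x$y_mean),
              paste(x$responses, collapse = ", ")))
  invisible(x)
}

#' One-row overview of a PLS model
#'
#' @param x A `pls_model`.
#' @param ... Unused.
#' @return Tibble with mode, component count, and variable/response counts.
#' @method glance pls_model
#' @export
glance.pls_model <- function(x, ...) {
  tibble(
    mode = x$mode, n_components = x$n_components,
    n_variables = length(x$x_mean), n_responses = length(x$y_mean),
    n_train = nrow(x$scores)
  )
}

#' Leave-one-out cross-validation RMSE per component count
#'
#' Full (leave-one-out) cross-validation: each sample is predicted from a
#' model refitted on the remaining samples, for every component count from 1
#' to `max_components`, yielding the RMSECV curve used to pick the model
#' size.
#'
#' @inheritParams fit_pls
#' @param max_components Largest component count to evaluate (capped with a
#'   warning at `n_samples - 2`).
#' @return List with `rmsecv` (matrix `max_components` x responses),
#'   `predictions` (array samples x responses x components of left-out
#'   predictions).
#' @export
cross_validate <- function(X, Y, max_components, mode = NULL) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  n <- nrow(X)
  assert_that(n >= 3, "cross-validation needs at least 3 samples")
  if (max_components >= n - 1) {
    warn(sprintf("max_components capped at %d (n - 2)", n - 2L))
    max_components <- n - 2L
  }
  q <- ncol(Y)
  preds <- array(NA_real_, c(n, q, max_components))
  for (i in seq_len(n)) {
    fit <- fit_pls(X[-i, , drop = FALSE], Y[-i, , drop = FALSE],
                   max_components, mode = mode)
    xc <- X[i, ] - fit$x_mean
    # cumulative prediction over components via the rotation
    tt <- drop(crossprod(fit$rotation, xc)) # scores of the left-out sample
    cum <- matrix(0, q, max_components)
    acc <- rep(0, q)
    for (k in seq_len(max_components)) {
      acc <- acc + fit$y_loadings[, k] * tt[k]
      cum[, k] <- acc
    }
    preds[i, , ] <- cum + fit$y_mean
  }
  rmsecv <- t(apply(preds, 3, function(pk) {
    sqrt(colMeans((matrix(pk, n, q) - Y)^2))
  }))
  rmsecv <- matrix(rmsecv, max_components, q)
  colnames(rmsecv) <- colnames(Y) %||% paste0("y", seq_len(q))
  list(rmsecv = rmsecv, predictions = preds)
}
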