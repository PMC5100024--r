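#' Compute a genomic relationship matrix from SNP dosages
#'
#' VanRaden-style GRM: `K = Z Z' / (2 * sum_j p_j (1 - p_j))` with `Z` the
#' dosage matrix column-centered at `2 p_j` and missing calls mean-imputed
#' before centering. Monomorphic SNPs contribute nothing to the numerator and
#' are excluded from the denominator. Under this normalization the mean
#' diagonal is close to 1 for an outbred-like panel.
#'
#' @param genotypes A [genotype_matrix].
#' @return A `grm` object: list with `line_ids` and `K` (symmetric
#'   `n_lines` x `n_lines` matrix).
#' @examples
#' g <- simulate_genotypes(10, 200, seed = 1)
#' K <- compute_grm(g)
#' mean(diag(K$K))
#' @export
compute_grm <- function(genotypes) {
  assert_that(inherits(genotypes, "genotype_matrix"),
              "`genotypes` must be a genotype_matrix")
  Z <- center_dosages(genotypes)
  denom <- attr(Z, "denom")
  if (denom <= 0) {
    abort("all SNPs are monomorphic: the GRM denominator is zero")
  }
  K <- tcrossprod(Z) / denom
  K <- (K + t(K)) / 2
  dimnames(K) <- list(genotypes$line_ids, genotypes$line_ids)
  structure(list(line_ids = genotypes$line_ids, K = K), class = "grm")
}

#' Construct a GRM object from a ready-made relationship matrix
#'
#' @param K Symmetric relationship matrix with line ids as dimnames (or
#'   supplied via `line_ids`).
#' @param line_ids Optional line identifiers.
#' @return A `grm` object.
#' @export
grm <- function(K, line_ids = NULL) {
  assert_that(is.matrix(K) && nrow(K) == ncol(K), "`K` must be square")
  assert_that(max(abs(K - t(K))) < 1e-8, "`K` must be symmetric")
  line_ids <- line_ids %||% rownames(K) %||% sprintf("L%03d", seq_len(nrow(K)))
  dimnames(K) <- list(line_ids, line_ids)
  structure(list(line_ids = line_ids, K = (K + t(K)) / 2), class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("<grm> %d lines, mean diagonal %.3f\n",
              nrow(x$K), mean(diag(x$K))))
  invisible(x)
}
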