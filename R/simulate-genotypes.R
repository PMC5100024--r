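#' Simulate SNP dosage genotypes for a panel of inbred-derived lines
#'
#' Draws biallelic SNP dosages under Hardy-Weinberg proportions: for SNP `j`
#' with allele frequency `p_j` drawn uniformly from `maf_range`, line dosages
#' are `Binomial(2, p_j)`. This stands in for dense array genotypes (the study
#' system used ~700k SNPs from a high-density rice array) at a desk-scale
#' number of markers.
#'
#' @param n_lines Number of lines (>= 2).
#' @param n_snps Number of SNPs (>= 1).
#' @param maf_range Length-2 numeric range for minor-allele frequencies,
#'   a subset of (0, 0.5]. A single value fixes all frequencies.
#' @param seed Integer seed; the generator is deterministic given it.
#'
#' @return A `genotype_matrix` object: list with `line_ids`, `dosages`
#'   (`n_lines` x `n_snps` integer matrix with entries 0/1/2 or `NA`), and
#'   `allele_freqs` (realized per-SNP alternate-allele frequency computed from
#'   the non-missing dosages).
#' @examples
#' g <- simulate_genotypes(10, 50, seed = 1)
#' dim(g$dosages)
#' @export
simulate_genotypes <- function(n_lines, n_snps, maf_range = c(0.05, 0.5),
                               seed = 1L) {
  assert_that(is_count(n_lines, 2L), "`n_lines` must be an integer >= 2")
  assert_that(is_count(n_snps, 1L), "`n_snps` must be an integer >= 1")
  if (length(maf_range) == 1L) maf_range <- rep(maf_range, 2L)
  assert_that(
    is.numeric(maf_range) && length(maf_range) == 2L &&
      all(maf_range > 0) && all(maf_range <= 0.5) &&
      maf_range[1] <= maf_range[2],
    "`maf_range` must lie within (0, 0.5]"
  )
  with_seed(seed, {
    p <- runif(n_snps, maf_range[1], maf_range[2])
    dos <- matrix(
      rbinom(n_lines * n_snps, size = 2L, prob = rep(p, each = n_lines)),
      nrow = n_lines, ncol = n_snps
    )
    genotype_matrix(dos, line_ids = sprintf("L%03d", seq_len(n_lines)))
  })
}

#' Construct a genotype matrix object from a dosage matrix
#'
#' @param dosages Numeric matrix (lines x SNPs) with entries in {0, 1, 2} or
#'   `NA` for missing calls.
#' @param line_ids Optional line identifiers (defaults to rownames or L001...).
#' @param snp_ids Optional SNP identifiers (defaults to colnames or S1...).
#' @return A `genotype_matrix` object.
#' @export
genotype_matrix <- function(dosages, line_ids = NULL, snp_ids = NULL) {
  assert_that(is.matrix(dosages), "`dosages` must be a matrix")
  assert_that(nrow(dosages) >= 2, "need at least 2 lines")
  ok <- dosages[!is.na(dosages)]
  assert_that(all(ok %in% c(0, 1, 2)), "dosages must be 0, 1, 2 or NA")
  line_ids <- line_ids %||% rownames(dosages) %||%
    sprintf("L%03d", seq_len(nrow(dosages)))
  snp_ids <- snp_ids %||% colnames(dosages) %||%
    sprintf("S%d", seq_len(ncol(dosages)))
  storage.mode(dosages) <- "double"
  dimnames(dosages) <- list(line_ids, snp_ids)
  freqs <- colMeans(dosages, na.rm = TRUE) / 2
  structure(
    list(line_ids = line_ids, dosages = dosages, allele_freqs = freqs),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d lines x %d SNPs (%.2f%% missing)\n",
    nrow(x$dosages), ncol(x$dosages),
    100 * mean(is.na(x$dosages))
  ))
  invisible(x)
}

#' @method as_tibble genotype_matrix
#' @export
as_tibble.genotype_matrix <- function(x, ...) {
  as_tibble(as.data.frame(x$dosages), rownames = "line")
}
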