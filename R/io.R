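#' Read a long-format phenotype CSV
#'
#' Expects columns `line`, `replicate`, `trait`, `value`; duplicate
#' `(line, replicate, trait)` keys are an error. Trait labels conventionally
#' follow [nsc_trait_names], but any vocabulary is accepted.
#'
#' @param path CSV file path.
#' @return Phenotype tibble.
#' @export
read_phenotypes <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("line", "replicate", "trait", "value")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(sprintf("phenotype file lacks column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  key <- paste(df$line, df$replicate, df$trait, sep = "\r")
  if (anyDuplicated(key) > 0) {
    abort("duplicated (line, replicate, trait) rows in phenotype file")
  }
  df$line <- as.character(df$line)
  df$trait <- as.character(df$trait)
  df$value <- as.numeric(df$value)
  as_tibble(df[need])
}

#' Write a phenotype table as long-format CSV
#'
#' @param pheno Phenotype tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  pheno <- check_pheno(pheno)
  readr::write_csv(pheno[c("line", "replicate", "trait", "value")], path)
  invisible(path)
}

#' Read genotypes from a CSV dosage matrix or a VCF
#'
#' CSV: first column line ids, remaining columns SNP dosages in {0, 1, 2}
#' with empty/NA for missing. VCF (requires the vcfR package): dosage is the
#' count of alternate alleles in the GT field; samples become lines.
#'
#' @param path File path.
#' @param format `"csv"` or `"vcf"` (guessed from the extension by default).
#' @return A [genotype_matrix].
#' @export
read_genotypes <- function(path, format = c("auto", "csv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "csv"
  }
  if (format == "csv") {
    df <- readr::read_csv(path, show_col_types = FALSE)
    ids <- as.character(df[[1]])
    m <- as.matrix(df[-1])
    storage.mode(m) <- "double"
    return(genotype_matrix(m, line_ids = ids, snp_ids = colnames(df)[-1]))
  }
  rlang::check_installed("vcfR", reason = "to read VCF genotypes")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  alleles <- function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
    parts <- strsplit(g, "[/|]")[[1]]
    if (length(parts) != 2L) {
      abort(sprintf("non-diploid GT '%s' in VCF", g))
    }
    if (any(parts == ".")) return(NA_real_)
    sum(parts != "0")
  }
  dos <- apply(gt, c(1, 2), alleles)
  genotype_matrix(t(dos), line_ids = colnames(gt), snp_ids = rownames(gt))
}

#' Write genotypes as a CSV dosage matrix
#'
#' @param genotypes A [genotype_matrix].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(genotypes, path) {
  assert_that(inherits(genotypes, "genotype_matrix"),
              "`genotypes` must be a genotype_matrix")
  df <- tibble::add_column(
    as_tibble(as.data.frame(genotypes$dosages)),
    line = genotypes$line_ids, .before = 1
  )
  readr::write_csv(df, path)
  invisible(path)
}

#' Read spectra from a wide CSV
#'
#' First column `wavenumber`, one column per sample; optional paired
#' wet-chemistry CSV with `sample_id`, constituent columns and optionally
#' `replicate`.
#'
#' @param path Spectra CSV path.
#' @param wetchem_path Optional wet-chemistry CSV path.
#' @return A [spectra_set].
#' @export
read_spectra <- function(path, wetchem_path = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  assert_that(names(df)[1] == "wavenumber",
              "first column must be `wavenumber`")
  wn <- df$wavenumber
  A <- t(as.matrix(df[-1]))
  wet <- NULL
  if (!is.null(wetchem_path)) {
    wet <- readr::read_csv(wetchem_path, show_col_types = FALSE)
    wet$sample_id <- as.character(wet$sample_id)
  }
  spectra_set(wn, A, sample_ids = colnames(df)[-1], constituents = wet)
}

#' Write spectra (and paired wet chemistry) as CSV
#'
#' @param spectra A [spectra_set].
#' @param path Spectra CSV path (wide: wavenumber + one column per sample).
#' @param wetchem_path Optional output path for the constituent table.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path, wetchem_path = NULL) {
  assert_that(inherits(spectra, "spectra_set"), "`spectra` must be a spectra_set")
  df <- tibble::add_column(
    as_tibble(as.data.frame(t(spectra$absorbance)), .name_repair = "minimal"),
    wavenumber = spectra$wavenumbers, .before = 1
  )
  names(df) <- c("wavenumber", spectra$sample_ids)
  readr::write_csv(df, path)
  if (!is.null(wetchem_path) && !is.null(spectra$constituents)) {
    readr::write_csv(spectra$constituents, wetchem_path)
  }
  invisible(path)
}
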