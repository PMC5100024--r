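#' Run the phenotyping-strategy pipeline from a configuration
#'
#' Executes the requested stages in dependency order — `simulate` (genotypes,
#' phenotypes, optionally spectra), `fit` (single-trait and/or bivariate
#' genetic models), `design_study`, `calibrate` — writing every output as CSV
#' plus a JSON manifest recording inputs, seeds, package version and stage
#' outcomes. Re-running an identical configuration reproduces identical
#' numeric outputs: every stochastic stage receives an explicit seed derived
#' from the single global seed.
#'
#' @param config Nested list (e.g. from [read_run_config()]). Recognized
#'   top-level keys: `seed`, `simulate`, `fit`, `design_study`, `calibrate`;
#'   unknown keys are rejected. See the package vignette for the full key
#'   dictionary.
#' @param out_dir Output directory (created if needed).
#' @return Path to `out_dir`, invisibly; the manifest lists all files
#'   written.
#' @export
run_pipeline <- function(config, out_dir) {
  assert_that(is.list(config), "`config` must be a list")
  known <- c("seed", "simulate", "fit", "design_study", "calibrate")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  seed <- config$seed %||% 1L
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    seed = seed,
    package_version = as.character(utils::packageVersion("nscpheno")),
    stages = list(), files = character()
  )
  emit <- function(name) {
    manifest$files <<- c(manifest$files, name)
    file.path(out_dir, name)
  }
  fail <- function(stage, err) {
    manifest$stages[[stage]] <<- paste("failed:", conditionMessage(err))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(err)))
  }

  geno <- NULL; pheno <- NULL; spectra <- NULL
  if (!is.null(config$simulate)) {
    tryCatch({
      sim <- config$simulate
      geno <- simulate_genotypes(
        n_lines = sim$n_lines %||% 36L, n_snps = sim$n_snps %||% 500L,
        maf_range = sim$maf_range %||% c(0.05, 0.5),
        seed = derive_seed(seed, "genotypes")
      )
      write_genotypes(geno, emit("genotypes.csv"))
      pcfg_args <- sim$phenotypes %||% list()
      pcfg <- do.call(pheno_sim_config, pcfg_args)
      pheno <- simulate_phenotypes(geno, pcfg,
                                   seed = derive_seed(seed, "phenotypes"))
      write_phenotypes(pheno, emit("phenotypes.csv"))
      if (isTRUE(sim$spectra$enabled %||% FALSE)) {
        n_samp <- sim$spectra$n_samples %||% 60L
        scfg <- spectra_sim_config(
          wetchem_replicates = sim$spectra$wetchem_replicates %||% 1L
        )
        conc <- with_seed(derive_seed(seed, "wetchem"), cbind(
          starch = runif(n_samp, 0.02, 0.40),
          sucrose = runif(n_samp, 0.02, 0.20)
        ))
        spectra <- simulate_spectra(conc, scfg,
                                    seed = derive_seed(seed, "spectra"))
        write_spectra(spectra, emit("spectra.csv"), emit("wetchem.csv"))
      }
      manifest$stages$simulate <- "ok"
    }, error = function(e) fail("simulate", e))
  }
  if (!is.null(config$fit)) {
    tryCatch({
      fc <- config$fit
      if (!is.null(fc$pheno)) pheno <- read_phenotypes(fc$pheno)
      if (!is.null(fc$geno)) geno <- read_genotypes(fc$geno)
      assert_that(!is.null(pheno) && !is.null(geno),
                  "fit stage needs phenotypes and genotypes")
      K <- compute_grm(geno)
      sp <- model_spec(
        error_family = fc$error_family %||% "gaussian",
        chains = fc$chains %||% 4L, warmup = fc$warmup %||% 500L,
        samples = fc$samples %||% 1000L, seed = derive_seed(seed, "mcmc")
      )
      traits <- fc$traits %||% unique(pheno$trait)
      fits <- lapply(traits, function(tr) fit_single_trait(pheno, K, tr, sp))
      summaries <- purrr::map_dfr(seq_along(traits), function(i) {
        tibble::add_column(summarize_posterior(fits[[i]]),
                           trait = traits[i], .before = 1)
      })
      readr::write_csv(summaries, emit("posterior_summary.csv"))
      gebvs <- purrr::map_dfr(seq_along(traits), function(i) {
        tibble::add_column(fits[[i]]$lines, trait = traits[i], .before = 1)
      })
      readr::write_csv(gebvs, emit("gebv.csv"))
      if (length(traits) >= 2) {
        pairs <- utils::combn(traits, 2, simplify = FALSE)
        bf <- lapply(pairs, function(pr) fit_bivariate(pheno, K, pr, sp))
        readr::write_csv(correlation_triplets(bf, "r_g"),
                         emit("genetic_correlations.csv"))
        readr::write_csv(correlation_triplets(bf, "r_e"),
                         emit("environmental_correlations.csv"))
      }
      manifest$stages$fit <- "ok"
    }, error = function(e) fail("fit", e))
  }
  if (!is.null(config$design_study)) {
    tryCatch({
      dc <- config$design_study
      assert_that(!is.null(pheno) && !is.null(geno),
                  "design_study stage needs phenotypes and genotypes")
      K <- compute_grm(geno)
      sp <- model_spec(
        chains = dc$chains %||% 2L, warmup = dc$warmup %||% 200L,
        samples = dc$samples %||% 400L, seed = derive_seed(seed, "mcmc")
      )
      cfg <- design_study_config(
        replicate_sizes = dc$replicate_sizes %||% c(2, 5, 10, 15),
        n_draws = dc$n_draws %||% 20L,
        seed = derive_seed(seed, "design"),
        traits_univariate = dc$traits_univariate,
        trait_pairs = dc$trait_pairs
      )
      study <- run_design_study(pheno, K, sp, cfg)
      readr::write_csv(study$results, emit("design_study_results.csv"))
      readr::write_csv(tidy(study), emit("design_study_summary.csv"))
      manifest$stages$design_study <- "ok"
    }, error = function(e) fail("design_study", e))
  }
  if (!is.null(config$calibrate)) {
    tryCatch({
      cc <- config$calibrate
      if (!is.null(cc$spectra)) {
        spectra <- read_spectra(cc$spectra, cc$wetchem)
      }
      assert_that(!is.null(spectra), "calibrate stage needs spectra")
      rep_out <- calibrate(
        spectra,
        responses = cc$responses %||% "TNC",
        n_components = cc$n_components %||% 8L,
        cal_size = cc$cal_size
      )
      readr::write_csv(tidy(rep_out), emit("calibration_report.csv"))
      write_pls_model(rep_out$model, emit("pls_model.json"))
      manifest$stages$calibrate <- "ok"
    }, error = function(e) fail("calibrate", e))
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file path.
#' @return Config list for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}
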