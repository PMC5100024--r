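#' Subsample replicates within lines
#'
#' Draws exactly `rs` replicates per line, uniformly without replacement
#' within each line and independently across lines — mimicking a smaller
#' experiment run on the same material. Deterministic given `seed`.
#'
#' @param pheno Long-format phenotype tibble (`line`, `replicate`, `trait`,
#'   `value`). Replicates are subsampled per line; all traits measured on a
#'   retained replicate are kept, so trait pairs stay aligned.
#' @param rs Replicate size to keep (>= 2).
#' @param seed Integer seed.
#' @return Phenotype tibble with exactly `rs` replicates per line.
#' @examples
#' g <- simulate_genotypes(5, 20, seed = 1)
#' ph <- simulate_phenotypes(g, pheno_sim_config(n_reps = 6), seed = 1)
#' nrow(subsample_replicates(ph, 2, seed = 1))
#' @export
subsample_replicates <- function(pheno, rs, seed = 1L) {
  pheno <- check_pheno(pheno)
  assert_that(is_count(rs, 2L), "`rs` must be an integer >= 2")
  reps_per_line <- dplyr::summarise(
    dplyr::group_by(dplyr::distinct(pheno, .data$line, .data$replicate),
                    .data$line),
    n = dplyr::n(), .groups = "drop"
  )
  short <- reps_per_line$line[reps_per_line$n < rs]
  if (length(short) > 0) {
    abort(sprintf("line(s) with fewer than %d replicates: %s", rs,
                  paste(short, collapse = ", ")))
  }
  with_seed(seed, {
    keep <- dplyr::group_modify(
      dplyr::group_by(dplyr::distinct(pheno, .data$line, .data$replicate),
                      .data$line),
      function(df, key) df[sample.int(nrow(df), rs), , drop = FALSE]
    )
    dplyr::inner_join(pheno, dplyr::ungroup(keep),
                      by = c("line", "replicate"))
  })
}

#' Accuracy of subsampled estimates relative to the full dataset
#'
#' Pearson correlation between per-line (or per-pair) estimate vectors from a
#' subsampled analysis and the full-data analysis.
#'
#' @param sub_estimates,full_estimates Aligned numeric vectors (length >= 3).
#' @return Correlation in `[-1, 1]`, or `NA` when either vector has zero
#'   variance (undefined, reported as missing).
#' @examples
#' accuracy(c(1, 2, 3, 5), c(1, 2, 3, 4))
#' @export
accuracy <- function(sub_estimates, full_estimates) {
  assert_that(length(sub_estimates) == length(full_estimates),
              "estimate vectors must be aligned")
  ok <- is.finite(sub_estimates) & is.finite(full_estimates)
  s <- sub_estimates[ok]
  f <- full_estimates[ok]
  assert_that(length(s) >= 3, "need at least 3 aligned estimates")
  if (sd(s) == 0 || sd(f) == 0) return(NA_real_)
  cor(s, f)
}

#' Relative deviation of a subsampled estimate from the full-data value
#'
#' @param sub_value,full_value Numeric (vectorized).
#' @return `(sub_value - full_value) / full_value`; `NA` where
#'   `full_value == 0` (undefined).
#' @examples
#' relative_deviation(0.45, 0.5)
#' @export
relative_deviation <- function(sub_value, full_value) {
  out <- (sub_value - full_value) / full_value
  out[full_value == 0] <- NA_real_
  out
}

#' Configuration for the replicate-size design study
#'
#' @param replicate_sizes Replicate sizes to evaluate (default `c(2, 5, 10,
#'   15)`, each >= 2 and at most the full replicate count).
#' @param n_draws Subsample draws per replicate size (default 20).
#' @param seed Integer seed governing subsampling and refits.
#' @param traits_univariate Traits to refit with the single-trait model
#'   (`NULL` = all traits present).
#' @param trait_pairs List of length-2 character vectors for bivariate refits
#'   (`NULL` = all pairs of the univariate traits; set `list()` to skip).
#' @return A `design_study_config` list.
#' @export
design_study_config <- function(replicate_sizes = c(2, 5, 10, 15),
                                n_draws = 20L, seed = 1L,
                                traits_univariate = NULL,
                                trait_pairs = NULL) {
  assert_that(all(replicate_sizes >= 2) && all(replicate_sizes == floor(replicate_sizes)),
              "`replicate_sizes` must be integers >= 2")
  assert_that(is_count(n_draws, 1L), "`n_draws` must be >= 1")
  structure(
    list(
      replicate_sizes = as.integer(sort(unique(replicate_sizes))),
      n_draws = as.integer(n_draws), seed = as.integer(seed),
      traits_univariate = traits_univariate, trait_pairs = trait_pairs
    ),
    class = "design_study_config"
  )
}

#' Run the replicate-size subsampling design study
#'
#' Fits the full dataset once, then for every replicate size `rs` and
#' subsample draw refits the model(s) on within-line subsamples and measures,
#' relative to the full-data fit: accuracy (Pearson correlation across lines)
#' of line means, GEBVs and line CVs; accuracy of the genetic-correlation
#' vector across trait pairs (when >= 3 pairs are fitted, otherwise per-pair
#' relative deviation only); and relative deviation of the variance
#' components and narrow-sense heritability.
#'
#' @param pheno Full replicated phenotype tibble.
#' @param grm A [grm].
#' @param spec A [model_spec] used for every fit (chain seeds vary per draw).
#' @param config A [design_study_config].
#' @return A `design_study` object: `results` (tibble with columns `rs`,
#'   `draw`, `trait`, `parameter`, `metric`, `value`), `cv_lines` (per-line
#'   subsampled CVs for the dispersion criterion), `full` (the full-data
#'   fits), `failed` (count of non-converged subsample fits, excluded from
#'   aggregation). Methods: `tidy()` (per-RS medians and quartiles),
#'   `autoplot()`.
#' @export
run_design_study <- function(pheno, grm, spec = model_spec(),
                             config = design_study_config()) {
  pheno <- check_pheno(pheno)
  assert_that(inherits(config, "design_study_config"),
              "`config` must come from design_study_config()")
  traits <- config$traits_univariate %||% unique(pheno$trait)
  pairs <- config$trait_pairs %||%
    (if (length(traits) >= 2) utils::combn(traits, 2, simplify = FALSE) else list())
  n_rep_full <- max(tabulate(factor(paste(pheno$line, pheno$trait))))
  assert_that(all(config$replicate_sizes <= n_rep_full),
              "replicate sizes exceed the full replicate count")

  fit_uni <- function(dat, fit_seed) {
    sp <- spec
    sp$seed <- fit_seed
    uni <- lapply(traits, function(tr) fit_single_trait(dat, grm, tr, sp))
    names(uni) <- traits
    if (!all(vapply(uni, function(f) isTRUE(f$converged), logical(1)))) {
      return(NULL)
    }
    uni
  }
  fit_biv <- function(dat, fit_seed) {
    sp <- spec
    sp$seed <- fit_seed
    biv <- lapply(pairs, function(pr) fit_bivariate(dat, grm, pr, sp))
    if (!all(vapply(biv, function(f) isTRUE(f$converged), logical(1)))) {
      return(NULL)
    }
    biv
  }
  extract_uni <- function(uni) {
    list(
      line_mean = lapply(uni, function(f) f$lines$line_mean),
      gebv = lapply(uni, function(f) f$lines$gebv),
      cv = lapply(uni, function(f) f$lines$cv),
      comps = lapply(uni, function(f) {
        s <- summarize_posterior(f)
        setNames(s$point, s$parameter)
      })
    )
  }
  extract_rg <- function(biv) {
    vapply(biv, function(f) mean(f$draws$r_g), numeric(1))
  }

  seed0 <- derive_seed(config$seed, "mcmc")
  full_uni <- fit_uni(pheno, seed0)
  full_biv <- if (length(pairs) > 0) fit_biv(pheno, seed0) else list()
  assert_that(!is.null(full_uni) && !is.null(full_biv),
              "the full-data fit did not converge; increase warmup/samples")
  full <- extract_uni(full_uni)
  full$r_g <- extract_rg(full_biv)

  rows <- list()
  cv_rows <- list()
  failed <- 0L
  comp_pars <- c("var_additive", "var_nonadditive", "var_error", "h2")
  for (rs in config$replicate_sizes) {
    for (dr in seq_len(config$n_draws)) {
      sseed <- derive_seed(config$seed, "subsample") %% 1000000L +
        rs * 100000L + dr
      sub <- subsample_replicates(pheno, rs, seed = sseed)
      # univariate and bivariate refits are gated on convergence
      # independently, so a flagged correlation fit does not discard the
      # draw's univariate metrics (and vice versa)
      uni <- tryCatch(fit_uni(sub, sseed + 7L), error = function(e) NULL)
      if (is.null(uni)) {
        failed <- failed + 1L
      } else {
        est <- extract_uni(uni)
        for (tr in traits) {
          acc <- c(
            line_mean = accuracy(est$line_mean[[tr]], full$line_mean[[tr]]),
            gebv = accuracy(est$gebv[[tr]], full$gebv[[tr]]),
            cv = accuracy(est$cv[[tr]], full$cv[[tr]])
          )
          dev <- relative_deviation(est$comps[[tr]][comp_pars],
                                    full$comps[[tr]][comp_pars])
          rows[[length(rows) + 1L]] <- tibble(
            rs = rs, draw = dr, trait = tr,
            parameter = c(names(acc), comp_pars),
            metric = c(rep("accuracy", 3), rep("relative_deviation", 4)),
            value = unname(c(acc, dev))
          )
          cv_rows[[length(cv_rows) + 1L]] <- tibble(
            rs = rs, draw = dr, trait = tr,
            line = uni[[tr]]$lines$line,
            cv_sub = est$cv[[tr]],
            cv_full = full$cv[[tr]]
          )
        }
      }
      if (length(pairs) > 0) {
        biv <- tryCatch(fit_biv(sub, sseed + 13L), error = function(e) NULL)
        if (is.null(biv)) {
          failed <- failed + 1L
        } else {
          r_g <- extract_rg(biv)
          val <- if (length(pairs) >= 3) accuracy(r_g, full$r_g) else NA_real_
          rows[[length(rows) + 1L]] <- tibble(
            rs = rs, draw = dr, trait = "all_pairs", parameter = "r_g",
            metric = "accuracy", value = val
          )
          rows[[length(rows) + 1L]] <- tibble(
            rs = rs, draw = dr,
            trait = vapply(pairs, paste, collapse = ":", FUN.VALUE = ""),
            parameter = "r_g", metric = "relative_deviation",
            value = relative_deviation(r_g, full$r_g)
          )
        }
      }
    }
  }
  structure(
    list(
      results = dplyr::bind_rows(rows),
      cv_lines = dplyr::bind_rows(cv_rows),
      full = full, config = config, failed = failed
    ),
    class = "design_study"
  )
}

#' @export
print.design_study <- function(x, ...) {
  cat(sprintf(
    "<design_study> RS in {%s}, %d draws each, %d failed fits excluded\n",
    paste(x$config$replicate_sizes, collapse = ", "),
    x$config$n_draws, x$failed
  ))
  print(tidy(x))
  invisible(x)
}

#' Per-replicate-size summary of a design study
#'
#' @param x A `design_study`.
#' @param ... Unused.
#' @return Tibble with median and quartiles of each metric per `rs`,
#'   `trait`, `parameter`.
#' @method tidy design_study
#' @export
tidy.design_study <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(x$results, .data$rs, .data$trait, .data$parameter,
                    .data$metric),
    median = median(.data$value, na.rm = TRUE),
    q25 = quantile(.data$value, 0.25, na.rm = TRUE, names = FALSE),
    q75 = quantile(.data$value, 0.75, na.rm = TRUE, names = FALSE),
    n = sum(is.finite(.data$value)),
    .groups = "drop"
  )
}

#' Replicate-size choice by the line-CV dispersion criterion
#'
#' A smaller experiment yields one realization of each line's CV estimate,
#' so the criterion asks how reliably that single estimate comes within
#' `[full / band, full * band]` of the full-data CV. Per line, the fraction
#' of subsample draws falling inside the band is computed; a line is
#' "reliable" at a given replicate size when that fraction is at least
#' `reliability`. The criterion picks the smallest replicate size at which
#' at least `min_fraction` of lines are reliable. With the default
#' `band = 1.5` this operationalizes the "within 1.5 times the full-set CV
#' estimate" rule.
#'
#' @param study A `design_study`.
#' @param band Multiplicative tolerance band (default 1.5).
#' @param reliability Required in-band probability per line (default 0.9).
#' @param min_fraction Minimum fraction of reliable lines (default 0.9).
#' @return Smallest qualifying replicate size (`NA` if none qualifies), with
#'   the per-RS reliable-line fractions as attribute `"fractions"`.
#' @export
rs_cv_criterion <- function(study, band = 1.5, reliability = 0.9,
                            min_fraction = 0.9) {
  assert_that(inherits(study, "design_study"), "`study` must be a design_study")
  per_line <- dplyr::summarise(
    dplyr::group_by(study$cv_lines, .data$rs, .data$trait, .data$line),
    in_band = mean(.data$cv_sub >= .data$cv_full / band &
                     .data$cv_sub <= .data$cv_full * band, na.rm = TRUE),
    .groups = "drop"
  )
  frac <- dplyr::summarise(
    dplyr::group_by(per_line, .data$rs),
    fraction = mean(.data$in_band >= reliability),
    .groups = "drop"
  )
  ok <- frac$rs[frac$fraction >= min_fraction]
  structure(if (length(ok) > 0) min(ok) else NA_integer_,
            fractions = frac)
}

#' Replicate-size choice by the accuracy-plateau criterion
#'
#' Smallest replicate size whose median accuracy for `parameter` comes within
#' `slack` of the best median accuracy over all evaluated replicate sizes —
#' i.e. the point beyond which there is little further gain.
#'
#' @param study A `design_study`.
#' @param parameter Parameter whose accuracy to use (default `"line_mean"`).
#' @param slack Allowed shortfall from the best median accuracy (default 0.05).
#' @return Smallest qualifying replicate size, with per-RS medians attached
#'   as attribute `"medians"`.
#' @export
rs_accuracy_criterion <- function(study, parameter = "line_mean",
                                  slack = 0.05) {
  assert_that(inherits(study, "design_study"), "`study` must be a design_study")
  s <- tidy(study)
  s <- s[s$parameter == parameter & s$metric == "accuracy", ]
  med <- dplyr::summarise(dplyr::group_by(s, .data$rs),
                          median = median(.data$median), .groups = "drop")
  ok <- med$rs[med$median >= max(med$median) - slack]
  structure(min(ok), medians = med)
}

#' Boxplots of design-study metrics by replicate size
#'
#' @param object A `design_study`.
#' @param metric `"accuracy"` or `"relative_deviation"`.
#' @param ... Unused.
#' @return A ggplot faceted by parameter.
#' @method autoplot design_study
#' @export
autoplot.design_study <- function(object, metric = "accuracy", ...) {
  df <- object$results[object$results$metric == metric, ]
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$rs), y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(ggplot2::vars(.data$parameter, .data$trait),
                        scales = "free_y") +
    ggplot2::labs(x = "replicate size", y = metric) +
    ggplot2::theme_minimal()
}
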