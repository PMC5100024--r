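# Shared fixture builders. Everything is generated in code under fixed
# seeds; nothing is read from disk.

tiny_panel <- function(n_lines = 15, n_snps = 80, n_reps = 4, seed = 1,
                       ...) {
  g <- simulate_genotypes(n_lines, n_snps, seed = seed)
  ph <- simulate_phenotypes(g, pheno_sim_config(n_reps = n_reps, ...),
                            seed = seed + 100)
  list(geno = g, grm = compute_grm(g), pheno = ph)
}

fast_spec <- function(...) {
  model_spec(chains = 2, warmup = 100, samples = 200, ...)
}

# noiseless linear-mixture spectra with known concentrations
clean_spectra <- function(n = 40, seed = 3, by = 16, background = NULL,
                          scatter_sdlog = 0, baseline_offset_sd = 0,
                          baseline_slope_sd = 0, noise_sd = 0,
                          wetchem_error_sd = 0, ...) {
  conc <- withr::with_seed(seed, cbind(
    starch = runif(n, 0.05, 0.45),
    sucrose = runif(n, 0.03, 0.18)
  ))
  cfg <- spectra_sim_config(
    wavenumbers = seq(3300, 12000, by = by), background = background,
    scatter_sdlog = scatter_sdlog, baseline_offset_sd = baseline_offset_sd,
    baseline_slope_sd = baseline_slope_sd, noise_sd = noise_sd,
    wetchem_error_sd = wetchem_error_sd, ...
  )
  list(spectra = simulate_spectra(conc, cfg, seed = seed + 1),
       conc = conc, config = cfg)
}
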