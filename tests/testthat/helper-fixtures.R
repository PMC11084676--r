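# Shared fixture builders. All data is generated in code at test time.

PLANTED_BANDS <- c(727, 956, 1045, 1065)

# Tiny two-cohort study for structural tests (fast: coarse grid, few patients)
tiny_synth <- function(seed = 1, replicates_per_patient = 2, ...) {
  synth_config(grid_step = 25,
               replicates_per_patient = replicates_per_patient,
               n_healthy_c1 = 3, n_preclinical_c1 = 3,
               n_healthy_c2 = 3, n_preclinical_c2 = 3, seed = seed, ...)
}

# Single-cohort patient-level study for variable-recovery tests:
# ~200 variables, planted class effect 0.3, within-class CV ~10% from the
# per-patient amplitude effect.
recovery_patients <- function(seed, n_per_class = 20, grid_step = 6, ...) {
  cfg <- synth_config(grid_step = grid_step, replicates_per_patient = 1,
                      n_healthy_c1 = n_per_class,
                      n_preclinical_c1 = n_per_class,
                      n_healthy_c2 = 1, n_preclinical_c2 = 1,
                      baseline_scale = 0, scatter_sd = 0, noise_sd = 0.02,
                      seed = seed, ...)
  d <- generate_study(cfg)
  d <- d[d$cohort == 1, , drop = FALSE]
  d$replicate <- NULL
  d
}

# selected wavenumbers hitting a planted band within one grid step
planted_hits <- function(selected, grid_step = 6) {
  vapply(PLANTED_BANDS, function(b) any(abs(selected - b) <= grid_step),
         logical(1))
}

# Patient tibble from a bare matrix + 0/1 response (toy algebraic tests)
toy_patients <- function(x, y, wavenumbers = 500 + 10 * seq_len(ncol(x))) {
  colnames(x) <- as.character(wavenumbers)
  dplyr::bind_cols(
    tibble::tibble(patient_id = sprintf("P%02d", seq_len(nrow(x))),
                   label = ifelse(y == 1, "PC", "H"), cohort = 1L),
    tibble::as_tibble(x)
  )
}
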