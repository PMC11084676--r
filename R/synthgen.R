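#' Describe a synthetic Raman band
#'
#' One row per band of a pseudo-Voigt (50/50 Gaussian--Lorentzian) peak table.
#' `class_effect` multiplies the amplitude for preclinical (PC) patients,
#' `batch_effect` multiplies it for cohort 2, so bands can be made
#' class-discriminative, batch-affected, both, or neither.
#'
#' @param center Band center, Raman shift in cm^-1.
#' @param width Full width at half maximum in cm^-1. Must be > 0.
#' @param base_amplitude Peak height in arbitrary intensity units. Must be > 0.
#' @param class_effect Multiplicative amplitude shift for the PC class
#'   (0 = non-discriminative). Must be > -1.
#' @param batch_effect Multiplicative amplitude shift for cohort 2. Must be > -1.
#' @return A one-row tibble; rows are combined with [dplyr::bind_rows()].
#' @export
#' @examples
#' peak_spec(1045, width = 12, base_amplitude = 1, class_effect = 0.3)
peak_spec <- function(center, width = 12, base_amplitude = 1,
                      class_effect = 0, batch_effect = 0) {
  check_number(center, "center")
  check_number(width, "width", min = 0, strict_min = TRUE)
  check_number(base_amplitude, "base_amplitude", min = 0, strict_min = TRUE)
  check_number(class_effect, "class_effect", min = -1, strict_min = TRUE)
  check_number(batch_effect, "batch_effect", min = -1, strict_min = TRUE)
  tibble(center = center, width = width, base_amplitude = base_amplitude,
         class_effect = class_effect, batch_effect = batch_effect)
}

#' Default planted band table
#'
#' Four class-discriminative bands at 727, 956, 1045 and 1065 cm^-1 (bands
#' reported as discriminative for preclinical Alzheimer's disease in dried
#' CSF droplets, here planted with a known +30% amplitude effect in the PC
#' class) plus non-discriminative filler bands across the fingerprint region,
#' several of which carry a cohort-2 batch effect so that batch structure is
#' present without being confounded with class.
#'
#' @param class_effect Amplitude shift applied to the discriminative bands.
#' @param batch_effect Amplitude shift applied to the batch-affected fillers.
#' @return A peak tibble as built by [peak_spec()].
#' @export
default_peaks <- function(class_effect = 0.3, batch_effect = 0.2) {
  dplyr::bind_rows(
    # planted discriminative bands
    peak_spec(727,  12, 1.0, class_effect = class_effect),
    peak_spec(956,  12, 1.0, class_effect = class_effect),
    peak_spec(1045, 12, 1.0, class_effect = class_effect),
    peak_spec(1065, 12, 1.0, class_effect = class_effect),
    # non-discriminative fillers; some batch-affected
    peak_spec(650,  16, 0.6),
    peak_spec(760,  14, 0.8),
    peak_spec(830,  14, 0.7),
    peak_spec(900,  16, 1.2, batch_effect = batch_effect),
    peak_spec(1004, 10, 1.5),
    peak_spec(1100, 18, 0.9),
    peak_spec(1160, 14, 0.7),
    peak_spec(1250, 20, 1.0, batch_effect = batch_effect),
    peak_spec(1340, 18, 0.8),
    peak_spec(1450, 18, 1.3, batch_effect = batch_effect),
    peak_spec(1580, 16, 0.7),
    peak_spec(1660, 20, 1.4, batch_effect = batch_effect),
    peak_spec(1740, 14, 0.5)
  )
}

#' Configuration of the synthetic two-cohort Raman study
#'
#' Defaults reproduce the study design the pipeline targets: two cohorts of
#' 40 (20 healthy + 20 preclinical) and 35 (20 + 15) patients, 15 replicate
#' spectra per patient acquired at the ring of the dried droplet, and a
#' fingerprint-region grid of 600--1800 cm^-1 at 1 cm^-1.
#'
#' @param grid_min,grid_max,grid_step Wavenumber grid in cm^-1.
#' @param peaks Peak tibble, see [peak_spec()] and [default_peaks()].
#' @param n_healthy_c1,n_preclinical_c1,n_healthy_c2,n_preclinical_c2 Patient
#'   counts per class and cohort.
#' @param replicates_per_patient Replicate spectra per patient.
#' @param baseline_order Polynomial degree of the per-spectrum baseline drift.
#' @param baseline_scale Baseline intensity scale (arbitrary units); 0 disables.
#' @param scatter_sd Standard deviation of the log of the per-spectrum
#'   multiplicative scatter factor (lognormal, median 1); 0 disables.
#' @param noise_sd Standard deviation of additive Gaussian noise; 0 disables.
#' @param patient_sd Standard deviation of the per-patient multiplicative
#'   amplitude effect, shared by all replicates of one patient; 0 disables.
#' @param seed Integer seed; identical configurations generate bit-identical
#'   datasets.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(grid_min = 600, grid_max = 1800, grid_step = 1,
                         peaks = default_peaks(),
                         n_healthy_c1 = 20, n_preclinical_c1 = 20,
                         n_healthy_c2 = 20, n_preclinical_c2 = 15,
                         replicates_per_patient = 15,
                         baseline_order = 3, baseline_scale = 0.5,
                         scatter_sd = 0.05, noise_sd = 0.02,
                         patient_sd = 0.1, seed = 1L) {
  check_number(grid_min, "grid_min")
  check_number(grid_max, "grid_max", min = grid_min, strict_min = TRUE)
  check_number(grid_step, "grid_step", min = 0, strict_min = TRUE)
  stopifnot(is.data.frame(peaks),
            all(c("center", "width", "base_amplitude",
                  "class_effect", "batch_effect") %in% names(peaks)))
  cfg <- list(
    grid_min = grid_min, grid_max = grid_max, grid_step = grid_step,
    peaks = as_tibble(peaks),
    n_healthy_c1 = check_count(n_healthy_c1, "n_healthy_c1"),
    n_preclinical_c1 = check_count(n_preclinical_c1, "n_preclinical_c1"),
    n_healthy_c2 = check_count(n_healthy_c2, "n_healthy_c2"),
    n_preclinical_c2 = check_count(n_preclinical_c2, "n_preclinical_c2"),
    replicates_per_patient = check_count(replicates_per_patient,
                                         "replicates_per_patient"),
    baseline_order = check_count(baseline_order, "baseline_order", min = 0L),
    baseline_scale = check_number(baseline_scale, "baseline_scale", min = 0),
    scatter_sd = check_number(scatter_sd, "scatter_sd", min = 0),
    noise_sd = check_number(noise_sd, "noise_sd", min = 0),
    patient_sd = check_number(patient_sd, "patient_sd", min = 0),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (nrow(cfg$peaks) > 0) {
    out <- cfg$peaks$center < grid_min | cfg$peaks$center > grid_max
    if (any(out)) {
      abort(paste0("peak center(s) outside the wavenumber grid: ",
                   paste(cfg$peaks$center[out], collapse = ", "), " cm^-1"))
    }
    stopifnot(all(cfg$peaks$width > 0), all(cfg$peaks$base_amplitude > 0),
              all(cfg$peaks$class_effect > -1), all(cfg$peaks$batch_effect > -1))
  }
  structure(cfg, class = "synth_config")
}

synth_grid <- function(config) {
  seq(config$grid_min, config$grid_max, by = config$grid_step)
}

# height-normalised 50/50 pseudo-Voigt profile
pseudo_voigt <- function(x, center, fwhm) {
  u <- (x - center) / (fwhm / 2)
  0.5 / (1 + u^2) + 0.5 * exp(-log(2) * u^2)
}

#' Generate one synthetic replicate spectrum
#'
#' Sums pseudo-Voigt bands with amplitude
#' `base_amplitude * (1 + class_effect[label == "PC"]) * (1 + batch_effect[cohort == 2])
#' * (1 + patient_effect)`, adds a smooth random polynomial baseline, applies a
#' lognormal multiplicative scatter factor, adds Gaussian noise, and clips at
#' zero. Uses the current RNG state: callers control reproducibility by
#' seeding ([generate_study()] does this per patient).
#'
#' @param config A [synth_config()].
#' @param label Class label, `"H"` or `"PC"`.
#' @param cohort Cohort id, 1 or 2.
#' @param patient_effect Dimensionless per-patient amplitude effect, drawn
#'   upstream once per patient.
#' @return Numeric intensity vector on the configured grid.
#' @export
generate_patient_spectrum <- function(config, label, cohort, patient_effect = 0) {
  stopifnot(inherits(config, "synth_config"))
  label <- match.arg(label, CLASS_LEVELS)
  stopifnot(cohort %in% c(1, 2))
  grid <- synth_grid(config)
  y <- numeric(length(grid))
  pk <- config$peaks
  if (nrow(pk) > 0) {
    amp <- pk$base_amplitude *
      (1 + pk$class_effect * (label == "PC")) *
      (1 + pk$batch_effect * (cohort == 2)) *
      (1 + patient_effect)
    for (i in seq_len(nrow(pk))) {
      y <- y + amp[i] * pseudo_voigt(grid, pk$center[i], pk$width[i])
    }
  }
  if (config$baseline_scale > 0) {
    u <- 2 * (grid - config$grid_min) / (config$grid_max - config$grid_min) - 1
    coefs <- c(stats::runif(1, 0.5, 1.5),
               stats::rnorm(config$baseline_order, 0, 0.5))
    y <- y + config$baseline_scale *
      drop(outer(u, 0:config$baseline_order, `^`) %*% coefs)
  }
  if (config$scatter_sd > 0) {
    y <- y * exp(stats::rnorm(1, 0, config$scatter_sd))
  }
  if (config$noise_sd > 0) {
    y <- y + stats::rnorm(length(grid), 0, config$noise_sd)
  }
  pmax(y, 0)
}

#' Generate a full synthetic two-cohort study
#'
#' Draws one multiplicative amplitude effect per patient (shared across that
#' patient's replicates, so per-patient averaging is statistically
#' meaningful), then generates `replicates_per_patient` spectra per patient.
#' Identical configurations (including `seed`) give bit-identical output.
#'
#' @param config A [synth_config()].
#' @return A spectra tibble: columns `patient_id`, `label`, `cohort`,
#'   `replicate`, then one intensity column per wavenumber (named by its
#'   cm^-1 value).
#' @export
#' @examples
#' d <- generate_study(synth_config(grid_step = 25, replicates_per_patient = 2,
#'                                  n_healthy_c1 = 2, n_preclinical_c1 = 2,
#'                                  n_healthy_c2 = 2, n_preclinical_c2 = 2,
#'                                  peaks = peak_spec(1045, 12, 1, 0.3)))
#' dim(d)
generate_study <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  design <- tibble(
    label = rep(c("H", "PC", "H", "PC"),
                c(config$n_healthy_c1, config$n_preclinical_c1,
                  config$n_healthy_c2, config$n_preclinical_c2)),
    cohort = rep(c(1L, 2L),
                 c(config$n_healthy_c1 + config$n_preclinical_c1,
                   config$n_healthy_c2 + config$n_preclinical_c2))
  )
  design$patient_id <- sprintf("C%d_%s%02d", design$cohort, design$label,
                               stats::ave(seq_len(nrow(design)),
                                          design$cohort, design$label,
                                          FUN = seq_along))
  n_rep <- config$replicates_per_patient
  grid <- synth_grid(config)
  withr::with_seed(config$seed, {
    rows <- vector("list", nrow(design))
    for (i in seq_len(nrow(design))) {
      pe <- if (config$patient_sd > 0) stats::rnorm(1, 0, config$patient_sd) else 0
      m <- matrix(0, n_rep, length(grid))
      for (r in seq_len(n_rep)) {
        m[r, ] <- generate_patient_spectrum(config, design$label[i],
                                            design$cohort[i], pe)
      }
      colnames(m) <- as.character(grid)
      rows[[i]] <- spectra_tibble(
        tibble(patient_id = design$patient_id[i], label = design$label[i],
               cohort = design$cohort[i], replicate = seq_len(n_rep)), m)
    }
    dplyr::bind_rows(rows)
  })
}

#' Read and write spectra tables as CSV
#'
#' The on-disk layout matches the in-memory one: metadata columns
#' (`patient_id,label,cohort,replicate` — `replicate` absent for patient
#' tables) followed by one column per wavenumber named by its cm^-1 value.
#' `write_spectra()` optionally writes a sidecar JSON (`<path>.json`)
#' recording the generating [synth_config()] including its seed.
#'
#' @param data A spectra or patient tibble.
#' @param path CSV file path.
#' @param config Optional [synth_config()] to record alongside the data.
#' @return `read_spectra()` returns the tibble; `write_spectra()` returns
#'   `path` invisibly.
#' @export
write_spectra <- function(data, path, config = NULL) {
  readr::write_csv(data, path)
  if (!is.null(config)) {
    cfg <- unclass(config)
    cfg$peaks <- as.data.frame(cfg$peaks)
    jsonlite::write_json(cfg, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_spectra
#' @export
read_spectra <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (col in intersect(c("cohort", "replicate"), names(d))) {
    d[[col]] <- as.integer(d[[col]])
  }
  d
}
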