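#' Preprocessing configuration
#'
#' Parameters for the per-spectrum pipeline: Savitzky--Golay smoothing, then
#' asymmetric-least-squares (Whittaker) baseline subtraction, then standard
#' normal variate (SNV) scaling — applied in that fixed order by
#' [preprocess_spectra()].
#'
#' @param sg_window Savitzky--Golay window length (odd number of points).
#' @param sg_polyorder Savitzky--Golay polynomial order, < `sg_window`.
#' @param whittaker_lambda Smoothness penalty of the Whittaker baseline
#'   smoother (dimensionless, > 0). Larger values give stiffer baselines.
#' @param whittaker_p Asymmetry weight in (0, 1); points above the baseline
#'   get weight `p`, points below get `1 - p`, so small `p` pushes the
#'   baseline under the peaks.
#' @param whittaker_maxiter Maximum reweighting iterations.
#' @param snv_ddof 0 (population sd) or 1 (sample sd) in the SNV divisor.
#' @return A validated `preprocess_config` list.
#' @export
preprocess_config <- function(sg_window = 11, sg_polyorder = 3,
                              whittaker_lambda = 1e5, whittaker_p = 0.01,
                              whittaker_maxiter = 20, snv_ddof = 1) {
  sg_window <- check_count(sg_window, "sg_window")
  sg_polyorder <- check_count(sg_polyorder, "sg_polyorder", min = 0L)
  if (sg_window %% 2 == 0 || sg_window <= sg_polyorder) {
    abort("`sg_window` must be odd and greater than `sg_polyorder`")
  }
  structure(list(
    sg_window = sg_window, sg_polyorder = sg_polyorder,
    whittaker_lambda = check_number(whittaker_lambda, "whittaker_lambda",
                                    min = 0, strict_min = TRUE),
    whittaker_p = check_number(whittaker_p, "whittaker_p", min = 0, max = 1,
                               strict_min = TRUE),
    whittaker_maxiter = check_count(whittaker_maxiter, "whittaker_maxiter"),
    snv_ddof = check_count(snv_ddof, "snv_ddof", min = 0L)
  ), class = "preprocess_config")
}

#' Savitzky--Golay smoothing
#'
#' Local least-squares polynomial smoothing; boundaries are handled by the
#' polynomial fit itself (interior-fit extrapolation), so polynomials up to
#' `polyorder` are reproduced exactly everywhere.
#'
#' @param spectrum Numeric intensity vector.
#' @param window Odd window length in points, > `polyorder`.
#' @param polyorder Polynomial order.
#' @return Smoothed vector of the same length.
#' @export
savgol_smooth <- function(spectrum, window = 11, polyorder = 3) {
  window <- check_count(window, "window")
  polyorder <- check_count(polyorder, "polyorder", min = 0L)
  if (window %% 2 == 0 || window <= polyorder) {
    abort("`window` must be odd and greater than `polyorder`")
  }
  if (length(spectrum) < window) {
    abort("spectrum shorter than the smoothing window")
  }
  as.numeric(signal::sgolayfilt(spectrum, p = polyorder, n = window))
}

#' Asymmetric-least-squares (Whittaker) baseline
#'
#' Estimates a baseline lying beneath the peaks by iteratively reweighted
#' Whittaker smoothing: solve (W + lambda * t(D2) %*% D2) z = W x with
#' second-difference penalty matrix D2, then reset the weights to `p` where
#' x > z and `1 - p` elsewhere, until the weights stabilise or `maxiter` is
#' reached (non-convergence returns the current baseline with a warning).
#' Constants and straight lines are in the null space of the penalty and are
#' reproduced exactly. Subtract the returned baseline from the spectrum to
#' correct it; corrected intensities may be negative and are not clipped.
#'
#' @param spectrum Numeric intensity vector (finite).
#' @param lambda Smoothness penalty, > 0.
#' @param p Asymmetry weight in (0, 1).
#' @param maxiter Maximum reweighting iterations.
#' @return Baseline vector of the same length.
#' @export
whittaker_baseline <- function(spectrum, lambda = 1e5, p = 0.01, maxiter = 20) {
  if (!all(is.finite(spectrum))) abort("spectrum contains non-finite values")
  check_number(lambda, "lambda", min = 0, strict_min = TRUE)
  check_number(p, "p", min = 0, max = 1, strict_min = TRUE)
  if (p >= 1) abort("`p` must be < 1")
  maxiter <- check_count(maxiter, "maxiter")
  m <- length(spectrum)
  if (m < 3) abort("spectrum must have at least 3 points")
  D <- Matrix::diff(Matrix::Diagonal(m), differences = 2)
  P <- lambda * Matrix::crossprod(D)
  w <- rep(1, m)
  z <- spectrum
  for (it in seq_len(maxiter)) {
    z <- as.numeric(Matrix::solve(Matrix::Diagonal(x = w) + P, w * spectrum))
    w_new <- ifelse(spectrum > z, p, 1 - p)
    if (all(w_new == w) && it > 1) return(z)
    w <- w_new
  }
  # final solve under the last weights; flag if they had not stabilised
  z_final <- as.numeric(Matrix::solve(Matrix::Diagonal(x = w) + P, w * spectrum))
  if (!all(ifelse(spectrum > z_final, p, 1 - p) == w)) {
    warn("Whittaker baseline weights did not stabilise within `maxiter`")
  }
  z_final
}

#' Standard normal variate scaling
#'
#' Centers and scales one spectrum to mean 0 and standard deviation 1,
#' removing additive offsets and multiplicative scatter.
#'
#' @param spectrum Numeric vector with at least 2 points and nonzero variance.
#' @param ddof 0 (population sd) or 1 (sample sd).
#' @param .id Identifier used in the zero-variance error message.
#' @return Scaled vector: mean 0, sd 1 under the chosen `ddof`.
#' @export
snv <- function(spectrum, ddof = 1, .id = NULL) {
  if (length(spectrum) < 2) abort("SNV needs at least 2 points")
  centred <- spectrum - mean(spectrum)
  denom <- sqrt(sum(centred^2) / (length(spectrum) - ddof))
  if (!is.finite(denom) || denom == 0) {
    abort(paste0("zero-variance spectrum in SNV",
                 if (!is.null(.id)) paste0(" (", .id, ")")))
  }
  centred / denom
}

#' Preprocess every spectrum of a dataset
#'
#' Applies, per spectrum and in this order: Savitzky--Golay smoothing,
#' Whittaker/AsLS baseline subtraction, SNV scaling. Metadata columns are
#' untouched. Errors from individual spectra are annotated with the
#' patient/replicate identity.
#'
#' @param data A spectra tibble (see [generate_study()]).
#' @param config A [preprocess_config()].
#' @return The preprocessed spectra tibble.
#' @export
preprocess_spectra <- function(data, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  m <- spectra_matrix(data)
  meta <- data[meta_cols(data)]
  ids <- if (all(c("patient_id", "replicate") %in% names(meta))) {
    paste0(meta$patient_id, " replicate ", meta$replicate)
  } else if ("patient_id" %in% names(meta)) {
    as.character(meta$patient_id)
  } else {
    paste("row", seq_len(nrow(m)))
  }
  for (i in seq_len(nrow(m))) {
    x <- tryCatch({
      x <- savgol_smooth(m[i, ], config$sg_window, config$sg_polyorder)
      x <- x - whittaker_baseline(x, config$whittaker_lambda,
                                  config$whittaker_p, config$whittaker_maxiter)
      # featureless spectra are fully absorbed by the baseline (up to solver
      # round-off); treat them as zero variance rather than scaling noise up
      if (stats::sd(x) < 1e-8 * max(1, max(abs(m[i, ])))) {
        abort(paste0("zero-variance spectrum after baseline removal (",
                     ids[i], ")"))
      }
      snv(x, ddof = config$snv_ddof, .id = ids[i])
    }, error = function(e) {
      abort(paste0("preprocessing failed for ", ids[i], ": ",
                   conditionMessage(e)))
    })
    m[i, ] <- x
  }
  spectra_tibble(meta, m)
}

#' Average replicate spectra per patient
#'
#' Collapses a (preprocessed) replicate-level spectra tibble to one
#' representative spectrum per patient: the arithmetic mean over that
#' patient's replicates. Row order follows first appearance of each patient.
#'
#' @param data A spectra tibble with `patient_id`, `label`, `cohort`,
#'   `replicate` metadata.
#' @return A patient tibble: `patient_id`, `label`, `cohort`, then one mean
#'   intensity column per wavenumber.
#' @export
average_per_patient <- function(data) {
  conflicts <- data |>
    dplyr::distinct(.data$patient_id, .data$label, .data$cohort) |>
    dplyr::count(.data$patient_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(conflicts) > 0) {
    abort(paste0("patient(s) with conflicting label/cohort across replicates: ",
                 paste(conflicts$patient_id, collapse = ", ")))
  }
  wn_cols <- wavenumber_cols(data)
  data |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      label = .data$label[1], cohort = .data$cohort[1],
      dplyr::across(dplyr::all_of(wn_cols), mean),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$patient_id, unique(data$patient_id)))
}

#' Per-class mean spectrum and standard error
#'
#' Reporting utility for mean-spectrum plots with standard-error bands.
#'
#' @param patients A patient tibble (see [average_per_patient()]).
#' @return A long tibble with columns `label`, `wavenumber`, `mean`, `se`,
#'   `n`. For a class with a single patient the standard error is `NA` and a
#'   warning is raised.
#' @export
class_mean_se <- function(patients) {
  if (length(unique(patients$label)) < 2) {
    abort("both classes must be present")
  }
  if (any(table(patients$label) < 2)) {
    warn("class with fewer than 2 patients: standard error undefined (NA)")
  }
  wn_cols <- wavenumber_cols(patients)
  patients |>
    tidyr::pivot_longer(dplyr::all_of(wn_cols), names_to = "wavenumber",
                        values_to = "intensity") |>
    dplyr::mutate(wavenumber = as.numeric(.data$wavenumber)) |>
    dplyr::group_by(.data$label, .data$wavenumber) |>
    dplyr::summarise(
      mean = mean(.data$intensity),
      se = stats::sd(.data$intensity) / sqrt(dplyr::n()),
      n = dplyr::n(), .groups = "drop"
    )
}
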