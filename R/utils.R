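#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
NULL

META_COLS <- c("patient_id", "label", "cohort", "replicate")
CLASS_LEVELS <- c("H", "PC")

#' Extract the intensity matrix from a spectra or patient tibble
#'
#' Spectral tables in this package are tibbles with metadata columns
#' (`patient_id`, `label`, `cohort`, and for replicate-level tables
#' `replicate`) followed by one numeric column per wavenumber, named by its
#' Raman shift in cm^-1. These helpers pull out the numeric block and the
#' wavenumber axis.
#'
#' @param data A spectra tibble (replicate level) or patient tibble.
#' @return `spectra_matrix()`: a numeric matrix, one row per spectrum, one
#'   column per wavenumber. `wavenumbers()`: the ascending numeric axis in
#'   cm^-1.
#' @export
spectra_matrix <- function(data) {
  wn_cols <- wavenumber_cols(data)
  m <- as.matrix(data[wn_cols])
  storage.mode(m) <- "double"
  colnames(m) <- wn_cols
  m
}

#' @rdname spectra_matrix
#' @export
wavenumbers <- function(data) {
  as.numeric(wavenumber_cols(data))
}

wavenumber_cols <- function(data) {
  nm <- names(data)
  wn <- suppressWarnings(as.numeric(nm))
  cols <- nm[!is.na(wn)]
  if (length(cols) == 0L) {
    abort("no wavenumber columns found (numeric column names in cm^-1)")
  }
  if (is.unsorted(as.numeric(cols), strictly = TRUE)) {
    abort("wavenumber columns must be strictly increasing")
  }
  cols
}

meta_cols <- function(data) {
  intersect(META_COLS, names(data))
}

# Rebuild a spectra tibble from metadata + matrix (column names = wavenumbers)
spectra_tibble <- function(meta, m) {
  stopifnot(nrow(meta) == nrow(m))
  dplyr::bind_cols(as_tibble(meta), as_tibble(m, .name_repair = "minimal"))
}

# 0/1 coding of the class labels (H = 0, PC = 1)
code_labels <- function(label) {
  bad <- setdiff(unique(label), CLASS_LEVELS)
  if (length(bad) > 0) {
    abort(paste0("unknown class label(s): ", paste(bad, collapse = ", "),
                 " (expected H or PC)"))
  }
  as.numeric(label == "PC")
}

# Deterministic stream of sub-seeds derived from one master seed, so that
# independent stages (per-patient draws, CV partitions, jackknife iterations,
# permutations) are reproducible yet decoupled.
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

check_flag <- function(x, name) {
  if (!(is.logical(x) && length(x) == 1L && !is.na(x))) {
    abort(paste0("`", name, "` must be TRUE or FALSE"))
  }
  x
}

check_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (!(is.numeric(x) && length(x) == 1L && is.finite(x))) {
    abort(paste0("`", name, "` must be a single finite number"))
  }
  if (strict_min && x <= min) abort(paste0("`", name, "` must be > ", min))
  if (!strict_min && x < min) abort(paste0("`", name, "` must be >= ", min))
  if (x > max) abort(paste0("`", name, "` must be <= ", max))
  x
}

check_count <- function(x, name, min = 1L) {
  check_number(x, name, min = min)
  if (x != as.integer(x)) abort(paste0("`", name, "` must be an integer"))
  as.integer(x)
}
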