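SR_CAP <- 1e12  # sentinel for zero-residual columns

#' Variable importance in projection (VIP)
#'
#' Standard VIP: for variable j,
#' VIP_j = sqrt(p * sum_a SSY_a (w_ja / ||w_a||)^2 / sum_a SSY_a), where
#' SSY_a is the y-variance explained by component a. Normalised so that the
#' mean squared VIP over variables is exactly 1.
#'
#' @param model A fitted [fit_plsda()] model.
#' @return A tibble with `wavenumber` and `vip`.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "plsda"))
  ssy <- model$q^2 * colSums(model$t_scores^2)
  p <- length(model$b)
  vip <- unname(sqrt(p * drop(model$w^2 %*% ssy) / sum(ssy)))
  tibble(wavenumber = model$wavenumbers, vip = vip)
}

#' Selectivity ratio (SR)
#'
#' Target-projection SR: the centered training matrix is projected onto the
#' normalised regression vector v = b / ||b||, giving the target-projection
#' reconstruction x_tp = X v v'; SR_j is the ratio of explained to residual
#' sum of squares of column j. Columns fully reconstructed (zero residual)
#' get a large sentinel value and are flagged in the `capped` column.
#'
#' @param model A fitted [fit_plsda()] model.
#' @param data The training patient tibble the model was fit on.
#' @return A tibble with `wavenumber`, `sr` and `capped`.
#' @export
selectivity_ratio <- function(model, data) {
  stopifnot(inherits(model, "plsda"))
  m <- spectra_matrix(data)[, as.character(model$wavenumbers), drop = FALSE]
  xc <- sweep(m, 2, model$x_mean)
  v <- model$b / sqrt(sum(model$b^2))
  t_p <- drop(xc %*% v)
  x_tp <- tcrossprod(t_p, v)
  explained <- colSums(x_tp^2)
  residual <- colSums((xc - x_tp)^2)
  capped <- unname(residual <= .Machine$double.eps * pmax(explained, 1))
  sr <- unname(ifelse(capped, SR_CAP, explained / residual))
  if (any(capped)) {
    warn(paste0(sum(capped), " column(s) with zero target-projection residual;",
                " SR capped at ", format(SR_CAP)))
  }
  tibble(wavenumber = model$wavenumbers, sr = sr, capped = capped)
}

#' Iterative backward variable elimination by VIP + SR
#'
#' At each step the latent-variable count is tuned by cross-validated RMSECV,
#' a model is fitted, VIP and SR scores are computed, and the variables with
#' the worst combined influence (elementwise sum of the VIP rank and the SR
#' rank, low rank = low influence) are dropped — `drop_fraction` of the
#' current set per step, at least one. Elimination stops when the RMSECV of a
#' step exceeds the best seen so far by more than `rel_tol` (relative) or
#' when `min_variables` is reached; the returned subset is the one with
#' minimum RMSECV over the whole trajectory. The same CV partitions (fixed
#' by `cv$seed`) are reused at every step so RMSECV values are comparable
#' across steps.
#'
#' @param data A patient tibble.
#' @param cv A [cv_config()].
#' @param drop_fraction Fraction of current variables dropped per step.
#' @param min_variables Floor on the subset size.
#' @param max_lv Largest candidate LV count at each step.
#' @param rel_tol Relative RMSECV degradation that stops the elimination.
#' @return An object of class `selection_result`: `selected` (wavenumbers of
#'   the best subset), `rmsecv` (at that subset), `trajectory` (tibble with
#'   step, n_variables, n_lv, rmsecv), `stop_reason`
#'   (`"no_improvement"` or `"floor_reached"`), `variables_per_step`.
#' @export
iterative_selection <- function(data, cv = cv_config(), drop_fraction = 0.1,
                                min_variables = 10, max_lv = 10,
                                rel_tol = 0.01) {
  check_number(drop_fraction, "drop_fraction", min = 0, max = 1,
               strict_min = TRUE)
  min_variables <- check_count(min_variables, "min_variables")
  vars <- wavenumbers(data)
  if (min_variables > length(vars)) {
    abort("`min_variables` exceeds the number of variables")
  }
  steps <- list(); vars_per_step <- list()
  best <- Inf
  stop_reason <- NULL
  step <- 0L
  repeat {
    step <- step + 1L
    sel <- select_n_lvs(data, max_lv, cv, variables = vars)
    rmse <- min(sel$rmsecv_curve$rmsecv)
    n_lv <- sel$n_lv
    steps[[step]] <- tibble(step = step, n_variables = length(vars),
                            n_lv = n_lv, rmsecv = rmse)
    vars_per_step[[step]] <- vars
    if (rmse < best) best <- rmse
    else if (rmse > best * (1 + rel_tol)) { stop_reason <- "no_improvement"; break }
    if (length(vars) <= min_variables) { stop_reason <- "floor_reached"; break }
    fit <- fit_plsda(data, n_lv, variables = vars)
    vip <- vip_scores(fit)$vip
    sr <- suppressWarnings(selectivity_ratio(fit, data)$sr)
    influence <- rank(vip) + rank(sr)  # low = least influential
    n_drop <- min(max(1L, floor(drop_fraction * length(vars))),
                  length(vars) - min_variables)
    vars <- vars[-order(influence)[seq_len(n_drop)]]
  }
  trajectory <- dplyr::bind_rows(steps)
  best_step <- which.min(trajectory$rmsecv)
  structure(list(
    selected = vars_per_step[[best_step]],
    rmsecv = trajectory$rmsecv[best_step],
    n_lv = trajectory$n_lv[best_step],
    trajectory = trajectory,
    stop_reason = stop_reason,
    variables_per_step = vars_per_step
  ), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("Variable selection: ", length(x$selected), " wavenumbers kept after ",
      nrow(x$trajectory), " step(s); RMSECV ", signif(x$rmsecv, 4),
      " (", x$stop_reason, ")\n", sep = "")
  invisible(x)
}

#' Jackknife stability selection
#'
#' Repeats the full iterative variable selection `n_iter` times, each time
#' excluding `holdout_per_class` randomly chosen patients from each class,
#' and counts how often each wavenumber survives. Per-iteration seeds (for
#' both the patient holdout and the CV partitions) are derived from `seed`,
#' so the whole procedure is reproducible.
#'
#' @param data A patient tibble.
#' @param cv A [cv_config()] used inside each iteration.
#' @param n_iter Number of jackknife iterations (study default 100).
#' @param holdout_per_class Patients excluded per class per iteration
#'   (study default 5, i.e. 10 of 75 patients).
#' @param seed Master seed (default derived from `cv$seed`).
#' @param ... Passed to [iterative_selection()].
#' @return A `frequency_table`: tibble with `wavenumber` and `count`
#'   (0..`n_iter`), with attribute `n_iterations`.
#' @export
stability_selection <- function(data, cv = cv_config(), n_iter = 100,
                                holdout_per_class = 5, seed = NULL, ...) {
  n_iter <- check_count(n_iter, "n_iter")
  holdout_per_class <- check_count(holdout_per_class, "holdout_per_class")
  seed <- if (is.null(seed)) derive_seeds(cv$seed + 2L, 1) else
    check_count(seed, "seed", min = 0L)
  patients <- split(data$patient_id, data$label)
  if (any(lengths(patients) <= holdout_per_class)) {
    abort("each class must have more than `holdout_per_class` patients")
  }
  wn <- wavenumbers(data)
  counts <- stats::setNames(integer(length(wn)), as.character(wn))
  iter_seeds <- derive_seeds(seed, 2L * n_iter)
  for (i in seq_len(n_iter)) {
    holdout <- withr::with_seed(iter_seeds[2L * i - 1L], unlist(
      lapply(patients, sample, size = holdout_per_class), use.names = FALSE))
    d <- data[!data$patient_id %in% holdout, , drop = FALSE]
    cv_i <- cv
    cv_i$seed <- iter_seeds[2L * i]
    sel <- iterative_selection(d, cv_i, ...)
    keep <- as.character(sel$selected)
    counts[keep] <- counts[keep] + 1L
  }
  structure(tibble(wavenumber = wn, count = unname(counts)),
            n_iterations = n_iter,
            class = c("frequency_table", class(tibble())))
}

#' Frequency-threshold model scan
#'
#' For each frequency threshold f, keeps the wavenumbers selected more than f
#' times over the jackknife iterations, tunes the LV count, cross-validates a
#' PLS-DA model on that subset and records its metrics. The best threshold is
#' the accuracy argmax; ties are broken toward the larger threshold (fewer
#' variables).
#'
#' @param data A patient tibble.
#' @param freq A `frequency_table` from [stability_selection()].
#' @param thresholds Frequency cut-offs; default a 10-step grid over
#'   0..0.9 x n_iterations plus 30 (when n_iterations >= 30).
#' @param cv A [cv_config()].
#' @param max_lv Largest candidate LV count.
#' @return A `threshold_scan` tibble: one row per threshold with
#'   `n_variables`, `n_lv`, `rmsecv` and the classification metrics (rows
#'   with no surviving variables carry NA metrics and `empty = TRUE`);
#'   attribute `best_threshold`.
#' @export
threshold_scan <- function(data, freq, thresholds = NULL, cv = cv_config(),
                           max_lv = 10) {
  n_iter <- attr(freq, "n_iterations") %||% max(freq$count)
  if (is.null(thresholds)) {
    thresholds <- unique(c(round(seq(0, 0.9, by = 0.1) * n_iter),
                           if (n_iter >= 30) 30))
  }
  thresholds <- sort(thresholds)
  if (any(thresholds < 0)) {
    abort("thresholds must be non-negative")
  }
  # thresholds above n_iterations are permitted: no variable can exceed the
  # iteration count, so those rows come back flagged empty rather than erroring
  rows <- purrr::map_dfr(thresholds, function(f) {
    vars <- freq$wavenumber[freq$count > f]
    if (length(vars) == 0) {
      return(tibble(threshold = f, n_variables = 0L, n_lv = NA_integer_,
                    rmsecv = NA_real_, auc = NA_real_, accuracy = NA_real_,
                    sensitivity = NA_real_, specificity = NA_real_,
                    empty = TRUE))
    }
    sel <- select_n_lvs(data, max_lv, cv, variables = vars)
    cvres <- cross_validate(data, sel$n_lv, cv, variables = vars)
    dplyr::bind_cols(
      tibble(threshold = f, n_variables = length(vars), n_lv = cvres$n_lv,
             rmsecv = cvres$rmsecv),
      cvres$metrics[c("auc", "accuracy", "sensitivity", "specificity")],
      tibble(empty = FALSE)
    )
  })
  ok <- !rows$empty
  best <- if (any(ok)) {
    cand <- rows$threshold[ok][rows$accuracy[ok] == max(rows$accuracy[ok])]
    max(cand)
  } else NA_real_
  structure(rows, best_threshold = best,
            class = c("threshold_scan", class(tibble())))
}
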