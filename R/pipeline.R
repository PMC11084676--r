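#' Configuration of a full pipeline run
#'
#' Bundles the generator, preprocessing, cross-validation and
#' variable-selection settings with one master seed. The master seed drives
#' every source of randomness (data generation, CV partitions, jackknife
#' holdouts, permutations) through derived sub-seeds, so a run is replayable
#' bit-identically from its configuration alone.
#'
#' @param synth A [synth_config()] (used when `input` is NULL).
#' @param input Optional path to a spectra CSV (layout of [write_spectra()]);
#'   overrides `synth`.
#' @param preprocess A [preprocess_config()].
#' @param cv A [cv_config()]; its seed is re-derived from `seed`.
#' @param stability_iterations Jackknife iterations (study default 100).
#' @param holdout_per_class Patients held out per class per jackknife
#'   iteration.
#' @param thresholds Frequency grid for [threshold_scan()]; NULL = default.
#' @param drop_fraction,min_variables,max_lv Passed to
#'   [iterative_selection()] / LV tuning.
#' @param n_permutations Label permutations for the final significance test
#'   (0 disables).
#' @param seed Master seed.
#' @param outdir Optional output directory for report CSVs and the manifest.
#' @return A validated `run_config` list.
#' @export
run_config <- function(synth = synth_config(), input = NULL,
                       preprocess = preprocess_config(), cv = cv_config(),
                       stability_iterations = 100, holdout_per_class = 5,
                       thresholds = NULL, drop_fraction = 0.1,
                       min_variables = 10, max_lv = 10, n_permutations = 99,
                       seed = 1L, outdir = NULL) {
  stopifnot(inherits(synth, "synth_config"),
            inherits(preprocess, "preprocess_config"),
            inherits(cv, "cv_config"))
  if (!is.null(input) && !file.exists(input)) {
    abort(paste0("input file does not exist: ", input))
  }
  structure(list(
    synth = synth, input = input, preprocess = preprocess, cv = cv,
    stability_iterations = check_count(stability_iterations,
                                       "stability_iterations"),
    holdout_per_class = check_count(holdout_per_class, "holdout_per_class"),
    thresholds = thresholds,
    drop_fraction = check_number(drop_fraction, "drop_fraction", min = 0,
                                 max = 1, strict_min = TRUE),
    min_variables = check_count(min_variables, "min_variables"),
    max_lv = check_count(max_lv, "max_lv"),
    n_permutations = check_count(n_permutations, "n_permutations", min = 0L),
    seed = check_count(seed, "seed", min = 0L),
    outdir = outdir
  ), class = "run_config")
}

#' Fit and evaluate one cohort's model
#'
#' The per-cohort arm of the experiment: iterative VIP+SR variable selection,
#' LV tuning on the selected subset, cross-validated PLS-DA and metrics.
#'
#' @param patients A patient tibble with both classes.
#' @param cohort_name Label for the report row (e.g. `"Dataset 1"`).
#' @param cv A [cv_config()].
#' @param drop_fraction,min_variables,max_lv See [iterative_selection()].
#' @return A list: `row` (one report row: cohort, matrix shape, AUC,
#'   accuracy, sensitivity, specificity, LVs, variables), `model` (fitted
#'   [fit_plsda()] on the selected subset), `selection`
#'   ([iterative_selection()] result), `cv_result`.
#' @export
run_cohort_model <- function(patients, cohort_name = "cohort",
                             cv = cv_config(), drop_fraction = 0.1,
                             min_variables = 10, max_lv = 10) {
  sel <- iterative_selection(patients, cv, drop_fraction = drop_fraction,
                             min_variables = min_variables, max_lv = max_lv)
  tune <- select_n_lvs(patients, max_lv, cv, variables = sel$selected)
  cvres <- cross_validate(patients, tune$n_lv, cv, variables = sel$selected)
  model <- fit_plsda(patients, tune$n_lv, variables = sel$selected)
  list(row = report_row(cohort_name, nrow(patients), cvres,
                        length(sel$selected)),
       model = model, selection = sel, cv_result = cvres)
}

report_row <- function(cohort, n, cvres, n_vars) {
  dplyr::bind_cols(
    tibble(cohort = cohort,
           matrix = sprintf("%d × %d", n, n_vars)),
    cvres$metrics[c("auc", "accuracy", "sensitivity", "specificity")],
    tibble(lvs = cvres$n_lv, variables = as.integer(n_vars))
  )
}

empty_report_row <- function(cohort, n) {
  tibble(cohort = cohort, matrix = sprintf("%d × 0", n),
         auc = NA_real_, accuracy = NA_real_, sensitivity = NA_real_,
         specificity = NA_real_, lvs = NA_integer_, variables = 0L)
}

#' Combined-cohort, common-variable and frequency-threshold models
#'
#' Reproduces the pooled arm of the experiment: (a) iterative selection and
#' PLS-DA on the pooled cohorts; (b) a model restricted to the wavenumbers
#' common to both per-cohort selections and the pooled selection (flagged
#' empty when the intersection is empty); (c) jackknife stability selection
#' on the pooled data followed by a frequency-threshold scan, reporting the
#' model at the best threshold.
#'
#' @param patients Pooled patient tibble (both cohorts, shared grid).
#' @param selection_c1,selection_c2 Per-cohort [iterative_selection()]
#'   results (their `selected` wavenumbers feed the common-variable model).
#' @param cv A [cv_config()].
#' @param stability_iterations,holdout_per_class,thresholds See
#'   [stability_selection()] / [threshold_scan()].
#' @param drop_fraction,min_variables,max_lv See [iterative_selection()].
#' @return A list: `rows` (three report rows), `pooled` (cohort-model list
#'   for the pooled selection), `common_variables`, `frequency`
#'   (`frequency_table`), `scan` (`threshold_scan`), `best_threshold`,
#'   `threshold_model` (list with model/cv_result, NULL if empty).
#' @export
run_combined_model <- function(patients, selection_c1, selection_c2,
                               cv = cv_config(), stability_iterations = 100,
                               holdout_per_class = 5, thresholds = NULL,
                               drop_fraction = 0.1, min_variables = 10,
                               max_lv = 10) {
  n <- nrow(patients)
  pooled <- run_cohort_model(patients, "Dataset 1 + Dataset 2", cv,
                             drop_fraction, min_variables, max_lv)

  common <- Reduce(intersect, list(selection_c1$selected,
                                   selection_c2$selected,
                                   pooled$selection$selected))
  if (length(common) == 0) {
    common_row <- empty_report_row("Dataset 1 + Dataset 2 in common", n)
    common_cv <- NULL
  } else {
    lv_cap <- min(max_lv, length(common))
    tune <- select_n_lvs(patients, lv_cap, cv, variables = common)
    common_cv <- cross_validate(patients, tune$n_lv, cv, variables = common)
    common_row <- report_row("Dataset 1 + Dataset 2 in common", n, common_cv,
                             length(common))
  }

  freq <- stability_selection(patients, cv, n_iter = stability_iterations,
                              holdout_per_class = holdout_per_class,
                              drop_fraction = drop_fraction,
                              min_variables = min_variables, max_lv = max_lv)
  scan <- threshold_scan(patients, freq, thresholds = thresholds, cv = cv,
                         max_lv = max_lv)
  best <- attr(scan, "best_threshold")
  if (is.na(best)) {
    thr_row <- empty_report_row(
      sprintf("Dataset 1 + Dataset 2 thr@%s", "NA"), n)
    thr_model <- NULL
  } else {
    thr_vars <- freq$wavenumber[freq$count > best]
    tune <- select_n_lvs(patients, max_lv, cv, variables = thr_vars)
    thr_cv <- cross_validate(patients, tune$n_lv, cv, variables = thr_vars)
    thr_row <- report_row(sprintf("Dataset 1 + Dataset 2 thr@%g", best), n,
                          thr_cv, length(thr_vars))
    thr_model <- list(model = fit_plsda(patients, tune$n_lv,
                                        variables = thr_vars),
                      cv_result = thr_cv, variables = thr_vars)
  }

  list(rows = dplyr::bind_rows(pooled$row, common_row, thr_row),
       pooled = pooled, common_variables = common, common_cv = common_cv,
       frequency = freq, scan = scan, best_threshold = best,
       threshold_model = thr_model)
}

#' Project patients onto the first two latent variables
#'
#' Score coordinates (LV1, LV2) per patient with class and cohort labels, for
#' latent-space plots. On the training table this reproduces the model's
#' training scores exactly.
#'
#' @param model A fitted [fit_plsda()] model with at least 2 LVs (a 1-LV
#'   model yields only LV1, with a warning).
#' @param data A patient tibble containing the model's wavenumbers.
#' @return A tibble: `patient_id`, `label`, `cohort`, `LV1` (and `LV2`).
#' @export
export_scores <- function(model, data) {
  stopifnot(inherits(model, "plsda"))
  m <- spectra_matrix(data)[, as.character(model$wavenumbers), drop = FALSE]
  xc <- sweep(m, 2, model$x_mean)
  t1 <- drop(xc %*% model$w[, 1])
  out <- dplyr::bind_cols(
    as_tibble(data[intersect(c("patient_id", "label", "cohort"), names(data))]),
    tibble(LV1 = t1))
  if (model$n_lv >= 2) {
    r <- xc - tcrossprod(t1, model$p_load[, 1])
    out$LV2 <- drop(r %*% model$w[, 2])
  } else {
    warn("model has a single latent variable; LV2 column absent")
  }
  out
}

#' Mean silhouette of a 2-D score embedding
#'
#' Average silhouette width of the LV1/LV2 coordinates under a grouping
#' (class or cohort); positive values mean the groups form separated
#' clusters in score space.
#'
#' @param scores A tibble from [export_scores()].
#' @param group Column name to group by (`"label"` or `"cohort"`).
#' @return Mean silhouette width (scalar in [-1, 1]).
#' @export
score_silhouette <- function(scores, group = "label") {
  x <- as.matrix(scores[intersect(c("LV1", "LV2"), names(scores))])
  g <- as.character(scores[[group]])
  if (length(unique(g)) < 2) abort("silhouette needs at least 2 groups")
  d <- as.matrix(stats::dist(x))
  s <- vapply(seq_along(g), function(i) {
    a <- mean(d[i, setdiff(which(g == g[i]), i)])
    b <- min(vapply(setdiff(unique(g), g[i]), function(h) {
      mean(d[i, g == h])
    }, numeric(1)))
    if (is.nan(a)) 0 else (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Run the full experiment pipeline
#'
#' Simulate (or load) spectra, preprocess and average per patient, fit the
#' per-cohort models, the pooled model, the common-variable model and the
#' frequency-threshold model, run the permutation test on the pooled model,
#' and assemble the five-row report plus LV1/LV2 score tables and a replay
#' manifest. Stage order is fixed: preprocessing, feature extraction, model
#' training, validation.
#'
#' @param config A [run_config()].
#' @return An object of class `pipeline_result`: `report` (five-row tibble),
#'   `scores` (LV1/LV2 per patient for the pooled model), `frequency`,
#'   `scan`, `permutation`, `models`, `manifest`. If `config$outdir` is set,
#'   the report tables and the manifest are also written there as
#'   CSV/JSON.
#' @export
run_full_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seeds <- derive_seeds(config$seed, 4)

  # stage 1: data
  if (!is.null(config$input)) {
    spectra <- read_spectra(config$input)
  } else {
    synth <- config$synth
    synth$seed <- seeds[1]
    spectra <- generate_study(synth)
  }

  # stage 2: preprocessing + per-patient averaging
  patients <- average_per_patient(preprocess_spectra(spectra, config$preprocess))

  cv <- config$cv
  cv$seed <- seeds[2]

  # stage 3/4: per-cohort models
  p1 <- patients[patients$cohort == 1, , drop = FALSE]
  p2 <- patients[patients$cohort == 2, , drop = FALSE]
  m1 <- run_cohort_model(p1, "Dataset 1", cv, config$drop_fraction,
                         config$min_variables, config$max_lv)
  m2 <- run_cohort_model(p2, "Dataset 2", cv, config$drop_fraction,
                         config$min_variables, config$max_lv)

  # combined arms
  cv_comb <- cv
  cv_comb$seed <- seeds[3]
  comb <- run_combined_model(patients, m1$selection, m2$selection, cv_comb,
                             config$stability_iterations,
                             config$holdout_per_class, config$thresholds,
                             config$drop_fraction, config$min_variables,
                             config$max_lv)

  # validation: permutation test of the pooled model
  permutation <- NULL
  if (config$n_permutations > 0) {
    permutation <- permutation_test(
      patients, comb$pooled$cv_result$n_lv, cv_comb,
      n_perm = config$n_permutations,
      variables = comb$pooled$selection$selected, seed = seeds[4])
  }

  report <- dplyr::bind_rows(m1$row, m2$row, comb$rows)
  scores <- export_scores(comb$pooled$model, patients)

  manifest <- list(
    package = "ramanpcad",
    version = as.character(utils::packageVersion("ramanpcad")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    master_seed = config$seed,
    derived_seeds = list(synth = seeds[1], cv = seeds[2],
                         combined_cv = seeds[3], permutation = seeds[4]),
    stage_order = c("preprocessing", "feature_extraction",
                    "model_training", "validation"),
    synth = if (is.null(config$input)) {
      cfg <- unclass(config$synth); cfg$peaks <- as.data.frame(cfg$peaks); cfg
    },
    input = config$input,
    preprocess = unclass(config$preprocess),
    cv = unclass(config$cv),
    stability_iterations = config$stability_iterations,
    holdout_per_class = config$holdout_per_class,
    drop_fraction = config$drop_fraction,
    min_variables = config$min_variables,
    max_lv = config$max_lv,
    n_permutations = config$n_permutations
  )

  result <- structure(list(
    report = report, scores = scores, frequency = comb$frequency,
    scan = as_tibble(comb$scan), best_threshold = comb$best_threshold,
    permutation = permutation,
    models = list(dataset1 = m1, dataset2 = m2, combined = comb),
    patients = patients, manifest = manifest
  ), class = "pipeline_result")

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(report, file.path(config$outdir, "report.csv"))
    readr::write_csv(result$frequency,
                     file.path(config$outdir, "frequency_table.csv"))
    readr::write_csv(result$scan, file.path(config$outdir, "threshold_scan.csv"))
    readr::write_csv(scores, file.path(config$outdir, "scores.csv"))
    if (!is.null(permutation)) {
      readr::write_csv(glance(permutation),
                       file.path(config$outdir, "permutation.csv"))
    }
    jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline report:\n")
  print(x$report)
  if (!is.null(x$permutation)) print(x$permutation)
  invisible(x)
}
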