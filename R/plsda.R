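#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

# ---- NIPALS PLS1 core (matrix level) ----------------------------------------

# x: n x p matrix, y: numeric response, n_lv: components.
# Returns centering info, unit-norm weights W, X-loadings P, y-loadings q,
# scores T and the collapsed regression vector b = W (P'W)^-1 q.
nipals_pls1 <- function(x, y, n_lv) {
  n <- nrow(x); p <- ncol(x)
  n_lv <- check_count(n_lv, "n_lv")
  if (n_lv > min(n - 1, p)) {
    abort(paste0("`n_lv` = ", n_lv, " exceeds min(n - 1, p) = ", min(n - 1, p)))
  }
  x_mean <- colMeans(x)
  y_mean <- mean(y)
  E <- sweep(x, 2, x_mean)
  f <- y - y_mean
  if (sum(f^2) == 0) abort("response has zero variance")
  W <- P <- matrix(0, p, n_lv)
  Tm <- matrix(0, n, n_lv)
  q <- numeric(n_lv)
  for (a in seq_len(n_lv)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < .Machine$double.eps * p) {
      abort(paste0("degenerate component ", a, ": weight vector has zero norm"))
    }
    w <- w / nw
    t_a <- drop(E %*% w)
    tt <- sum(t_a^2)
    p_a <- drop(crossprod(E, t_a)) / tt
    q[a] <- sum(f * t_a) / tt
    E <- E - tcrossprod(t_a, p_a)
    f <- f - q[a] * t_a
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a
  }
  b <- drop(W %*% solve(crossprod(P, W), q))
  list(x_mean = x_mean, y_mean = y_mean, w = W, p_load = P, q = q,
       t_scores = Tm, b = b, n_lv = n_lv)
}

# Cumulative predictions for components 1..A on new data, by score-by-score
# accumulation (algebraically equal to using b truncated at each A).
pls_predict_cum <- function(fit, x_new) {
  R <- sweep(x_new, 2, fit$x_mean)
  out <- matrix(fit$y_mean, nrow(x_new), fit$n_lv)
  acc <- rep(fit$y_mean, nrow(x_new))
  for (a in seq_len(fit$n_lv)) {
    t_a <- drop(R %*% fit$w[, a])
    acc <- acc + t_a * fit$q[a]
    out[, a] <- acc
    R <- R - tcrossprod(t_a, fit$p_load[, a])
  }
  out
}

# ---- user-facing fit / predict ----------------------------------------------

#' Fit a PLS-DA model on a patient table
#'
#' Partial least squares discriminant analysis: the class label is coded
#' numerically (H = 0, PC = 1), the spectra are mean-centered (not
#' autoscaled; they are assumed SNV-scaled upstream), and a PLS1 regression
#' is fitted by NIPALS with deflation. Classification applies `threshold` to
#' the predicted response (ties go to H).
#'
#' @param data A patient tibble (`patient_id`, `label`, `cohort` + wavenumber
#'   columns), e.g. from [average_per_patient()].
#' @param n_lv Number of latent variables, between 1 and min(n - 1, p).
#' @param variables Optional numeric vector of wavenumbers (cm^-1) to fit on;
#'   default all.
#' @param threshold Decision cut on the predicted response (default 0.5).
#' @return An object of class `plsda` with elements `x_mean`, `w`, `p_load`,
#'   `q`, `t_scores`, `b`, `n_lv`, `threshold`, `wavenumbers`, `y_mean`,
#'   `patients` (metadata of the training rows).
#' @export
fit_plsda <- function(data, n_lv, variables = NULL, threshold = 0.5) {
  m <- spectra_matrix(data)
  if (!is.null(variables)) {
    keep <- match(as.character(variables), colnames(m))
    if (anyNA(keep)) {
      abort(paste0("wavenumber(s) not in data: ",
                   paste(variables[is.na(keep)], collapse = ", ")))
    }
    m <- m[, keep, drop = FALSE]
  }
  y <- code_labels(data$label)
  if (length(unique(y)) < 2) abort("both classes (H, PC) must be present")
  fit <- nipals_pls1(m, y, n_lv)
  fit$threshold <- check_number(threshold, "threshold")
  fit$wavenumbers <- as.numeric(colnames(m))
  fit$class_coding <- c(H = 0, PC = 1)
  fit$patients <- data[intersect(c("patient_id", "label", "cohort"), names(data))]
  structure(fit, class = "plsda")
}

#' @export
print.plsda <- function(x, ...) {
  cat("PLS-DA model: ", length(x$b), " wavenumbers, ", x$n_lv,
      " latent variable(s), threshold ", x$threshold, "\n", sep = "")
  invisible(x)
}

#' Predict class scores and labels from a PLS-DA model
#'
#' @param object A fitted [fit_plsda()] model.
#' @param newdata A patient tibble containing the model's wavenumber columns.
#' @param ... Unused.
#' @return A tibble with `score` (continuous predicted response) and
#'   `predicted` (thresholded H/PC label), plus any of `patient_id`, `label`,
#'   `cohort` present in `newdata`.
#' @export
predict.plsda <- function(object, newdata, ...) {
  wn <- as.character(object$wavenumbers)
  missing_wn <- setdiff(wn, names(newdata))
  if (length(missing_wn) > 0) {
    abort(paste0("newdata lacks expected wavenumber(s): ",
                 paste(utils::head(missing_wn, 10), collapse = ", "),
                 if (length(missing_wn) > 10) " ..."))
  }
  m <- as.matrix(newdata[wn])
  storage.mode(m) <- "double"
  score <- drop(sweep(m, 2, object$x_mean) %*% object$b) + object$y_mean
  out <- newdata[intersect(c("patient_id", "label", "cohort"), names(newdata))]
  dplyr::bind_cols(as_tibble(out),
                   tibble(score = score,
                          predicted = classify_scores(score, object$threshold)))
}

#' Threshold continuous PLS-DA scores into class labels
#'
#' @param scores Numeric predicted responses.
#' @param threshold Decision cut; scores strictly above it are PC, ties and
#'   lower scores are H.
#' @return Character vector of H/PC labels.
#' @export
classify_scores <- function(scores, threshold = 0.5) {
  check_number(threshold, "threshold")
  ifelse(scores > threshold, "PC", "H")
}

# ---- metrics ----------------------------------------------------------------

#' Classification metrics for thresholded PLS-DA scores
#'
#' AUC is computed by the rank (Mann--Whitney) statistic with midrank tie
#' correction; accuracy, sensitivity and specificity come from the confusion
#' matrix at `threshold`. The positive class is PC.
#'
#' @param y_true Character H/PC labels (both classes present).
#' @param scores Continuous predicted responses.
#' @param threshold Decision cut (ties assigned to H).
#' @return One-row tibble: `auc`, `accuracy`, `sensitivity`, `specificity`,
#'   `tp`, `fp`, `tn`, `fn`.
#' @export
compute_metrics <- function(y_true, scores, threshold = 0.5) {
  y <- code_labels(y_true)
  if (length(unique(y)) < 2) {
    abort("AUC undefined: y_true contains a single class")
  }
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  r <- rank(scores)  # midranks handle ties
  auc <- (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  pred <- classify_scores(scores, threshold)
  tp <- sum(pred == "PC" & y == 1); fp <- sum(pred == "PC" & y == 0)
  tn <- sum(pred == "H" & y == 0);  fn <- sum(pred == "H" & y == 1)
  tibble(auc = auc,
         accuracy = (tp + tn) / length(y),
         sensitivity = tp / (tp + fn),
         specificity = tn / (tn + fp),
         tp = tp, fp = fp, tn = tn, fn = fn)
}

# ---- cross-validation -------------------------------------------------------

#' Random-subset cross-validation configuration
#'
#' The dataset is partitioned into `n_subsets` random folds, each held out
#' once per partition, and the whole partitioning is repeated `n_iterations`
#' times with fresh random splits. Defaults (15 subsets, 5 iterations) match
#' the study design this pipeline targets. Stratified partitioning keeps both
#' classes in every training split.
#'
#' @param n_subsets Fold count, >= 2.
#' @param n_iterations Number of repeated random partitions, >= 1.
#' @param seed Integer seed controlling the partitions.
#' @param stratified Stratify folds by class (default TRUE).
#' @return A validated `cv_config` list.
#' @export
cv_config <- function(n_subsets = 15, n_iterations = 5, seed = 1L,
                      stratified = TRUE) {
  structure(list(
    n_subsets = check_count(n_subsets, "n_subsets", min = 2L),
    n_iterations = check_count(n_iterations, "n_iterations"),
    seed = check_count(seed, "seed", min = 0L),
    stratified = check_flag(stratified, "stratified")
  ), class = "cv_config")
}

# One stratified random partition into n_subsets folds; redrawn (up to a cap)
# if some training complement would miss a class.
make_folds <- function(y, n_subsets, stratified = TRUE, max_retry = 20L) {
  n <- length(y)
  if (n < n_subsets) abort("fewer samples than CV subsets")
  for (attempt in seq_len(max_retry)) {
    folds <- integer(n)
    if (stratified) {
      for (cl in unique(y)) {
        idx <- sample(which(y == cl))
        folds[idx] <- rep_len(sample(n_subsets), length(idx))
      }
    } else {
      folds <- sample(rep_len(sample(n_subsets), n))
    }
    ok <- all(vapply(seq_len(n_subsets), function(k) {
      tr <- y[folds != k]
      length(tr) > 0 && length(unique(tr)) == length(unique(y))
    }, logical(1)))
    if (ok) return(folds)
  }
  abort("could not draw a partition keeping both classes in every training split")
}

# Matrix-level CV engine. Returns per-iteration cumulative-LV prediction
# matrices (n x max_lv) and fold assignments. max_lv is capped so every
# training split can support it.
cv_core <- function(x, y, max_lv, cv) {
  n <- nrow(x)
  min_train <- n - ceiling(n / cv$n_subsets)
  a_max <- min(max_lv, min_train - 1, ncol(x))
  if (a_max < 1) abort("too few samples for cross-validation")
  seeds <- derive_seeds(cv$seed, cv$n_iterations)
  preds <- vector("list", cv$n_iterations)
  folds_log <- vector("list", cv$n_iterations)
  for (it in seq_len(cv$n_iterations)) {
    folds <- withr::with_seed(seeds[it],
                              make_folds(y, cv$n_subsets, cv$stratified))
    yhat <- matrix(NA_real_, n, a_max)
    for (k in sort(unique(folds))) {
      te <- folds == k
      if (!any(te)) next
      fit <- nipals_pls1(x[!te, , drop = FALSE], y[!te],
                         min(a_max, sum(!te) - 1))
      ph <- pls_predict_cum(fit, x[te, , drop = FALSE])
      if (ncol(ph) < a_max) {  # fold too small for a_max: carry last component
        ph <- cbind(ph, ph[, rep(ncol(ph), a_max - ncol(ph)), drop = FALSE])
      }
      yhat[te, ] <- ph
    }
    preds[[it]] <- yhat
    folds_log[[it]] <- folds
  }
  rmsecv <- sqrt(colMeans(do.call(rbind, lapply(preds, function(m) {
    (m - y)^2
  }))))
  list(preds = preds, folds = folds_log, rmsecv = rmsecv, max_lv = a_max)
}

#' Cross-validate a PLS-DA model by repeated random subsets
#'
#' For each of `n_iterations` stratified random partitions into `n_subsets`
#' folds, fits on the complement of each fold and predicts the held-out fold,
#' so every patient is predicted exactly once per iteration. RMSECV pools the
#' squared errors over all iterations and patients; classification metrics
#' are computed from the pooled cross-validated predictions (and per
#' iteration).
#'
#' @param data A patient tibble with both classes.
#' @param n_lv Latent-variable count to evaluate.
#' @param cv A [cv_config()].
#' @param variables Optional wavenumber subset (cm^-1).
#' @param threshold Decision cut for the metrics.
#' @return An object of class `plsda_cv`: `predictions` (tibble patient x
#'   iteration with cross-validated scores), `rmsecv` (scalar at `n_lv`),
#'   `rmsecv_curve` (tibble lv/rmsecv for 1..n_lv), `metrics` (pooled one-row
#'   tibble), `per_iteration_metrics`, `n_lv`, `cv`.
#' @export
cross_validate <- function(data, n_lv, cv = cv_config(), variables = NULL,
                           threshold = 0.5) {
  stopifnot(inherits(cv, "cv_config"))
  m <- spectra_matrix(data)
  if (!is.null(variables)) {
    m <- m[, as.character(variables), drop = FALSE]
  }
  y <- code_labels(data$label)
  if (length(unique(y)) < 2) abort("both classes (H, PC) must be present")
  core <- cv_core(m, y, n_lv, cv)
  a <- core$max_lv
  pred_tbl <- purrr::imap_dfr(core$preds, function(p, it) {
    tibble(patient_id = data$patient_id, label = data$label,
           iteration = it, score = p[, a])
  })
  pooled <- compute_metrics(pred_tbl$label, pred_tbl$score, threshold)
  per_iter <- pred_tbl |>
    dplyr::group_by(.data$iteration) |>
    dplyr::group_modify(~ compute_metrics(.x$label, .x$score, threshold)) |>
    dplyr::ungroup()
  structure(list(
    predictions = pred_tbl,
    rmsecv = core$rmsecv[a],
    rmsecv_curve = tibble(lv = seq_len(a), rmsecv = core$rmsecv),
    metrics = pooled,
    per_iteration_metrics = per_iter,
    n_lv = a, cv = cv, threshold = threshold
  ), class = "plsda_cv")
}

#' @export
print.plsda_cv <- function(x, ...) {
  cat("PLS-DA cross-validation: ", x$n_lv, " LV(s), RMSECV ",
      signif(x$rmsecv, 4), "\n", sep = "")
  print(x$metrics)
  invisible(x)
}

#' Choose the latent-variable count by minimum RMSECV
#'
#' Runs one cross-validation pass producing the RMSECV curve for 1..`max_lv`
#' components and returns its argmin; ties are broken toward fewer LVs.
#' `max_lv` is capped at what the smallest training split supports.
#'
#' @param data A patient tibble.
#' @param max_lv Largest candidate LV count.
#' @param cv A [cv_config()].
#' @param variables Optional wavenumber subset.
#' @return A list: `n_lv` (chosen count), `rmsecv_curve` (tibble lv/rmsecv).
#' @export
select_n_lvs <- function(data, max_lv = 10, cv = cv_config(), variables = NULL) {
  m <- spectra_matrix(data)
  if (!is.null(variables)) m <- m[, as.character(variables), drop = FALSE]
  y <- code_labels(data$label)
  core <- cv_core(m, y, max_lv, cv)
  list(n_lv = which.min(core$rmsecv),
       rmsecv_curve = tibble(lv = seq_len(core$max_lv), rmsecv = core$rmsecv))
}

# ---- permutation test -------------------------------------------------------

#' Permutation test of a cross-validated PLS-DA model
#'
#' Re-runs the full cross-validation under random permutations of the class
#' labels and compares the observed pooled metric with its null distribution.
#' p = (1 + #\{null >= observed\}) / (n_perm + 1).
#'
#' @param data A patient tibble.
#' @param n_lv Latent-variable count.
#' @param cv A [cv_config()].
#' @param n_perm Number of label permutations.
#' @param metric `"accuracy"` or `"auc"`.
#' @param variables Optional wavenumber subset.
#' @param seed Seed for the permutations (default derived from `cv$seed`).
#' @return An object of class `permutation_result`: `observed_metric`,
#'   `null_metrics`, `p_value`, `n_perm`, `metric`, `seed`.
#' @export
permutation_test <- function(data, n_lv, cv = cv_config(), n_perm = 99,
                             metric = c("accuracy", "auc"), variables = NULL,
                             seed = NULL) {
  metric <- match.arg(metric)
  n_perm <- check_count(n_perm, "n_perm")
  seed <- if (is.null(seed)) derive_seeds(cv$seed + 1L, 1) else
    check_count(seed, "seed", min = 0L)
  obs <- cross_validate(data, n_lv, cv, variables)$metrics[[metric]]
  perm_seeds <- derive_seeds(seed, n_perm)
  null_metrics <- vapply(seq_len(n_perm), function(i) {
    d <- data
    d$label <- withr::with_seed(perm_seeds[i], sample(d$label))
    cross_validate(d, n_lv, cv, variables)$metrics[[metric]]
  }, numeric(1))
  structure(list(
    observed_metric = obs, null_metrics = null_metrics,
    p_value = (1 + sum(null_metrics >= obs)) / (n_perm + 1),
    n_perm = n_perm, metric = metric, seed = seed
  ), class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("Permutation test (", x$metric, "): observed ",
      signif(x$observed_metric, 4), ", p = ", signif(x$p_value, 4),
      " (", x$n_perm, " permutations)\n", sep = "")
  invisible(x)
}

# ---- broom-style methods ----------------------------------------------------

#' Tidy a PLS-DA model
#'
#' @param x A `plsda` object.
#' @param ... Unused.
#' @return A tibble with one row per wavenumber: the regression coefficient
#'   and the training-set centering mean.
#' @exportS3Method
tidy.plsda <- function(x, ...) {
  tibble(wavenumber = x$wavenumbers, coefficient = x$b, x_mean = x$x_mean)
}

#' @rdname tidy.plsda
#' @exportS3Method
glance.plsda <- function(x, ...) {
  tibble(n = nrow(x$t_scores), n_variables = length(x$b), n_lv = x$n_lv,
         threshold = x$threshold)
}

#' Tidy cross-validation results
#'
#' @param x A `plsda_cv` object.
#' @param ... Unused.
#' @return `tidy()`: the RMSECV curve (one row per LV count). `glance()`:
#'   one row with the pooled metrics and RMSECV at the evaluated LV count.
#' @exportS3Method
tidy.plsda_cv <- function(x, ...) x$rmsecv_curve

#' @rdname tidy.plsda_cv
#' @exportS3Method
glance.plsda_cv <- function(x, ...) {
  dplyr::bind_cols(tibble(n_lv = x$n_lv, rmsecv = x$rmsecv), x$metrics)
}

#' Tidy a permutation test
#'
#' @param x A `permutation_result`.
#' @param ... Unused.
#' @return `tidy()`: one row per permutation with the null metric.
#'   `glance()`: observed metric, p-value and permutation count.
#' @exportS3Method
tidy.permutation_result <- function(x, ...) {
  tibble(permutation = seq_len(x$n_perm), null_metric = x$null_metrics)
}

#' @rdname tidy.permutation_result
#' @exportS3Method
glance.permutation_result <- function(x, ...) {
  tibble(metric = x$metric, observed = x$observed_metric,
         p_value = x$p_value, n_perm = x$n_perm)
}
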