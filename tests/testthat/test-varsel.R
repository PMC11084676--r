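test_that("VIP scores satisfy the normalization identity on every fit", {
  withr::with_seed(41, {
    for (i in 1:8) {
      x <- matrix(rnorm(30 * 20), 30, 20)
      y <- rep(c(0, 1), 15)
      fit <- fit_plsda(toy_patients(x, y), n_lv = sample(1:5, 1))
      expect_lt(abs(mean(vip_scores(fit)$vip^2) - 1), 1e-8)
    }
  })
})

test_that("identical columns all get VIP 1", {
  withr::with_seed(42, {
    col <- rnorm(20)
    x <- matrix(col, 20, 6)
    y <- as.numeric(col > median(col))
    fit <- fit_plsda(toy_patients(x, y), n_lv = 1)
    expect_equal(vip_scores(fit)$vip, rep(1, 6), tolerance = 1e-10)
  })
})

test_that("a planted informative variable attains the maximum VIP", {
  hits <- vapply(1:20, function(s) {
    withr::with_seed(4100 + s, {
      n <- 40
      y <- rep(c(0, 1), each = n / 2)
      x <- cbind(y + rnorm(n, 0, 0.1), matrix(rnorm(n * 50), n, 50))
      fit <- fit_plsda(toy_patients(x, y), n_lv = 2)
      v <- vip_scores(fit)$vip
      which.max(v) == 1 && v[1] > 1
    })
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("selectivity ratio matches a per-column projection oracle", {
  withr::with_seed(43, {
    x <- matrix(rnorm(25 * 10), 25, 10)
    y <- rep(c(0, 1), c(12, 13))
    pt <- toy_patients(x, y)
    fit <- fit_plsda(pt, n_lv = 3)
    sr <- selectivity_ratio(fit, pt)$sr
    # oracle: explicit projection of each centered column onto b/||b||
    xc <- sweep(x, 2, colMeans(x))
    v <- fit$b / sqrt(sum(fit$b^2))
    tp <- drop(xc %*% v)
    for (j in 1:10) {
      fitted_j <- tp * v[j]
      expect_equal(sr[j], sum(fitted_j^2) / sum((xc[, j] - fitted_j)^2),
                   tolerance = 1e-10)
    }
  })
})

test_that("selectivity ratio edge cases: orthogonal column and rank-1 cap", {
  withr::with_seed(44, {
    # a column uncorrelated with y and with the informative column has b = 0,
    # hence SR = 0
    y <- rep(c(0, 1), each = 10)
    z <- rnorm(20)
    z <- z - mean(z)
    z <- z - (y - mean(y)) * sum(z * (y - mean(y))) / sum((y - mean(y))^2)
    x <- cbind(y, z)
    pt <- toy_patients(x, y)
    fit <- fit_plsda(pt, n_lv = 1)
    # the informative column is reconstructed exactly (capped); the orthogonal
    # column must get SR exactly 0
    sr <- suppressWarnings(selectivity_ratio(fit, pt))
    expect_equal(sr$sr[2], 0, tolerance = 1e-16)
    # exactly rank-1 data along b: residuals vanish, SR capped and flagged
    t_s <- rnorm(15)
    v <- c(2, -1, 0.5)
    x1 <- outer(t_s, v)
    y1 <- as.numeric(t_s > median(t_s))
    pt1 <- toy_patients(x1, y1)
    fit1 <- fit_plsda(pt1, n_lv = 1)
    expect_warning(sr1 <- selectivity_ratio(fit1, pt1), "capped")
    expect_true(all(sr1$capped))
    expect_true(all(sr1$sr >= 1e12))
  })
})

test_that("elimination bookkeeping: best subset achieves the trajectory minimum", {
  d <- recovery_patients(seed = 61)
  sel <- iterative_selection(d, cv_config(10, 2, seed = 6), max_lv = 6)
  expect_equal(sel$rmsecv, min(sel$trajectory$rmsecv))
  # the returned subset does at least as well as the full variable set
  expect_lte(sel$rmsecv, sel$trajectory$rmsecv[1])
  expect_true(sel$stop_reason %in% c("no_improvement", "floor_reached"))
  expect_gt(length(sel$selected), 0)
  expect_error(iterative_selection(d, min_variables = 10000), "min_variables")
})

test_that("one-variable-per-step elimination reproduces a greedy oracle", {
  withr::with_seed(45, {
    n <- 24
    y <- rep(c(0, 1), each = 12)
    x <- cbind(y + rnorm(n, 0, 0.2), matrix(rnorm(n * 4), n, 4))
    pt <- toy_patients(x, y)
    cv <- cv_config(6, 2, seed = 13)
    sel <- iterative_selection(pt, cv, drop_fraction = 1e-9,
                               min_variables = 2, max_lv = 3, rel_tol = 1e9)
    # oracle: explicit greedy backward elimination, one variable at a time,
    # with the same LV tuning and combined VIP+SR rank rule
    vars <- wavenumbers(pt)
    traj <- numeric(0)
    while (TRUE) {
      tune <- select_n_lvs(pt, 3, cv, variables = vars)
      traj <- c(traj, min(tune$rmsecv_curve$rmsecv))
      if (length(vars) <= 2) break
      f <- fit_plsda(pt, tune$n_lv, variables = vars)
      infl <- rank(vip_scores(f)$vip) +
        rank(suppressWarnings(selectivity_ratio(f, pt)$sr))
      vars <- vars[-which.min(infl)]
    }
    expect_equal(sel$trajectory$rmsecv, traj, tolerance = 1e-12)
    expect_equal(nrow(sel$trajectory), 4)  # 5 -> 4 -> 3 -> 2 variables
  })
})

test_that("stability selection counts are bounded and reproducible", {
  cfg <- synth_config(grid_step = 50, replicates_per_patient = 1,
                      peaks = default_peaks(class_effect = 1.5),
                      n_healthy_c1 = 12, n_preclinical_c1 = 12,
                      n_healthy_c2 = 1, n_preclinical_c2 = 1,
                      baseline_scale = 0, scatter_sd = 0, noise_sd = 0.01,
                      patient_sd = 0.02, seed = 91)
  d <- generate_study(cfg)
  d <- d[d$cohort == 1, ]
  cv <- cv_config(6, 2, seed = 8)
  freq <- stability_selection(d, cv, n_iter = 4, holdout_per_class = 2,
                              min_variables = 5, max_lv = 4)
  expect_true(all(freq$count >= 0 & freq$count <= 4))
  expect_equal(attr(freq, "n_iterations"), 4)
  # identical master seed implies an identical frequency table
  freq2 <- stability_selection(d, cv, n_iter = 4, holdout_per_class = 2,
                               min_variables = 5, max_lv = 4)
  expect_identical(as.data.frame(freq), as.data.frame(freq2))
  # overwhelming planted effect: planted bands survive every iteration
  planted_counts <- freq$count[vapply(freq$wavenumber, function(w) {
    any(abs(w - PLANTED_BANDS) <= 25)
  }, logical(1))]
  expect_true(any(planted_counts == 4))
  expect_error(
    stability_selection(d, cv, n_iter = 2, holdout_per_class = 12),
    "holdout_per_class"
  )
})

test_that("threshold scan keeps the right variable sets at the extremes", {
  d <- recovery_patients(seed = 62, grid_step = 24)
  cv <- cv_config(8, 2, seed = 14)
  freq <- stability_selection(d, cv, n_iter = 3, holdout_per_class = 2,
                              min_variables = 8, max_lv = 4)
  scan <- threshold_scan(d, freq, thresholds = c(0, 1, 3), cv = cv, max_lv = 4)
  ever <- sum(freq$count > 0)
  always <- sum(freq$count > 3)
  expect_equal(scan$n_variables[scan$threshold == 0], ever)
  # threshold = n_iterations keeps only always-selected variables (none can
  # exceed the iteration count)
  expect_equal(scan$n_variables[scan$threshold == 3], always)
  if (always == 0) expect_true(scan$empty[scan$threshold == 3])
  best <- attr(scan, "best_threshold")
  ok <- !scan$empty
  expect_true(best %in% scan$threshold[ok])
  top <- max(scan$accuracy[ok])
  expect_equal(best, max(scan$threshold[ok][scan$accuracy[ok] == top]))
})
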