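test_that("full-rank PLS predictions equal ordinary least squares", {
  withr::with_seed(11, {
    x <- matrix(rnorm(50), 10, 5)
    y <- rbinom(10, 1, 0.5)
    while (length(unique(y)) < 2) y <- rbinom(10, 1, 0.5)
    pt <- toy_patients(x, y)
    fit <- fit_plsda(pt, n_lv = 5)
    # normal-equations oracle
    ols <- lm(y ~ x)
    expect_equal(unname(predict(fit, pt)$score), unname(fitted(ols)),
                 tolerance = 1e-8)
  })
})

test_that("NIPALS scores are orthogonal and b reproduces factor predictions", {
  withr::with_seed(12, {
    for (i in 1:5) {
      x <- matrix(rnorm(30 * 12), 30, 12)
      y <- rep(c(0, 1), each = 15)
      fit <- fit_plsda(toy_patients(x, y), n_lv = 4)
      G <- crossprod(fit$t_scores)
      off <- abs(G[upper.tri(G)])
      expect_true(all(off < 1e-8 * max(diag(G))))
      # b-vector path vs score-by-score accumulation oracle
      xc <- sweep(x, 2, fit$x_mean)
      yhat_b <- drop(xc %*% fit$b) + fit$y_mean
      r <- xc
      yhat_fac <- rep(fit$y_mean, nrow(x))
      for (a in seq_len(fit$n_lv)) {
        t_a <- drop(r %*% fit$w[, a])
        yhat_fac <- yhat_fac + t_a * fit$q[a]
        r <- r - tcrossprod(t_a, fit$p_load[, a])
      }
      expect_equal(yhat_b, yhat_fac, tolerance = 1e-10)
    }
  })
})

test_that("prediction contracts: training reproduction and centered input", {
  withr::with_seed(13, {
    x <- matrix(rnorm(20 * 6), 20, 6)
    y <- rep(c(0, 1), 10)
    pt <- toy_patients(x, y)
    fit <- fit_plsda(pt, n_lv = 3)
    xc <- sweep(x, 2, fit$x_mean)
    expect_equal(predict(fit, pt)$score,
                 drop(xc %*% fit$b) + fit$y_mean)
    # a row at the training mean predicts the training y mean
    mean_row <- toy_patients(matrix(fit$x_mean, 1), 1)
    expect_equal(predict(fit, mean_row)$score, fit$y_mean)
    # variable mismatch errors list what is expected
    expect_error(predict(fit, pt[, 1:5]), "wavenumber")
  })
})

test_that("a single informative variable dominates the regression vector", {
  withr::with_seed(14, {
    y <- rep(c(0, 1), each = 15)
    x <- cbind(y + rnorm(30, 0, 0.01), matrix(rnorm(30 * 9, 0, 0.1), 30, 9))
    fit <- fit_plsda(toy_patients(x, y), n_lv = 1)
    expect_equal(which.max(abs(fit$b)), 1L)
    expect_gt(abs(fit$b[1]) / max(abs(fit$b[-1])), 5)
    expect_gt(cor(predict(fit, toy_patients(x, y))$score, y), 0.99)
  })
})

test_that("thresholding assigns PC above the cut and H at or below it", {
  expect_equal(classify_scores(c(0.9, 0.1), 0.5), c("PC", "H"))
  expect_equal(classify_scores(c(0.5, 0.50001), 0.5), c("H", "PC"))
  m <- compute_metrics(c("PC", "PC", "H", "H"), c(0.2, 0.3, 0.1, 0.05), 0.5)
  expect_equal(m$sensitivity, 0)  # everything below threshold -> all H
  expect_equal(m$specificity, 1)
})

test_that("metrics identities and tie handling hold", {
  m <- compute_metrics(c("PC", "PC", "H", "H"), c(0.9, 0.8, 0.2, 0.1), 0.5)
  expect_equal(m$auc, 1)
  expect_equal(m$accuracy, 1)
  # constant scores give AUC 0.5 under midrank tie correction
  tied <- compute_metrics(c("PC", "H", "PC", "H"), rep(0.4, 4), 0.5)
  expect_equal(tied$auc, 0.5)
  expect_error(compute_metrics(c("PC", "PC"), c(1, 2)), "single class")
  # identities over random confusion tables
  withr::with_seed(15, {
    for (i in 1:20) {
      n <- 40
      lab <- ifelse(rbinom(n, 1, 0.5) == 1, "PC", "H")
      if (length(unique(lab)) < 2) next
      sc <- round(runif(n), 1)  # ties on purpose
      m <- compute_metrics(lab, sc, 0.5)
      expect_equal(m$accuracy, (m$tp + m$tn) / (m$tp + m$tn + m$fp + m$fn))
      expect_equal(m$sensitivity, m$tp / (m$tp + m$fn))
      expect_equal(m$specificity, m$tn / (m$tn + m$fp))
      expect_equal(m$tp + m$fn, sum(lab == "PC"))
    }
  })
})

test_that("rank-statistic AUC equals ROC integration and pROC", {
  # trapezoidal integration over the exhaustive threshold sweep
  roc_auc <- function(y, s) {
    cuts <- c(-Inf, sort(unique(s)), Inf)
    tpr <- vapply(cuts, function(c) mean(s[y == 1] >= c), numeric(1))
    fpr <- vapply(cuts, function(c) mean(s[y == 0] >= c), numeric(1))
    ord <- order(fpr, tpr)
    sum(diff(fpr[ord]) * (utils::head(tpr[ord], -1) + utils::tail(tpr[ord], -1)) / 2)
  }
  withr::with_seed(16, {
    for (i in 1:1000) {
      n <- sample(6:25, 1)
      y <- rbinom(n, 1, 0.5)
      if (length(unique(y)) < 2) next
      s <- round(rnorm(n), sample(0:2, 1))  # frequent ties
      m <- compute_metrics(ifelse(y == 1, "PC", "H"), s)
      expect_equal(m$auc, roc_auc(y, s), tolerance = 1e-10)
    }
    y <- rep(c(0, 1), each = 25)
    s <- rnorm(50) + y
    expect_equal(
      compute_metrics(ifelse(y == 1, "PC", "H"), s)$auc,
      as.numeric(suppressMessages(pROC::auc(y, s, direction = "<"))),
      tolerance = 1e-10
    )
  })
})

test_that("random-subset CV predicts every sample once per iteration", {
  withr::with_seed(17, {
    x <- matrix(rnorm(30 * 8), 30, 8)
    y <- rep(c(0, 1), 15)
    pt <- toy_patients(x, y)
    cvres <- cross_validate(pt, 2, cv_config(n_subsets = 5, n_iterations = 3,
                                             seed = 21))
    counts <- table(cvres$predictions$patient_id, cvres$predictions$iteration)
    expect_true(all(counts == 1))
    expect_gte(cvres$rmsecv, 0)
    # determinism: identical seed, identical partitions and predictions
    cvres2 <- cross_validate(pt, 2, cv_config(n_subsets = 5, n_iterations = 3,
                                              seed = 21))
    expect_identical(cvres$predictions, cvres2$predictions)
    expect_identical(cvres$rmsecv, cvres2$rmsecv)
  })
})

test_that("leave-one-out CV matches a hand-rolled LOO oracle", {
  withr::with_seed(18, {
    x <- matrix(rnorm(12 * 5), 12, 5)
    y <- rep(c(0, 1), 6)
    pt <- toy_patients(x, y)
    cvres <- cross_validate(pt, 2,
                            cv_config(n_subsets = 12, n_iterations = 1,
                                      seed = 4, stratified = FALSE))
    # oracle: refit on each 11-sample complement via the public fit/predict
    oracle <- vapply(1:12, function(i) {
      f <- fit_plsda(pt[-i, ], 2)
      predict(f, pt[i, ])$score
    }, numeric(1))
    got <- cvres$predictions[order(match(cvres$predictions$patient_id,
                                         pt$patient_id)), ]
    expect_equal(got$score, oracle, tolerance = 1e-10)
    expect_equal(cvres$rmsecv, sqrt(mean((oracle - y)^2)), tolerance = 1e-10)
  })
})

test_that("cross-validated predictions do not leak the held-out label", {
  # flipping one sample's label must not change that sample's own
  # cross-validated score (unstratified partitions fixed by the seed)
  withr::with_seed(19, {
    x <- matrix(rnorm(24 * 6), 24, 6)
    y <- rep(c(0, 1), 12)
    pt <- toy_patients(x, y)
    cv <- cv_config(n_subsets = 6, n_iterations = 2, seed = 31,
                    stratified = FALSE)
    base <- cross_validate(pt, 2, cv)$predictions
    flipped <- pt
    flipped$label[1] <- ifelse(pt$label[1] == "PC", "H", "PC")
    alt <- cross_validate(flipped, 2, cv)$predictions
    p1 <- pt$patient_id[1]
    expect_equal(base$score[base$patient_id == p1],
                 alt$score[alt$patient_id == p1], tolerance = 1e-12)
  })
})

test_that("separable synthetic data cross-validates perfectly", {
  # strong planted effect, negligible patient variation
  cfg <- synth_config(grid_step = 12, replicates_per_patient = 1,
                      peaks = default_peaks(class_effect = 1),
                      n_healthy_c1 = 15, n_preclinical_c1 = 15,
                      n_healthy_c2 = 1, n_preclinical_c2 = 1,
                      baseline_scale = 0, scatter_sd = 0, noise_sd = 0.01,
                      patient_sd = 0.02, seed = 77)
  d <- generate_study(cfg)
  d <- d[d$cohort == 1, ]
  cvres <- cross_validate(d, 2, cv_config(n_subsets = 10, n_iterations = 2,
                                          seed = 5))
  expect_equal(cvres$metrics$accuracy, 1)
  expect_equal(cvres$metrics$auc, 1)
})

test_that("LV selection finds a known two-dimensional latent structure", {
  hits <- vapply(1:20, function(s) {
    withr::with_seed(1000 + s, {
      # two orthogonal latent directions of unequal variance, both needed:
      # the first PLS component is pulled toward the high-variance direction
      # and a second component must correct it
      n <- 60; p <- 15
      t1 <- rnorm(n, 0, 2); t2 <- rnorm(n, 0, 1)
      u1 <- rnorm(p); u2 <- rnorm(p)
      u2 <- u2 - u1 * sum(u1 * u2) / sum(u1^2)
      u1 <- u1 / sqrt(sum(u1^2)); u2 <- u2 / sqrt(sum(u2^2))
      x <- outer(t1, u1) + outer(t2, u2) + matrix(rnorm(n * p, 0, 0.02), n, p)
      yc <- t1 + 2 * t2
      keep <- abs(yc - median(yc)) > 0.6  # margin avoids boundary ambiguity
      y <- as.numeric(yc > median(yc))
      sel <- select_n_lvs(toy_patients(x[keep, ], y[keep]), max_lv = 6,
                          cv_config(n_subsets = 10, n_iterations = 5, seed = s))
      sel$n_lv == 2
    })
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("RMSECV curve is nonnegative and noise keeps the model small", {
  withr::with_seed(23, {
    x <- matrix(rnorm(30 * 10), 30, 10)
    y <- rep(c(0, 1), 15)
    sel <- select_n_lvs(toy_patients(x, y), max_lv = 6,
                        cv_config(n_subsets = 6, n_iterations = 2, seed = 9))
    expect_true(all(sel$rmsecv_curve$rmsecv >= 0))
    # pure-noise y: no latent direction helps, argmin stays at the low end
    expect_lte(sel$n_lv, 2)
  })
})

test_that("permutation p-values respect the add-one lower bound and recover
           significance on separable data", {
  cfg <- synth_config(grid_step = 25, replicates_per_patient = 1,
                      peaks = default_peaks(class_effect = 1),
                      n_healthy_c1 = 10, n_preclinical_c1 = 10,
                      n_healthy_c2 = 1, n_preclinical_c2 = 1,
                      baseline_scale = 0, scatter_sd = 0, noise_sd = 0.01,
                      patient_sd = 0.02, seed = 55)
  d <- generate_study(cfg)
  d <- d[d$cohort == 1, ]
  pr <- permutation_test(d, 2, cv_config(n_subsets = 5, n_iterations = 1,
                                         seed = 3),
                         n_perm = 19, metric = "auc")
  expect_gte(pr$p_value, 1 / 20)
  expect_equal(pr$p_value, 1 / 20)  # observed beats every null draw
  expect_length(pr$null_metrics, 19)
  expect_equal(glance(pr)$p_value, pr$p_value)
})

test_that("tidiers return the documented shapes", {
  withr::with_seed(29, {
    x <- matrix(rnorm(20 * 5), 20, 5)
    y <- rep(c(0, 1), 10)
    pt <- toy_patients(x, y)
    fit <- fit_plsda(pt, 2)
    td <- tidy(fit)
    expect_named(td, c("wavenumber", "coefficient", "x_mean"))
    expect_equal(nrow(td), 5)
    expect_equal(glance(fit)$n_lv, 2)
    cvres <- cross_validate(pt, 2, cv_config(4, 2, seed = 2))
    expect_named(tidy(cvres), c("lv", "rmsecv"))
    expect_true(all(c("auc", "accuracy") %in% names(glance(cvres))))
  })
})
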