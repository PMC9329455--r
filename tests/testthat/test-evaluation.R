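test_that("thresholded selection picks confident categories and misses ties", {
  expect_identical(select_category(c(0.9, 0.02, 0.02, 0.02, 0.02, 0.02))$selected,
                   1L)
  # uniform six-class output sits below the 0.17 threshold: missed
  expect_identical(select_category(rep(1 / 6, 6))$selected, NA_integer_)
  # ties at the maximum go to the lowest class index
  expect_identical(select_category(c(0.4, 0.4, 0.2, 0, 0, 0))$selected, 1L)
  expect_error(select_category(c(0.5, 0.6)), "sum to 1")
})

test_that("missed counting matches a direct scan of the probabilities", {
  confident <- lapply(1:5, function(i) {
    select_category(build_targets(i, 6)[1, ] * 0.94 + 0.01)
  })
  expect_identical(count_missed(confident), 0L)

  mixed <- c(confident, lapply(1:3, function(i) select_category(rep(1 / 6, 6))))
  expect_identical(count_missed(mixed), 3L)

  # network outputs on deliberately ambiguous trials: count equals the
  # direct scan of max probability against the threshold
  sim <- simulate_tmaze_dataset(trajectory_sim_config(
    n_participants = 4, trials_per_condition = 2, seed = 61))
  fit <- ffnet(tmaze_features(sim), sim$labels, consecutive_correct = 5,
               max_epochs = 40, seed = 2)
  noisy <- simulate_tmaze_dataset(trajectory_sim_config(
    n_participants = 4, trials_per_condition = 2, noise_sd = 0.4, seed = 62))
  P <- predict(fit, tmaze_features(noisy))
  dec <- predict(fit, tmaze_features(noisy), type = "decision")
  expect_identical(count_missed(dec), sum(apply(P, 1, max) <= 0.17))
})

test_that("confusion counts match enumeration and conserve totals", {
  # hand case: true (1,1,2), pred (1,2,2)
  cc <- confusion_counts(c(1, 1, 2), c(1, 2, 2), 2)
  expect_equal(cc[cc$class == 1, c("tp", "fp", "fn", "tn")],
               data.frame(tp = 1L, fp = 0L, fn = 1L, tn = 1L),
               ignore_attr = TRUE)

  # all-correct predictions: no false positives or negatives
  perfect <- confusion_counts(rep(1:4, 5), rep(1:4, 5), 4)
  expect_true(all(perfect$fp == 0) && all(perfect$fn == 0))

  set.seed(3)
  for (i in 1:100) {
    k <- sample(2:6, 1)
    n <- sample(5:40, 1)
    truth <- sample(k, n, replace = TRUE)
    pred <- sample(k, n, replace = TRUE)
    pred[sample(n, n %/% 5)] <- NA # some missed cases
    mine <- confusion_counts(truth, pred, k)
    expect_equal(mine, enum_confusion(truth, pred, k), ignore_attr = TRUE)
    expect_true(all(rowSums(mine[, c("tp", "fp", "fn", "tn")]) ==
                      sum(!is.na(pred))))
  }
})

test_that("metrics reproduce the published per-class percentages", {
  for (tab in list(ref_counts("tmaze"), ref_counts("ic"))) {
    m <- metrics_from_counts(tab)
    expect_equal(m$precision, tab$precision_pct)
    expect_equal(m$tpr, tab$tpr_pct)
    expect_equal(m$fpr, tab$fpr_pct)
    expect_equal(m$accuracy, tab$accuracy_pct)
  }

  perfect <- metrics_from_counts(data.frame(tp = 10, fp = 0, fn = 0, tn = 90))
  expect_equal(perfect$precision, 100.0)
  expect_equal(perfect$fpr, 0.0)

  # zero denominators give NA sentinels
  degenerate <- metrics_from_counts(data.frame(tp = 0, fp = 0, fn = 3, tn = 7))
  expect_true(is.na(degenerate$precision))
})

test_that("metric identities hold on random counts", {
  set.seed(12)
  for (i in 1:50) {
    ct <- as.list(sample(0:500, 4))
    names(ct) <- c("tp", "fp", "fn", "tn")
    pos <- ct$tp + ct$fn; neg <- ct$fp + ct$tn
    if (pos == 0 || neg == 0) next
    tpr <- ct$tp / pos
    fnr <- ct$fn / pos
    tnr <- ct$tn / neg
    expect_equal(tpr + fnr, 1)
    # accuracy is the prevalence-weighted mix of TPR and TNR
    expect_equal((ct$tp + ct$tn) / (pos + neg),
                 (tpr * pos + tnr * neg) / (pos + neg))
  }
})

test_that("ROC points match the threshold-enumeration oracle", {
  pts <- roc_points(c(0.9, 0.8, 0.4, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(pts$fpr, c(0, 0, 0, 0.5, 1))
  expect_equal(pts$tpr, c(0, 0.5, 1, 1, 1))
  expect_true(any(pts$fpr == 0 & pts$tpr == 1)) # perfect separation

  # constant scores collapse to the diagonal endpoints
  flat <- roc_points(rep(0.3, 6), c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(flat, data.frame(fpr = c(0, 1), tpr = c(0, 1)),
               ignore_attr = TRUE)

  expect_error(roc_points(1:3, c(TRUE, TRUE, TRUE)), "negative case")

  # monotone non-decreasing FPR (and TPR) along the sweep
  set.seed(21)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    truth <- c(TRUE, FALSE, runif(n - 2) > 0.5)
    sc <- round(runif(n), sample(1:3, 1)) # ties included
    pts <- roc_points(sc, truth)
    expect_true(all(diff(pts$fpr) >= 0))
    expect_true(all(diff(pts$tpr) >= 0))
  }
})

test_that("ROC points agree with pROC on random instances", {
  skip_if_not_installed("pROC")
  set.seed(31)
  for (i in 1:50) {
    n <- sample(6:40, 1)
    truth <- c(TRUE, FALSE, runif(n - 2) > 0.5)
    sc <- round(runif(n), 2)
    mine <- roc_points(sc, truth)
    r <- pROC::roc(response = truth, predictor = sc, quiet = TRUE,
                   direction = "<")
    ref <- unique(data.frame(fpr = rev(1 - r$specificities),
                             tpr = rev(r$sensitivities)))
    expect_equal(unique(mine), ref, ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("McNemar statistic and p-value match the printed comparison", {
  # discordant (3, 10): chi-square 49/13 = 3.769, p = 0.052
  stat <- mcnemar_statistic(3, 10)
  expect_equal(round(stat, 3), 3.769)
  expect_lt(abs(mcnemar_pvalue(stat) - 0.052), 5e-4)

  expect_equal(mcnemar_statistic(5, 5), 0)
  expect_error(mcnemar_statistic(0, 0), "undefined")

  # agrees with the uncorrected large-sample test in stats
  ref <- mcnemar.test(matrix(c(20, 3, 10, 30), 2), correct = FALSE)
  expect_equal(stat, unname(ref$statistic))
  expect_equal(mcnemar_pvalue(stat), unname(ref$p.value))

  ca <- c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE)
  cb <- c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE)
  expect_equal(discordant_counts(ca, cb), c(b = 2L, c = 1L))
})

test_that("the selection grid trains, reports and flags coherently", {
  sim <- simulate_tmaze_dataset(trajectory_sim_config(
    n_participants = 5, trials_per_condition = 2, seed = 71))
  X <- tmaze_features(sim)
  new1 <- tmaze_features(simulate_tmaze_dataset(trajectory_sim_config(
    n_participants = 3, trials_per_condition = 2, seed = 72)))

  grid <- model_selection_grid(X, sim$labels, newdata = list(fresh = new1),
                               consecutive = c(3L, 5L, 7L),
                               seed = 4, max_epochs = 60)
  expect_equal(nrow(grid), 6L) # 2 algorithms x 3 settings
  expect_true(all(grid$accuracy >= 0 & grid$accuracy <= 100))
  expect_true(all(grid$missed_fresh >= 0))
  expect_identical(sum(grid$best), 1L)

  # independent check of the two-stage selection rule
  correct <- attr(grid, "correct")
  top <- which.max(grid$accuracy)
  chis <- vapply(seq_len(nrow(grid)), function(i) {
    d <- discordant_counts(correct[[i]], correct[[top]])
    if (sum(d) == 0) 0 else (d[1] - d[2])^2 / sum(d)
  }, numeric(1))
  contenders <- which(chis < 3.841)
  expected_best <- contenders[order(grid$missed_fresh[contenders],
                                    -grid$accuracy[contenders])][1]
  expect_identical(which(grid$best), expected_best)

  # a crippled trainer scores strictly below its fully trained twin on
  # data noisy enough to need more than one full-batch update
  hard <- simulate_tmaze_dataset(trajectory_sim_config(
    n_participants = 8, trials_per_condition = 2, noise_sd = 0.4, seed = 71))
  Xh <- tmaze_features(hard)
  full <- model_selection_grid(Xh, hard$labels, algorithms = "scg",
                               consecutive = 8L, seed = 4, max_epochs = 80)
  crippled <- model_selection_grid(Xh, hard$labels, algorithms = "scg",
                                   consecutive = 8L, seed = 4,
                                   max_epochs = 1)
  expect_lt(crippled$accuracy[1], full$accuracy[1])
})
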