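# Constructed trials exercising each expert rule. Time axis: 3000
# samples over 13 s.

test_that("onset latency finds the first supra-threshold sample", {
  tt <- trial_time()
  zeros <- numeric(3000)
  expect_identical(onset_latency(make_trial(zeros, zeros)), Inf)

  y <- zeros; y[231:3000] <- -0.9
  expect_equal(onset_latency(make_trial(zeros, y)), 231 * 13 / 3000,
               tolerance = 1e-12)

  # sustained sub-threshold wobble never counts as onset
  expect_identical(onset_latency(make_trial(rep(0.05, 3000),
                                            rep(0.05, 3000))), Inf)
})

test_that("constructed trials hit each behavioral category", {
  tt <- trial_time()

  # fleeing: fast backward ramp, no sideways motion
  flee <- make_trial(numeric(3000), -0.9 * pmin(tt / 0.5, 1))
  expect_identical(classify_trial(flee), 1L)

  # approach safety via left turn: backward, then reversal with x = -0.6
  y <- ifelse(tt < 1.5, -0.8 * pmin(tt / 0.1, 1),
              pmin(-0.8 + 1.6 * (tt - 1.5) / 3.5, 0.8))
  x <- ifelse(tt > 1.5 & tt < 8, -0.6, 0)
  expect_identical(classify_trial(make_trial(x, y)), 2L)
  # same geometry turning right
  expect_identical(classify_trial(make_trial(-x, y)), 3L)

  # motionless until 2 s, then forward: conflict by latency
  late <- make_trial(numeric(3000),
                     ifelse(tt < 2, 0, 0.9 * pmin((tt - 2) / 0.5, 1)))
  expect_identical(classify_trial(late), 6L)

  # reaching out via right turn: forward from 0.5 s, x = +0.4 later
  reach_y <- 0.9 * pmin(pmax(tt - 0.5, 0) / 0.3, 1)
  reach_x <- 0.4 * pmin(pmax(tt - 4, 0) / 1, 1)
  expect_identical(classify_trial(make_trial(reach_x, reach_y)), 5L)
  expect_identical(classify_trial(make_trial(-reach_x, reach_y)), 4L)

  # backward-to-forward switch without turning: conflict
  switch_y <- ifelse(tt < 3.5, -0.6 * pmin(tt / 0.3, 1),
                     pmin(-0.6 + 1.4 * (tt - 3.5) / 0.6, 0.8))
  expect_identical(classify_trial(make_trial(numeric(3000), switch_y)), 6L)

  # sustained sub-threshold input stays unclassified
  expect_identical(classify_trial(make_trial(rep(0.2, 3000), numeric(3000))),
                   NA_integer_)
})

test_that("classification is pure and assigns exactly one state", {
  sim <- simulate_tmaze_dataset(trajectory_sim_config(
    n_participants = 5, trials_per_condition = 3, seed = 17))
  lab1 <- classify_trials(sim)
  lab2 <- classify_trials(sim)
  expect_identical(lab1, lab2)
  expect_true(all(is.na(lab1) | lab1 %in% 1:6))
})

test_that("mirroring x swaps left/right labels and fixes 1 and 6", {
  sim <- simulate_tmaze_dataset(trajectory_sim_config(
    n_participants = 6, trials_per_condition = 3, seed = 23))
  swap <- c(1L, 3L, 2L, 5L, 4L, 6L)
  base <- vapply(sim$trials, classify_trial, integer(1))
  mirrored <- vapply(sim$trials, function(tr) {
    classify_trial(trajectory_trial(-tr$x, tr$y, tr$participant,
                                    tr$trial, tr$condition))
  }, integer(1))
  expect_identical(mirrored, swap[base])
})

test_that("bad-performance outliers follow the median/MAD rule", {
  tt <- trial_time()
  smooth_y <- -0.8 * pmin(tt / 0.5, 1)
  smooth <- lapply(1:8, function(i) make_trial(numeric(3000), smooth_y, 1, i))

  # zero dispersion: no trial is flagged
  expect_false(any(vapply(smooth, performance_outlier, logical(1),
                          participant_trials = smooth)))

  # one heavily jittered trial among slightly varying smooth ones
  set.seed(5)
  varied <- lapply(1:8, function(i) {
    make_trial(numeric(3000),
               pmax(-1, pmin(1, smooth_y + rnorm(3000, 0, 0.002))), 1, i)
  })
  rough <- make_trial(pmax(-1, pmin(1, rnorm(3000, 0, 0.3))),
                      pmax(-1, pmin(1, smooth_y + rnorm(3000, 0, 0.3))),
                      1, 9)
  all_trials <- c(varied, list(rough))
  expect_true(performance_outlier(rough, all_trials))

  # direct median/MAD computation agrees
  roughness <- function(tr) mean(abs(diff(tr$x))) + mean(abs(diff(tr$y)))
  sc <- vapply(all_trials, roughness, numeric(1))
  expect_identical(performance_outlier(rough, all_trials),
                   roughness(rough) > median(sc) + 3 * mad(sc))

  # leave-one-out stability: flag survives removing the outlier itself
  expect_true(performance_outlier(rough, varied))
  expect_error(performance_outlier(rough, varied[1:3]), "at least 5")
})
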