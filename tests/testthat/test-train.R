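test_that("dataset splitting follows the floor rule with remainder to training", {
  s <- split_dataset(100, c(0.70, 0.15, 0.15), seed = 1)
  expect_equal(lengths(s), c(train = 70L, validation = 15L, test = 15L))
  s20 <- split_dataset(20, c(0.70, 0.15, 0.15), seed = 1)
  expect_equal(lengths(s20), c(train = 14L, validation = 3L, test = 3L))
  # disjoint and exhaustive
  expect_setequal(unlist(s), 1:100)
  expect_identical(split_dataset(100, seed = 9), split_dataset(100, seed = 9))
  expect_false(identical(split_dataset(100, seed = 9),
                         split_dataset(100, seed = 10)))
  expect_error(split_dataset(5, c(0.9, 0.05, 0.05), seed = 1), "empty")
  expect_error(split_dataset(10, c(0.5, 0.2, 0.2), seed = 1), "summing to 1")
})

test_that("the consecutive-correct rule fires exactly when a run exists", {
  expect_true(check_stopping(rep(TRUE, 150), 100, 1)$stop)
  expect_identical(check_stopping(rep(TRUE, 150), 100, 1)$reason,
                   "validation_run")
  alt <- rep(c(TRUE, FALSE), 100)
  expect_false(check_stopping(alt, 100, 1, grad_norm = 1)$stop)
  # a qualifying run after an early failure still fires
  seq3 <- c(rep(TRUE, 99), FALSE, rep(TRUE, 100))
  expect_identical(check_stopping(seq3, 100, 1)$reason, "validation_run")
  # rule that can never fire is a configuration error
  expect_error(check_stopping(rep(TRUE, 50), 100, 1), "exceeds")
})

test_that("the stopping rule agrees with a brute-force run scanner", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(5:60, 1)
    outcomes <- runif(n) < runif(1, 0.3, 0.95)
    k <- sample(1:n, 1)
    dec <- check_stopping(outcomes, k, epoch = 1, grad_norm = 1,
                          max_epochs = 10)
    expect_identical(dec$stop && dec$reason == "validation_run",
                     brute_longest_run(outcomes) >= k)
  }
})

test_that("safety stops report their reasons", {
  expect_identical(check_stopping(rep(FALSE, 10), 2, epoch = 50,
                                  grad_norm = 1, max_epochs = 50)$reason,
                   "max_epochs")
  expect_identical(check_stopping(rep(FALSE, 10), 2, epoch = 1,
                                  grad_norm = 1e-9)$reason,
                   "gradient_tolerance")
})

test_that("SCG drives a separable toy to 100% training accuracy quickly", {
  toy <- separable_toy()
  spec <- network_spec(2, 3, 2, 2)
  w <- init_network(spec, seed = 2)
  cl <- huangnet:::loss_grad_closures(spec, toy$X, toy$Y)
  losses <- numeric()
  res <- scg_optimize(huangnet:::flatten_weights(w), cl$fn, cl$gr,
                      max_iter = 50,
                      callback = function(iter, par, value, gn) {
                        losses <<- c(losses, value); FALSE
                      })
  P <- ffnet_forward(huangnet:::unflatten_weights(res$par, spec), toy$X)
  expect_equal(max.col(P), toy$y) # 100% training accuracy within 50 epochs
  expect_true(all(diff(losses[1:10]) <= 1e-12)) # monotone early descent
})

test_that("a stationary symmetric start terminates with weights unchanged", {
  spec <- network_spec(2, 3, 2, 2)
  X <- rbind(c(1, 2), c(1, 2))
  Y <- build_targets(c(1, 2), 2) # balanced batch, zero gradient at 0
  cl <- huangnet:::loss_grad_closures(spec, X, Y)
  par0 <- numeric(huangnet:::n_parameters(spec))
  res <- scg_optimize(par0, cl$fn, cl$gr)
  expect_identical(res$stop, "grad_tol")
  expect_equal(res$par, par0)
})

test_that("fitting is reproducible and records a coherent history", {
  sim <- simulate_tmaze_dataset(trajectory_sim_config(
    n_participants = 4, trials_per_condition = 2, seed = 31))
  X <- tmaze_features(sim)
  fit1 <- ffnet(X, sim$labels, consecutive_correct = 5, max_epochs = 60,
                seed = 3)
  fit2 <- ffnet(X, sim$labels, consecutive_correct = 5, max_epochs = 60,
                seed = 3)
  expect_identical(fit1$weights, fit2$weights)
  expect_identical(fit1$history, fit2$history)
  expect_lte(nrow(fit1$history), 60L)
  expect_true(fit1$stop_reason %in%
                c("validation_run", "max_epochs", "gradient_tolerance"))
  expect_true(all(diff(fit1$history$epoch) == 1))
  # longest run never exceeds the validation size
  expect_true(all(fit1$history$longest_run <= length(fit1$split$validation)))
  # over-long run requirement is rejected up front
  expect_error(ffnet(X, sim$labels, consecutive_correct = 100, seed = 3),
               "validation-split size")
})

test_that("fitted models expose the standard S3 surface", {
  sim <- simulate_tmaze_dataset(trajectory_sim_config(
    n_participants = 4, trials_per_condition = 2, seed = 32))
  X <- tmaze_features(sim)
  fit <- ffnet(X, sim$labels, consecutive_correct = 5, max_epochs = 80,
               seed = 4)

  expect_output(print(fit), "feedforward classifier")
  expect_output(print(summary(fit)), "per-class test metrics")
  cf <- coef(fit)
  expect_named(cf, c("W1", "b1", "W2", "b2", "W3", "b3"))
  expect_equal(dim(cf$W1), c(fit$spec$layer1, 6003L))

  P <- predict(fit, X)
  expect_equal(dim(P), c(nrow(X), 6L))
  expect_equal(rowSums(P), rep(1, nrow(X)), tolerance = 1e-9)
  cls <- predict(fit, X, type = "class")
  expect_s3_class(cls, "factor")
  dec <- predict(fit, X, type = "decision")
  # wherever a decision is made it agrees with argmax
  agree <- is.na(dec) | dec == max.col(P, ties.method = "first")
  expect_true(all(agree))
  expect_equal(fit$config$threshold, 0.17) # six classes: chance 1/6 -> 0.17

  r <- residuals(fit)
  expect_equal(dim(r), dim(P))
  expect_equal(rowSums(r), rep(0, nrow(P)), tolerance = 1e-9)

  simlab <- simulate(fit, nsim = 2, seed = 5)
  expect_equal(dim(simlab), c(nrow(X), 2L))
  expect_true(all(unlist(simlab) %in% 1:6))
})
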