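#' Seeded 70/15/15 split into training, validation and test sets
#'
#' Validation and test sizes are `floor(fraction * n)`; the remainder
#' goes to training. Assignment is a seeded uniform shuffle, so the same
#' seed always yields the same partition.
#'
#' @param n_cases Number of cases to partition (>= 3).
#' @param fractions Train/validation/test fractions, non-negative and
#'   summing to 1.
#' @param seed Integer seed.
#' @return A list with integer index vectors `train`, `validation`,
#'   `test` partitioning `1:n_cases`.
#' @examples
#' lengths(split_dataset(100, seed = 1)) # 70 15 15
#' @export
split_dataset <- function(n_cases, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  n_cases <- check_count(n_cases, "n_cases")
  if (n_cases < 3L) stop_domain("need at least 3 cases to split")
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    stop_domain("`fractions` must be 3 non-negative values summing to 1")
  }
  n_val <- floor(fractions[2] * n_cases)
  n_test <- floor(fractions[3] * n_cases)
  n_train <- n_cases - n_val - n_test
  if (min(n_train, n_val, n_test) < 1L) {
    stop_domain("split leaves an empty set; adjust fractions or n_cases")
  }
  perm <- with_seed(seed, sample.int(n_cases))
  list(train = sort(perm[seq_len(n_train)]),
       validation = sort(perm[n_train + seq_len(n_val)]),
       test = sort(perm[n_train + n_val + seq_len(n_test)]))
}

#' Consecutive-correct stopping decision
#'
#' The training protocol stops once some run of at least
#' `consecutive_correct` correctly classified validation cases occurs
#' within one (fixed-order) pass over the validation split. Epoch cap
#' and gradient tolerance act as safety stops.
#'
#' @param validation_correct Logical vector: per-case correctness of one
#'   full validation pass, in a fixed seeded order.
#' @param consecutive_correct Required run length (e.g. 100, 150, 200).
#' @param epoch Current epoch number.
#' @param grad_norm Current gradient norm.
#' @param max_epochs Epoch cap.
#' @param grad_tol Gradient-norm tolerance.
#' @return A list with `stop` (logical) and `reason` (`"validation_run"`,
#'   `"gradient_tolerance"`, `"max_epochs"`, or `NA` when not stopping).
#' @examples
#' check_stopping(rep(TRUE, 150), 100, epoch = 5)$reason
#' @export
check_stopping <- function(validation_correct, consecutive_correct,
                           epoch, grad_norm = Inf,
                           max_epochs = 2000L, grad_tol = 1e-6) {
  consecutive_correct <- check_count(consecutive_correct, "consecutive_correct")
  if (consecutive_correct > length(validation_correct)) {
    stop_domain(sprintf(
      "consecutive_correct (%d) exceeds the validation-set size (%d); the rule can never fire",
      consecutive_correct, length(validation_correct)))
  }
  if (longest_true_run(validation_correct) >= consecutive_correct) {
    return(list(stop = TRUE, reason = "validation_run"))
  }
  if (grad_norm <= grad_tol) {
    return(list(stop = TRUE, reason = "gradient_tolerance"))
  }
  if (epoch >= max_epochs) {
    return(list(stop = TRUE, reason = "max_epochs"))
  }
  list(stop = FALSE, reason = NA_character_)
}

#' Trainer hyperparameters
#'
#' Constants for the two trainers: Moller's published SCG defaults and
#' the Riedmiller-Braun Rprop defaults with initial step 0.07.
#'
#' @param scg_sigma Finite-perturbation scale of SCG.
#' @param scg_lambda0 Initial SCG damping.
#' @param rprop_eta_plus,rprop_eta_minus Rprop step growth/shrink.
#' @param rprop_delta0 Initial Rprop step size.
#' @param rprop_delta_max Rprop step-size cap.
#' @return A list of class `"ffnet_control"`.
#' @export
ffnet_control <- function(scg_sigma = 5e-5, scg_lambda0 = 5e-7,
                          rprop_eta_plus = 1.2, rprop_eta_minus = 0.5,
                          rprop_delta0 = 0.07, rprop_delta_max = 50) {
  stopifnot(scg_sigma > 0, scg_lambda0 > 0, rprop_delta0 > 0,
            rprop_delta_max > 0, rprop_eta_minus < 1, rprop_eta_plus > 1)
  structure(list(scg_sigma = scg_sigma, scg_lambda0 = scg_lambda0,
                 rprop_eta_plus = rprop_eta_plus,
                 rprop_eta_minus = rprop_eta_minus,
                 rprop_delta0 = rprop_delta0,
                 rprop_delta_max = rprop_delta_max),
            class = "ffnet_control")
}

#' Fit a Huang-sized two-hidden-layer feedforward classifier
#'
#' Fits the standardized pattern classifier: inputs are z-scored on the
#' training split, hidden-layer widths default to Huang's closed-form
#' sizes for the training-sample count, and the network is trained
#' full-batch by scaled conjugate gradient (`"scg"`) or resilient
#' backpropagation (`"rprop"`) until some run of `consecutive_correct`
#' validation cases is classified correctly in a row (argmax rule)
#' within one fixed-order validation pass, or a safety stop fires.
#'
#' @param x Numeric case-by-feature matrix (e.g. rows from
#'   [build_tmaze_vector()] or [build_ic_vector()]).
#' @param y Class labels: a factor, or integers `1..k`.
#' @param algorithm `"scg"` or `"rprop"`.
#' @param layers Integer pair of hidden-layer widths; `NULL` (default)
#'   uses [huang_layer_sizes()] with `N` = training-split size.
#' @param consecutive_correct Validation run length required to stop
#'   (must not exceed the validation-split size).
#' @param split Train/validation/test fractions (see [split_dataset()]).
#' @param max_epochs Epoch cap (one epoch = one full-batch update).
#' @param grad_tol Gradient-norm safety stop.
#' @param threshold Decision threshold used by `predict(type =
#'   "decision")`; default is the chance level `1/k` rounded up to two
#'   decimals (0.17 for six classes, 0.50 for two).
#' @param standardize Standardize features on the training split
#'   (default `TRUE`; disable only for pre-scaled inputs).
#' @param seed Integer seed controlling the split, the weight
#'   initialization and the validation pass order. Identical
#'   `(x, y, arguments, seed)` give identical fits.
#' @param control An [ffnet_control()] list of trainer constants.
#' @return An object of class `"ffnet"`: a list with the trained
#'   `weights`, `spec`, `levels`, `split` indices, per-epoch `history`
#'   (with a `stop_reason` attribute), fitted class probabilities for
#'   all cases (`fitted.values`), the observed labels (`y`), per-split
#'   `accuracy`, and the configuration. Methods: `print`, `summary`,
#'   `coef`, `predict`, `plot`, `residuals`, `simulate`.
#' @examples
#' sim <- simulate_tmaze_dataset(trajectory_sim_config(
#'   n_participants = 3, trials_per_condition = 2, seed = 7))
#' fit <- ffnet(tmaze_features(sim), sim$labels, consecutive_correct = 4,
#'              max_epochs = 50, seed = 1)
#' fit$accuracy
#' @export
ffnet <- function(x, y, algorithm = c("scg", "rprop"), layers = NULL,
                  consecutive_correct = 100L,
                  split = c(0.70, 0.15, 0.15), max_epochs = 2000L,
                  grad_tol = 1e-6, threshold = NULL, standardize = TRUE,
                  seed = 1L, control = ffnet_control()) {
  algorithm <- match.arg(algorithm)
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop_domain("`x` contains non-finite values")
  if (is.factor(y)) {
    levels_y <- levels(y)
    yi <- as.integer(y)
  } else {
    yi <- as.integer(y)
    if (any(is.na(yi)) || any(yi < 1L)) stop_domain("`y` must be a factor or positive integers")
    levels_y <- as.character(seq_len(max(yi)))
  }
  n <- nrow(x)
  if (length(yi) != n) stop_domain("`x` and `y` lengths differ")
  k <- length(levels_y)
  if (k < 2L) stop_domain("need at least two classes")

  idx <- split_dataset(n, split, seed = seed)
  if (consecutive_correct > length(idx$validation)) {
    stop_domain(sprintf(
      "consecutive_correct (%d) exceeds the validation-split size (%d)",
      consecutive_correct, length(idx$validation)))
  }

  # per-feature z-scoring fitted on the training split only
  if (standardize) {
    center <- colMeans(x[idx$train, , drop = FALSE])
    scale_ <- apply(x[idx$train, , drop = FALSE], 2L, sd)
    scale_[!is.finite(scale_) | scale_ < 1e-12] <- 1
  } else {
    center <- rep(0, ncol(x))
    scale_ <- rep(1, ncol(x))
  }
  xs <- sweep(sweep(x, 2L, center, "-"), 2L, scale_, "/")

  if (is.null(layers)) {
    layers <- huang_layer_sizes(length(idx$train), k)
  }
  spec <- network_spec(ncol(x), layers[1], layers[2], k)
  w0 <- init_network(spec, seed = seed + 1L)

  Y <- build_targets(yi, k)
  Xtr <- xs[idx$train, , drop = FALSE]
  Ytr <- Y[idx$train, , drop = FALSE]
  Xval <- xs[idx$validation, , drop = FALSE]
  yval <- yi[idx$validation]
  # one fixed seeded order for every validation pass
  val_order <- with_seed(seed + 2L, sample.int(length(yval)))

  cl <- loss_grad_closures(spec, Xtr, Ytr)
  history <- vector("list", max_epochs)
  stop_reason <- NULL
  callback <- function(iter, par, value, grad_norm) {
    w <- unflatten_weights(par, spec)
    pred_val <- max.col(forward_pass(w, Xval)$P, ties.method = "first")
    correct <- (pred_val == yval)[val_order]
    run <- longest_true_run(correct)
    history[[iter]] <<- data.frame(
      epoch = iter, loss = value,
      val_accuracy = mean(correct), longest_run = run,
      grad_norm = grad_norm)
    dec <- check_stopping(correct, consecutive_correct, iter, grad_norm,
                          max_epochs, grad_tol)
    if (dec$stop) stop_reason <<- dec$reason
    dec$stop
  }

  par0 <- flatten_weights(w0)
  res <- if (algorithm == "scg") {
    scg_optimize(par0, cl$fn, cl$gr, max_iter = max_epochs,
                 grad_tol = grad_tol, sigma = control$scg_sigma,
                 lambda0 = control$scg_lambda0, callback = callback)
  } else {
    rprop_optimize(par0, cl$fn, cl$gr, max_iter = max_epochs,
                   grad_tol = grad_tol,
                   eta_plus = control$rprop_eta_plus,
                   eta_minus = control$rprop_eta_minus,
                   delta0 = control$rprop_delta0,
                   delta_max = control$rprop_delta_max,
                   callback = callback)
  }
  if (is.null(stop_reason)) {
    stop_reason <- switch(res$stop, grad_tol = "gradient_tolerance",
                          max_iter = "max_epochs", res$stop)
  }
  history <- do.call(rbind, history[!vapply(history, is.null, logical(1))])
  if (is.null(history)) {
    history <- data.frame(epoch = integer(), loss = numeric(),
                          val_accuracy = numeric(), longest_run = integer(),
                          grad_norm = numeric())
  }
  attr(history, "stop_reason") <- stop_reason

  weights <- unflatten_weights(res$par, spec)
  P_all <- forward_pass(weights, xs)$P
  colnames(P_all) <- levels_y
  pred_all <- max.col(P_all, ties.method = "first")
  acc <- vapply(idx, function(i) mean(pred_all[i] == yi[i]), numeric(1))

  if (is.null(threshold)) threshold <- ceiling(100 / k) / 100

  out <- list(
    weights = weights, spec = spec, levels = levels_y,
    center = center, scale = scale_, standardize = standardize,
    split = idx, history = history, stop_reason = stop_reason,
    algorithm = algorithm, fitted.values = P_all, y = yi,
    accuracy = acc, epochs = res$iterations, final_loss = res$value,
    config = list(consecutive_correct = as.integer(consecutive_correct),
                  split = split, max_epochs = as.integer(max_epochs),
                  grad_tol = grad_tol, seed = as.integer(seed),
                  threshold = threshold, control = control),
    call = match.call()
  )
  class(out) <- "ffnet"
  out
}
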