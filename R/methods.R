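# S3 methods for fitted "ffnet" classifiers.

#' @export
print.ffnet <- function(x, ...) {
  s <- x$spec
  cat(sprintf("Two-hidden-layer feedforward classifier (%s)\n", x$algorithm))
  cat(sprintf("  architecture: %d -> %d -> %d -> %d\n",
              s$n_inputs, s$layer1, s$layer2, s$n_outputs))
  cat(sprintf("  epochs: %d (stop: %s)\n", x$epochs, x$stop_reason))
  cat(sprintf("  accuracy: train %.1f%%, validation %.1f%%, test %.1f%%\n",
              100 * x$accuracy[["train"]], 100 * x$accuracy[["validation"]],
              100 * x$accuracy[["test"]]))
  invisible(x)
}

#' Standardize new data with the scaling fitted on the training split
#' @noRd
scale_newdata <- function(object, newdata) {
  X <- as.matrix(newdata)
  if (ncol(X) != object$spec$n_inputs) {
    stop_domain(sprintf("newdata has %d features; the model expects %d",
                        ncol(X), object$spec$n_inputs))
  }
  sweep(sweep(X, 2L, object$center, "-"), 2L, object$scale, "/")
}

#' Predict method for ffnet classifiers
#'
#' @param object A fitted [ffnet()] model.
#' @param newdata Case-by-feature matrix on the original (unscaled)
#'   feature scale; omitted, the fitted probabilities are used.
#' @param type `"prob"` for the class-probability matrix, `"class"` for
#'   argmax labels, `"decision"` for thresholded category selection
#'   where cases whose maximum probability does not exceed the
#'   threshold are missed (`NA`).
#' @param threshold Decision threshold for `type = "decision"`;
#'   defaults to the model's configured threshold (0.17 for six
#'   classes).
#' @param ... Unused.
#' @return A probability matrix, a factor of class labels, or an
#'   integer vector with `NA` for missed cases.
#' @export
predict.ffnet <- function(object, newdata = NULL,
                          type = c("prob", "class", "decision"),
                          threshold = NULL, ...) {
  type <- match.arg(type)
  P <- if (is.null(newdata)) {
    object$fitted.values
  } else {
    forward_pass(object$weights, scale_newdata(object, newdata))$P
  }
  colnames(P) <- object$levels
  switch(type,
    prob = P,
    class = factor(object$levels[max.col(P, ties.method = "first")],
                   levels = object$levels),
    decision = {
      if (is.null(threshold)) threshold <- object$config$threshold
      apply(P, 1L, function(p) select_category(p, threshold)$selected)
    })
}

#' @export
coef.ffnet <- function(object, ...) {
  w <- object$weights
  list(W1 = w$W1, b1 = w$b1, W2 = w$W2, b2 = w$b2, W3 = w$W3, b3 = w$b3)
}

#' Response residuals (one-hot target minus fitted probability)
#' @param object A fitted [ffnet()] model.
#' @param ... Unused.
#' @export
residuals.ffnet <- function(object, ...) {
  build_targets(object$y, length(object$levels)) - object$fitted.values
}

#' Simulate class labels from the fitted probabilities
#'
#' Draws, for each case, a class label from the model's fitted class
#' probabilities — useful for parametric-bootstrap style checks.
#'
#' @param object A fitted [ffnet()] model.
#' @param nsim Number of simulated label vectors.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A data.frame with `nsim` columns of integer class labels.
#' @export
simulate.ffnet <- function(object, nsim = 1, seed = NULL, ...) {
  P <- object$fitted.values
  draw <- function() {
    apply(P, 1L, function(p) sample.int(length(p), 1L, prob = p))
  }
  out <- with_seed(seed, as.data.frame(replicate(nsim, draw())))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
summary.ffnet <- function(object, ...) {
  k <- length(object$levels)
  pred <- max.col(object$fitted.values, ties.method = "first")
  test <- object$split$test
  counts <- confusion_counts(object$y[test], pred[test], k)
  out <- list(spec = object$spec, algorithm = object$algorithm,
              epochs = object$epochs, stop_reason = object$stop_reason,
              accuracy = object$accuracy,
              consecutive_correct = object$config$consecutive_correct,
              threshold = object$config$threshold,
              test_metrics = metrics_from_counts(counts),
              n_parameters = n_parameters(object$spec))
  class(out) <- "summary.ffnet"
  out
}

#' @export
print.summary.ffnet <- function(x, ...) {
  s <- x$spec
  cat(sprintf("Two-hidden-layer feedforward classifier (%s)\n", x$algorithm))
  cat(sprintf("  architecture: %d -> %d -> %d -> %d (%d parameters)\n",
              s$n_inputs, s$layer1, s$layer2, s$n_outputs, x$n_parameters))
  cat(sprintf("  stopping: %d consecutive correct validation cases; stopped after %d epochs (%s)\n",
              x$consecutive_correct, x$epochs, x$stop_reason))
  cat(sprintf("  decision threshold: %.2f\n", x$threshold))
  cat(sprintf("  accuracy: train %.1f%%, validation %.1f%%, test %.1f%%\n",
              100 * x$accuracy[["train"]], 100 * x$accuracy[["validation"]],
              100 * x$accuracy[["test"]]))
  cat("  per-class test metrics (one-vs-rest):\n")
  print(x$test_metrics, row.names = FALSE)
  invisible(x)
}

#' Plot the training history
#'
#' Training loss (log scale) and validation accuracy per epoch, with
#' the longest consecutive-correct validation run.
#'
#' @param x A fitted [ffnet()] model.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ffnet <- function(x, ...) {
  h <- x$history
  if (nrow(h) == 0L) {
    stop_domain("no training history to plot (model stopped before the first epoch)")
  }
  op <- par(mfrow = c(1, 2))
  on.exit(par(op))
  plot(h$epoch, h$loss, type = "l", log = "y", xlab = "epoch",
       ylab = "training loss", main = "Loss", ...)
  plot(h$epoch, 100 * h$val_accuracy, type = "l", ylim = c(0, 100),
       xlab = "epoch", ylab = "%", main = "Validation", ...)
  lines(h$epoch, 100 * h$longest_run / max(1, length(x$split$validation)),
        lty = 2)
  legend("bottomright", lty = c(1, 2), bty = "n",
         legend = c("accuracy", "longest run (% of split)"))
  invisible(x)
}
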