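#' Model-selection grid over trainers and validation-run settings
#'
#' Trains one network per (algorithm, consecutive-correct) combination
#' on the same seeded split, reports each network's overall accuracy on
#' the held-out cases (validation + test splits) and its missed-trial
#' counts on any number of new datasets, and flags the best network by
#' the two-stage rule: take the row with the highest held-out accuracy;
#' every row whose paired McNemar statistic against it stays below
#' 3.841 (the 5% chi-square bound, df = 1) remains in contention; among
#' those, the fewest missed trials on the first new dataset wins.
#'
#' @param x,y Features and labels, as in [ffnet()].
#' @param newdata Named list of feature matrices ("new datasets") on
#'   which missed trials are counted with the decision threshold.
#' @param algorithms Trainers to try.
#' @param consecutive Consecutive-correct settings to try.
#' @param seed Split/init seed shared by every network.
#' @param ... Further arguments to [ffnet()] (e.g. `max_epochs`,
#'   `threshold`).
#' @return A data.frame with one row per trained network: `network`,
#'   `algorithm`, `consecutive`, `accuracy` (percent on held-out
#'   cases), `epochs`, `stop_reason`, one `missed_*` column per new
#'   dataset, and logical `best`. The fitted models are attached as
#'   attribute `"fits"`, the per-row held-out correctness vectors as
#'   `"correct"`.
#' @export
model_selection_grid <- function(x, y, newdata = list(),
                                 algorithms = c("scg", "rprop"),
                                 consecutive = c(100L, 150L, 200L),
                                 seed = 1L, ...) {
  combos <- expand.grid(consecutive = as.integer(consecutive),
                        algorithm = algorithms,
                        stringsAsFactors = FALSE)[, 2:1]
  fits <- vector("list", nrow(combos))
  correct <- vector("list", nrow(combos))
  rows <- vector("list", nrow(combos))
  if (length(newdata) > 0 && is.null(names(newdata))) {
    names(newdata) <- paste0("new", seq_along(newdata))
  }
  yi <- if (is.factor(y)) as.integer(y) else as.integer(y)

  for (i in seq_len(nrow(combos))) {
    fit <- ffnet(x, y, algorithm = combos$algorithm[i],
                 consecutive_correct = combos$consecutive[i],
                 seed = seed, ...)
    fits[[i]] <- fit
    held <- c(fit$split$validation, fit$split$test)
    pred <- max.col(fit$fitted.values[held, , drop = FALSE],
                    ties.method = "first")
    correct[[i]] <- pred == yi[held]
    missed <- vapply(newdata, function(Xn) {
      count_missed(predict(fit, Xn, type = "decision"))
    }, numeric(1))
    rows[[i]] <- data.frame(
      network = paste0("net", i),
      algorithm = combos$algorithm[i],
      consecutive = combos$consecutive[i],
      accuracy = round_half_up(100 * mean(correct[[i]]), 1),
      epochs = fit$epochs,
      stop_reason = fit$stop_reason)
    for (nm in names(newdata)) {
      rows[[i]][[paste0("missed_", nm)]] <- missed[[nm]]
    }
  }
  grid <- do.call(rbind, rows)

  # two-stage selection: accuracy first, missed counts break near-ties
  top <- which.max(grid$accuracy)
  chis <- vapply(seq_len(nrow(grid)), function(i) {
    if (i == top) return(0)
    d <- discordant_counts(correct[[i]], correct[[top]])
    if (sum(d) == 0) 0 else mcnemar_statistic(d["b"], d["c"])
  }, numeric(1))
  contenders <- which(chis < 3.841)
  best <- if (length(newdata) > 0) {
    m <- grid[[paste0("missed_", names(newdata)[1])]]
    contenders[order(m[contenders], -grid$accuracy[contenders])][1]
  } else {
    contenders[order(-grid$accuracy[contenders])][1]
  }
  grid$best <- seq_len(nrow(grid)) == best
  attr(grid, "fits") <- fits
  attr(grid, "correct") <- correct
  grid
}
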