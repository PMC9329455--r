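# Shared fixtures and independent oracles for the test suite.

# Hand-set 1-1-1-2 network: W1 = [1], W2 = [1], W3 rows [1], [-1], all
# biases zero.
tiny_net <- function() {
  w <- init_network(network_spec(1, 1, 1, 2), seed = 1)
  w$W1[] <- 1; w$W2[] <- 1
  w$W3 <- matrix(c(1, -1), 2, 1)
  w$b1[] <- 0; w$b2[] <- 0; w$b3[] <- 0
  w
}

# Trial from raw series (pads validation through the constructor).
make_trial <- function(x, y, participant = 1, trial = 1, condition = 1) {
  trajectory_trial(x, y, participant, trial, condition)
}

# Time axis matching the trial sampling (13 s over 3000 samples).
trial_time <- function() seq_len(3000) * 13 / 3000

# Central finite differences, the independent gradient oracle.
fd_gradient <- function(fn, par, h = 1e-6) {
  vapply(seq_along(par), function(i) {
    up <- par; up[i] <- up[i] + h
    dn <- par; dn[i] <- dn[i] - h
    (fn(up) - fn(dn)) / (2 * h)
  }, numeric(1))
}

# Brute-force longest-run scanner (oracle for the stopping rule).
brute_longest_run <- function(x) {
  best <- 0L; cur <- 0L
  for (v in x) {
    cur <- if (isTRUE(v)) cur + 1L else 0L
    best <- max(best, cur)
  }
  best
}

# Enumeration oracle for one-vs-rest confusion counts.
enum_confusion <- function(truth, pred, k) {
  keep <- !is.na(pred)
  truth <- truth[keep]; pred <- pred[keep]
  do.call(rbind, lapply(seq_len(k), function(cl) {
    tp <- 0L; fp <- 0L; fn <- 0L; tn <- 0L
    for (i in seq_along(truth)) {
      if (truth[i] == cl && pred[i] == cl) tp <- tp + 1L
      else if (truth[i] != cl && pred[i] == cl) fp <- fp + 1L
      else if (truth[i] == cl && pred[i] != cl) fn <- fn + 1L
      else tn <- tn + 1L
    }
    data.frame(class = cl, tp = tp, fp = fp, fn = fn, tn = tn)
  }))
}

ref_counts <- function(which = c("tmaze", "ic")) {
  which <- match.arg(which)
  read.csv(system.file("extdata", paste0(which, "_reference_counts.csv"),
                       package = "huangnet"))
}

# Small separable two-class batch: 4 distinct points in 2D.
separable_toy <- function() {
  X <- rbind(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  y <- c(1L, 1L, 2L, 2L)
  list(X = X, Y = build_targets(y, 2), y = y)
}
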