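# Internal helpers shared across the package.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so package functions never disturb the global stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

# Round half away from zero (the tables report e.g. 98.185 -> 98.2, where
# base round() would use banker's rounding).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stop_domain <- function(...) stop(..., call. = FALSE)

check_count <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 1 || x != floor(x)) {
    stop_domain(sprintf("`%s` must be a single positive integer", name))
  }
  as.integer(x)
}

# Longest run of TRUE in a logical vector (0 for empty input).
longest_true_run <- function(x) {
  if (length(x) == 0L) return(0L)
  r <- rle(as.logical(x))
  w <- r$lengths[r$values]
  if (length(w) == 0L) 0L else max(w)
}
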