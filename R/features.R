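# Input-vector layouts of the two classification problems. Block
# positions are fixed and 1-based in the documentation:
#   T-maze  : x 1-3000, y 3001-6000, pid 6001, trial 6002, condition 6003
#   IC      : time-course 1-1500, topography 1501-1532, spectrum
#             1533-1602 (1-70 Hz bands), pid 1603

#' An EEG independent component's feature triple
#'
#' @param timecourse Mean activation time-course, 1500 samples
#'   (arbitrary units; treated as an opaque fixed-length series).
#' @param topography 32 inverse weights, one per electrode slot of a
#'   32-channel montage.
#' @param spectrum 70 non-negative power values, one per 1-Hz band from
#'   1 to 70 Hz.
#' @param participant Participant id (integer).
#' @param label Optional `"artifact"` or `"signal"`.
#' @return An object of class `"ic_component"`.
#' @export
ic_component <- function(timecourse, topography, spectrum,
                         participant = 1L, label = NULL) {
  if (length(timecourse) != 1500L) stop_domain("timecourse must have 1500 samples")
  if (length(topography) != 32L) stop_domain("topography must have 32 elements")
  if (length(spectrum) != 70L) stop_domain("spectrum must have 70 bands")
  if (any(spectrum < 0)) stop_domain("spectral power must be non-negative")
  if (!is.null(label)) label <- match.arg(label, c("artifact", "signal"))
  structure(list(timecourse = as.numeric(timecourse),
                 topography = as.numeric(topography),
                 spectrum = as.numeric(spectrum),
                 participant = as.integer(participant),
                 label = label),
            class = "ic_component")
}

#' @export
print.ic_component <- function(x, ...) {
  cat(sprintf("EEG independent component: participant %d%s, peak band %d Hz\n",
              x$participant,
              if (is.null(x$label)) "" else paste0(" (", x$label, ")"),
              which.max(x$spectrum)))
  invisible(x)
}

#' Build the 6003-element T-maze input vector
#'
#' Concatenates, in order, the 3000 x samples, the 3000 y samples, the
#' participant id, the trial index and the condition number.
#'
#' @param trial A [trajectory_trial()].
#' @return Numeric vector of length 6003.
#' @export
build_tmaze_vector <- function(trial) {
  stopifnot(inherits(trial, "tmaze_trial"))
  c(trial$x, trial$y, trial$participant, trial$trial, trial$condition)
}

#' Build the 1603-element independent-component input vector
#'
#' Concatenates the 1500-sample mean time-course, the 32-element
#' topography, the 70 one-Hz-band spectral values and the participant
#' id.
#'
#' @param component An [ic_component()].
#' @return Numeric vector of length 1603.
#' @export
build_ic_vector <- function(component) {
  stopifnot(inherits(component, "ic_component"))
  c(component$timecourse, component$topography, component$spectrum,
    component$participant)
}

#' One-hot target matrix from class labels
#'
#' @param labels Integer class labels in `1..n_classes`.
#' @param n_classes Number of classes.
#' @return A `length(labels)` x `n_classes` matrix of one-hot rows.
#' @examples
#' build_targets(c(1, 6), 6)
#' @export
build_targets <- function(labels, n_classes) {
  n_classes <- check_count(n_classes, "n_classes")
  labels <- as.integer(labels)
  if (any(is.na(labels)) || any(labels < 1L) || any(labels > n_classes)) {
    stop_domain("labels must lie in 1..n_classes")
  }
  Y <- matrix(0, length(labels), n_classes)
  Y[cbind(seq_along(labels), labels)] <- 1
  Y
}

#' Feature matrix for a collection of T-maze trials
#'
#' Stacks [build_tmaze_vector()] rows; columns are named by block
#' (`x_0001..x_3000`, `y_0001..y_3000`, `pid`, `trial`, `cond`).
#'
#' @param trials A list of [trajectory_trial()] objects or a
#'   [simulate_tmaze_dataset()] result.
#' @return Numeric matrix, one row per trial, 6003 columns.
#' @export
tmaze_features <- function(trials) {
  if (inherits(trials, "tmaze_sim")) trials <- trials$trials
  X <- t(vapply(trials, build_tmaze_vector, numeric(6003)))
  colnames(X) <- c(sprintf("x_%04d", 1:3000), sprintf("y_%04d", 1:3000),
                   "pid", "trial", "cond")
  X
}

#' Feature matrix for a collection of independent components
#'
#' Stacks [build_ic_vector()] rows; columns are named by block
#' (`tc_0001..tc_1500`, `topo_01..topo_32`, `f01..f70`, `pid`).
#'
#' @param components A list of [ic_component()] objects or a
#'   [simulate_ic_dataset()] result.
#' @return Numeric matrix, one row per component, 1603 columns.
#' @export
ic_features <- function(components) {
  if (inherits(components, "ic_sim")) components <- components$components
  X <- t(vapply(components, build_ic_vector, numeric(1603)))
  colnames(X) <- c(sprintf("tc_%04d", 1:1500), sprintf("topo_%02d", 1:32),
                   sprintf("f%02d", 1:70), "pid")
  X
}

#' 70-band power spectrum of a component activation
#'
#' Averaged-periodogram (Welch, non-overlapping rectangular segments of
#' one second) power integrated into 70 contiguous 1-Hz bands centered
#' on 1..70 Hz. Total power over the bands is conserved relative to the
#' periodogram mass between 0.5 and 70.5 Hz.
#'
#' @param activation Numeric series, at least `2 * sampling_rate`
#'   samples long.
#' @param sampling_rate Sampling rate in Hz; must be at least 140 so
#'   that 70 Hz content is below Nyquist.
#' @return Numeric vector of 70 non-negative band powers.
#' @examples
#' fs <- 250
#' x <- sin(2 * pi * 10 * (0:(10 * fs - 1)) / fs)
#' which.max(component_spectrum(x, fs)) # 10
#' @export
component_spectrum <- function(activation, sampling_rate) {
  if (sampling_rate < 140) {
    stop_domain("sampling_rate must be >= 140 Hz to resolve 70 Hz content")
  }
  n <- length(activation)
  L <- round(sampling_rate) # one-second segments: 1 Hz bin spacing
  n_seg <- n %/% L
  if (n_seg < 2L) stop_domain("activation must span at least 2 seconds")
  # mean periodogram over segments; bin j (1-based j+1 in fft output)
  # sits at j * sampling_rate / L ~= j Hz
  pgram <- rowMeans(vapply(seq_len(n_seg), function(s) {
    seg <- activation[((s - 1L) * L + 1L):(s * L)]
    (Mod(fft(seg))^2 / L)[seq_len(L %/% 2L + 1L)]
  }, numeric(L %/% 2L + 1L)))
  freqs <- (seq_along(pgram) - 1L) * sampling_rate / L
  vapply(1:70, function(k) {
    sum(pgram[freqs > k - 0.5 & freqs <= k + 0.5])
  }, numeric(1))
}
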