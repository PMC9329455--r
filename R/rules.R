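# Expert rule system for six-category joystick behavior in the virtual
# T-maze. A trial is 13 s of joystick deflection sampled 3000 times per
# axis: x in [-1,1] (negative = left), y in [-1,1] (positive = forward,
# negative = backward). Thresholds are fractions of the device maximum
# (full deflection = 1), not per-participant empirical maxima.

N_SAMPLES <- 3000L

#' A single joystick trajectory trial
#'
#' @param x,y Numeric series of 3000 samples each in `[-1, 1]`;
#'   `x` is sideways deflection (negative = left), `y` forward/backward
#'   (positive = forward).
#' @param participant Participant id (integer).
#' @param trial 1-based trial index within the condition.
#' @param condition Condition code 1-5 (negative, positive,
#'   approach-avoidance, approach-approach, ambiguous).
#' @param duration Trial duration in seconds (default 13).
#' @return An object of class `"tmaze_trial"`.
#' @export
trajectory_trial <- function(x, y, participant = 1L, trial = 1L,
                             condition = 1L, duration = 13) {
  if (length(x) != N_SAMPLES || length(y) != N_SAMPLES) {
    stop_domain(sprintf("x and y must each have %d samples", N_SAMPLES))
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop_domain("trajectory samples must be finite")
  }
  if (max(abs(x)) > 1 + 1e-9 || max(abs(y)) > 1 + 1e-9) {
    stop_domain("trajectory samples must lie in [-1, 1]")
  }
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 participant = as.integer(participant),
                 trial = as.integer(trial),
                 condition = as.integer(condition),
                 duration = as.numeric(duration)),
            class = "tmaze_trial")
}

#' @export
print.tmaze_trial <- function(x, ...) {
  cat(sprintf(
    "T-maze trial: participant %d, trial %d, condition %d (%.0f s, %d samples/axis)\n",
    x$participant, x$trial, x$condition, x$duration, length(x$x)))
  invisible(x)
}

#' Thresholds and windows of the behavioral rule system
#'
#' All fractions are of the full joystick deflection (device maximum =
#' 1.0). Defaults implement the expert criteria: fleeing requires
#' backward deflection above 75% with sideways deflection below 50%
#' throughout the first 8 s; approach safety requires sideways
#' deflection above 15% plus a backward-to-forward reversal in the
#' first 8 s; reaching out requires forward deflection above 50% in the
#' first 8 s with backward deflection below 10% in the first 4 s; a
#' response-onset latency above 1.5 s forces the conflict category.
#'
#' @param flee_backward_frac Backward threshold for fleeing (0.75).
#' @param flee_sideways_max_frac Sideways cap for fleeing (0.50).
#' @param safety_sideways_min_frac Sideways minimum for approach safety
#'   (0.15).
#' @param reach_forward_min_frac Forward threshold for reaching out
#'   (0.50).
#' @param reach_backward_max_frac Backward cap for reaching out (0.10).
#' @param early_window_s Evaluation window for most rules (8 s).
#' @param reach_backward_window_s Window of the backward cap (4 s).
#' @param conflict_latency_s Onset latency that forces conflict (1.5 s).
#' @param movement_onset_frac Deflection counting as movement onset
#'   (0.10).
#' @param dwell_frac Fraction of the window a threshold crossing must
#'   be sustained for (0.20); single-sample crossings would make the
#'   rules noise-brittle.
#' @param outlier_z Robust z cut for the bad-performance conflict
#'   sub-rule (3.0).
#' @return A list of class `"rule_params"`.
#' @export
rule_params <- function(flee_backward_frac = 0.75,
                        flee_sideways_max_frac = 0.50,
                        safety_sideways_min_frac = 0.15,
                        reach_forward_min_frac = 0.50,
                        reach_backward_max_frac = 0.10,
                        early_window_s = 8,
                        reach_backward_window_s = 4,
                        conflict_latency_s = 1.5,
                        movement_onset_frac = 0.10,
                        dwell_frac = 0.20,
                        outlier_z = 3.0) {
  p <- list(flee_backward_frac = flee_backward_frac,
            flee_sideways_max_frac = flee_sideways_max_frac,
            safety_sideways_min_frac = safety_sideways_min_frac,
            reach_forward_min_frac = reach_forward_min_frac,
            reach_backward_max_frac = reach_backward_max_frac,
            early_window_s = early_window_s,
            reach_backward_window_s = reach_backward_window_s,
            conflict_latency_s = conflict_latency_s,
            movement_onset_frac = movement_onset_frac,
            dwell_frac = dwell_frac,
            outlier_z = outlier_z)
  fr <- unlist(p[c("flee_backward_frac", "flee_sideways_max_frac",
                   "safety_sideways_min_frac", "reach_forward_min_frac",
                   "reach_backward_max_frac", "movement_onset_frac",
                   "dwell_frac")])
  if (any(fr <= 0 | fr > 1)) stop_domain("rule fractions must lie in (0, 1]")
  class(p) <- "rule_params"
  p
}

# 3000 samples uniformly cover `duration` seconds (~230.8 Hz at 13 s);
# sample i corresponds to time i * duration / 3000.
samples_for <- function(seconds, duration) {
  max(1L, min(N_SAMPLES, floor(N_SAMPLES * seconds / duration)))
}

#' Movement-onset latency of a trial
#'
#' Time of the first sample where `max(|x|, |y|)` exceeds the movement
#' onset fraction (default 10% of full deflection), in seconds;
#' `Inf` if the joystick never leaves the dead zone.
#'
#' @param trial A [trajectory_trial()].
#' @param params A [rule_params()] list.
#' @return Latency in seconds, or `Inf`.
#' @export
onset_latency <- function(trial, params = rule_params()) {
  moved <- pmax(abs(trial$x), abs(trial$y)) > params$movement_onset_frac
  i <- which(moved)[1L]
  if (is.na(i)) Inf else i * trial$duration / length(trial$x)
}

# Turn direction from the sign of x at the sample of maximal |x| within
# the early window: negative -> left, otherwise right.
turn_is_left <- function(x_early) {
  x_early[which.max(abs(x_early))] < 0
}

# TRUE if, within y, a run of >= phase_n samples below zero ends before
# a run of >= phase_n samples above zero starts (backward -> forward).
has_back_to_forward <- function(y, phase_n) {
  s <- sign(y)
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  neg_ok <- r$values == -1 & r$lengths >= phase_n
  pos_ok <- r$values == 1 & r$lengths >= phase_n
  if (!any(neg_ok) || !any(pos_ok)) return(FALSE)
  min(ends[neg_ok]) < max(starts[pos_ok])
}

# TRUE if y has a sustained (>= seg_n samples) backward-dominant run and
# a sustained forward-dominant run anywhere in the trial.
has_behavior_switch <- function(y, onset_frac, seg_n) {
  back <- longest_true_run(y < -onset_frac) >= seg_n
  fwd <- longest_true_run(y > onset_frac) >= seg_n
  back && fwd
}

#' Classify one T-maze trial into the six behavioral categories
#'
#' Applies the expert rules in a fixed precedence order that makes the
#' categories mutually exclusive:
#' (a) conflict by latency — onset later than 1.5 s;
#' (b) reaching out (labels 4 left / 5 right) — sustained forward
#' deflection above 50% in the first 8 s with backward deflection under
#' 10% in the first 4 s;
#' (c) fleeing (label 1) — sustained backward deflection above 75% with
#' sideways deflection under 50% throughout the first 8 s;
#' (d) approach safety (labels 2 left / 3 right) — sideways deflection
#' above 15% plus a backward-to-forward reversal (each phase at least
#' 0.25 s) in the first 8 s;
#' (e) conflict by behavior switch or bad performance — both a
#' backward- and a forward-dominant segment of at least 1 s, or (when
#' `participant_trials` is supplied) a [performance_outlier()];
#' (f) otherwise unclassified (`NA`).
#'
#' Turn direction is the sign of `x` at the sample of maximal `|x|`
#' within the first 8 s (negative = left).
#'
#' @param trial A [trajectory_trial()].
#' @param params A [rule_params()] list.
#' @param participant_trials Optional list of the same participant's
#'   trials, enabling the bad-performance conflict sub-rule.
#' @return Integer label 1-6 (1 fleeing, 2/3 approach safety left/right,
#'   4/5 reach out left/right, 6 conflict) or `NA` (unclassified).
#' @export
classify_trial <- function(trial, params = rule_params(),
                           participant_trials = NULL) {
  stopifnot(inherits(trial, "tmaze_trial"))
  d <- trial$duration
  ew <- seq_len(samples_for(params$early_window_s, d))
  bw <- seq_len(samples_for(params$reach_backward_window_s, d))
  phase_n <- max(1L, round(0.25 * N_SAMPLES / d))
  seg_n <- max(1L, round(1.0 * N_SAMPLES / d))
  x <- trial$x; y <- trial$y

  # (a) conflict by latency
  if (onset_latency(trial, params) > params$conflict_latency_s) return(6L)

  # (b) reaching out
  fwd_dwell <- mean(y[ew] > params$reach_forward_min_frac)
  back_early <- max(-pmin(y[bw], 0))
  if (fwd_dwell >= params$dwell_frac &&
      back_early < params$reach_backward_max_frac) {
    return(if (turn_is_left(x[ew])) 4L else 5L)
  }

  # (c) fleeing
  back_dwell <- mean(-y[ew] > params$flee_backward_frac)
  if (back_dwell >= params$dwell_frac &&
      all(abs(x[ew]) < params$flee_sideways_max_frac)) {
    return(1L)
  }

  # (d) approach safety
  if (any(abs(x[ew]) > params$safety_sideways_min_frac) &&
      has_back_to_forward(y[ew], phase_n)) {
    return(if (turn_is_left(x[ew])) 2L else 3L)
  }

  # (e) conflict by behavior switch or bad performance
  if (has_behavior_switch(y, params$movement_onset_frac, seg_n)) return(6L)
  if (!is.null(participant_trials) &&
      performance_outlier(trial, participant_trials, params)) {
    return(6L)
  }

  # (f) unclassified
  NA_integer_
}

# Roughness score: mean absolute per-sample change of both axes.
trial_roughness <- function(trial) {
  mean(abs(diff(trial$x))) + mean(abs(diff(trial$y)))
}

#' Bad-performance outlier flag
#'
#' A trial counts as badly executed when its roughness (mean absolute
#' per-sample change of `x` plus `y`) exceeds the participant's median
#' roughness by more than `outlier_z` robust standard deviations
#' (1.4826 MAD). With zero dispersion (all reference trials alike) no
#' trial is flagged.
#'
#' @param trial A [trajectory_trial()].
#' @param participant_trials List of at least 5 trials from the same
#'   participant (the reference distribution).
#' @param params A [rule_params()] list.
#' @return `TRUE` or `FALSE`.
#' @export
performance_outlier <- function(trial, participant_trials,
                                params = rule_params()) {
  if (length(participant_trials) < 5L) {
    stop_domain("need at least 5 reference trials from the participant")
  }
  scores <- vapply(participant_trials, trial_roughness, numeric(1))
  med <- median(scores)
  robust_sd <- mad(scores, center = med) # 1.4826 * MAD
  trial_roughness(trial) > med + params$outlier_z * robust_sd
}

#' Label a collection of trials
#'
#' Applies [classify_trial()] to every trial; when `use_outlier` is
#' `TRUE`, each trial's participant's other trials feed the
#' bad-performance conflict sub-rule (participants with fewer than 5
#' trials skip that sub-rule).
#'
#' @param trials A list of [trajectory_trial()] objects or a
#'   [simulate_tmaze_dataset()] result.
#' @param params A [rule_params()] list.
#' @param use_outlier Enable the bad-performance sub-rule.
#' @return Integer vector of labels 1-6 with `NA` for unclassified.
#' @export
classify_trials <- function(trials, params = rule_params(),
                            use_outlier = TRUE) {
  if (inherits(trials, "tmaze_sim")) trials <- trials$trials
  pid <- vapply(trials, function(t) t$participant, integer(1))
  vapply(seq_along(trials), function(i) {
    ref <- NULL
    if (use_outlier) {
      ref <- trials[pid == pid[i]]
      if (length(ref) < 5L) ref <- NULL
    }
    classify_trial(trials[[i]], params, participant_trials = ref)
  }, integer(1))
}
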