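# Seeded generators for both classification problems. Trajectory
# templates are parameterized ramps (the classifier consumes joystick
# deflection only), built so that the expert rule system recovers the
# intended label exactly at zero noise. All randomness flows through
# the config seed; the caller's RNG state is untouched.

smooth_ramp <- function(t, t0, len) {
  s <- pmin(pmax((t - t0) / len, 0), 1)
  s * s * (3 - 2 * s)
}

#' Configuration of the T-maze trajectory generator
#'
#' Defaults mirror the study structure: 54 participants, 5 conditions,
#' 20 trials per condition (5400 trials). `category_mix` gives, per
#' condition, the probability of each behavioral category 1-6; the
#' default mix makes fleeing/approach-safety dominant in negative
#' trials, reaching dominant in positive and approach-approach trials,
#' and conflict most frequent in ambiguous trials, with every category
#' represented.
#'
#' @param n_participants Number of participants.
#' @param trials_per_condition Trials per participant and condition.
#' @param conditions Number of conditions (default 5: negative,
#'   positive, approach-avoidance, approach-approach, ambiguous).
#' @param category_mix `conditions` x 6 matrix of row-stochastic label
#'   probabilities; `NULL` for the default mix.
#' @param onset_mean_s,onset_sd_s Movement-onset jitter (seconds);
#'   onsets are clipped to `[0.1, 1.2]` s so that only the deliberate
#'   late-onset conflict variant crosses the 1.5 s latency rule.
#' @param noise_sd Additive Gaussian noise on both axes (default 0.02).
#' @param conflict_variants Weights over the three conflict mechanisms
#'   `late_onset`, `mid_switch`, `sloppy`.
#' @param seed Integer seed.
#' @return A list of class `"trajectory_sim_config"`.
#' @export
trajectory_sim_config <- function(n_participants = 54L,
                                  trials_per_condition = 20L,
                                  conditions = 5L,
                                  category_mix = NULL,
                                  onset_mean_s = 0.5, onset_sd_s = 0.15,
                                  noise_sd = 0.02,
                                  conflict_variants = c(late_onset = 1,
                                                        mid_switch = 1,
                                                        sloppy = 1),
                                  seed = 1L) {
  if (is.null(category_mix)) {
    category_mix <- rbind(
      c(0.45, 0.20, 0.20, 0.02, 0.03, 0.10), # negative
      c(0.02, 0.04, 0.04, 0.40, 0.40, 0.10), # positive
      c(0.20, 0.15, 0.15, 0.15, 0.15, 0.20), # approach-avoidance
      c(0.05, 0.05, 0.05, 0.35, 0.35, 0.15), # approach-approach
      c(0.15, 0.15, 0.15, 0.15, 0.15, 0.25)  # ambiguous
    )[rep_len(seq_len(5L), conditions), , drop = FALSE]
  }
  category_mix <- as.matrix(category_mix)
  if (nrow(category_mix) != conditions || ncol(category_mix) != 6L ||
      any(category_mix < 0) || any(abs(rowSums(category_mix) - 1) > 1e-9)) {
    stop_domain("category_mix must be a conditions x 6 row-stochastic matrix")
  }
  if (noise_sd < 0) stop_domain("noise_sd must be non-negative")
  structure(list(n_participants = check_count(n_participants, "n_participants"),
                 trials_per_condition = check_count(trials_per_condition,
                                                    "trials_per_condition"),
                 conditions = check_count(conditions, "conditions"),
                 category_mix = category_mix,
                 onset_mean_s = onset_mean_s, onset_sd_s = onset_sd_s,
                 noise_sd = noise_sd,
                 conflict_variants = conflict_variants / sum(conflict_variants),
                 seed = as.integer(seed)),
            class = "trajectory_sim_config")
}

draw_onset <- function(config) {
  min(max(rnorm(1, config$onset_mean_s, config$onset_sd_s), 0.1), 1.2)
}

# Slow low-amplitude wander used as sub-threshold x activity.
slow_wander <- function(t, amplitude) {
  amplitude * sin(2 * pi * runif(1, 0.1, 0.3) * t + runif(1, 0, 2 * pi))
}

#' Simulate one T-maze trial with a given intended label
#'
#' Canonical template per category -- fleeing: backward ramp to -0.9
#' with sub-threshold sideways wander; approach safety: a 0.3-0.6
#' backward phase, then a 0.6 sideways turn with the forward reversal
#' to +0.8; reaching out: forward ramp to +0.9 with a later 0.4
#' lateral deflection and no early backward motion; conflict: one of
#' late onset (> 1.5 s), a mid-trial backward-to-forward reversal
#' without turning, or the same reversal executed with heavy jitter
#' ("sloppy") -- plus onset jitter and additive Gaussian noise, clipped
#' to `[-1, 1]`. Right-turn templates (3, 5) are exact x-negations of
#' their left-turn counterparts under the same random draws.
#'
#' Randomness comes from the caller's RNG stream (wrap in a seeded
#' context, or use [simulate_tmaze_dataset()] which seeds for you).
#'
#' @param label Intended behavioral category 1-6.
#' @param condition Condition code stored in the trial.
#' @param config A [trajectory_sim_config()].
#' @param participant,trial Ids stored in the trial.
#' @return A [trajectory_trial()]; its conflict mechanism (for label 6)
#'   is attached as attribute `"variant"`.
#' @export
simulate_trajectory <- function(label, condition = 1L,
                                config = trajectory_sim_config(),
                                participant = 1L, trial = 1L) {
  if (!label %in% 1:6) stop_domain("label must be in 1..6")
  d <- 13
  t <- seq_len(N_SAMPLES) * d / N_SAMPLES
  side <- if (label %in% c(2L, 4L)) -1 else 1 # left turns are negative x
  o <- draw_onset(config)
  variant <- NA_character_

  if (label == 1L) { # fleeing
    y <- -0.9 * smooth_ramp(t, o, 0.4)
    x <- slow_wander(t, 0.05)
  } else if (label %in% c(2L, 3L)) { # approach safety
    b <- runif(1, 0.3, 0.6)
    t_turn <- runif(1, 1.5, 2.5)
    y <- -b * smooth_ramp(t, o, 0.3) + (b + 0.8) * smooth_ramp(t, t_turn, 0.8)
    x <- side * (0.6 * smooth_ramp(t, t_turn - 0.3, 0.5) -
                   0.5 * smooth_ramp(t, t_turn + 2, 1) +
                   slow_wander(t, 0.04))
  } else if (label %in% c(4L, 5L)) { # reaching out
    y <- 0.9 * smooth_ramp(t, o, 0.5)
    x <- side * (0.4 * smooth_ramp(t, 4, 1) + slow_wander(t, 0.03))
  } else { # behavioral conflict
    variant <- sample(names(config$conflict_variants), 1L,
                      prob = config$conflict_variants)
    if (variant == "late_onset") {
      L <- runif(1, 1.8, 3.0)
      y <- 0.9 * smooth_ramp(t, L, 0.5)
      x <- 0 * t
    } else {
      t_sw <- runif(1, 2.5, 4.5)
      y <- -0.6 * smooth_ramp(t, o, 0.3) + 1.4 * smooth_ramp(t, t_sw, 0.6)
      x <- slow_wander(t, 0.05)
      if (variant == "sloppy") { # markedly degraded execution of the switch
        y <- y + 0.2 * sin(2 * pi * 4 * t + runif(1, 0, 2 * pi)) *
          sin(2 * pi * 0.7 * t + runif(1, 0, 2 * pi))
      }
    }
  }

  if (config$noise_sd > 0) {
    x <- x + rnorm(N_SAMPLES, 0, config$noise_sd)
    y <- y + rnorm(N_SAMPLES, 0, config$noise_sd)
  }
  out <- trajectory_trial(pmin(pmax(x, -1), 1), pmin(pmax(y, -1), 1),
                          participant, trial, condition)
  attr(out, "variant") <- variant
  out
}

#' Simulate a labeled T-maze dataset
#'
#' `n_participants * conditions * trials_per_condition` trials with
#' labels drawn from the per-condition category mix; deterministic
#' given the config seed. The default config yields the study-sized
#' 54 x 5 x 20 = 5400 trials.
#'
#' @param config A [trajectory_sim_config()].
#' @return A list of class `"tmaze_sim"`: `trials` (list of
#'   [trajectory_trial()]), `labels` (intended categories 1-6),
#'   `variants` (conflict mechanism or `NA`), and the `config`.
#' @export
simulate_tmaze_dataset <- function(config = trajectory_sim_config()) {
  stopifnot(inherits(config, "trajectory_sim_config"))
  with_seed(config$seed, {
    grid <- expand.grid(trial = seq_len(config$trials_per_condition),
                        condition = seq_len(config$conditions),
                        participant = seq_len(config$n_participants))
    labels <- integer(nrow(grid))
    trials <- vector("list", nrow(grid))
    for (i in seq_len(nrow(grid))) {
      cond <- grid$condition[i]
      labels[i] <- sample.int(6L, 1L, prob = config$category_mix[cond, ])
      trials[[i]] <- simulate_trajectory(labels[i], cond, config,
                                         participant = grid$participant[i],
                                         trial = grid$trial[i])
    }
    structure(list(trials = trials, labels = labels,
                   variants = vapply(trials, function(tr)
                     attr(tr, "variant"), character(1)),
                   config = config),
              class = "tmaze_sim")
  })
}

#' @export
print.tmaze_sim <- function(x, ...) {
  cat(sprintf("Synthetic T-maze dataset: %d trials (%d participants x %d conditions x %d), noise sd %.3f\n",
              length(x$trials), x$config$n_participants,
              x$config$conditions, x$config$trials_per_condition,
              x$config$noise_sd))
  print(table(factor(x$labels, levels = 1:6)))
  invisible(x)
}

# Electrode-slot semantics of the fixed 32-slot montage (indices, no
# real coordinates): frontal 1-4, temporal 13-20, posterior 25-32,
# edge = outermost ring slots.
MONTAGE_SLOTS <- list(frontal = 1:4, temporal = 13:20, posterior = 25:32,
                      edge = c(1L, 4L, 13L, 16L, 17L, 20L, 29L, 32L))

#' Configuration of the EEG independent-component generator
#'
#' Defaults mirror the study structure: 51 participants with 32
#' components each (1632 components). The default artifact fraction of
#' 0.6 matches the roughly 60/40 artifact-to-signal balance typical of
#' 32-channel resting decompositions.
#'
#' @param n_participants Number of participants.
#' @param components_per_participant Components per participant
#'   (default 32).
#' @param artifact_fraction Expected share of artifact components.
#' @param artifact_kinds Weights over `blink`, `lateral_eye`, `muscle`,
#'   `pulse`, `line_noise`.
#' @param signal_kinds Weights over `alpha_posterior`, `broadband_1f`.
#' @param noise_sd Gaussian measurement noise on all three feature
#'   blocks.
#' @param seed Integer seed.
#' @return A list of class `"ic_sim_config"`.
#' @export
ic_sim_config <- function(n_participants = 51L,
                          components_per_participant = 32L,
                          artifact_fraction = 0.6,
                          artifact_kinds = c(blink = 1, lateral_eye = 1,
                                             muscle = 1, pulse = 1,
                                             line_noise = 1),
                          signal_kinds = c(alpha_posterior = 1,
                                           broadband_1f = 1),
                          noise_sd = 0.05, seed = 1L) {
  if (artifact_fraction < 0 || artifact_fraction > 1) {
    stop_domain("artifact_fraction must lie in [0, 1]")
  }
  if (any(artifact_kinds < 0) || any(signal_kinds < 0) ||
      sum(artifact_kinds) <= 0 || sum(signal_kinds) <= 0 || noise_sd < 0) {
    stop_domain("kind weights must be valid probability masses and noise_sd >= 0")
  }
  structure(list(n_participants = check_count(n_participants, "n_participants"),
                 components_per_participant =
                   check_count(components_per_participant,
                               "components_per_participant"),
                 artifact_fraction = artifact_fraction,
                 artifact_kinds = artifact_kinds / sum(artifact_kinds),
                 signal_kinds = signal_kinds / sum(signal_kinds),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "ic_sim_config")
}

IC_KINDS <- list(artifact = c("blink", "lateral_eye", "muscle", "pulse",
                              "line_noise"),
                 signal = c("alpha_posterior", "broadband_1f"))

# The 1500-sample time-course is treated as 6 s at 250 Hz for recipe
# purposes only; the classifier sees it as an opaque series.
ic_time <- function() seq_len(1500L) / 250

#' Simulate one EEG independent component of a given kind
#'
#' Kind-specific generative recipes: blink -- sparse 300-500 ms
#' positive lobes, frontal topography, spectral mass below 5 Hz;
#' lateral eye -- step-like time-course with an antisymmetric frontal
#' topography; muscle -- broadband 20-70 Hz spectrum loading on edge
#' slots; pulse -- ~1 Hz periodic time-course on temporal slots; line
#' noise -- a narrow 50 Hz spectral line; posterior alpha -- a 10 Hz
#' spectral peak over a 1/f floor with posterior topography; broadband
#' 1/f -- a smooth 1/f spectrum with distributed topography. Gaussian
#' measurement noise is added to all three blocks.
#'
#' Randomness comes from the caller's RNG stream (see
#' [simulate_ic_dataset()]).
#'
#' @param kind One of `blink`, `lateral_eye`, `muscle`, `pulse`,
#'   `line_noise`, `alpha_posterior`, `broadband_1f`.
#' @param config An [ic_sim_config()].
#' @param participant Participant id stored in the component.
#' @return An [ic_component()] labeled artifact or signal; the kind is
#'   attached as attribute `"kind"`.
#' @export
simulate_ic_component <- function(kind, config = ic_sim_config(),
                                  participant = 1L) {
  kind <- match.arg(kind, unname(unlist(IC_KINDS)))
  t <- ic_time()
  n <- length(t)
  topo <- numeric(32L)
  spec <- numeric(70L)
  bands <- 1:70
  amp <- runif(1, 0.8, 1.2)

  tc <- switch(kind,
    blink = {
      topo[MONTAGE_SLOTS$frontal] <- amp * c(1, 1, 0.6, 0.6)
      spec <- 2 * exp(-(bands - 1) / 1.2)
      centers <- runif(sample(3:6, 1L), 0.5, 5.5)
      width <- runif(1, 0.3, 0.5) / 2.355 # FWHM 300-500 ms
      rowSums(vapply(centers, function(cc) amp * exp(-(t - cc)^2 / (2 * width^2)),
                     numeric(n)))
    },
    lateral_eye = {
      topo[MONTAGE_SLOTS$frontal] <- amp * c(1, -1, 0.5, -0.5)
      spec <- 2 * exp(-(bands - 1) / 1.5)
      steps <- sort(runif(sample(2:5, 1L), 0.5, 5.5))
      lev <- amp * cumsum(c(sample(c(-1, 1), 1L),
                            sample(c(-2, 2), length(steps), replace = TRUE)))
      lev <- pmin(pmax(lev, -1.2), 1.2)
      findInterval(t, steps) |> (\(i) lev[i + 1L])()
    },
    muscle = {
      topo[MONTAGE_SLOTS$edge] <- amp * runif(8, 0.6, 1)
      spec <- 0.05 + (bands >= 20) * amp
      rnorm(n, 0, 0.5)
    },
    pulse = {
      topo[MONTAGE_SLOTS$temporal] <- amp * runif(8, 0.7, 1)
      spec <- 0.1 + 3 * exp(-(bands - 1)^2 / 2)
      beat <- exp(-((t %% 1) - 0.2)^2 / (2 * 0.03^2))
      amp * beat
    },
    line_noise = {
      topo <- runif(32, -0.2, 0.2)
      spec <- 0.02 + 5 * (bands == 50L)
      0.3 * sin(2 * pi * 50 * t + runif(1, 0, 2 * pi))
    },
    alpha_posterior = {
      topo[MONTAGE_SLOTS$posterior] <- amp * runif(8, 0.6, 1)
      spec <- 1 / bands + 1.5 * amp * exp(-(bands - 10)^2 / 2)
      amp * sin(2 * pi * 10 * t) * (0.6 + 0.4 * sin(2 * pi * 0.3 * t))
    },
    broadband_1f = {
      topo <- 0.3 * amp * sin(pi * seq_len(32L) / 33)
      spec <- 0.05 + amp / bands
      as.numeric(stats::filter(rnorm(n, 0, 0.4), rep(1 / 8, 8),
                               sides = 1L)) |>
        (\(v) { v[is.na(v)] <- 0; v })()
    })

  if (config$noise_sd > 0) {
    tc <- tc + rnorm(n, 0, config$noise_sd)
    topo <- topo + rnorm(32L, 0, config$noise_sd)
    spec <- spec + rnorm(70L, 0, config$noise_sd)
  }
  out <- ic_component(tc, topo, pmax(spec, 0), participant,
                      label = if (kind %in% IC_KINDS$artifact) "artifact"
                              else "signal")
  attr(out, "kind") <- kind
  out
}

#' Simulate a labeled independent-component dataset
#'
#' `n_participants * components_per_participant` components; each is an
#' artifact with probability `artifact_fraction`, with kinds drawn from
#' the configured weights. Deterministic given the config seed. The
#' default config yields the study-sized 51 x 32 = 1632 components.
#'
#' @param config An [ic_sim_config()].
#' @return A list of class `"ic_sim"`: `components` (list of
#'   [ic_component()]), `labels` (factor, artifact/signal), `kinds`,
#'   and the `config`.
#' @export
simulate_ic_dataset <- function(config = ic_sim_config()) {
  stopifnot(inherits(config, "ic_sim_config"))
  with_seed(config$seed, {
    total <- config$n_participants * config$components_per_participant
    pid <- rep(seq_len(config$n_participants),
               each = config$components_per_participant)
    is_art <- runif(total) < config$artifact_fraction
    kinds <- character(total)
    kinds[is_art] <- sample(names(config$artifact_kinds), sum(is_art),
                            replace = TRUE, prob = config$artifact_kinds)
    kinds[!is_art] <- sample(names(config$signal_kinds), sum(!is_art),
                             replace = TRUE, prob = config$signal_kinds)
    components <- lapply(seq_len(total), function(i) {
      simulate_ic_component(kinds[i], config, participant = pid[i])
    })
    structure(list(components = components,
                   labels = factor(ifelse(is_art, "artifact", "signal"),
                                   levels = c("artifact", "signal")),
                   kinds = kinds, config = config),
              class = "ic_sim")
  })
}

#' @export
print.ic_sim <- function(x, ...) {
  cat(sprintf("Synthetic IC dataset: %d components (%d participants x %d), noise sd %.3f\n",
              length(x$components), x$config$n_participants,
              x$config$components_per_participant, x$config$noise_sd))
  print(table(x$labels))
  invisible(x)
}
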