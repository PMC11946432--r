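# Synthetic multimodal recording generator with latent-state ground truth.
# Emulates the statistical structure the decoder assumes: a slow 2-state
# Markov process modulating EEG band variances, pupil dynamics, gaze
# velocity and vehicle speed.

#' Default simulation configuration
#'
#' The generator's defaults define the study conditions every test and
#' example runs under: 26 recordings of 600 s; latent 2-state chain at
#' 1 Hz with transition matrix `[[0.98, 0.02], [0.10, 0.90]]` (stationary
#' hypnosis occupancy 1/6 - the minority class); EEG 500 Hz x 4 channels
#' built from five band-limited noise components whose hypnotic-state
#' standard deviations are delta x1.5, theta x1.5, beta x0.6 of normal;
#' pupil fluctuations shrink from 0.25 to 0.08 mm SD in hypnosis; gaze
#' velocity drops from 3.5 to 0.8 deg/s; speed steadies (SD 1.2 -> 0.3
#' m/s) around a slightly higher cruise mean. `dominant_feature` records
#' which fused feature the design makes most discriminative.
#'
#' @param ... Named overrides of any default (nested lists merged).
#' @return A named list of generator parameters.
#' @export
sim_config <- function(...) {
  cfg <- list(
    duration_s = 600,
    n_recordings = 26,
    latent = list(
      rate = 1,
      pi = c(normal = 5 / 6, hypnosis = 1 / 6),
      A = matrix(c(0.98, 0.02, 0.10, 0.90), 2, 2, byrow = TRUE,
                 dimnames = list(c("normal", "hypnosis"),
                                 c("normal", "hypnosis")))),
    eeg = list(
      rate = 500, n_channels = 4,
      band_sd = list(normal = c(delta = 4, theta = 3, alpha = 2.5,
                                beta = 2, gamma = 1),
                     hypnosis = c(delta = 6, theta = 4.5, alpha = 2.5,
                                  beta = 1.2, gamma = 1))),
    eye = list(
      rate = 100, ar = 0.95, invalid_rate = 0.01,
      pupil_mean = c(normal = 4.0, hypnosis = 4.3),
      pupil_sd = c(normal = 0.25, hypnosis = 0.08),
      gaze_mean = c(normal = 3.5, hypnosis = 0.8),
      gaze_sd = c(normal = 1.5, hypnosis = 0.5),
      ipd_mean = 62, ipd_sd = 0.15),
    vehicle = list(
      rate = 10, ar = 0.95,
      speed_mean = c(normal = 12.5, hypnosis = 13.5),
      speed_sd = c(normal = 1.2, hypnosis = 0.3)),
    dominant_feature = "beta")
  merge_config(cfg, list(...))
}

#' Sample a latent state path and its hypnosis intervals
#'
#' Draws a Markov chain at the latent rate and returns both the state
#' sequence and the maximal hypnosis runs as half-open label intervals.
#'
#' @param pi Initial distribution over `c("normal", "hypnosis")` (or the
#'   state names of `A`).
#' @param A Transition matrix with rows summing to 1.
#' @param n_steps Number of steps.
#' @param seed Optional RNG seed.
#' @param rate Latent steps per second (default 1); step `i` (1-based)
#'   covers `[(i-1)/rate, i/rate)`.
#' @return A list: `states` (character vector), `intervals`
#'   ([event_intervals()] of the hypnosis runs).
#' @export
simulate_latent_path <- function(pi, A, n_steps, seed = NULL, rate = 1) {
  A <- as.matrix(A)
  if (any(A < 0) || any(abs(rowSums(A) - 1) > 1e-8)) {
    abort("Rows of A must be non-negative and sum to 1.")
  }
  states <- rownames(A) %||% c("normal", "hypnosis")
  if (!is.null(seed)) set.seed(seed)
  n_st <- nrow(A)
  s <- integer(n_steps)
  s[1] <- sample.int(n_st, 1, prob = pi)
  for (i in seq_len(n_steps - 1)) {
    s[i + 1] <- sample.int(n_st, 1, prob = A[s[i], ])
  }
  labels <- states[s]
  runs <- rle(labels)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  hyp <- runs$values == "hypnosis"
  intervals <- event_intervals((starts[hyp] - 1) / rate, ends[hyp] / rate,
                               rep("hypnosis", sum(hyp)))
  list(states = labels, intervals = intervals)
}

# expand one value per latent step into one value per output sample
expand_states <- function(per_step, n_out) {
  rep(per_step, each = ceiling(n_out / length(per_step)))[seq_len(n_out)]
}

# stationary AR(1) noise with a per-sample target standard deviation
ar1_noise <- function(n, phi, sd_series) {
  innov <- rnorm(n, sd = sd_series * sqrt(1 - phi^2))
  as.numeric(stats::filter(innov, phi, method = "recursive"))
}

#' Synthesize state-modulated EEG
#'
#' Each channel is the sum of five band-limited Gaussian noise components
#' (white noise passed through the same brick-wall mask the analysis
#' pipeline uses, rescaled to unit variance), each multiplied by the
#' state-dependent band standard deviation of the latent step covering the
#' sample.
#'
#' @param states Latent state labels, one per latent step.
#' @param config A [sim_config()].
#' @param seed Optional RNG seed.
#' @return A [sampled_signal()] at the configured EEG rate.
#' @export
synthesize_eeg <- function(states, config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fs <- config$eeg$rate
  n <- length(states) * fs / config$latent$rate
  bands <- eeg_bands()
  out <- matrix(0, n, config$eeg$n_channels)
  for (ch in seq_len(config$eeg$n_channels)) {
    x <- numeric(n)
    for (bi in seq_len(nrow(bands))) {
      b <- bands$band[bi]
      sd_state <- vapply(states, function(st) config$eeg$band_sd[[st]][[b]],
                         numeric(1))
      amp <- expand_states(sd_state, n)
      if (all(amp == 0)) next
      e <- sampled_signal(rnorm(n), fs)
      e <- bandpass_fft(e, bands$f1[bi], bands$f2[bi])
      comp <- e$values[, 1]
      comp <- comp / sd(comp)
      x <- x + comp * amp
    }
    out[, ch] <- x
  }
  colnames(out) <- paste0("ch", seq_len(config$eeg$n_channels))
  sampled_signal(out, fs, 0)
}

#' Synthesize state-modulated eye-tracking channels
#'
#' Pupil diameters follow a state-dependent mean plus AR(1) fluctuations
#' whose SD shrinks in hypnosis; gaze velocity is rectified Gaussian with a
#' state-dependent mean; IPD is near-constant. Invalid samples (flag 0,
#' value zeroed) are injected at the configured rate to exercise cleaning.
#'
#' @inheritParams synthesize_eeg
#' @return A [sampled_signal()] with the standard eye channels.
#' @export
synthesize_eye <- function(states, config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- config$eye
  fs <- cfg$rate
  n <- length(states) * fs / config$latent$rate
  mean_p <- expand_states(cfg$pupil_mean[states], n)
  sd_p <- expand_states(cfg$pupil_sd[states], n)
  pupil_l <- mean_p + ar1_noise(n, cfg$ar, sd_p)
  pupil_r <- mean_p * 0.98 + ar1_noise(n, cfg$ar, sd_p)
  gaze <- pmax(0, rnorm(n, expand_states(cfg$gaze_mean[states], n),
                        expand_states(cfg$gaze_sd[states], n)))
  ipd <- cfg$ipd_mean + ar1_noise(n, cfg$ar, rep(cfg$ipd_sd, n))
  valid <- as.numeric(runif(n) >= cfg$invalid_rate)
  pupil_l[valid == 0] <- 0
  pupil_r[valid == 0] <- 0
  v <- cbind(pupil_diameter_left = pupil_l, pupil_diameter_right = pupil_r,
             gaze_velocity = gaze, ipd = ipd, valid = valid)
  sampled_signal(v, fs, 0)
}

#' Synthesize state-modulated vehicle telemetry
#'
#' Speed follows a state-dependent mean plus AR(1) noise that steadies in
#' hypnosis; acceleration is the forward difference of speed (last value
#' held), so jerk computed downstream equals the second difference of
#' speed by construction.
#'
#' @inheritParams synthesize_eeg
#' @return A [sampled_signal()] with `speed` and `acceleration` channels.
#' @export
synthesize_vehicle <- function(states, config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- config$vehicle
  fs <- cfg$rate
  n <- length(states) * fs / config$latent$rate
  speed <- expand_states(cfg$speed_mean[states], n) +
    ar1_noise(n, cfg$ar, expand_states(cfg$speed_sd[states], n))
  accel <- c(diff(speed) * fs, 0)
  accel[n] <- accel[n - 1]
  sampled_signal(cbind(speed = speed, acceleration = accel), fs, 0)
}

#' Simulate one labeled multimodal recording
#'
#' Draws a latent path and synthesizes the three modality signals from it,
#' using decorrelated sub-seeds derived from `seed`.
#'
#' @param config A [sim_config()].
#' @param seed Master seed for this recording.
#' @return A [multimodal_recording()] whose labels are the true hypnosis
#'   intervals; the latent state sequence is attached as attribute
#'   `"states"`.
#' @export
simulate_recording <- function(config = sim_config(), seed = 1) {
  n_steps <- round(config$duration_s * config$latent$rate)
  sub <- function(k) (seed * 7919 + k) %% 2147483629
  lat <- simulate_latent_path(config$latent$pi, config$latent$A, n_steps,
                              seed = sub(1), rate = config$latent$rate)
  rec <- multimodal_recording(
    eeg = synthesize_eeg(lat$states, config, seed = sub(2)),
    eye = synthesize_eye(lat$states, config, seed = sub(3)),
    vehicle = synthesize_vehicle(lat$states, config, seed = sub(4)),
    labels = lat$intervals)
  attr(rec, "states") <- lat$states
  rec
}

#' Generate a dataset of independent recordings
#'
#' `k` recordings share the configured parameters but use distinct
#' sub-seeds. With `dir` set, each recording is written to
#' `<dir>/session_XX/` in the package CSV dialect.
#'
#' @param config A [sim_config()].
#' @param k Number of recordings (default from the config).
#' @param seed Master seed.
#' @param dir Optional output directory.
#' @return A list of [multimodal_recording()]s (invisibly when writing).
#' @export
generate_dataset <- function(config = sim_config(),
                             k = config$n_recordings, seed = 1,
                             dir = NULL) {
  if (k == 0) return(list())
  recs <- lapply(seq_len(k), function(i) {
    simulate_recording(config, seed = (seed * 1000003 + i) %% 2147483629)
  })
  if (!is.null(dir)) {
    for (i in seq_len(k)) {
      write_recording(recs[[i]],
                      file.path(dir, sprintf("session_%02d", i)))
    }
    return(invisible(recs))
  }
  recs
}
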