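# Small signal constructors shared across tests.

tone_signal <- function(freq, fs, dur_s = 1, amp = 1, start_time = 0) {
  t <- seq(0, dur_s - 1 / fs, by = 1 / fs)
  sampled_signal(amp * sin(2 * pi * freq * t), fs, start_time)
}

make_eye_signal <- function(n = 200, fs = 100, seed = 5) {
  set.seed(seed)
  v <- cbind(
    pupil_diameter_left = 4 + rnorm(n, sd = 0.1),
    pupil_diameter_right = 3.9 + rnorm(n, sd = 0.1),
    gaze_velocity = abs(rnorm(n, 3)),
    ipd = 62 + rnorm(n, sd = 0.1),
    valid = 1)
  sampled_signal(v, fs)
}

make_recording <- function(dur = 30, seed = 9, eeg_rate = 100) {
  # light-weight recording for plumbing tests (low EEG rate keeps it fast)
  cfg <- sim_config(duration_s = dur)
  cfg$eeg$rate <- eeg_rate
  simulate_recording(cfg, seed = seed)
}

# deterministic small fused table with both labels, for model-level tests
make_fused_pair <- function(n = 300, shift = 2, seed = 42) {
  set.seed(seed)
  lab <- rep(c("normal", "hypnosis"), length.out = n)
  x <- matrix(rnorm(n * 3), n, 3)
  x[lab == "hypnosis", 1] <- x[lab == "hypnosis", 1] + shift
  colnames(x) <- c("f1", "f2", "f3")
  list(x = x, labels = lab)
}
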