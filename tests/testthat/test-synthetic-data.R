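test_that("latent path sampling follows the chain and reports intervals", {
  # identity transition matrix from a normal start: no hypnosis intervals
  A_id <- diag(2)
  dimnames(A_id) <- list(c("normal", "hypnosis"), c("normal", "hypnosis"))
  lat <- simulate_latent_path(c(1, 0), A_id, 100, seed = 1)
  expect_true(all(lat$states == "normal"))
  expect_equal(nrow(lat$intervals), 0)

  # uniform chain: empirical transition frequencies within 0.02
  A_u <- matrix(0.5, 2, 2,
                dimnames = list(c("normal", "hypnosis"),
                                c("normal", "hypnosis")))
  lat2 <- simulate_latent_path(c(0.5, 0.5), A_u, 10000, seed = 2)
  est <- estimate_transitions(list(lat2$states), kappa = 0)
  expect_lt(max(abs(est$A - A_u)), 0.02)

  expect_identical(simulate_latent_path(c(0.5, 0.5), A_u, 50, seed = 9),
                   simulate_latent_path(c(0.5, 0.5), A_u, 50, seed = 9))
  expect_error(simulate_latent_path(c(1, 0), matrix(1, 2, 2), 10),
               "sum to 1")

  # intervals are exactly the maximal hypnosis runs
  lat3 <- simulate_latent_path(c(0.5, 0.5), A_u, 200, seed = 5)
  in_interval <- rep(FALSE, 200)
  for (i in seq_len(nrow(lat3$intervals))) {
    sel <- seq(lat3$intervals$t_start[i] + 1, lat3$intervals$t_end[i])
    in_interval[sel] <- TRUE
  }
  expect_identical(in_interval, lat3$states == "hypnosis")
})

test_that("long-run hypnosis occupancy matches the stationary distribution", {
  cfg <- sim_config()
  A <- cfg$latent$A
  statn <- A["normal", "hypnosis"] /
    (A["normal", "hypnosis"] + A["hypnosis", "normal"])
  lat <- simulate_latent_path(cfg$latent$pi, A, 10000, seed = 31)
  expect_lt(abs(mean(lat$states == "hypnosis") - statn), 0.03)
})

test_that("synthetic EEG carries the designed band-power contrast", {
  cfg <- sim_config(duration_s = 600)
  cfg$eeg$rate <- 250  # lighter rate, same band structure
  set.seed(1)
  states <- rep(c("normal", "hypnosis"), each = 300)
  eeg <- synthesize_eeg(states, cfg, seed = 17)
  bp <- sliding_band_power(bandpass_fft(eeg, 0.5, 40), window_s = 0.5,
                           step = 25)
  means <- band_power_means(bp)
  hyp <- means$time_s >= 300
  ratio <- mean(means$beta[hyp]) / mean(means$beta[!hyp])
  expect_lt(ratio, 0.8)
  theta_ratio <- mean(means$theta[hyp]) / mean(means$theta[!hyp])
  expect_gt(theta_ratio, 1.5)

  # zero band sds produce a silent signal
  cfg0 <- cfg
  cfg0$eeg$band_sd$normal[] <- 0
  z <- synthesize_eeg(rep("normal", 5), cfg0, seed = 1)
  expect_equal(max(abs(z$values)), 0)

  expect_identical(synthesize_eeg(states[1:10], cfg, seed = 3)$values,
                   synthesize_eeg(states[1:10], cfg, seed = 3)$values)
})

test_that("synthetic eye data shrink pupil fluctuations in hypnosis", {
  cfg <- sim_config()
  states <- rep(c("normal", "hypnosis"), each = 200)
  eye <- synthesize_eye(states, cfg, seed = 23)
  cleaned <- clean_eye(eye)
  pupil <- cleaned$values[, "pupil_diameter_left"]
  n_half <- length(pupil) / 2
  expect_lt(sd(pupil[(n_half + 1):length(pupil)]), sd(pupil[1:n_half]))

  cfg0 <- sim_config()
  cfg0$eye$invalid_rate <- 0
  eye0 <- synthesize_eye(states[1:20], cfg0, seed = 2)
  expect_true(all(eye0$values[, "valid"] == 1))

  expect_identical(synthesize_eye(states[1:20], cfg, seed = 4)$values,
                   synthesize_eye(states[1:20], cfg, seed = 4)$values)
})

test_that("synthetic vehicle streams are internally consistent", {
  cfg <- sim_config()
  states <- rep(c("normal", "hypnosis"), each = 50)
  veh <- synthesize_vehicle(states, cfg, seed = 29)
  sp <- veh$values[, "speed"]
  ac <- veh$values[, "acceleration"]
  t <- signal_times(veh)
  jk <- jerk(ac, t)$value
  dt <- 1 / cfg$vehicle$rate
  second_diff <- diff(sp, differences = 2) / dt^2
  n <- length(sp)
  expect_lt(max(abs(jk[1:(n - 2)] - second_diff)), 1e-9)

  cfg0 <- sim_config()
  cfg0$vehicle$speed_sd[] <- 0
  v0 <- synthesize_vehicle(c("normal", "normal", "hypnosis"), cfg0,
                           seed = 1)
  expect_equal(unique(v0$values[1:20, "speed"]),
               cfg0$vehicle$speed_mean[["normal"]])

  expect_identical(synthesize_vehicle(states, cfg, seed = 6)$values,
                   synthesize_vehicle(states, cfg, seed = 6)$values)
})

test_that("generate_dataset writes readable sessions deterministically", {
  cfg <- sim_config(duration_s = 20)
  cfg$eeg$rate <- 100
  expect_equal(generate_dataset(cfg, k = 0), list())

  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  generate_dataset(cfg, k = 2, seed = 3, dir = dir1)
  generate_dataset(cfg, k = 2, seed = 3, dir = dir2)
  expect_setequal(basename(list.dirs(dir1, recursive = FALSE)),
                  c("session_01", "session_02"))
  back <- read_recording(file.path(dir1, "session_01"))
  expect_s3_class(back, "multimodal_recording")
  # byte-identical output under the same master seed
  f1 <- file.path(dir1, "session_01", "eeg.csv")
  f2 <- file.path(dir2, "session_01", "eeg.csv")
  expect_identical(readLines(f1), readLines(f2))
})
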