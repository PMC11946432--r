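test_that("brick-wall bandpass passes the band and kills DC/out-of-band", {
  fs <- 500
  dc <- sampled_signal(rep(2, fs), fs)
  expect_lt(max(abs(bandpass_fft(dc, 0.5, 40)$values)), 1e-9 * 2)

  tone10 <- tone_signal(10, fs)
  out <- bandpass_fft(tone10, 0.5, 40)
  expect_lt(max(abs(out$values - tone10$values)), 1e-6)

  tone60 <- tone_signal(60, fs)
  expect_lt(max(abs(bandpass_fft(tone60, 0.5, 40)$values)), 1e-9)

  expect_error(bandpass_fft(tone10, 0.5, 300), "Nyquist")
})

test_that("bandpass with the ideal mask is idempotent", {
  set.seed(1)
  sig <- sampled_signal(matrix(rnorm(1000), 500, 2), 250)
  once <- bandpass_fft(sig, 1, 30)
  twice <- bandpass_fft(once, 1, 30)
  expect_lt(max(abs(twice$values - once$values)), 1e-9)
})

test_that("average reference removes the cross-channel mean", {
  sig <- sampled_signal(cbind(a = rep(1, 5), b = rep(3, 5)), 10)
  expect_equal(unname(average_reference(sig)$values),
               cbind(rep(-1, 5), rep(1, 5)))
  same <- sampled_signal(cbind(a = 1:5, b = 1:5), 10)
  expect_equal(max(abs(average_reference(same)$values)), 0)
  set.seed(2)
  rnd <- sampled_signal(matrix(rnorm(40), 10, 4), 10)
  expect_lt(max(abs(rowSums(average_reference(rnd)$values))), 1e-12)
  expect_error(average_reference(sampled_signal(1:5, 10)), "two channels")
})

test_that("drop_channels preserves order and rejects unknown names", {
  sig <- sampled_signal(cbind(a = 1:3, b = 4:6, c = 7:9), 10)
  expect_equal(drop_channels(sig, character())$channel_names,
               c("a", "b", "c"))
  expect_equal(drop_channels(sig, "b")$channel_names, c("a", "c"))
  expect_error(drop_channels(sig, "z"), "Unknown channel")
})

test_that("welch_psd matches the periodogram oracle and Parseval", {
  fs <- 500
  x <- sin(2 * pi * 10 * seq(0, 1 - 1 / fs, by = 1 / fs))
  # single rectangular segment == raw periodogram
  p <- welch_psd(x, fs, window_fn = "rectangular")
  X <- fft(x)
  per <- (abs(X)^2 / (fs * length(x)))[1:(length(x) / 2 + 1)]
  per[2:(length(x) / 2)] <- 2 * per[2:(length(x) / 2)]
  expect_equal(p$power[, 1], per, tolerance = 1e-12, ignore_attr = TRUE)
  # total one-sided power ~ variance 0.5, mass at the 10 Hz bin
  ph <- welch_psd(x, fs)
  tot <- sum(ph$power) * ph$resolution
  expect_lt(abs(tot - 0.5) / 0.5, 0.05)
  expect_equal(ph$frequencies[which.max(ph$power)], 10)
  expect_equal(max(abs(welch_psd(rep(0, 100), 100)$power)), 0)
  expect_error(welch_psd(numeric(0), 100), "Empty")
})

test_that("welch_psd of white noise is flat across 1-40 Hz", {
  set.seed(11)
  fs <- 128
  x <- rnorm(2^16)
  p <- welch_psd(x, fs, segment_length = 4096)
  band_means <- vapply(1:39, function(f0) {
    sel <- p$frequencies >= f0 & p$frequencies < f0 + 1
    mean(p$power[sel, 1])
  }, numeric(1))
  expect_lt(max(band_means) / min(band_means), 1.5)
})

test_that("band_power integrates the PSD over half-open bands", {
  # flat PSD of height c -> band power ~ c * width
  flat <- structure(list(frequencies = seq(0, 50, by = 0.5),
                         power = matrix(2, 101, 1), resolution = 0.5),
                    class = "psd_estimate")
  bp <- band_power(flat)
  widths <- eeg_bands()$f2 - eeg_bands()$f1
  expect_true(all(abs(bp$power - 2 * widths) <= 2 * 0.5))
  expect_error(band_power(flat, tibble::tibble(band = "x", f1 = 10,
                                               f2 = 200)),
               "outside")
  # 10 Hz tone: >= 90% of total 0.5-40 power lands in alpha
  p <- welch_psd(tone_signal(10, 500)$values, 500)
  bp2 <- band_power(p)
  expect_gte(bp2$power[bp2$band == "alpha"] / sum(bp2$power), 0.9)
})

test_that("the five default bands tile 0.5-40 Hz without overlap", {
  set.seed(3)
  p <- welch_psd(rnorm(1000), 250)
  bp <- band_power(p)
  sel <- p$frequencies >= 0.5 & p$frequencies < 40
  total <- sum(p$power[sel, 1]) * p$resolution
  expect_equal(sum(bp$power), total, tolerance = 1e-12)
})

test_that("sliding_band_power window arithmetic and stationarity", {
  sig <- tone_signal(10, 100, dur_s = 10)
  out <- sliding_band_power(sig, window_s = 2.5, step = 250)
  expect_equal(nrow(out), 4)
  out2 <- sliding_band_power(tone_signal(10, 100, dur_s = 3),
                             window_s = 2.5, step = 1)
  expect_equal(nrow(out2), 51)
  # stationary tone: constant alpha power across windows (5% rel. spread)
  alpha <- out2$alpha_ch1
  expect_lt((max(alpha) - min(alpha)) / mean(alpha), 0.05)
  expect_error(sliding_band_power(tone_signal(10, 100, dur_s = 1),
                                  window_s = 2), "longer than the signal")
})
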