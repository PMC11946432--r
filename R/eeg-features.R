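# EEG preprocessing and sliding-window Welch band-power extraction.

#' Canonical EEG frequency bands
#'
#' delta 0.5-4, theta 4-8, alpha 8-12, beta 12-30, gamma 30-40 Hz. Bands are
#' half-open `[f1, f2)`, so the five defaults tile `[0.5, 40)` without
#' overlap.
#'
#' @return A tibble with columns `band`, `f1`, `f2` (Hz).
#' @export
eeg_bands <- function() {
  tibble(band = c("delta", "theta", "alpha", "beta", "gamma"),
         f1 = c(0.5, 4, 8, 12, 30),
         f2 = c(4, 8, 12, 30, 40))
}

#' Brick-wall FFT bandpass filter
#'
#' Per channel: forward DFT, multiplication by an ideal mask that is 1 for
#' `low_cut <= |f| <= high_cut` and 0 elsewhere (applied symmetrically to
#' positive and negative frequencies so the output stays real), inverse DFT.
#' The ideal mask makes the operation idempotent.
#'
#' @param signal A [sampled_signal()].
#' @param low_cut,high_cut Passband edges in Hz;
#'   `0 <= low_cut < high_cut <= Nyquist`.
#' @return The filtered signal, same length and channels.
#' @export
bandpass_fft <- function(signal, low_cut = 0.5, high_cut = 40) {
  stopifnot(inherits(signal, "sampled_signal"))
  fs <- signal$sampling_rate
  if (low_cut < 0 || low_cut >= high_cut) {
    abort("Need 0 <= low_cut < high_cut.")
  }
  if (high_cut > fs / 2 + 1e-12) {
    abort(sprintf("high_cut (%g Hz) exceeds the Nyquist frequency (%g Hz).",
                  high_cut, fs / 2))
  }
  n <- n_samples(signal)
  if (n == 0) return(signal)
  k <- 0:(n - 1)
  f_abs <- pmin(k, n - k) * fs / n
  mask <- as.numeric(f_abs >= low_cut & f_abs <= high_cut)
  X <- mvfft(signal$values)
  y <- Re(mvfft(X * mask, inverse = TRUE)) / n
  sampled_signal(y, fs, signal$start_time, signal$channel_names)
}

#' Re-reference a multichannel signal to the average reference
#'
#' Subtracts the cross-channel mean from every channel at each sample, so
#' output rows sum to zero.
#'
#' @param signal A [sampled_signal()] with at least two channels.
#' @return The re-referenced signal.
#' @export
average_reference <- function(signal) {
  stopifnot(inherits(signal, "sampled_signal"))
  if (ncol(signal$values) < 2) {
    abort("Average referencing needs at least two channels.")
  }
  v <- signal$values - rowMeans(signal$values)
  sampled_signal(v, signal$sampling_rate, signal$start_time,
                 signal$channel_names)
}

#' Drop channels by name
#'
#' @param signal A [sampled_signal()].
#' @param names Channel names to remove; survivors keep their order.
#' @return The reduced signal.
#' @export
drop_channels <- function(signal, names) {
  stopifnot(inherits(signal, "sampled_signal"))
  unknown <- setdiff(names, signal$channel_names)
  if (length(unknown)) {
    abort(paste0("Unknown channel(s): ", paste(unknown, collapse = ", ")))
  }
  keep <- !(signal$channel_names %in% names)
  sampled_signal(signal$values[, keep, drop = FALSE], signal$sampling_rate,
                 signal$start_time, signal$channel_names[keep])
}

taper_window <- function(type, n) {
  k <- seq_len(n) - 1
  switch(type,
    hann = 0.5 - 0.5 * cos(2 * pi * k / (n - 1)),
    hamming = 0.54 - 0.46 * cos(2 * pi * k / (n - 1)),
    rectangular = rep(1, n),
    abort(sprintf("Unknown taper '%s'.", type)))
}

#' Welch power spectral density estimate
#'
#' Splits the input into non-overlapping segments of `segment_length`
#' samples, tapers each, and averages the one-sided periodograms
#' `|DFT(w * x)|^2 / (fs * sum(w^2))`. Interior bins are doubled so that the
#' Riemann sum of the density over frequency reproduces the mean square of
#' the input (Parseval). With one rectangular segment this is the raw
#' periodogram.
#'
#' @param values Numeric vector or `n x channels` matrix of samples.
#' @param sampling_rate Sampling rate in Hz.
#' @param segment_length Segment length in samples; defaults to the whole
#'   input (a single segment).
#' @param window_fn Taper: `"hann"` (default), `"hamming"` or
#'   `"rectangular"`.
#' @return An object of class `psd_estimate`: list with `frequencies` (Hz),
#'   `power` (`n_freq x channels`, units signal^2/Hz), `resolution` (Hz).
#' @export
welch_psd <- function(values, sampling_rate, segment_length = NULL,
                      window_fn = "hann") {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1)
  n <- nrow(values)
  if (n == 0) abort("Empty input.")
  ns <- segment_length %||% n
  if (ns > n) abort("segment_length exceeds the input length.")
  if (ns < 2) abort("segment_length must be at least 2 samples.")
  w <- taper_window(window_fn, ns)
  norm_w <- sum(w^2)
  n_seg <- n %/% ns
  acc <- matrix(0, ns, ncol(values))
  for (m in seq_len(n_seg)) {
    seg <- values[((m - 1) * ns + 1):(m * ns), , drop = FALSE] * w
    acc <- acc + abs(mvfft(seg))^2
  }
  pxx <- acc / (n_seg * sampling_rate * norm_w)
  n_keep <- ns %/% 2 + 1
  one_sided <- pxx[seq_len(n_keep), , drop = FALSE]
  dbl <- rep(2, n_keep)
  dbl[1] <- 1
  if (ns %% 2 == 0) dbl[n_keep] <- 1
  one_sided <- one_sided * dbl
  structure(
    list(frequencies = (seq_len(n_keep) - 1) * sampling_rate / ns,
         power = one_sided, resolution = sampling_rate / ns),
    class = "psd_estimate")
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf("<psd_estimate> %d bins x %d channels, df = %g Hz, [0, %g] Hz\n",
              length(x$frequencies), ncol(x$power), x$resolution,
              max(x$frequencies)))
  invisible(x)
}

#' Integrate a PSD over frequency bands
#'
#' Band power is the Riemann sum `sum(P(f) * df)` over the bins whose center
#' frequency lies in `[f1, f2)`.
#'
#' @param psd A [welch_psd()] estimate.
#' @param bands A band table as from [eeg_bands()].
#' @return A tibble with one row per band and channel: `band`, `channel`,
#'   `power`.
#' @export
band_power <- function(psd, bands = eeg_bands()) {
  stopifnot(inherits(psd, "psd_estimate"))
  f <- psd$frequencies
  if (any(bands$f2 > max(f) + psd$resolution / 2) || any(bands$f1 < 0)) {
    abort("Band edges fall outside the frequency grid.")
  }
  chans <- colnames(psd$power) %||% paste0("ch", seq_len(ncol(psd$power)))
  out <- lapply(seq_len(nrow(bands)), function(i) {
    sel <- f >= bands$f1[i] & f < bands$f2[i]
    tibble(band = bands$band[i], channel = chans,
           power = colSums(psd$power[sel, , drop = FALSE]) * psd$resolution)
  })
  bind_rows(out)
}

#' Sliding-window band power series
#'
#' Applies [welch_psd()] + [band_power()] to every placement of a window of
#' `window_s` seconds advanced by `step` samples. Window `i` covers samples
#' `i .. i + win - 1`; its band powers are timestamped at the window's last
#' sample (causal, right-edge convention).
#'
#' @param signal A [sampled_signal()] (already bandpassed/referenced as
#'   desired).
#' @param window_s Window length in seconds (default 0.5 s).
#' @param step Step between consecutive windows, in samples (default 1, the
#'   densest placement).
#' @param bands Band table, see [eeg_bands()].
#' @param window_fn Taper passed to [welch_psd()].
#' @return A tibble: `time_s`, then one `<band>_<channel>` column per band
#'   and channel, units signal^2 (density integrated over the band).
#' @export
sliding_band_power <- function(signal, window_s = 0.5, step = 1L,
                               bands = eeg_bands(), window_fn = "hann") {
  stopifnot(inherits(signal, "sampled_signal"))
  fs <- signal$sampling_rate
  win <- round(window_s * fs)
  if (win < 8) abort("Window must contain at least 8 samples.")
  n <- n_samples(signal)
  if (win > n) abort("Window is longer than the signal.")
  step <- as.integer(step)
  if (step < 1) abort("`step` must be a positive sample count.")
  starts <- seq.int(1L, n - win + 1L, by = step)
  n_ch <- ncol(signal$values)
  chans <- signal$channel_names
  w <- taper_window(window_fn, win)
  norm_w <- sum(w^2)
  n_keep <- win %/% 2 + 1
  f <- (seq_len(n_keep) - 1) * fs / win
  dbl <- rep(2, n_keep); dbl[1] <- 1
  if (win %% 2 == 0) dbl[n_keep] <- 1
  df <- fs / win
  band_sel <- lapply(seq_len(nrow(bands)), function(i) {
    f >= bands$f1[i] & f < bands$f2[i]
  })
  out <- matrix(0, length(starts), nrow(bands) * n_ch)
  for (j in seq_along(starts)) {
    seg <- signal$values[starts[j]:(starts[j] + win - 1L), , drop = FALSE] * w
    pxx <- (abs(mvfft(seg))^2)[seq_len(n_keep), , drop = FALSE] *
      dbl / (fs * norm_w)
    bp <- vapply(band_sel, function(sel) {
      colSums(pxx[sel, , drop = FALSE]) * df
    }, numeric(n_ch))
    out[j, ] <- as.numeric(bp)  # channel-major within band
  }
  cn <- as.character(outer(chans, bands$band,
                           function(ch, b) paste0(b, "_", ch)))
  colnames(out) <- cn
  # right-edge timestamps of each placement
  times <- signal$start_time + (starts + win - 2) / fs
  bind_cols(tibble(time_s = times), as_tibble(out))
}

#' Average a band-power table across channels
#'
#' Collapses the `<band>_<channel>` columns of [sliding_band_power()] output
#' to one column per band (mean over retained channels), the default feature
#' set fed to fusion.
#'
#' @param bp Output of [sliding_band_power()].
#' @param bands Band table used to produce `bp`.
#' @return A tibble `time_s` + one column per band.
#' @export
band_power_means <- function(bp, bands = eeg_bands()) {
  out <- tibble(time_s = bp$time_s)
  for (b in bands$band) {
    cols <- grep(paste0("^", b, "_"), names(bp), value = TRUE)
    out[[b]] <- rowMeans(bp[, cols, drop = FALSE])
  }
  out
}
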