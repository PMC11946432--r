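# Sliding-window and point-by-point kinematic features from vehicle
# telemetry (speed, acceleration).

window_starts <- function(t0, t_end, T_w, step) {
  starts <- seq(t0, t_end - T_w + 1e-12, by = step)
  if (!length(starts)) starts <- t0
  starts
}

#' Sliding-window mean of a sampled series
#'
#' Discrete mean of the samples falling in each half-open window
#' `[t_i, t_i + T_w)`; windows advance by `step` seconds. Each window is
#' timestamped at its right edge `t_i + T_w` (causal convention). A final
#' partial window (when the span is not a multiple of `step`) is truncated
#' and flagged with a warning.
#'
#' @param values Numeric vector of samples.
#' @param times Sample times in seconds (uniform).
#' @param T_w Window length in seconds (at least one sample period).
#' @param step Window step in seconds (default `T_w`).
#' @return A tibble `time_s`, `value`.
#' @export
sliding_mean <- function(values, times, T_w, step = T_w) {
  sliding_stat(values, times, T_w, step, mean)
}

#' Sliding-window population standard deviation
#'
#' Uses the population convention (divisor `N`, not `N - 1`).
#'
#' @inheritParams sliding_mean
#' @return A tibble `time_s`, `value`.
#' @export
sliding_std <- function(values, times, T_w, step = T_w) {
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  sliding_stat(values, times, T_w, step, pop_sd)
}

sliding_stat <- function(values, times, T_w, step, fn) {
  stopifnot(length(values) == length(times))
  dt <- if (length(times) > 1) times[2] - times[1] else T_w
  if (T_w < dt - 1e-12) abort("Window must cover at least one sample.")
  t0 <- times[1]
  t_end <- times[length(times)] + dt
  starts <- window_starts(t0, t_end, T_w, step)
  if (max(starts) + T_w > t_end + 1e-9) {
    warn("Last window extends past the signal span; it was truncated.")
  }
  out <- vapply(starts, function(s) {
    sel <- times >= s - 1e-9 & times < s + T_w - 1e-9
    if (!any(sel)) abort("Empty window encountered.")
    fn(values[sel])
  }, numeric(1))
  tibble(time_s = starts + T_w, value = out)
}

#' Jerk (forward-difference rate of change of acceleration)
#'
#' `jerk_i = (a_{i+1} - a_i) / (t_{i+1} - t_i)`, length `n - 1`,
#' timestamped at `t_i`.
#'
#' @param acceleration Acceleration samples (m/s^2).
#' @param times Strictly increasing sample times (s).
#' @return A tibble `time_s`, `value` (m/s^3).
#' @export
jerk <- function(acceleration, times) {
  stopifnot(length(acceleration) == length(times))
  if (length(times) < 2) abort("Need at least two samples.")
  dt <- diff(times)
  if (any(dt <= 0)) abort("Times must be strictly increasing.")
  tibble(time_s = times[-length(times)], value = diff(acceleration) / dt)
}

#' Kinematic feature table for a vehicle signal
#'
#' Computes sliding average speed, speed fluctuation (population SD),
#' sliding average acceleration (all on windows of `window_s` advanced by
#' `step_s`) plus per-sample jerk, resampled onto the window grid by the
#' trailing mean.
#'
#' @param signal A [sampled_signal()] with `speed` (m/s) and `acceleration`
#'   (m/s^2) channels.
#' @param window_s Window length in seconds (default 5).
#' @param step_s Window step in seconds (default 1).
#' @return A tibble `time_s`, `speed`, `std_speed`, `acceleration`, `jerk`.
#' @export
vehicle_features <- function(signal, window_s = 5, step_s = 1) {
  stopifnot(inherits(signal, "sampled_signal"))
  t <- signal_times(signal)
  sp <- signal$values[, "speed"]
  ac <- signal$values[, "acceleration"]
  avg_sp <- sliding_mean(sp, t, window_s, step_s)
  std_sp <- sliding_std(sp, t, window_s, step_s)
  avg_ac <- sliding_mean(ac, t, window_s, step_s)
  jk <- jerk(ac, t)
  jk_win <- sliding_mean(jk$value, jk$time_s, window_s, step_s)
  n <- min(nrow(avg_sp), nrow(jk_win))
  tibble(time_s = avg_sp$time_s[seq_len(n)],
         speed = avg_sp$value[seq_len(n)],
         std_speed = std_sp$value[seq_len(n)],
         acceleration = avg_ac$value[seq_len(n)],
         jerk = jk_win$value[seq_len(n)])
}

#' Convert speed from km/h to m/s
#'
#' @param speed_kmh Speed values in km/h.
#' @return Speed in m/s.
#' @export
kmh_to_ms <- function(speed_kmh) speed_kmh / 3.6
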