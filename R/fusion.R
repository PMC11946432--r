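# Feature standardization, time-grid alignment and assembly of the fused
# observation matrix.

#' Default fused feature order
#'
#' The 11 named observation features, in their fixed serialized order:
#' speed, acceleration, the five EEG band powers, gaze velocity, both pupil
#' diameters and the inter-pupillary distance.
#'
#' @return Character vector of feature names.
#' @export
fused_feature_names <- function() {
  c("speed", "acceleration", "delta", "theta", "alpha", "beta", "gamma",
    "gaze_velocity", "pupil_diameter_left", "pupil_diameter_right", "ipd")
}

#' Z-score features with stored or estimated moments
#'
#' Each feature column gets mean 0 and variance 1 using population moments
#' (divisor `n`). When `params` is supplied (inference), those moments are
#' applied unchanged; otherwise they are estimated and attached as the
#' `"scaling"` attribute so inference is reproducible.
#'
#' @param data A data frame of features (columns in `exclude` are passed
#'   through untouched).
#' @param params Optional scaling table (`feature`, `mu`, `sigma`) from a
#'   previous call.
#' @param exclude Columns never standardized.
#' @return A tibble with standardized feature columns and attribute
#'   `"scaling"`.
#' @export
standardize <- function(data, params = NULL,
                        exclude = c("time_s", "label")) {
  data <- as_tibble(data)
  cols <- setdiff(names(data), exclude)
  if (is.null(params)) {
    mu <- vapply(data[cols], mean, numeric(1))
    sigma <- vapply(data[cols], function(x) sqrt(mean((x - mean(x))^2)),
                    numeric(1))
    if (any(sigma == 0)) {
      abort(paste0("Zero-variance feature column(s): ",
                   paste(cols[sigma == 0], collapse = ", ")))
    }
    params <- tibble(feature = cols, mu = unname(mu), sigma = unname(sigma))
  } else {
    missing_cols <- setdiff(cols, params$feature)
    if (length(missing_cols)) {
      abort(paste0("Scaling parameters missing for: ",
                   paste(missing_cols, collapse = ", ")))
    }
  }
  for (cc in cols) {
    p <- params[params$feature == cc, ]
    data[[cc]] <- (data[[cc]] - p$mu) / p$sigma
  }
  attr(data, "scaling") <- params
  data
}

#' Align feature streams onto a common time grid
#'
#' Each stream (a tibble with `time_s` plus feature columns, at its native
#' rate) is resampled onto a uniform grid by the trailing mean of its
#' samples in the half-open window `(k - T, k]` ending at each grid time
#' `k`. Grid rows for which any stream has an empty window are dropped and
#' counted in the `"dropped_rows"` attribute.
#'
#' @param streams A list of tibbles, each `time_s` + feature columns;
#'   feature names must be unique across streams.
#' @param grid_rate Grid rate in Hz (default 1).
#' @param window_s Trailing window `T` in seconds (default one grid step).
#' @return A tibble `time_s` + all feature columns on the grid.
#' @export
align_features <- function(streams, grid_rate = 1,
                           window_s = 1 / grid_rate) {
  stopifnot(is.list(streams), length(streams) >= 1)
  g <- 1 / grid_rate
  lo <- max(vapply(streams, function(s) min(s$time_s), numeric(1)))
  hi <- min(vapply(streams, function(s) max(s$time_s), numeric(1)))
  if (hi <= lo) abort("Feature streams share no overlapping span.")
  grid <- seq(ceiling(lo / g - 1e-9) * g, floor(hi / g + 1e-9) * g, by = g)
  if (!length(grid)) abort("No grid point has a non-empty trailing window.")
  out <- tibble(time_s = grid)
  for (s in streams) {
    feats <- setdiff(names(s), "time_s")
    tt <- s$time_s
    # samples with time in (k - T, k]: cumulative counts via binary search
    hi_idx <- findInterval(grid + 1e-9, tt)
    lo_idx <- findInterval(grid - window_s + 1e-9, tt)
    cnt <- hi_idx - lo_idx
    for (fc in feats) {
      cs <- c(0, cumsum(s[[fc]]))
      out[[fc]] <- ifelse(cnt > 0, (cs[hi_idx + 1] - cs[lo_idx + 1]) / cnt,
                          NA_real_)
    }
  }
  keep <- stats::complete.cases(out)
  dropped <- sum(!keep)
  out <- out[keep, , drop = FALSE]
  attr(out, "dropped_rows") <- dropped
  out
}

#' Label fused rows from state intervals
#'
#' A grid row is labeled with a state when its time lies in one of that
#' state's half-open intervals `[t_start, t_end)`; all other rows get the
#' implicit normal-driving state.
#'
#' @param data A tibble with a `time_s` column.
#' @param intervals An [event_intervals()] table.
#' @param default Label for uncovered rows (default `"normal"`).
#' @return `data` with a `label` column (placed after `time_s`).
#' @export
label_rows <- function(data, intervals, default = "normal") {
  intervals <- event_intervals(intervals)
  lab <- rep(default, nrow(data))
  for (i in seq_len(nrow(intervals))) {
    hit <- data$time_s >= intervals$t_start[i] - 1e-9 &
      data$time_s < intervals$t_end[i] - 1e-9
    lab[hit] <- intervals$label[i]
  }
  data$label <- lab
  select(data, time_s, label, dplyr::everything())
}

#' Default pipeline configuration
#'
#' Collects every tunable of the extraction/fusion pipeline with its
#' default. Values can be overridden by passing a named list to the `...`
#' of the pipeline functions or via a YAML config in the CLI.
#'
#' @return A named list of parameters.
#' @export
pipeline_config <- function() {
  list(
    eeg = list(low_cut = 0.5, high_cut = 40, window_s = 0.5, step_s = 0.1,
               drop = character()),
    eye = list(fc_low = 8, order_low = 101, fc_high = 0.1, order_high = 201,
               ma_window = 20, pupil_range = c(1.5, 9), mad_k = 5),
    vehicle = list(window_s = 5, step_s = 1),
    fusion = list(grid_rate = 1, window_s = 1),
    hypnosis_label = "hypnosis"
  )
}

merge_config <- function(base, override) {
  if (is.null(override)) return(base)
  unknown <- setdiff(names(override), names(base))
  if (length(unknown)) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  for (nm in names(override)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      merge_config(base[[nm]], override[[nm]])
    } else {
      override[[nm]]
    }
  }
  base
}

#' Extract and fuse all modalities of a recording
#'
#' Runs the full observation pipeline: synchronize; EEG channel drop,
#' average reference, brick-wall bandpass and sliding Welch band power
#' (channel-averaged per band); eye cleaning, 8 Hz low-pass and 0.1 Hz
#' high-pass windowed-sinc FIR filters plus 20-sample moving average;
#' vehicle sliding mean speed/acceleration; trailing-mean alignment to the
#' fusion grid; state labeling. Standardization is *not* applied here - the
#' trainer estimates the moments on training data only.
#'
#' @param recording A [multimodal_recording()].
#' @param config Optional overrides of [pipeline_config()].
#' @return A tibble `time_s`, `label`, then the [fused_feature_names()]
#'   columns at the fusion grid rate.
#' @export
fuse_recording <- function(recording, config = NULL) {
  cfg <- merge_config(pipeline_config(), config)
  recording <- synchronize(recording)

  eeg <- recording$eeg
  if (length(cfg$eeg$drop)) eeg <- drop_channels(eeg, cfg$eeg$drop)
  if (ncol(eeg$values) >= 2) eeg <- average_reference(eeg)
  eeg <- bandpass_fft(eeg, cfg$eeg$low_cut, cfg$eeg$high_cut)
  step_samples <- max(1L, round(cfg$eeg$step_s * eeg$sampling_rate))
  bp <- sliding_band_power(eeg, cfg$eeg$window_s, step_samples)
  eeg_stream <- band_power_means(bp)

  eye <- clean_eye(recording$eye, cfg$eye$pupil_range, cfg$eye$mad_k)
  eye <- drop_channels(eye, "valid")
  lp <- design_fir(cfg$eye$fc_low, eye$sampling_rate, cfg$eye$order_low,
                   "low")
  hp <- design_fir(cfg$eye$fc_high, eye$sampling_rate, cfg$eye$order_high,
                   "high")
  eye <- moving_average(apply_fir(apply_fir(eye, lp), hp),
                        cfg$eye$ma_window)
  eye_stream <- as_tibble(eye)

  veh <- vehicle_features(recording$vehicle, cfg$vehicle$window_s,
                          cfg$vehicle$step_s)
  veh_stream <- veh[, c("time_s", "speed", "acceleration")]

  fused <- align_features(list(veh_stream, eeg_stream, eye_stream),
                          grid_rate = cfg$fusion$grid_rate,
                          window_s = cfg$fusion$window_s)
  fused <- label_rows(fused, recording$labels)
  select(fused, time_s, label, dplyr::all_of(fused_feature_names()))
}
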