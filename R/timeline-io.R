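# Synchronized multimodal recordings: sampled signals on one reference clock,
# labeled state intervals, and the package's delimited-text dialects.

#' Construct a uniformly sampled multichannel signal
#'
#' A `sampled_signal` holds an `n_samples x n_channels` matrix of values
#' sampled at a fixed rate, anchored on a shared reference clock. Sample `i`
#' (0-based) occurs at `start_time + i / sampling_rate`; a signal spans the
#' half-open interval `[start_time, start_time + n / sampling_rate)`.
#'
#' @param values Numeric matrix or data frame, samples in rows, channels in
#'   columns. A bare vector is treated as a single channel.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param start_time Time of the first sample in seconds on the reference
#'   clock.
#' @param channel_names Optional channel names; defaults to the column names
#'   of `values` (or `ch1..chN`).
#' @return An object of class `sampled_signal`.
#' @export
#' @examples
#' s <- sampled_signal(cbind(a = sin(1:100), b = cos(1:100)), sampling_rate = 10)
#' signal_span(s)
sampled_signal <- function(values, sampling_rate, start_time = 0,
                           channel_names = NULL) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (is.null(dim(values))) values <- matrix(values, ncol = 1)
  storage.mode(values) <- "double"
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      sampling_rate <= 0) {
    abort("`sampling_rate` must be a single positive number (Hz).")
  }
  if (is.null(channel_names)) {
    channel_names <- colnames(values) %||% paste0("ch", seq_len(ncol(values)))
  }
  if (length(channel_names) != ncol(values)) {
    abort("`channel_names` length must match the number of columns.")
  }
  if (anyDuplicated(channel_names)) {
    abort("Channel names must be unique.")
  }
  colnames(values) <- channel_names
  structure(
    list(values = values, sampling_rate = as.numeric(sampling_rate),
         start_time = as.numeric(start_time),
         channel_names = as.character(channel_names)),
    class = "sampled_signal"
  )
}

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf(
    "<sampled_signal> %d samples x %d channels @ %g Hz, span [%g, %g) s\n",
    nrow(x$values), ncol(x$values), x$sampling_rate,
    x$start_time, signal_span(x)[2]))
  cat("channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' Number of samples in a signal
#' @param signal A [sampled_signal()].
#' @return Integer sample count.
#' @export
n_samples <- function(signal) nrow(signal$values)

#' Sample times of a signal
#' @inheritParams n_samples
#' @return Numeric vector of times (s) on the reference clock.
#' @export
signal_times <- function(signal) {
  signal$start_time + (seq_len(n_samples(signal)) - 1) / signal$sampling_rate
}

#' Time span of a signal
#' @inheritParams n_samples
#' @return `c(start, end)` of the half-open span `[start, end)` in seconds.
#' @export
signal_span <- function(signal) {
  c(signal$start_time,
    signal$start_time + n_samples(signal) / signal$sampling_rate)
}

#' @export
as_tibble.sampled_signal <- function(x, ...) {
  bind_cols(tibble(time_s = signal_times(x)), as_tibble(x$values))
}

#' Validate a table of labeled state intervals
#'
#' Intervals are half-open `[t_start, t_end)` on the reference clock. Every
#' interval must have `t_start < t_end`, and intervals sharing a label may
#' not overlap.
#'
#' @param t_start,t_end Interval bounds in seconds, or `t_start` may be a
#'   data frame already holding `t_start`, `t_end`, `label` columns.
#' @param label State identifier per interval (e.g. `"hypnosis"`).
#' @return A tibble with columns `t_start`, `t_end`, `label`, sorted by
#'   start time.
#' @export
#' @examples
#' event_intervals(c(10, 60), c(25, 80), "hypnosis")
event_intervals <- function(t_start, t_end = NULL, label = NULL) {
  if (is.data.frame(t_start)) {
    df <- t_start
    missing_cols <- setdiff(c("t_start", "t_end", "label"), names(df))
    if (length(missing_cols)) {
      abort(paste0("Interval table lacks column(s): ",
                   paste(missing_cols, collapse = ", ")))
    }
  } else {
    df <- tibble(t_start = as.numeric(t_start), t_end = as.numeric(t_end),
                 label = as.character(label))
  }
  df <- as_tibble(df)[, c("t_start", "t_end", "label")]
  df$t_start <- as.numeric(df$t_start)
  df$t_end <- as.numeric(df$t_end)
  df$label <- as.character(df$label)
  if (any(df$t_start >= df$t_end)) {
    abort("Every interval must satisfy t_start < t_end.")
  }
  df <- arrange(df, t_start)
  for (lb in unique(df$label)) {
    sub <- df[df$label == lb, ]
    if (nrow(sub) > 1 &&
        any(sub$t_start[-1] < sub$t_end[-nrow(sub)] - 1e-12)) {
      abort(sprintf("Intervals labeled '%s' overlap.", lb))
    }
  }
  df
}

#' Assemble a synchronized multimodal recording
#'
#' Bundles the three modality signals and the labeled state intervals of one
#' driving session. All signals must be expressed on the same reference
#' clock; [synchronize()] crops them to their common span.
#'
#' @param eeg,eye,vehicle [sampled_signal()] objects. The eye signal must
#'   carry channels `pupil_diameter_left`, `pupil_diameter_right`,
#'   `gaze_velocity`, `ipd`, `valid`; the vehicle signal `speed` (m/s) and
#'   `acceleration` (m/s^2).
#' @param labels An [event_intervals()] table (may be empty: unlabeled time
#'   is implicitly the normal driving state).
#' @return An object of class `multimodal_recording`.
#' @export
multimodal_recording <- function(eeg, eye, vehicle,
                                 labels = event_intervals(numeric(),
                                                          numeric(),
                                                          character())) {
  for (nm in c("eeg", "eye", "vehicle")) {
    sig <- get(nm)
    if (!inherits(sig, "sampled_signal")) {
      abort(sprintf("`%s` must be a sampled_signal.", nm))
    }
  }
  missing_eye <- setdiff(eye_channel_set(), eye$channel_names)
  if (length(missing_eye)) {
    abort(paste0("Eye signal lacks channel(s): ",
                 paste(missing_eye, collapse = ", ")))
  }
  missing_veh <- setdiff(c("speed", "acceleration"), vehicle$channel_names)
  if (length(missing_veh)) {
    abort(paste0("Vehicle signal lacks channel(s): ",
                 paste(missing_veh, collapse = ", ")))
  }
  labels <- event_intervals(labels)
  structure(list(eeg = eeg, eye = eye, vehicle = vehicle, labels = labels),
            class = "multimodal_recording")
}

eye_channel_set <- function() {
  c("pupil_diameter_left", "pupil_diameter_right", "gaze_velocity",
    "ipd", "valid")
}

#' @export
print.multimodal_recording <- function(x, ...) {
  cat("<multimodal_recording>\n")
  for (nm in c("eeg", "eye", "vehicle")) {
    sp <- signal_span(x[[nm]])
    cat(sprintf("  %-7s %7d samples @ %6g Hz  [%g, %g) s\n", nm,
                n_samples(x[[nm]]), x[[nm]]$sampling_rate, sp[1], sp[2]))
  }
  cat(sprintf("  labels  %d interval(s)\n", nrow(x$labels)))
  invisible(x)
}

#' Crop a recording to the common time span of its modalities
#'
#' Timestamp synchronization: all three signals are cropped to the
#' intersection of their spans and label intervals are clipped to it.
#' Samples are never resampled or shifted, so relative sample times are
#' preserved bit-faithfully. The operation is idempotent.
#'
#' @param recording A [multimodal_recording()].
#' @return The cropped recording.
#' @export
synchronize <- function(recording) {
  stopifnot(inherits(recording, "multimodal_recording"))
  spans <- lapply(recording[c("eeg", "eye", "vehicle")], signal_span)
  lo <- max(vapply(spans, `[`, numeric(1), 1))
  hi <- min(vapply(spans, `[`, numeric(1), 2))
  if (hi <= lo + 1e-12) {
    abort(sprintf(
      paste0("Signals share no overlapping time span: eeg [%g, %g), ",
             "eye [%g, %g), vehicle [%g, %g)."),
      spans$eeg[1], spans$eeg[2], spans$eye[1], spans$eye[2],
      spans$vehicle[1], spans$vehicle[2]))
  }
  out <- recording
  for (nm in c("eeg", "eye", "vehicle")) {
    out[[nm]] <- crop_signal(recording[[nm]], lo, hi)
  }
  lab <- recording$labels
  if (nrow(lab)) {
    lab$t_start <- pmax(lab$t_start, lo)
    lab$t_end <- pmin(lab$t_end, hi)
    lab <- lab[lab$t_start < lab$t_end, , drop = FALSE]
  }
  out$labels <- as_tibble(lab)
  out
}

# keep samples whose time lies in [lo, hi); tolerance guards float jitter
crop_signal <- function(signal, lo, hi) {
  t <- signal_times(signal)
  keep <- which(t >= lo - 1e-9 & t < hi - 1e-9)
  if (!length(keep)) {
    return(sampled_signal(
      signal$values[0, , drop = FALSE], signal$sampling_rate, lo,
      signal$channel_names))
  }
  sampled_signal(signal$values[keep, , drop = FALSE], signal$sampling_rate,
                 t[keep[1]], signal$channel_names)
}

#' Extract and concatenate the signal segments carrying one label
#'
#' Restricts a signal to the intervals tagged with `label` (half-open
#' `[t_start, t_end)`, so a sample exactly at `t_end` is excluded) and
#' concatenates the segments in time order into one new signal whose start
#' time is the first interval's start. With no matching interval an empty
#' signal is returned (with a message), not an error.
#'
#' @param signal A [sampled_signal()].
#' @param intervals An [event_intervals()] table, clipped to the signal span.
#' @param label The state identifier to extract.
#' @return A [sampled_signal()] holding the concatenated segments.
#' @export
extract_intervals <- function(signal, intervals, label) {
  intervals <- event_intervals(intervals)
  sel <- intervals[intervals$label == label, , drop = FALSE]
  if (!nrow(sel)) {
    inform(sprintf("No interval labeled '%s'; returning an empty signal.",
                   label))
    return(sampled_signal(signal$values[0, , drop = FALSE],
                          signal$sampling_rate, signal$start_time,
                          signal$channel_names))
  }
  rate <- signal$sampling_rate
  idx <- unlist(lapply(seq_len(nrow(sel)), function(i) {
    # 0-based sample indices with time in [t_start, t_end)
    i0 <- ceiling((sel$t_start[i] - signal$start_time) * rate - 1e-9)
    i1 <- ceiling((sel$t_end[i] - signal$start_time) * rate - 1e-9) - 1
    i0 <- max(i0, 0)
    i1 <- min(i1, n_samples(signal) - 1)
    if (i1 < i0) integer() else seq.int(i0, i1)
  }))
  sampled_signal(signal$values[idx + 1, , drop = FALSE], rate,
                 sel$t_start[1], signal$channel_names)
}

#' Write a recording to the package's CSV dialect
#'
#' Writes `eeg.csv` (`time_s, ch1..chN`), `eye.csv`, `vehicle.csv` and
#' `labels.csv` (`t_start, t_end, label`) into `dir`. Values round-trip at
#' full double precision through [read_recording()].
#'
#' @param recording A [multimodal_recording()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_recording <- function(recording, dir) {
  stopifnot(inherits(recording, "multimodal_recording"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("eeg", "eye", "vehicle")) {
    readr::write_csv(as_tibble(recording[[nm]]),
                     file.path(dir, paste0(nm, ".csv")))
  }
  readr::write_csv(recording$labels, file.path(dir, "labels.csv"))
  invisible(dir)
}

#' Read a recording from the package's CSV dialect
#'
#' Expects the four files written by [write_recording()] (or any files
#' following the documented column schema). Sampling rates and start times
#' are recovered from the `time_s` column; rates within `1e-6` of an integer
#' are snapped to it.
#'
#' @param dir Directory holding `eeg.csv`, `eye.csv`, `vehicle.csv`,
#'   `labels.csv`; alternatively a named list/vector of the four file paths
#'   (`eeg`, `eye`, `vehicle`, `labels`).
#' @return A [multimodal_recording()].
#' @export
read_recording <- function(dir) {
  if (is.character(dir) && length(dir) == 1 && dir.exists(dir)) {
    paths <- file.path(dir, c(eeg = "eeg.csv", eye = "eye.csv",
                              vehicle = "vehicle.csv", labels = "labels.csv"))
    names(paths) <- c("eeg", "eye", "vehicle", "labels")
  } else {
    paths <- unlist(dir)
    missing_keys <- setdiff(c("eeg", "eye", "vehicle", "labels"),
                            names(paths))
    if (length(missing_keys)) {
      abort(paste0("Paths must name: ",
                   paste(missing_keys, collapse = ", ")))
    }
  }
  for (p in paths) {
    if (!file.exists(p)) abort(sprintf("File not found: %s", p))
  }
  sig <- lapply(paths[c("eeg", "eye", "vehicle")], read_signal_csv)
  lab <- readr::read_csv(paths[["labels"]], show_col_types = FALSE,
                         progress = FALSE)
  multimodal_recording(sig$eeg, sig$eye, sig$vehicle, event_intervals(lab))
}

read_signal_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        name_repair = "minimal")
  if (anyDuplicated(names(df))) {
    abort(sprintf("Duplicated channel name in %s.", basename(path)))
  }
  if (!"time_s" %in% names(df)) {
    abort(sprintf("Missing mandatory column `time_s` in %s.",
                  basename(path)))
  }
  t <- df$time_s
  if (nrow(df) > 1) {
    dt <- diff(t)
    if (any(dt <= 0)) {
      abort(sprintf("Non-monotone timestamps in %s.", basename(path)))
    }
    rate <- 1 / median(dt)
    if (abs(rate - round(rate)) < 1e-6) rate <- round(rate)
  } else {
    rate <- 1
  }
  sampled_signal(as.matrix(df[setdiff(names(df), "time_s")]), rate,
                 if (nrow(df)) t[1] else 0)
}
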