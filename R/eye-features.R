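# Eye-movement cleaning, windowed-sinc FIR filtering, moving-average
# smoothing, and locally linear embedding.

#' Clean eye-tracking channels
#'
#' Samples are marked invalid when the validity flag is 0, when a pupil
#' diameter leaves the physiological range, or when a value is farther than
#' `mad_k` robust MADs from the channel median. Invalid samples are replaced
#' by linear interpolation between valid neighbors; leading/trailing invalid
#' runs are held at the nearest valid value. The returned validity flag is
#' all 1.
#'
#' @param signal A [sampled_signal()] with the standard eye channels
#'   (`valid` flag optional if limits suffice).
#' @param pupil_range Plausible pupil diameter range in mm applied to
#'   channels whose name contains `pupil_diameter`.
#' @param mad_k Robust outlier cutoff in MAD units (default 5).
#' @return The cleaned signal.
#' @export
clean_eye <- function(signal, pupil_range = c(1.5, 9), mad_k = 5) {
  stopifnot(inherits(signal, "sampled_signal"))
  v <- signal$values
  has_flag <- "valid" %in% signal$channel_names
  flag_ok <- if (has_flag) v[, "valid"] != 0 else rep(TRUE, nrow(v))
  data_ch <- setdiff(signal$channel_names, "valid")
  for (ch in data_ch) {
    x <- v[, ch]
    ok <- flag_ok & is.finite(x)
    if (grepl("pupil_diameter", ch)) {
      ok <- ok & x >= pupil_range[1] & x <= pupil_range[2]
    }
    med <- median(x[ok])
    s <- mad(x[ok])
    if (is.finite(s) && s > 0) ok <- ok & abs(x - med) <= mad_k * s
    if (!any(ok)) {
      abort(sprintf("Channel '%s' has no valid samples after cleaning.", ch))
    }
    if (!all(ok)) {
      idx <- seq_along(x)
      v[, ch] <- approx(idx[ok], x[ok], xout = idx, rule = 2)$y
    }
  }
  if (has_flag) v[, "valid"] <- 1
  sampled_signal(v, signal$sampling_rate, signal$start_time,
                 signal$channel_names)
}

#' Design a windowed-sinc FIR filter
#'
#' Low-pass: the ideal impulse response
#' `h[k] = sin(2*pi*(fc/fs)*(k - M/2)) / (pi*(k - M/2))` with center value
#' `2*fc/fs`, multiplied by a Hamming taper and normalized to unit DC gain.
#' High-pass: spectral inversion of the complementary low-pass (negate, add
#' 1 at the center tap), which pins the DC gain to exactly 0. Coefficients
#' are symmetric, so the filter has linear phase with group delay
#' `(M - 1) / 2` samples.
#'
#' @param fc Cutoff frequency in Hz, `0 < fc < fs/2`.
#' @param fs Sampling rate in Hz.
#' @param M Filter order (number of taps); must be odd.
#' @param mode `"low"` or `"high"`.
#' @param taper Taper applied to the ideal response (default Hamming).
#' @return An object of class `fir_filter` with fields `coefficients`,
#'   `order`, `fc`, `fs`, `mode`.
#' @export
design_fir <- function(fc, fs, M, mode = c("low", "high"),
                       taper = "hamming") {
  mode <- arg_match(mode)
  if (M %% 2 == 0) abort("Filter order M must be odd.")
  if (fc <= 0 || fc >= fs / 2) abort("Need 0 < fc < fs/2.")
  mid <- (M - 1) / 2
  m <- (0:(M - 1)) - mid
  h <- ifelse(m == 0, 2 * fc / fs, sin(2 * pi * (fc / fs) * m) / (pi * m))
  h <- h * taper_window(taper, M)
  h <- h / sum(h)  # unit DC gain for the low-pass prototype
  if (mode == "high") {
    h <- -h
    h[mid + 1] <- h[mid + 1] + 1
  }
  structure(list(coefficients = h, order = M, fc = fc, fs = fs, mode = mode),
            class = "fir_filter")
}

#' @export
print.fir_filter <- function(x, ...) {
  cat(sprintf("<fir_filter> %s-pass, fc = %g Hz, fs = %g Hz, %d taps\n",
              x$mode, x$fc, x$fs, x$order))
  invisible(x)
}

#' Frequency response of an FIR filter
#'
#' @param filter A [design_fir()] filter.
#' @param f Frequencies (Hz) at which to evaluate.
#' @return Complex response `H(f)`.
#' @export
fir_response <- function(filter, f) {
  k <- seq_along(filter$coefficients) - 1
  vapply(f, function(ff) {
    sum(filter$coefficients * exp(-2i * pi * ff / filter$fs * k))
  }, complex(1))
}

#' Apply an FIR filter by direct convolution
#'
#' Direct-form convolution `y[n] = sum_k h[k] x[n-k]`. With
#' `compensate_delay = TRUE` the output is shifted back by the group delay
#' `(M-1)/2` so features stay time-aligned, and the edges are handled by
#' reflection padding; with `FALSE` the raw causal convolution (zero-padded)
#' is returned.
#'
#' @param signal A [sampled_signal()] longer than the filter.
#' @param filter A [design_fir()] filter.
#' @param compensate_delay Shift output to zero phase (default `TRUE`).
#' @return The filtered signal.
#' @export
apply_fir <- function(signal, filter, compensate_delay = TRUE) {
  stopifnot(inherits(signal, "sampled_signal"),
            inherits(filter, "fir_filter"))
  h <- filter$coefficients
  M <- length(h)
  n <- n_samples(signal)
  if (n <= M) abort("Signal must be longer than the filter order.")
  D <- (M - 1) / 2
  out <- signal$values
  for (j in seq_len(ncol(out))) {
    x <- signal$values[, j]
    if (compensate_delay) {
      xp <- c(rev(x[2:(D + 1)]), x, rev(x[(n - D):(n - 1)]))
      yf <- stats::filter(xp, h, method = "convolution", sides = 1)
      out[, j] <- as.numeric(yf[(M - 1) + seq_len(n)])
    } else {
      yf <- stats::filter(c(rep(0, M - 1), x), h, method = "convolution",
                          sides = 1)
      out[, j] <- as.numeric(yf[(M - 1) + seq_len(n)])
    }
  }
  sampled_signal(out, signal$sampling_rate, signal$start_time,
                 signal$channel_names)
}

#' Trailing moving-average smoother
#'
#' `H[n]` is the mean of the last `N` samples ending at `n`; the first
#' `N - 1` outputs use the mean of the available prefix.
#'
#' @param signal A [sampled_signal()].
#' @param N Window length in samples (default 20).
#' @return The smoothed signal.
#' @export
moving_average <- function(signal, N = 20) {
  stopifnot(inherits(signal, "sampled_signal"))
  N <- as.integer(N)
  if (N < 1) abort("N must be at least 1.")
  n <- n_samples(signal)
  out <- signal$values
  denom <- pmin(seq_len(n), N)
  for (j in seq_len(ncol(out))) {
    cs <- cumsum(signal$values[, j])
    lagged <- c(rep(0, N), head(cs, -N))[seq_len(n)]
    out[, j] <- (cs - lagged) / denom
  }
  sampled_signal(out, signal$sampling_rate, signal$start_time,
                 signal$channel_names)
}

#' Locally linear embedding
#'
#' Maps `n` points in `p` dimensions to `d` dimensions while preserving
#' local linear reconstruction: (i) `K` nearest neighbors by Euclidean
#' distance; (ii) per-point reconstruction weights minimizing
#' `||x_i - sum_j w_ij x_j||^2` subject to `sum_j w_ij = 1`, with
#' trace-scaled Tikhonov regularization of the local Gram matrix;
#' (iii) embedding = eigenvectors of `(I-W)'(I-W)` for the `d` smallest
#' non-trivial eigenvalues (the constant eigenvector is discarded).
#'
#' @param X Numeric matrix or data frame, points in rows.
#' @param K Number of neighbors, `K < n`.
#' @param d Target dimension, `1 <= d < p`.
#' @param reg Tikhonov regularization scale relative to the local Gram
#'   trace (default 1e-3).
#' @param symmetrize If `TRUE`, replace `W` by `(W + W')/2` before the
#'   eigenproblem (off by default: symmetrization conflicts with the
#'   row-sum-1 constraint).
#' @return An object of class `lle_embedding`: `coordinates` (`n x d`),
#'   `weights` (sparse `n x n`, rows sum to 1), `eigenvalues` (the `d`
#'   retained), `K`, `d`.
#' @export
lle_embed <- function(X, K, d, reg = 1e-3, symmetrize = FALSE) {
  if (is.data.frame(X)) X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (K >= n) abort("K must be smaller than the number of points.")
  if (d < 1 || d >= p) abort("Need 1 <= d < p.")
  if (all(apply(X, 2, function(col) diff(range(col)) == 0))) {
    abort("All points are identical; embedding is undefined.")
  }
  D2 <- as.matrix(stats::dist(X))^2
  idx <- matrix(0L, n, K)
  w_val <- matrix(0, n, K)
  for (i in seq_len(n)) {
    nb <- order(D2[i, ])[2:(K + 1)]
    idx[i, ] <- nb
    Z <- sweep(X[nb, , drop = FALSE], 2, X[i, ])
    G <- Z %*% t(Z)
    tr <- sum(diag(G))
    if (tr > 0) G <- G + diag(K) * reg * tr / K else G <- G + diag(K) * reg
    w <- solve(G, rep(1, K))
    w_val[i, ] <- w / sum(w)
  }
  W <- Matrix::sparseMatrix(i = rep(seq_len(n), each = K),
                            j = as.integer(t(idx)),
                            x = as.numeric(t(w_val)), dims = c(n, n))
  Wd <- as.matrix(W)
  if (symmetrize) Wd <- (Wd + t(Wd)) / 2
  Mm <- crossprod(diag(n) - Wd)
  eig <- eigen((Mm + t(Mm)) / 2, symmetric = TRUE)
  ord <- order(eig$values)       # ascending; first is the constant mode
  keep <- ord[2:(d + 1)]
  Y <- eig$vectors[, keep, drop = FALSE]
  structure(list(coordinates = Y, weights = W,
                 eigenvalues = eig$values[keep], K = K, d = d),
            class = "lle_embedding")
}

#' @export
print.lle_embedding <- function(x, ...) {
  cat(sprintf("<lle_embedding> %d points -> %d dims (K = %d)\n",
              nrow(x$coordinates), x$d, x$K))
  invisible(x)
}

#' Reconstruction cost of an embedding
#'
#' Evaluates `sum_i ||y_i - sum_j w_ij y_j||^2` for any candidate
#' coordinate matrix under the stored weights.
#'
#' @param embedding An [lle_embed()] result.
#' @param Y Candidate coordinates (defaults to the embedding's own).
#' @return Non-negative scalar cost.
#' @export
lle_cost <- function(embedding, Y = embedding$coordinates) {
  R <- Y - as.matrix(embedding$weights %*% Y)
  sum(R^2)
}
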