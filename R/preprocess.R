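#' Preprocessing configuration
#'
#' Defaults follow the standard myoelectric pipeline: order-20 Butterworth
#' band-pass from 20 to 500 Hz at 2 kS/s, then per-channel normalization and
#' 300 ms sliding windows with a 75 ms increment.
#'
#' @param band_low,band_high band edges in Hz.
#' @param filter_order overall band-pass order (must be even; the analog
#'   low-pass prototype has half this order).
#' @param fs sampling rate (S/s).
#' @param window_ms,increment_ms sliding-window length and increment (ms).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(band_low = 20, band_high = 500,
                              filter_order = 20, fs = 2000,
                              window_ms = 300, increment_ms = 75) {
  band_low <- check_positive(band_low, "band_low")
  band_high <- check_positive(band_high, "band_high")
  fs <- check_positive(fs, "fs")
  filter_order <- check_count(filter_order, "filter_order", min = 2)
  window_ms <- check_positive(window_ms, "window_ms")
  increment_ms <- check_positive(increment_ms, "increment_ms")
  if (!(band_low < band_high && band_high < fs / 2)) {
    abort("band edges must satisfy 0 < band_low < band_high < fs/2")
  }
  if (filter_order %% 2 != 0) abort("`filter_order` must be even")
  if (window_ms < increment_ms) abort("window_ms must be >= increment_ms")
  structure(list(band_low = band_low, band_high = band_high,
                 filter_order = filter_order, fs = fs,
                 window_ms = window_ms, increment_ms = increment_ms),
            class = "preprocess_config")
}

#' Design a zero-phase Butterworth band-pass as second-order sections
#'
#' Designs the analog Butterworth low-pass prototype of order `order/2`,
#' applies the low-pass to band-pass transform at the prewarped edges and the
#' bilinear transform, and pairs poles/zeros into biquad sections. The
#' cascade is numerically stable at high orders where a direct-form transfer
#' function is not; bilinear prewarping places the half-power (-3 dB) points
#' exactly at `band_low` and `band_high`.
#'
#' @param order total band-pass order (even).
#' @param band_low,band_high band edges in Hz.
#' @param fs sampling rate (S/s).
#' @return An object of class `sos_filter`: list of 3x2 `cbind(b, a)`
#'   biquad coefficient matrices plus an overall gain.
#' @export
design_bandpass <- function(order = 20, band_low = 20, band_high = 500,
                            fs = 2000) {
  order <- check_count(order, "order", min = 2)
  if (order %% 2 != 0) abort("`order` must be even")
  if (!(band_low < band_high && band_high < fs / 2)) {
    abort("band edges must satisfy 0 < band_low < band_high < fs/2")
  }
  n <- order %/% 2L
  k <- seq_len(n)
  p_lp <- exp(1i * pi * (2 * k + n - 1) / (2 * n))   # prototype poles
  wl <- 2 * fs * tan(pi * band_low / fs)             # prewarped edges
  wu <- 2 * fs * tan(pi * band_high / fs)
  bw <- wu - wl
  w0 <- sqrt(wl * wu)
  b2 <- p_lp * bw / 2
  disc <- sqrt(b2^2 - w0^2)
  p_bp <- c(b2 + disc, b2 - disc)                    # 2n analog poles
  fs2 <- 2 * fs
  pz <- (fs2 + p_bp) / (fs2 - p_bp)                  # bilinear
  # n zeros at z = 1 (from s = 0) and n at z = -1 (from s = infinity)
  wc <- 2 * atan(w0 / fs2)                           # digital center freq
  zz <- c(rep(1 + 0i, n), rep(-1 + 0i, n))
  H0 <- prod(exp(1i * wc) - zz) / prod(exp(1i * wc) - pz)
  g <- 1 / Mod(H0)

  # group conjugate pole pairs into biquads, one zero at +1 and -1 each
  ord <- order(-Mod(pz), Re(pz), abs(Im(pz)))
  pp <- pz[ord]
  used <- rep(FALSE, length(pp))
  sections <- list()
  for (i in seq_along(pp)) {
    if (used[i]) next
    used[i] <- TRUE
    j <- which(!used & Mod(pp - Conj(pp[i])) < 1e-8)[1]
    if (is.na(j)) j <- which(!used & abs(Im(pp)) < 1e-8)[1]
    if (is.na(j)) abort("failed to pair poles into sections")
    used[j] <- TRUE
    a <- Re(poly_from_roots(c(pp[i], pp[j])))
    b <- Re(poly_from_roots(c(1, -1)))               # z^2 - 1
    sections[[length(sections) + 1]] <- cbind(b = b, a = a)
  }
  structure(list(sections = sections, gain = g, order = order,
                 band = c(band_low, band_high), fs = fs),
            class = "sos_filter")
}

# monic polynomial coefficients from roots (descending powers)
poly_from_roots <- function(r) {
  cf <- 1
  for (x in r) cf <- c(cf, 0) - c(0, cf * x)
  cf
}

#' @rdname design_bandpass
#' @param filt an `sos_filter`.
#' @param f frequencies (Hz) at which to evaluate the single-pass complex
#'   response.
#' @return `sos_response()` returns a complex vector of the same length as
#'   `f`.
#' @export
sos_response <- function(filt, f) {
  stopifnot(inherits(filt, "sos_filter"))
  w <- 2 * pi * f / filt$fs
  e <- exp(-1i * outer(w, 0:2))
  H <- rep(filt$gain + 0i, length(w))
  for (s in filt$sections) {
    H <- H * drop(e %*% s[, "b"]) / drop(e %*% s[, "a"])
  }
  H
}

# zero-phase application: odd-reflection padding, then the full biquad
# cascade forward and backward. The overall gain is distributed across
# sections to keep intermediate amplitudes bounded; padding of about three
# periods of the lower band edge absorbs the start-up transients of the
# near-unit-circle low-frequency poles.
sos_filtfilt <- function(filt, x) {
  stopifnot(inherits(filt, "sos_filter"))
  n <- length(x)
  pad <- min(n - 1L, ceiling(3 * filt$fs / filt$band[1]))
  xx <- c(2 * x[1] - x[(pad + 1L):2],
          x,
          2 * x[n] - x[(n - 1L):(n - pad)])
  K <- length(filt$sections)
  gk <- filt$gain^(1 / K)
  one_pass <- function(v) {
    for (s in filt$sections) {
      v <- as.numeric(signal::filter(signal::Arma(b = gk * s[, "b"],
                                                  a = s[, "a"]), v))
    }
    v
  }
  yy <- rev(one_pass(rev(one_pass(xx))))
  yy[pad + seq_len(n)]
}

#' Band-pass filter a recording
#'
#' Applies the configured Butterworth band-pass to every channel with
#' zero-phase (forward-backward) filtering through the second-order-section
#' cascade. Note the effective two-pass magnitude response is the square of
#' the designed single-pass response.
#'
#' @param recording an [emg_tbl].
#' @param cfg a [preprocess_config()].
#' @return The filtered [emg_tbl] (same shape, labels preserved).
#' @export
bandpass_filter <- function(recording, cfg = preprocess_config()) {
  stopifnot(inherits(cfg, "preprocess_config"))
  if (!isTRUE(all.equal(emg_fs(recording), cfg$fs))) {
    abort("recording sampling rate does not match `cfg$fs`")
  }
  filt <- design_bandpass(cfg$filter_order, cfg$band_low, cfg$band_high,
                          cfg$fs)
  sig <- emg_channels(recording)
  out <- apply(sig, 2, function(x) sos_filtfilt(filt, x))
  set_channels(recording, out)
}

#' Rectify and normalize a filtered recording
#'
#' Per-channel maximum-absolute normalization over the full record (the
#' offline method used when no maximum-voluntary-contraction calibration is
#' available), returning both the signed-normalized view and its rectified
#' (absolute-value) counterpart. An identically-zero channel is passed
#' through unscaled with a warning.
#'
#' @param recording a filtered [emg_tbl].
#' @return A list with elements `signed` and `rectified`, both [emg_tbl]s
#'   with per-channel `max(abs(.)) == 1` (nonzero channels).
#' @export
rectify_normalize <- function(recording) {
  sig <- emg_channels(recording)
  scale <- apply(abs(sig), 2, max)
  zero <- scale == 0
  if (any(zero)) {
    warn(sprintf("channel(s) %s are identically zero; left unscaled",
                 paste(which(zero), collapse = ", ")))
    scale[zero] <- 1
  }
  signed <- sweep(sig, 2, scale, "/")
  list(signed = set_channels(recording, signed),
       rectified = set_channels(recording, abs(signed)))
}

#' Segment a recording into sliding windows
#'
#' Windows of `window_ms` slide in steps of `increment_ms`; the count is
#' `floor((N - W) / S) + 1`. Each window is labelled by the majority
#' per-sample movement label, ties resolved toward the lower label id.
#'
#' @param recording an [emg_tbl].
#' @param cfg a [preprocess_config()].
#' @return A tibble of class `window_stream` with columns `window` (index),
#'   `start` (first sample, 1-based), `length` (samples), `label` and
#'   `repetition` (majority values); window geometry is carried in
#'   attributes `window_samples` / `increment_samples`.
#' @export
segment_windows <- function(recording, cfg = preprocess_config()) {
  stopifnot(inherits(cfg, "preprocess_config"))
  W <- round(cfg$window_ms * emg_fs(recording) / 1000)
  S <- round(cfg$increment_ms * emg_fs(recording) / 1000)
  n <- nrow(recording)
  if (n < W) abort("recording is shorter than one window")
  starts <- seq(1L, n - W + 1L, by = S)
  lab <- recording$label
  rep_id <- recording$repetition
  maj <- function(v) {
    u <- sort(unique(v))
    u[which.max(tabulate(match(v, u)))]   # ties resolve to the lowest id
  }
  out <- tibble(
    window = seq_along(starts),
    start = starts,
    length = W,
    label = vapply(starts, function(s) maj(lab[s:(s + W - 1L)]), integer(1)),
    repetition = vapply(starts, function(s) maj(rep_id[s:(s + W - 1L)]),
                        integer(1))
  )
  new_tibble(out, window_samples = W, increment_samples = S,
             fs = emg_fs(recording), class = "window_stream")
}
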