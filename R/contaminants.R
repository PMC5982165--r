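#' Simulate a motion-artifact contaminant
#'
#' Low-frequency stochastic electrode-motion drift: band-limited (< 10 Hz)
#' Gaussian drift with a slowly varying burst envelope, plus a small
#' broadband "micro-motion" component (4% of total power, 10-200 Hz)
#' representing the impulsive electrode-pop content that survives band-pass
#' filtering in real recordings. Scaled so total power is
#' `10^(rel_power_db/10)` relative to a unit-power reference.
#'
#' @param n number of samples.
#' @param fs sampling rate (S/s).
#' @param seed integer seed.
#' @param rel_power_db output power in dB relative to unit power; `-Inf`
#'   yields a zero vector.
#' @return Numeric contaminant vector of length `n`.
#' @export
simulate_motion_artifact <- function(n, fs, seed = 0, rel_power_db = 0) {
  n <- check_count(n, "n")
  if (identical(rel_power_db, -Inf)) return(numeric(n))
  with_seed(seed, {
    lp <- signal::butter(2, min(5 / (fs / 2), 0.99), type = "low")
    drift <- signal::filtfilt(lp, rnorm(n))
    env_lp <- signal::butter(2, min(0.5 / (fs / 2), 0.9), type = "low")
    e <- signal::filtfilt(env_lp, rnorm(n))
    env <- 1 + 0.8 * e / max(sd(e), 1e-12)
    drift <- drift * pmax(env, 0.1)
    drift <- drift / sqrt(sig_power(drift))
    bp <- signal::butter(2, pmin(c(10, 200) / (fs / 2), c(0.5, 0.99)),
                         type = "pass")
    pops <- signal::filtfilt(bp, rnorm(n))
    pops <- pops / sqrt(sig_power(pops))
    x <- sqrt(0.96) * drift + sqrt(0.04) * pops
    x <- x / sqrt(sig_power(x))
    x * sqrt(10^(rel_power_db / 10))
  })
}

#' Simulate electrode displacement as additive white Gaussian noise
#'
#' Adds white Gaussian noise scaled so the signal-to-noise ratio
#' `10*log10(P_clean / P_noise)` equals `snr_db` (default 15 dB).
#'
#' @param clean clean signal vector with nonzero power.
#' @param snr_db target SNR in dB.
#' @param seed integer seed.
#' @return The contaminated vector `clean + noise`.
#' @export
simulate_displacement_awgn <- function(clean, snr_db = 15, seed = 0) {
  p <- sig_power(clean)
  if (p == 0) abort("`clean` must have nonzero power")
  if (identical(snr_db, Inf)) return(clean)
  with_seed(seed, {
    w <- rnorm(length(clean))
    w <- w * sqrt(p / 10^(snr_db / 10) / sig_power(w))
    clean + w
  })
}

#' Simulate amplifier-saturation interference
#'
#' Sum of `n_components` sinusoids with uniformly random frequencies in
#' \[200, 240\] Hz and random phases, the additive narrowband signature of a
#' saturating amplifier stage.
#'
#' @param n number of samples.
#' @param fs sampling rate (S/s), must exceed 480.
#' @param seed integer seed.
#' @param n_components number of sinusoids.
#' @param component_amplitude amplitude of each sinusoid (recording units).
#' @return Numeric vector with attribute `frequencies` listing the drawn
#'   component frequencies (Hz).
#' @export
simulate_saturation <- function(n, fs, seed = 0, n_components = 6,
                                component_amplitude = 0.3) {
  n <- check_count(n, "n")
  if (fs <= 480) abort("`fs` must exceed 480 S/s")
  n_components <- check_count(n_components, "n_components", min = 0)
  if (n_components == 0) {
    return(structure(numeric(n), frequencies = numeric(0)))
  }
  t <- (seq_len(n) - 1) / fs
  with_seed(seed, {
    freqs <- runif(n_components, 200, 240)
    phases <- runif(n_components, 0, 2 * pi)
    x <- numeric(n)
    for (i in seq_len(n_components)) {
      x <- x + component_amplitude * sin(2 * pi * freqs[i] * t + phases[i])
    }
    structure(x, frequencies = freqs)
  })
}

#' Simulate power-line interference
#'
#' A fundamental sinusoid of amplitude `amplitude` at `f0` plus
#' `n_harmonics` harmonics at `k*f0` with amplitude `amplitude / k`
#' (fundamental-dominant harmonic decay).
#'
#' @param n number of samples.
#' @param fs sampling rate (S/s).
#' @param amplitude fundamental amplitude (V).
#' @param f0 fundamental frequency (Hz).
#' @param n_harmonics number of harmonics above the fundamental.
#' @return Numeric vector of length `n`.
#' @export
simulate_powerline <- function(n, fs, amplitude = 0.4, f0 = 60,
                               n_harmonics = 3) {
  n <- check_count(n, "n")
  n_harmonics <- check_count(n_harmonics, "n_harmonics", min = 0)
  if (f0 * (n_harmonics + 1) >= fs / 2) {
    abort("highest harmonic would alias: f0 * (n_harmonics + 1) >= fs / 2")
  }
  t <- (seq_len(n) - 1) / fs
  x <- amplitude * sin(2 * pi * f0 * t)
  for (k in seq_len(n_harmonics) + 1) {
    x <- x + (amplitude / k) * sin(2 * pi * k * f0 * t)
  }
  x
}

#' Simulate ECG interference
#'
#' A normalized synthetic P-QRS-T waveform (see [synth_ecg()]) scaled so its
#' maximum absolute amplitude equals `max_amplitude`, emulating cardiac
#' bleed-through into proximal electrodes.
#'
#' @param n number of samples.
#' @param fs sampling rate (S/s).
#' @param max_amplitude peak absolute amplitude after scaling.
#' @param seed integer seed.
#' @param bpm heart rate (beats/minute).
#' @return Numeric vector of length `n`.
#' @export
simulate_ecg_interference <- function(n, fs, max_amplitude = 0.2, seed = 0,
                                      bpm = 72) {
  n <- check_count(n, "n")
  if (max_amplitude == 0) return(numeric(n))
  ecg <- synth_ecg(fs, n / fs, bpm = bpm, seed = seed)
  ecg <- ecg[seq_len(n)]
  ecg / max(abs(ecg)) * max_amplitude
}

#' The sixteen channel-degradation case studies
#'
#' Cases 1-8 contaminate one of the eight uniformly spaced forearm
#' electrodes; 9/10 the flexor and extensor digitorum electrodes; 11/12 the
#' biceps and triceps electrodes; 13 = both digitorum electrodes, 14 = both
#' biceps/triceps electrodes, 15 = all four anatomically placed electrodes,
#' 16 = all eight uniformly spaced electrodes.
#'
#' @param case_id optional case id 1-16; if missing, the full map.
#' @return A named list of integer channel vectors, or one such vector.
#' @export
contamination_cases <- function(case_id = NULL) {
  cases <- c(lapply(1:12, identity),
             list(c(9L, 10L), c(11L, 12L), c(9L, 10L, 11L, 12L), 1:8))
  cases <- lapply(cases, as.integer)
  names(cases) <- paste0("case", 1:16)
  if (is.null(case_id)) return(cases)
  if (!is.numeric(case_id) || length(case_id) != 1 ||
      !case_id %in% 1:16) {
    abort("`case_id` must be an integer in 1..16")
  }
  cases[[case_id]]
}

#' Contaminant specification
#'
#' Bundles a contaminant kind with its parameters and seed, for use with
#' [apply_case()]. Unspecified parameters take the simulator defaults.
#'
#' @param kind one of `"motion_artifact"`, `"electrode_displacement"`,
#'   `"saturation"`, `"power_line"`, `"ecg"`.
#' @param seed integer seed (per-channel seeds are derived from it).
#' @param ... kind-specific parameter overrides (e.g. `snr_db`,
#'   `amplitude`, `max_amplitude`, `rel_power_db`).
#' @return A list of class `contaminant_spec`.
#' @export
contaminant_spec <- function(kind = c("motion_artifact",
                                      "electrode_displacement",
                                      "saturation", "power_line", "ecg"),
                             seed = 0, ...) {
  kind <- match.arg(kind)
  structure(list(kind = kind, seed = as.integer(seed), params = list(...)),
            class = "contaminant_spec")
}

#' Apply a contamination case to a recording
#'
#' Adds the specified contaminant over the entire record to exactly the
#' channels of the chosen case; all other channels are bit-identical to the
#' input. Contamination is applied to the raw signal, before filtering and
#' window segmentation. Per-channel contaminant draws use seeds derived from
#' `spec$seed` so the same spec is reproducible.
#'
#' @param recording a raw [emg_tbl].
#' @param case_id case id 1-16 (see [contamination_cases()]).
#' @param spec a [contaminant_spec()].
#' @return The contaminated [emg_tbl], with a `provenance` attribute listing
#'   `(case, kind, seed, channels)`.
#' @export
apply_case <- function(recording, case_id, spec) {
  stopifnot(inherits(spec, "contaminant_spec"))
  channels <- contamination_cases(case_id)
  sig <- emg_channels(recording)
  if (max(channels) > ncol(sig)) {
    abort("case refers to channels beyond the recording's channel count")
  }
  fs <- emg_fs(recording)
  n <- nrow(sig)
  p <- spec$params
  for (j in seq_along(channels)) {
    ch <- channels[j]
    seed_j <- spec$seed + 1000L * ch
    sig[, ch] <- switch(
      spec$kind,
      motion_artifact = sig[, ch] + do.call(simulate_motion_artifact,
        c(list(n = n, fs = fs, seed = seed_j), p)),
      electrode_displacement = do.call(simulate_displacement_awgn,
        c(list(clean = sig[, ch], seed = seed_j), p)),
      saturation = sig[, ch] + as.numeric(do.call(simulate_saturation,
        c(list(n = n, fs = fs, seed = seed_j), p))),
      power_line = sig[, ch] + do.call(simulate_powerline,
        c(list(n = n, fs = fs), p)),
      ecg = sig[, ch] + do.call(simulate_ecg_interference,
        c(list(n = n, fs = fs, seed = seed_j), p))
    )
  }
  out <- set_channels(recording, sig)
  attr(out, "provenance") <- list(case = case_id, kind = spec$kind,
                                  seed = spec$seed, channels = channels)
  out
}

#' Measure the signal-to-noise ratio of a contaminated signal
#'
#' `10*log10(P_clean / P_(contaminated - clean))` in dB.
#'
#' @param clean,contaminated equal-length numeric vectors.
#' @return SNR in dB.
#' @export
measure_snr <- function(clean, contaminated) {
  if (length(clean) != length(contaminated)) abort("length mismatch")
  pn <- sig_power(contaminated - clean)
  if (pn == 0) abort("zero noise power: signals are identical")
  10 * log10(sig_power(clean) / pn)
}
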