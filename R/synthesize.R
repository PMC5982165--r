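#' Acquisition protocol for synthetic sEMG recordings
#'
#' Describes a 12-electrode acquisition session in which each movement is
#' held for `movement_duration` seconds and followed by
#' `rest_duration` seconds of rest, repeated `n_repetitions` times per
#' movement. Defaults emulate the public NINAPro protocol: 17 movements,
#' 6 repetitions, 2 kS/s, 5 s movement / 3 s rest, 12 channels.
#'
#' @param seed integer seed controlling every random draw derived from the
#'   protocol.
#' @param n_movements,n_repetitions counts (>= 1).
#' @param fs sampling rate in samples per second.
#' @param movement_duration,rest_duration segment durations in seconds.
#' @param n_channels electrode count.
#' @return An object of class `emg_protocol`.
#' @export
#' @examples
#' p <- emg_protocol(seed = 0)
#' p$total_duration  # 17 * 6 * (5 + 3) = 816 s
emg_protocol <- function(seed = 0, n_movements = 17, n_repetitions = 6,
                         fs = 2000, movement_duration = 5, rest_duration = 3,
                         n_channels = 12) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed) || seed < 0) {
    abort("`seed` must be a nonnegative integer")
  }
  p <- list(
    seed = as.integer(seed),
    n_movements = check_count(n_movements, "n_movements"),
    n_repetitions = check_count(n_repetitions, "n_repetitions"),
    fs = check_positive(fs, "fs"),
    movement_duration = check_positive(movement_duration, "movement_duration"),
    rest_duration = check_positive(rest_duration, "rest_duration"),
    n_channels = check_count(n_channels, "n_channels", min = 2)
  )
  p$total_duration <- with(p, n_movements * n_repetitions *
                             (movement_duration + rest_duration))
  structure(p, class = "emg_protocol")
}

#' @export
print.emg_protocol <- function(x, ...) {
  cat(sprintf(
    "<emg_protocol> %d movements x %d repetitions, %g s move / %g s rest,\n  %d channels at %g S/s (total %g s), seed %d\n",
    x$n_movements, x$n_repetitions, x$movement_duration, x$rest_duration,
    x$n_channels, x$fs, x$total_duration, x$seed))
  invisible(x)
}

#' Latent-source channel mixing for the synthetic generator
#'
#' The generator drives all electrodes from a small set of shared latent
#' sources so that channels are mutually correlated -- the property the
#' multichannel cross-correlation virtual sensor relies on. `activation`
#' holds per-movement, per-channel envelope gains (each movement excites
#' every channel with a distinct random gain pattern, which is what makes
#' movements separable from amplitude features); `mixing` holds the
#' channels x sources weights, drawn positive so co-activated channels are
#' positively correlated with magnitude strictly inside (0, 1).
#'
#' The generator is organised around muscle synergies. Each channel belongs
#' mainly to one of `n_synergies` synergy groups (round-robin assignment,
#' with `crosstalk`-level loading on the others); each movement drives the
#' synergies with its own nonnegative intensity vector, skewed so that for
#' a given movement some synergies -- hence some channels -- are nearly
#' silent, as real muscle selectivity dictates. The activation-gain matrix
#' is the synergy product with multiplicative jitter. The carrier mixing
#' shares the same group structure (one latent source per synergy plus one
#' global source), so channels of a synergy are strongly correlated with
#' each other and mildly with the rest. This is what makes the
#' cross-correlation virtual sensor meaningful: the channels most
#' correlated with a degraded electrode are those sharing its synergy, and
#' their weighted sum tracks the degraded channel's movement-wise
#' activation, including its silent movements.
#'
#' @param protocol an [emg_protocol].
#' @param n_synergies number of synergy groups (and of group-specific
#'   latent sources; one extra global source is added).
#' @param crosstalk loading of a channel on synergies other than its own.
#' @param mean_gain mean activation gain after scaling.
#' @param jitter half-width of the multiplicative per-(movement, channel)
#'   gain jitter.
#' @return A list with elements `activation` (movements x channels),
#'   `mixing` (channels x sources) and `synergy` (channel group ids),
#'   class `emg_mixing`.
#' @export
channel_mixing <- function(protocol, n_synergies = 3, crosstalk = 0.1,
                           mean_gain = 0.7, jitter = 0.15) {
  stopifnot(inherits(protocol, "emg_protocol"))
  M <- protocol$n_channels
  K <- check_count(n_synergies, "n_synergies")
  with_seed(protocol$seed + 101L, {
    syn <- rep(seq_len(K), length.out = M)
    Vs <- matrix(crosstalk, M, K)
    Vs[cbind(seq_len(M), syn)] <- 1
    # skewed synergy intensities: some synergies nearly off per movement
    U <- matrix(runif(protocol$n_movements * K)^1.5 + 0.05,
                nrow = protocol$n_movements)
    activation <- (U %*% t(Vs)) *
      matrix(runif(protocol$n_movements * M, 1 - jitter, 1 + jitter),
             nrow = protocol$n_movements)
    activation <- activation / mean(activation) * mean_gain
    # latent carrier sources: one per synergy + one global
    mixing <- matrix(0.1 * abs(rnorm(M * (K + 1))), nrow = M)
    mixing[cbind(seq_len(M), syn)] <- 0.9
    mixing[, K + 1] <- 0.3
    mixing <- mixing / sqrt(rowSums(mixing^2))   # unit rows: unit-RMS mixtures
    structure(list(activation = activation, mixing = mixing, synergy = syn),
              class = "emg_mixing")
  })
}

# raised-cosine on/off envelope for one movement segment
movement_envelope <- function(n, fs, ramp_s = 0.25) {
  r <- min(round(ramp_s * fs), floor(n / 2))
  env <- rep(1, n)
  if (r > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(r) / r))
    env[seq_len(r)] <- ramp
    env[n - r + seq_len(r)] <- rev(ramp)
  }
  env
}

# band-limited (20-450 Hz), spectrally tilted unit-RMS noise carrier.
# The tilt (4th-order low-pass at 120 Hz) reproduces the steeply decaying
# spectrum typical of sEMG (median frequency near 100 Hz, negligible power
# above ~300 Hz), so broadband contaminants are spectrally distinguishable.
emg_carrier <- function(n, fs) {
  x <- rnorm(n)
  bp <- design_bandpass(order = 8, band_low = 20, band_high = 450, fs = fs)
  x <- sos_filtfilt(bp, x)
  lp <- signal::butter(4, 120 / (fs / 2), type = "low")
  x <- signal::filtfilt(lp, x)
  x / sd(x)
}

#' Generate a synthetic multichannel sEMG recording
#'
#' Builds the labelled protocol timeline (movement and rest segments), then
#' synthesizes each channel as an amplitude-modulated mixture of shared
#' band-limited (20-450 Hz) Gaussian carriers plus low-level independent
#' baseline noise. Movement onsets/offsets use a 250 ms raised-cosine ramp.
#' Baseline (rest) noise sits 20 dB below the mean movement RMS. The output
#' is bit-reproducible from `(protocol, mixing, seed)`.
#'
#' @param protocol an [emg_protocol].
#' @param mixing an `emg_mixing` from [channel_mixing()]; defaults to
#'   `channel_mixing(protocol)`.
#' @param seed integer seed for the carrier and noise draws.
#' @param amplitude overall movement-segment amplitude scale (RMS of a
#'   unit-gain channel), in the recording's arbitrary voltage units.
#' @param rep_jitter half-width of the multiplicative per-(movement,
#'   repetition, channel) gain variation, emulating the repetition-to-
#'   repetition amplitude variability of real contractions (effort,
#'   posture and fatigue drift between repetitions).
#' @return An [emg_tbl] with `protocol` and `mixing` attached as attributes.
#' @export
synth_recording <- function(protocol, mixing = NULL, seed = 1,
                            amplitude = 0.15, rep_jitter = 0.15) {
  stopifnot(inherits(protocol, "emg_protocol"))
  mixing <- mixing %||% channel_mixing(protocol)
  M <- protocol$n_channels
  if (nrow(mixing$activation) != protocol$n_movements ||
      ncol(mixing$activation) != M || nrow(mixing$mixing) != M) {
    abort("`mixing` dimensions are inconsistent with the protocol")
  }
  fs <- protocol$fs
  n_mov <- round(protocol$movement_duration * fs)
  n_rest <- round(protocol$rest_duration * fs)
  n_seg <- n_mov + n_rest
  n_total <- protocol$n_movements * protocol$n_repetitions * n_seg

  label <- integer(n_total)
  repetition <- integer(n_total)
  gain_t <- matrix(0, n_total, M)  # per-sample, per-channel envelope gain
  env <- movement_envelope(n_mov, fs)
  with_seed(seed + 7L, {
    rj <- array(runif(protocol$n_movements * protocol$n_repetitions * M,
                      1 - rep_jitter, 1 + rep_jitter),
                dim = c(protocol$n_movements, protocol$n_repetitions, M))
  })
  pos <- 0L
  for (m in seq_len(protocol$n_movements)) {
    for (r in seq_len(protocol$n_repetitions)) {
      idx <- pos + seq_len(n_mov)
      label[idx] <- m
      repetition[idx] <- r
      gain_t[idx, ] <- env %o% (mixing$activation[m, ] * rj[m, r, ])
      pos <- pos + n_seg
    }
  }

  with_seed(seed, {
    K <- ncol(mixing$mixing)
    sources <- vapply(seq_len(K), function(k) emg_carrier(n_total, fs),
                      numeric(n_total))
    common <- sources %*% t(mixing$mixing)          # unit-RMS correlated beds
    mov_rms <- amplitude * mean(mixing$activation)  # mean movement-channel RMS
    base_rms <- mov_rms / 10^(20 / 20)              # rest floor at -20 dB
    baseline <- vapply(seq_len(M), function(j) base_rms * emg_carrier(n_total, fs),
                       numeric(n_total))
    sig <- amplitude * gain_t * common + baseline
  })

  out <- emg_tbl(sig, fs = fs, label = label, repetition = repetition)
  attr(out, "protocol") <- protocol
  attr(out, "mixing") <- mixing
  out
}

#' Synthetic single-lead ECG template
#'
#' Periodic P-QRS-T waveform built as a sum of Gaussian bumps per beat, with
#' small seeded beat-to-beat period jitter, normalized to unit maximum
#' absolute amplitude. Used to synthesize cardiac interference.
#'
#' @param fs sampling rate (S/s).
#' @param duration length in seconds.
#' @param bpm heart rate in beats/minute, within \[30, 200\].
#' @param seed integer seed for the period jitter.
#' @return Numeric vector of `round(fs * duration)` samples with
#'   `max(abs(.)) == 1`.
#' @export
synth_ecg <- function(fs, duration, bpm = 60, seed = 0) {
  fs <- check_positive(fs, "fs")
  duration <- check_positive(duration, "duration")
  if (!is.numeric(bpm) || bpm < 30 || bpm > 200) {
    abort("`bpm` must lie in [30, 200]")
  }
  n <- round(fs * duration)
  t <- (seq_len(n) - 1) / fs
  period <- 60 / bpm
  # Gaussian bumps: (amplitude, center offset s, width s) per wave
  waves <- list(P = c(0.12, -0.22, 0.045),
                Q = c(-0.10, -0.040, 0.012),
                R = c(1.00, 0.000, 0.018),
                S = c(-0.18, 0.040, 0.014),
                T = c(0.30, 0.25, 0.080))
  x <- numeric(n)
  with_seed(seed, {
    beat_t <- 0.4
    while (beat_t < duration + period) {
      for (w in waves) {
        x <- x + w[1] * exp(-0.5 * ((t - beat_t - w[2]) / w[3])^2)
      }
      beat_t <- beat_t + period * (1 + 0.03 * rnorm(1))
    }
  })
  x / max(abs(x))
}
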