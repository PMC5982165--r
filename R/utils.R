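# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# mean power of a vector
sig_power <- function(x) mean(x^2)

# one-sided periodogram (frequency Hz, power); no taper, used for band-power
# fractions where only relative power matters.
periodogram <- function(x, fs) {
  n <- length(x)
  X <- stats::fft(x)
  half <- seq_len(floor(n / 2) + 1)
  p <- Mod(X[half])^2 / n
  tibble(freq = (half - 1) * fs / n, power = p)
}

# fraction of total power within [lo, hi] Hz
band_power_fraction <- function(x, fs, lo, hi) {
  pg <- periodogram(x, fs)
  tot <- sum(pg$power)
  if (tot == 0) return(0)
  sum(pg$power[pg$freq >= lo & pg$freq <= hi]) / tot
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < min ||
      x != floor(x)) {
    abort(sprintf("`%s` must be an integer >= %d", name, min))
  }
  as.integer(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a positive number", name))
  }
  as.numeric(x)
}
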