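MFL_SENTINEL <- -10

#' Time-domain features of one signal window
#'
#' The five window-level features used for movement classification:
#' \describe{
#'   \item{MAV}{mean absolute value, `mean(abs(x))`}
#'   \item{RMS}{root mean square, `sqrt(mean(x^2))`}
#'   \item{WL}{waveform length, `sum(abs(diff(x)))`}
#'   \item{MFL}{maximum fractal length, `log10(sqrt(sum(diff(x)^2)))`}
#'   \item{PWR}{mean power, `mean(x^2)` (identically `RMS^2`)}
#' }
#' A constant window has undefined MFL; it is returned as the sentinel
#' minimum `-10` with a warning.
#'
#' @param window numeric vector of at least 2 samples.
#' @param warn_constant warn when MFL is replaced by the sentinel.
#' @return Named numeric vector `c(MAV, RMS, WL, MFL, PWR)`.
#' @export
#' @examples
#' feature_vector(c(1, -1, 1, -1))  # MAV = RMS = PWR = 1, WL = 6
feature_vector <- function(window, warn_constant = TRUE) {
  if (length(window) < 2) abort("window must have at least 2 samples")
  d <- diff(window)
  mfl_arg <- sqrt(sum(d^2))
  if (mfl_arg == 0) {
    if (warn_constant) warn("constant window: MFL undefined, sentinel used")
    mfl <- MFL_SENTINEL
  } else {
    mfl <- log10(mfl_arg)
  }
  c(MAV = mean(abs(window)),
    RMS = sqrt(mean(window^2)),
    WL = sum(abs(d)),
    MFL = mfl,
    PWR = mean(window^2))
}

#' Assemble the per-window feature table of a recording
#'
#' One row per window position; columns `ch{c}_{feat}` hold the five
#' features of every channel, followed by the window's majority `label` and
#' `repetition`. Optional per-channel provenance flags record whether a
#' channel's samples are original or virtual-sensor output.
#'
#' @param stream a `window_stream` from [segment_windows()].
#' @param recording the matching [emg_tbl] (signed-normalized view; MAV and
#'   RMS are rectification-equivalent).
#' @param provenance optional character vector, one entry per channel
#'   (e.g. `"clean"`, `"contaminated"`, `"virtual"`).
#' @return A tibble with `5 * n_channels` feature columns plus `window`,
#'   `label`, `repetition`.
#' @export
build_feature_table <- function(stream, recording, provenance = NULL) {
  stopifnot(inherits(stream, "window_stream"))
  sig <- emg_channels(recording)
  W <- attr(stream, "window_samples")
  if (max(stream$start) + W - 1L > nrow(sig)) {
    abort("window stream extends beyond the recording")
  }
  M <- ncol(sig)
  feats <- lapply(seq_len(M), function(ch) {
    X <- t(vapply(stream$start, function(s) {
      feature_vector(sig[s:(s + W - 1L), ch], warn_constant = FALSE)
    }, numeric(5)))
    colnames(X) <- paste0("ch", ch, "_", c("MAV", "RMS", "WL", "MFL", "PWR"))
    X
  })
  out <- as_tibble(as.data.frame(do.call(cbind, feats)))
  out$window <- stream$window
  out$label <- stream$label
  out$repetition <- stream$repetition
  if (!is.null(provenance)) {
    stopifnot(length(provenance) == M)
    attr(out, "provenance") <- provenance
  }
  out
}
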