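#' Multichannel sEMG recordings as tibbles
#'
#' An `emg_tbl` is a tibble with one row per sample: numeric channel columns
#' `ch1..chM`, an integer `label` column (0 = rest, 1..K = movement id) and an
#' integer `repetition` column (0 during rest). The sampling rate in samples
#' per second is carried in the `fs` attribute.
#'
#' @param signal numeric matrix, samples x channels.
#' @param fs sampling rate in samples per second.
#' @param label integer vector of per-sample movement ids, same length as
#'   `nrow(signal)`.
#' @param repetition integer vector of per-sample repetition ids.
#'
#' @return A tibble of class `emg_tbl`.
#' @export
emg_tbl <- function(signal, fs, label = NULL, repetition = NULL) {
  signal <- as.matrix(signal)
  if (!is.numeric(signal) || !all(is.finite(signal))) {
    abort("`signal` must be a finite numeric matrix")
  }
  fs <- check_positive(fs, "fs")
  n <- nrow(signal)
  label <- if (is.null(label)) integer(n) else as.integer(label)
  repetition <- if (is.null(repetition)) integer(n) else as.integer(repetition)
  if (length(label) != n || length(repetition) != n) {
    abort("`label` and `repetition` must have one entry per sample")
  }
  colnames(signal) <- paste0("ch", seq_len(ncol(signal)))
  out <- as_tibble(as.data.frame(signal))
  out$label <- label
  out$repetition <- repetition
  new_tibble(out, fs = fs, class = "emg_tbl")
}

#' @export
print.emg_tbl <- function(x, ...) {
  cat(sprintf("# An sEMG recording: %d samples x %d channels at %g S/s (%.1f s)\n",
              nrow(x), n_channels(x), emg_fs(x), nrow(x) / emg_fs(x)))
  NextMethod()
}

#' Accessors for `emg_tbl` recordings
#'
#' `emg_channels()` returns the samples x channels signal matrix,
#' `emg_fs()` the sampling rate and `n_channels()` the channel count.
#'
#' @param x an [emg_tbl] (or any data frame with `ch*` columns).
#' @return A numeric matrix, a rate, or a count.
#' @export
emg_channels <- function(x) {
  cols <- grep("^ch[0-9]+$", names(x), value = TRUE)
  if (length(cols) == 0) abort("no channel columns `ch1..chM` found")
  cols <- cols[order(as.integer(sub("^ch", "", cols)))]
  as.matrix(x[cols])
}

#' @rdname emg_channels
#' @export
emg_fs <- function(x) {
  fs <- attr(x, "fs")
  if (is.null(fs)) abort("recording has no `fs` attribute")
  fs
}

#' @rdname emg_channels
#' @export
n_channels <- function(x) sum(grepl("^ch[0-9]+$", names(x)))

# replace the signal matrix, keeping labels and attributes
set_channels <- function(x, signal) {
  signal <- as.matrix(signal)
  stopifnot(nrow(signal) == nrow(x), ncol(signal) == n_channels(x))
  for (j in seq_len(ncol(signal))) x[[paste0("ch", j)]] <- signal[, j]
  x
}

#' Write and read sEMG recordings as delimited text
#'
#' Recordings are stored as delimited matrices with a header row: channel
#' columns `ch1..chM`, then `label` and `repetition`. The sampling rate is
#' written in a `# fs: <rate>` comment on the first line.
#'
#' @param x an [emg_tbl].
#' @param path file path.
#' @param format `"csv"` or `"tsv"`.
#' @return `write_emg()` returns `path` invisibly; `read_emg()` returns an
#'   [emg_tbl].
#' @export
write_emg <- function(x, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  delim <- if (format == "csv") "," else "\t"
  writeLines(sprintf("# fs: %.10g", emg_fs(x)), path)
  readr::write_delim(as.data.frame(x), path, delim = delim, append = TRUE,
                     col_names = TRUE)
  invisible(path)
}

#' @rdname write_emg
#' @param fs sampling rate override; defaults to the value stored in the
#'   file's `# fs:` comment (2000 S/s if absent).
#' @export
read_emg <- function(path, format = c("csv", "tsv"), fs = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  delim <- if (format == "csv") "," else "\t"
  first <- readLines(path, n = 1)
  if (is.null(fs)) {
    fs <- if (grepl("^# fs:", first)) as.numeric(sub("^# fs:\\s*", "", first)) else 2000
  }
  dat <- readr::read_delim(path, delim = delim, comment = "#",
                           show_col_types = FALSE, progress = FALSE)
  ch_cols <- grep("^ch[0-9]+$", names(dat), value = TRUE)
  if (length(ch_cols) == 0) abort("no channel columns `ch1..chM` in file")
  if (!"label" %in% names(dat)) abort("missing `label` column")
  if (!"repetition" %in% names(dat)) abort("missing `repetition` column")
  if (length(ch_cols) != 12) {
    warn(sprintf("recording has %d channels (12 expected); channel count inferred",
                 length(ch_cols)))
  }
  sig <- as.matrix(dat[ch_cols])
  if (!is.numeric(sig)) abort("non-numeric channel data")
  emg_tbl(sig, fs = fs, label = dat$label, repetition = dat$repetition)
}

#' Plot channel traces of a recording
#'
#' @param object an [emg_tbl].
#' @param channels channel ids to draw.
#' @param start_s,duration_s plotted time span in seconds.
#' @param ... unused.
#' @return A ggplot object with one facet per channel, movement segments
#'   shaded by label.
#' @exportS3Method ggplot2::autoplot
autoplot.emg_tbl <- function(object, channels = seq_len(min(4, n_channels(object))),
                             start_s = 0, duration_s = 10, ...) {
  fs <- emg_fs(object)
  i0 <- max(1L, round(start_s * fs) + 1L)
  i1 <- min(nrow(object), i0 + round(duration_s * fs) - 1L)
  sl <- object[i0:i1, ]
  df <- tidyr::pivot_longer(
    dplyr::mutate(as_tibble(sl), time = (i0:i1 - 1) / fs),
    cols = dplyr::all_of(paste0("ch", channels)),
    names_to = "channel", values_to = "amplitude")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~channel, ncol = 1, strip.position = "right") +
    ggplot2::labs(x = "time (s)", y = "amplitude",
                  title = sprintf("sEMG channels (labels %s)",
                                  paste(unique(sl$label), collapse = ", ")))
}
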