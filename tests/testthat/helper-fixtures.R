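# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

fix_get <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

tiny_protocol <- function() {
  emg_protocol(seed = 0, n_movements = 3, n_repetitions = 2,
               movement_duration = 2, rest_duration = 1)
}

tiny_recording <- function() {
  fix_get("rec", function() synth_recording(tiny_protocol(), seed = 7))
}

tiny_norm <- function() {
  fix_get("norm", function() {
    rectify_normalize(bandpass_filter(tiny_recording(),
                                      preprocess_config()))$signed
  })
}

tiny_stream <- function() {
  fix_get("stream", function() {
    segment_windows(tiny_norm(), preprocess_config())
  })
}

# list of per-window vectors for the given channels of a recording
window_list <- function(recording, channels, stream = tiny_stream()) {
  sig <- emg_channels(recording)
  W <- attr(stream, "window_samples")
  unlist(lapply(channels, function(ch) {
    lapply(stream$start, function(s) sig[s:(s + W - 1L), ch])
  }), recursive = FALSE)
}

# detector trained on the tiny fixture against all five contaminants
tiny_detector <- function() {
  fix_get("detector", function() {
    train_detector_from_recording(tiny_recording(), seed = 3,
                                  n_per_class = 400)
  })
}
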