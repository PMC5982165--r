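#' Build a detector training set from a recording
#'
#' Collects clean windows from the preprocessed recording and contaminated
#' windows from copies degraded by each requested contaminant (cases 15 and
#' 16 together cover all twelve channels), then trains the two-class
#' detector on them. Only windows from actually-degraded channels enter the
#' contaminated class.
#'
#' @param recording a raw [emg_tbl] (ideally a separate training session).
#' @param kinds contaminant kinds to train against.
#' @param cfg a [preprocess_config()].
#' @param seed integer seed for contaminant draws and window subsampling.
#' @param n_per_class maximum windows per class.
#' @param ... passed to [train_detector()].
#' @return An `sftd_model`.
#' @export
train_detector_from_recording <- function(recording,
                                          kinds = c("motion_artifact",
                                                    "electrode_displacement",
                                                    "saturation",
                                                    "power_line", "ecg"),
                                          cfg = preprocess_config(),
                                          seed = 0, n_per_class = 700, ...) {
  fs <- emg_fs(recording)
  norm <- rectify_normalize(bandpass_filter(recording, cfg))$signed
  stream <- segment_windows(norm, cfg)
  W <- attr(stream, "window_samples")
  pull_windows <- function(rec, channels) {
    sig <- emg_channels(rec)
    unlist(lapply(channels, function(ch) {
      lapply(stream$start, function(s) sig[s:(s + W - 1L), ch])
    }), recursive = FALSE)
  }
  M <- n_channels(recording)
  clean_w <- pull_windows(norm, seq_len(M))
  cont_w <- list()
  for (i in seq_along(kinds)) {
    for (case_id in c(15L, 16L)) {
      spec <- contaminant_spec(kinds[i], seed = seed + 7L * i + case_id)
      cr <- apply_case(recording, case_id, spec)
      crn <- rectify_normalize(bandpass_filter(cr, cfg))$signed
      cont_w <- c(cont_w, pull_windows(crn, contamination_cases(case_id)))
    }
  }
  with_seed(seed, {
    if (length(clean_w) > n_per_class) {
      clean_w <- clean_w[sample(length(clean_w), n_per_class)]
    }
    if (length(cont_w) > n_per_class) {
      cont_w <- cont_w[sample(length(cont_w), n_per_class)]
    }
  })
  train_detector(clean_w, cont_w, seed = seed, fs = fs, ...)
}

#' Evaluate fault-tolerant classification end to end
#'
#' For each (contaminant kind, channel case) combination: contaminates the
#' raw recording, preprocesses it, flags windows with the detector,
#' reconstructs activated channels with both virtual-sensor models, builds
#' the four feature bundles (clean / contaminated / TVARMA / Kalman) and
#' runs the requested classification settings over repetition folds.
#'
#' @param recording a raw [emg_tbl] from [synth_recording()] (or real
#'   data with the same layout).
#' @param detector a trained `sftd_model`.
#' @param kinds contaminant kinds to evaluate.
#' @param cases integer channel-case ids (1-16).
#' @param settings classification settings to run (subset of 1:7).
#' @param folds fold table from [enumerate_kfolds()]; defaults to all
#'   repetition partitions. Use a subset of rows for a cheaper evaluation.
#' @param cfg a [preprocess_config()].
#' @param contaminant_seed base seed for contaminant draws.
#' @param history_mode calibration history for the MCC matrix and
#'   virtual-sensor models: `"per_movement"` (default) concatenates the
#'   first repetition of every movement, so the input-to-channel map is fit
#'   across the full movement repertoire; `"first_seconds"` uses the first
#'   `history_seconds` of movement-labelled signal (the short-buffer online
#'   analogue).
#' @param history_seconds seconds of movement-labelled clean signal used
#'   when `history_mode = "first_seconds"`.
#' @param ... passed to [train_classifier()] (e.g. `cost_grid`,
#'   `gamma_grid`).
#' @return An `emg_eval` tibble with columns `setting`, `contaminant`,
#'   `case`, `fold`, `accuracy`, `confusion`.
#' @export
evaluate_fault_tolerance <- function(recording, detector,
                                     kinds = c("electrode_displacement",
                                               "saturation",
                                               "motion_artifact"),
                                     cases = c(2L, 13L),
                                     settings = 1:7,
                                     folds = NULL,
                                     cfg = preprocess_config(),
                                     contaminant_seed = 100,
                                     history_mode = c("per_movement",
                                                      "first_seconds"),
                                     history_seconds = 3, ...) {
  history_mode <- match.arg(history_mode)
  protocol <- attr(recording, "protocol")
  n_reps <- if (!is.null(protocol)) protocol$n_repetitions else
    max(recording$repetition)
  folds <- folds %||% enumerate_kfolds(n_reps, floor(n_reps / 2))
  fs <- emg_fs(recording)

  clean_norm <- rectify_normalize(bandpass_filter(recording, cfg))$signed
  stream <- segment_windows(clean_norm, cfg)
  clean_ft <- build_feature_table(stream, clean_norm)

  # clean movement-labelled history for MCC and model fitting
  hist_idx <- if (history_mode == "per_movement") {
    which(recording$label > 0 & recording$repetition == 1L)
  } else {
    mov_idx <- which(recording$label > 0)
    mov_idx[seq_len(min(length(mov_idx), round(history_seconds * fs)))]
  }
  history <- emg_channels(clean_norm)[hist_idx, , drop = FALSE]

  purrr::map_dfr(kinds, function(kind) {
    purrr::map_dfr(cases, function(case_id) {
      spec <- contaminant_spec(kind, seed = contaminant_seed + case_id)
      cont <- apply_case(recording, case_id, spec)
      cont_norm <- rectify_normalize(bandpass_filter(cont, cfg))$signed
      flags <- detect_recording(detector, cont_norm, stream)
      recon_a <- reconstruct_channel(cont_norm, flags, "tvarma", cfg,
                                     history = history)
      recon_k <- reconstruct_channel(cont_norm, flags, "tvk", cfg,
                                     history = history)
      removed <- which(attr(recon_a, "reconstruction")$removal_flag)
      bundles <- list(
        clean = clean_ft,
        contaminated = build_feature_table(stream, cont_norm),
        tvarma = build_feature_table(stream, recon_a),
        tvk = build_feature_table(stream, recon_k)
      )
      purrr::map_dfr(settings, function(s) {
        out <- run_setting(s, bundles, folds,
                           removed_channels = removed, ...)
        out$contaminant <- kind
        out$case <- case_id
        out
      })
    })
  }) |>
    (\(x) new_tibble(x, class = "emg_eval"))()
}
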