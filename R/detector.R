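#' Detector feature vector for one signal window
#'
#' Nine features feed the two-class contamination detector: the five
#' time-domain classification features (MAV, RMS, WL, MFL, PWR) plus four
#' spectral descriptors -- spectral centroid, fraction of power below 20 Hz,
#' fraction of power in 55-65 Hz, and fraction of power above 350 Hz -- that
#' expose low-frequency drift, mains interference, and the broadband noise
#' floor (surface EMG carries almost no power above ~300 Hz, so the
#' high-band fraction is a sensitive white-noise indicator). Spectral terms
#' of an all-zero window are defined as 0.
#'
#' @param window numeric signal segment (one channel).
#' @param fs sampling rate (S/s).
#' @return Named numeric vector of length 9.
#' @export
extract_detector_features <- function(window, fs = 2000) {
  if (length(window) == 0) abort("empty window")
  fv <- feature_vector(window, warn_constant = FALSE)
  zero_sp <- c(centroid = 0, frac_lf = 0, frac_mains = 0, frac_hf = 0)
  if (all(window == 0)) {
    sp <- zero_sp
  } else {
    pg <- periodogram(window - mean(window), fs)
    tot <- sum(pg$power)
    if (tot == 0) {
      sp <- zero_sp
    } else {
      sp <- c(centroid = sum(pg$freq * pg$power) / tot,
              frac_lf = sum(pg$power[pg$freq < 20]) / tot,
              frac_mains = sum(pg$power[pg$freq >= 55 & pg$freq <= 65]) / tot,
              frac_hf = sum(pg$power[pg$freq >= 350]) / tot)
    }
  }
  c(fv, sp)
}

# feature matrix for a list/matrix of windows (rows = windows)
detector_feature_matrix <- function(windows, fs) {
  t(vapply(windows, extract_detector_features, numeric(9), fs = fs))
}

#' Train the two-class contamination detector
#'
#' Fits a radial-basis-function support-vector machine on detector features
#' of clean versus contaminated windows. Features are z-scored with scaling
#' parameters frozen at training time; `(cost, gamma)` are chosen by k-fold
#' cross-validated grid search, and a held-out fraction of the data reports
#' an unbiased accuracy estimate.
#'
#' @param clean_windows,contaminated_windows lists of numeric window
#'   vectors (or matrices with one window per row).
#' @param seed integer seed for fold assignment and the held-out split.
#' @param fs sampling rate (S/s).
#' @param cost_grid,gamma_grid hyperparameter candidates.
#' @param holdout fraction of windows reserved for the held-out accuracy
#'   report.
#' @return An object of class `sftd_model` with elements `svm`, `center`,
#'   `scale`, `holdout_accuracy`, `best` and `fs`.
#' @export
train_detector <- function(clean_windows, contaminated_windows, seed = 0,
                           fs = 2000, cost_grid = c(1, 10, 100),
                           gamma_grid = c(0.05, 0.125, 0.5),
                           holdout = 0.25) {
  as_list <- function(w) {
    if (is.matrix(w)) lapply(seq_len(nrow(w)), function(i) w[i, ]) else w
  }
  clean_windows <- as_list(clean_windows)
  contaminated_windows <- as_list(contaminated_windows)
  if (length(clean_windows) == 0 || length(contaminated_windows) == 0) {
    abort("both classes must be non-empty")
  }
  X <- rbind(detector_feature_matrix(clean_windows, fs),
             detector_feature_matrix(contaminated_windows, fs))
  y <- factor(rep(c("clean", "contaminated"),
                  c(length(clean_windows), length(contaminated_windows))),
              levels = c("clean", "contaminated"))
  with_seed(seed, {
    n <- nrow(X)
    hold <- sample(n, max(2, round(holdout * n)))
    # ensure both classes in the training part
    if (length(unique(y[-hold])) < 2) hold <- seq_len(min(2, n - 2))
    Xtr <- X[-hold, , drop = FALSE]; ytr <- y[-hold]
    ctr <- colMeans(Xtr)
    scl <- apply(Xtr, 2, sd)
    scl[scl == 0] <- 1
    Ztr <- scale(Xtr, ctr, scl)
    folds <- sample(rep(1:3, length.out = nrow(Ztr)))
    grid <- expand.grid(cost = cost_grid, gamma = gamma_grid)
    cv_acc <- vapply(seq_len(nrow(grid)), function(g) {
      mean(vapply(1:3, function(k) {
        tr <- folds != k
        if (length(unique(ytr[tr])) < 2) return(NA_real_)
        fit <- e1071::svm(Ztr[tr, , drop = FALSE], ytr[tr],
                          kernel = "radial", cost = grid$cost[g],
                          gamma = grid$gamma[g], scale = FALSE)
        mean(predict(fit, Ztr[!tr, , drop = FALSE]) == ytr[!tr])
      }, numeric(1)), na.rm = TRUE)
    }, numeric(1))
    best <- grid[which.max(cv_acc), ]
    fit <- e1071::svm(Ztr, ytr, kernel = "radial", cost = best$cost,
                      gamma = best$gamma, scale = FALSE)
    Zh <- scale(X[hold, , drop = FALSE], ctr, scl)
    holdout_acc <- mean(predict(fit, Zh) == y[hold])
    structure(list(svm = fit, center = ctr, scale = scl,
                   holdout_accuracy = holdout_acc,
                   best = as.list(best), fs = fs,
                   n_train = nrow(Ztr), seed = seed),
              class = "sftd_model")
  })
}

#' @export
print.sftd_model <- function(x, ...) {
  cat(sprintf(
    "<sftd_model> RBF-SVM contamination detector (cost %g, gamma %g)\n  trained on %d windows; held-out accuracy %.1f%%\n",
    x$best$cost, x$best$gamma, x$n_train, 100 * x$holdout_accuracy))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.sftd_model <- function(x, ...) {
  tibble(n_train = x$n_train, cost = x$best$cost, gamma = x$best$gamma,
         holdout_accuracy = x$holdout_accuracy)
}

#' Classify windows as clean or contaminated
#'
#' `detect_window()` flags a single window; `detect_recording()` scans every
#' (channel, window) position of a segmented recording and returns a tidy
#' flag table.
#'
#' @param model an `sftd_model`.
#' @param window one numeric window.
#' @return `detect_window()`: `"clean"` or `"contaminated"`.
#' @export
detect_window <- function(model, window) {
  stopifnot(inherits(model, "sftd_model"))
  z <- scale(matrix(extract_detector_features(window, model$fs), 1),
             model$center, model$scale)
  as.character(predict(model$svm, z))
}

#' @rdname detect_window
#' @param recording a preprocessed [emg_tbl] (signed-normalized view).
#' @param stream a `window_stream` from [segment_windows()].
#' @return `detect_recording()`: a tibble with columns `channel`, `window`,
#'   `start`, and logical `contaminated`.
#' @export
detect_recording <- function(model, recording, stream) {
  stopifnot(inherits(model, "sftd_model"), inherits(stream, "window_stream"))
  sig <- emg_channels(recording)
  W <- attr(stream, "window_samples")
  out <- purrr::map_dfr(seq_len(ncol(sig)), function(ch) {
    Z <- t(vapply(stream$start, function(s) {
      extract_detector_features(sig[s:(s + W - 1L), ch], model$fs)
    }, numeric(9)))
    Z <- scale(Z, model$center, model$scale)
    tibble(channel = ch, window = stream$window, start = stream$start,
           contaminated = predict(model$svm, Z) == "contaminated")
  })
  out
}

#' Temporal activation logic for the virtual sensor
#'
#' Per channel, a ring buffer holds the contamination flags of the sliding
#' windows covering the trailing 3 s (37 windows at the default 300 ms / 75
#' ms geometry). The virtual sensor activates when more than
#' `activate_frac` (70%) of the trailing buffer is flagged; the channel is
#' marked for removal (classifier retraining without it) when at least
#' `remove_frac` (80%) of all windows seen so far are flagged. Unfilled
#' buffer positions count as clean, so activation needs a genuinely
#' sustained contamination: a contiguous burst must last longer than
#' 0.7 x 3 s (about 2.1 s) before the sensor engages. Once engaged, the
#' sensor stays on until the flagged fraction falls below
#' `deactivate_frac` (hysteresis), so a detector that flags a degraded
#' channel imperfectly does not toggle the replacement on and off.
#'
#' @param n_channels channel count.
#' @param horizon_windows buffer length in windows (default 37 = number of
#'   300 ms windows starting within a 3 s horizon at 75 ms increments).
#' @param activate_frac,remove_frac,deactivate_frac thresholds.
#' @return An `activation_state` object.
#' @export
new_activation_state <- function(n_channels, horizon_windows = 37,
                                 activate_frac = 0.70, remove_frac = 0.80,
                                 deactivate_frac = 0.35) {
  structure(list(
    buffer = matrix(FALSE, horizon_windows, n_channels),
    filled = 0L,
    total = integer(n_channels) + 0L,
    total_flagged = integer(n_channels) + 0L,
    horizon = as.integer(horizon_windows),
    activate_frac = activate_frac,
    remove_frac = remove_frac,
    deactivate_frac = deactivate_frac,
    virtual_sensor_active = logical(n_channels),
    removal_flag = logical(n_channels)
  ), class = "activation_state")
}

#' @rdname new_activation_state
#' @param state an `activation_state`.
#' @param flags logical vector (one new window flag per channel).
#' @return The updated `activation_state`.
#' @export
update_activation <- function(state, flags) {
  stopifnot(inherits(state, "activation_state"),
            length(flags) == ncol(state$buffer))
  state$buffer <- rbind(state$buffer[-1, , drop = FALSE], as.logical(flags))
  state$filled <- min(state$filled + 1L, state$horizon)
  state$total <- state$total + 1L
  state$total_flagged <- state$total_flagged + as.integer(flags)
  frac <- colSums(state$buffer) / state$horizon
  state$virtual_sensor_active <- frac > state$activate_frac |
    (state$virtual_sensor_active & frac > state$deactivate_frac)
  state$removal_flag <- state$total_flagged / state$total >= state$remove_frac
  state
}

# Run the activation logic over a full per-channel flag table
# (from detect_recording); returns per-window activation and final removal.
activation_trace <- function(flag_table, n_channels,
                             horizon_windows = 37,
                             activate_frac = 0.70, remove_frac = 0.80,
                             deactivate_frac = 0.35) {
  wide <- tidyr::pivot_wider(flag_table[c("channel", "window", "contaminated")],
                             names_from = "channel",
                             values_from = "contaminated")
  wide <- wide[order(wide$window), ]
  fm <- as.matrix(wide[, -1, drop = FALSE])
  state <- new_activation_state(n_channels, horizon_windows,
                                activate_frac, remove_frac,
                                deactivate_frac)
  act <- matrix(FALSE, nrow(fm), n_channels)
  for (i in seq_len(nrow(fm))) {
    state <- update_activation(state, fm[i, ])
    act[i, ] <- state$virtual_sensor_active
  }
  list(active = act, state = state, windows = wide$window)
}
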