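#' Replace degraded channel windows with virtual-sensor output
#'
#' Runs the temporal activation logic over the per-window contamination
#' flags; for every channel whose virtual sensor activates (more than 70%
#' of the trailing 3 s of windows flagged), all samples covered by flagged
#' windows from activation onward are replaced by the selected model's
#' output. The MCC matrix is fitted on a clean multichannel history segment
#' with the degraded channels excluded, and the model (TVARMA or Kalman) is
#' fitted on the target's clean history against the MCC input.
#'
#' Online, the clean history is the buffered signal preceding degradation;
#' offline callers pass it explicitly via `history` (a clean recording
#' span). If `history` is `NULL`, the span of windows before the first
#' flagged window is used, when long enough.
#'
#' @param recording preprocessed [emg_tbl] (signed-normalized view) whose
#'   flagged channels are to be repaired.
#' @param flag_table per-(channel, window) flags from [detect_recording()].
#' @param method `"tvarma"` or `"tvk"`.
#' @param cfg the [preprocess_config()] that produced the window stream.
#' @param history optional clean multichannel segment (matrix or
#'   [emg_tbl]) used to fit the MCC matrix and the models.
#' @param basis a [basis_config()] for the TVARMA coefficients.
#' @param P,Q TVARMA orders.
#' @param r_inflate factor by which the Kalman measurement covariance `R`
#'   is inflated while the measurement is contaminated.
#' @param horizon_windows,activate_frac,remove_frac activation parameters
#'   (see [new_activation_state()]).
#' @return The repaired [emg_tbl]; attribute `reconstruction` records, per
#'   channel, the replaced sample count, the method and the removal flag.
#' @export
reconstruct_channel <- function(recording, flag_table,
                                method = c("tvarma", "tvk"),
                                cfg = preprocess_config(),
                                history = NULL,
                                basis = basis_config(),
                                P = 4, Q = 2, r_inflate = 10,
                                horizon_windows = 37,
                                activate_frac = 0.70, remove_frac = 0.80) {
  method <- match.arg(method)
  sig <- emg_channels(recording)
  M <- ncol(sig)
  fs <- emg_fs(recording)
  W <- round(cfg$window_ms * fs / 1000)
  S <- round(cfg$increment_ms * fs / 1000)

  tr <- activation_trace(flag_table, M, horizon_windows,
                         activate_frac, remove_frac)
  degraded <- which(colSums(tr$active) > 0)
  prov <- list(method = method, removal_flag = tr$state$removal_flag,
               replaced = integer(M))
  if (length(degraded) == 0) {
    attr(recording, "reconstruction") <- prov
    return(recording)
  }
  if (length(degraded) >= M) {
    abort("all channels degraded simultaneously: no clean sources remain")
  }

  # clean multichannel history for MCC + model fitting
  hist_sig <- if (is.null(history)) {
    first_flag <- min(which(rowSums(tr$active) > 0))
    first_start <- (tr$windows[first_flag] - 1L) * S + 1L
    if (first_start - 1L < 4L * W) {
      abort("no clean history available before degradation; pass `history`")
    }
    sig[seq_len(first_start - 1L), , drop = FALSE]
  } else if (is.data.frame(history)) {
    emg_channels(history)
  } else {
    as.matrix(history)
  }
  if (ncol(hist_sig) != M) abort("`history` channel count mismatch")

  mcc <- mcc_matrix(hist_sig, excluded = degraded)
  out <- sig
  for (ch in degraded) {
    u_hist <- mcc_input(mcc, hist_sig, ch)
    y_hist <- hist_sig[, ch]
    # per-sample replacement mask: samples covered by activation-flagged windows
    mask <- logical(nrow(sig))
    act_w <- tr$windows[tr$active[, ch]]
    for (w in act_w) {
      s0 <- (w - 1L) * S + 1L
      mask[s0:min(s0 + W - 1L, nrow(sig))] <- TRUE
    }
    if (!any(mask)) next
    u_all <- mcc_input(mcc, sig, ch)
    spans <- span_runs(mask)
    if (method == "tvarma") {
      model <- fit_tvarma(y_hist, u_hist, basis, P = P, Q = Q,
                          estimation = "two_stage")
      for (sp in spans) {
        seed_idx <- (sp[1] - P):(sp[1] - 1)     # time order, newest last
        y_seed <- vapply(seed_idx, function(i) {
          if (i >= 1) out[i, ch]                 # prior samples (or repairs)
          else if (length(y_hist) + i >= 1) y_hist[length(y_hist) + i]
          else 0
        }, numeric(1))
        out[sp[1]:sp[2], ch] <- predict_tvarma(model, u_all[sp[1]:sp[2]],
                                               y_seed = y_seed)
      }
    } else {
      model <- fit_tvk(y_hist, u_hist)
      g <- kalman_gain(model$A, model$C, model$G, model$Qw,
                       model$R * r_inflate)
      for (sp in spans) {
        # the identity-A state has unit DC gain from the input only when
        # the MCC input is fed in incremental form
        u_sp <- u_all[sp[1]:sp[2]]
        du <- c(0, diff(u_sp))
        out[sp[1]:sp[2], ch] <- tvk_estimate(model, du,
                                             sig[sp[1]:sp[2], ch],
                                             x0 = u_sp[1],
                                             gain = g$Mgain)
      }
    }
    prov$replaced[ch] <- sum(mask)
  }
  res <- set_channels(recording, out)
  attr(res, "reconstruction") <- prov
  res
}

# contiguous TRUE runs of a logical mask as list of c(start, end)
span_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  purrr::map2(starts[r$values], ends[r$values], c)
}
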