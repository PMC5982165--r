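#' Normalized cross-correlation between two channels
#'
#' Absolute Pearson correlation at zero lag, so that channel contributions
#' are nonnegative weights regardless of polarity. A constant input has no
#' defined correlation and contributes 0 (logged).
#'
#' @param x,y equal-length numeric vectors (>= 2 samples).
#' @return A scalar in \[0, 1\].
#' @export
cross_corr_coeff <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    abort("`x` and `y` must be equal-length vectors of >= 2 samples")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    inform("constant channel segment: correlation defined as 0")
    return(0)
  }
  abs(cor(x, y))
}

#' Multichannel cross-correlation (MCC) percentage-contribution matrix
#'
#' Entry `p[x, t]` is the percentage contribution of source channel `x` to
#' target channel `t`: the normalized cross-correlation `c[x, t]` divided by
#' the sum of correlations between `t` and all available source channels.
#' The diagonal is 0 and the rows of excluded (contaminated) channels are
#' zeroed before normalization, so for every target with at least one
#' available source the contributions over available sources sum to 1 and
#' the weighted source sum of Eq-style reconstruction is a convex
#' combination.
#'
#' @param signals numeric matrix (samples x channels), a recent clean
#'   segment.
#' @param excluded integer ids of channels zeroed as contaminated.
#' @return An object of class `mcc_matrix`: list with `p` (M x M), `c`
#'   (raw absolute correlations), `excluded`, `M`.
#' @export
mcc_matrix <- function(signals, excluded = integer(0)) {
  signals <- as.matrix(signals)
  M <- ncol(signals)
  excluded <- as.integer(excluded)
  available <- setdiff(seq_len(M), excluded)
  if (length(available) < 2) {
    abort("fewer than 2 available channels: cannot form the MCC matrix")
  }
  sds <- apply(signals, 2, sd)
  if (any(sds == 0)) {
    inform(sprintf("constant channel(s) %s: correlations defined as 0",
                   paste(which(sds == 0), collapse = ", ")))
  }
  ok <- sds > 0
  cmat <- matrix(0, M, M)
  if (sum(ok) >= 2) {
    cmat[ok, ok] <- abs(suppressWarnings(cor(signals[, ok, drop = FALSE])))
  }
  diag(cmat) <- 0
  cmat[excluded, ] <- 0              # excluded channels cannot be sources
  p <- cmat
  for (t in seq_len(M)) {
    s <- sum(cmat[, t])
    if (s > 0) p[, t] <- cmat[, t] / s
  }
  structure(list(p = p, c = cmat, excluded = excluded, M = M),
            class = "mcc_matrix")
}

#' @export
print.mcc_matrix <- function(x, ...) {
  cat(sprintf("<mcc_matrix> %d x %d percentage contributions", x$M, x$M))
  if (length(x$excluded)) {
    cat(sprintf(" (excluded: %s)", paste(x$excluded, collapse = ", ")))
  }
  cat("\n")
  print(round(x$p, 3))
  invisible(x)
}

#' Exogenous virtual-sensor input from the MCC matrix
#'
#' The model input for a target channel is the sample-wise weighted sum of
#' the available source channels, weighted by the target's column of the
#' MCC matrix: `u(n) = sum_x p[x, target] * y_x(n)`.
#'
#' @param mcc an [mcc_matrix()].
#' @param signals numeric matrix (samples x channels) providing the source
#'   samples.
#' @param target target channel id.
#' @return Numeric vector of `nrow(signals)` samples.
#' @export
mcc_input <- function(mcc, signals, target) {
  stopifnot(inherits(mcc, "mcc_matrix"))
  signals <- as.matrix(signals)
  if (ncol(signals) != mcc$M) abort("channel count mismatch with MCC matrix")
  w <- mcc$p[, target]
  if (sum(w) == 0) abort("target has no available source channels")
  drop(signals %*% w)
}

#' Heatmap of an MCC matrix
#'
#' @param object an `mcc_matrix`.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mcc_matrix <- function(object, ...) {
  df <- tidyr::expand_grid(source = seq_len(object$M),
                           target = seq_len(object$M))
  df$contribution <- object$p[cbind(df$source, df$target)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$target, y = .data$source,
                                   fill = .data$contribution)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse(breaks = seq_len(object$M)) +
    ggplot2::scale_x_continuous(breaks = seq_len(object$M)) +
    ggplot2::scale_fill_viridis_c(limits = c(0, max(object$p))) +
    ggplot2::labs(x = "target channel", y = "source channel",
                  fill = "p[x,t]",
                  title = "Multichannel cross-correlation contributions")
}
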