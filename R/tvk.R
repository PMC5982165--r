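#' Steady-state Kalman innovation gain via the algebraic Riccati equation
#'
#' Iterates the discrete Riccati recursion
#' `P <- A P A' - A P C' (C P C' + R)^-1 C P A' + G Qw G'`
#' to its fixed point `Pss` (residual below `tol`), then forms the
#' innovation gain `Mgain = Pss C' (C Pss C' + R)^-1`.
#'
#' @param A,C,G state, output and noise-input matrices (scalars accepted).
#' @param Qw process-noise covariance.
#' @param R measurement-noise covariance (positive definite).
#' @param tol convergence tolerance on the max-abs residual.
#' @param max_iter iteration cap.
#' @return A list with `Pss` and `Mgain` (matrices).
#' @export
kalman_gain <- function(A, C, G, Qw, R, tol = 1e-10, max_iter = 100000) {
  A <- as.matrix(A); C <- as.matrix(C); G <- as.matrix(G)
  Qw <- as.matrix(Qw); R <- as.matrix(R)
  if (any(eigen(R, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    abort("`R` must be positive definite")
  }
  nx <- nrow(A)
  P <- diag(1, nx)
  Qbar <- G %*% Qw %*% t(G)
  for (i in seq_len(max_iter)) {
    S <- C %*% P %*% t(C) + R
    K <- A %*% P %*% t(C) %*% solve(S)
    Pn <- A %*% P %*% t(A) - K %*% C %*% P %*% t(A) + Qbar
    Pn <- (Pn + t(Pn)) / 2
    if (max(abs(Pn - P)) < tol) {
      P <- Pn
      Mgain <- P %*% t(C) %*% solve(C %*% P %*% t(C) + R)
      return(list(Pss = P, Mgain = Mgain))
    }
    P <- Pn
  }
  abort("Riccati iteration did not converge within `max_iter`")
}

#' Fit a Kalman virtual-sensor model
#'
#' State-space virtual sensor with identity state matrices: the state tracks
#' the channel, driven by the MCC input `u(n)` as a control, with process
#' noise `w(n)` and measurement noise `v(n)`. The measurement-noise
#' covariance `R` defaults to the residual variance of the MCC input as a
#' one-step predictor of the clean history, and `Qw` to `qw_ratio * R`.
#' The steady-state innovation gain is solved from the algebraic Riccati
#' equation.
#'
#' @param y_history clean target-channel segment.
#' @param u_history matching MCC-input segment.
#' @param A,B,C,G state matrices (identity by default).
#' @param R,Qw optional covariance overrides.
#' @param qw_ratio ratio `Qw / R` when `Qw` is not given.
#' @return An object of class `tvk_model` with the state matrices,
#'   covariances, `Pss` and `Mgain`.
#' @export
fit_tvk <- function(y_history, u_history, A = 1, B = 1, C = 1, G = 1,
                    R = NULL, Qw = NULL, qw_ratio = 0.1) {
  if (length(y_history) != length(u_history)) abort("history lengths differ")
  if (is.null(R)) {
    R <- var(y_history - u_history)
    if (!is.finite(R) || R <= 0) R <- max(var(y_history), 1e-8)
  }
  if (is.null(Qw)) Qw <- qw_ratio * R
  g <- kalman_gain(A, C, G, Qw, R)
  structure(list(A = as.matrix(A), B = as.matrix(B), C = as.matrix(C),
                 G = as.matrix(G), Qw = as.matrix(Qw), R = as.matrix(R),
                 Pss = g$Pss, Mgain = g$Mgain),
            class = "tvk_model")
}

#' @export
print.tvk_model <- function(x, ...) {
  cat(sprintf(
    "<tvk_model> R = %.3g, Qw = %.3g, steady-state gain %.3g\n",
    x$R[1, 1], x$Qw[1, 1], x$Mgain[1, 1]))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.tvk_model <- function(x, ...) {
  tibble(R = x$R[1, 1], Qw = x$Qw[1, 1], Pss = x$Pss[1, 1],
         Mgain = x$Mgain[1, 1])
}

#' Filtered channel estimate from the Kalman virtual sensor
#'
#' Runs the innovation-gain predictor recursion
#' `xpred[n+1] = A xpred[n] + B u(n) + Mgain (y(n) - C xpred[n])` and emits
#' the filtered output `yhat[n|n] = C (I - Mgain C) xpred[n] + C Mgain y(n)`.
#' During contamination the measurement is still fed, but callers may solve
#' the gain with an inflated `R` (see [reconstruct_channel()]) so the
#' estimate leans on the MCC input.
#'
#' @param model a `tvk_model`.
#' @param u MCC-input vector.
#' @param y_meas measured (possibly contaminated) channel samples, aligned
#'   with `u`.
#' @param x0 initial state estimate.
#' @param gain optional gain override (e.g. from an inflated `R`).
#' @return Numeric vector of filtered estimates `yhat[n|n]`.
#' @export
tvk_estimate <- function(model, u, y_meas, x0 = 0, gain = NULL) {
  stopifnot(inherits(model, "tvk_model"))
  if (length(u) != length(y_meas)) abort("`u` and `y_meas` length mismatch")
  Mg <- gain %||% model$Mgain
  A <- model$A; B <- model$B; C <- model$C
  nx <- nrow(A)
  I <- diag(1, nx)
  xpred <- matrix(rep(x0, length.out = nx), nx, 1)
  yhat <- numeric(length(u))
  IMC <- I - Mg %*% C
  for (n in seq_along(u)) {
    yhat[n] <- drop(C %*% IMC %*% xpred + C %*% Mg * y_meas[n])
    xpred <- A %*% xpred + B * u[n] + Mg %*% (y_meas[n] - C %*% xpred)
  }
  yhat
}
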