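#' Basis configuration for time-varying coefficients
#'
#' Time-varying AR and MA coefficients are expanded on a finite basis
#' `f(n, m)`, `m = 0..V`, evaluated over a segment of `N` samples. The
#' constant term `f(n, 0) = 1` always holds. Families:
#' \describe{
#'   \item{legendre}{Legendre polynomials on time normalized to \[-1, 1\]
#'     (the default; orthogonal, mild and smooth variation).}
#'   \item{fourier}{Cosine basis `cos(m * pi * t01)` with `t01` in
#'     \[0, 1\].}
#'   \item{time_power}{Raw powers of time normalized to \[-1, 1\].}
#' }
#'
#' @param family basis family.
#' @param V maximum basis index (>= 0).
#' @param N segment length in samples (>= 2).
#' @return A list of class `basis_config`.
#' @export
basis_config <- function(family = c("legendre", "fourier", "time_power"),
                         V = 2, N = 600) {
  family <- match.arg(family)
  V <- check_count(V, "V", min = 0)
  N <- check_count(N, "N", min = 2)
  structure(list(family = family, V = V, N = N), class = "basis_config")
}

#' @rdname basis_config
#' @param n sample index (0-based, `0 <= n < N`); vectorized.
#' @param m basis index (`0 <= m <= V`).
#' @param cfg a `basis_config`.
#' @return `basis_f()` returns the basis values at the given samples.
#' @export
basis_f <- function(n, m, cfg) {
  stopifnot(inherits(cfg, "basis_config"))
  if (any(n < 0) || any(n >= cfg$N)) abort("sample index out of range")
  if (m < 0 || m > cfg$V) abort("basis index out of range")
  if (m == 0) return(rep(1, length(n)))
  t11 <- if (cfg$N == 1) rep(0, length(n)) else 2 * n / (cfg$N - 1) - 1
  switch(cfg$family,
    legendre = legendre_poly(m, t11),
    fourier = cos(m * pi * (n / (cfg$N - 1))),
    time_power = t11^m
  )
}

# Legendre polynomial P_m via the three-term recurrence
legendre_poly <- function(m, x) {
  if (m == 0) return(rep(1, length(x)))
  if (m == 1) return(x)
  pm2 <- rep(1, length(x)); pm1 <- x
  for (k in 2:m) {
    pm <- ((2 * k - 1) * x * pm1 - (k - 1) * pm2) / k
    pm2 <- pm1; pm1 <- pm
  }
  pm1
}

# full basis matrix: N x (V+1), column m+1 = f(., m)
basis_matrix <- function(cfg) {
  vapply(0:cfg$V, function(m) basis_f(0:(cfg$N - 1), m, cfg),
         numeric(cfg$N))
}

#' Fit a time-varying ARMA virtual-sensor model
#'
#' The target channel `y(n)` is modelled as a linear combination of its own
#' past `P` samples and the past `Q` samples of the exogenous MCC input
#' `u(n)`, with coefficients that vary over the segment through the basis
#' expansion `a(i, n) = sum_m alpha(i, m) f(n, m)` (and likewise
#' `b(j, n)`). The expansion coefficients are estimated by ordinary least
#' squares on the implied linear regression, with regressors
#' `y(n - i) f(n, m)` and `u(n - j) f(n, m)`; a rank-deficient regressor
#' matrix falls back to a small ridge penalty (logged).
#'
#' Joint estimation regresses on the y- and u-lag regressors together (the
#' plain least-squares reading of the model equation). On strongly
#' autocorrelated signals the y-lags absorb nearly all predictive weight,
#' which is optimal for one-step prediction but degenerate for the
#' zero-innovation free run a virtual sensor needs (the input coefficients
#' come out near zero and the free run decays). `estimation = "two_stage"`
#' therefore first regresses the target on the input lags alone (the
#' input-to-channel map) and then fits the AR part to the residual; the
#' deployed virtual sensor uses this form.
#'
#' @param y_history clean target-channel segment.
#' @param u_history matching MCC-input segment (same length).
#' @param cfg a [basis_config()]; its `N` is reset to the history length.
#' @param P autoregressive order.
#' @param Q exogenous (moving-average input) order.
#' @param estimation `"joint"` (default) or `"two_stage"` least squares.
#' @return An object of class `tvarma_model` with `alpha` (P x (V+1)),
#'   `beta` (Q x (V+1)), `sigma2` (residual variance), `cfg`, `P`, `Q`,
#'   `estimation`.
#' @export
fit_tvarma <- function(y_history, u_history, cfg = basis_config(),
                       P = 4, Q = 2,
                       estimation = c("joint", "two_stage")) {
  estimation <- match.arg(estimation)
  stopifnot(inherits(cfg, "basis_config"))
  P <- check_count(P, "P"); Q <- check_count(Q, "Q")
  N <- length(y_history)
  if (length(u_history) != N) abort("history lengths differ")
  V <- cfg$V
  if (N <= (P + Q) * (V + 1) + max(P, Q)) {
    abort("history too short for the requested orders and basis size")
  }
  cfg$N <- N
  Fb <- basis_matrix(cfg)                      # N x (V+1)
  lag_block <- function(x, lags, idx) {
    out <- matrix(0, length(idx), length(lags) * (V + 1))
    col <- 0L
    for (l in lags) {
      for (m in 0:V) {
        col <- col + 1L
        out[, col] <- x[idx - l] * Fb[idx, m + 1]
      }
    }
    out
  }
  ls_solve <- function(reg, rhs) {
    fit <- stats::lm.fit(reg, rhs)
    if (fit$rank < ncol(reg)) {
      inform("rank-deficient TVARMA regressors: using ridge fallback")
      lambda <- 1e-8 * sum(diag(crossprod(reg))) / ncol(reg)
      coefs <- drop(solve(crossprod(reg) + diag(lambda, ncol(reg)),
                          crossprod(reg, rhs)))
      list(coefs = coefs, resid = rhs - drop(reg %*% coefs))
    } else {
      list(coefs = unname(fit$coefficients), resid = fit$residuals)
    }
  }
  to_mat <- function(coefs, nlags) matrix(coefs, nrow = nlags, byrow = TRUE)

  if (estimation == "joint") {
    idx <- (max(P, Q) + 1L):N
    reg <- cbind(lag_block(y_history, seq_len(P), idx),
                 lag_block(u_history, seq_len(Q), idx))
    sol <- ls_solve(reg, y_history[idx])
    alpha <- to_mat(sol$coefs[seq_len(P * (V + 1))], P)
    beta <- to_mat(sol$coefs[P * (V + 1) + seq_len(Q * (V + 1))], Q)
    resid <- sol$resid
    n_par <- ncol(reg)
  } else {
    # stage A: input map, u-lags only
    idxA <- (Q + 1L):N
    solA <- ls_solve(lag_block(u_history, seq_len(Q), idxA),
                     y_history[idxA])
    beta <- to_mat(solA$coefs, Q)
    # stage B: AR dynamics of the input-map residual
    v <- y_history
    v[idxA] <- solA$resid
    idxB <- (P + Q + 1L):N
    solB <- ls_solve(lag_block(v, seq_len(P), idxB), v[idxB])
    alpha <- to_mat(solB$coefs, P)
    resid <- solB$resid
    n_par <- (P + Q) * (V + 1)
  }
  structure(list(alpha = alpha, beta = beta,
                 sigma2 = sum(resid^2) / max(1, length(resid) - n_par),
                 cfg = cfg, P = P, Q = Q, estimation = estimation),
            class = "tvarma_model")
}

#' @export
print.tvarma_model <- function(x, ...) {
  cat(sprintf(
    "<tvarma_model> P = %d, Q = %d, %s basis V = %d; residual variance %.3g\n",
    x$P, x$Q, x$cfg$family, x$cfg$V, x$sigma2))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.tvarma_model <- function(x, ...) {
  a <- tibble(term = "a", lag = rep(seq_len(x$P), each = x$cfg$V + 1),
              basis = rep(0:x$cfg$V, x$P),
              estimate = as.vector(t(x$alpha)))
  b <- tibble(term = "b", lag = rep(seq_len(x$Q), each = x$cfg$V + 1),
              basis = rep(0:x$cfg$V, x$Q),
              estimate = as.vector(t(x$beta)))
  dplyr::bind_rows(a, b)
}

#' @exportS3Method generics::glance
glance.tvarma_model <- function(x, ...) {
  tibble(P = x$P, Q = x$Q, V = x$cfg$V, family = x$cfg$family,
         sigma2 = x$sigma2)
}

#' Reconstruct a channel segment with a fitted TVARMA model
#'
#' For a jointly estimated model: recursive mean prediction (innovation
#' term set to zero): each output sample is the coefficient-weighted sum of
#' the previous `P` outputs and the previous `Q` input samples. For a
#' two-stage model the mean prediction decomposes as the time-varying
#' input map applied to the input plus the AR free run of the residual
#' process; the latter decays from an unknown initial state and is taken as
#' zero, so the output is the input map alone.
#' Time-varying coefficients are evaluated
#' on the reconstruction segment's own time axis. The recursion is guarded:
#' if the output magnitude exceeds `guard` times the input scale it is
#' clipped and the event recorded in the `clipped` attribute.
#'
#' @param model a `tvarma_model`.
#' @param u exogenous MCC-input vector covering the reconstruction span.
#' @param y_seed the last `P` clean samples preceding the span (most recent
#'   last).
#' @param guard clipping multiple of the input/seed scale.
#' @param stabilize project the instantaneous AR polynomial's roots inside
#'   the unit circle (radius `max_radius`) before the recursion. Least
#'   squares does not constrain stability, and a marginally unstable AR
#'   part makes the mean (zero-innovation) free run diverge over long
#'   spans.
#' @param max_radius pole-radius bound used when `stabilize = TRUE`.
#' @return Numeric vector of `length(u)` reconstructed samples.
#' @export
predict_tvarma <- function(model, u, y_seed = numeric(model$P), guard = 50,
                           stabilize = TRUE, max_radius = 0.99) {
  stopifnot(inherits(model, "tvarma_model"))
  P <- model$P; Q <- model$Q
  if (length(y_seed) < P) y_seed <- c(numeric(P - length(y_seed)), y_seed)
  N <- length(u)
  cfg <- model$cfg
  cfg$N <- max(N, 2)
  Fb <- basis_matrix(cfg)[seq_len(N), , drop = FALSE]
  a_n <- Fb %*% t(model$alpha)                 # N x P time-varying AR coefs
  b_n <- Fb %*% t(model$beta)                  # N x Q
  if (stabilize && P > 0) {
    a_n <- t(apply(a_n, 1, stabilize_ar, max_radius = max_radius))
    if (P == 1) a_n <- t(a_n)
  }
  bound <- guard * max(1e-12, max(abs(u)), max(abs(y_seed)))
  if (identical(model$estimation, "two_stage")) {
    upad <- c(rep(u[1], Q), u)
    y <- numeric(N)
    for (j in seq_len(Q)) {
      y <- y + b_n[, j] * upad[Q - j + seq_len(N)]
    }
    over <- abs(y) > bound
    if (any(over)) {
      warn("TVARMA input map exceeded the guard bound; output clipped")
      y[over] <- sign(y[over]) * bound
      attr(y, "clipped") <- TRUE
    }
    return(y)
  }
  y <- numeric(N)
  ybuf <- rev(tail(y_seed, P))                 # ybuf[i] = y(n - i)
  ubuf <- rep(u[1], Q)
  clipped <- FALSE
  for (n in seq_len(N)) {
    val <- sum(a_n[n, ] * ybuf) + sum(b_n[n, ] * ubuf)
    if (is.finite(val) && abs(val) > bound) {
      val <- sign(val) * bound
      clipped <- TRUE
    } else if (!is.finite(val)) {
      val <- 0
      clipped <- TRUE
    }
    y[n] <- val
    if (P > 1) ybuf <- c(val, ybuf[seq_len(P - 1)]) else ybuf <- val
    if (Q > 1) ubuf <- c(u[n], ubuf[seq_len(Q - 1)]) else ubuf <- u[n]
  }
  if (clipped) {
    warn("TVARMA recursion exceeded the guard bound; output clipped")
    attr(y, "clipped") <- TRUE
  }
  y
}

# Shrink the roots of 1 - sum_i a_i z^-i onto radius <= max_radius.
stabilize_ar <- function(a, max_radius = 0.99) {
  P <- length(a)
  # roots of z^P - a1 z^(P-1) - ... - aP (ascending coefficients for polyroot)
  r <- polyroot(c(-rev(a), 1))
  if (all(Mod(r) <= max_radius)) return(a)
  r <- ifelse(Mod(r) > max_radius, r * max_radius / Mod(r), r)
  cf <- Re(poly_from_roots(r))     # monic, descending
  -cf[-1]
}
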