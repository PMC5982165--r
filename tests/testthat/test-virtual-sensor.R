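test_that("normalized cross-correlation follows the absolute-value convention", {
  set.seed(1)
  x <- rnorm(500)
  expect_equal(cross_corr_coeff(x, x), 1)
  expect_equal(cross_corr_coeff(x, -x), 1)
  a <- rnorm(1e5); b <- rnorm(1e5)
  expect_lte(cross_corr_coeff(a, b), 0.02)
  expect_message(cc <- cross_corr_coeff(rep(1, 10), rnorm(10)), "constant")
  expect_equal(cc, 0)
  expect_error(cross_corr_coeff(1:3, 1:4), "equal-length")
})

test_that("MCC matrix normalizes contributions per target", {
  set.seed(2)
  s2 <- matrix(rnorm(400), 200, 2)
  m2 <- mcc_matrix(s2)
  expect_equal(m2$p, matrix(c(0, 1, 1, 0), 2))

  # three channels with equal pairwise correlation -> all entries 1/2
  base <- rnorm(2000)
  s3 <- sapply(1:3, function(i) base + rnorm(2000))
  m3 <- mcc_matrix(s3)
  off <- m3$p[row(m3$p) != col(m3$p)]
  expect_equal(off, rep(0.5, 6), tolerance = 0.05)
  expect_equal(diag(m3$p), rep(0, 3))
})

test_that("MCC equals a brute-force evaluation entry by entry", {
  set.seed(3)
  src <- matrix(rnorm(3000), 1000, 3)
  sig <- src %*% matrix(runif(12, 0.2, 1), 3, 4)
  m <- mcc_matrix(sig)
  cmat <- matrix(0, 4, 4)
  for (x in 1:4) for (y in 1:4) {
    if (x != y) cmat[x, y] <- abs(cor(sig[, x], sig[, y]))
  }
  p_brute <- matrix(0, 4, 4)
  for (y in 1:4) p_brute[, y] <- cmat[, y] / sum(cmat[, y])
  expect_equal(m$p, p_brute, tolerance = 1e-12)
})

test_that("MCC invariants: column sums, diagonal, scaling, exclusion", {
  set.seed(4)
  for (i in 1:10) {
    M <- sample(3:8, 1)
    sig <- matrix(rnorm(500 * 3), 500, 3) %*% matrix(runif(3 * M), 3, M)
    m <- mcc_matrix(sig)
    expect_equal(unname(colSums(m$p)), rep(1, M), tolerance = 1e-12)
    expect_equal(diag(m$p), rep(0, M))
    expect_true(all(m$p >= 0))
    # positive rescaling leaves contributions unchanged
    m_scaled <- mcc_matrix(sweep(sig, 2, runif(M, 0.5, 4), "*"))
    expect_equal(m_scaled$p, m$p, tolerance = 1e-9)
    # excluding a channel redistributes its mass; columns still sum to 1
    ex <- sample(M, 1)
    mex <- mcc_matrix(sig, excluded = ex)
    expect_equal(unname(mex$p[ex, ]), rep(0, M))
    expect_equal(unname(colSums(mex$p)), rep(1, M), tolerance = 1e-12)
  }
  expect_error(mcc_matrix(matrix(rnorm(30), 10, 3), excluded = 1:2),
               "fewer than 2")
})

test_that("the MCC input is the weighted source sum", {
  set.seed(5)
  s <- rnorm(300)
  same <- cbind(s, s, s)
  m <- mcc_matrix(same + 1e-6 * matrix(rnorm(900), 300, 3))
  u <- mcc_input(m, same, 2)
  expect_equal(u, s, tolerance = 1e-9)

  sig <- matrix(rnorm(1200), 300, 4)
  m4 <- mcc_matrix(sig, excluded = c(2, 3))
  u4 <- mcc_input(m4, sig, 2)
  brute <- sig %*% m4$p[, 2]
  expect_equal(u4, drop(brute))
  # single available source: input equals that source
  m2 <- mcc_matrix(sig[, 1:2])
  expect_equal(mcc_input(m2, sig[, 1:2], 1), sig[, 2])
})

test_that("basis families satisfy their closed forms", {
  cfg <- basis_config("legendre", V = 3, N = 601)
  expect_equal(basis_f(0:600, 0, cfg), rep(1, 601))
  expect_equal(basis_f(300, 1, cfg), 0)  # odd polynomial at midpoint
  # P2(x) = (3x^2 - 1) / 2
  x <- 2 * (0:600) / 600 - 1
  expect_equal(basis_f(0:600, 2, cfg), (3 * x^2 - 1) / 2)

  cfgf <- basis_config("fourier", V = 3, N = 100)
  expect_equal(basis_f(0:99, 2, cfgf), cos(2 * pi * (0:99) / 99))

  cfgt <- basis_config("time_power", V = 2, N = 11)
  expect_equal(basis_f(0:10, 2, cfgt), (2 * (0:10) / 10 - 1)^2)

  expect_error(basis_f(0, 5, cfg), "out of range")
  expect_error(basis_f(601, 1, cfg), "out of range")
})

test_that("joint least squares equals the brute-force normal equations", {
  set.seed(6)
  ys <- rnorm(200); us <- rnorm(200)
  fit <- fit_tvarma(ys, us, basis_config("legendre", V = 1), P = 2, Q = 1)
  cfg <- basis_config("legendre", V = 1, N = 200)
  Fo <- vapply(0:1, function(m) basis_f(0:199, m, cfg), numeric(200))
  idx <- 3:200
  R <- cbind(ys[idx - 1] * Fo[idx, 1], ys[idx - 1] * Fo[idx, 2],
             ys[idx - 2] * Fo[idx, 1], ys[idx - 2] * Fo[idx, 2],
             us[idx - 1] * Fo[idx, 1], us[idx - 1] * Fo[idx, 2])
  co <- solve(t(R) %*% R, t(R) %*% ys[idx])
  expect_equal(c(t(fit$alpha)), co[1:4], tolerance = 1e-8)
  expect_equal(c(t(fit$beta)), co[5:6], tolerance = 1e-8)
})

test_that("known time-varying coefficients are recovered from data", {
  set.seed(42)
  n <- 10000
  cfgb <- basis_config("legendre", V = 1, N = n)
  Fb <- vapply(0:1, function(m) basis_f(0:(n - 1), m, cfgb), numeric(n))
  alpha_true <- matrix(c(0.5, 0.1, -0.2, 0.05, 0.1, -0.02, 0.05, 0.01),
                       nrow = 4, byrow = TRUE)
  beta_true <- matrix(c(0.8, 0.2, 0.3, -0.1), nrow = 2, byrow = TRUE)
  u <- rnorm(n)
  y <- numeric(n)
  innov <- rnorm(n)
  # pilot pass to set the innovation variance 30 dB below the signal
  for (pass in 1:2) {
    sd_e <- if (pass == 1) 0 else sqrt(var(y) / 1000)
    y <- numeric(n)
    for (t in 5:n) {
      a <- Fb[t, ] %*% t(alpha_true)
      b <- Fb[t, ] %*% t(beta_true)
      y[t] <- sum(a * y[t - (1:4)]) + sum(b * u[t - (1:2)]) +
        sd_e * innov[t]
    }
  }
  fit <- fit_tvarma(y, u, basis_config("legendre", V = 1))
  expect_lt(max(abs(fit$alpha - alpha_true)), 0.05)
  expect_lt(max(abs(fit$beta - beta_true)), 0.05)
})

test_that("V = 0 reduces to a time-invariant AR fit", {
  set.seed(7)
  n <- 20000
  a_true <- c(0.6, -0.3, 0.1, -0.05)
  y <- as.numeric(stats::arima.sim(list(ar = a_true), n))
  fit <- fit_tvarma(y, rnorm(n), basis_config("legendre", V = 0), P = 4, Q = 2)
  ref <- stats::ar.ols(y, order.max = 4, aic = FALSE, demean = FALSE,
                       intercept = FALSE)
  expect_equal(drop(fit$alpha), drop(ref$ar), tolerance = 0.02)
  expect_lt(max(abs(drop(fit$beta))), 0.05)
  expect_error(fit_tvarma(rnorm(10), rnorm(10)), "too short")
})

test_that("TVARMA mean prediction honors trivial model structures", {
  zero_model <- structure(list(
    alpha = matrix(0, 4, 3), beta = matrix(0, 2, 3), sigma2 = 0,
    cfg = basis_config(), P = 4, Q = 2, estimation = "joint"),
    class = "tvarma_model")
  expect_equal(predict_tvarma(zero_model, rnorm(100), rnorm(4)),
               numeric(100))

  rw <- structure(list(
    alpha = cbind(c(1, 0, 0, 0), 0, 0), beta = matrix(0, 2, 3), sigma2 = 0,
    cfg = basis_config(), P = 4, Q = 2, estimation = "joint"),
    class = "tvarma_model")
  out <- predict_tvarma(rw, numeric(50), y_seed = c(0, 0, 0, 0.7),
                        stabilize = FALSE)
  expect_equal(out, rep(0.7, 50))
})

test_that("the deployed virtual sensor beats the zero predictor", {
  norm <- tiny_norm()
  sig <- emg_channels(norm)
  hist_idx <- 1:8000
  test_idx <- 8001:16000
  mcc <- mcc_matrix(sig[hist_idx, ], excluded = 1)
  u_h <- mcc_input(mcc, sig[hist_idx, ], 1)
  fit <- fit_tvarma(sig[hist_idx, 1], u_h, estimation = "two_stage")
  u_t <- mcc_input(mcc, sig[test_idx, ], 1)
  pred <- predict_tvarma(fit, u_t)
  truth <- sig[test_idx, 1]
  nrmse <- sqrt(mean((pred - truth)^2)) / sqrt(mean(truth^2))
  expect_lt(nrmse, 1)
  expect_gt(cor(pred, truth), 0.5)
})

test_that("the Riccati fixed point matches closed forms", {
  # no process noise: the covariance decays to zero (harmonically, so the
  # iterate stops near the fixed point rather than at it)
  g0 <- kalman_gain(1, 1, 1, 0, 1)
  expect_lt(g0$Pss[1, 1], 1e-4)
  expect_lt(g0$Mgain[1, 1], 1e-4)

  g <- kalman_gain(1, 1, 1, 1, 1)
  phi <- (1 + sqrt(5)) / 2
  expect_equal(g$Pss[1, 1], phi, tolerance = 1e-9)
  expect_equal(g$Mgain[1, 1], phi / (phi + 1), tolerance = 1e-9)

  # residual of the Riccati equation at the fixed point
  A <- diag(1, 2); Qw <- diag(c(1, 2)); R <- diag(c(1, 0.5))
  g2 <- kalman_gain(A, A, A, Qw, R)
  S <- A %*% g2$Pss %*% t(A) -
    A %*% g2$Pss %*% t(A) %*% solve(g2$Pss + R) %*% g2$Pss %*% t(A) + Qw
  expect_lt(max(abs(g2$Pss - S)), 1e-8)
  # identity 2x2 system decouples into scalar solutions
  s1 <- kalman_gain(1, 1, 1, 1, 1)$Pss[1, 1]
  s2 <- kalman_gain(1, 1, 1, 2, 0.5)$Pss[1, 1]
  expect_equal(diag(g2$Pss), c(s1, s2), tolerance = 1e-8)
  expect_error(kalman_gain(1, 1, 1, 1, 0), "positive definite")
})

test_that("Kalman estimate limits: perfect measurement and full prior trust", {
  set.seed(8)
  y <- rnorm(200)
  m_perfect <- fit_tvk(rnorm(50), rnorm(50), R = 1e-12, Qw = 1)
  expect_equal(tvk_estimate(m_perfect, numeric(200), y), y,
               tolerance = 1e-4)

  m_prior <- fit_tvk(rnorm(50), rnorm(50), R = 1, Qw = 1e-14)
  est <- tvk_estimate(m_prior, numeric(200), y, x0 = 0)
  expect_lt(max(abs(est)), 1e-3)
  expect_error(tvk_estimate(m_prior, numeric(5), y), "length")
})

test_that("Kalman filtering beats the raw measurement and smoothing baseline", {
  set.seed(9)
  n <- 5000
  a <- 0.95; qw <- 0.1; r <- 1
  w <- rnorm(n, sd = sqrt(qw)); v <- rnorm(n, sd = sqrt(r))
  x <- numeric(n)
  for (t in 2:n) x[t] <- a * x[t - 1] + w[t]
  y <- x + v
  model <- fit_tvk(rnorm(50), rnorm(50), A = a, R = r, Qw = qw)
  est <- tvk_estimate(model, numeric(n), y)
  err_kalman <- var((est - x)[100:n])
  err_meas <- var((y - x)[100:n])
  smooth <- stats::filter(0.8 * y, 0.2, method = "recursive")
  err_smooth <- var((as.numeric(smooth) - x)[100:n])
  expect_lt(err_kalman, err_meas)
  expect_lt(err_kalman, err_smooth)
})

test_that("reconstruction replaces flagged channels and only those", {
  norm <- tiny_norm()
  st <- tiny_stream()
  no_flags <- tidyr::expand_grid(channel = 1:12, window = st$window)
  no_flags$start <- st$start[no_flags$window]
  no_flags$contaminated <- FALSE
  same <- reconstruct_channel(norm, no_flags, "tvarma")
  expect_identical(emg_channels(same), emg_channels(norm))

  flags <- no_flags
  flags$contaminated <- flags$channel == 2
  hist <- emg_channels(norm)[1:8000, ]
  for (method in c("tvarma", "tvk")) {
    rep2 <- reconstruct_channel(norm, flags, method, history = hist)
    d <- emg_channels(rep2) - emg_channels(norm)
    expect_equal(unname(which(colSums(abs(d)) > 0)), 2L)
    expect_gt(attr(rep2, "reconstruction")$replaced[2], 0)
  }

  all_flags <- no_flags
  all_flags$contaminated <- TRUE
  expect_error(reconstruct_channel(norm, all_flags, "tvk", history = hist),
               "all channels degraded")
})
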