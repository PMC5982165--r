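test_that("configuration invariants are enforced", {
  expect_error(preprocess_config(band_high = 1500), "band edges")
  expect_error(preprocess_config(filter_order = 7), "even")
  expect_error(preprocess_config(window_ms = 50, increment_ms = 75), ">=")
  cfg <- preprocess_config()
  expect_equal(cfg$band_low, 20)
  expect_equal(cfg$band_high, 500)
  expect_equal(cfg$filter_order, 20L)
})

test_that("band-pass design puts half-power points at the band edges", {
  filt <- design_bandpass(20, 20, 500, 2000)
  # dense grid around each edge
  f_hi <- seq(480, 520, by = 0.05)
  mag_hi <- Mod(sos_response(filt, f_hi))
  upper <- f_hi[which(mag_hi < 1 / sqrt(2))[1]]
  expect_lt(abs(upper - 500), 1)

  f_lo <- seq(10, 30, by = 0.05)
  mag_lo <- Mod(sos_response(filt, f_lo))
  lower <- f_lo[rev(which(mag_lo < 1 / sqrt(2)))[1]]
  expect_lt(abs(lower - 20), 1)

  # pass band is flat, stop band strongly attenuated (single pass)
  expect_lt(Mod(sos_response(filt, 10)), 0.05)
  expect_gt(Mod(sos_response(filt, 100)), 0.95)
})

test_that("band-pass response matches an independent direct-form design", {
  filt <- design_bandpass(20, 20, 500, 2000)
  bt <- signal::butter(10, c(20, 500) / 1000, type = "pass")
  f <- c(50, 100, 200, 300, 400)
  mine <- Mod(sos_response(filt, f))
  ref <- vapply(f, function(fr) {
    z <- exp(-1i * 2 * pi * fr / 2000 * (0:(length(bt$b) - 1)))
    Mod(sum(bt$b * z) / sum(bt$a * z))
  }, numeric(1))
  expect_equal(mine, ref, tolerance = 1e-6)
})

test_that("zero-phase filtering attenuates the stop band and passes the band", {
  fs <- 2000
  t <- (seq_len(20000) - 1) / fs
  rec10 <- emg_tbl(cbind(sin(2 * pi * 10 * t), sin(2 * pi * 100 * t)), fs)
  out <- bandpass_filter(rec10, preprocess_config())
  mid <- 4000:16000
  sig <- emg_channels(out)
  expect_lt(sd(sig[mid, 1]), 0.05 * sd(sin(2 * pi * 10 * t[mid])))
  expect_equal(sd(sig[mid, 2]), sd(sin(2 * pi * 100 * t[mid])),
               tolerance = 0.05)
})

test_that("filtering is linear and scale-equivariant", {
  set.seed(5)
  x <- rnorm(5000)
  filt <- design_bandpass(20, 20, 500, 2000)
  expect_equal(sos_filtfilt(filt, 3 * x), 3 * sos_filtfilt(filt, x),
               tolerance = 1e-8)
})

test_that("normalization is scale-invariant with unit max per channel", {
  rec <- tiny_recording()
  filt <- bandpass_filter(rec, preprocess_config())
  nv <- rectify_normalize(filt)
  expect_equal(unname(apply(abs(emg_channels(nv$signed)), 2, max)),
               rep(1, n_channels(rec)))
  expect_equal(emg_channels(nv$rectified), abs(emg_channels(nv$signed)))

  scaled <- set_channels(filt, emg_channels(filt) * 3)
  nv2 <- rectify_normalize(scaled)
  expect_equal(emg_channels(nv2$signed), emg_channels(nv$signed),
               tolerance = 1e-12)

  # re-normalizing changes nothing (idempotence)
  nv3 <- rectify_normalize(nv$signed)
  expect_equal(emg_channels(nv3$signed), emg_channels(nv$signed),
               tolerance = 1e-12)

  zero <- set_channels(filt, cbind(emg_channels(filt)[, 1:11], 0))
  expect_warning(rectify_normalize(zero), "zero")
})

test_that("window segmentation count and labels follow the sliding scheme", {
  fs <- 2000
  mk <- function(n, label = integer(n)) emg_tbl(matrix(0, n, 2), fs, label)
  cfg <- preprocess_config()
  expect_equal(nrow(segment_windows(mk(6000), cfg)), 37)
  expect_equal(nrow(segment_windows(mk(600), cfg)), 1)
  expect_error(segment_windows(mk(599), cfg), "shorter")

  # majority labels with ties resolved toward the lower id
  lab <- c(rep(2L, 300), rep(1L, 300))
  st <- segment_windows(mk(600, lab), cfg)
  expect_equal(st$label, 1L)
  lab2 <- c(rep(0L, 250), rep(3L, 350))
  expect_equal(segment_windows(mk(600, lab2), cfg)$label, 3L)
})

test_that("window count formula agrees with brute-force enumeration", {
  set.seed(11)
  for (i in 1:25) {
    W <- sample(50:400, 1)
    S <- sample(10:W, 1)
    N <- W + sample(0:2000, 1)
    fs <- 1000
    cfg <- preprocess_config(band_low = 10, band_high = 400,
                             window_ms = W, increment_ms = S, fs = fs)
    st <- segment_windows(emg_tbl(matrix(0, N, 1), fs), cfg)
    Ws <- round(W * fs / 1000); Ss <- round(S * fs / 1000)
    brute <- 0; s <- 1
    while (s + Ws - 1 <= N) { brute <- brute + 1; s <- s + Ss }
    expect_equal(nrow(st), brute)
    expect_equal(nrow(st), floor((N - Ws) / Ss) + 1)
    expect_true(all(diff(st$start) == Ss))
  }
})

test_that("recordings round-trip through delimited text", {
  rec <- synth_recording(
    emg_protocol(seed = 2, n_movements = 1, n_repetitions = 1,
                 movement_duration = 0.5, rest_duration = 0.5), seed = 3)
  for (fmt in c("csv", "tsv")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_emg(rec, path, fmt)
    back <- read_emg(path, fmt)
    expect_equal(emg_channels(back), emg_channels(rec), tolerance = 1e-10)
    expect_identical(back$label, rec$label)
    expect_identical(back$repetition, rec$repetition)
    expect_equal(emg_fs(back), emg_fs(rec))
  }

  # 11 channels: accepted with a warning, M inferred
  path <- withr::local_tempfile(fileext = ".csv")
  rec11 <- emg_tbl(matrix(rnorm(220), 20, 11), 2000)
  write_emg(rec11, path)
  expect_warning(back <- read_emg(path), "11 channels")
  expect_equal(n_channels(back), 11)

  # missing label column rejected
  readr::write_csv(data.frame(ch1 = 1:5, repetition = 0L), path)
  expect_error(read_emg(path), "label")
})
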