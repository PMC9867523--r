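test_that("band-pass removes DC, passes 10 Hz, rejects 60 Hz", {
  fs <- 500
  t <- seq(0, 10, by = 1 / fs)
  dc <- bandpass_fir(rep(3, length(t)), fs = fs)
  expect_lt(max(abs(dc)), 3e-6)

  trim <- 500:4500
  pass <- bandpass_fir(sin(2 * pi * 10 * t), fs = fs)
  expect_gt(max(abs(pass[trim])), 0.9)
  expect_lt(max(abs(pass[trim])), 1.1)

  stop60 <- bandpass_fir(sin(2 * pi * 60 * t), fs = fs)
  expect_lt(max(abs(stop60[trim])), 10^(-20 / 20))  # >= 20 dB down

  expect_lt(max(abs(bandpass_fir(sin(2 * pi * 10 * t), fs = fs) -
                      pass)), 1e-12)  # deterministic
  expect_error(bandpass_fir(rnorm(100), fs = 500), "too short")
  expect_error(bandpass_fir(rnorm(1000), fs = 80), "band edge")
})

test_that("zero-phase filtering introduces no group delay", {
  fs <- 500
  g <- gen_ecg(fs = fs, duration_s = 30, hr_bpm = 60, seed = 5)
  y <- bandpass_fir(g$signal)
  peaks <- vapply(g$rpeaks[3:25], function(r) {
    w <- (r - 20):(r + 20)
    w[which.max(y$samples[w])]
  }, numeric(1))
  expect_true(all(abs(peaks - g$rpeaks[3:25]) <= 2))
})

test_that("detector finds clean beats at the stated rates", {
  g60 <- gen_ecg(fs = 500, duration_s = 60, hr_bpm = 60, seed = 7)
  rp <- detect_rpeaks(g60$signal)
  expect_true(abs(length(rp) - 60) <= 1)
  m <- match_rpeaks(g60$rpeaks, rp, tol_ms = 20, fs = 500)
  expect_equal(m$TP, length(rp))  # every detection within 20 ms of truth

  g75 <- gen_ecg(fs = 500, duration_s = 60, hr_bpm = 75, seed = 3)
  rp75 <- detect_rpeaks(g75$signal)
  expect_lt(abs(median(diff(rp75)) / 500 - 0.8), 0.01)

  expect_identical(detect_rpeaks(numeric(5000), fs = 500), integer(0))
  expect_error(detect_rpeaks(rnorm(5000), fs = 80), "too low")
})

test_that("segment_beats drops boundary beats, keeps shape", {
  fs <- 500
  x <- rnorm(5000)
  rp <- c(10, 500, 1000, 4950)
  b <- segment_beats(x, rp, window = c(200, 400), fs = fs)
  expect_equal(b$r_indices, c(500, 1000))  # 10 and 4950 cross boundaries
  expect_equal(ncol(b$beats), round(0.6 * fs))
  expect_equal(b$beats[1, b$r_offset], x[500])
  allin <- segment_beats(x, c(500, 1000, 2000), fs = fs)
  expect_equal(nrow(allin$beats), 3)
  expect_error(segment_beats(x, c(100, 100), fs = fs), "increasing")
})

test_that("heart_rate uses only consecutive plausible intervals", {
  hr <- heart_rate(seq(1, 4001, by = 400), fs = 500)
  expect_true(all(hr$bpm == 75))
  expect_equal(heart_rate(c(100), fs = 500)$bpm, numeric(0))
  # the 2000-sample gap (25 bpm) is implausible and excluded
  hr2 <- heart_rate(c(1, 401, 801, 2801), fs = 500)
  expect_equal(hr2$bpm, c(75, 75))
  expect_equal(hr2$n_excluded, 1L)
  # chain bookkeeping: removing the middle beat of three kills both
  # intervals
  mask <- outlier_mask(c(FALSE, TRUE, FALSE), "manual", list())
  kept <- apply_mask(c(1, 401, 801), mask)
  expect_equal(heart_rate(kept, fs = 500)$bpm, numeric(0))
  # invariant to sampling-rate rescaling
  a <- heart_rate(c(1, 401, 801), fs = 500)
  b <- heart_rate(c(1, 801, 1601), fs = 1000)
  expect_equal(a$bpm, b$bpm)
})

test_that("greedy peak matching matches the worked example", {
  m <- match_rpeaks(c(100, 600, 1100), c(102, 1105, 1500), tol_ms = 100,
                    fs = 500)
  expect_equal(c(m$TP, m$FP, m$FN), c(2, 1, 1))
  ident <- match_rpeaks(1:10 * 100, 1:10 * 100, tol_ms = 100, fs = 500)
  expect_equal(c(ident$TP, ident$FP), c(10, 0))
  none <- match_rpeaks(1:5 * 100, integer(0), tol_ms = 100, fs = 500)
  expect_equal(c(none$TP, none$FP, none$FN), c(0, 0, 5))
})

test_that("greedy matching equals brute-force optimum (property)", {
  set.seed(12)
  for (i in 1:40) {
    nr <- sample(0:12, 1)
    ne <- sample(0:12, 1)
    ref <- sort(sample(1:2000, nr))
    exp <- sort(sample(1:2000, ne))
    tol <- 50
    m <- match_rpeaks(ref, exp, tol_ms = tol / 500 * 1000, fs = 500)
    expect_equal(m$TP, match_oracle_count(ref, exp, tol))
  }
})

test_that("performance/accuracy follow their defining ratios", {
  pa <- performance_accuracy(match_rpeaks(1:10 * 100, 1:10 * 100, 100, 500))
  expect_equal(c(pa$performance, pa$accuracy), c(100, 100))
  m <- structure(list(TP = 8, FP = 2, FN = 2, N_ref = 10),
                 class = "match_result")
  pa2 <- performance_accuracy(m)
  expect_equal(c(pa2$performance, pa2$accuracy), c(80, 80))
  m0 <- structure(list(TP = 0, FP = 0, FN = 10, N_ref = 10),
                  class = "match_result")
  pa0 <- performance_accuracy(m0)
  expect_equal(pa0$performance, 0)
  expect_true(is.na(pa0$accuracy))
  mbad <- structure(list(TP = 0, FP = 0, FN = 0, N_ref = 0),
                    class = "match_result")
  expect_error(performance_accuracy(mbad), "no R-peaks")
})

test_that("compare_signals: scaling invariance and equal-power noise", {
  x <- sin(seq(0, 20, by = 0.01))
  same <- compare_signals(x, x)
  expect_equal(same$cosine, 1.0)
  expect_equal(same$snr_db, 100)  # capped sentinel
  twice <- compare_signals(2 * x, x)
  expect_equal(twice$cosine, 1.0)
  expect_equal(twice$snr_db, 100)
  expect_equal(twice$alpha, 2)

  set.seed(77)
  n <- 30000
  s <- rnorm(n)
  noisy <- compare_signals(s + rnorm(n), s)
  expect_lt(abs(noisy$snr_db), 0.5)  # equal power -> ~0 dB
  expect_error(compare_signals(numeric(10), rnorm(10)), "zero-norm")
  expect_error(compare_signals(rnorm(5), rnorm(6)), "equal length")
})

test_that("r_amplitude subtracts the pre-QRS baseline", {
  b <- segment_beats(rep(0, 3000), c(1000, 2000), fs = 500)
  b$beats[, b$r_offset] <- 1.0
  amp <- r_amplitude(b)
  expect_equal(amp$mean, 1.0)
  expect_equal(amp$sd, 0)
  shifted <- b
  shifted$beats <- shifted$beats + 5
  expect_equal(r_amplitude(shifted)$mean, 1.0)  # shift invariant
  expect_equal(r_amplitude(b, scale = 2)$mean, 2.0)

  g <- gen_ecg(fs = 500, duration_s = 60, hr_bpm = 60, seed = 13)
  beats <- segment_beats(g$signal, g$rpeaks[2:59])
  expect_lt(abs(r_amplitude(beats)$mean - 0.8), 0.05)
})
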