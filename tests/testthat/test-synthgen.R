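test_that("packaged posture stats load and validate", {
  st <- posture_stats()
  expect_equal(nrow(st), 8)
  expect_equal(st["P1", "mean_x"], 15.25)
  expect_equal(st["P6", "sd_x"], 0.99)
  expect_true(all(st$min_x <= st$mean_x & st$mean_x <= st$max_x))
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("class,mean_x", bad)
  expect_error(posture_stats(bad), "lacks column")
})

test_that("CM sampling reproduces the stated cluster statistics", {
  st <- posture_stats()
  p1 <- gen_cm_samples(st, "P1", 10000, seed = 100)
  expect_lt(abs(mean(p1$CMx) - 15.25), 0.02)
  expect_lt(abs(mean(p1$CMy) - 3.20), 0.04)
  p6 <- gen_cm_samples(st, "P6", 10000, seed = 101)
  expect_lt(abs(sd(p6$CMx) - 0.99), 0.03)
  expect_error(gen_cm_samples(st, "P9", 5), "unknown class")
  one <- gen_cm_samples(st, "P2", 1, seed = 55)
  expect_identical(one, gen_cm_samples(st, "P2", 1, seed = 55))
})

test_that("per-class generated moments sit within 4 SE of the table", {
  st <- posture_stats()
  n <- 4000
  for (cl in c("P1", "P3", "P5", "P7")) {
    s <- gen_cm_samples(st, cl, n, seed = 7)
    expect_lt(abs(mean(s$CMx) - st[cl, "mean_x"]),
              4 * st[cl, "sd_x"] / sqrt(n))
    expect_lt(abs(mean(s$CMy) - st[cl, "mean_y"]),
              4 * st[cl, "sd_y"] / sqrt(n))
    expect_lt(abs(sd(s$CMx) - st[cl, "sd_x"]),
              4 * st[cl, "sd_x"] / sqrt(2 * (n - 1)))
  }
})

test_that("truncated sampling respects the class box", {
  st <- posture_stats()
  s <- gen_cm_samples(st, "P7", 3000, seed = 9, truncate = TRUE)
  expect_true(all(s$CMx >= st["P7", "min_x"] & s$CMx <= st["P7", "max_x"]))
  expect_true(all(s$CMy >= st["P7", "min_y"] & s$CMy <= st["P7", "max_y"]))
})

test_that("invert_cm inverts compute_cm exactly", {
  g <- chair_geometry()
  w <- invert_cm(15.15, 8.70, 60000, g)
  expect_equal(unlist(w, use.names = FALSE), rep(20000, 3))
  origin <- invert_cm(0, 0, 60000, g)
  expect_equal(origin$RB, 60000)
  expect_error(invert_cm(30, 25, 60000, g), "triangle")

  set.seed(19)
  lam <- matrix(rexp(3000), ncol = 3)
  lam <- lam / rowSums(lam)  # uniform-ish barycentric interior points
  x <- lam[, 2] * g$dRL + lam[, 1] * g$dRF
  y <- lam[, 1] * g$dBF
  wi <- invert_cm(x, y, 70000, g)
  cm <- compute_cm(wi$F, wi$LB, wi$RB, g)
  expect_lt(max(abs(cm$CMx - x)), 1e-9)
  expect_lt(max(abs(cm$CMy - y)), 1e-9)
  expect_true(all(abs(wi$F + wi$LB + wi$RB - 70000) < 1e-9))
})

test_that("posture sessions conserve weight and are deterministic", {
  plan <- session_plan(c("P1", "P5"), duration_s = 15, noise_sd_g = 25,
                       seed = 4)
  a <- gen_posture_session(plan, fs = 20)
  b <- gen_posture_session(plan, fs = 20)
  expect_identical(a$stream$channels, b$stream$channels)
  tot <- a$stream$channels$F_g + a$stream$channels$LB_g +
    a$stream$channels$RB_g
  expect_true(all(abs(tot - plan$body_weight_g) < 4 * 25 * sqrt(3)))

  clean <- gen_posture_session(session_plan("P2", duration_s = 10,
                                            noise_sd_g = 0, seed = 4),
                               fs = 20)
  tot0 <- clean$stream$channels$F_g + clean$stream$channels$LB_g +
    clean$stream$channels$RB_g
  expect_lt(max(abs(tot0 - 65000)), 1e-6)
})

test_that("bout splitting reproduces generator intervals exactly", {
  cls <- c("P1", "P2", "P3", "P5", "P6", "P7", "P8")
  plan <- session_plan(cls, duration_s = 8, transition_s = 3, seed = 13)
  sess <- gen_posture_session(plan, fs = 20)
  b <- split_static_bouts(sess$stream$channels$button, cls)
  expect_equal(b$start, sess$truth$bouts$start)
  expect_equal(b$end, sess$truth$bouts$end)
  expect_equal(b$label, sess$truth$bouts$label)
})

test_that("injected spikes are exactly repaired", {
  plan <- session_plan(c("P1", "P3"), duration_s = 30, noise_sd_g = 10,
                       spike_rate = 0.01, seed = 6)
  sess <- gen_posture_session(plan, fs = 20)
  g <- chair_geometry()
  expect_gt(nrow(sess$truth$spikes), 0)
  for (ch in c("F_g", "LB_g", "RB_g")) {
    v <- sess$stream$channels[[ch]]
    hit <- sess$truth$spikes$sample[sess$truth$spikes$channel == ch]
    expect_true(all(v[hit] > g$max_capacity_g))  # injection bookkeeping
    r <- repair_extreme_outliers(v, g$max_capacity_g)
    expect_true(all(r <= g$max_capacity_g))
    expect_identical(r[-hit], v[-hit])
  }
})

test_that("synthetic ECG beat count and rate behave as specified", {
  g <- gen_ecg(fs = 500, duration_s = 60, hr_bpm = 60, seed = 1)
  expect_length(g$rpeaks, 60)
  expect_true(all(diff(g$rpeaks) == 500))  # hr_sd = 0 -> constant RR

  g75 <- gen_ecg(fs = 500, duration_s = 300, hr_bpm = 75, hr_sd = 0.04,
                 seed = 2)
  realized <- 60 * 500 / mean(diff(g75$rpeaks))
  expect_lt(abs(realized - 75), 1)

  expect_error(gen_ecg(hr_bpm = 250), "30, 220")
  expect_error(gen_ecg(fs = 100), "250")
})

test_that("artifact bursts are localized and bookkept", {
  g <- gen_ecg(fs = 500, duration_s = 60, hr_bpm = 60, seed = 3)
  none <- inject_artifacts(g$signal, burst_rate = 0, seed = 5)
  expect_identical(none$signal$samples, g$signal$samples)
  inj <- inject_artifacts(g$signal, burst_rate = 10, burst_amp = 3,
                          seed = 5)
  expect_gt(nrow(inj$bursts), 0)
  inside <- rep(FALSE, length(g$signal$samples))
  for (i in seq_len(nrow(inj$bursts))) {
    inside[inj$bursts$start[i]:inj$bursts$end[i]] <- TRUE
  }
  expect_identical(inj$signal$samples[!inside], g$signal$samples[!inside])
  expect_gt(sd(inj$signal$samples[inside] - g$signal$samples[inside]), 0.5)
})

test_that("bursts induce false positives that DBSCAN flags", {
  fx <- burst_fixture(seed = 42)
  filt <- bandpass_fir(fx$noisy)
  rp <- detect_rpeaks(filt)
  base <- match_rpeaks(fx$truth$rpeaks, rp, tol_ms = 100, fs = 500)
  expect_gt(base$FP, 0)
  beats <- segment_beats(filt, rp)
  mask <- dbscan_outliers(beats)
  inside <- vapply(beats$r_indices, function(r) {
    any(r >= fx$bursts$start & r <= fx$bursts$end)
  }, logical(1))
  if (sum(inside) >= 5) {
    expect_gte(mean(mask$flags[inside]), 0.8)
  }
})
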