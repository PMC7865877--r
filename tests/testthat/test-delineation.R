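test_that("QRS detection recovers generator beats at 60 and 120 bpm", {
  for (hr in c(60, 120)) {
    lr <- syn_rec(duration = 30, heart_rate = hr, seed = 21)
    rec <- clean_record(lr$record)
    peaks <- detect_qrs(rec)
    det_s <- (peaks - 1) / rec$sampling_rate
    truth <- lr$ground_truth$qrs_peak
    expect_lte(abs(length(peaks) - length(truth)), if (hr == 60) 1 else 2)
    m <- match_beats(det_s, truth)
    expect_gte(m$sens, 0.99)
    expect_gte(m$ppv, 0.99)
    expect_true(all(diff(peaks) >= 0.2 * rec$sampling_rate))
  }
})

test_that("QRS detection refuses silent records", {
  z <- ecg_record(rep(0, 1250))
  expect_error(detect_qrs(z), "no-signal")
  flagged <- clean_record(z)
  expect_error(detect_qrs(flagged), "no-signal")
  expect_error(detect_qrs(ecg_record(rnorm(100))), "too short")
})

test_that("delineation finds P peaks and honours the ordering invariant", {
  lr <- syn_rec(duration = 30, heart_rate = 60, seed = 22)
  rec <- clean_record(lr$record)
  fs <- rec$sampling_rate
  ann <- delineate_waves(rec, detect_qrs(rec))
  expect_lt(mean(is.na(ann$p_peak)), 0.1)
  # match beats to ground truth and compare P peak timing
  gt <- lr$ground_truth
  err <- c()
  for (i in seq_len(nrow(ann))) {
    if (is.na(ann$p_peak[i])) next
    tdet <- (ann$qrs_peak[i] - 1) / fs
    j <- which.min(abs(gt$qrs_peak - tdet))
    if (abs(gt$qrs_peak[j] - tdet) > 0.05 || is.na(gt$p_peak[j])) next
    err <- c(err, (ann$p_peak[i] - 1) / fs - gt$p_peak[j])
  }
  expect_lte(stats::median(abs(err)), 0.04)

  # ordering invariant across rhythms
  for (rhythm in c("normal_sinus", "ectopic_pvc_like", "wide_qrs_block_like",
                   "irregular_af_like")) {
    lr2 <- syn_rec(duration = 20, rhythm = rhythm, seed = 23)
    rec2 <- clean_record(lr2$record)
    a <- delineate_waves(rec2, detect_qrs(rec2))
    ok <- !is.na(a$p_offset) & !is.na(a$t_onset)
    expect_true(all(a$p_offset[ok] <= a$qrs_onset[ok]))
    expect_true(all(a$qrs_onset < a$qrs_offset))
    expect_true(all(a$qrs_offset[ok] <= a$t_onset[ok]))
    expect_true(all(diff(a$qrs_peak) > 0))
  }
})

test_that("fibrillation-like records yield absent P waves", {
  lr <- syn_rec(duration = 30, rhythm = "irregular_af_like", seed = 24)
  rec <- clean_record(lr$record)
  ann <- delineate_waves(rec, detect_qrs(rec))
  expect_gte(mean(is.na(ann$p_peak)), 0.8)
})

test_that("measurements follow the interval definitions exactly", {
  # QTc: Bazett identity at RR = 1 s, exact value at RR = 0.64 s
  fs <- 1000
  peaks <- as.integer(c(1000, 2000, 3000))
  ann <- make_annotations(fs, qrs_peak = peaks, qrs_onset = peaks - 40L,
                          t_offset = peaks - 40L + 360L)
  m <- compute_measurements(ann, fs)
  expect_equal(unname(m$summary["qt_interval_ms"]), 360)
  expect_equal(unname(m$summary["qtc_interval_ms"]), 360)

  peaks2 <- as.integer(seq(1000, by = 640, length.out = 4))
  ann2 <- make_annotations(fs, qrs_peak = peaks2, qrs_onset = peaks2 - 40L,
                           t_offset = peaks2 - 40L + 300L)
  m2 <- compute_measurements(ann2, fs)
  expect_equal(unname(m2$summary["qtc_interval_ms"]), 0.375 * 1000)

  # ventricular rate from constant RR = 0.5 s
  peaks3 <- as.integer(seq(500, by = 500, length.out = 6))
  ann3 <- make_annotations(fs, qrs_peak = peaks3, qrs_onset = peaks3 - 40L,
                           t_offset = peaks3 + 260L)
  expect_equal(unname(compute_measurements(ann3, fs)$summary["ventricular_rate_bpm"]), 120)

  # too few beats
  ann1 <- make_annotations(fs, qrs_peak = 1000L, qrs_onset = 960L, t_offset = 1320L)
  expect_error(compute_measurements(ann1, fs), "insufficient")
})

test_that("atrial rate is absent without P waves", {
  fs <- 125
  peaks <- as.integer(seq(100, by = 100, length.out = 5))
  ann <- make_annotations(fs, qrs_peak = peaks, qrs_onset = peaks - 5L,
                          t_offset = peaks + 40L)
  m <- compute_measurements(ann, fs)
  expect_true(is.na(m$summary["atrial_rate_bpm"]))
  expect_true(is.na(m$summary["pr_interval_ms"]))
})

test_that("average beat equals the single beat for perfectly periodic input", {
  fs <- 125
  beat <- c(rep(0, 30), dnorm(seq(-3, 3, length.out = 15)), rep(0, 80))
  x <- rep(beat, 10)
  rec <- ecg_record(x)
  peaks <- as.integer(30 + 8 + (0:9) * length(beat)) # apex of each copy
  avg <- compute_average_beat(rec, peaks)
  pre <- round(0.3 * fs)
  one <- x[(peaks[5] - pre):(peaks[5] + round(0.5 * fs))]
  expect_equal(avg$template, one, tolerance = 1e-12)
  expect_error(compute_average_beat(rec, peaks[1:4]), "insufficient")
})

test_that("averaging reduces additive noise as 1/sqrt(n)", {
  fs <- 125
  set.seed(99)
  beat <- c(rep(0, 38), 1.2 * exp(-((-7:7)^2) / 8), rep(0, 72))
  n_beats <- 50
  sigma <- 0.05
  x <- rep(beat, n_beats) + rnorm(length(beat) * n_beats, 0, sigma)
  peaks <- as.integer(38 + 8 + (0:(n_beats - 1)) * length(beat))
  avg <- compute_average_beat(ecg_record(x), peaks)
  pre <- round(0.3 * fs)
  clean <- rep(beat, 3)[(length(beat) + peaks[1] - pre):(length(beat) + peaks[1] + round(0.5 * fs))]
  expect_lte(rms(avg$template - clean), 3 * sigma / sqrt(n_beats))
})

test_that("HRV statistics match definitions and a brute-force recomputation", {
  fs <- 125
  const <- as.integer(seq(100, by = 100, length.out = 10))
  h <- compute_hrv(const, fs)
  expect_equal(h$sdnn, 0)
  expect_equal(h$rmssd, 0)
  expect_equal(h$pnn50, 0)
  expect_equal(h$n_intervals, 9)

  # alternating 0.8 / 0.6 s
  rr <- rep(c(0.8, 0.6), 10)
  peaks <- as.integer(round(cumsum(c(1, rr)) * fs))
  h2 <- compute_hrv(peaks, fs)
  expect_equal(h2$rmssd, 0.2, tolerance = 1e-9)
  expect_equal(h2$pnn50, 1.0)

  # property: brute-force recomputation from the RR sequence
  set.seed(7)
  for (k in 1:5) {
    peaks <- sort(sample.int(100000, 50))
    h3 <- compute_hrv(peaks, 1000)
    rr <- diff(peaks) / 1000
    expect_equal(h3$sdnn, sqrt(sum((rr - mean(rr))^2) / (length(rr) - 1)), tolerance = 1e-9)
    expect_equal(h3$rmssd, sqrt(mean(diff(rr)^2)), tolerance = 1e-9)
    expect_equal(h3$pnn50, mean(abs(diff(rr)) > 0.05), tolerance = 1e-12)
    expect_equal(h3$mean_rr, mean(rr), tolerance = 1e-12)
  }
  expect_error(compute_hrv(c(1L, 500L), fs), "insufficient")
})

test_that("HRV recovers the dispersion of a known RR distribution", {
  set.seed(42)
  rr <- rnorm(300, 0.8, 0.05)
  peaks <- as.integer(round(cumsum(c(1, rr)) * 1000))
  h <- compute_hrv(peaks, 1000)
  expect_gte(h$sdnn, 0.04)
  expect_lte(h$sdnn, 0.06)
})

test_that("RR scatter pairs consecutive intervals", {
  fs <- 125
  peaks <- as.integer(c(0, 1, 2, 3) * fs + 1)
  sc <- rr_scatter(peaks, fs)
  expect_equal(nrow(sc), 2)
  expect_equal(sc$rr_s, c(1, 1))
  expect_equal(sc$rr_next_s, c(1, 1))

  peaks2 <- as.integer(seq(1, by = 75, length.out = 12))
  sc2 <- rr_scatter(peaks2, fs)
  expect_equal(nrow(sc2), length(peaks2) - 2)
  expect_true(all(sc2$rr_s == sc2$rr_next_s)) # constant RR: on the diagonal
  expect_error(rr_scatter(peaks2[1:2], fs), "insufficient")
})
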