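# Simulator contracts: template bounds, determinism, beat timing, label
# consistency, windowing shapes, and the learnability properties of the
# morphology coupling.

test_that("noiseless uncoupled records hit the exact SBP/DBP bounds", {
  cfg <- sim_config(n_subjects = 2, duration_s = 10, fs = 125,
                    hr_range = c(60, 60), sbp_range = c(120, 120),
                    dbp_range = c(80, 80), noise_sd = 0,
                    coupling_strength = 0)
  rec <- simulate_record(cfg, 1)
  expect_true(all(rec$abp >= 80 - 1e-9 & rec$abp <= 120 + 1e-9))
  ex <- extract_sbp_dbp(rec$abp, rec$beat_onsets)
  expect_equal(unique(ex$sbp), 120)
  expect_equal(unique(ex$dbp), 80)
})

test_that("records are bit-identical for the same (seed, subject) and differ across subjects", {
  cfg <- sim_config(n_subjects = 3, duration_s = 12, fs = 50, seed = 42)
  r1 <- simulate_record(cfg, 2)
  r2 <- simulate_record(cfg, 2)
  expect_identical(r1, r2)
  # order independence: generating subject 1 first must not change subject 2
  invisible(simulate_record(cfg, 1))
  expect_identical(simulate_record(cfg, 2), r1)
  expect_false(identical(simulate_record(cfg, 1), r1))
})

test_that("beat onsets match the configured heart rate", {
  cfg <- sim_config(n_subjects = 1, duration_s = 10, fs = 125,
                    hr_range = c(60, 60))
  rec <- simulate_record(cfg, 1)
  # duration * hr / 60 = 10 beats; spacing fs * 60/hr = 125 samples
  expect_length(rec$beat_onsets, 10L)
  expect_true(all(abs(diff(rec$beat_onsets) - 125) <= 1))
})

test_that("per-beat labels are recovered from the noiseless ABP", {
  cfg <- sim_config(n_subjects = 4, duration_s = 30, fs = 125, noise_sd = 0,
                    coupling_strength = 1, seed = 5)
  for (s in 1:4) {
    rec <- simulate_record(cfg, s)
    ex <- extract_sbp_dbp(rec$abp, rec$beat_onsets)
    k <- length(ex$sbp)
    expect_true(max(abs(ex$sbp - rec$sbp_per_beat[seq_len(k)])) < 0.5)
    expect_true(max(abs(ex$dbp - rec$dbp_per_beat[seq_len(k)])) < 0.5)
    expect_true(all(rec$sbp_per_beat > rec$dbp_per_beat))
  }
})

test_that("extract_sbp_dbp handles analytic and degenerate waveforms", {
  expect_equal(extract_sbp_dbp(rep(100, 20), c(1, 11))$sbp, 100)
  expect_equal(extract_sbp_dbp(rep(100, 20), c(1, 11))$dbp, 100)
  # one full sine cycle per beat: max 120, min 80
  t <- seq(0, 1, length.out = 101)[-101]
  wave <- 100 + 20 * sin(2 * pi * t)
  ex <- extract_sbp_dbp(c(wave, wave), c(1L, 101L, 200L))
  expect_equal(ex$sbp[1], max(wave))
  expect_equal(ex$dbp[1], min(wave))
  expect_equal(max(wave), 120, tolerance = 1e-3)
  expect_equal(min(wave), 80, tolerance = 1e-3)
  expect_true(all(ex$sbp >= ex$dbp))
  expect_error(extract_sbp_dbp(wave, 1L),
               class = "pg_insufficient_beats_error")
})

test_that("invalid configurations name the violated field", {
  expect_error(sim_config(fs = -1), class = "pg_config_error")
  expect_error(sim_config(sbp_range = c(100, 90)), class = "pg_config_error")
  expect_error(sim_config(coupling_strength = 2), class = "pg_config_error")
  err <- tryCatch(sim_config(sbp_range = c(80, 120), dbp_range = c(60, 90)),
                  error = identity)
  expect_match(conditionMessage(err), "sbp_range")
  cfg <- sim_config(n_subjects = 2)
  expect_error(simulate_record(cfg, 3), class = "pg_config_error")
})

test_that("make_dataset emits the expected window counts and shapes", {
  cfg <- sim_config(n_subjects = 2, duration_s = 10, fs = 50, seed = 3)
  d1 <- make_dataset(cfg, window_s = 10, stride_s = 10)
  expect_equal(nrow(d1$ppg), 2L)                  # 1 window per subject
  d2 <- make_dataset(cfg, window_s = 5, stride_s = 5)
  expect_equal(nrow(d2$ppg), 4L)                  # 2 windows per subject
  expect_true(all(ncol(d2$ppg) == 5 * 50, ncol(d2$ecg) == 5 * 50,
                  ncol(d2$abp) == 5 * 50))
  expect_error(make_dataset(cfg, 5, 0), class = "pg_config_error")
  expect_error(make_dataset(cfg, 20, 5), class = "pg_config_error")
  # determinism end to end
  expect_identical(make_dataset(cfg, 5, 5), d2)
})

test_that("coupling controls whether inputs carry BP information", {
  make <- function(coupling, noise) {
    cfg <- sim_config(n_subjects = 8, duration_s = 56, fs = 50,
                      noise_sd = noise, coupling_strength = coupling,
                      seed = 31)
    make_dataset(cfg, 4, 2)
  }
  # full coupling, no noise: nearest neighbour on held-out windows of seen
  # subjects pins BP from morphology alone
  ds <- make(coupling = 1, noise = 0)
  n <- nrow(ds$ppg)
  expect_gte(n, 200)
  test <- seq(1, n, by = 4)
  train <- setdiff(seq_len(n), test)
  d <- as.matrix(dist(ds$ppg))
  nn <- train[apply(d[test, train], 1, which.min)]
  expect_lt(mean(abs(ds$sbp[nn] - ds$sbp[test])), 5)

  # no coupling: across subjects the inputs carry no BP information, so
  # nearest neighbour cannot beat the mean predictor (within-subject splits
  # would leak subject identity through heart rate, hence the subject-wise
  # evaluation here)
  ds0 <- make(coupling = 0, noise = 0.05)
  d0 <- as.matrix(dist(ds0$ppg))
  errs <- sapply(unique(ds0$subject), function(s) {
    te <- which(ds0$subject == s)
    tr <- which(ds0$subject != s)
    nn <- tr[apply(d0[te, tr, drop = FALSE], 1, which.min)]
    c(nn = mean(abs(ds0$sbp[nn] - ds0$sbp[te])),
      mean = mean(abs(mean(ds0$sbp[tr]) - ds0$sbp[te])))
  })
  expect_gt(mean(errs["nn", ]), mean(errs["mean", ]) * 0.9)
})

test_that("ECG R-peaks precede the pulse with a BP-dependent lag", {
  cfg <- sim_config(n_subjects = 1, duration_s = 30, fs = 125, noise_sd = 0,
                    coupling_strength = 1, seed = 9)
  rec <- simulate_record(cfg, 1)
  peaks <- which(rec$ecg == 1)
  expect_gt(length(peaks), 10)
  # each peak sits before a beat onset by under 0.5 s
  lags <- vapply(peaks, function(p) {
    nxt <- rec$beat_onsets[rec$beat_onsets >= p][1]
    (nxt - p) / rec$fs
  }, 1.0)
  expect_true(all(lags >= 0 & lags < 0.5))
})
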