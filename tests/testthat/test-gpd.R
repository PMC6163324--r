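test_that("GPD finds one peak per stride at a mid-range threshold", {
  # swings only: with stance-pivot humps disabled every peak is a stride
  sim <- clean_sim("flat", 10, seed = 8, stance_rot_range = c(0, 0))
  fs <- sim$recording$sample_rate_hz
  gf <- lowpass(sim$recording$gyro_ap, filter_spec(6, 8, fs))
  thr <- 0.5 * mean_peak_amplitude(sim$recording)
  pk <- gpd_detect(gf, thr, fs)
  ref <- cycle_times(sim$truth, "ps")
  expect_length(pk, 10)
  expect_true(all(vapply(ref, function(p) min(abs((pk - 1) / fs - p)) < 0.05,
                         logical(1))))
  expect_length(gpd_detect(gf, max(gf) * 1.01, fs), 0)
  expect_error(gpd_detect(gf, -1, fs), "positive")
})

test_that("calibration follows its definitions on constructed recordings", {
  # synthetic gyro with peaks of exactly known amplitude
  mk <- function(A, n = 8, fs = 231) {
    tt <- (0:(round(n * 1.2 * fs) - 1)) / fs
    g <- rep(0, length(tt))
    for (k in seq_len(n)) {
      i <- tt > (k - 1) * 1.2 + 0.3 & tt < (k - 1) * 1.2 + 0.7
      g[i] <- A * sin(pi * (tt[i] - (k - 1) * 1.2 - 0.3) / 0.4)
    }
    cane_recording(rep(0, length(tt)), g, fs)
  }
  # lowpass barely touches these smooth lobes, so means are ~exact
  thr <- calibrate_threshold(gpd_policy("IFS", 0.5), list(mk(80)))
  expect_equal(thr, 40, tolerance = 0.02 * 40)
  thr_u <- calibrate_threshold(gpd_policy("U", 0.5), list(mk(80), mk(40)))
  expect_equal(thr_u, 0.5 * (80 + 40) / 2, tolerance = 0.02 * 30)
  expect_error(calibrate_threshold(gpd_policy("U"), list()), "empty")
  expect_error(calibrate_threshold(gpd_policy("O"), list(mk(80))),
               "annotations")
})

test_that("the oracle policy reaches F1 = 1 on a clean recording", {
  # swings only: stance-pivot humps off, so a threshold can be perfect
  sim <- clean_sim("flat", 12, seed = 13, stance_rot_range = c(0, 0))
  thr <- calibrate_threshold(gpd_policy("O"), list(sim$recording), sim$truth)
  cyc <- gpd_cycles(sim$recording, thr)
  cnt <- classify_strides(cyc, sim$truth, on = "ps")
  expect_equal(unname(cnt[c("tp", "fp", "fn")]), c(12L, 0L, 0L))
})

test_that("threshold sweep rates are monotone as the fraction falls", {
  sim <- simulate_recording(sim_config(
    segments = list(list(terrain = "flat", n_strides = 10),
                    list(terrain = "upstairs", n_strides = 8)),
    artifact_rates = default_artifacts, seed = 37))
  roc <- threshold_sweep(list(sim$recording), list(sim$truth))
  expect_equal(roc$fraction, seq(0.8, 0.2, by = -0.05))
  expect_false(is.unsorted(roc$tpr))
  expect_false(is.unsorted(roc$fpr))
  expect_true(all(roc$tpr >= 0 & roc$tpr <= 1))
})

test_that("a flat-calibrated threshold misses reduced stair swings", {
  sim <- simulate_recording(sim_config(
    segments = list(list(terrain = "flat", n_strides = 10),
                    list(terrain = "upstairs", n_strides = 10)),
    seed = 19))
  flat <- simulate_recording(sim_config(seed = 1019))
  thr <- calibrate_threshold(gpd_policy("IFS", 0.5), list(flat$recording))
  gps <- cycle_times(gpd_cycles(sim$recording, thr), "ps")
  tdf <- cycles_df(sim$truth)
  stair_ps <- tdf$ps_s[tdf$valid & tdf$terrain == "upstairs"]
  missed <- sum(vapply(stair_ps,
                       function(p) all(abs(gps - p) > 0.5), logical(1)))
  expect_gte(missed, 1)
  # the multi-sensor segmenter keeps them all
  expect_equal(recall_of(segment_msmf(sim$recording, flat_template),
                         sim$truth), 1)
})

test_that("GPD is amplitude sensitive where the matched filter is not", {
  sim <- clean_sim("flat", 10, seed = 8)
  thr <- 0.5 * mean_peak_amplitude(sim$recording)
  n_base <- length(gpd_cycles(sim$recording, thr))
  r2 <- sim$recording
  r2$gyro_ap <- r2$gyro_ap * 0.4
  expect_lt(length(gpd_cycles(r2, thr)), n_base)
})

test_that("per-terrain oracle detections stay in time order", {
  sim <- simulate_recording(sim_config(
    segments = list(list(terrain = "flat", n_strides = 8),
                    list(terrain = "upstairs", n_strides = 8)),
    seed = 53))
  cyc <- gpd_oracle_cycles(sim$recording, sim$truth)
  ps <- cycle_times(cyc, "ps")
  expect_false(is.unsorted(ps))
  expect_gte(length(ps), 14)
})
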