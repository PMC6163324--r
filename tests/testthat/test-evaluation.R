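mk_cycle <- function(ic, valid = TRUE, terrain = "flat") {
  gait_cycle(ic, ic + 0.6, ic + 0.85, ic + 1.1, valid = valid,
             terrain = terrain, check = FALSE)
}

test_that("classification counts behave on identity and deletion", {
  ref <- annotation_set(c(lapply(c(0, 1.1, 2.2, 3.3), mk_cycle),
                          list(mk_cycle(4.4, valid = FALSE))))
  det <- lapply(c(0, 1.1, 2.2, 3.3), mk_cycle)
  expect_equal(classify_strides(det, ref),
               c(tp = 4L, tn = 1L, fp = 0L, fn = 0L))
  expect_equal(classify_strides(det[-2], ref)[["fn"]], 1L)
  extra <- c(det, list(mk_cycle(7.7)))
  expect_equal(classify_strides(extra, ref)[["fp"]], 1L)
})

test_that("greedy matching equals the exhaustive bipartite oracle", {
  set.seed(61)
  for (rep in 1:6) {
    sim <- simulate_recording(sim_config(
      segments = list(list(terrain = "flat", n_strides = 8)),
      artifact_rates = default_artifacts, seed = 100 + rep))
    cyc <- segment_msmf(sim$recording, flat_template)
    cnt <- classify_strides(cyc, sim$truth)
    det <- cycle_times(cyc, "ic")
    ref <- cycle_times(sim$truth, "ic")
    expect_equal(unname(cnt["tp"]),
                 max_bipartite_matches(det, ref, 0.5))
  }
})

test_that("classification is invariant to uniform time translation", {
  ref_t <- c(0, 1.1, 2.2, 3.3)
  det_t <- c(0.05, 1.2, 3.25)
  shift <- 17.3
  a <- classify_strides(lapply(det_t, mk_cycle),
                        annotation_set(lapply(ref_t, mk_cycle)))
  b <- classify_strides(lapply(det_t + shift, mk_cycle),
                        annotation_set(lapply(ref_t + shift, mk_cycle)))
  expect_identical(a, b)
})

test_that("stride variability matches hand computation and needs 3 cycles", {
  ps <- cumsum(c(0.9, 1.0, 1.2, 1.0, 1.2))
  cyc <- lapply(ps, function(p)
    gait_cycle(p - 0.85, p - 0.25, p, p + 0.25, TRUE, check = FALSE))
  expect_equal(stride_variability(cyc), stats::var(c(1.0, 1.2, 1.0, 1.2)))
  # perfectly periodic strides have zero variability
  per <- lapply(seq(0, 8.8, by = 1.1), mk_cycle)
  expect_equal(stride_variability(per), 0)
  expect_error(stride_variability(per[1:2]),
               class = "canegait_insufficient_cycles")
})

test_that("intervals across standstills are bout boundaries, not strides", {
  ps <- c(1, 2.1, 3.2, 10, 11.1, 12.2)   # 6.8 s standstill in the middle
  cyc <- lapply(ps, function(p)
    gait_cycle(p - 0.85, p - 0.25, p, p + 0.25, TRUE, check = FALSE))
  expect_equal(stride_variability(cyc), stats::var(rep(1.1, 4)))
})

test_that("recovered interval variance tracks the configured spread", {
  v <- vapply(1:8, function(s) {
    sim <- simulate_recording(sim_config(
      segments = list(list(terrain = "flat", n_strides = 50)),
      seed = 700 + s))
    stride_variability(segment_msmf(sim$recording, flat_template))
  }, numeric(1))
  expect_equal(mean(v), 0.05^2, tolerance = 0.25)
})

test_that("timing errors follow the switch sign convention exactly", {
  fs <- 100
  sw <- rep(0, 1000)
  sw[201:300] <- 1   # closes at sample 201 (2.00 s), opens at 301 (3.00 s)
  cyc <- list(gait_cycle(2.00, 3.00, 3.4, 3.8, TRUE, check = FALSE))
  te <- timing_errors(cyc, sw, fs)
  expect_equal(te$ic_ms, 0)
  expect_equal(te$tc_ms, 0)
  # detecting everything 20 ms later shifts both errors by -20 ms
  cyc2 <- list(gait_cycle(2.02, 3.02, 3.42, 3.82, TRUE, check = FALSE))
  te2 <- timing_errors(cyc2, sw, fs)
  expect_equal(te2$ic_ms, -20, tolerance = 1e-6)
  expect_equal(te2$tc_ms, -20, tolerance = 1e-6)
  # a cycle with no nearby transition is skipped with a warning
  cyc3 <- c(cyc, list(gait_cycle(7, 7.6, 7.9, 8.1, TRUE, check = FALSE)))
  expect_warning(timing_errors(cyc3, sw, fs), "skipped")
})

test_that("the simulated switch makes strain-based IC detection early", {
  sim <- simulate_recording(sim_config(
    segments = list(list(terrain = "flat", n_strides = 15)), seed = 73))
  cyc <- segment_msmf(sim$recording, flat_template)
  te <- timing_errors(cyc, sim$recording$switch,
                      sim$recording$sample_rate_hz)
  # switch needs substantial load: it closes after the zero-crossing IC
  expect_gt(mean(te$ic_ms), 0)
  # and it opens before loading fully ends
  expect_lt(mean(te$tc_ms), 0)
})

test_that("evaluation reports assemble counts, variance and per-terrain", {
  sim <- simulate_recording(sim_config(
    segments = list(list(terrain = "flat", n_strides = 8),
                    list(terrain = "upstairs", n_strides = 8)),
    seed = 83))
  cyc <- segment_msmf(sim$recording, flat_template)
  rep <- eval_report(cyc, sim$truth, recording = sim$recording)
  expect_s3_class(rep, "cane_eval_report")
  expect_equal(sum(rep$counts), length(cycles_df(sim$truth)$valid))
  expect_true(is.finite(rep$stride_variance_s2))
  expect_named(rep$per_terrain, c("flat", "upstairs"))
  expect_output(print(rep), "strides: TP")
})
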