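test_that("clean flat walking is segmented perfectly with tight timing", {
  sim <- clean_sim("flat", 20, seed = 2)
  cyc <- segment_msmf(sim$recording, flat_template)
  df <- cycles_df(cyc)
  expect_equal(sum(df$valid), 20)
  rep <- eval_report(cyc, sim$truth)
  expect_equal(rep$recall, 1)
  expect_equal(rep$precision, 1)
  expect_lte(max_truth_error_ms(cyc, sim$truth, "ic"), 15)
  expect_lte(max_truth_error_ms(cyc, sim$truth, "tc"), 15)
})

test_that("all-zero channels yield no cycles", {
  rec <- cane_recording(rep(0, 3000), rep(0, 3000), 231)
  expect_length(segment_msmf(rec, flat_template), 0)
})

test_that("a loading hold without swing never becomes a valid cycle", {
  sim <- simulate_recording(sim_config(
    segments = list(list(terrain = "flat", n_strides = 15)),
    artifact_rates = c(load_without_swing = 0.3, swing_without_load = 0,
                      pause = 0),
    seed = 31))
  tdf <- cycles_df(sim$truth)
  expect_gt(sum(!tdf$valid), 0)   # at least one hold was injected
  cyc <- segment_msmf(sim$recording, flat_template)
  rep <- eval_report(cyc, sim$truth)
  expect_equal(unname(rep$counts["fp"]), 0L)
  # every detected valid IC sits near a truth-valid IC, never inside a hold
  dv <- cycles_df(cyc); dv <- dv[dv$valid, ]
  ref_ic <- tdf$ic_s[tdf$valid]
  expect_true(all(vapply(dv$ic_s, function(x) min(abs(ref_ic - x)) < 0.1,
                         logical(1))))
})

test_that("halved stair swing amplitude does not cost the segmenter recall", {
  cfg <- sim_config(segments = list(list(terrain = "flat", n_strides = 10),
                                    list(terrain = "upstairs",
                                         n_strides = 10)),
                    seed = 17)
  sim <- simulate_recording(cfg)
  cyc <- segment_msmf(sim$recording, flat_template)
  expect_equal(recall_of(cyc, sim$truth), 1)
})

test_that("segmentation is invariant to positive channel rescaling", {
  cfg <- sim_config(segments = list(list(terrain = "flat", n_strides = 8),
                                    list(terrain = "downstairs",
                                         n_strides = 6)),
                    seed = 23)
  sim <- simulate_recording(cfg)
  base <- cycles_df(segment_msmf(sim$recording, flat_template))
  for (scale in list(c(4.2, 1), c(1, 0.25), c(0.3, 12))) {
    r2 <- sim$recording
    r2$strain <- r2$strain * scale[1]
    r2$gyro_ap <- r2$gyro_ap * scale[2]
    out <- cycles_df(segment_msmf(r2, flat_template))
    expect_identical(out[c("ic_s", "tc_s", "ps_s", "ec_s", "valid")],
                     base[c("ic_s", "tc_s", "ps_s", "ec_s", "valid")])
    expect_equal(out$similarity, base$similarity, tolerance = 1e-6)
  }
})

test_that("segmentation is deterministic and cycles are well ordered", {
  sim <- simulate_recording(sim_config(
    segments = list(list(terrain = "flat", n_strides = 12)),
    artifact_rates = default_artifacts, seed = 29))
  a <- segment_msmf(sim$recording, flat_template)
  b <- segment_msmf(sim$recording, flat_template)
  expect_identical(cycles_df(a), cycles_df(b))
  df <- cycles_df(a)
  expect_false(is.unsorted(df$ic_s))
  dv <- df[df$valid, ]
  expect_true(all(dv$ic_s < dv$tc_s & dv$tc_s < dv$ps_s & dv$ps_s < dv$ec_s))
  expect_true(all(dv$ec_s - dv$ic_s <= 3 + 1e-9))
  # loading phases of consecutive valid cycles never overlap
  if (nrow(dv) > 1)
    expect_true(all(dv$ic_s[-1] >= dv$tc_s[-nrow(dv)]))
})

test_that("recall stays high under default sensor noise", {
  rec <- vapply(1:5, function(s) {
    sim <- simulate_recording(sim_config(
      segments = list(list(terrain = "flat", n_strides = 15)), seed = 40 + s))
    recall_of(segment_msmf(sim$recording, flat_template), sim$truth)
  }, numeric(1))
  expect_gte(mean(rec), 0.98)
})

test_that("sample-rate mismatch between template and recording errors", {
  sim <- clean_sim("flat", 3, seed = 2)
  tmpl100 <- stride_template(flat_template$values, sample_rate_hz = 100)
  expect_error(segment_msmf(sim$recording, tmpl100), "sample rate")
})
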