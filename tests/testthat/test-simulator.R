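test_that("a single clean stride has exactly the advertised events", {
  st <- make_stride(terrain_profile("flat"))
  expect_length(positive_zero_crossings(st$strain), 1)
  expect_length(negative_zero_crossings(st$strain), 1)
  expect_length(rate_reversals(st$gyro_ap), 1)
  tr <- st$truth
  expect_true(tr$ic$time_s < tr$tc$time_s &&
                tr$tc$time_s < tr$ps$time_s &&
                tr$ps$time_s < tr$ec$time_s)
  # the crossing samples sit at the generative IC/TC instants
  fs <- st$sample_rate_hz
  expect_lte(abs((positive_zero_crossings(st$strain) - 1) / fs -
                   tr$ic$time_s), 1.5 / fs)
  expect_lte(abs((negative_zero_crossings(st$strain) - 1) / fs -
                   tr$tc$time_s), 1.5 / fs)
})

test_that("terrain parameters echo into the waveforms", {
  up <- make_stride(terrain_profile("upstairs"))
  fl <- make_stride(terrain_profile("flat"))
  expect_equal(max(up$gyro_ap) / max(fl$gyro_ap), 50 / 100,
               tolerance = 0.02)
  expect_equal(max(up$strain) + 0.15, 1.2, tolerance = 0.02)
})

test_that("truth ordering holds across a sweep of random profiles", {
  set.seed(97)
  for (i in 1:2000) {
    pr <- terrain_profile("custom",
                          load_amp = runif(1, 0.3, 3),
                          swing_amp_dps = runif(1, 20, 200),
                          stride_period_mean_s = runif(1, 0.7, 2.2),
                          stride_period_sd_s = runif(1, 0, 0.1),
                          load_duty = runif(1, 0.35, 0.75),
                          swing_cv = 0.1)
    Tn <- pr$stride_period_mean_s
    L <- pr$load_duty * Tn
    tr <- make_stride(pr)$truth
    tt <- c(tr$ic$time_s, tr$tc$time_s, tr$ps$time_s, tr$ec$time_s)
    expect_true(all(diff(tt) > 0))
    expect_lte(tr$ec$time_s - tr$ic$time_s, 3)
  }
})

test_that("simulation is bitwise deterministic under a fixed seed", {
  cfg <- sim_config(segments = list(list(terrain = "flat", n_strides = 6),
                                    list(terrain = "uphill", n_strides = 5)),
                    artifact_rates = default_artifacts, seed = 123)
  a <- simulate_recording(cfg)
  b <- simulate_recording(cfg)
  expect_identical(a$recording$strain, b$recording$strain)
  expect_identical(a$recording$gyro_ap, b$recording$gyro_ap)
  expect_identical(cycles_df(a$truth), cycles_df(b$truth))
})

test_that("truth cycles respect ordering, windows and terrain labels", {
  sim <- simulate_recording(sim_config(
    segments = list(list(terrain = "flat", n_strides = 10),
                    list(terrain = "downstairs", n_strides = 10)),
    artifact_rates = c(load_without_swing = 0.1, swing_without_load = 0.1,
                      pause = 0.1),
    seed = 131))
  df <- cycles_df(sim$truth)
  dv <- df[df$valid, ]
  expect_true(all(dv$ic_s < dv$tc_s & dv$tc_s < dv$ps_s & dv$ps_s < dv$ec_s))
  expect_true(all(dv$ec_s - dv$ic_s <= 3))
  expect_setequal(unique(df$terrain), c("flat", "downstairs"))
})

test_that("the switch closes after IC and opens before EC", {
  sim <- clean_sim("flat", 12, seed = 7)
  fs <- sim$recording$sample_rate_hz
  closes <- (which(diff(sim$recording$switch) == 1)) / fs
  opens <- (which(diff(sim$recording$switch) == -1)) / fs
  df <- cycles_df(sim$truth)
  for (i in seq_len(nrow(df))) {
    cl <- closes[which.min(abs(closes - df$ic_s[i]))]
    expect_gt(cl, df$ic_s[i])
    op <- opens[which.min(abs(opens - df$tc_s[i]))]
    expect_lt(op, df$tc_s[i])
    expect_lt(op, df$ec_s[i])
  }
})

test_that("the flat template generalizes across terrains but not to noise", {
  # self-similarity
  st <- make_stride(terrain_profile("flat"))
  r <- correlate_template(flat_template, st$strain)
  expect_gte(max(r), 0.999)
  # stair strides share the shape family: still above the 50% gate
  up <- make_stride(terrain_profile("upstairs"))
  expect_gte(max(correlate_template(flat_template, up$strain)), 0.5)
  # pure noise never clears the gate
  set.seed(201)
  worst <- max(vapply(1:100, function(i)
    max(correlate_template(flat_template, rnorm(800))), numeric(1)))
  expect_lt(worst, 0.5)
})

test_that("empirical stride-interval variance converges to the configured one", {
  sim <- simulate_recording(sim_config(
    segments = list(list(terrain = "flat", n_strides = 500)), seed = 211))
  iv <- diff(cycle_times(sim$truth, "ps"))
  expect_equal(var(iv), 0.05^2, tolerance = 0.15)
})

test_that("scenario presets cover the seven study walks", {
  expect_length(scenario_names(), 7)
  for (sc in scenario_names()) {
    cfg <- scenario_config(sc, 18)
    expect_s3_class(cfg, "sim_config")
    expect_equal(sum(vapply(cfg$segments, function(sg) sg$n_strides,
                            integer(1))), 18)
  }
  expect_error(scenario_config("moon"), "unknown")
})
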