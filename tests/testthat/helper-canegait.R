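# shared fixtures and independent oracles, built in code at test time

flat_template <- make_template()

# per-window Pearson correlation, computed independently of the package's
# running-sum implementation
pearson_oracle <- function(h, x) {
  m <- length(h)
  vapply(seq_len(length(x) - m + 1), function(k) {
    w <- x[k:(k + m - 1)]
    if (stats::sd(w) == 0 || stats::sd(h) == 0) return(0)
    stats::cor(w, h)
  }, numeric(1))
}

# exhaustive maximum bipartite matching between detected and reference
# event times (small instances only)
max_bipartite_matches <- function(det, ref, tol) {
  if (!length(det) || !length(ref)) return(0L)
  best <- max_bipartite_matches(det[-1], ref, tol)
  for (j in seq_along(ref))
    if (abs(det[1] - ref[j]) <= tol)
      best <- max(best, 1L + max_bipartite_matches(det[-1], ref[-j], tol))
  best
}

# noise-free single-terrain walk
clean_sim <- function(terrain = "flat", n = 20, seed = 1, ...) {
  simulate_recording(sim_config(
    segments = list(list(terrain = terrain, n_strides = n)),
    noise_sd = c(strain = 0, gyro_ap = 0), seed = seed, ...))
}

default_artifacts <- c(load_without_swing = 0.02, swing_without_load = 0.02,
                       pause = 0.02)

recall_of <- function(cycles, truth) eval_report(cycles, truth)$recall

max_truth_error_ms <- function(cycles, truth, kind) {
  det <- cycle_times(cycles, kind)
  ref <- cycle_times(truth, kind)
  max(vapply(det, function(x) min(abs(ref - x)), numeric(1))) * 1000
}
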