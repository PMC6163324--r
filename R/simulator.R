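#' Terrain profile
#'
#' Generative parameters of one walking terrain: mean peak cane load (strain
#' units), mean peak-swing AP velocity (degrees/s), stride period mean/SD
#' (seconds) and the loading-phase duty fraction of the cycle. Swing
#' amplitude falls substantially on stairs relative to level walking, which
#' is the behaviour that defeats amplitude-thresholding segmenters; stair
#' strides are also slower and spend a larger fraction of the cycle loaded.
#'
#' Named presets (`flat`, `upstairs`, `downstairs`, `uphill`, `downhill`)
#' are read from the versioned table shipped at
#' `inst/extdata/terrain_profiles.json`; any field can be overridden.
#'
#' @param name Preset name, or any label when all numeric fields are given.
#' @param load_amp Mean peak load (strain units).
#' @param swing_amp_dps Mean PS amplitude (degrees/s).
#' @param stride_period_mean_s,stride_period_sd_s Stride period mean and SD.
#' @param load_duty Loading-phase fraction of the cycle, in (0, 1).
#' @param swing_cv Stride-to-stride coefficient of variation of swing
#'   amplitude. Stair swings are short and hesitant, hence far more
#'   variable than level-ground swings.
#' @return An object of class `terrain_profile`.
#' @export
terrain_profile <- function(name = "flat", load_amp = NULL,
                            swing_amp_dps = NULL,
                            stride_period_mean_s = NULL,
                            stride_period_sd_s = NULL, load_duty = NULL,
                            swing_cv = NULL) {
  presets <- terrain_presets()
  base <- presets[[name]]
  p <- list(name = name,
            load_amp = load_amp %||% base$load_amp,
            swing_amp_dps = swing_amp_dps %||% base$swing_amp_dps,
            stride_period_mean_s = stride_period_mean_s %||%
              base$stride_period_mean_s,
            stride_period_sd_s = stride_period_sd_s %||%
              base$stride_period_sd_s,
            load_duty = load_duty %||% base$load_duty,
            swing_cv = swing_cv %||% base$swing_cv %||% 0.12)
  if (any(vapply(p[-1], is.null, logical(1))))
    stop("unknown terrain '", name, "' and not all parameters supplied")
  if (p$load_amp <= 0 || p$swing_amp_dps <= 0 ||
      p$stride_period_mean_s <= 0 || p$stride_period_sd_s < 0 ||
      p$load_duty <= 0 || p$load_duty >= 1 || p$swing_cv < 0)
    stop("invalid terrain parameters")
  structure(p, class = "terrain_profile")
}

terrain_presets <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "terrain_profiles.json",
                          package = "canegait")
      cache <<- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    }
    cache
  }
})

# fixed within-stride geometry (fractions of the swing phase)
.backswing_frac <- 0.15   # backswing duration / swing duration
.overrun_frac <- 0.30     # forward lobe tail past the next contact
.rise_frac <- 0.35        # rise fraction of the forward lobe (skew)
.backswing_depth <- 0.25  # backswing amplitude / forward amplitude

# loading lobe: sine clamped onto a constant -undershoot baseline so the
# noise-free signal crosses zero exactly at IC and TC
strain_lobe <- function(tt, t0, L, A, u) {
  th <- asin(min(u / A, 1))            # pi*d/(L+2d) = th
  d <- th * L / (pi - 2 * th)
  v <- rep(NA_real_, length(tt))
  inl <- tt > (t0 - d) & tt < (t0 + L + d)
  v[inl] <- A * sin(pi * (tt[inl] - t0 + d) / (L + 2 * d)) - u
  v
}

# biphasic swing velocity: short backswing dip, then a skewed forward lobe
# peaking at PS and overrunning the next contact by .overrun_frac * S
gyro_lobe <- function(tt, tc, S, W) {
  v <- rep(0, length(tt))
  bs <- .backswing_frac * S
  i <- tt > tc & tt < tc + bs
  v[i] <- -.backswing_depth * W * sin(pi * (tt[i] - tc) / bs)
  M <- S * (1 - .backswing_frac + .overrun_frac)
  rise <- .rise_frac * M
  t_r <- tc + bs
  i <- tt >= t_r & tt <= t_r + rise
  v[i] <- W * sin((pi / 2) * (tt[i] - t_r) / rise)
  i <- tt > t_r + rise & tt < t_r + M
  v[i] <- W * cos((pi / 2) * (tt[i] - t_r - rise) / (M - rise))
  v
}

# PS offset from TC, given swing duration S
ps_offset <- function(S) {
  S * (.backswing_frac +
         .rise_frac * (1 - .backswing_frac + .overrun_frac))
}

#' Generate a single synthetic stride
#'
#' One noise-free stride of the given terrain: a loading pulse on the
#' strain channel whose zero-crossings sit exactly at the generative IC and
#' TC instants, and a biphasic swing-velocity waveform with exactly one
#' negative-to-positive rate reversal and one forward peak (the PS
#' instant). All waveforms are analytic so the truth events are known
#' exactly; visual realism is secondary to testability.
#'
#' @param profile A [terrain_profile()].
#' @param sample_rate_hz Sampling rate (default 231 Hz).
#' @param undershoot Baseline depth below zero between loading pulses, in
#'   strain units (default 0.15).
#' @param lead_in_s Quiet padding before IC (default 0.3 s).
#' @return A list with `strain`, `gyro_ap`, `sample_rate_hz` and `truth`
#'   (a valid [gait_cycle()]; its EC is the nominal next contact).
#' @export
make_stride <- function(profile, sample_rate_hz = 231, undershoot = 0.15,
                        lead_in_s = 0.3) {
  stopifnot(inherits(profile, "terrain_profile"))
  Tn <- profile$stride_period_mean_s
  L <- profile$load_duty * Tn
  S <- Tn - L
  dur <- lead_in_s + Tn + .overrun_frac * S + 0.1
  n <- round(dur * sample_rate_hz) + 1L
  tt <- (seq_len(n) - 1) / sample_rate_hz
  t0 <- lead_in_s
  strain <- strain_lobe(tt, t0, L, profile$load_amp, undershoot)
  strain[is.na(strain)] <- -undershoot
  gyro <- gyro_lobe(tt, t0 + L, S, profile$swing_amp_dps)
  truth <- gait_cycle(ic = t0, tc = t0 + L, ps = t0 + L + ps_offset(S),
                      ec = t0 + Tn, valid = TRUE,
                      sample_rate_hz = sample_rate_hz,
                      terrain = profile$name)
  list(strain = strain, gyro_ap = gyro, sample_rate_hz = sample_rate_hz,
       truth = truth)
}

#' Simulation configuration
#'
#' @param segments Ordered list of walking segments, each a list with
#'   `terrain` (a name or [terrain_profile()]) and `n_strides`.
#' @param sample_rate_hz Sampling rate (default 231).
#' @param noise_sd Named vector: additive white Gaussian noise SD for
#'   `strain` (strain units) and `gyro_ap` (degrees/s), applied before any
#'   filtering.
#' @param artifact_rates Named vector of per-stride probabilities for the
#'   invalid-cycle artifacts `load_without_swing` (a 3.5-5 s loading hold
#'   with no swing), `swing_without_load` (a swing with the cane carried,
#'   no loading) and `pause` (a 1.2-2.2 s standstill after the stride).
#' @param switch_close_load Load level (strain units) at which the
#'   simulated push-switch closes; the tip switch needs a substantial load
#'   before registering contact, so closure trails IC (default 0.25).
#' @param undershoot Baseline depth below zero (strain units, default 0.15).
#' @param amp_cv Named vector of stride-to-stride coefficients of variation
#'   for peak `load` and `swing` amplitude (defaults 0.10 and 0.12): no two
#'   strides are pushed or swung identically hard.
#' @param stance_rot_range While loaded, the cane pivots forward over its
#'   tip, producing a positive AP-velocity hump mid-stance whose size varies
#'   stride to stride; its peak is drawn uniformly from this range as a
#'   fraction of the stride's swing amplitude (default `c(0.2, 0.7)`;
#'   `c(0, 0)` disables it). These humps are genuine angular motion, not
#'   strides, and are the main source of sub-swing peaks that amplitude
#'   thresholds must discriminate against.
#' @param seed Integer seed; fixed seed gives a bitwise-identical
#'   recording.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(segments = list(list(terrain = "flat",
                                            n_strides = 20)),
                       sample_rate_hz = 231,
                       noise_sd = c(strain = 0.02, gyro_ap = 2),
                       artifact_rates = c(load_without_swing = 0,
                                          swing_without_load = 0,
                                          pause = 0),
                       switch_close_load = 0.25, undershoot = 0.15,
                       amp_cv = c(load = 0.10, swing = 0.12),
                       stance_rot_range = c(0.2, 0.7),
                       seed = NULL) {
  ns <- c(strain = 0.02, gyro_ap = 2)
  ns[names(noise_sd)] <- noise_sd
  ar <- c(load_without_swing = 0, swing_without_load = 0, pause = 0)
  ar[names(artifact_rates)] <- artifact_rates
  if (any(ar < 0 | ar > 1)) stop("artifact rates must lie in [0, 1]")
  if (any(ns < 0)) stop("noise SDs must be >= 0")
  if (switch_close_load <= 0) stop("`switch_close_load` must be positive")
  cv <- c(load = 0.10, swing = 0.12)
  cv[names(amp_cv)] <- amp_cv
  if (any(cv < 0)) stop("`amp_cv` must be >= 0")
  if (length(stance_rot_range) != 2 || any(stance_rot_range < 0) ||
      stance_rot_range[1] > stance_rot_range[2])
    stop("`stance_rot_range` must be an increasing pair of fractions >= 0")
  segments <- lapply(segments, function(sg) {
    pr <- sg$terrain
    if (!inherits(pr, "terrain_profile")) pr <- terrain_profile(pr)
    if (sg$n_strides < 0) stop("`n_strides` must be >= 0")
    list(terrain = pr, n_strides = as.integer(sg$n_strides))
  })
  structure(list(segments = segments, sample_rate_hz = sample_rate_hz,
                 noise_sd = ns, artifact_rates = ar,
                 switch_close_load = switch_close_load,
                 undershoot = undershoot, amp_cv = cv,
                 stance_rot_range = as.numeric(stance_rot_range),
                 seed = seed),
            class = "sim_config")
}

#' Simulate a cane-gait recording with ground truth
#'
#' Concatenates strides segment by segment. Within-stride geometry (loading
#' and swing durations) is fixed at each terrain's mean period; stride-to-
#' stride variability enters through the onset spacing, drawn from the
#' terrain's period distribution (clipped at 3 SD and at the point where a
#' stride would collide with its predecessor's swing peak). Artifacts are
#' injected at the configured per-stride rates and labelled invalid in the
#' truth. The push-switch channel closes wherever the noise-free load
#' reaches `switch_close_load`, so it closes strictly after the true IC and
#' opens strictly before the true EC. White noise is added per channel
#' last. The walk ends with a short cane plant, which gives the final
#' stride its end contact.
#'
#' @param config A [sim_config()].
#' @return A list with `recording` (a [cane_recording()] with switch
#'   channel) and `truth` (an [annotation_set()] with validity labels and
#'   terrain tags).
#' @export
simulate_recording <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(config$seed)
  }
  fs <- config$sample_rate_hz
  u <- config$undershoot
  ar <- config$artifact_rates

  # --- plan the stride sequence -------------------------------------------
  plan <- list()
  t0 <- 0.5
  for (sg in config$segments) {
    pr <- sg$terrain
    Tn <- pr$stride_period_mean_s
    L <- pr$load_duty * Tn
    S <- Tn - L
    for (k in seq_len(sg$n_strides)) {
      type <- "normal"
      if (runif(1) < ar["load_without_swing"]) type <- "load_without_swing"
      else if (runif(1) < ar["swing_without_load"]) type <- "swing_without_load"
      A_i <- pr$load_amp * max(rnorm(1, 1, config$amp_cv["load"]), 0.5)
      W_i <- pr$swing_amp_dps *
        max(rnorm(1, 1, pr$swing_cv %||% config$amp_cv["swing"]), 0.3)
      rot <- runif(1, config$stance_rot_range[1], config$stance_rot_range[2])
      if (type == "load_without_swing") {
        hold <- runif(1, 3.5, 5)
        adv <- hold + 0.6
        st <- list(type = type, profile = pr, t0 = t0, hold = hold,
                   A = A_i)
      } else {
        lo <- Tn - min(3 * pr$stride_period_sd_s, 0.35 * S)
        hi <- Tn + 3 * pr$stride_period_sd_s
        Ti <- min(max(rnorm(1, Tn, pr$stride_period_sd_s), lo), hi)
        jit <- 0
        if (type == "swing_without_load") {
          jit <- runif(1, 0.15, 0.45)
          # repositioning an unloaded cane is gentler than a gait swing
          W_i <- W_i * runif(1, 0.4, 0.7)
        }
        st <- list(type = type, profile = pr, t0 = t0 + jit, period = Ti,
                   A = A_i, W = W_i, rot = rot,
                   rot_c = runif(1, 0.45, 0.55))
        adv <- Ti
      }
      if (runif(1) < ar["pause"]) adv <- adv + runif(1, 1.2, 2.2)
      plan[[length(plan) + 1L]] <- st
      t0 <- t0 + adv
    }
  }
  plant_t0 <- t0
  plant_L <- 0.4
  plant_amp <- if (length(plan))
    plan[[length(plan)]]$profile$load_amp else 1
  dur <- plant_t0 + plant_L + 1.0

  # --- synthesize channels ------------------------------------------------
  n <- round(dur * fs) + 1L
  tt <- (seq_len(n) - 1) / fs
  strain <- rep(-u, n)
  gyro <- rep(0, n)
  overlay_load <- function(strain, t0, L, A) {
    v <- strain_lobe(tt, t0, L, A, u)
    ok <- !is.na(v)
    strain[ok] <- v[ok]
    strain
  }
  for (st in plan) {
    pr <- st$profile
    Tn <- pr$stride_period_mean_s
    L <- pr$load_duty * Tn
    S <- Tn - L
    if (st$type %in% c("normal", "load_without_swing")) {
      Lx <- if (st$type == "load_without_swing") st$hold else L
      strain <- overlay_load(strain, st$t0, Lx, st$A)
    }
    if (st$type %in% c("normal", "swing_without_load"))
      gyro <- gyro + gyro_lobe(tt, st$t0 + L, S, st$W)
    if (st$type == "normal" && st$rot > 0) {
      # mid-stance pivot of the cane over its tip: positive AP hump
      c0 <- st$t0 + st$rot_c * L
      w2 <- 0.15 * L
      i <- tt > c0 - w2 & tt < c0 + w2
      gyro[i] <- gyro[i] +
        st$rot * st$W * sin(pi * (tt[i] - c0 + w2) / (2 * w2))
    }
  }
  strain <- overlay_load(strain, plant_t0, plant_L, plant_amp)
  switch <- as.integer(strain >= config$switch_close_load)
  strain <- strain + rnorm(n, 0, config$noise_sd["strain"])
  gyro <- gyro + rnorm(n, 0, config$noise_sd["gyro_ap"])

  # --- ground-truth cycles ------------------------------------------------
  contact_t <- c(vapply(plan, function(st)
    if (st$type %in% c("normal", "load_without_swing")) st$t0 else NA_real_,
    numeric(1)), plant_t0)
  contact_t <- contact_t[!is.na(contact_t)]
  cycles <- vector("list", length(plan))
  for (i in seq_along(plan)) {
    st <- plan[[i]]
    pr <- st$profile
    Tn <- pr$stride_period_mean_s
    L <- pr$load_duty * Tn
    S <- Tn - L
    if (st$type == "normal") {
      ic <- st$t0; tc <- ic + L
      ps <- tc + ps_offset(S)
      ec <- contact_t[contact_t > tc][1]
      ok <- !is.na(ec) && (ec - ic) <= 3 && ps < ec
      cycles[[i]] <- gait_cycle(ic, tc, ps, ec, valid = ok,
                                sample_rate_hz = fs, terrain = pr$name,
                                check = FALSE)
    } else if (st$type == "load_without_swing") {
      ic <- st$t0; tc <- ic + st$hold
      ec <- contact_t[contact_t > tc][1]
      cycles[[i]] <- gait_cycle(ic, tc, NA_real_, ec, valid = FALSE,
                                sample_rate_hz = fs, terrain = pr$name,
                                check = FALSE)
    } else { # swing without load: nominal times, no contact happens
      ic <- st$t0; tc <- ic + L
      ps <- tc + ps_offset(S)
      cycles[[i]] <- gait_cycle(ic, tc, ps, NA_real_, valid = FALSE,
                                sample_rate_hz = fs, terrain = pr$name,
                                check = FALSE)
    }
  }
  seg_tab <- data.frame(
    terrain = vapply(config$segments, function(sg) sg$terrain$name,
                     character(1)),
    n_strides = vapply(config$segments, function(sg) sg$n_strides,
                       integer(1)))
  rec <- cane_recording(strain, gyro, sample_rate_hz = fs, switch = switch,
                        meta = list(seed = config$seed, segments = seg_tab))
  list(recording = rec,
       truth = annotation_set(cycles, provenance = "simulator"))
}

#' Flat-terrain stride template
#'
#' One noise-free stride of strain data starting at IC, the canonical
#' matched-filter template. A single flat-surface template is reused across
#' all terrains; the loading pulses on other terrains share its shape
#' family, so normalized correlation stays high even as amplitude and
#' duration change.
#'
#' @param profile A [terrain_profile()] (default flat).
#' @param sample_rate_hz Sampling rate (default 231).
#' @param undershoot Baseline depth (default 0.15).
#' @return A [stride_template()].
#' @export
make_template <- function(profile = terrain_profile("flat"),
                          sample_rate_hz = 231, undershoot = 0.15) {
  Tn <- profile$stride_period_mean_s
  L <- profile$load_duty * Tn
  m <- round(Tn * sample_rate_hz)
  tt <- (seq_len(m) - 1) / sample_rate_hz
  v <- strain_lobe(tt, 0, L, profile$load_amp, undershoot)
  v[is.na(v)] <- -undershoot
  stride_template(v, sample_rate_hz,
                  source = sprintf("synthetic single stride, terrain=%s",
                                   profile$name))
}

#' Preset terrain scenarios
#'
#' The seven walk scenarios used throughout: five single-terrain walks and
#' two transition walks (flat-upstairs-flat, flat-downstairs-flat). For
#' transition scenarios the stride budget is split roughly into thirds.
#'
#' @param name Scenario name: `"flat"`, `"upstairs"`, `"downstairs"`,
#'   `"uphill"`, `"downhill"`, `"flat_upstairs_flat"`,
#'   `"flat_downstairs_flat"`.
#' @param n_strides Total strides in the walk (default 20).
#' @param ... Passed to [sim_config()].
#' @return A [sim_config()].
#' @export
scenario_config <- function(name, n_strides = 20, ...) {
  single <- c("flat", "upstairs", "downstairs", "uphill", "downhill")
  segs <- if (name %in% single) {
    list(list(terrain = name, n_strides = n_strides))
  } else if (name == "flat_upstairs_flat") {
    k <- round(n_strides / 3)
    list(list(terrain = "flat", n_strides = k),
         list(terrain = "upstairs", n_strides = n_strides - 2 * k),
         list(terrain = "flat", n_strides = k))
  } else if (name == "flat_downstairs_flat") {
    k <- round(n_strides / 3)
    list(list(terrain = "flat", n_strides = k),
         list(terrain = "downstairs", n_strides = n_strides - 2 * k),
         list(terrain = "flat", n_strides = k))
  } else stop("unknown scenario: ", name)
  sim_config(segments = segs, ...)
}

#' Names of the preset walk scenarios
#'
#' @return Character vector of the scenario names accepted by
#'   [scenario_config()].
#' @export
scenario_names <- function() {
  c("flat", "upstairs", "downstairs", "uphill", "downhill",
    "flat_upstairs_flat", "flat_downstairs_flat")
}
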