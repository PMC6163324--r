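#' Gyroscope peak detection (GPD) baseline
#'
#' The comparison segmenter: a stride is declared at every local maximum of
#' the (filtered) AP angular velocity that exceeds an amplitude threshold.
#' Candidate peaks are first extracted threshold-free with a greedy minimum
#' separation (the taller peak wins a conflict); the threshold then selects
#' a subset, so lowering the threshold always grows the detection set
#' monotonically.
#'
#' Unlike the matched-filter segmenter, GPD is deliberately *not*
#' amplitude-invariant: rescaling the signal against a fixed threshold
#' changes the detections. That sensitivity is its documented failure mode
#' on terrain transitions where swing amplitude drops.
#'
#' @param gyro_ap Filtered AP angular velocity vector.
#' @param threshold Positive amplitude threshold (degrees/s).
#' @param sample_rate_hz Sampling rate in Hz.
#' @param min_separation_s Minimum inter-peak separation (default 0.5 s).
#' @return Integer vector of detected peak (PS event) sample indices.
#' @export
gpd_detect <- function(gyro_ap, threshold, sample_rate_hz,
                       min_separation_s = 0.5) {
  if (threshold <= 0) stop("`threshold` must be positive")
  cand <- gpd_peak_candidates(gyro_ap, sample_rate_hz, min_separation_s,
                              floor_frac = 0)
  cand[gyro_ap[cand] >= threshold]
}

#' Threshold-free candidate swing peaks
#'
#' Positive local maxima with greedy minimum separation, optionally floored
#' at a fraction of the global maximum. Calibration uses the floor so that
#' the "mean peak amplitude" of a walk reflects its stride swings rather
#' than noise ripples or the smaller stance-phase rotation humps.
#'
#' @inheritParams gpd_detect
#' @param floor_frac Discard candidates below this fraction of the global
#'   maximum (default 0.5 for calibration; [gpd_detect()] uses 0).
#' @return Integer vector of candidate peak indices, increasing.
#' @export
gpd_peak_candidates <- function(gyro_ap, sample_rate_hz,
                                min_separation_s = 0.5, floor_frac = 0.5) {
  x <- gyro_ap
  n <- length(x)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  cand <- i[x[i] > x[i - 1] & x[i] >= x[i + 1] & x[i] > 0]
  if (floor_frac > 0) cand <- cand[x[cand] >= floor_frac * max(x)]
  if (!length(cand)) return(integer(0))
  sep <- round(min_separation_s * sample_rate_hz)
  ord <- cand[order(-x[cand], cand)]
  kept <- integer(0)
  for (p in ord)
    if (!length(kept) || all(abs(kept - p) >= sep)) kept <- c(kept, p)
  sort(kept)
}

#' GPD threshold policy
#'
#' How the amplitude threshold is calibrated:
#' * `"O"` - oracle/optimal: per recording and terrain, the threshold in a
#'   dense fraction sweep that maximizes detection F1 against reference
#'   annotations (an idealized upper bound, impractical in deployment);
#' * `"IFS"` - individual flat-surface: calibrated from that participant's
#'   flat walk;
#' * `"UFS"` - universal flat-surface: mean over all participants' flat
#'   walks;
#' * `"U"` - universal: mean over all terrains and participants;
#' * `"fixed"` - an explicit fraction with no calibration data.
#'
#' For the calibration-based policies the threshold is
#' `fraction * mean(candidate peak amplitudes)` over the calibration
#' recordings.
#'
#' @param kind One of `"O"`, `"IFS"`, `"UFS"`, `"U"`, `"fixed"`.
#' @param fraction Threshold as a fraction of mean peak amplitude, in
#'   `(0, 1]` (default 0.5).
#' @return An object of class `gpd_policy`.
#' @export
gpd_policy <- function(kind = c("fixed", "O", "IFS", "UFS", "U"),
                       fraction = 0.5) {
  kind <- match.arg(kind)
  if (fraction <= 0 || fraction > 1) stop("`fraction` must be in (0, 1]")
  structure(list(kind = kind, fraction = fraction), class = "gpd_policy")
}

#' Mean swing-peak amplitude of a recording
#'
#' Filters the gyroscope channel and averages the prominent candidate
#' peaks (see [gpd_peak_candidates()]); fraction-based GPD thresholds are
#' expressed relative to this quantity.
#'
#' @param rec A [cane_recording()].
#' @param params An [msmf_params()] supplying the gyro filter settings.
#' @param min_separation_s Minimum inter-peak separation (default 0.5 s).
#' @return Mean candidate peak amplitude (degrees/s).
#' @export
mean_peak_amplitude <- function(rec, params = msmf_params(),
                                min_separation_s = 0.5) {
  fs <- rec$sample_rate_hz
  gf <- lowpass(rec$gyro_ap,
                filter_spec(params$filter_order, params$gyro_cutoff_hz, fs))
  pk <- gpd_peak_candidates(gf, fs, min_separation_s, floor_frac = 0.5)
  if (!length(pk)) stop("no swing peaks found in calibration recording")
  mean(gf[pk])
}

#' Calibrate a GPD amplitude threshold
#'
#' @param policy A [gpd_policy()].
#' @param recordings List of [cane_recording()] calibration recordings
#'   appropriate for the policy kind (IFS: the participant's flat walk;
#'   UFS: all participants' flat walks; U: all recordings from all terrains;
#'   O: exactly one recording, with reference annotations).
#' @param annotations For `kind = "O"`, the [annotation_set()] for the
#'   single recording.
#' @param match_tol_s Peak-to-reference matching tolerance for the O sweep.
#' @param fractions Fraction grid for the O sweep (0.05 steps; ties go to
#'   the larger fraction).
#' @return The absolute amplitude threshold (degrees/s).
#' @export
calibrate_threshold <- function(policy, recordings, annotations = NULL,
                                match_tol_s = 0.5,
                                fractions = seq(0.95, 0.05, by = -0.05)) {
  stopifnot(inherits(policy, "gpd_policy"))
  if (!length(recordings)) stop("empty calibration set")
  if (inherits(recordings, "cane_recording")) recordings <- list(recordings)
  if (policy$kind == "fixed")
    stop("a fixed policy carries its own fraction; nothing to calibrate ",
         "against recordings without a mean peak reference. Use kind ",
         "'IFS'/'UFS'/'U' with calibration data instead.")
  amps <- vapply(recordings, mean_peak_amplitude, numeric(1))
  if (policy$kind %in% c("IFS", "UFS", "U"))
    return(policy$fraction * mean(amps))
  # O: F1-maximizing fraction on one recording against its annotations
  if (is.null(annotations))
    stop("policy 'O' requires reference annotations")
  if (length(recordings) != 1L)
    stop("policy 'O' is calibrated per recording; supply exactly one")
  rec <- recordings[[1]]
  fs <- rec$sample_rate_hz
  gf <- lowpass(rec$gyro_ap, filter_spec(6, 8, fs))
  ref_ps <- cycle_times(annotations, "ps", valid_only = TRUE)
  amp <- amps[1]
  best <- c(f1 = -1, frac = NA_real_)
  for (fr in sort(fractions, decreasing = TRUE)) {
    det <- gpd_detect(gf, fr * amp, fs)
    det_t <- (det - 1) / fs
    cnt <- match_event_counts(det_t, ref_ps, numeric(0), match_tol_s)
    f1 <- unname(if (2 * cnt["tp"] + cnt["fp"] + cnt["fn"] == 0) 0 else
      2 * cnt["tp"] / (2 * cnt["tp"] + cnt["fp"] + cnt["fn"]))
    if (f1 > best["f1"]) best <- c(f1 = f1, frac = fr)
  }
  unname(best["frac"]) * amp
}

# a time stamp for each invalid reference cycle: its PS when the artifact
# has a swing, otherwise the middle of its loading phase
invalid_reference_times <- function(ann) {
  df <- cycles_df(ann)
  df <- df[!df$valid, , drop = FALSE]
  t <- ifelse(is.na(df$ps_s), (df$ic_s + df$tc_s) / 2, df$ps_s)
  t[!is.na(t)]
}

# any-within-tolerance matching counts used by the sweep and the O
# calibration: a reference is hit if any detection lies within tol; a
# detection is a false positive if it is within tol of no valid reference.
# This counting is monotone in the detection set.
match_event_counts <- function(det_t, ref_valid_t, ref_invalid_t, tol) {
  hit <- vapply(ref_valid_t,
                function(r) any(abs(det_t - r) <= tol), logical(1))
  fp <- sum(vapply(det_t,
                   function(d) all(abs(ref_valid_t - d) > tol) ||
                     !length(ref_valid_t), logical(1)))
  tn <- sum(vapply(ref_invalid_t,
                   function(r) !length(det_t) || all(abs(det_t - r) > tol),
                   logical(1)))
  c(tp = sum(hit), fn = sum(!hit), fp = fp, tn = tn)
}

#' ROC threshold sweep for GPD
#'
#' Sweeps the detection threshold from a high to a low fraction of each
#' recording's mean peak amplitude and pools true/false positive rates over
#' recordings, one ROC point per fraction. Because the candidate peak set is
#' fixed and the threshold only selects from it, both rates are
#' non-decreasing as the fraction falls.
#'
#' @param recordings List of [cane_recording()].
#' @param annotations List of matching [annotation_set()] reference truths.
#' @param fractions Descending fraction grid (default 0.8 to 0.2 in 0.05
#'   steps).
#' @param match_tol_s Peak-to-reference matching tolerance in seconds.
#' @return A data frame with columns `fraction`, `tpr`, `fpr`.
#' @export
threshold_sweep <- function(recordings, annotations,
                            fractions = seq(0.8, 0.2, by = -0.05),
                            match_tol_s = 0.5) {
  if (inherits(recordings, "cane_recording")) recordings <- list(recordings)
  if (inherits(annotations, "annotation_set")) annotations <- list(annotations)
  stopifnot(length(recordings) == length(annotations))
  prep <- lapply(recordings, function(rec) {
    fs <- rec$sample_rate_hz
    gf <- lowpass(rec$gyro_ap, filter_spec(6, 8, fs))
    list(gf = gf, fs = fs, amp = mean_peak_amplitude(rec))
  })
  out <- lapply(fractions, function(fr) {
    tot <- c(tp = 0, fn = 0, fp = 0, tn = 0)
    for (i in seq_along(prep)) {
      p <- prep[[i]]
      det <- gpd_detect(p$gf, fr * p$amp, p$fs)
      cnt <- match_event_counts(
        (det - 1) / p$fs,
        cycle_times(annotations[[i]], "ps", valid_only = TRUE),
        invalid_reference_times(annotations[[i]]),
        match_tol_s)
      tot <- tot + cnt
    }
    data.frame(fraction = fr,
               tpr = if (tot["tp"] + tot["fn"] == 0) 0 else
                 unname(tot["tp"] / (tot["tp"] + tot["fn"])),
               fpr = if (tot["fp"] + tot["tn"] == 0) 0 else
                 unname(tot["fp"] / (tot["fp"] + tot["tn"])))
  })
  do.call(rbind, out)
}

#' Crop a recording to a time window
#'
#' @param rec A [cane_recording()].
#' @param from_s,to_s Window bounds in seconds (clamped to the recording).
#' @return A [cane_recording()] covering the window; its time vector keeps
#'   the original clock so event times remain comparable.
#' @export
crop_recording <- function(rec, from_s, to_s) {
  stopifnot(inherits(rec, "cane_recording"), from_s < to_s)
  i <- which(rec$t >= from_s & rec$t <= to_s)
  if (length(i) < 2) stop("window contains fewer than 2 samples")
  cane_recording(rec$strain[i], rec$gyro_ap[i],
                 sample_rate_hz = rec$sample_rate_hz,
                 switch = if (!is.null(rec$switch)) rec$switch[i],
                 t = rec$t[i], meta = rec$meta)
}

#' Oracle GPD with per-terrain thresholds
#'
#' The idealized GPD-O baseline: the recording is split into contiguous
#' terrain blocks (taken from the reference annotations' terrain labels),
#' an F1-optimal threshold is calibrated separately for each block against
#' the reference, and detections are pooled. This is an upper bound on what
#' amplitude thresholding can do - in deployment the terrain would have to
#' be known before segmenting, which is circular.
#'
#' @param rec A [cane_recording()].
#' @param reference An [annotation_set()] whose cycles carry terrain labels.
#' @param min_separation_s Minimum inter-peak separation (default 0.5 s).
#' @return A list of GPD pseudo-cycles (see [gpd_cycles()]) in time order.
#' @export
gpd_oracle_cycles <- function(rec, reference, min_separation_s = 0.5) {
  df <- cycles_df(reference)
  if (all(is.na(df$terrain))) stop("reference cycles carry no terrain labels")
  blocks <- rle(df$terrain)
  idx_end <- cumsum(blocks$lengths)
  idx_start <- idx_end - blocks$lengths + 1L
  out <- list()
  for (b in seq_along(blocks$values)) {
    rows <- idx_start[b]:idx_end[b]
    t_lo <- min(df$ic_s[rows], na.rm = TRUE) - 1
    t_hi <- max(c(df$ec_s[rows], df$ps_s[rows], df$tc_s[rows]),
                na.rm = TRUE) + 1
    sub_rec <- crop_recording(rec, max(t_lo, rec$t[1]),
                              min(t_hi, rec$t[length(rec$t)]))
    # re-zero the clock for filtering, then shift detections back
    off <- sub_rec$t[1]
    sub0 <- cane_recording(sub_rec$strain, sub_rec$gyro_ap,
                           sample_rate_hz = sub_rec$sample_rate_hz,
                           switch = sub_rec$switch)
    sub_ann <- annotation_set(lapply(rows, function(i) {
      cy <- reference$cycles[[i]]
      gait_cycle(cy$ic$time_s - off, cy$tc$time_s - off,
                 cy$ps$time_s - off, cy$ec$time_s - off,
                 valid = cy$valid, similarity = cy$similarity,
                 sample_rate_hz = rec$sample_rate_hz,
                 terrain = cy$terrain, check = FALSE)
    }), provenance = reference$provenance)
    thr <- calibrate_threshold(gpd_policy("O"), list(sub0), sub_ann)
    cyc <- gpd_cycles(sub0, thr, min_separation_s)
    out <- c(out, lapply(cyc, function(cy) {
      sh <- function(e) if (is.na(e$time_s)) NA_real_ else e$time_s + off
      gait_cycle(sh(cy$ic), sh(cy$tc), sh(cy$ps), sh(cy$ec),
                 valid = cy$valid, sample_rate_hz = rec$sample_rate_hz,
                 terrain = blocks$values[b], check = FALSE)
    }))
  }
  out[order(vapply(out, function(cy) cy$ps$time_s, numeric(1)))]
}

#' GPD pseudo-cycles
#'
#' Wraps GPD detections as cycle objects so that the evaluation metrics can
#' score both segmenters identically. Each supra-threshold peak is a PS
#' event and a counted stride. IC and TC are estimated from the gyroscope
#' alone (the only channel GPD uses): TC as the last negative-to-positive
#' rate reversal before the peak (swing initiation) and IC as the first
#' positive-to-negative zero-crossing after the peak (the swing lobe dying
#' out around ground contact). These surrogates are what gives GPD its
#' characteristic timing error against a contact switch.
#'
#' @param rec A [cane_recording()].
#' @param threshold Absolute amplitude threshold (degrees/s).
#' @param min_separation_s Minimum inter-peak separation (default 0.5 s).
#' @return A list of unchecked [gait_cycle()] objects (EC is `NA`).
#' @export
gpd_cycles <- function(rec, threshold, min_separation_s = 0.5) {
  stopifnot(inherits(rec, "cane_recording"))
  fs <- rec$sample_rate_hz
  gf <- lowpass(rec$gyro_ap, filter_spec(6, 8, fs))
  pk <- gpd_detect(gf, threshold, fs, min_separation_s)
  up <- positive_zero_crossings(gf)
  dn <- negative_zero_crossings(gf)
  lapply(pk, function(p) {
    tc <- rev(up[up < p])[1]
    ic <- dn[dn > p][1]
    idx2t <- function(i) if (is.na(i)) NA_real_ else (i - 1) / fs
    gait_cycle(idx2t(ic), idx2t(tc), idx2t(p), NA_real_, valid = TRUE,
               sample_rate_hz = fs, check = FALSE)
  })
}
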