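#' MSMF segmenter parameters
#'
#' Tunable parameters of the multi-sensor matched-filter segmenter.
#'
#' @param similarity_threshold Minimum normalized template correlation for a
#'   matched-filter peak to anchor a stride (default 0.5, i.e. "50%
#'   correlation").
#' @param ic_window_s Half-width of the symmetric search window around an
#'   anchor peak inside which the IC zero-crossing must lie (default 0.5 s).
#' @param cycle_window_s A cycle is valid only if TC, PS and EC all fall
#'   within this many seconds of IC (default 3 s).
#' @param min_separation_s Minimum separation between anchor peaks; `NULL`
#'   (default) means half the template duration.
#' @param filter_order Order of both low-pass filters (default 6).
#' @param strain_cutoff_hz Strain-channel low-pass cutoff (default 4 Hz).
#' @param gyro_cutoff_hz Gyroscope-channel low-pass cutoff (default 8 Hz).
#' @return An object of class `msmf_params`.
#' @export
msmf_params <- function(similarity_threshold = 0.5, ic_window_s = 0.5,
                        cycle_window_s = 3, min_separation_s = NULL,
                        filter_order = 6, strain_cutoff_hz = 4,
                        gyro_cutoff_hz = 8) {
  if (ic_window_s <= 0 || ic_window_s >= cycle_window_s)
    stop("need 0 < ic_window_s < cycle_window_s")
  if (similarity_threshold <= 0 || similarity_threshold > 1)
    stop("`similarity_threshold` must be in (0, 1]")
  structure(list(similarity_threshold = similarity_threshold,
                 ic_window_s = ic_window_s, cycle_window_s = cycle_window_s,
                 min_separation_s = min_separation_s,
                 filter_order = filter_order,
                 strain_cutoff_hz = strain_cutoff_hz,
                 gyro_cutoff_hz = gyro_cutoff_hz),
            class = "msmf_params")
}

#' Multi-sensor matched-filter gait segmentation
#'
#' Segments cane-assisted gait into IC-TC-PS-EC cycles by fusing the strain
#' and gyroscope channels through a four-state sequence:
#'
#' 1. both channels are zero-phase low-pass filtered (4 Hz strain, 8 Hz
#'    gyro);
#' 2. the stride template is correlated against the strain channel and
#'    positive peaks with similarity of at least the threshold become
#'    stride anchors;
#' 3. IC is the positive strain zero-crossing nearest the anchor within a
#'    symmetric `ic_window_s` window (ties broken toward the earlier
#'    sample);
#' 4. TC is the first negative strain zero-crossing after IC;
#' 5. EC is the first ground contact after the swing, operationalized as
#'    the next positive strain zero-crossing after TC (in continuous
#'    walking this coincides with the next cycle's IC);
#' 6. PS is the maximum of AP angular velocity between the first
#'    negative-to-positive rate reversal after TC and EC. No amplitude
#'    threshold is applied, which is what makes the segmenter robust to
#'    terrain-dependent swing amplitude.
#'
#' A cycle is valid when all four events exist, are strictly ordered and EC
#' falls within `cycle_window_s` of IC; anchors whose search window holds no
#' positive zero-crossing produce no cycle at all.
#'
#' Because anchoring uses normalized correlation and all other rules are
#' sign- or argmax-based, the output is invariant to positive rescaling of
#' either channel.
#'
#' @param rec A [cane_recording()].
#' @param template A [stride_template()] at the recording's sample rate.
#' @param params An [msmf_params()].
#' @return A list of [gait_cycle()] objects in chronological order, each
#'   carrying the anchoring similarity. Invalid cycles are retained (with
#'   `valid = FALSE` and possibly `NA` events) so that downstream
#'   classification can count them.
#' @export
segment_msmf <- function(rec, template, params = msmf_params()) {
  stopifnot(inherits(rec, "cane_recording"),
            inherits(template, "stride_template"))
  fs <- rec$sample_rate_hz
  if (abs(template$sample_rate_hz - fs) > 1e-6 * fs)
    stop("template sample rate (", template$sample_rate_hz,
         " Hz) does not match the recording (", fs, " Hz)")
  sf <- lowpass(rec$strain,
                filter_spec(params$filter_order, params$strain_cutoff_hz, fs))
  gf <- lowpass(rec$gyro_ap,
                filter_spec(params$filter_order, params$gyro_cutoff_hz, fs))
  tf <- lowpass(template$values,
                filter_spec(params$filter_order, params$strain_cutoff_hz, fs))
  r <- correlate_template(stride_template(tf, fs, template$source), sf)
  min_sep <- params$min_separation_s %||%
    (0.5 * length(template$values) / fs)
  pk <- detect_anchor_peaks(r, params$similarity_threshold, min_sep, fs)
  pzc <- positive_zero_crossings(sf)
  nzc <- negative_zero_crossings(sf)
  rv <- rate_reversals(gf)
  w_ic <- round(params$ic_window_s * fs)
  w_cyc <- round(params$cycle_window_s * fs)

  # map anchors to IC crossings; if two anchors claim one crossing the
  # higher-similarity anchor wins
  ic_score <- new.env(parent = emptyenv())
  for (k in seq_along(pk$indices)) {
    a <- pk$indices[k]
    cand <- pzc[pzc >= a - w_ic & pzc <= a + w_ic]
    if (!length(cand)) next   # no IC in window: no stride emitted
    ic <- cand[which.min(abs(cand - a))]  # nearest; ties -> earlier sample
    key <- as.character(ic)
    sc <- pk$scores[k]
    if (is.null(ic_score[[key]]) || sc > ic_score[[key]])
      ic_score[[key]] <- sc
  }
  ics <- sort(as.integer(ls(ic_score)))
  cycles <- vector("list", length(ics))
  for (j in seq_along(ics)) {
    ic <- ics[j]
    sc <- ic_score[[as.character(ic)]]
    tc <- nzc[nzc > ic][1]
    ec <- if (!is.na(tc)) pzc[pzc > tc][1] else NA_integer_
    ps <- NA_integer_
    if (!is.na(tc) && !is.na(ec)) {
      r1 <- rv[rv > tc & rv < ec][1]
      if (!is.na(r1) && r1 < ec - 1L) {
        win <- r1:(ec - 1L)
        ps <- win[which.max(gf[win])]
      }
    }
    idx2t <- function(i) if (is.na(i)) NA_real_ else (i - 1) / fs
    ok <- !anyNA(c(tc, ps, ec)) && ic < tc && tc < ps && ps < ec &&
      (ec - ic) <= w_cyc
    cycles[[j]] <- gait_cycle(idx2t(ic), idx2t(tc), idx2t(ps), idx2t(ec),
                              valid = ok, similarity = sc,
                              sample_rate_hz = fs,
                              cycle_window_s = params$cycle_window_s,
                              check = FALSE)
  }
  cycles
}
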