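#' Four-way stride classification against reference annotations
#'
#' Greedily matches detected valid cycles one-to-one to reference valid
#' cycles when their event times agree within `match_tol_s`:
#' * TP - matched pairs (stride found by both algorithm and reference);
#' * FN - unmatched reference valid cycles (missed strides);
#' * FP - unmatched detected valid cycles (spurious strides);
#' * TN - reference-invalid cycles with no detected counterpart (artifacts
#'   correctly rejected).
#'
#' Matching is on IC times by default; gyroscope-only baselines whose
#' natural stride marker is the swing peak can match on PS instead.
#'
#' @param detected List of detected [gait_cycle()] objects.
#' @param reference An [annotation_set()] (or list of cycles).
#' @param match_tol_s Matching tolerance in seconds (default 0.5, half the
#'   shortest plausible stride period).
#' @param on Which event time to match on: `"ic"` (default) or `"ps"`.
#' @return Named integer vector `c(tp, tn, fp, fn)`.
#' @export
classify_strides <- function(detected, reference, match_tol_s = 0.5,
                             on = c("ic", "ps")) {
  on <- match.arg(on)
  det <- sort(cycle_times(detected, on, valid_only = TRUE))
  det <- det[!is.na(det)]
  ref <- cycles_df(reference)
  ref_col <- paste0(on, "_s")
  refv <- sort(ref[[ref_col]][ref$valid])
  refi <- invalid_reference_times(reference)
  matched <- rep(FALSE, length(refv))
  tp <- 0L; fp <- 0L
  for (d in det) {
    free <- which(!matched & abs(refv - d) <= match_tol_s)
    if (length(free)) {
      j <- free[which.min(abs(refv[free] - d))]
      matched[j] <- TRUE
      tp <- tp + 1L
    } else fp <- fp + 1L
  }
  tn <- if (!length(refi)) 0L else
    sum(vapply(refi, function(r) !length(det) || all(abs(det - r) > match_tol_s),
               logical(1)))
  c(tp = tp, tn = as.integer(tn), fp = fp, fn = sum(!matched))
}

#' Stride-time variability
#'
#' The sample variance of consecutive peak-swing (PS) intervals of the
#' detected valid cycles, in s^2. False positives and false negatives both
#' perturb the interval sequence, so an accurate segmenter yields the
#' lowest variance, approaching the walker's true stride variability.
#'
#' Variability is a within-bout statistic: a PS-to-PS interval longer than
#' `max_interval_s` (default 3 s, the cycle-validity window) cannot join
#' two consecutive strides of one walking bout - it spans a standstill or
#' a rejected stretch - and is treated as a bout boundary rather than a
#' stride interval. Without this, a single pause would dominate the
#' variance of every algorithm and say nothing about segmentation quality.
#'
#' @param detected List of [gait_cycle()] objects (or [annotation_set()]).
#' @param max_interval_s Longest interval still counted as consecutive
#'   strides (default 3 s).
#' @return Variance of within-bout PS-to-PS intervals (s^2).
#' @export
stride_variability <- function(detected, max_interval_s = 3) {
  ps <- sort(cycle_times(detected, "ps", valid_only = TRUE))
  ps <- ps[!is.na(ps)]
  if (length(ps) < 3)
    stop(structure(class = c("canegait_insufficient_cycles", "error",
                             "condition"),
                   list(message = paste0("stride variability needs at least ",
                                         "3 valid cycles, got ", length(ps)),
                        call = sys.call(-1))))
  iv <- diff(ps)
  iv <- iv[iv <= max_interval_s]
  if (length(iv) < 2)
    stop(structure(class = c("canegait_insufficient_cycles", "error",
                             "condition"),
                   list(message = "fewer than 2 within-bout stride intervals",
                        call = sys.call(-1))))
  stats::var(iv)
}

#' Push-switch timing errors
#'
#' Compares detected IC/TC event times with the binary push-switch channel.
#' The switch closes only once a load threshold is exceeded, so sign
#' conventions follow the contact geometry:
#' * IC error = `t_switch_close - t_IC_detected`; positive means the
#'   algorithm dates initial contact *before* the switch has fully closed;
#' * TC error = `t_switch_open - t_TC_detected`; negative means the
#'   algorithm dates terminal contact after the switch has opened.
#'
#' Each valid cycle is paired with the nearest switch transition within
#' `match_tol_s`; cycles with no nearby transition are skipped with a
#' warning.
#'
#' @param detected List of [gait_cycle()] objects.
#' @param switch Binary 0/1 switch vector.
#' @param sample_rate_hz Sampling rate of `switch`.
#' @param match_tol_s Transition-to-event pairing tolerance (default 0.5 s).
#' @return List with numeric vectors `ic_ms` and `tc_ms` (milliseconds).
#' @export
timing_errors <- function(detected, switch, sample_rate_hz,
                          match_tol_s = 0.5) {
  if (is.null(switch)) stop("recording has no switch channel")
  sw <- as.integer(switch)
  closes <- (which(diff(sw) == 1L) + 1L - 1) / sample_rate_hz
  opens <- (which(diff(sw) == -1L) + 1L - 1) / sample_rate_hz
  ic_t <- cycle_times(detected, "ic", valid_only = TRUE)
  tc_t <- cycle_times(detected, "tc", valid_only = TRUE)
  nearest <- function(t, ref) {
    if (is.na(t) || !length(ref)) return(NA_real_)
    d <- ref[which.min(abs(ref - t))]
    if (abs(d - t) <= match_tol_s) d else NA_real_
  }
  ic_ms <- vapply(ic_t, function(t) (nearest(t, closes) - t) * 1000,
                  numeric(1))
  tc_ms <- vapply(tc_t, function(t) (nearest(t, opens) - t) * 1000,
                  numeric(1))
  n_skip <- sum(is.na(ic_ms)) + sum(is.na(tc_ms))
  if (n_skip > 0)
    warning(n_skip, " event(s) had no switch transition within ",
            match_tol_s, " s and were skipped")
  list(ic_ms = ic_ms[!is.na(ic_ms)], tc_ms = tc_ms[!is.na(tc_ms)])
}

#' Assemble an evaluation report
#'
#' Combines stride classification, stride-time variability and (when a
#' switch channel is available) push-switch timing errors, overall and per
#' terrain when the reference cycles carry terrain labels.
#'
#' @param detected List of detected [gait_cycle()] objects.
#' @param reference An [annotation_set()].
#' @param recording Optional [cane_recording()] with a switch channel.
#' @param match_tol_s Matching tolerance in seconds.
#' @param on Event matched on for classification (`"ic"` or `"ps"`).
#' @return An object of class `cane_eval_report`: a list with `counts`,
#'   `recall`, `precision`, `stride_variance_s2`, `ic_error_ms`,
#'   `tc_error_ms` (each `c(mean, sd)` or `NULL`) and `per_terrain`.
#' @export
eval_report <- function(detected, reference, recording = NULL,
                        match_tol_s = 0.5, on = "ic") {
  counts <- classify_strides(detected, reference, match_tol_s, on)
  rec_rate <- if (counts["tp"] + counts["fn"] == 0) NA_real_ else
    unname(counts["tp"] / (counts["tp"] + counts["fn"]))
  prec <- if (counts["tp"] + counts["fp"] == 0) NA_real_ else
    unname(counts["tp"] / (counts["tp"] + counts["fp"]))
  sv <- tryCatch(stride_variability(detected),
                 canegait_insufficient_cycles = function(e) NA_real_)
  te <- NULL
  if (!is.null(recording) && !is.null(recording$switch))
    te <- timing_errors(detected, recording$switch,
                        recording$sample_rate_hz, match_tol_s)
  summ <- function(x) if (is.null(x) || !length(x)) NULL else
    c(mean = mean(x), sd = stats::sd(x))
  per_terrain <- NULL
  ref_df <- cycles_df(reference)
  terrains <- unique(ref_df$terrain[!is.na(ref_df$terrain)])
  if (length(terrains) > 1) {
    det_df <- cycles_df(detected)
    # a detected cycle inherits the terrain of the nearest reference cycle
    key <- if (on == "ic") "ic_s" else "ps_s"
    det_terrain <- vapply(det_df[[key]], function(t) {
      if (is.na(t)) return(NA_character_)
      ref_df$terrain[which.min(abs(ref_df[[key]] - t))]
    }, character(1))
    per_terrain <- lapply(terrains, function(tr) {
      di <- which(det_terrain == tr)
      ri <- which(ref_df$terrain == tr)
      cnt <- classify_strides(
        lapply(di, function(i) detected[[i]]),
        annotation_set(lapply(ri, function(i) reference$cycles[[i]]),
                       provenance = reference$provenance),
        match_tol_s, on)
      list(counts = cnt)
    })
    names(per_terrain) <- terrains
  }
  structure(list(counts = counts, recall = rec_rate, precision = prec,
                 stride_variance_s2 = sv,
                 ic_error_ms = summ(te$ic_ms), tc_error_ms = summ(te$tc_ms),
                 timing = te, per_terrain = per_terrain),
            class = "cane_eval_report")
}

#' @export
print.cane_eval_report <- function(x, ...) {
  cat("<cane_eval_report>\n")
  cat(sprintf("  strides: TP %d  TN %d  FP %d  FN %d  (recall %.3f, precision %.3f)\n",
              x$counts["tp"], x$counts["tn"], x$counts["fp"], x$counts["fn"],
              x$recall, x$precision))
  cat(sprintf("  stride variance: %s s^2\n",
              format(x$stride_variance_s2, digits = 4)))
  if (!is.null(x$ic_error_ms))
    cat(sprintf("  IC timing error: %.1f +/- %.1f ms\n",
                x$ic_error_ms["mean"], x$ic_error_ms["sd"]))
  if (!is.null(x$tc_error_ms))
    cat(sprintf("  TC timing error: %.1f +/- %.1f ms\n",
                x$tc_error_ms["mean"], x$tc_error_ms["sd"]))
  if (!is.null(x$per_terrain))
    for (tr in names(x$per_terrain)) {
      cnt <- x$per_terrain[[tr]]$counts
      cat(sprintf("  [%s] TP %d TN %d FP %d FN %d\n", tr,
                  cnt["tp"], cnt["tn"], cnt["fp"], cnt["fn"]))
    }
  invisible(x)
}
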