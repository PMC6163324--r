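#' Multichannel cane recording
#'
#' Container for a uniformly sampled recording from an instrumented cane:
#' strain-gauge loading, gyroscope anteroposterior (AP) angular velocity and,
#' optionally, a binary push-switch contact channel. Strain units are left
#' arbitrary (positive under load); all downstream processing is shape- and
#' sign-based, never absolute-amplitude-based. AP velocity is in degrees/s,
#' positive during forward swing.
#'
#' @param strain Numeric vector of strain-gauge loading values.
#' @param gyro_ap Numeric vector of AP angular velocity (degrees/s), same
#'   length as `strain`.
#' @param sample_rate_hz Sampling rate in Hz (default 231, the cane's rate).
#' @param switch Optional binary (0/1) push-switch channel, same length.
#' @param t Optional explicit time vector in seconds. Defaults to
#'   `(0:(n-1))/sample_rate_hz`. Must be uniform at `1/sample_rate_hz`
#'   within 1e-9 relative tolerance.
#' @param meta Free-form named list (participant id, terrain labels, seed).
#'
#' @return An object of class `cane_recording`: a list with elements
#'   `sample_rate_hz`, `t`, `strain`, `gyro_ap`, `switch` (possibly `NULL`)
#'   and `meta`.
#' @export
cane_recording <- function(strain, gyro_ap, sample_rate_hz = 231,
                           switch = NULL, t = NULL, meta = list()) {
  if (!is.numeric(strain) || !is.numeric(gyro_ap))
    stop("`strain` and `gyro_ap` must be numeric vectors")
  n <- length(strain)
  if (n < 2L) stop("recording must contain at least 2 samples")
  if (length(gyro_ap) != n)
    stop("channel length mismatch: strain has ", n, " samples, gyro_ap has ",
         length(gyro_ap))
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1L ||
      sample_rate_hz <= 0)
    stop("`sample_rate_hz` must be a positive scalar")
  if (is.null(t)) t <- (seq_len(n) - 1) / sample_rate_hz
  if (length(t) != n) stop("`t` must match the channel length")
  dt <- 1 / sample_rate_hz
  if (any(abs(diff(t) - dt) > 1e-9 * dt))
    stop("time vector is not uniform at 1/sample_rate_hz")
  if (!is.null(switch)) {
    if (length(switch) != n) stop("`switch` must match the channel length")
    if (!all(switch %in% c(0, 1)))
      stop("`switch` must contain only 0/1 values")
    switch <- as.integer(switch)
  }
  structure(list(sample_rate_hz = sample_rate_hz, t = t,
                 strain = as.numeric(strain), gyro_ap = as.numeric(gyro_ap),
                 switch = switch, meta = meta),
            class = "cane_recording")
}

#' @export
print.cane_recording <- function(x, ...) {
  cat(sprintf("<cane_recording> %d samples @ %g Hz (%.2f s)%s\n",
              length(x$strain), x$sample_rate_hz,
              length(x$strain) / x$sample_rate_hz,
              if (is.null(x$switch)) "" else ", with switch channel"))
  invisible(x)
}

#' Stride template for matched filtering
#'
#' One stride of strain-gauge data used as the matched-filter template. The
#' template is non-degenerate (not all values equal) and at least 10 samples
#' long.
#'
#' @param values Numeric vector, one stride of strain data.
#' @param sample_rate_hz Sampling rate of the template in Hz.
#' @param source Free-form provenance string.
#' @return An object of class `stride_template`.
#' @export
stride_template <- function(values, sample_rate_hz = 231,
                            source = "unspecified") {
  if (!is.numeric(values) || length(values) < 10L)
    stop("template must be a numeric vector of length >= 10")
  if (diff(range(values)) == 0)
    stop("template is degenerate: all values are equal")
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0)
    stop("`sample_rate_hz` must be a positive scalar")
  structure(list(sample_rate_hz = sample_rate_hz,
                 values = as.numeric(values),
                 source = as.character(source)[1]),
            class = "stride_template")
}

#' Gait event
#'
#' A time-stamped gait event of one of the four kinds: initial contact (IC),
#' terminal contact (TC), peak swing (PS) or end contact (EC). The sample
#' index is 1-based: `index = round(time_s * sample_rate_hz) + 1`.
#'
#' @param kind One of `"IC"`, `"TC"`, `"PS"`, `"EC"`.
#' @param time_s Event time in seconds (>= 0), or `NA` for an event that was
#'   not observed (only meaningful inside invalid cycles).
#' @param sample_rate_hz Sampling rate of the owning recording.
#' @return An object of class `gait_event`.
#' @export
gait_event <- function(kind, time_s, sample_rate_hz = 231) {
  kind <- match.arg(kind, c("IC", "TC", "PS", "EC"))
  if (!is.na(time_s) && time_s < 0) stop("event time must be >= 0")
  structure(list(kind = kind, time_s = as.numeric(time_s),
                 index = if (is.na(time_s)) NA_integer_
                         else as.integer(round(time_s * sample_rate_hz)) + 1L),
            class = "gait_event")
}

#' Gait cycle
#'
#' An IC-TC-PS-EC quadruple with a validity flag and the matched-filter
#' similarity score at the anchoring peak. A valid cycle satisfies the strict
#' ordering IC < TC < PS < EC and EC - IC <= `cycle_window_s`.
#'
#' @param ic,tc,ps,ec Event times in seconds (`NA` allowed when `valid` is
#'   `FALSE`).
#' @param valid Logical validity flag.
#' @param similarity Matched-filter similarity in `[-1, 1]`, or `NA`.
#' @param sample_rate_hz Sampling rate used to derive sample indices.
#' @param terrain Optional terrain label carried from annotations.
#' @param cycle_window_s Maximum valid cycle duration in seconds (default 3).
#' @param check If `TRUE` (default), enforce the ordering/window invariants
#'   for valid cycles. Baseline segmenters that only estimate a subset of the
#'   events construct unchecked pseudo-cycles.
#' @return An object of class `gait_cycle`.
#' @export
gait_cycle <- function(ic, tc, ps, ec, valid, similarity = NA_real_,
                       sample_rate_hz = 231, terrain = NA_character_,
                       cycle_window_s = 3, check = TRUE) {
  valid <- isTRUE(valid)
  if (check && valid) {
    tt <- c(ic, tc, ps, ec)
    if (anyNA(tt))
      stop("a valid cycle must carry all four event times")
    if (any(diff(tt) <= 0))
      stop("valid cycle violates IC < TC < PS < EC ordering")
    if (ec - ic > cycle_window_s + 1e-9)
      stop("valid cycle exceeds the ", cycle_window_s, " s window")
  }
  if (!is.na(similarity) && (similarity < -1 || similarity > 1))
    stop("similarity must lie in [-1, 1]")
  structure(list(ic = gait_event("IC", ic, sample_rate_hz),
                 tc = gait_event("TC", tc, sample_rate_hz),
                 ps = gait_event("PS", ps, sample_rate_hz),
                 ec = gait_event("EC", ec, sample_rate_hz),
                 valid = valid, similarity = as.numeric(similarity),
                 terrain = as.character(terrain)[1]),
            class = "gait_cycle")
}

#' Annotation set
#'
#' Reference gait cycles, either from a human expert or from the simulator's
#' ground truth. Cycles are ordered by IC time and valid loading phases do
#' not overlap.
#'
#' @param cycles List of [gait_cycle()] objects.
#' @param provenance `"expert"` or `"simulator"`.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(cycles, provenance = c("simulator", "expert")) {
  provenance <- match.arg(provenance)
  ics <- vapply(cycles, function(cy) cy$ic$time_s, numeric(1))
  if (anyNA(ics)) {
    ord <- order(ics, na.last = TRUE)
  } else ord <- order(ics)
  if (is.unsorted(ics[!is.na(ics)]))
    cycles <- cycles[ord]
  # valid loading phases (IC..TC) must not overlap
  vi <- vapply(cycles, function(cy) isTRUE(cy$valid), logical(1))
  if (sum(vi) > 1) {
    icv <- vapply(cycles[vi], function(cy) cy$ic$time_s, numeric(1))
    tcv <- vapply(cycles[vi], function(cy) cy$tc$time_s, numeric(1))
    if (any(icv[-1] < tcv[-length(tcv)] - 1e-9))
      stop("overlapping loading phases in valid cycles")
  }
  structure(list(cycles = cycles, provenance = provenance),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  nv <- sum(vapply(x$cycles, function(cy) isTRUE(cy$valid), logical(1)))
  cat(sprintf("<annotation_set> %d cycles (%d valid), provenance: %s\n",
              length(x$cycles), nv, x$provenance))
  invisible(x)
}

#' Extract event times from a list of cycles
#'
#' @param cycles List of [gait_cycle()] objects (or an [annotation_set()]).
#' @param kind Which event time to extract: `"ic"`, `"tc"`, `"ps"` or `"ec"`.
#' @param valid_only Drop invalid cycles first (default `TRUE`).
#' @return Numeric vector of event times in seconds (may contain `NA`).
#' @export
cycle_times <- function(cycles, kind = c("ic", "tc", "ps", "ec"),
                        valid_only = TRUE) {
  kind <- match.arg(kind)
  if (inherits(cycles, "annotation_set")) cycles <- cycles$cycles
  if (valid_only)
    cycles <- Filter(function(cy) isTRUE(cy$valid), cycles)
  vapply(cycles, function(cy) cy[[kind]]$time_s, numeric(1))
}

#' Summarise a list of cycles as a data frame
#'
#' @param cycles List of [gait_cycle()] objects or an [annotation_set()].
#' @return A data frame with columns `ic_s`, `tc_s`, `ps_s`, `ec_s`,
#'   `valid`, `similarity`, `terrain`.
#' @export
cycles_df <- function(cycles) {
  if (inherits(cycles, "annotation_set")) cycles <- cycles$cycles
  data.frame(
    ic_s = vapply(cycles, function(cy) cy$ic$time_s, numeric(1)),
    tc_s = vapply(cycles, function(cy) cy$tc$time_s, numeric(1)),
    ps_s = vapply(cycles, function(cy) cy$ps$time_s, numeric(1)),
    ec_s = vapply(cycles, function(cy) cy$ec$time_s, numeric(1)),
    valid = vapply(cycles, function(cy) isTRUE(cy$valid), logical(1)),
    similarity = vapply(cycles, function(cy) cy$similarity, numeric(1)),
    terrain = vapply(cycles, function(cy) cy$terrain, character(1)),
    stringsAsFactors = FALSE)
}
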