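#' Zero-crossing and rate-reversal detectors
#'
#' Sample-level event primitives used by the segmenter:
#' * positive zero-crossings, where the signal transitions from negative to
#'   non-negative (IC/EC detection on strain);
#' * negative zero-crossings, the mirror image (TC detection on strain);
#' * rate reversals, negative-to-positive sign changes of the AP angular
#'   velocity marking the initiation of forward swing.
#'
#' A crossing between samples `i` and `i + 1` is reported at `i + 1`, the
#' first sample on the new side of zero.
#'
#' @param x Numeric vector (filtered signal).
#' @return Integer vector of crossing sample indices (possibly empty).
#' @export
positive_zero_crossings <- function(x) {
  if (any(!is.finite(x))) stop("signal contains non-finite values")
  n <- length(x)
  if (n < 2) return(integer(0))
  which(x[-n] < 0 & x[-1] >= 0) + 1L
}

#' @rdname positive_zero_crossings
#' @export
negative_zero_crossings <- function(x) {
  if (any(!is.finite(x))) stop("signal contains non-finite values")
  n <- length(x)
  if (n < 2) return(integer(0))
  which(x[-n] > 0 & x[-1] <= 0) + 1L
}

#' @rdname positive_zero_crossings
#' @param gyro_ap Filtered AP angular velocity vector.
#' @export
rate_reversals <- function(gyro_ap) {
  positive_zero_crossings(gyro_ap)
}
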