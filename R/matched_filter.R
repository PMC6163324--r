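#' Normalized matched-filter correlation
#'
#' Slides the stride template across the strain signal and returns, for
#' every lag, the normalized correlation between the template and the
#' aligned strain window. Both the template and each window are centred and
#' scaled (Pearson-style), so the output lies in `[-1, 1]`, equals 1 exactly
#' when the window is a positive affine scaling of the template, and the
#' "50% correlation" similarity gate is amplitude-independent. Windows with
#' zero variance (flat signal, which contains no stride) score 0 rather
#' than NaN.
#'
#' @param template A [stride_template()].
#' @param strain Numeric strain vector (same sample rate as the template,
#'   at least as long).
#' @return Numeric vector of length `length(strain) - length(template) + 1`;
#'   element `k` is the similarity of the window starting at sample `k`.
#' @export
correlate_template <- function(template, strain) {
  stopifnot(inherits(template, "stride_template"))
  h <- template$values
  m <- length(h)
  n <- length(strain)
  if (n < m)
    stop("template (", m, " samples) is longer than the signal (", n, ")")
  if (any(!is.finite(strain))) stop("strain contains non-finite values")
  # centring the whole signal first improves the conditioning of the
  # running sums; per-window Pearson scores are unaffected by the shift
  x0 <- strain - mean(strain)
  h0 <- h - mean(h)
  h0 <- h0 / sqrt(sum(h0^2))
  # sliding dot product: dot[k] = sum_j h0[j] * x0[k + j - 1]
  dot <- as.numeric(stats::filter(x0, rev(h0), method = "convolution",
                                  sides = 1))[m:n]
  cs <- cumsum(x0)
  cs2 <- cumsum(x0^2)
  wsum <- cs[m:n] - c(0, cs[seq_len(n - m)])
  wssq <- cs2[m:n] - c(0, cs2[seq_len(n - m)])
  denom <- sqrt(pmax(wssq - wsum^2 / m, 0))
  eps <- 1e-7 * sqrt(m) * (stats::sd(x0) + .Machine$double.xmin)
  r <- ifelse(denom > eps, dot / denom, 0)
  pmin(1, pmax(-1, r))
}

#' Similarity-gated anchor peaks
#'
#' Extracts local maxima of a matched-filter trace whose similarity reaches
#' the threshold, greedily enforcing a minimum separation (on conflict the
#' higher-scoring peak survives). Spurious positive peaks below the
#' similarity gate are discarded and never anchor a stride.
#'
#' @param r Matched-filter similarity trace (from [correlate_template()]).
#' @param similarity_threshold Minimum similarity in `(0, 1]` (default 0.5).
#' @param min_separation_s Minimum peak separation in seconds. Two strides
#'   cannot overlap by more than one loading phase, so half a template
#'   duration is the usual choice.
#' @param sample_rate_hz Sampling rate of the underlying signal.
#' @return A list with `indices` (strictly increasing sample indices of the
#'   retained peaks) and `scores` (their similarities). Both are empty when
#'   nothing clears the gate.
#' @export
detect_anchor_peaks <- function(r, similarity_threshold = 0.5,
                                min_separation_s, sample_rate_hz) {
  if (any(!is.finite(r))) stop("similarity trace contains non-finite values")
  if (similarity_threshold <= 0 || similarity_threshold > 1)
    stop("`similarity_threshold` must be in (0, 1]")
  n <- length(r)
  empty <- list(indices = integer(0), scores = numeric(0))
  if (n < 3) return(empty)
  i <- 2:(n - 1)
  is_max <- r[i] > r[i - 1] & r[i] >= r[i + 1]
  cand <- i[is_max & r[i] >= similarity_threshold]
  if (!length(cand)) return(empty)
  sep <- round(min_separation_s * sample_rate_hz)
  ord <- cand[order(-r[cand], cand)]
  kept <- integer(0)
  for (p in ord)
    if (!length(kept) || all(abs(kept - p) >= sep)) kept <- c(kept, p)
  kept <- sort(kept)
  list(indices = kept, scores = r[kept])
}
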