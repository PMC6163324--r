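---
title: "Multi-sensor matched-filter segmentation of cane-assisted gait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-sensor matched-filter segmentation of cane-assisted gait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canegait)
```

## The problem

An instrumented cane measures two complementary things: how hard the user
leans on it (strain gauges in the shaft) and how it moves (an IMU; here
only the anteroposterior angular velocity is used). Cane gait alternates
between a *loading phase* — tip on the ground, weight applied, bounded by
initial contact (IC) and terminal contact (TC) — and a *swing phase* — the
cane repositioned through the air, passing a velocity maximum (peak swing,
PS) and ending at the next ground contact (end contact, EC). Downstream
analyses (stride counts, stride-time variability, loading symmetry, fall
risk screening) all start from a segmentation of the raw channels into
IC–TC–PS–EC cycles.

The standard IMU-only approach — declare a stride at every angular-velocity
peak above a threshold (gyroscope peak detection, GPD) — works on level
ground and fails on terrain changes, because the swing-velocity amplitude
is terrain dependent (roughly halved on stairs) while the threshold is
fixed. The segmenter implemented here fuses the two channels so that no
amplitude threshold is needed anywhere.

## The segmentation model

Write $h(t)$ for a one-stride strain template and $x(t)$ for the unknown
strain signal. The matched filter correlates the two,
$r(\tau) = \int h(t)\,x(t+\tau)\,dt$, and occurrences of the template
produce positive peaks in $r$. Two normalization decisions make this
usable as a *similarity*:

* both the template and each sliding window are centred and scaled
  (Pearson normalization), so $r(\tau) \in [-1, 1]$ and $r = 1$ exactly
  when the window is a positive affine image of the template;
* windows with zero variance score 0 — a flat signal contains no stride.

A peak is accepted as a stride *anchor* when $r \ge 0.5$ ("at least 50%
correlation"). The gate is a statement about signal shape, not amplitude,
so a harder or softer push changes nothing. Anchoring tolerates
terrain-induced shape drift: the loading pulses of stair and slope strides
are stretched and rescaled versions of the flat pulse, and their
normalized correlation with a single flat template stays well above the
gate (numerically ≥ 0.84 across this package's terrain presets — measured,
and asserted in the test suite at the 0.5 gate the segmenter actually
uses).

Events are then taken from a fixed sequence of sign-based rules:

| event | rule |
|---|---|
| IC | negative→positive strain zero-crossing nearest the anchor, within ±0.5 s (ties to the earlier sample) |
| TC | first positive→negative strain zero-crossing after IC |
| EC | first negative→positive strain zero-crossing after TC (the next ground contact; equals the next IC in continuous walking) |
| PS | maximum of AP velocity between the first negative→positive rate reversal after TC and EC |

A cycle is **valid** when all four events exist in strict order and EC
falls within 3 s of IC. That window is the mechanism that rejects
"load-without-swing" episodes (leaning on the cane): loading continues
past the window, so no valid cycle is emitted. "Swing-without-load"
episodes (carrying the cane) produce no strain pulse, hence no anchor, and
are never seen. Anchors whose ±0.5 s window contains no positive
zero-crossing emit nothing.

Note the interval for PS is bounded by EC, not by a fixed duration: the
swing of interest is the one that ends at the next contact. The PS rule is
an argmax with *no* amplitude threshold — this is the design point that
makes the whole pipeline invariant to positive rescaling of either
channel, a property asserted exactly (event times and validity) in the
test suite.

### Parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `similarity_threshold` | 0.5 | – | minimum normalized correlation for an anchor |
| `ic_window_s` | 0.5 | s | half-width of the IC search window around an anchor; taken symmetric (the source material does not state sidedness) |
| `cycle_window_s` | 3 | s | validity window for TC/PS/EC after IC |
| `min_separation_s` | half the template duration | s | anchor separation; two strides cannot overlap by more than one loading phase |
| filter order / cutoffs | 6; 4 Hz (strain), 8 Hz (gyro) | – / Hz | preprocessing low-pass |

## Preprocessing

Both channels pass through sixth-order low-pass Butterworth filters (4 Hz
strain, 8 Hz gyro) applied forward–backward, i.e. zero phase. Zero phase
matters because timing errors are reported in milliseconds; a causal
filter's group delay would bias every event. The filter family is a
choice: only "sixth-order low-pass" is inherent to the design, and
Butterworth is the convention in gait processing (maximally flat passband,
no ripple to generate spurious zero-crossings).

Two numerical decisions, both measured rather than assumed:

* **Cascaded second-order sections.** A single direct-form order-6
  recursion with a 4 Hz cutoff at 231 Hz has poles crowded near $z = 1$
  and a round-off noise floor around $4\times10^{-5}$ of the input — far
  above the analytic two-pass stopband ($4\times10^{-9}$ at 20 Hz). The
  cascade realizes the stopband to near machine precision.
* **Mirror-reflection padding.** The signal is extended by even (mirror)
  reflection over three filter time constants
  ($3 f_s/f_c$ samples) before each pass, and each pass subtracts its
  first sample so a signal entering at steady state excites no startup
  transient. Odd (point) reflection — the other common convention — injects
  a step of $2x[n]$ into the pad whenever an edge value is nonzero; that
  step is in-band and rings into the interior. Mirror reflection preserves
  the local mean and leaves only a slope kink, which the low-pass removes.
  (A fixed padding of a few filter orders — the other common convention —
  is far shorter than the order-6 transient at these cutoffs, which is
  why the length scales with the filter time constant instead.)

## The GPD baselines

The comparison segmenter declares a stride (a PS event) at each AP-velocity
local maximum above a threshold, with a 0.5 s minimum peak separation.
Candidate peaks are extracted threshold-free first; the threshold then
selects a subset, which makes detection sets provably monotone in the
threshold — the property behind the ROC sweep's non-decreasing rates.

Threshold calibration follows the four conventional policies: `O`
(oracle: per recording *and per terrain*, the F1-maximizing threshold on a
0.05-step fraction grid against reference annotations, ties to the larger
fraction — an idealized upper bound, since deployment would need the
terrain before segmenting it), `IFS` (that participant's flat walk),
`UFS` (all participants' flat walks) and `U` (all recordings). For the
calibration-based policies the threshold is
`fraction × mean prominent peak amplitude` of the calibration set, with
"prominent" meaning at least 50% of the walk's maximum — so the mean
reflects stride swings rather than the smaller stance-phase rotation
humps. The fraction defaults to 0.5, the midpoint of the conventional
0.8→0.2 sweep.

For push-switch timing comparisons GPD must date IC and TC from the only
channel it uses. The surrogates implemented are the last ascending
zero-crossing before the peak (TC ≈ swing initiation) and the first
descending zero-crossing after it (IC ≈ the swing lobe dying out around
contact). How the original baseline dated these events is not specified in
the literature it descends from; these surrogates are the natural
gyroscope-only choices, and their systematic lateness relative to true
contact is exactly the error mode a contact switch exposes.

## Evaluation metrics

**Stride classification.** Detected valid cycles are greedily matched
one-to-one to reference valid cycles within 0.5 s (half the shortest
plausible stride period; the matching event is IC, or PS for
gyroscope-only baselines whose stride marker is the peak). TP = matched,
FN = unmatched reference, FP = unmatched detection, TN =
reference-invalid cycle with no detected counterpart. Greedy matching
equals exhaustive bipartite matching whenever events are separated by more
than twice the tolerance, which stride-periodic data guarantees; the test
suite checks the equality against a brute-force matcher.

**Stride-time variability.** The sample variance of consecutive PS-to-PS
intervals of detected valid cycles. Both error types perturb it: a missed
stride doubles an interval, a spurious detection splits one. Two
definitional choices were open:

* *intervals, not timestamps* — timestamp variance grows without bound in
  any correct segmentation;
* *within bouts* — intervals longer than the 3 s cycle window cannot join
  consecutive strides of one walking bout; they span standstills and are
  treated as bout boundaries. Without this exclusion a single pause
  dominates the variance of every algorithm quadratically, and — worse —
  rewards detectors that hallucinate events inside gaps, because an extra
  detection either splits the outlier interval or merely grows the
  variance denominator. Measured on gap-heavy simulations, an amplitude
  detector's "variability" fell *below the ground truth's own*, which is
  the signature of a broken statistic rather than of good segmentation.

**Push-switch timing error.** A cane-tip switch closes only once a
substantial load is applied and opens when the load falls below it again.
Signs follow the contact geometry: IC error
$= t_\text{close} - t_\text{IC}$, positive when the algorithm dates
contact before the switch can close (it should — the strain zero-crossing
precedes the load build-up); TC error $= t_\text{open} - t_\text{TC}$,
negative when the algorithm dates lift-off after the switch has opened.
Each event pairs with the nearest transition within 0.5 s; when
algorithms are compared, only cycles detected by all of them enter the
comparison.

## The simulator

Every waveform is analytic, so ground-truth instants are exact; realism
is sacrificed deliberately for testability.

* **Loading pulse**: a sine lobe clamped onto a constant baseline of
  −0.15 strain units, with the zero-crossings placed exactly at the
  generative IC and TC. The undershoot depth was chosen by measuring the
  zero-phase 4 Hz filter's crossing displacement on noise-free pulse
  trains: at −0.15 the displacement is 0–6 ms against a 15 ms event-timing
  budget, while shallower baselines (−0.05) displace crossings by up to
  17 ms because the filter smooths across the nearby baseline kink.
* **Swing velocity**: a short backswing dip (15% of the swing, 25% of the
  forward amplitude), then a skewed forward lobe peaking at PS (rise
  fraction 0.35) and overrunning the next contact by 30% of the swing
  duration — the cane is still rotating forward when the tip touches down,
  so the gyroscope's descending zero-crossing trails true contact. This
  overrun is what gives gyroscope-only IC estimates their characteristic
  lag.
* **Stance rotation**: while loaded, the cane pivots over its tip,
  producing a positive mid-stance velocity hump at 0.2–0.7 of the
  stride's swing amplitude. These humps are genuine angular motion that an
  amplitude threshold must reject; the matched-filter segmenter never sees
  them because its PS search is confined to the swing interval.
* **Variability**: stride periods are drawn per stride
  (SD 0.05–0.06 s by terrain, clipped at 3 SD); jitter moves stride
  *onsets* while within-stride geometry stays at the terrain mean, so
  PS-to-PS intervals equal the drawn periods exactly and the configured
  interval variance is recoverable from a correct segmentation. Swing
  amplitudes vary stride to stride (CV 0.12 on level ground, 0.22–0.25 on
  stairs — stair swings are short and hesitant), loads with CV 0.10.
* **Artifacts**, labelled invalid in the truth: `load_without_swing`
  (a 3.5–5 s loading hold; rejected by the 3 s validity window),
  `swing_without_load` (a carried-cane swing at 0.4–0.7 of normal
  amplitude — unloaded repositioning is gentler), and `pause`
  (a 1.2–2.2 s standstill, straddling the validity window so some
  adjacent cycles become intermittent-gait invalids). Default rates are
  0.02/stride, matching occasional abnormalities in healthy instructed
  walking; every walk ends with a short cane plant that closes the final
  stride's EC.
* **Push-switch**: closes wherever the noise-free load is at least
  `switch_close_load` (default 0.25 strain units, a substantial fraction
  of the ~1.0 peak load, emulating a tip switch that needs real weight).
  By the pulse geometry it closes ~58 ms after the true IC and opens
  symmetrically before TC, which generates the positive-IC/negative-TC
  error signature.
* **Noise**: additive white Gaussian per channel (SD 0.02 strain units,
  2 °/s) before filtering.

Terrain presets live in `inst/extdata/terrain_profiles.json` (invented,
versioned, not presented as measured): swing amplitude 100 °/s on flat
ground falling to 50–60 °/s on stairs, periods 1.10–1.30 s, loading duty
0.55–0.60. Seven walk scenarios (five single-terrain, two transition
walks) mirror a protocol in which each participant covers all of them.

**What the simulator does not emulate** — and hence what passing tests do
not establish about real data: measured strain/velocity waveform shapes
(the pulse family is analytic, not recorded), impact vibration and sensor
drift, turning and obstacle avoidance, pathological gaits, template
mismatch across users (one synthetic template matches all synthetic
strides by construction; with real data the single-template assumption is
a measured result, not a given), and any absolute strain calibration
(strain stays dimensionless throughout; nothing thresholds its absolute
value except the simulated switch).

## Numerical and degenerate-input choices

* Normalized correlation uses a sliding dot product plus running sums over
  a globally centred signal; windows whose standard deviation falls below
  $10^{-7}$ of the signal's score 0 (flat windows; the residual there is
  running-sum cancellation noise, not signal).
* Anchor peaks and GPD peaks break score ties toward the earlier sample;
  the IC search breaks distance ties toward the earlier crossing.
* Zero-crossings are reported at the first sample on the new side of zero;
  a crossing needs a strictly negative (resp. positive) sample before it,
  so a signal that starts at zero does not cross at its first sample.
* Two anchors claiming the same IC crossing collapse into one cycle,
  keeping the higher similarity.
* All-zero recordings segment to an empty cycle list; recordings shorter
  than three filter orders refuse to filter; templates must be at least 10
  samples and non-constant.
* Stride variability requires at least 3 valid cycles and 2 within-bout
  intervals, and signals a typed condition otherwise rather than returning
  a number.

## Scale of the shipped checks

The test suite and the acceptance script run entirely on simulated data:
100 random signal/template pairs up to 5000 samples for the correlation
oracle, 7 scenarios × 20 strides for clean event recovery, and 30
seeded "participants" (each walking all seven scenarios, ~140 strides)
for the ordering and timing comparisons. These sizes keep the full run in
the low minutes on one core while leaving the Monte-Carlo margins of the
qualitative orderings comfortable (the variance ordering holds in every
one of the 30 participants, not just in the mean).

## Known limitations

* The segmenter is offline: anchors, crossings and argmaxes are computed
  over the whole recording. Streaming operation would need a causal
  re-formulation of the zero-phase filter and of the PS window.
* EC is operationalized as the next positive strain zero-crossing after
  TC. A final stride before stopping therefore gets its EC from the
  terminal cane plant; a recording truncated mid-swing leaves the last
  cycle invalid.
* Baseline drift in the strain channel is not corrected (the simulator is
  drift-free); real recordings may need detrending before the
  zero-crossing rules apply.
* The 0.5 s IC window is symmetric by choice; a one-sided reading of
  "within 0.5 s" would shift behaviour only when strides are shorter than
  the window, i.e. implausibly fast cane gait.
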