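---
title: "Detecting gait events from an ear-worn IMU: methods and design notes"
author: "tpear authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting gait events from an ear-worn IMU: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpear)
```

## The problem

Most gait metrics start from a segmentation of a walking recording into gait
cycles, delimited by **initial contacts** (IC, foot strikes the ground) and
subdivided by **terminal contacts** (TC, the same foot lifts off). An
ear-worn six-axis IMU sees both legs through the head's coupling to the
trunk, but its mediolateral (ML) acceleration — which established ear-IMU
detectors use to find TCs and to assign laterality — is corrupted whenever
the head moves laterally: during instructed horizontal head turns and during
body turns. The package implements a baseline ML-dependent detector and
TP-EAR, which derives both events from the superior–inferior (SI) channel
and is therefore robust to those movements, together with the preprocessing,
turn segmentation, temporal parameters and evaluation protocol needed to use
and validate them.

All analysis happens in a body-referenced frame: `si` positive superior,
`ml` positive toward the participant's left, `ap` positive forward.
Accelerations are in m/s² (gravity included), angular rates in deg/s, and
the nominal sampling rate is 100 Hz. The north–east–down (NED) aerospace
convention appears only inside the orientation filter.

## Preprocessing and data quality

Lost transmission packets produce runs of missing samples. Following common
practice for wireless IMU rigs, a trial is **excluded** when more than 10
consecutive samples are missing, or — in evaluation workflows where labelled
ground-truth events exist — when any gap falls within 0.3 s of a reference
IC, since such a gap would directly corrupt the detection being scored
(`detect_gaps()`). The proximity rule needs reference events, so
detection-only workflows apply the long-gap rule alone. Gap detection treats
explicit `NA` rows and sample-index discontinuities identically; both occur
with dropped packets.

Surviving gaps are repaired channel-wise by a cubic spline through the
observed samples (`fill_gaps()`, Forsythe–Malcolm–Moler end conditions, so
polynomials up to cubic are reproduced exactly). Observed samples are never
touched. Leading/trailing gaps have no bracketing data and are filled by
nearest-value hold instead of spline extrapolation, which can diverge
cubically; trials damaged badly enough for this to matter are typically
caught by the exclusion rules first.

## Singular spectrum analysis

Both detectors rest on SSA of a 1-D acceleration signal
(`ssa_decompose()`). The signal of length $N$ is embedded in an $L \times K$
Hankel trajectory matrix ($K = N - L + 1$), decomposed by SVD, and each
eigentriple is mapped back to a series by anti-diagonal averaging. The
window is $L = 2\,\mathrm{s} \times f_s$ — long enough to separate the gait
fundamental from its harmonics even for slow walkers — falling back to 1 s
for recordings shorter than 4 s. At most 30 eigentriples are reconstructed
individually (gait signals concentrate their energy in a handful); the
remainder is folded into one residual series so the stored components always
sum to the input exactly, which the test suite asserts to $10^{-8}$ relative
error against a dense brute-force implementation.

Components are grouped as:

* **trend** — components with ≥ 95 % of spectral energy below 0.5 Hz *or*
  a dominant FFT frequency below 0.5 Hz. The second criterion catches
  secondary trend eigentriples that rank below the oscillatory pair; with
  only a leading-block rule, a drifting baseline leaves a visible mean
  offset in the trend-removed signal.
* **dominant** — among non-trend components, the pair whose dominant FFT
  frequencies agree within 20 % and whose combined singular-value energy is
  largest (a sinusoid occupies a pair of near-equal eigentriples); a lone
  oscillatory component is accepted when no pair matches. A constant or
  empty signal has no dominant group and `dominant_oscillation()` raises a
  flat-signal error rather than returning noise.
* **residual** — everything else.

This grouping is a design choice: classical SSA leaves grouping to the
analyst, and "dominant frequency" has to be made operational somehow. The
pair rule with an FFT-peak criterion is standard harmonic grouping. Known
limitation: when a slow trend is much larger than the oscillation
(drift range ≫ oscillation amplitude), trend–harmonic mixing leaks a small
offset into the dominant pair that no grouping can remove; over a typical
30 s trial the residual mean is below 1 % of the drift range.

## The detectors

Both start by zero-phase band-pass filtering (`bandpass()`): 0.5–5 Hz for
the baseline detector, 0.5–12 Hz for TP-EAR, whose branch rules need the
sharp IC/TC impact transients to remain visible. The filter is a Butterworth
cascade — a second-order high-pass at 0.5 Hz followed by a low-pass of the
configured order (default 4) — applied forward and backward. A single
band-pass transfer function with a lower edge at 0.01 of Nyquist places
poles at $|z| \approx 0.99$ and misbehaves numerically, which is why the
stages are separate. Short odd-reflection padding lets the filter state
settle outside the data.

**Baseline (Diao/Seifer).** ICs are the local maxima of the dominant SI
oscillation. Laterality comes from the signed difference between
consecutive samples of the dominant ML oscillation at the IC: positive
(ML rising, sway accelerating leftward) means a left IC, otherwise right.
The TC paired with an IC is the next local extremum of the *trend-removed*
ML signal — a maximum after a left IC, a minimum after a right one. The
polarity mapping depends on the ML sign convention, so it is exposed
(`invert_laterality`) with the default matching ML-positive-left. The chain
IC side → extremum polarity → TC is precisely what breaks under lateral
head motion, and a misclassified side sends the search to the wrong
extremum.

**TP-EAR.** For each dominant-SI peak a trusted-swing window opens at the
last point before the peak where the dominant signal is at 80 % of the peak
amplitude and closes at the next dominant minimum (`tpear_window()`).
The peaks of the band-passed SI signal inside the window are counted:

1. **two peaks** — first is the IC, second the TC (the usual straight-line
   walking pattern: the foot-strike transient, then the contralateral
   foot-off transient in early stance);
2. **more than two** — the IC is the peak closest to the dominant peak
   (ties resolve to the earlier peak); the TC is the latest peak with a
   positive (band-passed) value;
3. **one peak** — the segment is passed through a peak sharpener and
   re-counted; if one peak still remains, the IC is the dominant peak
   itself and the TC is the point of minimum gradient between the IC and
   the window end. An empty window (pathological noise) takes the same
   fallback, keeping one IC per dominant peak.

Laterality is assigned exactly as in the baseline. A final pass enforces
that every emitted TC lies strictly between its IC and the next IC.

Peak finding uses strict local maxima with a topographic-prominence guard of
5 % of the window's peak-to-peak range and no minimum-distance constraint
(the window already localizes events). Prominence is measured on the full
filtered series rather than the window slice, so a genuine peak sitting at
the window edge is not undervalued. Dominant-oscillation peaks — a smooth,
nearly sinusoidal series — are taken as derivative zero crossings with a
relative height gate (20 % of the series maximum) that suppresses the
decaying oscillation the SSA reconstruction rings into the quiet padding
before and after the bout. The gate is deliberately lenient: raising it
towards the ringing/real-peak margin risks dropping attenuated genuine
peaks mid-turn, and spurious edge events appear only as false positives,
which none of the reported metrics use.

The peak sharpener (`sharpen_peaks()`) subtracts a weighted, 3-sample
smoothed second difference taken on a 3-sample stencil,
$y_i = x_i - w\,(x_{i-3} - 2x_i + x_{i+3})$ smoothed. Curvature is most
negative at peaks and at shoulder inflections, so subtraction deepens the
notch between a peak and its shoulder without displacing well-separated
maxima; the stencil matches the ~30 ms width of heel-strike transients at
100 Hz. The operation is deterministic and sits behind an interface, since
any sharpener with these properties would do.

## Orientation and turn segmentation

Turns are found from the yaw angle, which requires an attitude estimate.
`estimate_orientation()` runs a quaternion **error-state Kalman filter** in
the NED frame: gyro propagation of the nominal quaternion, a 3-state
attitude-error covariance, and gravity-direction measurement updates from
the accelerometer, gated to samples whose specific-force norm is within 5 %
of gravity so that stride impacts and free-fall-like spans coast on the
gyro. Roll and pitch are observable from gravity; yaw is pure gyro
integration, initialized to zero — headings are relative, which is all the
turn criteria need, and no magnetometer is assumed. Defaults
(`gyro_noise = 0.01` rad/s/√Hz, `accel_noise = 0.1`, `init_cov = 1e-4`
rad²) are ordinary MEMS values; the filter sits behind an interface so a
complementary filter could be swapped in. Euler angles follow the intrinsic
Z–Y–X (yaw–pitch–roll) convention in degrees.

Yaw is unwrapped before differentiation and differentiated by central
differences (one-sided at the ends): the 30°/s threshold needs a low-noise
derivative, and central differences halve the phase error of one-sided
stencils. An optional moving-average smoother on the rate exists but is off
by default. `segment_turn()` then declares the turn start at the earliest
sample with $|\psi| > 15°$ **and** $|\dot\psi| > 30°/s$ (both at the same
sample — the criteria are a conjunction), and the end at the earliest
subsequent sample with $|\psi| \ge |\psi|_{\max} - 5°$, where the maximum
is taken over the whole trial because the turn ends when the head has
completed its rotation. The angle margins suppress false starts from
incidental head movements. If no sample meets the start criterion, or the
yaw excursion never exceeds 15°, a no-turn result (`NULL`) is returned —
distinct from an error.

## Temporal parameters

`build_cycles()` pairs consecutive same-side ICs (left cycles from L ICs,
right from R, independently) and computes, with $f_s$ the sampling rate:

$$\mathrm{stride} = \frac{IC_{end} - IC_{start}}{f_s},\quad
  \mathrm{stance} = \frac{TC - IC_{start}}{f_s},\quad
  \mathrm{swing} = \frac{IC_{end} - TC}{f_s}.$$

Stride is stored as stance + swing so the identity holds to the last bit.
Detected TCs carry no laterality, so the TC attributed to a cycle is the
first TC strictly inside the span; if several fall there the first is used
and a warning logged; a cycle with none is skipped (it costs sensitivity
downstream, never a crash). **Convention note:** when an event stream
contains both feet's foot-offs — as the simulator's ground truth does — the
first in-span TC is the *contralateral* foot-off, so the `stance` column
measures the IC-to-first-foot-off interval (terminal double support plus
nothing else, $(\text{stance fraction} - 0.5) \times \text{stride}$ for the
simulator's geometry) rather than anatomical ipsilateral stance. With
single-foot streams it is true stance. The attribution is deliberately
simple and symmetric between truth and detection, so error statistics
compare like with like.

## Evaluation protocol

Detected events are scored per kind (ICs against ICs, TCs against TCs),
ignoring side. A detected event may match a ground-truth event at most
300 ms away (`match_events()`); among feasible assignments the matching
maximizes the number of pairs, then minimizes the total absolute offset.
Because both streams are time-ordered, an optimal assignment is
non-crossing, and a dynamic program finds it exactly — the suite checks it
against exhaustive enumeration. Unmatched truth events are counted as
**false negatives** (the natural reading for a sensitivity statistic:
$\mathrm{sens} = 100\,\mathrm{TP}/(\mathrm{TP}+\mathrm{FN})$), unmatched
detections as false positives; the report notes this convention explicitly.
Laterality accuracy is the percentage of side-equal matched IC pairs.
Temporal errors pair truth and detected cycles through their matched
bounding ICs and report mean ± SD of the absolute and signed errors
(detected − truth) in ms. Parameter errors beyond 300 ms are retained by
default — large outliers are informative — with an optional exclusion left
to the caller. When ground truth comes from a separately clocked system,
`align_start()` removes the start-time offset by maximizing the integer-lag
cross-correlation of a shared signal.

## The simulator

`simulate_trial()` generates trials with exact ground truth so every stage
is testable without access to a motion-capture laboratory. Morphology:

* **SI**: gravity plus two Gaussian transients per step — a larger one at
  the IC (default 2 m/s², σ = 30 ms) and a smaller one (60 %) at the
  following foot-off. Gaussian bumps rather than recorded waveforms: their
  peak locations are analytically known, so detector correctness is
  decidable to the sample.
* **ML**: a sinusoid with one period per stride (the head sways toward the
  stance side once per stride), phased so that its slope at each IC encodes
  the side — rising at left ICs under the ML-positive-left convention —
  and its first correct-polarity extremum after an IC lands on the first
  following foot-off, the pattern the baseline TC rule assumes. This
  encoding is exactly the convention the detectors read, so laterality
  tests validate the chain end to end but cannot probe convention-breaking
  gaits (they would need real pathological data).
* **Trials are trimmed bouts**, as laboratory recordings are: the recording
  opens mid-swing (the pre-recording step's foot-off occurs shortly after
  the first IC) and closes while the final stance foot is still down. With
  20 cycles per side this yields exactly 40 ICs and 40 TCs, every
  trusted-swing window contains an IC/TC pair, and the truth stance column
  is uniform.
* **Head turns** (WalkV/WalkH emulation): additive sinusoids at the
  instructed ~2 Hz — on ML plus a yaw gyro oscillation for horizontal
  turns, on SI plus a pitch oscillation for vertical — at a default
  amplitude of half the ML sway (0.4 m/s²). That moderate default
  reproduces the qualitative failure mode that motivates TP-EAR
  (ML disrupted, SI untouched) without obliterating laterality entirely,
  which is what participants' actual head turns do to neither channel.
* **Body turn** (Turn emulation): a smoothstep yaw profile (onset,
  duration, total angle configurable), consistent gyro output, and a small
  ML coupling proportional to the yaw rate.
* White Gaussian noise on all accelerometer (default 0.05 m/s²; tests use
  0.1 as "moderate") and gyro channels; identical seeds reproduce trials
  bit for bit, and the noise streams are drawn before perturbations are
  applied, so enabling a head turn changes nothing else.

What the simulator does **not** emulate: step-to-step timing and amplitude
variability, asymmetric or festinating gait, soft-tissue and mounting
resonances, sensor bias drift and scale error, non-sinusoidal head-turn
kinematics, and turning-while-stepping interaction beyond the additive
coupling. Passing tests therefore demonstrate algorithmic correctness under
the stated signal model, not clinical performance on real recordings.

## Numerical choices and degenerate inputs

* Sample indices in event tables and CSVs are 0-based (device convention);
  in-memory series indices are 1-based (R convention); conversions happen
  at the event-table boundary.
* Threshold crossings (turn criteria, 80 % window opening) are evaluated on
  the sample grid with strict inequalities as stated; a ramp that touches a
  threshold exactly crosses at the next sample.
* The tie between equidistant window peaks ("closest to the dominant
  peak") resolves to the earlier peak.
* Zero ML difference at an IC maps to "right" (the rule is "positive means
  left, otherwise right").
* Empty inputs: an event stream without same-side IC pairs yields zero
  cycles; matching against an empty stream yields all-FN or all-FP;
  sensitivity with no truth events is `NA` (not applicable), never a crash.
* The SSA cap (30 eigentriples) is config-exposed; the residual remainder
  column keeps the reconstruction identity exact regardless.

## Validation problem sizes

The test suite validates reconstruction identities on 100 random signals
(lengths 300–1000), turn segmentation against a per-sample criteria scan on
50 seeded noisy logistic profiles, matching against exhaustive enumeration
on 100 random instances (≤ 12 events per side), end-to-end event recovery
on 25 seeded noiseless 20-cycle trials plus 30 moderate-noise seeds, and
the head-turn robustness contrast on 15 paired seeds. `scripts/acceptance.R`
re-runs the four task families at 10 seeds each and writes the resulting
sensitivities, laterality accuracies, temporal errors and turn-boundary
error to JSON.

## Known limitations

* Yaw from gyro integration drifts on long recordings; the turn criteria
  use relative yaw over tens of seconds, where drift at MEMS noise levels
  is negligible, but multi-minute recordings would need re-referencing.
* SSA edge effects ring a decaying oscillation into quiet spans adjacent to
  the walking bout; with the lenient dominant-peak gate this can emit a few
  false-positive events outside the bout. They are excluded from no
  reported metric, but a downstream step counter should trim to the bout.
* The baseline detector's ICs are dominant-oscillation peaks, which lag the
  raw impact transient by the fundamental's phase shift whenever the step
  cycle is asymmetric (a foot-off transient follows each strike). The lag
  cancels in stride time but appears as a constant stance/swing bias —
  visible in the acceptance report — which is intrinsic to the method, not
  a defect of the implementation; TP-EAR's raw-peak ICs avoid it.
* `match_events()` is quadratic in events per trial: fine for minutes of
  gait, not for hour-long streams.
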