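---
title: "Methods: eigenworm decomposition and synthetic validation in wormgait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eigenworm decomposition and synthetic validation in wormgait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(wormgait)
```

This vignette explains the models and procedures the package
implements, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the design decisions taken
where the methodology was genuinely open. It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## 1. Posture representation and the eigenworm model

A crawling worm's shape is reduced to a 26-point midline and the 24
signed turning angles between consecutive segments, head (#1) to tail
(#24), in radians. This representation is translation- and
rotation-invariant and is the common currency of all downstream
analysis.

`fit_eigenworms()` pools the valid frames of one or more recordings,
centers each angle by its time-mean, and takes the eigenvectors of the
24 × 24 covariance matrix: the eigenworms EW1…EW24, ordered by
explained variance. Assumptions worth making explicit:

- *linearity* — postures are modeled as linear combinations of fixed
  shapes; strongly coiled frames violate this and are flagged invalid
  upstream rather than decomposed;
- *stationarity of the basis* — one basis describes all conditions
  compared against each other. The package ships a canonical basis
  (`canonical_eigenworms()`, a plain-text fixture fitted on a
  50-recording synthetic default ensemble, marked synthetic in its file
  name) so that cross-condition comparisons share coordinates;
- *centering* — the covariance is computed on per-angle-centered data,
  and the projection step centers with the same means. Centering in
  both places is the internally consistent choice; the alternative
  (centering only at projection) would make the basis depend on the
  mean posture.

Sign of an eigenvector is arbitrary; for reproducibility each vector's
first nonzero component is made positive. All downstream statistics are
invariant to these sign choices (tested).

## 2. Mode decomposition and the additivity identity

`decompose()` reconstructs the **undulation mode** as the per-angle
means plus the projection of the centered angles onto EW1–2, and
defines the **turning mode** as the residual, which is identically the
EW3–24 reconstruction. Adding the means back into *both* modes would
double-count them and break the additivity identity
`undulation + turning = posture`; assigning them to the undulation mode
keeps the identity exact (residuals at machine precision, ~1e-16, with
a 1e-10 test bound) while the turning mode remains a pure deviation
from the mean shape. Mode amplitude is Σₖ|θₖ| per frame; for a
traveling wave of peak A the time-mean amplitude is 24·A·(2/π), which
the tests verify against numerical integration.

**Phase velocity.** The projection pair (a₁, a₂) rotates as the wave
travels. The pair is smoothed with a centered moving average
(`phase_smooth_s`, default 0.5 s — "gentle" smoothing narrow enough to
leave the ~0.45 cycles/s rotation untouched), the phase is unwrapped by
smallest-angle increments, and the signed rotation rate is estimated by
central differences. Frames whose projection magnitude falls below 1 %
of the series median are masked: the phase of a near-zero vector is
numerically meaningless (this happens when the wave is suspended, e.g.
during deep coils). The sign convention is per-basis; what is
physically meaningful is the *dominant* sign within a recording
(animals crawl forward most of the time), and reversal detection uses
deviations from it.

## 3. The resampling test on variance spectra

`variance_resampling_test()` compares two groups of recordings by the
summed absolute difference between their cumulative variance-fraction
curves (per-group PCA on pooled valid frames). The null distribution
shuffles series-level group labels, preserving group sizes; frames are
never split across groups because frames within a series are strongly
dependent. The reported p-value is an upper bound,
`max(#exceedances, 1)/n_iter`: a permutation run can never claim p = 0,
only p ≤ 1/n_iter. Two practical notes: (i) p-values under the null
are uniform on {1/n_iter, …, 1} (tested at n_iter = 200 over 200
simulated nulls); (ii) with very small groups the original labelling
recurs among the shuffles — with 4 + 4 series it is redrawn about once
per 35 shuffles, making zero exceedances impossible — so the package's
own demonstrations use groups of ≥ 10 series.

## 4. Image → skeleton → angles

`render_worm()` builds a filled polygon from the 26-point midline, 25
fixed segment lengths and 26 cross-sectional widths (50 quadrilaterals
plus triangular head- and tail-most pieces). The body tables are
package data scaled to a 1 mm worm: widths peak (80 µm) at 40 % of body
length, rise from the head as √s (a blunt head cap) and fall toward the
tail as u^0.6. The tail exponent matters: a near-linear taper is
sub-pixel wide over its last several pixels, so a rasterized silhouette
genuinely loses tail length, and the roundtrip below would be comparing
against geometry the image cannot contain.

`extract_skeleton()` runs: Zhang–Suen thinning (implemented in the
package; no installed dependency offers 2-D binary thinning), removal
of the 2 × 2 pixel blocks thinning can leave, a skeleton-pixel graph
with redundant diagonal edges dropped, and the longest end-to-end
geodesic as the midline (this is the branch-trimming step: spurs lose
to the main path). A cyclic skeleton graph means the body closes on
itself — a coil — and the frame is invalid; similarly,
`clean_binarize()` flags frames whose hole-filling closed a region
larger than 20 % of the body area (a filled coil would otherwise
skeletonize into a plausible-looking short midline). The traced path is
spline-smoothed against arc length (`spline_df = 14`), recentered on
the ridge of the distance transform (thinning and smoothing bias the
trace by up to a pixel; the ridge is the medial axis), followed by a
ridge walk from each end through the tapered tips to the boundary, and
resampled to 26 points equally spaced in arc length.

Skeletons shorter than 60 % of the running-median body length (11-frame
window) are artifacts and flagged invalid. Head assignment
(`orient_head()`) starts from the motion direction of the centroid
track and then propagates by endpoint proximity; during flagged omega
frames the proximity rule is suspended in favor of the direction rule.
The dorsoventral sign convention is arbitrary per recording (a single
frame cannot distinguish a worm from its mirror image); all shipped
statistics are sign-symmetric.

At the default rendering scale of 0.003 mm/px (chosen so that the
silhouette resolves the midline; the worm is ~330 px long and ~27 px
wide) the render → binarize → skeletonize → angles roundtrip recovers
smooth postures with |θ| ≤ 0.4 rad to a maximum error below 0.1 rad and
RMS below 0.05 rad (tested over 100 random frames). "Random" frames are
random *smooth* postures — a wave of random phase and amplitude plus a
random turn bump — because independent per-angle noise produces midline
wiggles below the body-width scale that no silhouette can represent.

A note on arc geometry: 26 points equally spaced on a semicircle give
25 chords whose direction advances by π/25 between neighbours, so each
of the 24 inter-segment angles equals π/25 (≈ 0.1257 rad), not π/24;
the test asserts the analytic value.

## 5. Behavioral-state detection

**Reversals.** Wave direction defines crawl direction, so the primary
detector flags sustained (≥ 0.3 s) phase velocity of sign opposite to
the recording's dominant sign. Frames whose projection magnitude is
below 30 % of the series median are not eligible: when the wave is
suspended (coils) the phase is undefined and its apparent sign is
noise. A centroid-only fallback (heading flips > 120° within 0.5 s) is
provided for tracks without posture and marked low-confidence.

**Omega turns.** A deep coil makes the midline point cloud compact and
swings the body axis. Eccentricity is computed from the eigenvalue
ratio of the point cloud — but averaged over 0.5 s, because for a
near-circular coil the single-frame ratio is noise-degenerate (λ₂ ≈ λ₁,
so tiny angle noise flips the ratio wildly). Events are timed by
sustained eccentricity below `e_min = 0.7` and confirmed by a body-axis
swing faster than `omega_min = 1.5` rad/s within ±0.75 s of the bout.
The axis speed is the 1 s *signed-mean* of the axis angular velocity:
the undulation wobbles the axis back and forth, and signed averaging
cancels the wobble while keeping the monotone swing of a forming coil.
The two conditions are combined at event level rather than frame-wise
because maximal compactness and maximal swing occur at different phases
of the maneuver. These thresholds were calibrated on synthetic injected
coils against the deepest shallow-turn C-shapes; the pre-calibration
starting values (0.85 and 2 rad/s on raw frame-wise signals) separate
poorly because ordinary C-shaped postures pass an 0.85 eccentricity
threshold and the wave wobble alone exceeds 2 rad/s.

**Pauses.** Phases of at least 2 s below 0.05 mm/s, tolerating
above-threshold gaps up to 1 s, on the symmetric-difference speed (the
window spans ±0.5 s at 10 frames/s, ±15 frames at 30). Note that this
windowing erodes roughly a second from each end of a stop, so stops
barely over 2 s are undetectable in principle; the generator's default
pause duration is 4 s for this reason.

`classify_states()` merges the three detectors into exclusive per-frame
labels (omega > reverse > pause > forward) and suppresses reversal
calls within ±0.75 s of a detected omega, where coil-phase artifacts
masquerade as backward waves. Against generator ground truth all three
detectors reach sensitivity and precision ≥ 0.9 (event-level matching
by interval overlap).

## 6. Track metrics

Speed is the distance between smoothed centroid positions
`half_window` frames apart divided by elapsed time, with values above
0.6 mm/s masked as tracking artifacts. Track curvature is |Δheading|
per distance crossed, heading taken from displacement across a 1 s
window; frames below 0.03 mm/s are masked (centroid wobble dominates)
and values above 31 rad/mm removed. Displacement per 30 s bin is the
straight start-to-end distance, reverse movement included.

## 7. O₂-gradient navigation

The arena maps position linearly to O₂ (defaults 4–21 % over 33 mm,
preferred isoline at 16 %). Bearing folds the angle between the
smoothed heading and the direction toward the optimum isoline into
[0°, 180°]; frames within 0.55 mm of the arena edges or below the
heading speed floor are masked. The weathervaning analysis (curving
bias dB/dX within forward runs, 20° bearing bins, summarized over
40–150°) is restricted to the sub-optimum region. The event- and
speed-based bearing statistics are *not* restricted (the module's
`restrict_below_optimum` flag): a hard spatial boundary skews the
bearing attribution of events that straddle it, and measured on an
unbiased random walker the restricted reversal statistic shows a
spurious contrast while the unrestricted one is clean.

Measurement choices that matter, each verified on null (gain-0)
ensembles:

- reversal events are attributed to the bearing 1 s *before* onset,
  restricted to forward frames: at the onset itself the smoothed
  heading is already contaminated by the flip;
- dB/dX is capped at 31 rad/mm like track curvature — near-stationary
  frames otherwise contribute unbounded values;
- the curving-bias and speed statistics exclude ±1 s around detected
  turn peaks (> 0.2 rad): path curling during a turn depresses
  displacement-based speed, and because bearing is folded, large random
  kicks near 0° or 180° masquerade as systematic steering;
- run segmentation drops forward runs shorter than 3 s or displacing
  less than 1 mm.

With these choices, each navigation gain of the population generator —
weathervaning, reversal bias, ARS slowing, ARS turning — moves only its
own summary statistic beyond 3 SE on a 20-run ensemble while the other
three and the full null stay within noise (tested).

The population profile uses 13 equal bins along the arena (bin width
1.3 % O₂); the chemotaxis index subtracts a paired control profile per
bin, and the cumulative low-O₂ index sums bins with centers below a
configurable zero-crossing concentration (default 13.8 %, in the source
study defined empirically as the bin where gradient and control
accumulation balance).

## 8. Calcium traces

dR/R is (R − mean R)/mean R in percent, the mean taken over valid
frames only, so the valid-frame mean of dR/R is zero by construction
and the quantity is invariant to rescaling both channels. Artifact
rules (all configurable, defaults chosen as procedure-faithful
stand-ins for per-cell manual thresholds): reference-channel drops
> 30 % of the rolling 1 s median, ratios beyond 5 MADs of the trace
median, single-frame relative jumps > 50 %. Exclusion never revalidates
a frame. One caveat the analysis drivers demonstrate: on a trace whose
genuine dynamic range is small, the MAD rule can flag real physiology
(e.g. pause-related dips), so exclusion belongs before, not after,
checking what the trace's normal range is.

Lag estimation takes the peak of the normalized cross-correlation
(positive lag = activity follows behavior); a peak on the boundary of
the searched range is flagged rather than trusted. Binned
activity-versus-behavior curves block-average both series over 0.5 s
before pooling; when the trace was acquired with a known or estimated
lag, the ratio is re-aligned by that lag before binning — without this,
behaviors briefer than the lag decorrelate entirely.

## 9. What the generator emulates — and what it does not

`generate_posture_series()` produces angle series
`A(t)·sin(ψ(t) − k·φ) + turning + noise` with: phase advancing at the
undulation frequency, reversing during reversals and freezing during
pauses; raised-cosine turning transients (default width 1 s) in
directions orthogonal to the two leading wave shapes, onsets locked to
wave-phase zero-crossings plus a 0.6 s lag; omega turns as held coils
(Tukey envelope, 30 % taper) of 5.4–5.7 rad total bend over segments
2–22, during which wave and turn transients are suspended — a coil is
an interruption of crawling, not a superposition, and the bend range
is where a 24-segment arc is roundest; Gaussian angle noise
(0.05 rad); and a centroid track integrated from the wave (speed ≈
speed_gain·A·f ≈ 0.2 mm/s), steered by the turn transients (per-event
reorientation proportional to signed amplitude), with heading diffusion
(0.04 rad/√s) and a gait-locked lateral sway (8 µm) because real
centroid tracks are never noiseless. An O₂ downshift drive (leaky
integrator of concentration drops, recovery τ = 90 s, normalized to
the full 21→4 % range) scales turning rate and amplitude up
(`turn_gain`, default 1.5) and undulation amplitude and frequency down
(`und_gain`, default 0.35), reproducing reciprocal, monophasic
regulation with gradual recovery.

Default study conditions used by the tests and the acceptance script:
50 recordings × 60 s at 10 frames/s for basis fitting; 15 × 180 s for
detector scoring; 20 worms × 300 s per navigation configuration;
n_iter = 1000 for the resampling demonstration. These sizes give the
ensembles enough events for stable statistics while keeping each
analysis re-runnable in minutes.

Known limits of the emulation — hence of what green tests can and
cannot certify about real data:

- turning transients live in a low-dimensional shape family; real
  turning postures are richer, so real eigenspectra will put less
  variance in the first components than the synthetic ~97 % (the
  acceptance bound is one-sided at 85 % for exactly this reason);
- the coupling model multiplies rate *and* amplitude of turn
  transients; under this coupling the skewness of the turning-amplitude
  distribution saturates as the tail fills, so the package's
  distribution checks assert the monotone rightward stretch of the
  distribution (mean and 90th percentile), not a monotone skew
  increase;
- frame-level correlation between track curvature and turning amplitude
  is diluted by the turning-mode noise floor (Σ|noise| over 22
  components); the graded relation is a property of the binned-median
  curve, which is what the package tests;
- the body model's widths and segment lengths are package data, not
  measurements; the roundtrip accuracy statement is self-consistent
  with respect to them;
- no biomechanics (no thrust, friction or body-environment
  interaction), no neural circuitry, no 3-D or swimming gaits, no
  multi-worm collisions.

## 10. Numerical conventions

Angles in radians, coordinates in mm, time in seconds everywhere;
conversions happen only at ingestion. Missing values are explicit NAs;
invalid frames keep their rows. Cross-correlation convention: a peak at
positive lag means the second signal lags the first. Eigenvector sign:
first nonzero component positive. Permutation p-values are upper
bounds and never zero. Track tables are versioned delimited text;
configuration is YAML merged strictly over documented defaults
(unknown keys are errors), and pipeline outputs carry the
configuration hash and seed so that a run is a pure function of
(inputs, config, seed).
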