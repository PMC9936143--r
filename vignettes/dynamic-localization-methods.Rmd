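---
title: "Methods: simulating and analysing dynamic sound localization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing dynamic sound localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynloc)
```

This vignette documents the models, conventions, numerical choices and
limitations behind `dynloc`. The package implements the machinery of a
dynamic sound-localization experiment — binaural stimuli whose cues are
selectively manipulated, gated after a small instructed head rotation, and
scored with lateral/polar precision errors and front–back confusion (FBC)
rates — together with a synthetic-listener simulator so that the whole
chain can be exercised and validated without measured data.

## Coordinate conventions

Azimuth is positive toward the listener's **left**, elevation positive up;
interaural-polar coordinates use the lateral angle `lat = asin(y)` and polar
angle `pol = atan2(z, x)` of the unit vector (x front, y left, z up), with
the polar angle wrapped to [−90°, 270°): 0° is front at eye level, 90°
overhead, 180° behind. Directions sharing one lateral angle form a sagittal
plane ("cone of confusion") — the locus the ITD cannot disambiguate, which
is why the polar dimension and the front/back distinction are carried by
monaural spectral cues and by cue dynamics under head rotation. The
literature is split on whether positive azimuth means left or right; the
choice only relabels signs and affects no metric. Head orientations compose
yaw → pitch → roll about body axes; positive yaw turns left (matching
positive azimuth) and positive pitch tilts up. Roll is carried but never
driven by the experiment generators. At the interaural poles
(|lateral| = 90°) the polar angle is undefined; `atan2(0, 0) = 0` is used
as a stable canonical value.

Angular distance is computed as `atan2(|v1 × v2|, v1 · v2)` rather than
`acos(v1 · v2)`: the `acos` form cannot resolve angles below about
1.2 × 10⁻⁶ degrees in double precision, which matters for the VBAP
reconstruction checks.

## Source grid and sessions

The default grid places 41 directions on seven sagittal planes (lateral 0°,
±20°, ±40°, ±60°), 11 of them on the median plane, with denser polar
sampling near and above the overhead point, all within elevations
[−47°, 90°] (the coverage of a full-sphere loudspeaker array truncated
below −47°). The exact coordinates are a parameterised choice constrained
by those published facts (counts, ranges, density); any layout satisfying
them exercises the pipeline identically, so the constructor accepts
arbitrary plane layouts and validates uniqueness and elevation range.
Median-plane directions enter each test list twice (left–right symmetry
halves the effective sampling there), giving 52 entries. A static session
is 3 conditions × 3 repetitions = 9 blocks of 52 trials; a dynamic session
is 4 conditions × 3 repetitions = 12 blocks of 4 arrows × 52 = 208 trials.
The static session omits the frozen condition because a frozen set is
indistinguishable from the full set while the head is stationary. Block
order is randomized per subject and trial order per block, all derived
from one session seed through a splittable linear-congruential scheme, so
plans are bit-reproducible.

## HRTF chain

**Minimum phase.** Two constructions are provided. The default (`"exact"`)
computes the roots of each FIR's coefficient polynomial, reflects the
non-minimum-phase zeros across the unit circle (scaling by the reflected
radii to keep the magnitude), and then imposes the input's exact FFT
magnitude on the resulting phase. This preserves magnitude to machine
precision *and* satisfies the minimum-energy-delay property (the cumulative
energy curve dominates the input's at every sample) exactly, including for
spectra with deep dips. The `"cepstrum"` method (folded real cepstrum) is
kept as the fast approximation for internal use — e.g. as the zero-delay
reference in TOA estimation — where only magnitude fidelity matters; its
energy-delay property degrades when cepstral aliasing is significant.

**TOA.** Estimated as the lag maximising the cross-correlation between an
impulse response and its own minimum-phase version, with parabolic peak
refinement. The model TOA is the single-ear spherical-head (Woodworth-type)
form `τ = (r/c)(1 − cos γ)` on the ipsilateral side and
`τ = (r/c)(1 + γ_rad − π/2)` in the shadow zone — continuous at γ = 90° —
with defaults r = 8.75 cm, c = 343 m/s, giving a maximum ITD of
(r/c)(1 + π/2) ≈ 0.656 ms.

**Mesh and VBAP.** The sparse grid is triangulated by its convex hull (an
incremental algorithm written in the package, since no installed R package
provides 3-D hulls); faces are subdivided by sphere-projected edge
midpoints, deduplicated across shared edges, so one pass maps V → V + E and
F → 4F (icosahedron: 12 → 42 → 162 → 642 vertices over three passes; the
91-direction default grid gives 5,698 dense directions — the package
reports its own Euler-consistent counts and hard-codes none). VBAP gains
solve `L g = p` for the face whose solution is all-nonnegative and
normalise `g` to unit Euclidean norm, so the reconstructed direction
`L g ∝ p` is exact to solver precision.

**Interpolation.** Dense magnitudes are blended in the **dB (log) domain**
with VBAP gains renormalised to sum to one. Log-domain blending treats
spectral cues as level ratios and avoids the comb artifacts of
linear-amplitude averaging; whether the original real-time engines blended
in dB or linear amplitude is generally unstated, and the choice is
confined to one function. Phase is rebuilt as the minimum phase of the
blended magnitude and the model TOA is applied as a delay.

**Fractional delay.** TOAs are inserted as an *exact frequency-domain
linear phase* (circular, Hermitian-symmetric) rather than a windowed-sinc
FIR: it is the ideal band-limited shift, preserves the magnitude spectrum
exactly at every bin except Nyquist, and makes the dITD vary smoothly with
direction. The one unavoidable artifact of any real-valued fractional
delay is the Nyquist bin, which must carry a factor cos(πd); consequently
"identical" impulse responses that have been through different numbers of
delay–rebuild cycles agree bit-tight in magnitude at all non-Nyquist bins
but only to ~10⁻³ in the time domain. Tests therefore compare magnitudes
excluding the Nyquist bin tightly, and impulse responses loosely.

## Cue conditions

**Flat.** Within 1–16 kHz the per-direction, per-ear log-magnitude `m` is
replaced by `m̄ + C(m − m̄)`; `C = 0` removes all monaural spectral
contrast, `C = 1` is the identity. The reference level `m̄` is the dB value
of the in-band **power mean** (RMS level), not the arithmetic mean of dB
values: with deep spectral notches the arithmetic-dB mean sits ~1 dB below
the energy level, and flattening to it would shift the broadband level —
and hence corrupt the ILD, which the flat condition is explicitly supposed
to keep. With the power-mean reference the per-ear broadband level is
preserved (< 0.2 dB change on the synthetic listener) and the stored TOA
is re-applied unchanged, so ITD and dITD survive exactly.

**Frozen.** Every direction receives the reference direction's per-ear
magnitude (MSS and ILD frozen) while keeping its own TOA (ITD and dITD
intact). The reference can be any grid direction or, with
`interpolate = TRUE`, an off-grid direction blended by VBAP — the renderer
uses this to freeze a set to the head-relative source direction at
stimulus onset, which is the experimentally relevant reference.

Freeze and flatten commute (both orders yield the flattened reference
magnitude everywhere with per-direction TOA), which the tests verify.

## Rendering

The stimulus is a seeded white-noise burst, brick-wall band-limited to
20 Hz–20 kHz (clipped to Nyquist), peak-normalised and gated with 5-ms
raised-cosine ramps; default duration 2 s. Rendering cuts the stimulus
into 50%-overlapping squared-sine frames with a 5-ms hop (constant
overlap-add, so a static head reproduces direct convolution exactly — the
hop is shorter than typical tracking latencies and inaudible on noise
carriers); each frame is convolved with the nearest dense-grid HRTF for
the head-relative source direction at the frame centre, with the tracking
latency subtracted from the lookup time. Gating measures rotation about
the **instructed axis only** (matching the screening definition), finds
the first crossing of the 10° threshold by linear interpolation between
tracker samples, and ramps the *output* to exact zero over 5 ms. The
free-field condition is represented by its VBAP loudspeaker gain vector;
no room or transducer acoustics are modelled.

## Synthetic listener

The parametric HRTF model provides the three static cues and their
dynamics: spherical-head TOA (ITD), a high-shelf head shadow proportional
to the sine of the lateral angle (ILD, up to ~8 dB per ear), and a
Gaussian-in-log-frequency spectral notch whose centre rises from 6 to
12 kHz as the polar angle goes from −45° to 90° (MSS), mirrored with a
slight downshift and an extra rear tilt behind the listener so front and
back are spectrally distinguishable. A small seeded spectral ripple makes
directions generic. The default measurement grid has 91 directions over
elevations −47°…90°.

Trajectories are zero during a reaction delay, then follow a
raised-cosine velocity profile about the instructed axis covering a 20°
excursion, with smoothed Gaussian wobble (SD 0.5–0.6°) on the orthogonal
axis. Peak velocities and reaction times are drawn **log-normal with
moment matching** to the configured population values (36.41 ± 23.03 °/s
yaw, 28.54 ± 17.50 °/s pitch, reaction ≈ 150 ms): these quantities are
positive and right-skewed, and a truncated normal would bias the mean
upward by ~3 °/s.

Responses perturb the target's interaural-polar coordinates: Gaussian
lateral scatter (clamped to ±90°), wrapped Gaussian polar scatter, and
with the cell's reversal probability a prior mirror of the polar angle
across the frontal plane (`pol → 180° − pol`), i.e. a confusion on the
same cone. Modelling the reversal as a polar mirror keeps FBC and polar
precision separable, mirroring how the metrics are defined. Subject
heterogeneity enters the scatters multiplicatively (log-normal, CV set
from the configured between-subject SD) and the reversal probability
additively on the log-odds scale. The default cell table encodes the
population-level pattern such experiments report — static free-field
scatter near 9.3° lateral / 20.4° polar with ~15% reversals, strong FBC
reduction under yaw (most pronounced without spectral cues: 0.40 → 0.15
in the flat condition), no comparable reduction under pitch, and only
small precision differences — so the inferential stage has a realistic
alternative hypothesis; every value is overridable. Dynamic trials carry
rotation summaries drawn from the trajectory model, including a
configurable fraction of lapsed trials (undershot rotations, excess
off-axis wobble) for the screening stage to remove.

Two caveats on interpreting recovery: the *measured* FBC rate slightly
exceeds the generating reversal probability whenever targets sit near the
front/back boundary, because ordinary polar scatter can leak a response
more than 10° past the boundary without any reversal having occurred;
recovery tests therefore use targets well away from the boundary, where
the label is unambiguous. And the lateral clamp at ±90° mildly shrinks
lateral scatter for extreme lateral targets.

## Screening and metrics

Dynamic trials are kept iff on-axis rotation ≥ 5° and off-axis rotation
≤ 2° (both inclusive); static trials iff total movement ≤ 2° (the static
threshold is not dictated by the dynamic rules and is configurable and
logged). FBC classification excludes targets with |lateral| > 60°; the
target hemifield is front for polar ∈ [−90°, 90°]; a response counts as a
confusion iff it lies more than 10° past the front/back boundary (polar
90° / 270°) into the opposite hemifield. The "midline" that responses may
cross is read as the **frontal plane** — the rule governs front/back
classification, and a median-plane reading would not interact with
hemifields at all; both the boundary and the allowance are parameters,
and a stricter preset (30° lateral limit, zero allowance) is available as
an alternative definition. Per subject × condition × rotation cell: LPE is
the SD (n−1) of lateral errors about the cell mean; the FBC rate is the
percentage of confusions among eligible trials; PPE is the SD of circular
polar errors with confused trials removed first (keeping the metrics
independent). FBC-ineligible targets have no label and remain in the PPE
sample; cells with fewer than two usable trials report `NA` rather
than 0.

## Inference

Precision metrics are analysed at the cell level (one LPE/PPE value per
subject × condition × rotation) with
`value ~ condition * rotation + (1 | subject)` by REML; trial-level FBC
labels with the analogous logistic mixed model (Laplace approximation) —
the natural reading of "precision was analysed with a linear mixed model,
FBC with mixed-effects logistic regression". Singular REML fits fall back
to ML with a warning; factors with fewer than two observed levels drop
out of the fixed structure; rank deficiency caused *exactly* by empty
design cells (e.g. no frozen × static cell, since the static session
omits frozen) is tolerated — lme4 drops the aliased columns and the
affected marginal means are flagged non-estimable, whose contrasts are
omitted from the output, matching how such designs are tabulated.
Any further deficiency is an error naming the aliased terms. Marginal
means are compared pairwise with Tukey adjustment, one family per
grouping level (all rotation contrasts within one cue form a family, or
vice versa). The Monte-Carlo harness re-runs simulate → screen → metrics
→ model on a compact 12-direction grid (~40 trials per cell, 7 subjects)
and records rejection of a pre-specified contrast: under null parameters
the rejection rate of the static-vs-yaw LPE contrast estimates the type-I
error; under the default reversal drop (0.40 → 0.15 under yaw in the flat
condition) the logistic rotation contrast estimates power. Two hundred
replicates of each run in a couple of minutes on one core; these problem
sizes are the package's validation choices and are parameters of the
harness.

## Numerical notes and limitations

- Tolerances: minimum-phase magnitude preservation and VBAP reconstruction
  are asserted at 10⁻⁹ dB and 10⁻⁶ degrees; flatten/freeze magnitude
  identities at 10⁻⁹ dB excluding the Nyquist bin (see above); frozen-set
  ITD preservation within 1 sample at 48 kHz.
- `estimate_toa` assumes impulse responses whose energy concentrates after
  a clean onset (true of the synthetic listener and of minimum-phase
  reconstructions); heavily reverberant responses would need onset
  detection instead.
- The behavioral simulator is decoupled from audio rendering: responses
  are generated from cue-level parameters, not by decoding rendered
  signals, so the renderer is validated by signal-level properties
  (convolution exactness, gating, crossfade continuity, frozen-spectrum
  stability) rather than by behavior. Passing tests demonstrate that the
  analysis recovers the generative parameters of this response model —
  not that the response model captures every feature of human data
  (direction-dependent biases, learning, attention lapses are all absent).
- The hull-based dense grid is a closed mesh; a physical loudspeaker array
  open below its lowest ring would yield slightly different dense-grid
  counts. The package reports whatever its own subdivision arithmetic
  gives and treats the count as an output, not a constant.
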