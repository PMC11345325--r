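---
title: "Simulating and quantifying the VA-ECMO mixing zone with vector flow imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and quantifying the VA-ECMO mixing zone with vector flow imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Under veno-arterial extracorporeal membrane oxygenation (VA-ECMO), oxygenated
blood is returned retrogradely through the femoral artery while the native
heart keeps ejecting anterogradely. The two streams meet in the aorta at the
*mixing zone*. Its location governs cerebral oxygen delivery and left
ventricular afterload, so tracking it while titrating the ECMO flow rate is
clinically important. High-frame-rate ultrasound vector flow imaging (VFI)
can visualize both flow direction and speed at kilohertz frame rates and is
a candidate bedside monitor for this.

`vfimix` implements, end to end and fully synthetically, the computational
chain of a bench-top VFI study of this problem: a pulsatile/counterflow
scene generator standing in for the aorta phantom, dual-angle plane-wave
Doppler acquisition, least-squares vector estimation, cardiac-phase
segmentation, five-group flow categorization with area-ratio statistics and
Welch comparisons, mixing-zone localization, and vector-projectile style
rendering.

## The synthetic flow scene

Each imaged plane is a 38 mm x 40 mm window (x lateral, z depth, z away
from the probe; angles counterclockwise from +x — this convention is used
everywhere). The vessel is a straight segment through the image center at
the position's anterograde axis angle; the lumen is the band within half a
vessel diameter of the centerline. Per-pixel *path coordinates* measure
distance from the aortic root along the centerline; the three default
positions are centered at 50, 110 and 180 mm (ascending aorta, distal arch,
mid descending aorta) with diameters 26.9, 24.0 and 23.7 mm. The ascending
and mid-descending diameters follow the phantom's printed outlet bores; the
arch diameter is not printed anywhere, so 24 mm is used as a plausible
intermediate. The default axis tilts are 15, 0 and -15 degrees: gentle
tilts representative of longitudinal views that also keep peak systolic
Doppler shifts below the per-angle Nyquist limit (at 0.7 m/s and steeper
tilts the depth component would alias; aliasing still occurs and is
handled, but it should not dominate the defaults).

**Cardiac stream.** A parabolic (Poiseuille-like) profile across the
diameter, gated in time by a smoothed systolic window
(`sin^2`, onset 0.1 s, width 0.3 s per cycle). The peak is calibrated so
that the cycle-mean volumetric flux through the root cross-section
(axisymmetric integration) equals the pump's cardiac output —
30 mL x 90 bpm = 2.7 L/min, giving centerline systolic peaks of about
0.7 m/s, so anterograde speeds sweep through the 0.25 m/s fast/slow
threshold. A full Womersley solution is deliberately out of scope; the
parabolic profile reproduces the qualitative regimes the analysis needs.

**ECMO stream.** A steady retrograde parabolic jet of 12 mm width — the
bore of the ECMO return tube — flux-matched to the set rate (0.35 or
1.0 L/min). The narrow jet gives realistic retrograde speeds (about 0.30
and 0.10 m/s centerline) that straddle the threshold at the high setting.

**The interface.** The two streams are blended logistically along the path
coordinate (half-width 4 mm, a tunable). The interface position follows a
momentum balance: `m = L * Qc^2 / (Qc^2 + Qe^2)` with `L = 230` mm of
modeled path, because where two opposed streams meet is set by their
dynamic pressures (`rho v^2`), which scale with the squared flux at fixed
cross-section. No analytic interface model is given for the phantom; this
form satisfies the qualitative constraints — distal end without ECMO flow,
root without cardiac flux, monotone rootward motion as ECMO flow rises —
and it is the simplest one that separates the two study regimes. The
cardiac flux driving `m` is low-pass filtered (time constant 0.15 s),
emulating the inertia of the decelerating cardiac stream: the interface
then sweeps distally through systole and collapses rootward through
diastole. With this single choice the high-ECMO interface reaches the
ascending aorta in late diastole while the low-ECMO interface stays around
the descending aorta — the contrast the bench study was designed to
produce. The time constant is a stream-momentum decay scale of order
100 ms, plausible for decelerating aortic flow; it was fixed once from
that reasoning.

**Vortices.** Lamb-Oseen vortices (Gaussian-smoothed core, divergence-free)
are injected during configurable time windows with a smooth 50 ms ramp. By
default the ascending aorta carries one vortex in early diastole under low
ECMO flow and a counter-rotating pair under high flow (colliding-stream
interactions grow with the ECMO rate), core radius 5 mm, peak tangential
speeds near 0.2 m/s, centers jittered by a seeded 0.5 mm perturbation. All
scene stochasticity draws from one seeded stream, so a scene is a pure
function of its configuration and seed.

**Pressure.** The pump's pressure trace is a periodic two-bump shape
(main systolic bump plus a smaller valve-bounce bump at 0.62 of the cycle,
reproducing the measured bi-modal waveform), scaled exactly to the
configured 81/57 mmHg.

## Acquisition and estimation

Plane-wave transmits alternate between -10 and +10 degrees at a 10 kHz
PRF, so each angle is sampled at 5 kHz. With 4 transmit pairs per vector
frame, a frame spans 8 events = 800 microseconds (1250 fps, the displayed
rate). The ensemble size per frame is not documented for the reference
system; 4 pairs is the smallest ensemble consistent with the printed frame
rate.

For steering angle `a`, transmit along the steered direction and receive
along depth give the round-trip Doppler frequency

    f_d = (f0 / c) * (v_x sin a + v_z (1 + cos a)),

the standard steered-plane-wave form. Frequencies wrap modularly into
`(-PRF/2, +PRF/2]` per angle and wrapped pixels are flagged; no unwrapping
is attempted by default. Measurement noise is zero-mean Gaussian in the
frequency domain (default SD 5 Hz — the phantom's silica scatterers give
high Doppler SNR; at 5 Hz the per-pixel velocity noise stays below the
0.02 m/s flow-area floor, while larger values are available for
noise-robustness experiments). In IQ mode the same frequencies are instead
synthesized as slow-time complex exponentials (plus complex white noise)
and read back with the Kasai lag-one autocorrelation estimator, which is
exact below Nyquist on clean exponentials.

Per pixel and frame the two (or more) Doppler equations are solved by
least squares (`argmin ||A v - f||`); with two angles this is an exact 2x2
solve, and the implementation goes through the general normal-equations
path so more angles work unchanged. Validity masking combines the lumen
mask, the aliasing flags and — only with more than two angles, where it is
informative — a residual threshold (3x the noise SD). No spatial or
temporal regularization is applied, matching the plain least-squares
contract of the reference framework.

## Phases, categorization, statistics

The systole onset is detected as the first frame where anterograde vectors
(within the 30-degree cone) occupy more than 5% of the proximal ROI — the
20% of lumen pixels nearest the inflow edge of the ascending-aorta image.
A pixelwise "first observation" would be noise-fragile; the 5% area
fraction is the smallest robust version of the same idea. The speed floor
for detection defaults to the analysis floor (0.02 m/s), which under the
smooth systolic gate delays detection by roughly 15 ms past the true gate
opening — visible in the pipeline's detected onset of ~0.11 s versus the
generator's 0.10 s and acceptable against the 0.3 s systole.

The cycle is partitioned into half-open windows: late diastole
`[0, onset)`, systole `[onset, onset + 0.3 s)`, early diastole
`[onset + 0.3, cycle)`. Half-open intervals resolve the boundary ambiguity
at the window edges; every frame belongs to exactly one phase.

Categorization follows the five-group rule: direction within 30 degrees of
the anterograde axis (one constant axis per position) is anterograde,
within 30 degrees of the opposite axis retrograde, anything else "other";
anterograde/retrograde further split at 0.25 m/s. Boundary conventions are
explicit and tested: exactly 0.25 m/s is *slow* (fast means strictly
above), a vector exactly on the cone edge is *inside*, zero-magnitude
vectors have undefined direction and are background, and the flow-area
denominator counts valid pixels at or above the 0.02 m/s floor (the
reference study does not define the denominator; the floor keeps
noise-level pixels from diluting the ratios). Per frame, the five ratios
sum to one whenever flow is present; empty frames carry an `NA` sentinel
rather than a fabricated ratio.

Per-phase summaries are arithmetic means and sample SDs (n-1) of the
per-frame ratios. Between-condition comparisons use Welch's t-test
(unequal variances, Welch-Satterthwaite degrees of freedom), implemented
from the closed form so that degenerate inputs (zero pooled variance) are
handled explicitly, and cross-checked against `stats::t.test` in the test
suite. P-values are reported per comparison without multiplicity
correction, as in the reference analysis; consecutive frames are not
independent, so these p-values describe the synthetic frame samples, not
beats.

**Mixing-zone localization.** Label maps from all positions are pooled
onto 4 mm path bins using the per-pixel path coordinates. For each bin and
frame, anterograde and retrograde area ratios within the bin are computed,
and their per-bin time averages give two profiles along the path; the
estimate is where they cross (linear interpolation at the sign change).
Averaging frame ratios rather than raw counts matters: the narrow
retrograde jet present in many diastolic frames would otherwise be
outvoted by the full-width systolic stream. Corner bins with little pixel
support are dropped; if the profiles have not crossed by the last sampled
bin but their difference is still declining, the crossing is extrapolated
from the last two bins (the mixing zone lies distal of the imaged field)
and clamped to the modeled path; otherwise a sentinel is returned.

## Rendering

The vector-projectile display seeds arrow "projectiles" in the lumen
(dense-small style: 30 per cm²; sparse-large, for vortex visibility:
8 per cm² with 2.5x arrows), advects them with explicit Euler steps at the
frame interval — at 800 microseconds and sub-m/s speeds the Euler error is
negligible, as the rotation-conservation test verifies — and respawns any
projectile that leaves the lumen or outlives its lifetime at a seeded
random position. Arrows are colored on a [0, 0.6] m/s ramp whose warm/cool
split marks the 0.25 m/s threshold. Composition places the synchronized
panels over the shared pressure trace with a moving cursor and writes a
PNG frame sequence plus a JSON manifest carrying frame rate, slowdown
(1/10-speed replay is `slowdown = 10`, encoded as output fps), offsets and
per-frame cursor metadata. Loop synchronization maximizes the circular
cross-correlation of the cycle-folded pressure waveforms (folding avoids
bias when the 1.5 s recording is not an integer number of 0.667 s cycles);
sub-sample refinement is out of scope.

## What the generator does and does not emulate

It emulates: the two-stream counterflow topology and its flow-rate-
dependent interface, cardiac gating with realistic speed ranges on both
sides of the 0.25 m/s threshold, diastolic vortices, Doppler physics
(projection, aliasing, noise, ensemble estimation) and the bi-modal pump
pressure. It does not emulate: speckle and beamforming (no point-spread
function — each pixel sees the true local velocity), wall deformation,
blood viscosity/non-Newtonian effects, 3D/out-of-plane flow, curvature of
the vessel within one image, or beat-to-beat variability (cycles are
identical). Passing tests therefore demonstrate the correctness of the
*computational chain* and the qualitative hemodynamic contrasts, not
quantitative agreement with any physical measurement: the bench study's
printed percentages are phantom outcomes and are mirrored here only as
directions of effect (high-ECMO late-diastole retrograde dominance at the
arch; low-ECMO systolic anterograde dominance in the descending aorta),
which the acceptance script recomputes at run time.

## Problem sizes and numerics

The default pipeline grid is a 2 mm pitch (20 x 21 pixels per plane) at
the full 1250 fps over 1.5 s — a coarse analysis grid that keeps the
two-condition, three-position demo fast while leaving dozens of pixels
across each lumen; flux-calibration checks use a 1 mm grid where the
trapezoidal cross-section integral is accurate to well under 5%.
Determinism is bit-exact: every stochastic stage derives its seed from the
run's global seed, and seeded helpers restore the caller's RNG state.
Degenerate inputs are first-class: equal systolic/diastolic pressure gives
a constant (unalignable) waveform, zero cardiac output puts the interface
at the root, all-retrograde fields raise an onset-not-found error, empty
frames carry ratio sentinels, and duplicate transmit angles are rejected
as rank-deficient.
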