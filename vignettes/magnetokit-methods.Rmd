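---
title: "magnetokit: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{magnetokit: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magnetokit)
```

magnetokit is a hardware-free companion to low-frequency magnetic
neuromodulation rigs: solenoid drivers switched by H-bridges, a sensor-gated
closed-loop controller, and camera-based rodent tracking. Every component is
computable at the desk: coil designs are evaluated analytically, stimulation
protocols are compiled and checked symbolically, and the controller and
tracking algorithms run on synthetic streams and rendered frames. This
vignette records the models, the tunable parameters, the numerical choices,
and what the synthetic tests do and do not establish.

## The magnetostatic field engine

### Model

All circular apparatuses are axisymmetric: a winding with rectangular
cross-section carrying uniformly distributed current. The engine
discretises each cross-section into `n_r x n_z` filamentary loops (default
20 x 20) with equal current share `turns * current / (n_r * n_z)` — the
same uniform-current-density idealisation a 2-D axisymmetric finite-element
model makes — and superposes the exact filament field, which is a closed
form in the complete elliptic integrals $K$ and $E$:

$$k^2 = \frac{4ar}{(a+r)^2 + z^2},$$
$$B_z = \frac{\mu_0 I}{2\pi\sqrt{(a+r)^2+z^2}}
  \left[K + \frac{a^2-r^2-z^2}{(a-r)^2+z^2}\,E\right], \qquad
B_r = \frac{\mu_0 I z}{2\pi r\sqrt{(a+r)^2+z^2}}
  \left[-K + \frac{a^2+r^2+z^2}{(a-r)^2+z^2}\,E\right].$$

Rectangular coils are discretised into rectangular filament loops; each
straight side contributes through the finite-segment Biot–Savart formula in
its numerically stable vector form.

The engine is validated two independent ways: against on-axis and
Helmholtz/square-loop closed forms, and against brute-force Biot–Savart
line-integral quadrature (20 000 segments), which agrees with the elliptic
form to better than $10^{-6}$ relative error off axis.

### Homogeneity

Field quality over a region is summarised by

$$H = \frac{B_{\max} - B_{\min}}{B_{\text{mean}}} \times 100\%$$

computed over $|B|$ samples on a regular grid (default 1 mm). We use the
vector magnitude $|B|$, not $B_z$ alone, because that is what a Hall probe
aligned with the local field reports; the choice matters only off the
mid-plane where $B_r$ is non-zero. Regions are centred on the array's
geometric mid-plane. Samples falling inside a winding volume are excluded
from the statistics (with a reported count) rather than erroring, since the
filament superposition is meaningless there.

### Numerical choices

* Filament grid 20 x 20 per cross-section: refining to 40 x 40 moves the
  reported homogeneities by less than 0.05 percentage points (tested).
* Evaluation grids at 1 mm inside stated regions; the grid is part of the
  definition of the reported extrema, since $B_{\max}$ of the arena regions
  sits at the region's radial edge a few millimetres from the winding.
* Points on a filament raise an explicit singularity error; there is no
  regularisation.
* `field_grid()` orders samples lexicographically by $(r, z)$ and
  `export_field_map()` writes 17 significant digits so text round trips are
  bit-exact.

### Where the analytic solution and FEM-style figures part ways

For a fixed geometry and drive, the analytic superposition is exact for the
uniform-current-density model, so we treat it as ground truth and treat
published finite-element figures for the same designs as consistency
checks with generous tolerances (field extrema 10% relative; homogeneity
max(2 percentage points, 25% relative)). Two systematic effects are worth
knowing about. First, FEM solutions computed in a finite air box with a
flux-line outer boundary are effectively shielded: the image currents
flatten and slightly depress the interior profile, and the effect grows
with coil size relative to the domain. Second, homogeneity is invariant
under uniform scaling of the field, so it is sensitive purely to profile
*shape*; a few percent of profile flattening can move a homogeneity figure
by several points while every field value stays within a few percent. The
six-coil 20 cm arena shows both effects most strongly; its design-stage
homogeneity figures computed here run a few points above the FEM-style
values, with the largest gap for the 15 cm-height region.

The nominal-wire resistance and Wheeler inductance estimators are
engineering conveniences with property tests only; as-built coils (lead
lengths, packing, temperature, actual turn counts) routinely read far from
nominal, so these are never treated as checks against hardware.

## The protocol compiler

A protocol is an ordered list of phases: `stim_duration` of field at
`frequency`, then `rest_duration`, repeated. Each phase begins with its
stimulation period (the gating that produces effects like "field only in
the dark chamber" belongs to the controller, not to phase ordering).

Bidirectional mode alternates the H-bridge direction every half-period
$1/(2f)$, opening each half-period with a both-pins-low **dead time**
(default 1 ms) so the bridge can never shoot through; the direction is then
held for $1/(2f) - t_{dead}$. Unidirectional mode is an on/off square wave
at 50% duty (the duty is a package choice; it makes the unidirectional
waveform the natural single-sided counterpart of the bidirectional one).
Dead time must be strictly below the half-period, validated at
construction. Stimulation windows compile in whole half-periods; a
fractional trailing remainder stays off.

Compiled waveforms satisfy, by construction and by randomized test (1000
protocols): pins never simultaneously high; every direction change
separated by at least the configured dead time; energized time exactly
`stim - transitions * dead_time`. Timing feasibility encodes the measured
behaviour of the firmware: with continuous sensing enabled the switching
is stable strictly below 200 Hz; with sensing disabled the compiler
accepts higher rates. The two extra per-cycle sensor reads are scheduled
at direction changes (the alternative — period boundaries — is
indistinguishable at the log level).

## The closed-loop controller

Stimulation is commanded iff three gates hold simultaneously:

1. the protocol timeline is in an ON interval;
2. every enabled sensor's latest reading is within its limits;
3. the tracked subject is inside the target area.

Gates are evaluated at poll instants only (default 20 Hz) — sampled
control, not continuous — which yields the latency bound: any breach gates
stimulation off within one poll interval. Further choices, all fail-safe:

* a reading exactly at a limit counts as a breach ("within limits" is
  read strictly);
* a sensor whose latest reading is older than two poll intervals is stale
  and gates stimulation off;
* `breach_action = "pause"` (default) resumes stimulation as soon as
  readings recover mid-interval; `"abort"` latches off. A physical rig
  might instead wait for the next ON interval; resuming immediately is the
  least surprising reading of "pauses stimulation" and the alternative is
  one latch away.

Logs are plain CSV with strictly increasing poll times; identical inputs
produce byte-identical logs.

## Tracking

The two chamber detectors mirror what a simple threshold tracker on a
webcam does. Frames are 8-bit grayscale (colour sources should be reduced
with the standard luma weights 0.299/0.587/0.114); pixel coordinates are
image-convention: x = column, y = row, 0-based, origin top-left.

A detection step is: crop to ROI, median blur (default kernel 5; the
kernel size is not dictated by the original method description, so it is
configurable), then threshold at 127 — above maps to white, at-or-below to
black. Median-blur borders use replicate padding, pinned down by a
pixel-by-pixel reference implementation in the tests. A pixel count at
exactly the count threshold means "in ROI" (the negative case is defined
by "below").

* **Light–dark**: the camera images only the light box. Enough target
  pixels in the ROI means the subject is visible, hence in the light
  chamber; otherwise it is in the dark chamber.
* **Three-chamber**: the camera images the middle chamber through two
  ROIs (its left and right halves). Either ROI above threshold means
  "middle", and the side memory records which ROI (the fuller one if
  both). Both below threshold means the subject has left towards the
  remembered side. With no memory yet the result is explicitly
  `undetermined`, never a guess; undetermined frames accumulate separately
  and are excluded from occupancy fractions.
* **Open field**: the centroid of the target pixels tracks locomotion;
  total distance is the summed centroid displacement times the user's
  mm/px calibration (the scale must come from the user's setup), and
  frames with no detection are bridged by measuring displacement to the
  next detection.

## Synthetic data and the virtual rig

The generators exist to make every algorithm testable end to end with
known ground truth:

* Arenas map the physical chamber sizes (14 cm boxes, 20 cm middle
  chamber, 10 cm open field) at 10 px/cm. The subject is a black disc of
  radius 12 px (2.4 cm — the scale of a crouched mouse seen from above)
  on a white background, matching the dark-coat-on-white-floor contrast
  the detectors are designed for.
* Walks are reflected correlated random walks: constant step length,
  Gaussian heading noise, reflection at walls. This is the simplest model
  that exercises every chamber-transition path; it is not a behavioural
  model of a mouse.
* Rendered frames optionally add i.i.d. Gaussian pixel noise. There is no
  motion blur, illumination drift, occlusion or shadow — so a passing
  recovery test says the algorithms are implemented correctly, not that
  they are robust to difficult real video.
* Sensor traces are per-kind baselines plus seeded Gaussian noise, with
  rectangular anomalies added over their windows.
* `virtual_rig()` wires walk, renderer, tracker and controller together
  at a common 20 Hz so each controller poll has a fresh position, and
  returns the log together with the ground truth for assertions.

Every generator is a pure function of its seed. Recovery guarantees are
stated on *unambiguous* frames — disc fully inside one decision zone, with
the deciding pixel count at least twice the threshold, and (for side
chambers) the side memory already initialised; frames straddling a zone
boundary are ambiguous for any threshold rule and carry no guarantee.

## Sensor models and statistics

Voltage conversions use nominal part behaviour — Hall: ratiometric with
null at mid-supply and 31.25 mV/mT at 5 V; temperature: 10 mV/°C with a
0.5 V offset; sound: 50 dB/V — and clip to the catalogue detection ranges
with an explicit flag. These constants are replaceable calibration values,
not measurements; the accelerometer is digital and is modelled as already
reporting g.

Agreement statistics are the standard ones: sample Pearson correlation and
Bland–Altman bias with limits of agreement at bias ± 1.96 times the
sample (n−1) standard deviation of the differences. The SUS questionnaire
scores as `(sum(odd - 1) + sum(5 - even)) * 2.5`. Device-agreement numbers
from physical bench sessions, behavioural statistics from animals, and
usability scores from human raters cannot be recomputed at the desk; the
package implements the metric definitions and validates them against
direct-formula oracles on synthetic data instead.

## Problem sizes used in the shipped tests

The test suite runs the full design evaluation at the 1 mm grid (231 to
20 301 samples per region), 1000 randomized protocols, 100 seeded breach
times at 20 Hz over 30 s sessions, and 20 seeded 400-frame videos per
chamber paradigm plus three 200-frame constant-speed walks; these sizes
keep the whole suite comfortably fast on one CPU while leaving every
property non-trivially exercised.

## Known limitations

* No magnetic materials, eddy currents, AC impedance or coil heating: the
  engine is strictly magnetostatic with air cores.
* The 24-well rectangular-coil apparatus is evaluated by the rectangular
  engine, but its published design figures are not used as checks: the
  two-cross-section model is ambiguous (planar vs axisymmetric reading,
  unstated axial gap), so only closed-form and quadrature properties are
  asserted.
* The controller is an offline/sampled emulation; it makes no real-time
  scheduling claims.
* Single subject, single blob: no multi-animal tracking or pose.
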