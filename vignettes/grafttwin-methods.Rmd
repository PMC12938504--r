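---
title: "grafttwin: models, controller design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{grafttwin: models, controller design and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grafttwin)
```

## What the package models

`grafttwin` is a desk-scale digital twin of an automated perfusion platform
for tissue-engineered vascular grafts (TEVGs). The platform pressurizes
small-caliber tubular samples with a roller pump and shapes the luminal
pressure waveform by proportionally pinching the outlet tubing with a
pinch-valve, under a two-stage control algorithm: an open-loop *pre-setting*
search for the valve closure levels that produce the target minimum and
maximum pressures, followed by closed-loop per-cycle PID regulation during
stimulation. The twin reproduces the platform's two operating modes:

* **Compliance testing** (ISO 7198): one sample, sinusoidal valve motion at
  1 Hz sweeping one of three pressure regimes (50–90, 80–120, 110–150 mmHg),
  with the sample filmed and its dynamic radial compliance measured from the
  video.
* **Coronary-like stimulation**: three samples perfused in parallel at
  540 mL/min total (180 mL/min each), with a *service compliance* chamber
  upstream and a piecewise valve law (half-sine closure over a 0.35 s
  systole, minimal compression for the 0.65 s diastole). Closing the valve
  raises pressure while flow is diverted into the service compliance;
  opening it releases the stored volume through the samples, producing the
  counter-phase, diastolic-dominant flow pattern characteristic of coronary
  perfusion.

## The hydraulic circuit model

The circuit is a three-node lumped-parameter (Windkessel-style) network:

```
pump --> [n1: reservoir+filter C] --R_up--> [n2: sensor "P", C_s] --R_s/n-->
    [n3] --R_down + R_valve(c)--> vented reservoir
```

Each node obeys volume conservation, `C_i dP_i/dt = inflow − outflow`, with
pressures in mmHg, flows in mL/min and time in seconds. The bench platform's
tubing resistances and chamber compliances are not catalogued anywhere, so
the element values are calibration choices of the twin, fixed once:

| element | default | rationale |
|---|---|---|
| sample resistance | 0.2 mmHg·min/mL | ~36 mmHg drop at 180 mL/min, a physiological coronary-bed order of magnitude |
| reservoir + filter compliance | 2.0 mL/mmHg | two 60 mL air-cushioned syringes |
| upstream segment resistance | 1.0 (compliance) / 0.25 (coronary) mmHg·min/mL | decouples the damping stage: its time constant with the reservoir compliance is tens of seconds, so over one 1 s cycle the stage is a stiff constant-flow feed, while pump ripple is still absorbed |
| service compliance `C_s` | 0.04 mL/mmHg | sized so one 0.35 s systolic closure can store enough of the 540 mL/min pump output to swing the sensor pressure by the full 40 mmHg excursion, with ~50% headroom; deliberately config-exposed, as it is the main flow-shaping knob |
| tubing compliance | 0.005 mL/mmHg | parasitic; gives every node a state |
| pump | constant-flow source, ≤ 600 mL/min | roller pump; ripple damped upstream, optional ripple hook off by default |

The valve maps closure fraction `c ∈ [0, 1]` to hydraulic resistance. No
transfer function is published for the pinch-valve, so the default is a
geometric (log-linear) interpolation, `R(c) = R_open (R_occ/R_open)^(c^k)`
with `R_open = 0.02`, `R_occ = 200` mmHg·min/mL and `k = 1`: the resistance
decades are spread evenly over the stroke, which gives the controller a
roughly uniform *relative* sensitivity across regimes. A power-law kind is
also available; both are strictly increasing and continuous, and the
occluded/open ratio is required to be at least 10^4 so that full closure
effectively blocks the line.

Integration is fixed-step explicit Euler at 1 ms. The fastest node time
constant under the defaults is ≥ 6 ms, so the scheme is comfortably stable;
halving the step changes simulated pressures by < 0.1%. Volume is conserved
by construction and the per-run ledger (pumped − returned − stored) is
reported; the suite checks it stays below 0.1% of pumped volume.

Simulated runs start with the damping stage *primed* at its cycling
equilibrium (mid-regime pressure plus the upstream resistive drop). Without
this, the stage's minute-scale charging transient siphons pump flow away
from the samples for the entire run — the warmed-up platform, not a cold
start, is the condition the bench numbers describe.

## Controller design

The pre-setting phase ramps closure upward from fully open in 0.02 steps
against the steady-state plant map (available in closed form for the lumped
network), brackets each target, and refines by bisection until the steady
sensor pressure is within tolerance (default 2 mmHg — the bench protocol's
tolerance is not published; 2 mmHg is consistent with the reported per-cycle
SDs). The Pmin level is found first, then the ramp continues to the Pmax
level, mirroring the platform's gradual closure adjustment.

During stimulation the motion law is scaled between the two pre-set
closures, and after every cycle the measured per-cycle extremes of the
emulated sensor stream (40 Hz, Gaussian noise SD 0.5 mmHg, 3-point moving
average) are compared with the targets. Two independent discrete PID
channels correct the closure envelope — `c_lo` from the Pmin error, `c_hi`
from the Pmax error — with anti-windup clamping on the integral and hard
clamping of commanded closures to [0, 1]. Whether the bench controller acts
continuously within a cycle or on per-cycle extremes is not published;
per-cycle envelope correction is the simplest reading consistent with a
cyclic reference waveform, and it is what the twin implements.

The two knobs see very different plants. In the compliance configuration
the sensor node is quasi-static, so sensitivity is the steady map slope
(~500–1100 mmHg per unit closure); gains `kp = 2e-3`, `ki = 5e-4`
closure/mmHg give a loop gain near 0.6 and settling within ~5 cycles. In
the coronary configuration the service compliance integrates flow during
the 0.35 s systole, attenuating the peak-pressure response to ~100 mmHg per
unit closure, while the diastolic minimum remains near-quasi-static; the
defaults are therefore per-knob (`kp = 6e-3, ki = 3e-3` for the max
channel, `kp = 1.2e-3, ki = 6e-4` for the min channel). All gains are
config-exposed.

The safety interlock emulates the platform's hardware watchdog: every
simulator-resolution sensor sample is checked against the configured window
(default −10 to 250 mmHg); a breach stops the run at that sample, zeroes the
pump and opens the valve, and the truncated traces are flagged.

## Phantom, fluid and wall shear stress

The test article is a silicone phantom (3.2 mm inner diameter, 0.4 mm
wall). Its distension law is linear, `D_i(p) = D_ref (1 + δ (p − p_ref))`,
with constant wall thickness; over any one 40 mmHg regime the bench
pressure–diameter anchors are near-linear, and the ISO compliance equation
is itself a two-point characterization. The diameter follows pressure
instantaneously (no viscoelastic lag). A consequence worth stating
explicitly: a *single* linear law makes the measured compliance
`C = δ·10^4·D_ref/D(Pmin)` — essentially regime-independent, decreasing
by < 1% from hypo- to hypertension. A bench phantom that shows compliance
*rising* with regime is slightly convex in its distension; the twin does not
model that, and its synthetic ground truth is self-defined through
`phantom_with_compliance()`.

Working-fluid viscosity uses Cheng's (2008) glycerol–water correlation
(0–100 °C, full composition range); at the platform's 50% w/w and 37 °C it
gives 3.40 mPa·s, matching the intended ~3.5 mPa·s blood-mimicking
viscosity. Wall shear stress is the Poiseuille estimate
`τ = 4μQ/(πr³)`, reported in Pa; at 188.42 mL/min it gives ≈ 3.4 Pa.

## Synthetic video and the compliance pipeline

`render_frames()` stands in for the stereo-microscope camera: the phantom is
a bright horizontal band on a dark background, rasterized with exact
area-coverage anti-aliasing, with optional Gaussian pixel noise and rigid
integer-pixel translation jitter. Ground truth (per-frame diameters, jitter
offsets, seed) rides along in the stack metadata.

Two deliberate rendering choices matter for measurement fidelity:

* a small **linear taper** (default 1 px across the width) emulates the
  slight conicity of a mounted sample. The ten measurement stations then
  sample the pixel-rounding staircase at evenly spread sub-pixel phases, so
  their average resolves diameter changes of a fraction of a pixel — the
  same dithering that station-averaging provides on the bench;
* the band centre sits a **quarter pixel off** the pixel grid. Centred
  exactly on a grid line, the two band edges cross pixel rows in lockstep
  and column counts quantize in 2 px steps.

The analysis pipeline mirrors the platform's script: register (integer-shift
projection correlation against the first frame), binarize (Otsu's global
threshold), count foreground pixels in each of ten evenly spaced columns at
fractions (i+0.5)/10 of the width, average the stations, take per-cycle
diameter extremes across frames, subtract twice the wall thickness, and
evaluate per cycle
\[
C = \frac{(D_{Pmax} - D_{Pmin})/D_{Pmin}}{P_{max} - P_{min}} \times 10^4
\quad [\% \; 10^{-2}\,\mathrm{mmHg}^{-1}]
\]
with that cycle's *measured* pressure extremes, reporting mean ± SD across
cycles. Total column counts and longest-run counts coincide because
fixtures are hole-free. A horizontal translation of the axis-uniform band is
unobservable (and harmless — it does not change column counts); the
generator's optional `fiducial` marker makes both jitter components
recoverable when registration itself is under test.

At 0.001 mm/px the pipeline recovers generator ground truth within ±1%
for `C*` from 0.3 to 1.5 (the suite checks ±2% with jitter enabled); at
0.0015 mm/px the stiffest phantoms degrade to ~2.5% as the per-cycle
diameter excursion approaches two pixels. Coarser calibrations degrade
further — quantization of the excursion, not of the diameter, is the
limiting factor.

## Waveform analytics and stability statistics

Acquisition emulation decimates simulator traces to the sensor rates (40 Hz
pressure, 200 Hz flow), applies sensor noise once, and filters with the
3-point moving average (endpoints average their available neighbours, so
length is preserved). Cycles are anchored at pressure minima — the
controller is pressure-referenced — located as windowed minima chained with
a ±25% spacing gate around the nominal period. Counter-phase is quantified
two ways: the lag of the pressure–flow cross-correlation peak, and the
diastolic flow fraction (share of per-cycle flow volume delivered outside
the 0.35 s systolic window, aligned to detected cycle starts).

Long-term stability is emulated as independent seeded repeats of the same
configuration, one per "day"; per-cycle values within a run form the group
sample for Welch's heteroscedastic one-way ANOVA
(`stats::oneway.test(var.equal = FALSE)`), metric by metric, at α = 0.05.
Which grouping the bench analysis used (cycles within a day vs repeated
acquisitions) is not published; per-cycle grouping is the recorded
convention here. Because the emulation has no drift mechanism, the null is
true by construction and p-values are uniform; a drift hook in the
configuration is the place to break it deliberately.

## What the synthetic data does and does not show

The generator reproduces the study conditions — sampling rates, filtering,
frame rate, phantom geometry, regimes, flow split — and passing tests show
that the *algorithms* (controller, pipeline, analytics) recover what the
generator put in, under sensor-grade noise and jitter. They do not show
robustness to what real bench data contains and the twin deliberately
omits: illumination gradients and lens distortion, actuator slew and
hysteresis, viscoelastic wall lag, pump calibration offsets (a measured mean
flow a few percent above nominal, where the twin's split is exact), or
non-rigid sample motion. Those are stated non-goals, absorbed here into
calibration anchors and configuration constants.

## Problem sizes

The bench protocol's video window is 30 s at 150 fps; the package default
configuration keeps that, while the test suite and the reproduction script
exercise the same code paths at desk scale (6–8 s at 20–30 fps,
0.001 mm/px, 10-seed sweeps; regulated runs of 36 cycles with a 5-cycle
settling window and 30 measured cycles, matching the bench's 30-period
averaging).
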