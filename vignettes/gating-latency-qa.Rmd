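---
title: "Measuring respiratory-gating beam latencies from portal images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring respiratory-gating beam latencies from portal images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gatelag)
```

## The measurement problem

Respiratory gating switches the treatment beam on when a monitored surface
enters a position window and off when it leaves. Neither transition is
instantaneous: the optical system must detect the crossing, the decision
must propagate, and the linac must ramp its dose rate up or down. The
end-to-end lag — tens to hundreds of milliseconds — displaces the delivered
dose relative to the plan, so task-group guidance asks clinics to measure
it routinely. `gatelag` implements a portal-image method for doing that
with equipment every clinic has: a programmable motion phantom carrying a
cube with an embedded metal ball, and the linac's own EPID.

The idea is geometric. Drive the phantom at a known constant speed $v$
through the gate. If radiation actually starts $t$ milliseconds after the
surface crossed the beam-on boundary, the ball in the beam-on image sits

$$\Delta x = P_{meas} - P_{ref}, \qquad t = \Delta x / v$$

millimetres past its position in a static reference image acquired at the
boundary. Measuring a latency therefore reduces to measuring a sub-pixel
ball displacement on two images. With $v = 24$ mm/s and a 0.34 mm imager
pitch at 1.6x magnification, one detector pixel corresponds to
$0.34/1.6/24 \cdot 1000 \approx 8.85$ ms, which sets the natural
resolution of the method.

## Geometry and conventions

Positions live in two planes. The phantom moves in the *isocenter plane*
(SAD, 1000 mm from the source by default); the image is formed in the
*detector plane* (SID, 1600 mm by default). Similar triangles give the
magnification $M = \mathrm{SID}/\mathrm{SAD}$, and
`displacementIsocenter()` divides detector-plane displacements by $M$.
Because both the reference and the motion image magnify identically,
extending the imager arm changes pixel offsets but cancels out of every
latency — a property the test suite checks by doubling the SID.

Throughout the package the motion axis is the image column axis, positions
increase with column index and are measured from the image center, and a
"descending" phantom (positions decreasing with time) moves toward smaller
column positions. The direction is declared in the gate configuration, not
inferred from images: a single snapshot cannot reveal it.

The gate is a band of halfwidth 1 mm (configurable) about a center level.
The beam-on reference position is the boundary the phantom crosses on
entry and the beam-off reference the boundary crossed on exit, so for a
descending phantom through a gate centered at 1 mm they are 2 mm and 0 mm
respectively (`gateReferencePositions()`).

## Velocity

`fitVelocity()` fits an ordinary least-squares line to the (time,
position) samples of the phantom waveform inside an explicit time window
and reports the absolute slope, $R^2$ and the two-sided slope t-test
p-value (n − 2 degrees of freedom, the conventional choice). The window is
an argument rather than an auto-segmentation because the gate-crossing
segment of a programmed waveform is known to the operator, and an explicit
window is reproducible. The standard conditions use 24 mm/s.

## Locating the ball

`locateBallCenter()` works on a one-dimensional profile: the image is
averaged over a transverse band centered on the ball (default half-width:
the ball radius, estimated from the transverse attenuation FWHM — wide
enough to average noise, narrow enough to exclude pure background), and
the attenuation (background minus intensity) is analysed along the motion
axis. The center is the centroid of the attenuation *excess* above 50% of
the maximum depth over the contiguous above-threshold region. The excess
weighting matters: a hard 50% cut with raw attenuation weights leaves the
boundary pixels with large weight, and whether they fall inside the cut
flips with sub-pixel position, producing a bias we measured at about
0.15 px. With excess weights the boundary contributes nothing and the
residual bias is below 0.02 px. Background is estimated robustly (upper
quartile, then the median of pixels attenuated by less than 20% of the
apparent depth) so that a trace covering half the profile does not drag
it down.

Degenerate inputs are refused rather than guessed at: a profile whose
depth does not exceed 6 background-noise SDs and 2% of the background is
"no ball found"; two disjoint above-threshold regions of at least 3 px
are "ambiguous".

## The beam-off trace and its matching

A beam-off image integrates the moving ball over the whole exposure, so
the footprint is an elongated ellipse. Its interior is a plateau; each
edge is the integral of the ball footprint, one ball-width wide. A
consequence worth stating precisely, because it drives two design
decisions: along every row the stop-side attenuation ramps *linearly*
from the plateau to zero, and the 50%-of-plateau crossing falls exactly
at the ball-center position where the exposure ended. `locateTraceEdges()`
therefore returns 50% crossings that estimate the ball-center positions
at the start and stop of the exposure, with no radius correction.

The primary beam-off estimator, `beamOffDelay()`, is a displaced-reference
matcher: shift the reference ball by a candidate displacement $d$ along
the motion direction and ask whether a ball stopping there would leave the
observed trace. Because the trace is a time integral, the comparison must
integrate the shifted reference profile along the motion direction before
comparing (a trapezoid cumulative — a rectangle rule shifts the template
by half a pixel, a bias we saw directly). Comparing the raw reference
profile against the trace instead would match a dome against a
plateau-plus-ramp and is biased by a sizeable fraction of the ball radius.
Both profiles are normalised to unit plateau depth (the trace has many MU
behind it, the reference typically one), and the sum of squared
differences is evaluated on the stop-side window from mid-plateau to
1.5 ball-widths beyond the stop edge — the region whose shape encodes the
beam-off moment. The candidate grid steps 0.25 px over a configurable
search range (default 0–15 mm at the isocenter, comfortably spanning
latencies up to ~600 ms at 24 mm/s) and refines to 0.05 px around the
minimum; a minimum on the range boundary is an error, not an answer. The
50%-crossing edge supplies an independent estimate of the same quantity,
reported in the diagnostics; disagreement beyond 2 px raises a warning.

Noise-free, both phases recover simulated ground truth to well under
0.1 px (≈ 0.9 ms); the acceptance grid in the test suite bounds the error
by one pixel-equivalent (8.85 ms).

## Aggregation conventions

Five repeats per beam mode are aggregated by `aggregateRepeats()`: the
mean displacement (MDD), the mean delay, and the *sample* SD (divisor
n − 1) over repeats — the usual convention for repeated measurements.
Cross-energy summaries (`summarizeSystem()`) average the per-mode mean
delays and report the *population* SD (divisor N): the modes tested are
the complete set of conditions, not a sample, and only this divisor
reproduces the bundled reference aggregates exactly at their printed
2-decimal precision — the suite contains a discriminating test pinning
the convention. Delays are reported at 2 decimals (ms), MDD at 2 decimals
(mm). Action levels (`checkTolerance()`) always come from configuration;
no numeric tolerance is hard-coded.

## What the simulator does and does not emulate

The simulator exists so that every stage is testable without a linac. It
renders the ball as an opaque disk of configurable diameter (default
6 mm — a package default; use the diameter of your own phantom) with
area-weighted antialiased edges, magnified onto a 0.34 mm-pitch imager;
the beam-on image is an instantaneous snapshot (the 1 MU exposure is
treated as a position sample) and the beam-off image the exact closed-form
time integral of the moving disk, optionally with a linear dose-rate
ramp-down of configurable duration (default 0: hard cutoff). Noise is
seeded additive Gaussian on detector counts. Scenario defaults are the
standard study conditions: 24 mm/s, ±1 mm gate, SAD 1000 / SID 1600 mm,
0.34 mm pitch, 256×256 images, 1 s of beam-on travel for traces.

Deliberately not modelled: radiological path length through a sphere
(only the footprint and its edges are used), scatter, penumbra, imager
lag and ghosting, and the internals of any optical surface-tracking
system. Passing round-trip tests therefore demonstrates the correctness
of the *analysis* under known geometry and noise; it does not certify
performance against detector artefacts the simulator omits, and real
commissioning should still include a sanity check against a known
hardware latency.

## A worked run

```{r worked-run}
dir <- tempfile("gatelag-demo")
manifest <- simulateRun(dir, "beam_off", c("6xFFF, 1200" = 97.69),
                        nRepeats = 3, noiseSigma = 400, seed = 42L)
cfg <- loadConfig(NULL)   # standard defaults
cfg$systemLabel <- "simulated"
cfg$logLevel <- "quiet"
out <- runEndToEnd(manifest, cfg, tolerance = 150)
out$results[["6xFFF, 1200"]]
out$summaries$beam_off
```

## Numerical choices and limitations

* Problem sizes: 256×256 images and 5 repeats per mode keep a full
  simulate-analyse-report cycle under a second per repeat; accuracy is
  set by the profile analysis, not the image size.
* The 50% threshold (detection and edges) and the 0.25/0.05 px grid steps
  are fixed design constants, recorded here and in the function
  documentation rather than exposed as knobs, because the validation
  bounds were established under them.
* Sub-pixel interpolation is linear everywhere (profile shifts, edge
  crossings); at 0.34 mm pitch with antialiased edges the associated
  error is far below the pixel-equivalent tolerance, and nothing smoother
  is warranted by the data.
* The method measures the end-to-end latency only; it cannot decompose it
  into camera, processing and beam-servo contributions, and it assumes
  constant velocity through the gate. Amplitude- vs phase-gating
  differences and irregular breathing are out of scope.
* A negative latency (system gating early) is reported as negative and
  flagged, never clamped: hiding it would mask a real fault.
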