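---
title: "Methods: simulating and reconstructing off-axis holograms of cell layers"
author: "holoqpi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and reconstructing off-axis holograms of cell layers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holoqpi)
```

## The measurement this package models

Digital holographic microscopy (DHM) records the interference pattern
between light transmitted through a transparent sample (the object beam) and
a clean reference beam. With a small tilt between the two beams — off-axis
geometry — the interference fringes carry a spatial carrier frequency, and a
single camera frame encodes the full complex optical field. The phase of
that field measures optical path length: for a cell of thickness $h$ and
refractive-index contrast $\Delta n$ against the medium,

$$\varphi(x, y) = \frac{2\pi}{\lambda}\,\Delta n\, h(x, y),$$

so a calibrated phase map is a label-free 3-D thickness map, from which
per-cell volume, cell count and confluency follow. The package models the
specific use of this measurement for transwell (insert) co-culture models of
the blood–brain barrier: endothelial cells, pericytes and astrocytes on and
around a porous membrane, imaged before and after treatment with
drug-loaded extracellular vesicles, with treatment effects read out as
percent decreases in cell volume and count, and vesicle uptake quantified by
flow-cytometry-style gating.

Because no raw holograms are publicly available for this workflow, the
package is built as a closed loop: a synthetic-scene generator with an exact
ground truth, a physical forward model that renders realistic holograms from
that truth, the reconstruction and morphometry pipeline under test, and
statistics that recover the configured effect sizes. Every accuracy claim in
the test suite is a forward–inverse comparison against the generator's truth
record.

## The synthetic scene generator

Cells are spherical caps resting on the substrate. A cap with base radius
$r$ and apex height $h$ belongs to a sphere of radius
$R = (r^2 + h^2)/(2h)$, has the single-valued profile
$z(\rho) = \sqrt{R^2 - \rho^2} - (R - h)$ for $\rho \le r$, and the
closed-form volume $V = \pi h^2 (3R - h)/3$. The cap family was chosen
precisely because of that closed form: it provides an analytic oracle for
every volume measurement downstream, at the cost of idealizing cell shape.
Caps must satisfy $h \le r$ (sub-hemispherical) so the profile remains a
height map. Overlapping caps — which only arise when a user renders
hand-placed cells — combine by pointwise maximum, as abutting cells occlude
rather than stack.

Scenes place `n_cells` caps by rejection sampling (radii and heights uniform
over configured ranges, centers uniform, pairwise center distances larger
than the radius sums; 10,000 retries before a "field too crowded" error).
Defaults: 0.26 µm/pixel object sampling (5.2 µm camera pitch at 20×),
radii 4–6 µm, heights 2–4 µm, refractive contrast
$\Delta n = 0.05$ (cell 1.385 vs medium 1.335, a mid-range literature value
for adherent cells — the underlying study never reports its $\Delta n$, so
height maps carry the value used as metadata). The optional membrane is a
square lattice of pores rendered as negative-phase wells, 0.4 µm diameter at
4 µm pitch by default (the commercial-insert scale; pores are sub-pixel and
anti-aliased by linear edge coverage so their integrated area stays exact).

Treatments rescale volumes: each surviving cell draws a shrink fraction
$s_i$ from a normal with dispersion $\sigma_s$ truncated to $[0, 1)$, and
its volume becomes $(1 - s_i) V_i$, with the footprint fixed and the new cap
height solved from the volume cubic — cells stay exact caps, so the analytic
bookkeeping survives treatment. The normal's location is adjusted so the
*truncated mean* equals the configured shrink exactly: plain truncation
would lift the population mean by $+0.72$ points at $s = 7.4\,\%$,
$\sigma_s = 0.05$, and the configured value is meant to be the population
mean the study reports. A cell-loss count removes random cells. The
configured shrink means for the four vesicle formulations are 7.406 %
(si-EV), 14.62 % (fol-si-EV), 27.25 % (DOX-EV) and 48.54 % (fol-DOX-EV),
with a per-cell dispersion of 0.05; reported cell-count changes are
sign-ambiguous in the source material, so cell loss defaults to zero and is
purely configuration-driven.

Flow-cytometry events are a two-component log-normal intensity mixture
(negative autofluorescence: meanlog $\log 50$, sdlog 0.4; positive:
meanlog $\log 5000$, sdlog 0.5 — well separated). Each event is positive
with the configured probability; a paired control table shares the negative
component. When the component log-locations differ by less than one
log-scale unit the table is flagged: gate recovery is then not guaranteed.

What the generator does **not** emulate: organelle-scale internal structure,
cell motility or time-lapse dynamics, optical aberrations beyond a uniform
background tilt, partial coherence, and membrane autofluorescence. Passing
the closed-loop tests therefore demonstrates the correctness of the
reconstruction mathematics and the statistical pipeline under idealized
optics, not robustness to every artifact of real acquisitions.

## Forward model

The object field is pure phase, $U = e^{i\varphi}$. Free-space propagation
uses the angular spectrum method — exact scalar diffraction: multiply the
2-D spectrum by
$H(f_x, f_y; z) = \exp\!\big(i 2\pi z \sqrt{(n/\lambda)^2 - f_x^2 - f_y^2}\big)$
and transform back. Evanescent components (negative radicand) are zeroed by
default (band-limited propagation; exponential damping is available). The
transfer-function form preserves sampling and is unitary on the propagating
band, which the tests exploit: propagate–unpropagate round trips must agree
to $10^{-9}$ RMS, and a Gaussian beam's divergence must match
$w(z) = w_0\sqrt{1 + (z\lambda/\pi w_0^2)^2}$ within 2 %. A warning flags
propagation distances beyond the aliasing guard
$z_{\max} = N\,\mathrm{px}\,\sqrt{(n/\lambda)^2 - f_{occ}^2}/(2 f_{occ})$,
where $f_{occ}$ is the highest spatial frequency holding more than $10^{-3}$
of the spectral peak — an occupancy-based bound, since a fixed bound wildly
over-flags smooth fields.

Holograms form $I = |O + R|^2$ with a tilted plane-wave reference at the
carrier (default 0.25 cycles/pixel on both axes, placing the +1 order
outside the NA-limited band around DC). Poisson shot noise at a configurable
photon scale and Gaussian read noise are applied, the noise-free mean maps
to half the detector full scale, and values are quantized to the configured
bit depth (8 by default; clipped fraction recorded).

**Reference-to-object amplitude ratio (default 3).** At ratio 1 the object
self-interference term $|O|^2$ of a dense, defocused scene leaks a few
percent of its power into the sideband window. That contaminant is "in
focus" at the camera plane, and it biases amplitude-variance autofocus
toward half the true defocus. Raising the reference amplitude to 3× leaves
the cross term dominant (the $|O|^2$ term is independent of the reference
amplitude) and restores refocusing accuracy to a couple of µm over a
±100 µm search. This is a standard off-axis design trade-off — carrier
separation and reference strength against fringe contrast within the
detector's dynamic range — and both parameters are configurable.

## Reconstruction pipeline

`reconstruct()` composes six stages; each is independently exported and
tested.

1. **Sideband extraction.** The hologram's 2-D spectrum is searched for its
   strongest peak outside a DC exclusion disc (default 0.05 cycles/px),
   restricted to the half-plane of positive column frequency; the peak must
   exceed 5× the median spectral magnitude or a "no carrier" error is
   raised. A circular window — radius $\min(0.45\,|f_c|,\ \mathrm{NA}
   /\lambda \cdot \mathrm{px})$ — is applied, the windowed sideband is
   recentered to zero frequency and inverse-transformed. The demodulated
   field is conjugated, so a positive synthesis carrier yields $+\arg O$;
   with the opposite sign convention the phase (and heights) would flip.
2. **Autofocus.** The field is propagated over a z grid and the normalized
   amplitude variance $\mathrm{var}|U| / \overline{|U|}^2$ evaluated — a
   pure-phase object in focus has flat amplitude, so the metric is minimal
   at focus; parabolic interpolation refines the grid optimum. The object
   and all reference candidates are propagated to the same plane.
3. **Reference selection.** For each candidate reference the wrapped
   difference $\arg(O \bar R)$ is formed; the winner minimizes background
   roughness, defined as the circular standard deviation of the 3×3
   circular-median-filtered difference. This criterion is the package's own
   operationalization of "choose the optimal reference image".
4. **Filtering.** A 3×3 median filter; wrapped maps are filtered on the
   complex unit circle (median of $\cos$ and $\sin$ components, argument
   re-taken) so the ±π seam introduces no artifacts.
5. **Unwrapping.** Reliability-sorted region growing: pixel reliabilities
   from wrapped second differences, edges between 4-neighbours processed
   most-reliable-first, groups merged with a single $2\pi k$ shift
   (implemented in C++; $O(N \log N)$). Exact up to one global $2\pi k$ on
   residue-free inputs; residue counts are recorded, and residue-laden
   inputs still return with errors confined to low-reliability regions. The
   output is anchored by the multiple of $2\pi$ nearest the background
   median — anchoring by an arbitrary constant would break the pixel-wise
   `output − input ≡ 0 (mod 2π)` identity, so exact piston calibration is
   deferred to the next stage.
6. **Calibration and conversion.** A least-squares plane (piston + tilt) is
   fitted on the background — iteratively re-fitting on the lower-residual
   half so cells do not drag the plane — and subtracted; the background
   median is zeroed; heights follow from
   $h = \varphi \lambda / (2\pi \Delta n)$.

A QC record accompanies every reconstruction: detected carrier, chosen
reference, best focus, residue count, background roughness, clipped pixel
fraction.

## Morphometry

Segmentation thresholds height at the Otsu level floored by 0.3 µm (the
floor resists membrane texture), then splits touching cells by a watershed
on the Gaussian-smoothed height (σ = 2 px, tolerance 0.3 µm) and drops
regions under 5 µm². Coverage fraction is the thresholded footprint share
of the field.

**Volume integration uses an expanded footprint.** The thresholded footprint
excludes the cell rim below the threshold; integrating height over it alone
under-measures volume, and the bias is relatively larger for flatter
(post-treatment) cells — enough to shift recovered shrink percentages by
several points. `measure_cells()` therefore assigns every pixel above a low
floor (0.3 µm), dilated by 4 px, to its nearest region by seeded propagation
and integrates height there. Background noise inside the expanded annulus is
near-zero-mean after piston calibration, so the expansion removes the
systematic underestimate without adding bias.

Pore detection measures depressions below the field median; pixels deeper
than half the maximum well depth are labeled, and each component's area is
its depth integral divided by the field-wide well depth — a
fractional-coverage estimator that remains unbiased for sub-pixel pores
rendered with partial pixel coverage. Mean equivalent diameter, median
nearest-neighbour pitch and a QC flag (mean diameter ≤ 0.5 µm by default)
are reported.

## Group statistics

Per condition, paired pre/post fields give
$\mathrm{decrease}_f = 100\,(1 - V^{post}_f / V^{pre}_f)$ on field-level
total volume (the per-cell-mean variant is a config option; field totals
were chosen because the source material's per-cell vs per-field definition
is ambiguous). Summaries are mean ± SD across fields; conditions are
compared by Welch's unequal-variance t-test (the source reports p-values
without naming a test; Welch is the safe default). At five fields per group
Welch's true size is ≈ 4.4 % at nominal 5 % — slightly conservative, which
the calibration test's acceptance band accommodates.

Uptake gating places the gate at the 99th percentile of the paired negative
control (standard flow practice). The raw percent positive then carries a
$+(1 - f)\cdot 1\%$ background by construction, so the standard
control-background correction
$\hat f = (p_{obs} - 0.01)/0.99$ is also reported; closed-loop recovery
checks use the corrected estimate, averaged over five replicate experiments
of 10,000 events with the pooled binomial standard error as the comparison
scale.

The type-I calibration simulates pairs of groups from identical generating
parameters using truth-only scenes (no holography), 1,000 simulations of
5 + 5 fields, and checks the rejection rate at α = 0.05.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use: 256² px fields with 10
cells for forward–inverse fidelity; 192² px fields for effect recovery
through the full pipeline (6 cells × 20 replicate fields per treatment in
the tests, 8 cells × 40 fields in the acceptance script; the pipeline runs
twice per field, ≈ 0.2 s per reconstruction); 64² px fields for the 100
random unwrapping checks; truth-only 96² scenes for the 1,000-simulation
calibration. These sizes were chosen so the whole loop stays interactive on
one CPU while keeping Monte-Carlo errors well below the acceptance bands.
The seeding-density comparison maps 15,000 / 30,000 seeded cells per insert
to 10 / 20 cells in one representative 192² px field (a fixed 1:1500
scale); only the ordering of coverages is asserted, not absolute coverage.

Ties and degenerate inputs: all randomness is scoped with `withr::with_seed`
(operations are pure functions of inputs and seed). Derived seeds — per
field, stage and condition — are scrambled through one RNG round rather than
used as arithmetic sequences: structured seed sequences produce measurably
correlated Mersenne-Twister streams (shrink-draw means consistently ~2σ low
before the fix). Spectral peak ties
resolve to the first index in column-major order; an all-background height
map segments to an empty report rather than an error; zero pre-treatment
volumes exclude the pair with a warning; constant-versus-constant condition
comparisons return p = 1 on equal means.

## Known limitations

- Cells are homogeneous phase objects; dry-mass-like readouts, organelle
  texture and scattering are out of scope.
- The forward model has no lens aberrations beyond what a user injects as a
  static phase screen through the scene, and no partial coherence; the
  reference-selection stage is therefore exercised on synthetic tilt/defect
  differences only.
- Heights are optical thickness: absolute volumes scale with the configured
  $\Delta n$, and only ratios (percent decreases) are robust to a wrong
  $\Delta n$.
- Pore morphometry on *reconstructed* (band-limited) heights blurs sub-pixel
  pores; the diameter estimator is validated on ground-truth membrane
  fields.
- Watershed splitting is validated for moderate (≈20 %) footprint overlap;
  heavily confluent layers will undercount.
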