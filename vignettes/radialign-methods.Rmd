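---
title: "Methods: orientation, alignment and stimulation analytics in radialign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: orientation, alignment and stimulation analytics in radialign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radialign)
```

radialign packages the quantitative read-outs used to evaluate engineered
muscle grown under radial mechanical stretch: does the tissue develop fibers
with a coherent local orientation, do those orientations organize radially
(as in a diaphragm, whose myofibers radiate from a central tendon), and did
the bioreactor actually deliver the stimulation protocol it was asked for?
This vignette explains each model, the parameters that matter, and what the
test suite does and does not establish.

## 1. Structure-tensor orientation and coherency

### Model

Local orientation is estimated from the structure tensor
$J = \langle \nabla f, \nabla f^T\rangle_w$, the $2\times 2$ matrix of
window-weighted inner products of the image gradient components. $J$ is
symmetric positive semi-definite; the eigenvector of $\lambda_{max}$
maximizes the windowed directional-derivative energy
$\|D_u f\|_w^2 = u^T J u$, so it points along the dominant *gradient* axis.
In a striped or fibrous texture gradients are perpendicular to the fibers,
so `orientation_coherency()` reports the fiber axis as the gradient axis
rotated by 90° and also exposes the raw gradient axis. Coherency
$C = (\lambda_{max}-\lambda_{min})/(\lambda_{max}+\lambda_{min})$ is 1 for
a single orientation and 0 for an isotropic texture. A closed-form coherency
expression in terms of the tensor entries circulates with inconsistent signs
and powers; the eigenvalue form is the one that respects the $[0,1]$ bound,
and it is the one implemented. Its correctness is cross-checked by an
independent route: `dominant_direction_bruteforce()` sweeps a probe axis
over $[0°, 180°)$ and evaluates $\|D_u f\|_w^2$ by direct per-pixel
summation; tests require the arg-max axis to match the eigen axis within the
sweep step on seeded random fiber fields, and the energy at the eigen axis
to equal $\lambda_{max}$ to $10^{-8}$ (the Rayleigh-quotient identity).

### Parameters

- `sigma` (Gaussian-derivative scale, px, default **1.5**): kernels are
  normalized so a unit ramp gives gradient exactly 1; support radius
  $\lceil 3\sigma\rceil$. Features narrower than ~2 px are under-resolved,
  which is why the synthetic generators default to 3 px strokes.
- `window_size_L` (px, default **32** for maps): box profile by default (a
  square section of side $L$; $|x-c| \le L/2$, i.e. $L{+}1$ pixels across);
  an isotropic Gaussian profile (SD $L/4$) is optional. Must be
  $\ge 4\sigma$.
- `energy_threshold_frac` (default **1e-3**): tiles whose energy
  $\mathrm{tr}\,J$ is at or below this fraction of the maximum tile energy
  are flagged invalid — blank regions carry no orientation, and no angle is
  fabricated for them (`theta_deg = NA`).

The gradient estimator, window profile and energy masking are package
choices: the upstream analyses this emulates (OrientationJ-style plugins)
do not pin them down, so they are explicit arguments and are recorded in
every CLI manifest.

### Numerical choices and degeneracies

Angles are axial, wrapped to $[-90°, 90°)$, counter-clockwise from $+x$
with $y$ up (file rows are flipped on load; this is the display convention
of common orientation tools). Eigen-decomposition is closed-form;
$\lambda_{max}+\lambda_{min} = \mathrm{tr}\,J$ holds to $10^{-10}$ by
construction and is asserted. Exactly isotropic tensors
($\lambda_{max}=\lambda_{min}$) report coherency 0 and an undefined angle.
Boundary handling is by reflection; gradients within $\lceil 3\sigma\rceil$
pixels of the border are biased where the reflected continuation breaks the
texture. On a noise-free grating, tiles whose windows avoid that margin
agree to well under 0.1°, while border tiles can deviate by ~1–2°; the
whole-image coherency of the acceptance grating is 0.992 rather than
exactly 1 for the same reason. Tests therefore assert sub-degree agreement
on interior tiles and a looser 3° bound on border tiles.

## 2. Orientation histogram, Gaussian peak fit, alignment score

Axial angles (or valid orientation-map tiles, optionally weighted by energy
or coherency·energy so textured regions dominate) are binned into **90 bins
of 2°** by default. The peak model
$b + A\exp(-\Delta(\theta,\mu)^2/2\sigma^2)$ uses the periodic angular
distance $\Delta$ (period 180°), so a peak at ±90° is not split. Fitting is
nonlinear least squares (Nelder–Mead, two restarts: the modal bin and the
strongest mode at least 30° away, keeping the lower residual) and the
goodness is $\max(0, 1 - SS_{res}/SS_{tot})$, clipped to $[0,1]$. The
score's endpoints match its published interpretation — 1 for good
alignment, 0 for none — but the formula is this package's choice of the
standard coefficient-of-determination; equivalence with any particular
plugin's internal score is not claimed. A histogram that is exactly a
Gaussian evaluated at the bin centers is fitted with goodness 1 to
$10^{-6}$ (the model is realizable); an exactly flat histogram fits
amplitude ≈ 0 and goodness ≈ 0. Goodness is invariant to histogram
normalization and to a common rotation of all angles, and is monotone in
the generator's von Mises concentration $\kappa$ over $\{0, 2, 10, 50\}$ —
all asserted in tests.

## 3. Radial-organization comparison

`radial_reference()` defines, for every position, the axial angle of the
vector from a center — the orientation a perfectly radial fiber field would
show. Deviations $d = \min(|\theta-\theta_{ref}|, 180°-|\theta-\theta_{ref}|)
\in [0°, 90°]$ are summarized by an energy-weighted mean: 0° for a radial
field, 45° expected for a uniform-random axial field. `compare_to_controls()`
operationalizes "more similar to the radial control than to the isotropic
control" on two deliberately independent axes: the Kolmogorov–Smirnov
distance between tile-coherency distributions, and the difference in mean
radial deviation. The verdict is *radial-like* (or *isotropic-like*) only
when **both** axes agree, otherwise *indeterminate* — a conservative choice,
since the source analyses never define "similar" operationally. The center
is user-supplied (physiologically, the central tendon); the default is the
tile-grid centroid. No significance testing is attached to the verdict.

## 4. Membrane inflation model and protocol compiler

### Spherical-cap surrogate

The bioreactor stretches constructs by pumping fluid against clamped
circular PDMS membranes (deformable diameter 22 or 24 mm). The published
strain↔volume functions come from nonlinear FEM of the Neo-Hookean membrane
(initial modulus 1 MPa) in its rigid PMMA frame; that analysis is not
reproducible from printed information alone, so this package substitutes a
purely kinematic **spherical-cap** model with zero free parameters: volume
$\Delta V = \pi h(3a^2+h^2)/6$ determines the apex height $h$, and the
average radial strain is the meridian elongation $(s-2a)/2a$ with
$s = 2R\operatorname{asin}(a/R)$, $R=(a^2+h^2)/2h$. It reproduces the
qualitative shape of the FEM functions (zero at zero, strictly increasing,
superlinear), satisfies the small-deflection limit
$\varepsilon \approx \tfrac23 (h/a)^2$ to 1% for $h/a < 0.05$, and has the
exact hemisphere endpoint $(\pi-2)/2 \approx 57.1\%$ used as a closed-form
test anchor. It is a documented surrogate: it does **not** reproduce the
FEM's absolute volumes, the membrane–construct interaction, or the reported
4–6% strain field in the construct. Membrane thickness and modulus are
carried as metadata only. `volume_for_strain()` inverts the map exactly by
root-finding on $h$ (round-trip $<10^{-8}$, cross-checked against an
independent bisection on volume); compiled waveforms use a monotone-spline
inverse of the same closed forms (error $<10^{-6}$ relative, tested).

### Protocol compiler

Protocols are ordered phases: linear strain **ramps** (the conditioning
stimulus is 0→10% over 7 h followed by 17 h rest), **rest**, and **cyclic**
training (a cycle of 10 stretches in 10 min — 1/min — given 3×/day at 5%
strain). The intra-stretch waveform is unpublished; each stretch is a
symmetric triangular ramp-and-release of default 4 s at the start of its
slot, a stated choice. The default grid is $dt = 1$ s, on which pulse peaks
are exactly representable; at coarser $dt$ the sampled waveform can step
over a pulse, so the event log (one row per stretch with its exact peak
time and magnitude) — not the sampled maximum — is the authoritative record
of commanded peaks. `capability_check()` flags phases beyond the validated
envelope of 30% strain and 16 cycles/min.

## 5. Calcium transients

$\Delta F/F_0 = (F - F_0)/F_0$ with $F_0$ the **mean** fluorescence over a
pre-stimulus baseline window (default: all samples strictly before the
annotated stimulus). A single-sample "intensity at time 0" would be fragile
to acquisition noise at typical 16 fps video; the windowed mean keeps the
baseline segment of $\Delta F/F_0$ exactly zero-mean and the whole series
invariant to any positive rescaling of the trace — both asserted. Peak
amplitude and time-to-peak (from stimulus) are reported. Input is a trace,
not video: ROI extraction is out of scope.

## 6. What the synthetic data does and does not establish

The generators are pure functions of their spec (seed included):

- **Gratings**: exact single-orientation sinusoids in $[0,1]$ — the
  sharpest possible test of angle recovery and the coherency upper bound.
- **Fiber fields / nuclei**: anti-aliased strokes/ellipses with axial
  angles drawn from an axial von Mises distribution via angle-doubling
  (sample $2\alpha$, halve, wrap) — $\kappa = 0$ is the isotropic control,
  large $\kappa$ the oriented one; sampled angles are returned as ground
  truth. Stroke width defaults to 3 px so gradients are resolvable at
  $\sigma = 1.5$. Fibers and nuclei may overlap.
- **Radial spokes**: strokes radiating from a center with small seeded
  angular jitter — a stand-in for radial control images whose construction
  was never published, labelled as such.
- **Calcium traces**: flat baseline, instantaneous rise, exponential decay,
  optional Gaussian noise.

Defaults (256×256 px, 150 fibers/nuclei, axis ratio 3, $\kappa \in
\{0, 2, 10, 50\}$, 16 fps / 30 s traces) were chosen once as realistic for
confocal fields of myotube cultures and stereomicroscope video, and are not
tuned to test outcomes. These images have ideal contrast, no uneven
illumination, no out-of-focus blur, no touching-object segmentation
ambiguity and no photobleaching; a green suite establishes that the
*estimators* are correct on their stated models, not that the pipeline is
robust to every real-microscopy artifact.

## 7. Known limitations

- Border tiles of orientation maps are biased by reflection padding (see
  §1); exclude a margin of $L/2 + \lceil 3\sigma\rceil$ px for unbiased
  statistics.
- The membrane model is kinematic: its volumes are not the FEM's, only the
  functional shape and endpoints are trustworthy.
- The radial verdict is descriptive (no inferential statistics).
- TIFF input is not supported in this environment; PNG, plain PGM and
  lossless CSV matrices are.
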