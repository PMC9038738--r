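# radialign

Quantitative analytics for engineered skeletal muscle cultured under
**radial mechanical stimulation** — the read-outs used to judge whether a
diaphragm-like construct in a membrane-inflation bioreactor is developing
radially organized, aligned muscle fibers:

- **Local fiber orientation and coherency** from the weighted structure
  tensor of a microscopy image (myotubes, nuclei, SHG collagen),
- an **alignment score** from a Gaussian peak fitted to the orientation
  histogram,
- **radial-organization scoring** of an orientation field against radial and
  isotropic control patterns,
- the bioreactor's **strain ↔ reservoir-volume membrane model** and a
  compiler for two-phase (**slow ramp** + **cyclic training**) stimulation
  protocols,
- **ΔF/F₀ calcium-transient quantification**,
- seeded **synthetic-data generators** (gratings, fiber fields, radial spoke
  patterns, elongated nuclei, fluorescence transients) with exact ground
  truth, so the entire pipeline is testable without microscopy data.

## The statistics at the core

For an image *f* with gradient ∇f = (f_x, f_y) and a non-negative window
*w*, the **structure tensor** is the matrix of windowed inner products

    J = [ <f_x,f_x>_w   <f_x,f_y>_w ]
        [ <f_x,f_y>_w   <f_y,f_y>_w ]

J is symmetric positive semi-definite. The axis *u* maximizing the windowed
directional-derivative energy ‖D_u f‖²_w = uᵀJu is the eigenvector of the
larger eigenvalue λ_max (the gradient-dominant axis, perpendicular to the
fibers in a striped texture; the reported fiber axis is that axis + 90°).
The **coherency**

    C = (λ_max − λ_min) / (λ_max + λ_min)  ∈ [0, 1]

is 1 for a perfectly oriented texture and 0 for an isotropic one. Axial
orientations (period 180°) are binned into a histogram and fitted with a
periodic Gaussian peak `baseline + A·exp(−Δ(θ, μ)²/2σ²)`; the **goodness**
`max(0, 1 − SS_res/SS_tot)` ∈ [0, 1] is the alignment score (1 = good
alignment, 0 = none). The bioreactor membrane is modeled as a clamped
circular membrane inflated into a **spherical cap**: a volume change ΔV
determines the apex height h through ΔV = πh(3a² + h²)/6, and the average
radial strain is the meridian elongation (s − 2a)/(2a), s = 2R·asin(a/R),
R = (a² + h²)/(2h) — strictly increasing and analytically invertible up to
the hemisphere strain (π − 2)/2 ≈ 57.1%. Calcium transients are reported as
ΔF/F₀ with F₀ the mean pre-stimulus baseline fluorescence.

## Worked example

```r
library(radialign)

# a noise-free grating at 30 deg: orientation and coherency
img <- make_grating(fiber_field_spec(stripe_angle_deg = 30, wavelength_px = 16))
orientation_coherency(structure_tensor(compute_gradients(img)))
#> <orientation_result> fiber axis 29.86 deg, coherency 0.9918, energy 882.8

# alignment score of strongly oriented synthetic nuclei
nuc <- make_nuclei_image(nuclei_field_spec(orientation_kappa = 50, seed = 5))
alignment_score(nuc$image)
#> <gaussian_peak_fit> mu -0.08 deg, sigma 5.71 deg, goodness 0.9575

# membrane model: strain from volume, volume for strain (22 mm membrane)
cap_strain_from_volume(c(100, 400), membrane_params(22))
#>   delta_volume_uL cap_height_mm radial_strain radial_strain_percent
#> 1             100     0.5257317   0.001522136             0.1522136
#> 2             400     2.0797468   0.023663295             2.3663295
volume_for_strain(5, membrane_params(22))   # 591.5 uL for 5% strain

# compile one conditioning day (0->10% ramp in 7 h, 17 h rest) plus one
# training day (3 cycles x 10 stretches at 5%)
wf <- compile_protocol(standard_protocol(ramp_days = 1, training_days = 1))
wf
#> <stimulation_waveform> 172801 samples over 172800 s, peak 10.00%, 30 stretch events
capability_check(standard_protocol())$pass   # within 30% / 16 cycles-per-min
#> [1] TRUE

# calcium transient quantification
tr <- make_calcium_trace(baseline = 1, amplitude = 0.8, noise_sd = 0.02, seed = 4)
delta_f_over_f0(tr)
#> <calcium_trace> 481 samples over 30.0 s; F0 = 1.001, peak dF/F0 = 0.805 at 10.00 s
```

The fiber angle of 29.86° recovers the constructed 30° stripe axis to
within the sub-degree accuracy the tests require; coherency 0.992 sits at
the oriented-texture end of its [0, 1] range (the small deficit is a border
artifact of reflection padding). The nuclei goodness of 0.957 says the
orientation histogram is nearly a single Gaussian peak — tight alignment.
Peak ΔF/F₀ ≈ 0.805 recovers the generated amplitude/baseline ratio of 0.8
within the noise.

## Command line

```sh
radialign synth --kind grating --stripe-angle-deg 30 --out-dir out/
radialign orient --input out/synthetic.csv --window-size-L 32 --out-dir out/
radialign protocol --spec inst/extdata/standard_protocol.yaml --out-dir out/
radialign calcium --input trace.csv --out-dir out/
```

(the launcher installs to `system.file("exec", "radialign", package =
"radialign")`; run it via `Rscript` or add it to `PATH`). Every run writes
a `manifest.json` with the full configuration and seeds; fixed config +
seed gives byte-identical outputs.

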