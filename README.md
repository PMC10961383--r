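# holoqpi

Off-axis digital holographic microscopy (DHM) of cell layers, end to end in
R: simulate ground-truth scenes of cells on porous transwell membranes,
render realistic off-axis holograms, reconstruct quantitative phase and 3-D
height maps, and quantify treatment effects the way DHM studies of in-vitro
blood–brain-barrier (BBB) insert models report them — per-cell volume, cell
count, coverage fraction, membrane pore statistics, percent volume decrease
per treatment, and flow-cytometry-style uptake percentages.

## Who this is for

Quantitative phase imaging (QPI) turns an interference pattern into a
thickness map: a cell of thickness $h$ and refractive-index contrast
$\Delta n$ imprints the phase

$$\varphi = \frac{2\pi}{\lambda}\,\Delta n\,h ,$$

so label-free morphometry (volume, confluency, shrinkage after treatment)
falls out of one camera frame. The catch is that every step between the
camera and the volume table — sideband demodulation, numerical refocusing,
reference subtraction, filtering, 2-D phase unwrapping, segmentation — can
silently bias the result. `holoqpi` packages the whole chain *plus its
physics twin*: a forward model that renders holograms from a scene with an
exact analytic truth record, so the pipeline is testable closed-loop without
any raw data. It is aimed at people building or validating DHM/QPI analysis
for cell cultures, and at anyone who needs a reproducible synthetic
benchmark for phase-reconstruction code.

## The pipeline

```
simulate_scene() ─► phase_to_field() ─► synthesize_hologram()   forward model
                                               │
        ┌──────────────────────────────────────┘
        ▼
extract_sideband() ─► autofocus() ─► select_reference() ─►      reconstruction
filter_phase() ─► unwrap_phase() ─► phase_to_height()
        │
        ▼
segment_cells() ─► measure_cells() / detect_pores()             morphometry
        │
        ▼
volume_change() ─► compare_conditions();  gate_positive()       statistics
```

Key algorithms: angular-spectrum propagation (exact scalar diffraction),
Fourier sideband demodulation with automatic carrier detection,
amplitude-variance autofocus, circular (unit-circle) median filtering, and a
reliability-sorted region-growing phase unwrapper (C++), exact up to a
global 2πk on residue-free inputs. Defaults mirror a Mach–Zehnder
transmission DHM: 632.8 nm, 20× / 0.65 NA, 5.2 µm camera pitch, 8-bit
detector, small reference tilt as the off-axis carrier.

## Worked example

Simulate a 10-cell field, image it with detector noise, reconstruct, and
measure — then apply the strongest treatment effect (fol-DOX-EV, 48.54 %
mean volume shrink) and quantify the decrease:

```r
library(holoqpi)

optics <- optical_config()                      # 632.8 nm, 20x/0.65 NA, 5.2 um, 8-bit
params <- scene_params(n_cells = 10, seed = 42) # 256x256 px @ 0.26 um/px
scene  <- simulate_scene(params)

holo <- synthesize_hologram(phase_to_field(scene$true_phase, optics), optics,
                            noise = noise_meta(photon_scale = 1000, read_noise_sigma = 1))
ref  <- reference_hologram(optics, params$field_size_px,
                           noise = noise_meta(1000, 1, seed = 2))
rec  <- reconstruct(holo, ref, optics,
                    reconstruct_options(autofocus_range_um = c(-20, 20),
                                        autofocus_steps = 9))
report <- measure_cells(segment_cells(rec$height), rec$height)
report
#> <morphometry_report> 10 cells, total volume 2096 um^3, coverage 0.212
sum(scene$true_cell_volumes_um3)                # analytic truth: 2063 um^3

treated <- apply_treatment(scene, ev_treatment_effects()[["fol-DOX-EV"]], seed = 7)
holo2   <- synthesize_hologram(phase_to_field(treated$true_phase, optics), optics,
                               noise = noise_meta(1000, 1, seed = 3))
rec2    <- reconstruct(holo2, ref, optics,
                       reconstruct_options(autofocus_range_um = c(-20, 20),
                                           autofocus_steps = 9))
volume_change(list(report),
              list(measure_cells(segment_cells(rec2$height), rec2$height)),
              "fol-DOX-EV")
#> <condition_summary> fol-DOX-EV (n = 1 fields)
#>   volume decrease 49.22 % +- 0 %; count change 0 +- 0
```

The measured total volume (2096 µm³) sits within 2 % of the analytic truth
(2063 µm³) despite shot noise and 8-bit quantization, and the single-field
volume decrease (49.2 %) recovers the configured 48.54 % shrink. With
replicate fields (`run_pipeline()`, or the statistics functions directly)
the recovery lands within Monte-Carlo error of the configured effect; the
methods vignette (`vignettes/holoqpi-methods.Rmd`) explains each stage, the
tunable parameters, and what the synthetic benchmark does and does not
demonstrate.

A YAML-configured command-line interface covering `simulate`,
`reconstruct`, `measure`, `compare` and the full `run` pipeline is installed
at `inst/cli/holoqpi`.

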