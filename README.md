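# t1aniso

Orientation-dependent T1 relaxometry versus white-matter microstructure.

In highly ordered white matter (WM), the longitudinal relaxation time T1
depends on the angle between the fibre axis and the main magnetic field B0
(the fibre-to-field angle θ_FB, computed from the principal diffusion
eigenvector as θ = arccos(|V1·B0|) ∈ [0°, 90°]). At 3 T, T1(θ) shows a
broad peak near 54° in WM with high FA or low orientation dispersion (ODI);
at 7 T the peak sits near 40° and fibres parallel to B0 have longer T1 than
perpendicular ones. `t1aniso` is for researchers in quantitative MRI who
want to quantify this effect — on real NIfTI data or on a fully synthetic
brain phantom with known ground truth.

The package provides, as separately usable modules:

* a **synthetic phantom**: Watson-dispersed fibre bundles sweeping 0–90°,
  two-shell diffusion signals with Rician noise, six-TI inversion-recovery
  series whose true T1 follows a field-dependent angular law
  `T1(θ) = T_base + A·exp(−(θ−θ_p)²/2σ_p²) + G·(1−θ/90)`;
* a **weighted-least-squares diffusion tensor fit** (FA, MD, eigenvalues,
  eigenvectors, FSL-style outputs);
* **fibre-to-field angle maps** and the analytic Watson relation
  `ODI = (2/π)·atan(1/κ)`;
* **multi-TI IR T1 fitting** of the magnitude model
  `y(TI) = |S0(1 − 2η·e^{−TI/T1})|` (grid-initialized Gauss–Newton);
* the **orientation-resolved statistics**: 4.5°-binned angular T1/S0
  profiles conditioned on a microstructural index window, a two-anchor
  straight-line baseline (means over 0–20° and 80–90°), the peak contrast
  ΔT1(54°)/ΔT1(40°), the parallel-minus-perpendicular contrast
  ΔT1(0°–90°), percent-of-mean ratios, 2D angle-by-index surfaces,
  S0 normalization, corpus-callosum ROI comparisons with Welch t-tests,
  mask SNR with Rician-corrected noise floor, and a cross-field group
  summary table;
* **NIfTI-1 / FSL bval-bvec readers and writers** and a YAML-configured
  pipeline with a CLI (`inst/cli/t1aniso.R`).

The preset scenarios `scenario_3T()` / `scenario_7T()` are calibrated so
that the noise-free analysis reproduces the published cohort summary
values (mean WM T1 829.3 / 917.8 ms; ODI-selected peak delta 59.4 ms at
3 T, 37.0 ms at 7 T; 0–90° delta 75.6 ms at 7 T; peak percent 7.3% / 4.7%),
making every pipeline stage verifiable by parameter recovery.

## Worked example

```r
library(t1aniso)

# a reduced 3 T study: 2 subjects, small grid (fast; defaults emulate the
# full acquisition: 40x40x20 grid, 64 directions/shell, 11 subjects)
sc  <- scenario_3T(n_subjects = 2, grid_shape = c(24, 24, 12),
                   voxels_per_bundle = 30, n_dirs_per_shell = 32)
tbl <- run_cohort(sc)   # simulate + tensor fit + angle map + T1 fit

# condition on low orientation dispersion and measure the angular contrast
cd <- cohort_deltas(tbl, selection_rule("ODI", 0, 0.2), peak_angle = 54)
cat(sprintf("median ODI %.2f | mean T1 %.1f ms | dT1(54) %.1f ms | %.1f%% of mean\n",
            cd$median_index, cd$mean, cd$deltas$delta_peak,
            cd$deltas$percent_of_mean))
plot(cd$profile)
```

Output from this exact snippet:

```
median ODI 0.10 | mean T1 820.7 ms | dT1(54) 51.4 ms | 6.3% of mean
```

That is: voxels with ODI ≤ 0.2 have a median true ODI of 0.10, a mean
fitted T1 of ~821 ms, and a baseline-subtracted T1 elevation of ~51 ms in
the bin containing 54° — about 6.3% of the mean T1, recovering the
injected 3 T angular law (the calibrated target is 59.4 ms / 7.3%; a
2-subject mini-cohort carries several ms of between-subject amplitude
noise — the full 11-subject preset recovers the targets to a few
percent, see `scripts/acceptance.R`).

A full report bundle (per-subject NIfTI maps, profile CSVs, group table,
plots, provenance log):

```r
yaml::write_yaml(list(scenario = list(preset = "3T"),
                      out_dir = "results/run3T", seed = 42), "cfg.yaml")
run_pipeline("cfg.yaml")
```

or from the shell:

```sh
Rscript inst/cli/t1aniso.R all --config cfg.yaml --out results/run3T
```

## Documentation

The methods vignette (`vignettes/t1-anisotropy-methods.Rmd`) describes the
signal models, the fitting algorithms, what the phantom does and does not
emulate, the calibration of the presets, and the numerical design choices;
function-level documentation is in the roxygen comments.
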