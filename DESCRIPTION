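Package: t1aniso
Title: Orientation-Dependent T1 Relaxometry Versus White-Matter Microstructure
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to study the dependence of longitudinal relaxation time (T1)
    on the white-matter fibre-to-field angle, conditioned on diffusion-MRI
    microstructural indices. Provides a synthetic brain-phantom generator with
    Watson-dispersed fibre bundles and a known field-dependent angular T1 law,
    a weighted-least-squares diffusion tensor fit with FA/MD/eigenvector maps,
    fibre-to-field angle maps, multi-TI inversion-recovery T1 estimation, and
    orientation-resolved statistics: angle-binned 1D/2D profiles, two-anchor
    baseline subtraction, peak and parallel-versus-perpendicular T1 contrasts,
    corpus-callosum ROI comparisons, SNR estimation and group tables. Includes
    minimal NIfTI-1 and FSL bval/bvec readers and writers so every stage runs
    on standard neuroimaging file layouts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
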