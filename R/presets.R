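# Printed summary values the preset phantoms are calibrated to: per field,
# the (mean T1, peak delta, 0-90 delta) triplets for the FA-selected and
# ODI-selected white matter, the global mean T1 over FA 0.45-0.9, the peak
# angle, and the acquisition geometry.
published_targets <- function(field) {
  switch(as.character(field),
    "3" = list(fa = c(mean = 817.6, dpeak = 38.7, d090 = -4.6),
               odi = c(mean = 817.8, dpeak = 59.4, d090 = 17.2),
               global_mean = 829.3, theta_peak = 54,
               TIs = c(200, 300, 600, 900, 1200, 1500),
               bvals = c(1500, 3000), gm_t1 = 1300, n_subjects = 11),
    "7" = list(fa = c(mean = 905.0, dpeak = 22.4, d090 = 47.2),
               odi = c(mean = 907.1, dpeak = 37.0, d090 = 75.6),
               global_mean = 917.8, theta_peak = 40,
               TIs = c(300, 600, 1000, 1500, 2000, 3000),
               bvals = c(1000, 2000), gm_t1 = 1800, n_subjects = 6),
    stop("field must be 3 or 7", call. = FALSE))
}

#' Selection rules used by the scenario presets
#'
#' The index windows conditioning the angular profiles: `FA` in
#' `[0.7, 0.9]`, `ODI` in `[0, 0.2]` (the published figure ranges), and the
#' `global` white-matter window `FA` in `[0.45, 0.9]` over which the overall
#' mean T1 is reported.
#'
#' @return named list of [selection_rule()] objects.
#' @export
preset_rules <- function() list(
  FA = selection_rule("FA", 0.7, 0.9),
  ODI = selection_rule("ODI", 0, 0.2),
  global = selection_rule("FA", 0.45, 0.9))

# Noise-free measurement of a set of class laws over the standard fan:
# equal voxel counts per bundle and class, binned profile, two-anchor
# baseline. Returns (mean, dpeak, d090). Uses the production profile code
# so the calibration is consistent with the analysis by construction.
fan_measure <- function(laws, theta_peak) {
  th <- rep(fan_angles(), length(laws))
  vals <- unlist(lapply(laws, eval_t1_law, theta = fan_angles()))
  pr <- profile_1d(vals, th)
  ds <- baseline_and_deltas(pr, theta_peak)
  c(mean = mean(vals), dpeak = ds$delta_peak, d090 = ds$delta_par_perp)
}

# Solve the class law parameters (base, peak and gradient amplitude for the
# coherent and low-ODI classes; base only for the flat dispersed class) so
# that the noise-free forward measurement reproduces the printed targets.
# The measurement operator is linear in the parameters, so one 7x7 solve
# inverts it exactly.
calibrate_fan_laws <- function(targets, sigma_peak = 12) {
  tp <- targets$theta_peak
  mk <- function(p) {
    lawA <- angular_t1_law(p[1], p[2], tp, sigma_peak, p[3])
    lawB <- angular_t1_law(p[4], p[5], tp, sigma_peak, p[6])
    lawC <- angular_t1_law(p[7], 0, tp, sigma_peak, 0)
    list(A = lawA, B = lawB, C = lawC)
  }
  measure <- function(p) {
    l <- mk(p)
    c(fan_measure(list(l$A), tp),
      fan_measure(list(l$A, l$B), tp),
      fan_measure(list(l$A, l$B, l$C), tp)[["mean"]])
  }
  M <- vapply(1:7, function(j) measure(replace(numeric(7), j, 1)), numeric(7))
  y <- c(targets$fa, targets$odi, targets$global_mean)
  p <- solve(M, y)
  mk(p)
}

# Shared preset construction: three fan white-matter classes with known ODI
# plus an isotropic grey-matter background.
build_preset <- function(field, n_subjects, seed, snr_b0, snr_ir,
                         grid_shape, voxels_per_bundle, n_dirs_per_shell,
                         sigma_peak = 12, ...) {
  tg <- published_targets(field)
  laws <- calibrate_fan_laws(tg, sigma_peak)
  classes <- list(
    tissue_class("coherent_wm", "fan", c(1, 0, 0),
                 kappa = kappa_from_odi(0.05),
                 lambda_par = 1.7e-3, lambda_perp = 0.3e-3,
                 law = laws$A),
    tissue_class("low_odi_wm", "fan", c(1, 0, 0),
                 kappa = kappa_from_odi(0.15),
                 lambda_par = 1.7e-3, lambda_perp = 0.3e-3,
                 law = laws$B),
    tissue_class("dispersed_wm", "fan", c(1, 0, 0),
                 kappa = kappa_from_odi(0.22),
                 lambda_par = 1.9e-3, lambda_perp = 0.1e-3,
                 law = laws$C),
    tissue_class("gm", "isotropic", c(0, 0, 0), kappa = 0,
                 lambda_par = 1e-3, lambda_perp = 0.999e-3, d_iso = 0.8e-3,
                 law = angular_t1_law(tg$gm_t1, 0, tg$theta_peak, sigma_peak, 0),
                 s0_base = 1100))
  scenario_config(field_strength = field, grid_shape = grid_shape,
                  classes = classes, bvals = tg$bvals,
                  n_dirs_per_shell = n_dirs_per_shell,
                  TIs = tg$TIs, snr_b0 = snr_b0, snr_ir = snr_ir,
                  n_subjects = n_subjects, seed = seed,
                  voxels_per_bundle = voxels_per_bundle, ...)
}

#' Preset synthetic scenarios calibrated to the published summary values
#'
#' `scenario_3T()` emulates the 3 T study (11 subjects, shells at 1500 and
#' 3000 s/mm^2, six TIs from 200 to 1500 ms, T1 peak at 54 degrees) and
#' `scenario_7T()` the 7 T study (6 subjects, shells at 1000 and
#' 2000 s/mm^2, TIs from 300 to 3000 ms, peak at 40 degrees plus a
#' parallel-minus-perpendicular T1 gradient). Class angular-T1 laws are
#' solved at construction time so the noise-free pipeline reproduces the
#' printed mean-T1, peak-delta and 0-90-delta values for the FA- and
#' ODI-selected white matter.
#'
#' @param n_subjects cohort size.
#' @param seed master seed.
#' @param snr_b0,snr_ir noise levels (see [scenario_config()]).
#' @param grid_shape,voxels_per_bundle,n_dirs_per_shell size knobs; the
#'   defaults are the stated study emulation, smaller values are useful for
#'   quick tests.
#' @param ... passed to [scenario_config()].
#' @return a `scenario_config`.
#' @export
scenario_3T <- function(n_subjects = 11, seed = 1, snr_b0 = 40, snr_ir = 80,
                        grid_shape = c(40, 40, 20), voxels_per_bundle = 100,
                        n_dirs_per_shell = 64, ...) {
  build_preset(3, n_subjects, seed, snr_b0, snr_ir, grid_shape,
               voxels_per_bundle, n_dirs_per_shell, ...)
}

#' @rdname scenario_3T
#' @export
scenario_7T <- function(n_subjects = 6, seed = 1, snr_b0 = 40, snr_ir = 80,
                        grid_shape = c(40, 40, 20), voxels_per_bundle = 100,
                        n_dirs_per_shell = 64, ...) {
  build_preset(7, n_subjects, seed, snr_b0, snr_ir, grid_shape,
               voxels_per_bundle, n_dirs_per_shell, ...)
}

#' Corpus-callosum demonstration scenario
#'
#' A single coherent bundle perpendicular to B0 split into four segments
#' with different baseline T1 (genu, mid-motor, somato-motor, splenium),
#' emulating the published callosal ROI contrast (somato-motor about 150 ms
#' longer than genu at 3 T, about 90 ms at 7 T).
#'
#' @inheritParams scenario_3T
#' @param field 3 or 7.
#' @return a `scenario_config`; ROI boxes for the four segments are
#'   attached as attribute `rois`.
#' @export
scenario_cc <- function(field = 3, n_subjects = 6, seed = 1, snr_b0 = 40,
                        snr_ir = 80, voxels_per_bundle = 60, ...) {
  tg <- published_targets(field)
  base <- if (field == 3) 780 else 880
  offs <- if (field == 3) c(genu = 0, mid_motor = 100, somato_motor = 150,
                            splenium = 10)
          else c(genu = 0, mid_motor = 60, somato_motor = 90, splenium = 10)
  cl <- tissue_class("cc", "fixed", c(1, 0, 0),
                     kappa = kappa_from_odi(0.05),
                     lambda_par = 1.7e-3, lambda_perp = 0.3e-3,
                     law = angular_t1_law(base, 0, tg$theta_peak, 12, 0),
                     fibre_axes = list(c(1, 0, 0)), t1_offsets = unname(offs))
  gm <- tissue_class("gm", "isotropic", c(0, 0, 0), kappa = 0,
                     d_iso = 0.8e-3, lambda_par = 1e-3, lambda_perp = 0.999e-3,
                     law = angular_t1_law(tg$gm_t1, 0, tg$theta_peak, 12, 0),
                     s0_base = 1100)
  sc <- scenario_config(field_strength = field, grid_shape = c(24, 24, 10),
                        classes = list(cl, gm), bvals = tg$bvals,
                        n_dirs_per_shell = 32, TIs = tg$TIs,
                        snr_b0 = snr_b0, snr_ir = snr_ir,
                        n_subjects = n_subjects, seed = seed,
                        voxels_per_bundle = voxels_per_bundle, ...)
  # segment voxels are laid out in order from the first interior voxel;
  # recover each segment's bounding box as an ROI spec (0-based half-open)
  ph <- build_phantom(sc)
  rois <- list()
  for (si in seq_len(4)) {
    vox <- which(ph$seg_of == si)
    ijk <- arrayInd(vox, ph$grid)
    rois[[names(offs)[si]]] <- list(min = apply(ijk, 2, min) - 1L,
                                    max = apply(ijk, 2, max))
  }
  attr(sc, "rois") <- rois
  sc
}
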