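#' Angular T1 law
#'
#' Ground-truth dependence of T1 on the fibre-to-field angle used by the
#' phantom generator: a Gaussian peak plus a linear parallel-to-perpendicular
#' gradient on top of a flat base,
#' \deqn{T_1(\theta) = t_{base} + A e^{-(\theta-\theta_p)^2 / 2\sigma_p^2}
#'       + G (1 - \theta/90).}
#' With `peak_amp = grad_amp = 0` the law is constant at `t1_base`. For
#' voxels without a defined fibre angle (isotropic tissue) the law evaluates
#' to `t1_base`.
#'
#' @param t1_base baseline T1 (ms).
#' @param peak_amp Gaussian peak amplitude (ms).
#' @param theta_peak peak position (degrees, in `[0, 90]`).
#' @param sigma_peak Gaussian width (degrees, > 0).
#' @param grad_amp amplitude of the linear 0->90 degree decrease (ms); the
#'   full value is added at 0 degrees, nothing at 90.
#' @return an `angular_t1_law` object.
#' @export
angular_t1_law <- function(t1_base, peak_amp = 0, theta_peak = 54,
                           sigma_peak = 12, grad_amp = 0) {
  if (theta_peak < 0 || theta_peak > 90) stop("theta_peak must be in [0, 90]", call. = FALSE)
  if (sigma_peak <= 0) stop("sigma_peak must be > 0", call. = FALSE)
  structure(list(t1_base = t1_base, peak_amp = peak_amp,
                 theta_peak = theta_peak, sigma_peak = sigma_peak,
                 grad_amp = grad_amp), class = "angular_t1_law")
}

#' Evaluate an angular T1 law
#' @param law an [angular_t1_law()].
#' @param theta angles in degrees (NA = no fibre; returns `t1_base`).
#' @return T1 values in ms.
#' @export
eval_t1_law <- function(law, theta) {
  stopifnot(inherits(law, "angular_t1_law"))
  out <- rep(law$t1_base, length(theta))
  ok <- !is.na(theta)
  out[ok] <- law$t1_base +
    law$peak_amp * exp(-(theta[ok] - law$theta_peak)^2 / (2 * law$sigma_peak^2)) +
    law$grad_amp * (1 - theta[ok] / 90)
  out
}

#' Tissue class of the synthetic phantom
#'
#' A tissue class bundles the microstructural ground truth of a group of
#' voxels: up to three fibre populations with volume fractions
#' `f1 >= f2 >= f3`, an isotropic fraction `f_iso = 1 - f1 - f2 - f3`, a
#' Watson concentration `kappa` shared by the fibre populations (hence a
#' known ODI), zeppelin diffusivities, and the class's angular T1 law.
#'
#' @param name label.
#' @param geometry `"fan"`: straight mini-bundles, one per 4.5-degree
#'   angular bin at the bin centres (2.25, 6.75, ..., 87.75 degrees to B0),
#'   so every bin is populated and angle noise does not spill bundles
#'   across bin edges; `"fixed"`: the axes given in `fibre_axes`;
#'   `"isotropic"`: no fibres (background tissue).
#' @param volume_fractions `c(f1, f2, f3)`; the isotropic fraction is the
#'   complement.
#' @param kappa Watson concentration (>= 0); `Inf` = perfectly coherent.
#' @param lambda_par,lambda_perp axial/radial zeppelin diffusivities
#'   (mm^2/s), `lambda_par >= lambda_perp > 0`.
#' @param d_iso isotropic diffusivity (mm^2/s).
#' @param law an [angular_t1_law()].
#' @param s0_base non-diffusion-weighted signal level (arbitrary units).
#' @param fibre_axes list of unit 3-vectors (only for `geometry = "fixed"`).
#' @param t1_offsets optional per-segment additive T1 offsets (ms) for
#'   `"fixed"` geometry with several segments (e.g. callosal subregions).
#' @return a `tissue_class` object.
#' @export
tissue_class <- function(name, geometry = c("fan", "fixed", "isotropic"),
                         volume_fractions = c(1, 0, 0), kappa = Inf,
                         lambda_par = 1.7e-3, lambda_perp = 0.3e-3,
                         d_iso = 3.0e-3, law, s0_base = 1000,
                         fibre_axes = list(c(0, 0, 1)), t1_offsets = NULL) {
  geometry <- match.arg(geometry)
  f <- volume_fractions
  if (length(f) != 3L || any(f < 0) || f[1] < f[2] || f[2] < f[3])
    stop("volume fractions must satisfy f1 >= f2 >= f3 >= 0", call. = FALSE)
  f_iso <- 1 - sum(f)
  if (f_iso < -1e-9) stop("volume fractions must sum to <= 1", call. = FALSE)
  f_iso <- max(0, f_iso)
  if (kappa < 0) stop("kappa must be >= 0", call. = FALSE)
  if (!(lambda_par >= lambda_perp) || lambda_perp <= 0)
    stop("need lambda_par >= lambda_perp > 0", call. = FALSE)
  if (geometry != "isotropic") {
    nfib <- sum(f > 0)
    if (geometry == "fixed" && length(fibre_axes) < nfib)
      stop("fixed geometry needs one axis per fibre population", call. = FALSE)
    for (ax in fibre_axes) stopifnot_unit(ax, "fibre axis")
  }
  stopifnot(inherits(law, "angular_t1_law"))
  structure(list(name = name, geometry = geometry,
                 volume_fractions = f, f_iso = f_iso, kappa = kappa,
                 lambda_par = lambda_par, lambda_perp = lambda_perp,
                 d_iso = d_iso, law = law, s0_base = s0_base,
                 fibre_axes = fibre_axes, t1_offsets = t1_offsets),
            class = "tissue_class")
}

#' Scenario configuration for a synthetic study
#'
#' All ground-truth parameters of one synthetic multi-subject acquisition:
#' field strength, tissue classes and their spatial layout, two-shell
#' diffusion geometry, inversion times, noise levels, cohort size and the
#' master seed. The B0 axis is the grid z-axis; all randomness derives from
#' `seed` through named substreams, so output is fully reproducible.
#'
#' @param field_strength 3 or 7 (tesla); informational label.
#' @param grid_shape integer 3-vector of voxel counts.
#' @param classes list of [tissue_class()] objects. Classes are laid out in
#'   order; an `"isotropic"` class absorbs all remaining voxels. Two voxel
#'   slabs at both x-faces are left as signal-free background (air) for
#'   noise estimation.
#' @param bvals non-zero shell b-values (s/mm^2).
#' @param n_dirs_per_shell gradient directions per shell (deterministic
#'   Fibonacci hemisphere scheme).
#' @param n_b0 number of b=0 volumes.
#' @param TIs inversion times (ms) of the IR series.
#' @param snr_b0 SNR of the b=0 signal at the white-matter S0 level
#'   (`Inf` = noise-free).
#' @param snr_ir SNR of the IR series at S0 (`Inf` = noise-free).
#' @param eta inversion efficiency of the simulated IR signal.
#' @param fit_eta_range inversion-efficiency bounds used by the *pipeline*
#'   T1 fit. Default `c(1, 1)`: efficiency pinned at the full adiabatic
#'   inversion the simulation uses. With the short 3 T TI range, fitting
#'   `eta` freely is nearly degenerate with T1 at realistic SNR; pass
#'   `c(0.5, 1)` to fit it anyway (the module-level default for real data).
#' @param n_subjects cohort size.
#' @param seed master seed.
#' @param voxels_per_bundle voxels per fan mini-bundle.
#' @param n_watson axis samples per class used for the Watson-averaged
#'   tensor.
#' @param subject_t1_sd between-subject SD of a global additive T1 offset
#'   (ms).
#' @param subject_amp_sd between-subject SD of the multiplicative scale on
#'   peak and gradient amplitudes.
#' @param s0_slope optional relative S0 increase from 0 to 90 degrees
#'   (e.g. 0.02 for 2 percent); default 0 (off).
#' @return a `scenario_config` object.
#' @export
scenario_config <- function(field_strength, grid_shape = c(40, 40, 20),
                            classes, bvals, n_dirs_per_shell = 64, n_b0 = 4,
                            TIs, snr_b0 = 40, snr_ir = 80, eta = 1,
                            fit_eta_range = c(1, 1),
                            n_subjects = 11, seed = 1,
                            voxels_per_bundle = 100, n_watson = 300,
                            subject_t1_sd = 10, subject_amp_sd = 0.08,
                            s0_slope = 0) {
  if (!field_strength %in% c(3, 7)) stop("field_strength must be 3 or 7", call. = FALSE)
  if (any(bvals <= 0)) stop("shell b-values must be > 0", call. = FALSE)
  if (any(TIs <= 0)) stop("TIs must be > 0", call. = FALSE)
  if (length(grid_shape) != 3L || any(grid_shape < 4))
    stop("grid_shape must be 3 positive integers", call. = FALSE)
  structure(list(field_strength = field_strength,
                 grid_shape = as.integer(grid_shape), classes = classes,
                 bvals = bvals, n_dirs_per_shell = n_dirs_per_shell,
                 n_b0 = n_b0, TIs = TIs, snr_b0 = snr_b0, snr_ir = snr_ir,
                 eta = eta, fit_eta_range = fit_eta_range,
                 n_subjects = n_subjects, seed = seed,
                 voxels_per_bundle = voxels_per_bundle, n_watson = n_watson,
                 subject_t1_sd = subject_t1_sd,
                 subject_amp_sd = subject_amp_sd, s0_slope = s0_slope,
                 s0_ref = 1000),
            class = "scenario_config")
}

# Nominal fan angles: straight mini-bundles sweeping 0..90 degrees, one per
# angular bin, placed at the bin centres. Centre placement matters: with
# bundles on bin edges, angle-estimation noise spills half of each bundle
# into the neighbouring bin, which biases the first-minus-last-bin contrast
# by more than a cohort SD at the default SNR. At bin centres the spill is
# second-order and symmetric.
fan_angles <- function(bin_width = 4.5)
  seq(bin_width / 2, 90 - bin_width / 2, by = bin_width)

# Spatial layout: segment table + per-voxel segment id. A segment is a run
# of voxels sharing one class, one nominal axis and one T1 offset.
build_phantom <- function(scenario) {
  grid <- scenario$grid_shape
  nvox <- prod(grid)
  xidx <- slice.index(array(0, grid), 1)
  air <- xidx <= 2 | xidx >= grid[1] - 1
  interior <- which(!air)

  segs <- list()
  for (ci in seq_along(scenario$classes)) {
    cl <- scenario$classes[[ci]]
    if (cl$geometry == "fan") {
      for (th in fan_angles()) {
        ax <- c(sin(th * pi / 180), 0, cos(th * pi / 180))
        segs[[length(segs) + 1L]] <- list(class = ci, theta = th, axis = ax,
                                          n = scenario$voxels_per_bundle,
                                          t1_offset = 0)
      }
    } else if (cl$geometry == "fixed") {
      offs <- if (is.null(cl$t1_offsets)) 0 else cl$t1_offsets
      for (k in seq_along(offs)) {
        ax <- cl$fibre_axes[[1]]
        segs[[length(segs) + 1L]] <- list(class = ci,
                                          theta = fibre_to_field_angle(ax),
                                          axis = ax,
                                          n = scenario$voxels_per_bundle,
                                          t1_offset = offs[k])
      }
    }
  }
  iso_class <- which(vapply(scenario$classes,
                            function(c) c$geometry == "isotropic", logical(1)))
  need <- sum(vapply(segs, `[[`, numeric(1), "n"))
  if (need > length(interior))
    stop("grid too small for the requested layout (need ", need,
         " voxels, have ", length(interior), ")", call. = FALSE)
  seg_of <- integer(nvox)           # 0 = air
  pos <- 1L
  for (si in seq_along(segs)) {
    take <- interior[pos:(pos + segs[[si]]$n - 1L)]
    seg_of[take] <- si
    pos <- pos + segs[[si]]$n
  }
  if (length(iso_class)) {
    rest <- interior[pos:length(interior)]
    segs[[length(segs) + 1L]] <- list(class = iso_class[1], theta = NA_real_,
                                      axis = c(0, 0, 1), n = length(rest),
                                      t1_offset = 0)
    seg_of[rest] <- length(segs)
  }
  list(segs = segs, seg_of = seg_of, air = air, grid = grid)
}

# Deterministic near-uniform hemisphere directions (Fibonacci spiral), with
# a seed-dependent azimuthal offset so different scenarios decorrelate.
fibonacci_dirs <- function(n, seed = 0, shell = 1) {
  i <- seq_len(n) - 0.5
  z <- i / n                     # upper hemisphere
  phi <- 2 * pi * i * (sqrt(5) - 1) / 2 +
    2 * pi * ((seed %% 997) / 997 + 0.37 * shell)
  s <- sqrt(pmax(0, 1 - z^2))
  rbind(s * cos(phi), s * sin(phi), z)
}

# Watson-averaged zeppelin tensor about +z for one class and subject.
# Average of per-axis tensors lambda_perp I + (lambda_par - lambda_perp) nn'
# over n_watson sampled axes, symmetrized about the mean axis: only the
# sampled concentration tau1 = mean(cos^2) is kept, so dispersion lowers the
# tensor anisotropy (as in tissue) while the principal axis stays exactly on
# the bundle axis. kappa = Inf short-circuits to the coherent tensor.
watson_avg_tensor_z <- function(cl, n_watson, seed) {
  tau1 <- if (is.infinite(cl$kappa)) 1 else {
    ax <- sample_watson(c(0, 0, 1), cl$kappa, n_watson, seed = seed)
    mean(ax[, 3]^2)
  }
  M <- diag(c((1 - tau1) / 2, (1 - tau1) / 2, tau1))
  cl$lambda_perp * diag(3) + (cl$lambda_par - cl$lambda_perp) * M
}

#' Simulate a two-shell diffusion acquisition of the phantom
#'
#' Per voxel the noise-free signal is
#' \eqn{S(b, g) = S_0 [\sum_i f_i e^{-b g^T \bar D_i g} + f_{iso} e^{-b d_{iso}}]}
#' with \eqn{\bar D_i} the Watson-averaged zeppelin tensor of fibre
#' population i (so orientation dispersion lowers the fitted FA, as in
#' tissue). Rician noise is applied at `snr_b0` relative to the
#' white-matter S0 level; air voxels contain pure noise.
#'
#' @param scenario a [scenario_config()].
#' @param subject subject index (1-based); selects the noise and
#'   Watson-sampling substreams.
#' @return a [dwi_dataset()].
#' @export
simulate_dwi <- function(scenario, subject = 1) {
  stopifnot(inherits(scenario, "scenario_config"))
  ph <- build_phantom(scenario)
  grid <- ph$grid
  nsh <- length(scenario$bvals)
  dirs <- lapply(seq_len(nsh), function(s)
    fibonacci_dirs(scenario$n_dirs_per_shell, scenario$seed, s))
  bvals <- c(rep(0, scenario$n_b0),
             rep(scenario$bvals, each = scenario$n_dirs_per_shell))
  bvecs <- cbind(matrix(0, 3, scenario$n_b0), do.call(cbind, dirs))
  nvol <- length(bvals)

  # Watson-averaged tensor per class (cached per subject substream)
  Dz <- lapply(seq_along(scenario$classes), function(ci)
    watson_avg_tensor_z(scenario$classes[[ci]], scenario$n_watson,
                        substream_seed(scenario$seed, scenario$field_strength, subject, ci, "watson")))

  g <- t(bvecs)                                   # nvol x 3
  seg_signal <- matrix(0, length(ph$segs), nvol)
  for (si in seq_along(ph$segs)) {
    sg <- ph$segs[[si]]
    cl <- scenario$classes[[sg$class]]
    s <- rep(0, nvol)
    if (cl$geometry == "isotropic") {
      s <- cl$f_iso * exp(-bvals * cl$d_iso)
    } else {
      f <- cl$volume_fractions
      nfib <- sum(f > 0)
      for (i in seq_len(nfib)) {
        ax <- if (cl$geometry == "fan" || i == 1L) sg$axis else cl$fibre_axes[[i]]
        R <- rotation_z_to(ax)
        D <- R %*% Dz[[sg$class]] %*% t(R)
        q <- rowSums((g %*% D) * g)               # g' D g per volume
        s <- s + f[i] * exp(-bvals * q)
      }
      if (cl$f_iso > 0) s <- s + cl$f_iso * exp(-bvals * cl$d_iso)
    }
    seg_signal[si, ] <- cl$s0_base * s
  }

  S <- matrix(0, prod(grid), nvol)
  inseg <- ph$seg_of > 0L
  S[inseg, ] <- seg_signal[ph$seg_of[inseg], ]
  sigma <- if (is.infinite(scenario$snr_b0)) 0 else scenario$s0_ref / scenario$snr_b0
  if (sigma > 0) {
    S <- with_seed(substream_seed(scenario$seed, scenario$field_strength, subject, "dwi_noise"),
                   matrix(add_rician(as.vector(S), sigma), nrow(S), ncol(S)))
  }
  dwi_dataset(array(S, c(grid, nvol)), bvals, bvecs,
              mask = array(inseg, grid))
}

#' Simulate the multi-TI inversion-recovery series of the phantom
#'
#' The ground-truth T1 of a voxel follows its class's angular law evaluated
#' at the voxel's fibre-to-field angle, plus a per-subject global T1 offset
#' and a per-subject multiplicative scale on the angular amplitudes
#' (between-subject variability). The signal is the magnitude IR model
#' \eqn{y(TI) = |S_0 (1 - 2 \eta e^{-TI/T_1})|} with Rician noise at
#' `snr_ir`.
#'
#' @inheritParams simulate_dwi
#' @param theta_map optional 3D array of fibre-to-field angles (degrees) to
#'   drive the law; default: the phantom's true angles.
#' @return list with `data` (4D array, one volume per TI), `TIs`, and the
#'   ground-truth `t1_true`, `s0_true` maps.
#' @export
simulate_ir <- function(scenario, subject = 1, theta_map = NULL) {
  stopifnot(inherits(scenario, "scenario_config"))
  if (any(scenario$TIs <= 0)) stop("TIs must be > 0", call. = FALSE)
  ph <- build_phantom(scenario)
  grid <- ph$grid
  nvox <- prod(grid)
  fx <- with_seed(substream_seed(scenario$seed, scenario$field_strength, subject, "subject_fx"), list(
    t1_offset = stats::rnorm(1, 0, scenario$subject_t1_sd),
    amp_scale = stats::rnorm(1, 1, scenario$subject_amp_sd)))

  theta <- rep(NA_real_, nvox)
  t1 <- s0 <- rep(NA_real_, nvox)
  for (si in seq_along(ph$segs)) {
    sg <- ph$segs[[si]]
    cl <- scenario$classes[[sg$class]]
    vox <- which(ph$seg_of == si)
    th <- if (is.null(theta_map)) rep(sg$theta, length(vox))
          else as.vector(theta_map)[vox]
    theta[vox] <- th
    law <- cl$law
    base <- law$t1_base + sg$t1_offset + fx$t1_offset
    amp <- law$peak_amp * fx$amp_scale
    grd <- law$grad_amp * fx$amp_scale
    tl <- angular_t1_law(base, amp, law$theta_peak, law$sigma_peak, grd)
    t1[vox] <- eval_t1_law(tl, th)
    s0v <- rep(cl$s0_base, length(vox))
    if (scenario$s0_slope != 0 && !all(is.na(th)))
      s0v <- s0v * (1 + scenario$s0_slope * ifelse(is.na(th), 0, th) / 90)
    s0[vox] <- s0v
  }
  TIs <- scenario$TIs
  Y <- matrix(0, nvox, length(TIs))
  ok <- !is.na(t1)
  for (j in seq_along(TIs))
    Y[ok, j] <- abs(s0[ok] * (1 - 2 * scenario$eta * exp(-TIs[j] / t1[ok])))
  sigma <- if (is.infinite(scenario$snr_ir)) 0 else scenario$s0_ref / scenario$snr_ir
  if (sigma > 0)
    Y <- with_seed(substream_seed(scenario$seed, scenario$field_strength, subject, "ir_noise"),
                   matrix(add_rician(as.vector(Y), sigma), nrow(Y), ncol(Y)))
  list(data = array(Y, c(grid, length(TIs))), TIs = TIs,
       t1_true = array(t1, grid), s0_true = array(s0, grid),
       subject_effects = fx)
}

#' Export the phantom's ground-truth maps
#'
#' The stand-in for the microstructural model outputs that the analysis
#' conditions on: true ODI (via the analytic Watson relation), fibre volume
#' fractions F1-F3, fibre-to-field angle, T1 and S0 truth maps, class
#' labels and masks. Optionally written as NIfTI files for recovery checks.
#'
#' @inheritParams simulate_dwi
#' @param dir optional output directory; when given, maps are written as
#'   NIfTI with FSL-style suffixes.
#' @return named list of 3D arrays: `odi`, `f1`, `f2`, `f3`, `theta`,
#'   `t1_true`, `s0_true`, `label`, `mask_head`, `mask_wm`.
#' @export
export_ground_truth <- function(scenario, subject = 1, dir = NULL) {
  ph <- build_phantom(scenario)
  grid <- ph$grid; nvox <- prod(grid)
  lab <- integer(nvox); odi <- f1 <- f2 <- f3 <- theta <- rep(NA_real_, nvox)
  wm <- rep(FALSE, nvox)
  for (si in seq_along(ph$segs)) {
    sg <- ph$segs[[si]]
    cl <- scenario$classes[[sg$class]]
    vox <- which(ph$seg_of == si)
    lab[vox] <- sg$class
    odi[vox] <- odi_from_kappa(cl$kappa)
    f1[vox] <- cl$volume_fractions[1]
    f2[vox] <- cl$volume_fractions[2]
    f3[vox] <- cl$volume_fractions[3]
    theta[vox] <- sg$theta
    wm[vox] <- cl$geometry != "isotropic"
  }
  ir <- simulate_ir(scenario, subject)
  out <- list(odi = array(odi, grid), f1 = array(f1, grid),
              f2 = array(f2, grid), f3 = array(f3, grid),
              theta = array(theta, grid),
              t1_true = ir$t1_true, s0_true = ir$s0_true,
              label = array(lab, grid),
              mask_head = array(ph$seg_of > 0L, grid),
              mask_wm = array(wm, grid))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(out))
      write_nifti(out[[nm]] + 0, file.path(dir, paste0("truth_", nm, ".nii")))
  }
  out
}
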