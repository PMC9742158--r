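test_that("b0 volumes without noise equal the class S0", {
  sc <- tiny_3T(n_subjects = 1, snr_b0 = Inf)
  dwi <- simulate_dwi(sc, 1)
  truth <- export_ground_truth(sc, 1)
  b0 <- dwi$data[, , , 1]
  wm <- truth$label >= 1 & truth$label <= 3
  expect_equal(unique(round(b0[wm], 9)), 1000)
  expect_equal(unique(round(b0[truth$label == 4], 9)), 1100)  # GM
  expect_true(all(b0[!truth$mask_head] == 0))                 # air
})

test_that("noise-free signals equal their closed forms", {
  sc <- tiny_3T(n_subjects = 1, snr_b0 = Inf)
  dwi <- simulate_dwi(sc, 1)
  truth <- export_ground_truth(sc, 1)
  ph <- t1aniso:::build_phantom(sc)
  # pick one bundle of the most coherent class and recompute independently
  si <- 5L
  sg <- ph$segs[[si]]
  cl <- sc$classes[[sg$class]]
  Dz <- t1aniso:::watson_avg_tensor_z(cl, sc$n_watson,
          t1aniso:::substream_seed(sc$seed, sc$field_strength, 1, sg$class,
                                   "watson"))
  R <- t1aniso:::rotation_z_to(sg$axis)
  D <- R %*% Dz %*% t(R)
  vox <- which(ph$seg_of == si)[1]
  ijk <- arrayInd(vox, sc$grid_shape)
  for (v in c(1, 7, 20, length(dwi$bvals))) {
    expected <- 1000 * exp(-dwi$bvals[v] *
                             drop(t(dwi$bvecs[, v]) %*% D %*% dwi$bvecs[, v]))
    expect_equal(dwi$data[ijk[1], ijk[2], ijk[3], v], expected,
                 tolerance = 1e-10)
  }
})

test_that("coherent single-fibre attenuation has the exp(-b lambda_par) closed form", {
  law <- angular_t1_law(800)
  cl <- tissue_class("stick", "fixed", c(1, 0, 0), kappa = Inf,
                     lambda_par = 1.7e-3, lambda_perp = 0.2e-3, law = law,
                     fibre_axes = list(c(0, 0, 1)))
  gm <- tissue_class("bg", "isotropic", c(0, 0, 0), kappa = 0,
                     lambda_par = 1e-3, lambda_perp = 0.999e-3,
                     d_iso = 0.8e-3, law = law)
  sc <- scenario_config(3, grid_shape = c(10, 10, 4), classes = list(cl, gm),
                        bvals = 1000, n_dirs_per_shell = 16,
                        TIs = c(200, 300, 600, 900, 1200, 1500),
                        snr_b0 = Inf, snr_ir = Inf, n_subjects = 1,
                        voxels_per_bundle = 10)
  dwi <- simulate_dwi(sc, 1)
  tf <- fit_tensor_wls(dwi)
  truth <- export_ground_truth(sc, 1)
  vox <- which(truth$label == 1)[1]
  ijk <- arrayInd(vox, sc$grid_shape)
  ev <- tf$evals[ijk[1], ijk[2], ijk[3], ]
  expect_equal(ev, c(1.7e-3, 0.2e-3, 0.2e-3), tolerance = 1e-7)
  # S/S0 along the fibre at b = 1000 is exp(-1.7)
  expect_equal(exp(-1000 * ev[1]), exp(-1.7), tolerance = 1e-6)
})

test_that("orientation dispersion lowers the fitted FA", {
  sc_coh <- tiny_3T(n_subjects = 1, snr_b0 = Inf)
  tblc <- run_subject(sc_coh, 1)
  fa_by_class <- tapply(tblc$fa, tblc$label, mean)
  # classes 1 and 2 share diffusivities; class 2 has higher dispersion
  expect_lt(fa_by_class["2"], fa_by_class["1"])
})

test_that("Rician floor: air voxels have mean magnitude sigma * sqrt(pi/2)", {
  sc <- tiny_3T(n_subjects = 1, snr_b0 = 40, grid_shape = c(24, 24, 12))
  dwi <- simulate_dwi(sc, 1)
  truth <- export_ground_truth(sc, 1)
  sigma <- sc$s0_ref / sc$snr_b0
  bg <- dwi$data[rep(!truth$mask_head, dim(dwi$data)[4])]
  expect_gt(length(bg), 1e4)
  expect_equal(mean(bg), sigma * sqrt(pi / 2), tolerance = 0.02)
})

test_that("simulation is bit-identical under fixed seeds", {
  sc <- tiny_3T(n_subjects = 2)
  expect_identical(simulate_dwi(sc, 1)$data, simulate_dwi(sc, 1)$data)
  expect_identical(simulate_ir(sc, 2)$data, simulate_ir(sc, 2)$data)
  # different subjects get different noise
  expect_false(identical(simulate_dwi(sc, 1)$data, simulate_dwi(sc, 2)$data))
})

test_that("ground-truth maps carry the analytic ODI and volume fractions", {
  sc <- tiny_3T(n_subjects = 1)
  truth <- export_ground_truth(sc, 1)
  expect_equal(unique(truth$odi[truth$label == 1]), 0.05, tolerance = 1e-12)
  expect_equal(unique(truth$odi[truth$label == 2]), 0.15, tolerance = 1e-12)
  expect_true(all(truth$f2[truth$mask_wm] == 0))
  expect_true(all(truth$f3[truth$mask_wm] == 0))
  expect_true(all(truth$f1[truth$label %in% 1:3] == 1))
})

test_that("a perpendicular bundle has a 90-degree truth angle", {
  sc <- scenario_cc(3, n_subjects = 1)
  truth <- export_ground_truth(sc, 1)
  expect_equal(unique(truth$theta[truth$label == 1]), 90)
})

test_that("the IR ground truth follows the angular law", {
  sc <- tiny_3T(n_subjects = 1, snr_ir = Inf, subject_t1_sd = 0,
                subject_amp_sd = 0)
  ir <- simulate_ir(sc, 1)
  truth <- export_ground_truth(sc, 1)
  lawA <- sc$classes[[1]]$law
  sel <- truth$label == 1
  expect_equal(ir$t1_true[sel], eval_t1_law(lawA, truth$theta[sel]),
               tolerance = 1e-12)
  # flat law gives a constant T1 map
  lawflat <- angular_t1_law(900)
  expect_equal(eval_t1_law(lawflat, c(0, 30, 54, 90, NA)), rep(900, 5))
})

test_that("the printed 3 T peak contrast is built into the law", {
  law <- angular_t1_law(817.8, peak_amp = 59.4, theta_peak = 54,
                        sigma_peak = 12, grad_amp = 0)
  peak_minus_ends <- eval_t1_law(law, 54) - mean(eval_t1_law(law, c(0, 90)))
  expect_equal(peak_minus_ends, 59.4, tolerance = 0.05)
})

test_that("invalid scenario inputs are rejected", {
  law <- angular_t1_law(800)
  expect_error(tissue_class("x", "fan", c(0.2, 0.5, 0), kappa = 1, law = law),
               "f1 >= f2")
  expect_error(tissue_class("x", "fan", c(1, 0, 0), kappa = 1,
                            lambda_par = 1e-3, lambda_perp = 2e-3, law = law),
               "lambda_par")
  expect_error(angular_t1_law(800, theta_peak = 120), "theta_peak")
  expect_error(angular_t1_law(800, sigma_peak = 0), "sigma_peak")
  sc <- tiny_3T()
  sc$TIs <- c(-100, 300)
  expect_error(simulate_ir(sc, 1), "TIs")
})
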