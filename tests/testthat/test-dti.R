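test_that("FA matches the arithmetic oracle", {
  # direct evaluation: sqrt(3/2) * ||dev|| / ||lambda||
  lam <- c(1.7e-3, 0.2e-3, 0.2e-3)
  oracle <- sqrt(1.5) * sqrt(sum((lam - mean(lam))^2)) / sqrt(sum(lam^2))
  expect_equal(fa(lam), oracle, tolerance = 1e-12)
  expect_equal(fa(lam), 0.8704, tolerance = 1e-4)
  expect_equal(fa(c(1, 1, 1)), 0)
  expect_equal(fa(c(1, 0, 0)), 1)
  expect_true(is.na(fa(c(0, 0, 0))))
  expect_error(fa(c(1, -0.1, 0)), ">= 0")
  # matrix input
  expect_equal(fa(rbind(c(1, 1, 1), lam)), c(0, oracle), tolerance = 1e-12)
})

test_that("noise-free single-tensor voxels are recovered exactly", {
  for (ax in list(c(0, 0, 1), c(1, 1, 0) / sqrt(2))) {
    D <- axisym_tensor(1.7e-3, 0.2e-3, ax)
    dwi <- synth_tensor_dwi(D)
    tf <- fit_tensor_wls(dwi)
    ev <- tf$evals[1, 1, 1, ]
    expect_equal(ev, c(1.7e-3, 0.2e-3, 0.2e-3), tolerance = 1e-8)
    expect_equal(tf$s0[1, 1, 1], 1000, tolerance = 1e-6)
    v1 <- tf$v1[1, 1, 1, ]
    expect_lt(fibre_to_field_angle(v1, ax), 0.5)
    expect_equal(tf$fa[1, 1, 1], fa(c(1.7e-3, 0.2e-3, 0.2e-3)),
                 tolerance = 1e-7)
  }
})

test_that("isotropic voxel gives FA 0 and correct MD", {
  dwi <- synth_tensor_dwi(diag(rep(0.7e-3, 3)))
  tf <- fit_tensor_wls(dwi)
  expect_equal(tf$fa[1, 1, 1], 0, tolerance = 1e-7)
  expect_equal(tf$md[1, 1, 1], 0.7e-3, tolerance = 1e-10)
  expect_true(tf$degenerate[1, 1, 1])
})

test_that("shell policy selects b0 + lowest shell", {
  D <- axisym_tensor(1.7e-3, 0.3e-3)
  dwi <- synth_tensor_dwi(D, bvals = c(0, 0, rep(1500, 20), rep(3000, 20)))
  tf <- fit_tensor_wls(dwi, shell_policy = "b0+low")
  expect_true(all(dwi$bvals[tf$volumes_used] %in% c(0, 1500)))
  tf_all <- fit_tensor_wls(dwi, shell_policy = "all")
  expect_equal(length(tf_all$volumes_used), 42L)
  # noise-free mono-exponential data: both agree with truth
  expect_equal(tf$evals[1, 1, 1, ], tf_all$evals[1, 1, 1, ], tolerance = 1e-8)
})

test_that("FA decreases monotonically with orientation dispersion", {
  fas <- vapply(c(Inf, 12.7, 4.2, 1.4), function(k) {
    tau1 <- if (is.infinite(k)) 1 else watson_tau1(k)
    lpar <- 1.7e-3; lperp <- 0.3e-3
    Dbar <- diag(c(rep(lperp + (lpar - lperp) * (1 - tau1) / 2, 2),
                   lperp + (lpar - lperp) * tau1))
    dwi <- synth_tensor_dwi(Dbar)
    fit_tensor_wls(dwi)$fa[1, 1, 1]
  }, numeric(1))
  expect_true(all(diff(fas) < 0))
})

test_that("degenerate inputs are flagged, not fitted", {
  D <- axisym_tensor(1.7e-3, 0.3e-3)
  dwi <- synth_tensor_dwi(D, grid = c(2, 2, 1))
  dwi$data[1, 1, 1, ] <- 0                      # all-zero voxel
  dwi$data[2, 1, 1, 3] <- -5                    # one negative sample
  dwi2 <- dwi_dataset(dwi$data, dwi$bvals, dwi$bvecs,
                      mask = array(TRUE, c(2, 2, 1)))
  tf <- fit_tensor_wls(dwi2)
  expect_false(tf$mask[1, 1, 1])                # masked out
  expect_true(is.na(tf$fa[1, 1, 1]))
  expect_true(tf$nonpos[2, 1, 1])               # flagged, still fitted
  expect_false(is.na(tf$fa[2, 1, 1]))
  expect_error(fit_tensor_wls(synth_tensor_dwi(D, bvals = c(0, rep(1500, 4)))),
               "at least 7")
})
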