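centers <- seq(2.25, 87.75, by = 4.5)

test_that("the two-anchor baseline annihilates affine profiles exactly", {
  for (ab in list(c(800, 0), c(800, 1.3), c(900, -2))) {
    th <- rep(centers, each = 3)
    vals <- ab[1] + ab[2] * th
    pr <- profile_1d(vals, th)
    for (peak in c(40, 54, 70)) {
      ds <- baseline_and_deltas(pr, peak)
      expect_equal(ds$delta_peak, 0, tolerance = 1e-10)
    }
  }
})

test_that("flat profiles give zero parallel-minus-perpendicular contrast", {
  pr <- profile_1d(rep(850, 20), centers)
  ds <- baseline_and_deltas(pr, 54)
  expect_identical(ds$delta_par_perp, 0)
  expect_identical(ds$delta_peak, 0)
})

test_that("delta(0-90) is antisymmetric under theta -> 90 - theta", {
  set.seed(9)
  vals <- 800 + rnorm(20, 0, 30)
  pr <- profile_1d(vals, centers)
  pr_flip <- profile_1d(vals, 90 - centers)
  d1 <- baseline_and_deltas(pr, 54)$delta_par_perp
  d2 <- baseline_and_deltas(pr_flip, 54)$delta_par_perp
  expect_equal(d2, -d1, tolerance = 1e-12)
})

test_that("percent_of_mean is exact arithmetic", {
  th <- rep(centers, 2)
  vals <- 800 + 50 * exp(-(th - 54)^2 / 288)
  pr <- profile_1d(vals, th)
  ds <- baseline_and_deltas(pr, 54, mean_t1 = 820)
  expect_equal(ds$percent_of_mean, 100 * ds$delta_peak / 820,
               tolerance = 1e-12)
})

test_that("selection rules validate and report medians", {
  expect_error(selection_rule("FA", 0.9, 0.7), "lower < upper")
  expect_error(selection_rule("XX", 0, 1))
  r <- selection_rule("fa", 0.45, 0.9)
  expect_equal(r$index_name, "FA")
  idx <- c(0.2, 0.5, 0.6, 0.8, NA)
  s <- select_voxels(idx, r)
  expect_equal(s$n, 3L)
  expect_equal(s$median_index, 0.6)
  expect_error(select_voxels(idx, selection_rule("FA", 0.95, 0.99)),
               "empty selection.*0.95")
  expect_error(select_voxels(idx, r, mask = c(TRUE, FALSE)), "mask length")
})

test_that("profiles record empty bins as missing, never zero", {
  th <- c(2, 3, 50)         # bins 1 and 12 occupied only
  pr <- profile_1d(c(800, 810, 900), th)
  expect_equal(pr$per_subject[1, 1], 805)
  expect_true(is.na(pr$per_subject[1, 2]))
  expect_equal(sum(!is.na(pr$per_subject)), 2L)
  expect_equal(pr$n_vox[1, 2], 0L)
})

test_that("cohort averaging is per-subject first", {
  th <- rep(c(10, 50), each = 4)
  vals <- c(800, 800, 900, 900, 820, 820, 940, 940)
  subj <- c(1, 1, 2, 2, 1, 1, 2, 2)
  pr <- profile_1d(vals, th, subj)
  b <- t1aniso:::theta_bin_index(10)
  expect_equal(pr$per_subject[1, b], 800)
  expect_equal(pr$per_subject[2, b], 900)
  expect_equal(pr$mean[b], 850)                       # mean of subject means
  expect_equal(pr$sd[b], sd(c(800, 900)))
})

test_that("binning follows the right-open 4.5-degree convention", {
  expect_equal(t1aniso:::theta_bin_index(0), 1L)
  expect_equal(t1aniso:::theta_bin_index(4.5), 2L)
  expect_equal(t1aniso:::theta_bin_index(53.999), 12L)
  expect_equal(t1aniso:::theta_bin_index(54), 13L)    # 54 opens bin 13
  expect_equal(t1aniso:::theta_bin_index(90), 20L)    # last bin closed
  expect_true(is.na(t1aniso:::theta_bin_index(90.5)))
})

test_that("missing anchor bins raise an error", {
  th <- seq(30, 60, by = 4.5)
  pr <- profile_1d(rep(800, length(th)), th)
  expect_error(baseline_and_deltas(pr, 54), "anchor")
})

test_that("2D surfaces: separable laws and constant maps", {
  set.seed(10)
  n <- 4000
  th <- runif(n, 0, 90)
  idx <- runif(n, 0, 1)
  vals <- 800 + 60 * exp(-(th - 54)^2 / 288) * (idx > 0.5)
  s <- profile_2d(vals, th, idx, n_index_bins = 2, index_range = c(0, 1))
  # high-index row reproduces the 1D angular law, low-index row is flat
  hi <- s$surface[2, ]
  expect_gt(max(hi) - hi[1], 40)
  lo <- s$surface[1, ]
  expect_lt(max(lo) - min(lo), 1e-9)
  sc <- profile_2d(rep(7, n), th, idx)
  expect_true(all(abs(sc$surface - 7) < 1e-12, na.rm = TRUE))
})

test_that("S0 normalization by a reference selection", {
  s0 <- c(900, 1000, 1100, 1200)
  idx <- c(0.18, 0.22, 0.5, 0.7)
  r <- selection_rule("FA", 0.15, 0.25)
  out <- normalize_s0(s0, idx, r)
  expect_equal(out, s0 / 950)
  # whole-map reference: mean of normalized map is 1
  out2 <- normalize_s0(s0, idx, selection_rule("FA", 0, 1))
  expect_equal(mean(out2), 1)
  expect_equal(normalize_s0(rep(5, 4), idx, r), rep(1, 4))
  expect_error(normalize_s0(s0, idx, selection_rule("FA", 0.9, 0.95)),
               "empty selection")
})

test_that("an injected S0 angular slope survives normalization", {
  sc <- tiny_3T(n_subjects = 1, s0_slope = 0.02, snr_ir = Inf)
  truth <- export_ground_truth(sc, 1)
  wm <- truth$label == 1
  r <- selection_rule("ODI", 0.1, 0.3)   # reference: the mid-dispersion class
  ns0 <- normalize_s0(as.vector(truth$s0_true)[as.vector(wm)],
                      rep(0.2, sum(wm)), selection_rule("ODI", 0.1, 0.3))
  pr <- profile_1d(ns0, as.vector(truth$theta)[as.vector(wm)], quantity = "S0")
  ratio <- pr$mean[20] / pr$mean[1]
  expect_equal(ratio, 1 + 0.02 * (87.75 - 2.25) / 90, tolerance = 1e-3)
})

test_that("CC ROI statistics: contrast detection and degenerate inputs", {
  sc <- scenario_cc(3, n_subjects = 6)
  rois <- attr(sc, "rois")
  maps <- lapply(1:6, function(s) {
    r <- run_subject(sc, s, keep_maps = TRUE)
    attr(r, "maps")$relax$t1
  })
  st <- cc_roi_stats(maps, rois, alpha = 0.005)
  expect_equal(st$stats$mean[st$stats$roi == "somato_motor"] -
                 st$stats$mean[st$stats$roi == "genu"], 150, tolerance = 15)
  tt <- st$tests
  expect_true(tt$significant[tt$roi_a == "genu" & tt$roi_b == "somato_motor"])
  # identical injected T1 (same box twice): non-significant
  dup <- list(a = rois$genu, b = rois$genu)
  stf <- cc_roi_stats(maps, dup, alpha = 0.005)
  expect_equal(stf$tests$p, 1)
  expect_false(stf$tests$significant)
  one_vox <- list(min = c(3L, 0L, 0L), max = c(4L, 1L, 1L))
  expect_error(cc_roi_stats(maps[[1]], list(a = one_vox)), "fewer than 2")
  outside <- list(min = c(0L, 0L, 0L), max = c(99L, 2L, 2L))
  expect_error(cc_roi_stats(maps[[1]], list(a = outside)), "outside")
})

test_that("mask SNR: known sigma, worst-case axis, noise-free sentinel", {
  sc <- scenario_cc(3, n_subjects = 1, snr_b0 = 40)
  dwi <- simulate_dwi(sc, 1)
  truth <- export_ground_truth(sc, 1)
  cc_mask <- truth$label == 1
  snr <- mask_snr(dwi, cc_mask, background = !truth$mask_head)
  sigma_true <- sc$s0_ref / sc$snr_b0
  expect_equal(attr(snr, "sigma"), sigma_true, tolerance = 0.05)
  b0row <- snr[snr$axis == "b0", ]
  expect_equal(b0row$snr, 1000 / sigma_true, tolerance = 0.05)
  # x-oriented bundle: strongest attenuation, hence lowest SNR, along x
  for (b in unique(snr$b[snr$b > 0])) {
    sh <- snr[snr$b == b, ]
    expect_lte(sh$snr[sh$axis == "x"], sh$snr[sh$axis == "y"])
    expect_lte(sh$snr[sh$axis == "x"], sh$snr[sh$axis == "z"])
  }
  # noise-free data: infinite SNR sentinel
  scnf <- scenario_cc(3, n_subjects = 1, snr_b0 = Inf)
  dwinf <- simulate_dwi(scnf, 1)
  snrnf <- mask_snr(dwinf, cc_mask, background = !truth$mask_head)
  expect_true(all(is.infinite(snrnf$snr)))
  expect_error(mask_snr(dwi, array(FALSE, dim(cc_mask))), "mask is empty")
})

test_that("group table: structure, suppressed tests, omitted rows", {
  sc <- tiny_3T(n_subjects = 2)
  tbl <- run_cohort(sc)
  rules <- preset_rules()[c("FA", "ODI")]
  # identical cohorts at both fields: all tests non-significant
  gt <- group_table(list("3T" = tbl, "7T" = tbl), rules,
                    c("3T" = 54, "7T" = 54), alpha = 0.01)
  expect_true(all(!gt$sig_delta_peak, na.rm = TRUE))
  expect_true(all(gt$p_delta_peak > 0.9, na.rm = TRUE))
  expect_setequal(gt$index, c("FA", "ODI"))
  # single-subject cohort: descriptive only
  tbl1 <- tbl[tbl$subject == 1, ]
  gt1 <- group_table(list("3T" = tbl1, "7T" = tbl1), rules["FA"],
                     c("3T" = 54, "7T" = 54))
  expect_true(all(is.na(gt1$sig_delta_peak)))
  # empty selection: row omitted with a warning
  rules_bad <- list(F2 = selection_rule("F2", 0.9, 0.95))
  expect_warning(
    expect_error(group_table(list("3T" = tbl), rules_bad, c("3T" = 54)),
                 "no non-empty rows"),
    "omitted")
})
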