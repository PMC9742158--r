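TIs3 <- c(200, 300, 600, 900, 1200, 1500)
TIs7 <- c(300, 600, 1000, 1500, 2000, 3000)

test_that("noise-free IR signals are recovered to 0.1 ms", {
  for (tt in list(c(830, 1000, 1), c(600, 500, 1), c(1400, 2000, 0.85))) {
    y <- abs(tt[2] * (1 - 2 * tt[3] * exp(-TIs3 / tt[1])))
    f <- fit_ir_voxel(y, TIs3)
    expect_true(f$converged)
    expect_equal(f$t1, tt[1], tolerance = 0.1 / tt[1])
    expect_equal(f$s0, tt[2], tolerance = 1e-4)
    expect_equal(f$eta, tt[3], tolerance = 1e-3)
  }
})

test_that("null-point signal is zero and handled by the magnitude model", {
  t1 <- 830
  TIs <- c(200, 400, t1 * log(2), 1200, 1500)
  y <- abs(1000 * (1 - 2 * exp(-TIs / t1)))
  expect_equal(y[3], 0, tolerance = 1e-9)
  f <- fit_ir_voxel(y, TIs, t1_range = c(200, 3500))
  expect_equal(f$t1, t1, tolerance = 1e-3)
})

test_that("constant signal is flagged as non-converged, not fitted", {
  f <- fit_ir_voxel(rep(500, 6), TIs3)
  expect_false(f$converged)
  expect_true(is.na(f$t1))
})

test_that("input validation", {
  expect_error(fit_ir_voxel(c(1, 2, 3), c(100, 200, 300)), "at least 4")
  expect_error(fit_ir_voxel(rep(1, 6), c(-1, TIs3[-1])), "TIs must be > 0")
  expect_error(fit_ir_voxel(c(-1, rep(1, 5)), TIs3), ">= 0")
  expect_error(fit_ir_voxel(rep(1, 5), TIs3), "equal length")
})

test_that("scale equivariance: S0 scales, T1 and eta do not", {
  y <- abs(1000 * (1 - 2 * 0.95 * exp(-TIs7 / 900)))
  y <- y + abs(sin(seq_along(y)))            # deterministic perturbation
  f1 <- fit_ir_voxel(y, TIs7)
  f2 <- fit_ir_voxel(1000 * y, TIs7)
  expect_equal(f2$t1, f1$t1, tolerance = 1e-8)
  expect_equal(f2$eta, f1$eta, tolerance = 1e-8)
  expect_equal(f2$s0, 1000 * f1$s0, tolerance = 1e-8)
})

test_that("TI-unit sanity: seconds in, seconds out", {
  y <- abs(1000 * (1 - 2 * exp(-TIs3 / 830)))
  f_ms <- fit_ir_voxel(y, TIs3, t1_range = c(200, 3500))
  f_s <- fit_ir_voxel(y, TIs3 / 1000, t1_range = c(0.2, 3.5))
  expect_equal(f_s$t1, f_ms$t1 / 1000, tolerance = 1e-6)
})

test_that("Rician noise at SNR 50 leaves T1 bias below 10 ms (500 replicates)", {
  set.seed(42)
  t1true <- 900; sig <- 20; nrep <- 500
  s <- abs(1000 * (1 - 2 * exp(-outer(rep(1, nrep), TIs7) / t1true)))
  Y <- sqrt((s + matrix(rnorm(nrep * 6, 0, sig), nrep))^2 +
              matrix(rnorm(nrep * 6, 0, sig), nrep)^2)
  f <- t1aniso:::ir_fit_engine(Y, TIs7)
  expect_lt(abs(mean(f$t1) - t1true), 10)
})

test_that("volume fit recovers the truth map voxel-wise without noise", {
  sc <- tiny_3T(n_subjects = 1, snr_b0 = Inf, snr_ir = Inf)
  ir <- simulate_ir(sc, 1)
  rm_ <- fit_t1_volume(ir, mask = !is.na(ir$t1_true),
                       eta_range = sc$fit_eta_range)
  err <- abs(rm_$t1 - ir$t1_true)
  expect_lt(max(err, na.rm = TRUE), 0.1)
  qc <- attr(rm_, "qc")
  expect_equal(qc$frac_converged, 1)
})

test_that("volume fit QC: all-background volume converges nowhere", {
  arr <- array(0, c(4, 4, 2, 6))
  rm_ <- fit_t1_volume(arr, TIs = TIs3)
  expect_equal(attr(rm_, "qc")$n_fitted, 0L)
  expect_true(all(is.na(rm_$t1)))
  expect_false(any(rm_$converged))
})

test_that("volume fit rejects a TI count mismatch", {
  arr <- array(1, c(2, 2, 2, 5))
  expect_error(fit_t1_volume(arr, TIs = TIs3), "does not match")
})

test_that("noisy volume T1 RMSE agrees with the brute-force oracle", {
  # independent oracle: dense grid + quadratic refinement, eta pinned
  brute_fit <- function(Y, TIs) {
    t1g <- exp(seq(log(300), log(2500), length.out = 300))
    B <- vapply(t1g, function(t1) abs(1 - 2 * exp(-TIs / t1)), numeric(length(TIs)))
    sc <- (Y %*% B)^2 / rep(colSums(B^2), each = nrow(Y))
    t1g[max.col(sc)]
  }
  sc <- tiny_3T(n_subjects = 1, snr_b0 = Inf, snr_ir = 40)
  ir <- simulate_ir(sc, 1)
  mask <- !is.na(ir$t1_true) & ir$t1_true < 1000     # white matter range
  rm_ <- fit_t1_volume(ir, mask = mask, eta_range = c(1, 1))
  rel_rmse <- sqrt(mean(((rm_$t1 - ir$t1_true) / ir$t1_true)[mask]^2))
  Y <- matrix(ir$data, prod(sc$grid_shape), 6)[as.vector(mask), ]
  bt1 <- brute_fit(Y, sc$TIs)
  oracle_rmse <- sqrt(mean(((bt1 - ir$t1_true[mask]) / ir$t1_true[mask])^2))
  # engine matches the oracle and stays within the oracle-derived 2.5% bound
  expect_lt(abs(rel_rmse - oracle_rmse) / oracle_rmse, 0.25)
  expect_lt(rel_rmse, 0.025)
})
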