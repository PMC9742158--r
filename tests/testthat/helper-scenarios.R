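# Reduced-size scenarios for fast unit tests. The statistical structure
# (classes, laws, calibration) is identical to the full presets; only grid,
# directions and cohort size are scaled down.
tiny_3T <- function(...) {
  args <- utils::modifyList(list(n_subjects = 2, voxels_per_bundle = 15,
                                 grid_shape = c(18, 18, 10),
                                 n_dirs_per_shell = 24, seed = 7),
                            list(...))
  do.call(scenario_3T, args)
}

tiny_7T <- function(...) {
  args <- utils::modifyList(list(n_subjects = 2, voxels_per_bundle = 15,
                                 grid_shape = c(18, 18, 10),
                                 n_dirs_per_shell = 24, seed = 7),
                            list(...))
  do.call(scenario_7T, args)
}

# Synthetic single-tensor diffusion dataset with known ground truth,
# independent of the phantom generator (for tensor-fit oracles).
synth_tensor_dwi <- function(D, s0 = 1000, bvals = c(0, 0, rep(1500, 30)),
                             seed = 5, sigma = 0, grid = c(3, 3, 1)) {
  set.seed(seed)
  nvol <- length(bvals)
  g <- matrix(rnorm(3 * nvol), 3)
  g <- sweep(g, 2, sqrt(colSums(g^2)), "/")
  g[, bvals == 0] <- 0
  s <- vapply(seq_len(nvol), function(j)
    s0 * exp(-bvals[j] * drop(t(g[, j]) %*% D %*% g[, j])), numeric(1))
  nvox <- prod(grid)
  S <- matrix(rep(s, each = nvox), nvox, nvol)
  if (sigma > 0)
    S <- sqrt((S + rnorm(length(S), 0, sigma))^2 + rnorm(length(S), 0, sigma)^2)
  dwi_dataset(array(S, c(grid, nvol)), bvals, g,
              mask = array(TRUE, grid))
}

axisym_tensor <- function(lpar, lperp, axis = c(0, 0, 1)) {
  R <- t1aniso:::rotation_z_to(axis / sqrt(sum(axis^2)))
  R %*% diag(c(lperp, lperp, lpar)) %*% t(R)
}
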