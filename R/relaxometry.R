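# Inversion-recovery magnitude model: y(TI) = | S0 (1 - 2 eta exp(-TI/T1)) |.
ir_model <- function(TIs, t1, s0, eta) abs(s0 * (1 - 2 * eta * exp(-TIs / t1)))

# Core fitting engine, vectorized over voxels (rows of Y).
# Initialization: exhaustive search over a log-spaced T1 grid crossed with an
# eta grid; S0 has a closed form per grid point (linear in |model shape|).
# Two zoom stages shrink the grid around each voxel's best point, then a
# damped Gauss-Newton polish refines (S0, T1, eta) jointly with eta kept in
# bounds. The magnitude is taken inside the residual so the null-point sign
# flip needs no polarity restoration.
ir_fit_engine <- function(Y, TIs, t1_range = c(200, 3500), n_grid = 40,
                          eta_range = c(0.5, 1), n_eta = 6,
                          max_iter = 15) {
  nv <- nrow(Y); nt <- length(TIs)
  if (nt < 4L) stop("need at least 4 inversion times", call. = FALSE)
  if (any(TIs <= 0)) stop("all TIs must be > 0", call. = FALSE)
  if (any(Y < 0)) stop("magnitude signals must be >= 0", call. = FALSE)

  sumY2 <- rowSums(Y^2)
  rngY <- apply(Y, 1, function(y) diff(range(y)))
  degen <- !is.finite(sumY2) | sumY2 <= 0 | rngY <= 1e-12 * sqrt(sumY2 / nt)
  fit_eta <- diff(eta_range) > 1e-12
  if (!fit_eta) n_eta <- 1L

  # --- coarse grid: shared shapes across voxels
  t1g <- exp(seq(log(t1_range[1]), log(t1_range[2]), length.out = n_grid))
  etag <- seq(eta_range[1], eta_range[2], length.out = n_eta)
  combos <- expand.grid(t1 = t1g, eta = etag)
  Bm <- vapply(seq_len(nrow(combos)),
               function(j) abs(1 - 2 * combos$eta[j] * exp(-TIs / combos$t1[j])),
               numeric(nt))                       # nt x ncombo
  denom <- colSums(Bm^2)
  score <- (Y %*% Bm)^2 / rep(denom, each = nv)   # larger = lower rss
  best <- max.col(score, ties.method = "first")
  t1 <- combos$t1[best]; eta <- combos$eta[best]

  # --- zoom stages: per-voxel local grids (loop over relative offsets)
  ratio <- log(t1g[2] / t1g[1])
  deta <- if (n_eta > 1) etag[2] - etag[1] else 0
  for (stage in 1:2) {
    rr <- seq(-ratio, ratio, length.out = 7)
    ee <- seq(-deta, deta, length.out = 5)
    bscore <- rep(-Inf, nv); bt1 <- t1; bet <- eta
    for (dr in rr) for (de in ee) {
      t1c <- pmin(pmax(t1 * exp(dr), t1_range[1] / 4), t1_range[2] * 4)
      etc <- pmin(pmax(eta + de, eta_range[1]), eta_range[2])
      Mc <- abs(1 - 2 * outer(etc, rep(1, nt)) *
                  exp(-outer(1 / t1c, TIs)))
      dn <- rowSums(Mc^2)
      sc <- rowSums(Y * Mc)^2 / dn
      upd <- sc > bscore
      bscore[upd] <- sc[upd]; bt1[upd] <- t1c[upd]; bet[upd] <- etc[upd]
    }
    t1 <- bt1; eta <- bet
    ratio <- ratio / 3; deta <- deta / 2
  }
  Mm <- abs(1 - 2 * eta * exp(-outer(1 / t1, TIs)))
  s0 <- rowSums(Y * Mm) / rowSums(Mm^2)

  # --- Gauss-Newton polish
  relstep <- rep(Inf, nv)
  for (it in seq_len(max_iter)) {
    E <- exp(-outer(1 / t1, TIs))
    m <- 1 - 2 * eta * E
    a <- abs(m); sg <- sign(m)
    r <- Y - s0 * a
    J1 <- a
    J2 <- s0 * sg * (-2 * eta) * E * outer(1 / t1^2, TIs)
    if (fit_eta) {
      J3 <- s0 * sg * (-2) * E
      A11 <- rowSums(J1 * J1); A12 <- rowSums(J1 * J2); A13 <- rowSums(J1 * J3)
      A22 <- rowSums(J2 * J2); A23 <- rowSums(J2 * J3); A33 <- rowSums(J3 * J3)
      # relative (per-diagonal) damping keeps the solve scale-equivariant
      A11 <- A11 * (1 + 1e-10); A22 <- A22 * (1 + 1e-10); A33 <- A33 * (1 + 1e-10)
      b1 <- rowSums(J1 * r); b2 <- rowSums(J2 * r); b3 <- rowSums(J3 * r)
      det <- A11 * (A22 * A33 - A23^2) - A12 * (A12 * A33 - A23 * A13) +
        A13 * (A12 * A23 - A22 * A13)
      det[abs(det) < 1e-300] <- NA
      d1 <- (b1 * (A22 * A33 - A23^2) - A12 * (b2 * A33 - A23 * b3) +
               A13 * (b2 * A23 - A22 * b3)) / det
      d2 <- (A11 * (b2 * A33 - b3 * A23) - b1 * (A12 * A33 - A23 * A13) +
               A13 * (A12 * b3 - b2 * A13)) / det
      d3 <- (A11 * (A22 * b3 - A23 * b2) - A12 * (A12 * b3 - b2 * A13) +
               b1 * (A12 * A23 - A22 * A13)) / det
    } else {
      A11 <- rowSums(J1 * J1); A12 <- rowSums(J1 * J2); A22 <- rowSums(J2 * J2)
      A11 <- A11 * (1 + 1e-10); A22 <- A22 * (1 + 1e-10)
      b1 <- rowSums(J1 * r); b2 <- rowSums(J2 * r)
      det <- A11 * A22 - A12^2
      det[abs(det) < 1e-300] <- NA
      d1 <- (b1 * A22 - A12 * b2) / det
      d2 <- (A11 * b2 - A12 * b1) / det
      d3 <- rep(0, nv)
    }
    bad <- !is.finite(d1) | !is.finite(d2) | !is.finite(d3)
    d1[bad] <- 0; d2[bad] <- 0; d3[bad] <- 0
    d2 <- pmin(pmax(d2, -0.3 * t1), 0.3 * t1)   # damp T1 steps
    s0n <- pmax(s0 + d1, 1e-12)
    t1n <- pmin(pmax(t1 + d2, t1_range[1] / 4), t1_range[2] * 4)
    etan <- pmin(pmax(eta + d3, eta_range[1]), eta_range[2])
    relstep <- abs(t1n - t1) / t1 + abs(s0n - s0) / pmax(s0, 1e-12) +
      abs(etan - eta)
    s0 <- s0n; t1 <- t1n; eta <- etan
    if (all(relstep[!degen] < 1e-12)) break
  }
  Mf <- abs(1 - 2 * eta * exp(-outer(1 / t1, TIs)))
  rss <- rowSums((Y - s0 * Mf)^2)
  conv <- !degen & is.finite(rss) & s0 > 0 &
    (relstep < 1e-6 | rss <= 1e-16 * pmax(sumY2, 1e-300))
  t1[degen] <- NA_real_; s0[degen] <- NA_real_; eta[degen] <- NA_real_
  list(t1 = t1, s0 = s0, eta = eta, rss = rss, converged = conv)
}

#' Fit the inversion-recovery model in one voxel
#'
#' Nonlinear least squares of the magnitude IR model
#' \eqn{y(TI) = |S_0 (1 - 2\eta e^{-TI/T_1})|} to one voxel's multi-TI
#' signals. Initialization by exhaustive grid search (log-spaced T1 crossed
#' with inversion efficiency), then Gauss-Newton refinement. A constant
#' signal (no TI dependence) is flagged as non-converged rather than fitted.
#'
#' @param y non-negative magnitude signals, one per TI.
#' @param TIs inversion times in ms (same length as `y`, at least 4).
#' @param t1_range search range for T1 (same units as `TIs`).
#' @param eta_range bounds for the inversion efficiency (default `[0.5, 1]`).
#' @param n_grid number of T1 grid points for initialization.
#' @return list with `t1`, `s0`, `eta`, `rss`, `converged`.
#' @export
#' @examples
#' TIs <- c(200, 300, 600, 900, 1200, 1500)
#' y <- abs(1000 * (1 - 2 * exp(-TIs / 830)))
#' fit_ir_voxel(y, TIs)$t1  # ~830
fit_ir_voxel <- function(y, TIs, t1_range = c(200, 3500),
                         eta_range = c(0.5, 1), n_grid = 40) {
  if (length(y) != length(TIs))
    stop("y and TIs must have equal length", call. = FALSE)
  f <- ir_fit_engine(matrix(y, 1), TIs, t1_range = t1_range,
                     eta_range = eta_range, n_grid = n_grid)
  lapply(f, `[[`, 1L)
}

#' Voxel-wise T1 and S0 maps from a multi-TI inversion-recovery series
#'
#' Applies the magnitude IR fit to every voxel inside the mask and returns
#' T1 (ms), S0, inversion efficiency, residual sum of squares and a
#' convergence flag as maps, plus a QC summary (fraction converged, median
#' residual) as an attribute.
#'
#' @param ir_series 4D array (x, y, z, TI) of magnitude signals, or an object
#'   with elements `data` and `TIs` as produced by [simulate_ir()].
#' @param TIs inversion times in ms (one per volume); taken from `ir_series`
#'   if it carries them.
#' @param mask logical 3D array; default: voxels with any positive signal.
#' @inheritParams fit_ir_voxel
#' @return a `relax_maps` list of 3D arrays `t1`, `s0`, `eta`, `rss`,
#'   `converged`, `mask`, with attribute `qc`.
#' @export
fit_t1_volume <- function(ir_series, TIs = NULL, mask = NULL,
                          t1_range = c(200, 3500), eta_range = c(0.5, 1),
                          n_grid = 40) {
  if (is.list(ir_series) && !is.null(ir_series$data)) {
    if (is.null(TIs)) TIs <- ir_series$TIs
    ir_series <- ir_series$data
  }
  if (is.null(TIs)) stop("TIs must be supplied", call. = FALSE)
  dm <- dim(ir_series)
  if (length(dm) != 4L) stop("ir_series must be a 4D array", call. = FALSE)
  if (dm[4] != length(TIs))
    stop("number of volumes (", dm[4], ") does not match number of TIs (",
         length(TIs), ")", call. = FALSE)
  grid <- dm[1:3]
  Y <- matrix(ir_series, prod(grid), dm[4])
  if (is.null(mask)) mask <- array(rowSums(Y) > 0, grid)
  idx <- which(as.vector(mask))
  out <- list(t1 = rep(NA_real_, prod(grid)), s0 = rep(NA_real_, prod(grid)),
              eta = rep(NA_real_, prod(grid)), rss = rep(NA_real_, prod(grid)),
              converged = rep(FALSE, prod(grid)))
  if (length(idx) > 0L) {
    f <- ir_fit_engine(Y[idx, , drop = FALSE], TIs, t1_range = t1_range,
                       eta_range = eta_range, n_grid = n_grid)
    out$t1[idx] <- f$t1; out$s0[idx] <- f$s0; out$eta[idx] <- f$eta
    out$rss[idx] <- f$rss; out$converged[idx] <- f$converged
  }
  out <- lapply(out, array, dim = grid)
  out$mask <- array(as.vector(mask), grid)
  qc <- list(
    n_fitted = length(idx),
    frac_converged = if (length(idx)) mean(out$converged[idx]) else 0,
    median_rss = if (length(idx)) stats::median(out$rss[idx], na.rm = TRUE) else NA_real_)
  structure(out, qc = qc, class = "relax_maps")
}
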