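#' Fractional anisotropy from tensor eigenvalues
#'
#' `FA = sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||`, clipped to
#' `[0, 1]`. Eigenvalues must be non-negative (clamp first if a noisy fit
#' produced negative values).
#'
#' @param evals numeric length-3 vector or `n x 3` matrix of eigenvalues.
#' @return FA value(s); `NA` where all three eigenvalues are zero.
#' @export
#' @examples
#' fa(c(1.7e-3, 0.2e-3, 0.2e-3))  # ~0.870
fa <- function(evals) {
  if (is.null(dim(evals))) evals <- matrix(evals, ncol = 3)
  if (ncol(evals) != 3L) stop("evals must have 3 columns", call. = FALSE)
  if (any(evals < 0, na.rm = TRUE)) stop("eigenvalues must be >= 0", call. = FALSE)
  m <- rowMeans(evals)
  num <- sqrt(rowSums((evals - m)^2))
  den <- sqrt(rowSums(evals^2))
  out <- sqrt(1.5) * num / den
  out[den == 0] <- NA_real_
  out <- pmin(1, pmax(0, out))
  if (length(out) == 1L) out[[1L]] else out
}

#' Mean diffusivity from tensor eigenvalues
#' @param evals length-3 vector or `n x 3` matrix.
#' @return mean of the three eigenvalues.
#' @export
md <- function(evals) {
  if (is.null(dim(evals))) evals <- matrix(evals, ncol = 3)
  out <- rowMeans(evals)
  if (length(out) == 1L) out[[1L]] else out
}

# Design matrix of the log-linear tensor model:
# log S = log s0 - b g' D g, columns (1, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz).
dti_design <- function(bvals, bvecs) {
  g <- t(bvecs)
  b <- bvals
  cbind(1,
        -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
        -2 * b * g[, 1] * g[, 2],
        -2 * b * g[, 1] * g[, 3],
        -2 * b * g[, 2] * g[, 3])
}

#' Weighted-least-squares diffusion tensor fit
#'
#' Per-voxel fit of the diffusion tensor in the log-signal domain: ordinary
#' least squares first, then one weighted pass with weights equal to the
#' squared *predicted* signals (the standard WLS scheme of FSL's tensor
#' fitting tool). By default only the b=0 volumes and the lowest non-zero
#' shell are used, matching common single-shell tensor practice.
#'
#' Non-positive signals in a voxel are replaced by the smallest positive
#' signal observed in that voxel before taking logs (and the voxel flagged);
#' all-zero voxels are removed from the fit mask. Negative eigenvalues are
#' clamped to zero with a per-voxel flag. Voxels with a degenerate leading
#' eigenvalue pair are flagged orientationally unreliable.
#'
#' @param dwi a `dwi_dataset` (see [dwi_dataset()]).
#' @param shell_policy `"b0+low"` (default): b=0 plus the lowest non-zero
#'   shell; `"all"`: every volume.
#' @param b0_max b-values at or below this count as b=0 (s/mm^2).
#' @return a `tensor_field`: list of 3D/4D arrays `fa`, `md`, `s0`, `evals`
#'   (last dim 3, sorted descending), `v1`/`v2`/`v3` (last dim 3), `tensor`
#'   (last dim 6: xx,yy,zz,xy,xz,yz), logical `mask`, `degenerate`,
#'   `clamped`, `nonpos` flags.
#' @export
fit_tensor_wls <- function(dwi, shell_policy = c("b0+low", "all"), b0_max = 50) {
  stopifnot(inherits(dwi, "dwi_dataset"))
  shell_policy <- match.arg(shell_policy)
  dm <- dim(dwi$data)
  grid <- dm[1:3]
  nvol <- dm[4]
  is_b0 <- dwi$bvals <= b0_max
  use <- if (shell_policy == "all") rep(TRUE, nvol) else {
    shells <- sort(unique(dwi$bvals[!is_b0]))
    if (length(shells) == 0L) stop("no diffusion-weighted volumes", call. = FALSE)
    is_b0 | dwi$bvals == shells[1]
  }
  if (sum(use) < 7L) stop("need at least 7 usable volumes", call. = FALSE)
  X <- dti_design(dwi$bvals[use], dwi$bvecs[, use, drop = FALSE])

  Y <- matrix(dwi$data, prod(grid), nvol)[, use, drop = FALSE]
  mask <- as.vector(dwi$mask)
  allzero <- rowSums(Y > 0) == 0L
  fitmask <- mask & !allzero
  idx <- which(fitmask)
  Yf <- Y[idx, , drop = FALSE]

  nonpos <- rowSums(Yf <= 0) > 0L
  if (any(nonpos)) {
    for (r in which(nonpos)) {
      y <- Yf[r, ]
      y[y <= 0] <- min(y[y > 0])
      Yf[r, ] <- y
    }
  }
  L <- log(Yf)

  XtXi <- solve(crossprod(X))
  B <- XtXi %*% crossprod(X, t(L))          # 7 x nfit, OLS
  P <- X %*% B                               # predicted log-signals
  n <- length(idx)
  for (r in seq_len(n)) {
    w <- exp(2 * P[, r])
    Xw <- X * w
    B[, r] <- tryCatch(solve(crossprod(Xw, X), crossprod(Xw, L[r, ])),
                       error = function(e) B[, r])
  }

  evals <- matrix(NA_real_, n, 3)
  v1 <- v2 <- v3 <- matrix(NA_real_, n, 3)
  degen <- clamped <- logical(n)
  for (r in seq_len(n)) {
    d <- B[, r]
    D <- matrix(c(d[2], d[5], d[6],
                  d[5], d[3], d[7],
                  d[6], d[7], d[4]), 3, 3)
    e <- eigen(D, symmetric = TRUE)
    ev <- e$values
    if (any(ev < 0)) { clamped[r] <- TRUE; ev <- pmax(ev, 0) }
    evals[r, ] <- ev
    v1[r, ] <- e$vectors[, 1]; v2[r, ] <- e$vectors[, 2]; v3[r, ] <- e$vectors[, 3]
    sc <- max(ev[1], .Machine$double.eps)
    if ((e$values[1] - e$values[2]) / sc < 1e-6) degen[r] <- TRUE
  }

  full <- function(m) {
    out <- matrix(NA_real_, prod(grid), ncol(m)); out[idx, ] <- m
    array(out, c(grid, ncol(m)))
  }
  fullv <- function(v) { out <- rep(NA_real_, prod(grid)); out[idx] <- v; array(out, grid) }
  fulll <- function(l) { out <- rep(FALSE, prod(grid)); out[idx] <- l; array(out, grid) }

  tens <- t(B[c(2, 3, 4, 5, 6, 7), , drop = FALSE])
  structure(list(
    fa = fullv(fa(evals)), md = fullv(md(evals)), s0 = fullv(exp(B[1, ])),
    evals = full(evals), v1 = full(v1), v2 = full(v2), v3 = full(v3),
    tensor = full(tens),
    mask = array(fitmask, grid),
    degenerate = fulll(degen), clamped = fulll(clamped), nonpos = fulll(nonpos),
    shell_policy = shell_policy, volumes_used = which(use)
  ), class = "tensor_field")
}
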