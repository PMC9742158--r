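#' Fibre-to-field angle
#'
#' Angle in degrees between a fibre axis (typically the principal diffusion
#' eigenvector V1) and the main magnetic field axis B0, folded into
#' `[0, 90]` degrees: \eqn{\theta = \arccos(|v_1 \cdot b_0|)}. Invariant to the
#' sign of either vector, as axes are.
#'
#' @param v1 unit 3-vector or `n x 3` matrix of fibre axes.
#' @param b0_axis unit 3-vector of the field direction in image coordinates
#'   (default the grid z-axis).
#' @return angle(s) in degrees in `[0, 90]`; `NA` for zero/invalid vectors.
#' @export
#' @examples
#' fibre_to_field_angle(c(1, 0, 0))   # 90
#' fibre_to_field_angle(c(0, 0, -1))  # 0
fibre_to_field_angle <- function(v1, b0_axis = c(0, 0, 1)) {
  stopifnot_unit(b0_axis, "b0_axis")
  if (is.null(dim(v1))) v1 <- matrix(v1, ncol = 3)
  nrm <- sqrt(rowSums(v1^2))
  bad <- !is.finite(nrm) | nrm < 1e-12
  ct <- abs(as.vector(v1 %*% b0_axis)) / ifelse(bad, NA_real_, nrm)
  th <- acos(pmin(1, pmax(0, ct))) * 180 / pi
  th[bad] <- NA_real_
  if (length(th) == 1L) th[[1L]] else th
}

#' Fibre-to-field angle map from a tensor field
#'
#' Applies [fibre_to_field_angle()] to the per-voxel principal eigenvector of
#' a fitted tensor field. Voxels flagged as orientationally unreliable
#' (degenerate leading eigenvalues) or outside the fit mask are `NA`.
#'
#' @param tf a `tensor_field` from [fit_tensor_wls()].
#' @param b0_axis field axis in image coordinates, default `c(0, 0, 1)`.
#' @return 3D array of angles in degrees.
#' @export
angle_map <- function(tf, b0_axis = c(0, 0, 1)) {
  stopifnot(inherits(tf, "tensor_field"))
  v1 <- matrix(tf$v1, ncol = 3)
  th <- fibre_to_field_angle(v1, b0_axis)
  th[!as.vector(tf$mask)] <- NA_real_
  th[as.vector(tf$degenerate)] <- NA_real_
  array(th, dim = dim(tf$fa))
}

#' Orientation dispersion index from Watson concentration
#'
#' `ODI = (2/pi) * atan(1/kappa)`: a strictly decreasing bijection from
#' concentration `[0, Inf)` onto `(0, 1]`, with ODI 1 for the isotropic case
#' and ODI tending to 0 for perfectly coherent fibres.
#'
#' @param kappa concentration(s) `>= 0`.
#' @return ODI value(s) in `(0, 1]`.
#' @export
#' @examples
#' odi_from_kappa(1)      # 0.5
#' kappa_from_odi(0.05)   # ~12.7
odi_from_kappa <- function(kappa) {
  if (any(!is.finite(kappa) & !is.infinite(kappa)) || any(kappa < 0, na.rm = TRUE))
    stop("kappa must be >= 0", call. = FALSE)
  ifelse(is.infinite(kappa), 0, (2 / pi) * atan2(1, kappa))
}

#' @rdname odi_from_kappa
#' @param odi dispersion index value(s) in `(0, 1]`.
#' @export
kappa_from_odi <- function(odi) {
  if (any(!is.finite(odi)) || any(odi <= 0) || any(odi > 1))
    stop("ODI must lie in (0, 1]", call. = FALSE)
  1 / tan(odi * pi / 2)
}
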