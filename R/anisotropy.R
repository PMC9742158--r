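#' Voxel selection rule on a microstructural index
#'
#' A closed interval `[lower, upper]` applied to exactly one index map
#' (FA, ODI, F1, F2, F3). Used to condition angular T1/S0 profiles on
#' microstructure, e.g. `FA in [0.7, 0.9]` or `ODI in [0, 0.2]`.
#'
#' @param index_name one of `"FA"`, `"ODI"`, `"F1"`, `"F2"`, `"F3"`.
#' @param lower,upper interval bounds, `lower < upper`.
#' @return a `selection_rule` object.
#' @export
selection_rule <- function(index_name, lower, upper) {
  index_name <- match.arg(toupper(index_name), c("FA", "ODI", "F1", "F2", "F3"))
  if (!is.finite(lower) || !is.finite(upper) || lower >= upper)
    stop("selection rule requires lower < upper", call. = FALSE)
  structure(list(index_name = index_name, lower = lower, upper = upper),
            class = "selection_rule")
}

#' @export
format.selection_rule <- function(x, ...)
  sprintf("%s in [%g, %g]", x$index_name, x$lower, x$upper)

#' @export
print.selection_rule <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Select voxels by an index window
#'
#' Returns the logical selection of voxels whose index value lies inside the
#' rule's interval (within an optional mask), plus the median index over the
#' selection. Errors on an empty selection, echoing the rule.
#'
#' @param index numeric vector or array of index values (NA = invalid voxel).
#' @param rule a [selection_rule()].
#' @param mask optional logical vector/array of the same length.
#' @return list with `sel` (logical vector), `median_index`, `n`.
#' @export
select_voxels <- function(index, rule, mask = NULL) {
  stopifnot(inherits(rule, "selection_rule"))
  x <- as.vector(index)
  sel <- !is.na(x) & x >= rule$lower & x <= rule$upper
  if (!is.null(mask)) {
    m <- as.vector(mask)
    if (length(m) != length(x)) stop("mask length mismatch", call. = FALSE)
    sel <- sel & m & !is.na(m)
  }
  if (!any(sel))
    stop("empty selection for rule ", format(rule), call. = FALSE)
  list(sel = sel, median_index = stats::median(x[sel]), n = sum(sel))
}

# Fibre-to-field angle binning: right-open intervals [k*w, (k+1)*w) except
# the last bin, which is closed at theta_max so 90 degrees is included.
theta_bin_index <- function(theta, bin_width = 4.5, theta_max = 90) {
  nb <- as.integer(round(theta_max / bin_width))
  idx <- floor(theta / bin_width) + 1L
  idx[theta >= theta_max] <- nb
  idx[theta < 0 | theta > theta_max | is.na(theta)] <- NA_integer_
  idx
}

#' Angle-binned 1D profile of a quantity
#'
#' Bins a per-voxel quantity (T1 or S0) by fibre-to-field angle in fixed-width
#' bins (default 4.5 degrees over 0-90, i.e. 20 bins). Averaging is
#' per-subject first, then across subjects: the cohort curve is the mean of
#' subject bin means and the spread is the across-subject SD. Bins with no
#' voxels for a subject are recorded as missing, never as zero.
#'
#' @param values numeric vector, the profiled quantity for selected voxels.
#' @param theta fibre-to-field angles in degrees, same length.
#' @param subject subject identifier per value (default: single subject).
#' @param bin_width bin width in degrees; `theta_max/bin_width` must be a
#'   whole number.
#' @param theta_max upper end of the angle range (degrees).
#' @param quantity label, e.g. `"T1"` or `"S0"`.
#' @return an `angular_profile`: list with `bin_edges`, `centers`,
#'   `per_subject` (subject x bin matrix of means), `n_vox` (counts),
#'   `mean`, `sd` (cohort), `subjects`, `quantity`.
#' @export
profile_1d <- function(values, theta, subject = NULL, bin_width = 4.5,
                       theta_max = 90, quantity = "T1") {
  if (length(values) != length(theta))
    stop("values and theta must have equal length", call. = FALSE)
  if (is.null(subject)) subject <- rep(1L, length(values))
  ok <- !is.na(values) & !is.na(theta)
  values <- values[ok]; theta <- theta[ok]; subject <- subject[ok]
  if (!length(values)) stop("no usable voxels for profile", call. = FALSE)
  nb <- round(theta_max / bin_width)
  if (abs(nb - theta_max / bin_width) > 1e-9)
    stop("bin_width must divide theta_max", call. = FALSE)
  bin <- theta_bin_index(theta, bin_width, theta_max)
  subs <- sort(unique(subject))
  S <- length(subs); nb <- as.integer(nb)
  ps <- matrix(NA_real_, S, nb)
  nv <- matrix(0L, S, nb)
  si <- match(subject, subs)
  cell <- (si - 1L) * nb + bin
  sums <- tapply(values, cell, sum)
  cnts <- tapply(values, cell, length)
  at <- as.integer(names(sums))
  mns <- as.numeric(sums) / as.numeric(cnts)
  ps[cbind(((at - 1L) %/% nb) + 1L, ((at - 1L) %% nb) + 1L)] <- mns
  nv[cbind(((at - 1L) %/% nb) + 1L, ((at - 1L) %% nb) + 1L)] <- as.integer(cnts)
  structure(list(
    bin_edges = seq(0, theta_max, by = bin_width),
    centers = seq(bin_width / 2, theta_max - bin_width / 2, by = bin_width),
    per_subject = ps, n_vox = nv,
    mean = colMeans(ps, na.rm = TRUE),
    sd = apply(ps, 2, stats::sd, na.rm = TRUE),
    subjects = subs, quantity = quantity,
    bin_width = bin_width, theta_max = theta_max
  ), class = "angular_profile")
}

#' Two-anchor baseline and T1 contrasts of an angular profile
#'
#' The baseline is the straight line joining the mean of the bin means over
#' 0-20 degrees to the mean over 80-90 degrees (anchor abscissae are the mean
#' centres of the contributing bins, which makes the operator annihilate
#' affine profiles exactly). Reported per subject, then averaged:
#' * `delta_peak`: profile value in the bin containing `peak_angle` minus the
#'   baseline at that bin's centre;
#' * `delta_par_perp`: first-bin mean minus last-bin mean (parallel minus
#'   perpendicular);
#' * `percent_of_mean`: `100 * delta_peak / mean_t1` when per-subject mean T1
#'   over the selected voxels is supplied.
#'
#' @param profile an [profile_1d()] result.
#' @param peak_angle angle in degrees whose bin is evaluated (54 at 3 T,
#'   40 at 7 T in the presets).
#' @param mean_t1 optional per-subject mean of the quantity over the selected
#'   voxels (for `percent_of_mean`).
#' @param anchor_low,anchor_high angle ranges (degrees) whose fully-contained
#'   bins form the two baseline anchors.
#' @return a `delta_summary`: per-subject data frame plus cohort mean/SD of
#'   each contrast, baseline parameters, and the peak bin used.
#' @export
baseline_and_deltas <- function(profile, peak_angle, mean_t1 = NULL,
                                anchor_low = c(0, 20), anchor_high = c(80, 90)) {
  stopifnot(inherits(profile, "angular_profile"))
  ed <- profile$bin_edges
  nb <- length(ed) - 1L
  lo_bins <- which(ed[-length(ed)] >= anchor_low[1] & ed[-1] <= anchor_low[2])
  hi_bins <- which(ed[-length(ed)] >= anchor_high[1] & ed[-1] <= anchor_high[2])
  if (!length(lo_bins) || !length(hi_bins))
    stop("anchor ranges contain no bins", call. = FALSE)
  pk <- theta_bin_index(peak_angle, profile$bin_width, profile$theta_max)
  if (is.na(pk)) stop("peak_angle outside the profile range", call. = FALSE)
  ps <- profile$per_subject
  S <- nrow(ps)
  if (!is.null(mean_t1) && length(mean_t1) != S)
    stop("mean_t1 must have one value per subject", call. = FALSE)
  res <- data.frame(subject = profile$subjects, delta_peak = NA_real_,
                    delta_par_perp = NA_real_, percent_of_mean = NA_real_,
                    baseline_at_peak = NA_real_)
  for (s in seq_len(S)) {
    lo_oc <- lo_bins[!is.na(ps[s, lo_bins])]
    hi_oc <- hi_bins[!is.na(ps[s, hi_bins])]
    if (!length(lo_oc) || !length(hi_oc))
      stop("baseline anchor bins are empty for subject ", profile$subjects[s],
           call. = FALSE)
    x1 <- mean(profile$centers[lo_oc]); y1 <- mean(ps[s, lo_oc])
    x2 <- mean(profile$centers[hi_oc]); y2 <- mean(ps[s, hi_oc])
    slope <- (y2 - y1) / (x2 - x1)
    bl <- y1 + slope * (profile$centers[pk] - x1)
    res$baseline_at_peak[s] <- bl
    if (!is.na(ps[s, pk])) res$delta_peak[s] <- ps[s, pk] - bl
    if (!is.na(ps[s, 1L]) && !is.na(ps[s, nb]))
      res$delta_par_perp[s] <- ps[s, 1L] - ps[s, nb]
    if (!is.null(mean_t1))
      res$percent_of_mean[s] <- 100 * res$delta_peak[s] / mean_t1[s]
  }
  structure(list(
    per_subject = res,
    delta_peak = mean(res$delta_peak, na.rm = TRUE),
    delta_peak_sd = stats::sd(res$delta_peak, na.rm = TRUE),
    delta_par_perp = mean(res$delta_par_perp, na.rm = TRUE),
    delta_par_perp_sd = stats::sd(res$delta_par_perp, na.rm = TRUE),
    percent_of_mean = if (is.null(mean_t1)) NA_real_
                      else mean(res$percent_of_mean, na.rm = TRUE),
    peak_bin = pk, peak_bin_center = profile$centers[pk],
    anchor_bins = list(low = lo_bins, high = hi_bins)
  ), class = "delta_summary")
}

#' 2D angle-by-index binned surface
#'
#' Mean of a quantity over a (fibre-to-field angle bin) x (index bin) grid,
#' per-subject means averaged across subjects. Index bins are equal-width
#' over `index_range` (default the observed range), 10 bins by default.
#'
#' @inheritParams profile_1d
#' @param index per-voxel index values (FA, ODI, ...).
#' @param n_index_bins number of equal-width index bins.
#' @param index_range length-2 range for the index axis.
#' @return list with `surface` (index bin x angle bin matrix of cohort
#'   means), `counts`, `theta_centers`, `index_centers`.
#' @export
profile_2d <- function(values, theta, index, subject = NULL, bin_width = 4.5,
                       theta_max = 90, n_index_bins = 10, index_range = NULL) {
  if (length(values) != length(theta) || length(values) != length(index))
    stop("values, theta and index must have equal length", call. = FALSE)
  if (is.null(subject)) subject <- rep(1L, length(values))
  ok <- !is.na(values) & !is.na(theta) & !is.na(index)
  values <- values[ok]; theta <- theta[ok]; index <- index[ok]
  subject <- subject[ok]
  if (!length(values)) stop("no usable voxels for profile", call. = FALSE)
  if (is.null(index_range)) index_range <- range(index)
  iw <- diff(index_range) / n_index_bins
  ib <- pmin(pmax(floor((index - index_range[1]) / iw) + 1L, 1L),
             as.integer(n_index_bins))
  nb <- as.integer(round(theta_max / bin_width))
  tb <- theta_bin_index(theta, bin_width, theta_max)
  subs <- sort(unique(subject))
  acc <- array(NA_real_, c(length(subs), n_index_bins, nb))
  cnt <- array(0L, c(n_index_bins, nb))
  for (s in seq_along(subs)) {
    w <- subject == subs[s]
    mt <- tapply(values[w], list(factor(ib[w], 1:n_index_bins),
                                 factor(tb[w], 1:nb)), mean)
    acc[s, , ] <- mt
    ct <- table(factor(ib[w], 1:n_index_bins), factor(tb[w], 1:nb))
    cnt <- cnt + unclass(ct)
  }
  list(surface = apply(acc, c(2, 3), mean, na.rm = TRUE),
       counts = cnt,
       theta_centers = seq(bin_width / 2, theta_max - bin_width / 2, by = bin_width),
       index_centers = index_range[1] + (seq_len(n_index_bins) - 0.5) * iw)
}

#' Normalize S0 by a reference tissue selection
#'
#' Divides an S0 map by the mean S0 of reference voxels picked by an index
#' window (e.g. FA within 0.2 +/- 0.05, or ODI within 0.7 +/- 0.05),
#' providing the baseline normalization used for proton-density proxies.
#'
#' @param s0 numeric vector/array of S0 values.
#' @param index index values aligned with `s0`.
#' @param reference_rule a [selection_rule()] defining the reference voxels.
#' @param mask optional logical mask.
#' @return `s0` divided by the reference mean (same shape as input).
#' @export
normalize_s0 <- function(s0, index, reference_rule, mask = NULL) {
  ref <- select_voxels(index, reference_rule, mask)
  ref_mean <- mean(as.vector(s0)[ref$sel], na.rm = TRUE)
  if (!is.finite(ref_mean) || ref_mean <= 0)
    stop("reference selection has no positive S0", call. = FALSE)
  s0 / ref_mean
}

#' Region-of-interest T1 statistics with pairwise tests
#'
#' Mean and SD of T1 in rectangular ROIs (voxel coordinates, 0-based,
#' half-open boxes) for each subject, plus pairwise Welch t-tests between
#' ROIs across subjects at a Bonferroni-corrected threshold. Intended for
#' corpus-callosum segment comparisons (genu / mid-motor / somato-motor /
#' splenium).
#'
#' @param t1_maps a single 3D T1 array or a list of per-subject arrays.
#' @param rois named list; each element `list(min = c(x,y,z), max = c(x,y,z))`
#'   in 0-based, half-open voxel coordinates.
#' @param alpha Bonferroni-corrected significance threshold (default 0.005).
#' @return list with `stats` (per-ROI mean, sd, n across subjects) and
#'   `tests` (pairwise Welch t-tests, if >= 2 subjects).
#' @export
cc_roi_stats <- function(t1_maps, rois, alpha = 0.005) {
  if (!is.list(t1_maps) || !is.null(dim(t1_maps))) t1_maps <- list(t1_maps)
  if (is.array(t1_maps)) t1_maps <- list(t1_maps)
  grid <- dim(t1_maps[[1]])
  roivals <- function(map, roi) {
    lo <- roi$min + 1L; hi <- roi$max   # 0-based half-open -> 1-based closed
    if (any(lo < 1L) || any(hi > grid) || any(hi < lo))
      stop("ROI box outside the image grid", call. = FALSE)
    v <- map[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
    v <- v[!is.na(v)]
    if (length(v) < 2L)
      stop("ROI has fewer than 2 usable voxels; SD undefined", call. = FALSE)
    v
  }
  S <- length(t1_maps)
  means <- sapply(names(rois), function(rn)
    vapply(t1_maps, function(m) mean(roivals(m, rois[[rn]])), numeric(1)))
  means <- matrix(means, nrow = S, dimnames = list(NULL, names(rois)))
  stats_df <- data.frame(
    roi = names(rois),
    mean = colMeans(means),
    sd = apply(means, 2, stats::sd),
    n_subjects = S, row.names = NULL)
  tests <- NULL
  if (S >= 2L && length(rois) >= 2L) {
    prs <- utils::combn(names(rois), 2)
    tests <- data.frame(roi_a = prs[1, ], roi_b = prs[2, ],
                        p = NA_real_, significant = NA)
    for (k in seq_len(ncol(prs))) {
      tt <- stats::t.test(means[, prs[1, k]], means[, prs[2, k]])
      tests$p[k] <- tt$p.value
      tests$significant[k] <- tt$p.value < alpha
    }
  }
  list(stats = stats_df, tests = tests, alpha = alpha, subject_means = means)
}

#' Mask-based SNR of a diffusion dataset
#'
#' `SNR = mean(signal in mask) / sigma`, with the noise SD estimated from
#' background voxels via the Rician floor of a magnitude image
#' (`mean(background) = sigma * sqrt(pi/2)` for pure noise). Reported for the
#' mean b=0 image and, per shell, for the gradient directions closest to the
#' x, y and z axes (for a callosal mask the x direction carries the most
#' attenuated signal, hence the worst-case SNR).
#'
#' @param dwi a `dwi_dataset`.
#' @param mask logical 3D array of signal voxels (e.g. a CC-like ROI).
#' @param background logical 3D array of noise-only voxels; default: eight
#'   3x3x3 corner blocks of the grid.
#' @return data frame with columns `b`, `axis`, `direction`, `snr`.
#'   Noise-free data yield `Inf`.
#' @export
mask_snr <- function(dwi, mask, background = NULL) {
  stopifnot(inherits(dwi, "dwi_dataset"))
  dm <- dim(dwi$data); grid <- dm[1:3]
  if (is.null(background)) {
    background <- array(FALSE, grid)
    cs <- function(n) list(1:min(3, n), max(1, n - 2):n)
    for (i in cs(grid[1])) for (j in cs(grid[2])) for (k in cs(grid[3]))
      background[i, j, k] <- TRUE
  }
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  if (!any(background)) stop("no background voxels", call. = FALSE)
  Y <- matrix(dwi$data, prod(grid), dm[4])
  bg <- Y[as.vector(background), , drop = FALSE]
  sigma <- mean(bg) / sqrt(pi / 2)
  msel <- as.vector(mask)
  snr_of <- function(v) {
    s <- mean(Y[msel, v])
    if (sigma <= 0) Inf else s / sigma
  }
  is_b0 <- dwi$bvals <= 50
  out <- data.frame(b = 0, axis = "b0", direction = I(list(c(0, 0, 0))),
                    snr = mean(vapply(which(is_b0), snr_of, numeric(1))))
  for (b in sort(unique(dwi$bvals[!is_b0]))) {
    vols <- which(dwi$bvals == b)
    for (ax in 1:3) {
      align <- abs(dwi$bvecs[ax, vols])
      v <- vols[which.max(align)]
      out <- rbind(out, data.frame(
        b = b, axis = c("x", "y", "z")[ax],
        direction = I(list(dwi$bvecs[, v])), snr = snr_of(v)))
    }
  }
  attr(out, "sigma") <- sigma
  out
}
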