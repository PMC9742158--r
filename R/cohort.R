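index_column <- c(FA = "fa", ODI = "odi", F1 = "f1", F2 = "f2", F3 = "f3")

#' Run the full pipeline for one synthetic subject
#'
#' Simulates the diffusion and inversion-recovery acquisitions, fits the
#' diffusion tensor (WLS), derives the fibre-to-field angle map from the
#' principal eigenvector, fits voxel-wise T1, and assembles one row per
#' white-matter voxel with the fitted and ground-truth quantities.
#'
#' @param scenario a [scenario_config()].
#' @param subject subject index.
#' @param keep_maps also return the full map objects (tensor field, relax
#'   maps, truth).
#' @return data frame with columns `subject`, `t1`, `s0`, `theta`, `fa`,
#'   `odi`, `f1`, `f2`, `f3`, `t1_true`, `theta_true`, `label`; maps in
#'   attribute `maps` when requested.
#' @export
run_subject <- function(scenario, subject = 1, keep_maps = FALSE) {
  truth <- export_ground_truth(scenario, subject)
  dwi <- simulate_dwi(scenario, subject)
  tf <- fit_tensor_wls(dwi)
  theta_fit <- angle_map(tf)
  ir <- simulate_ir(scenario, subject)
  rm_ <- fit_t1_volume(ir, mask = truth$mask_head,
                       eta_range = scenario$fit_eta_range)
  wm <- as.vector(truth$mask_wm) & as.vector(rm_$converged)
  tbl <- data.frame(
    subject = subject,
    t1 = as.vector(rm_$t1)[wm], s0 = as.vector(rm_$s0)[wm],
    theta = as.vector(theta_fit)[wm], fa = as.vector(tf$fa)[wm],
    odi = as.vector(truth$odi)[wm], f1 = as.vector(truth$f1)[wm],
    f2 = as.vector(truth$f2)[wm], f3 = as.vector(truth$f3)[wm],
    t1_true = as.vector(truth$t1_true)[wm],
    theta_true = as.vector(truth$theta)[wm],
    label = as.vector(truth$label)[wm])
  if (keep_maps)
    attr(tbl, "maps") <- list(dwi = dwi, tensor = tf, theta = theta_fit,
                              ir = ir, relax = rm_, truth = truth)
  tbl
}

#' Run a cohort of synthetic subjects
#'
#' @inheritParams run_subject
#' @param subjects subject indices (default `1:n_subjects`).
#' @param verbose print per-subject progress.
#' @return stacked per-voxel data frame (see [run_subject()]) with the
#'   scenario in attribute `scenario`.
#' @export
run_cohort <- function(scenario, subjects = NULL, verbose = FALSE) {
  if (is.null(subjects)) subjects <- seq_len(scenario$n_subjects)
  out <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    if (verbose) message("subject ", subjects[i])
    out[[i]] <- run_subject(scenario, subjects[i])
  }
  tbl <- do.call(rbind, out)
  attr(tbl, "scenario") <- scenario
  tbl
}

#' Selection-conditioned angular statistics of a cohort table
#'
#' Applies a microstructural selection rule to a cohort voxel table, builds
#' the per-subject 4.5-degree angular T1 profile, and derives the
#' two-anchor-baseline contrasts (peak delta, parallel-minus-perpendicular
#' delta, percent of mean).
#'
#' @param tbl cohort table from [run_cohort()].
#' @param rule a [selection_rule()].
#' @param peak_angle angle (degrees) of the evaluated peak bin.
#' @param quantity column to profile (default `"t1"`).
#' @return list with `rule`, `median_index`, `n_voxels`, `mean` /`sd` of the
#'   per-subject selected-voxel means, `profile` (an `angular_profile`) and
#'   `deltas` (a `delta_summary`).
#' @export
cohort_deltas <- function(tbl, rule, peak_angle, quantity = "t1") {
  col <- index_column[[rule$index_name]]
  sel <- select_voxels(tbl[[col]], rule)
  d <- tbl[sel$sel, ]
  subj_mean <- tapply(d[[quantity]], d$subject, mean)
  pr <- profile_1d(d[[quantity]], d$theta, d$subject,
                   quantity = toupper(quantity))
  ds <- baseline_and_deltas(pr, peak_angle,
                            mean_t1 = as.numeric(subj_mean))
  list(rule = rule, median_index = sel$median_index, n_voxels = sel$n,
       mean = mean(subj_mean), sd = stats::sd(subj_mean),
       subj_mean = subj_mean, profile = pr, deltas = ds)
}

#' Cross-field summary table of angular T1 statistics
#'
#' Builds a summary in the style of the published study tables: one row per
#' (microstructural index, field) giving the median index over the
#' selection, the mean and SD of T1, the baseline-subtracted peak delta and
#' the 0-90-degree delta (per subject, then averaged), plus Welch t-tests
#' comparing the two fields per index at a Bonferroni-corrected threshold.
#' Indices with an empty selection are omitted with a warning; tests are
#' suppressed for single-subject cohorts.
#'
#' @param cohorts named list of cohort tables, e.g.
#'   `list("3T" = tbl3, "7T" = tbl7)`.
#' @param rules named list of [selection_rule()]s, one per table row.
#' @param peak_angles named numeric, peak angle per cohort (e.g.
#'   `c("3T" = 54, "7T" = 40)`).
#' @param alpha Bonferroni-corrected significance threshold (default 0.01).
#' @param file optional CSV path for the formatted table.
#' @return data frame; per-field delta vectors in attribute `details`.
#' @export
group_table <- function(cohorts, rules, peak_angles, alpha = 0.01,
                        file = NULL) {
  rows <- list(); details <- list()
  for (idx in names(rules)) {
    per_field <- list()
    for (fn in names(cohorts)) {
      cd <- tryCatch(cohort_deltas(cohorts[[fn]], rules[[idx]],
                                   peak_angles[[fn]]),
                     error = function(e) e)
      if (inherits(cd, "error")) {
        warning("row ", idx, " (", fn, ") omitted: ",
                conditionMessage(cd), call. = FALSE)
        next
      }
      per_field[[fn]] <- cd
      n_sub <- length(cd$subj_mean)
      rows[[paste(idx, fn)]] <- data.frame(
        index = idx, field = fn,
        median_index = cd$median_index, n_voxels = cd$n_voxels,
        n_subjects = n_sub,
        t1_mean = cd$mean, t1_sd = cd$sd,
        delta_peak = cd$deltas$delta_peak,
        delta_peak_sd = cd$deltas$delta_peak_sd,
        delta_par_perp = cd$deltas$delta_par_perp,
        delta_par_perp_sd = cd$deltas$delta_par_perp_sd,
        percent_of_mean = cd$deltas$percent_of_mean)
    }
    details[[idx]] <- per_field
    if (length(per_field) == 2L) {
      a <- per_field[[1]]$deltas$per_subject
      b <- per_field[[2]]$deltas$per_subject
      can_test <- nrow(a) >= 2L && nrow(b) >= 2L
      for (what in c("delta_peak", "delta_par_perp")) {
        p <- if (can_test)
          stats::t.test(a[[what]], b[[what]])$p.value else NA_real_
        for (fn in names(per_field)) {
          rows[[paste(idx, fn)]][[paste0("p_", what)]] <- p
          rows[[paste(idx, fn)]][[paste0("sig_", what)]] <-
            if (can_test) p < alpha else NA
        }
      }
    }
  }
  if (!length(rows)) stop("no non-empty rows in group table", call. = FALSE)
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(out, "details") <- details
  attr(out, "alpha") <- alpha
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}
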