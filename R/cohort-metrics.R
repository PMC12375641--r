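#' Plan-quality metrics for one dose grid on a phantom
#'
#' The standard PTV panel (Min/Max/Mean/Median/Mode/STD/CI/GM/D2%/D50%/D98%)
#' plus organ-at-risk means and Vx values (lungs mean/V5/V20/V30, per-lung
#' mean, heart V30/V40, esophagus mean/D2%).
#'
#' @param grid a [dose_grid()].
#' @param phantom the [generate_phantom()] the grid lives on.
#' @param prescription prescription dose (cGy).
#' @param ci_variant conformity-index variant (see [conformity_index()]).
#' @return named numeric vector of metrics.
#' @export
compute_plan_metrics <- function(grid, phantom, prescription,
                                 ci_variant = "rtog") {
  m <- phantom$masks
  ptv <- summary_metrics(grid, m$PTV, prescription = prescription,
                         body = m$Body, ci_variant = ci_variant)
  oar_stats <- function(mask, vx = NULL) {
    s <- summary_metrics(grid, mask, vx_doses = vx)
    s
  }
  lungs <- oar_stats(m$Lungs, vx = c(500, 2000, 3000))
  heart <- oar_stats(m$Heart, vx = c(3000, 4000))
  eso <- oar_stats(m$Esophagus)
  c(PTV_Min = ptv$d_min, PTV_Max = ptv$d_max, PTV_Mean = ptv$d_mean,
    PTV_Median = ptv$d_median, PTV_Mode = ptv$d_mode, PTV_STD = ptv$d_std,
    PTV_CI = ptv$ci, PTV_GM = ptv$gm,
    PTV_D2 = ptv$d2, PTV_D50 = ptv$d50, PTV_D98 = ptv$d98,
    Lungs_Mean = lungs$d_mean, Lungs_V5 = lungs$vx[["V500"]],
    Lungs_V20 = lungs$vx[["V2000"]], Lungs_V30 = lungs$vx[["V3000"]],
    LungL_Mean = summary_metrics(grid, m$Lung_L)$d_mean,
    LungR_Mean = summary_metrics(grid, m$Lung_R)$d_mean,
    Heart_V30 = heart$vx[["V3000"]], Heart_V40 = heart$vx[["V4000"]],
    Esophagus_Mean = eso$d_mean, Esophagus_D2 = eso$d2)
}

#' Long-format metric table for a synthetic cohort
#'
#' @param cohort a [generate_cohort()] result.
#' @param metrics optional character vector restricting which metrics to
#'   keep (names as in [compute_plan_metrics()]); NULL keeps all.
#' @return `data.frame` with columns patient, condition, metric, value
#'   (ready for [compare_cohort()]).
#' @export
compute_cohort_metrics <- function(cohort, metrics = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  rx <- cohort$config$prescription
  rows <- list()
  for (pid in names(cohort$grids)) {
    ph <- cohort$phantoms[[pid]]
    for (cond in names(cohort$grids[[pid]])) {
      vals <- compute_plan_metrics(cohort$grids[[pid]][[cond]], ph, rx)
      if (!is.null(metrics)) vals <- vals[names(vals) %in% metrics]
      rows[[length(rows) + 1L]] <- data.frame(
        patient = pid, condition = cond, metric = names(vals),
        value = unname(vals), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Per-structure DVH sets for a cohort
#'
#' @param cohort a [generate_cohort()] result.
#' @param structures structure names to histogram; default the ones the
#'   built-in model registry needs.
#' @param bin_width DVH bin width (cGy).
#' @return nested list `dvhs[[patient]][[condition]][[structure]]` of
#'   [differential_dvh()], suitable for [evaluate_outcomes()].
#' @export
compute_cohort_dvhs <- function(cohort,
                                structures = c("PTV", "Lungs", "Esophagus"),
                                bin_width = 10) {
  stopifnot(inherits(cohort, "cohort"))
  out <- list()
  for (pid in names(cohort$grids)) {
    ph <- cohort$phantoms[[pid]]
    out[[pid]] <- list()
    for (cond in names(cohort$grids[[pid]])) {
      g <- cohort$grids[[pid]][[cond]]
      out[[pid]][[cond]] <- lapply(
        stats::setNames(structures, structures),
        function(s) grid_to_differential_dvh(g, ph$masks[[s]],
                                             bin_width = bin_width))
    }
  }
  out
}
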