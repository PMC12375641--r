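#' Summary dose metrics for one structure
#'
#' Computes the standard plan-report statistics on the masked voxel doses:
#' raw min/max/mean/median (so "Min"/"Max" really are the extreme voxels),
#' population standard deviation (divide by n, the TPS convention), the mode
#' as the centre of the most occupied differential-DVH bin, the DVH-derived
#' D2%/D50%/D98%, and optional Vx values. Conformity index and gradient
#' measure need a prescription and a body mask and are only filled when both
#' are supplied.
#'
#' @param grid a [dose_grid()].
#' @param mask a [structure_mask()]; must be non-empty.
#' @param bin_width DVH bin width (cGy) used for the mode and Dx% values.
#' @param vx_doses optional numeric vector of dose thresholds (cGy) for Vx
#'   entries (percent of structure volume at or above each dose).
#' @param prescription optional prescription dose (cGy) enabling `ci`, `gm`.
#' @param body optional body [structure_mask()] used for `ci`/`gm` isodose
#'   volumes.
#' @param ci_variant conformity index variant, `"rtog"` (default) or
#'   `"paddick"`.
#' @return object of class `dose_metrics`: a list with fields `d_min`,
#'   `d_max`, `d_mean`, `d_median`, `d_mode`, `d_std`, `d2`, `d50`, `d98`,
#'   `ci`, `gm`, `vx`.
#' @export
summary_metrics <- function(grid, mask, bin_width = 10, vx_doses = NULL,
                            prescription = NULL, body = NULL,
                            ci_variant = c("rtog", "paddick")) {
  check_congruent(grid, mask)
  ci_variant <- match.arg(ci_variant)
  doses <- grid$values[mask$voxels]
  if (length(doses) == 0L)
    stop(sprintf("structure '%s' is empty: metrics undefined", mask$name))
  dvh <- grid_to_differential_dvh(grid, mask, bin_width = bin_width)
  cdvh <- differential_to_cumulative(dvh)
  mode_bin <- which.max(dvh$bin_volume)
  vx <- NULL
  if (!is.null(vx_doses)) {
    vx <- vapply(vx_doses, function(d) volume_at_dose(cdvh, d), numeric(1))
    names(vx) <- paste0("V", format(vx_doses, trim = TRUE))
  }
  ci <- NA_real_; gm <- NA_real_
  if (!is.null(prescription) && !is.null(body)) {
    ci <- conformity_index(grid, mask, prescription, body = body,
                           variant = ci_variant)
    gm <- gradient_measure(grid, body, prescription)
  }
  structure(list(
    structure = mask$name,
    d_min = min(doses), d_max = max(doses), d_mean = mean(doses),
    d_median = stats::median(doses),
    d_mode = dvh_bin_centers(dvh)[mode_bin],
    d_std = sqrt(mean((doses - mean(doses))^2)),
    d2 = dose_at_volume(cdvh, 2), d50 = dose_at_volume(cdvh, 50),
    d98 = dose_at_volume(cdvh, 98),
    ci = ci, gm = gm, vx = vx
  ), class = "dose_metrics")
}

#' @export
print.dose_metrics <- function(x, ...) {
  cat(sprintf("<dose_metrics> %s\n", x$structure))
  cat(sprintf("  min %.1f  max %.1f  mean %.1f  median %.1f  mode %.1f  sd %.1f cGy\n",
              x$d_min, x$d_max, x$d_mean, x$d_median, x$d_mode, x$d_std))
  cat(sprintf("  D2%% %.1f  D50%% %.1f  D98%% %.1f cGy\n", x$d2, x$d50, x$d98))
  if (!is.na(x$ci)) cat(sprintf("  CI %.3f  GM %.3f cm\n", x$ci, x$gm))
  invisible(x)
}

#' Conformity index of the prescription isodose
#'
#' `rtog`: ratio of the prescription isodose volume (within the body) to the
#' target volume. `paddick`: (target volume covered by the prescription
#' isodose)^2 / (target volume x prescription isodose volume), in (0, 1].
#'
#' @param grid a [dose_grid()].
#' @param target the target [structure_mask()] (PTV).
#' @param prescription prescription dose (cGy), > 0.
#' @param body [structure_mask()] bounding the isodose volume; defaults to
#'   the whole grid.
#' @param variant `"rtog"` (default) or `"paddick"`.
#' @return dimensionless conformity index.
#' @export
conformity_index <- function(grid, target, prescription,
                             body = NULL, variant = c("rtog", "paddick")) {
  check_congruent(grid, target)
  variant <- match.arg(variant)
  if (!is.finite(prescription) || prescription <= 0)
    stop("`prescription` must be > 0")
  in_body <- if (is.null(body)) {
    array(TRUE, dim(grid$values))
  } else {
    check_congruent(grid, body)
    body$voxels
  }
  iso <- (grid$values >= prescription) & in_body
  piv <- sum(iso)                                # prescription isodose voxels
  tv <- sum(target$voxels)
  if (piv == 0L) stop("prescription isodose volume is empty")
  if (tv == 0L) stop("target volume is empty")
  if (variant == "rtog") {
    piv / tv
  } else {
    tv_piv <- sum(iso & target$voxels)
    (tv_piv^2) / (tv * piv)
  }
}

#' Gradient measure of the dose falloff
#'
#' Difference between the equivalent-sphere radii of the 50% and 100%
#' prescription isodose volumes inside the body: `GM = r_eq(V50) - r_eq(V100)`
#' with `r_eq(V) = (3V / 4 pi)^(1/3)`, reported in cm.
#'
#' @param grid a [dose_grid()].
#' @param body [structure_mask()] bounding the isodose volumes.
#' @param prescription prescription dose (cGy), > 0.
#' @return gradient measure in cm (>= 0).
#' @export
gradient_measure <- function(grid, body, prescription) {
  check_congruent(grid, body)
  if (!is.finite(prescription) || prescription <= 0)
    stop("`prescription` must be > 0")
  vv <- body$voxel_volume
  v100 <- sum(grid$values >= prescription & body$voxels) * vv
  v50 <- sum(grid$values >= prescription / 2 & body$voxels) * vv
  if (v100 <= 0) stop("100% prescription isodose volume is empty")
  r_eq <- function(v_cc) (3 * v_cc / (4 * pi))^(1 / 3)   # cc -> cm
  r_eq(v50) - r_eq(v100)
}

#' ICRU homogeneity check
#'
#' Passes when the near-minimum dose (D98%) is at least 95% of the
#' prescription and the near-maximum dose (D2%) is at most 107%, the ICRU62
#' -5%/+7% planning window. Near-min/near-max use D98%/D2% per ICRU83
#' practice rather than the raw extreme voxels.
#'
#' @param metrics a `dose_metrics` object from [summary_metrics()].
#' @param prescription prescription dose (cGy), > 0.
#' @return list with `pass` (logical), `lower_margin_pct` = signed deviation
#'   of the near-minimum from the prescription (% of prescription; must be
#'   >= -5 to pass) and `upper_margin_pct` = signed deviation of the
#'   near-maximum (must be <= +7 to pass).
#' @export
homogeneity_check <- function(metrics, prescription) {
  stopifnot(inherits(metrics, "dose_metrics"))
  if (!is.finite(prescription) || prescription <= 0)
    stop("`prescription` must be > 0")
  lower <- 100 * (metrics$d98 / prescription - 1)
  upper <- 100 * (metrics$d2 / prescription - 1)
  list(pass = lower >= -5 && upper <= 7,
       lower_margin_pct = lower, upper_margin_pct = upper,
       near_min = metrics$d98, near_max = metrics$d2)
}
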