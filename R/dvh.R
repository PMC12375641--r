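#' Differential dose-volume histogram
#'
#' Bins a structure's volume by dose. `bin_edges` has one more element than
#' `bin_volume`; bin i covers `[bin_edges[i], bin_edges[i+1])` and holds
#' `bin_volume[i]` cc. Bin volumes must sum to `total_volume` (1e-6 relative
#' tolerance).
#'
#' @param bin_edges monotone increasing dose bin boundaries (cGy).
#' @param bin_volume volume per bin (cc), non-negative.
#' @param structure structure label.
#' @param total_volume total structure volume (cc); defaults to
#'   `sum(bin_volume)`.
#' @return object of class `dvh_diff`.
#' @export
differential_dvh <- function(bin_edges, bin_volume, structure = "structure",
                             total_volume = sum(bin_volume)) {
  bin_edges <- as.numeric(bin_edges)
  bin_volume <- as.numeric(bin_volume)
  if (length(bin_edges) != length(bin_volume) + 1L)
    stop("need length(bin_edges) == length(bin_volume) + 1")
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop("`bin_edges` must be strictly increasing")
  if (any(bin_volume < 0)) stop("bin volumes must be non-negative")
  if (total_volume <= 0) stop("total volume must be positive")
  if (abs(sum(bin_volume) - total_volume) > 1e-6 * total_volume)
    stop("sum(bin_volume) must equal total_volume within 1e-6 relative")
  structure(list(bin_edges = bin_edges, bin_volume = bin_volume,
                 total_volume = total_volume, structure = structure),
            class = "dvh_diff")
}

#' @export
print.dvh_diff <- function(x, ...) {
  cat(sprintf("<dvh_diff> %s: %d bins over [%.0f, %.0f] cGy, %.2f cc\n",
              x$structure, length(x$bin_volume),
              min(x$bin_edges), max(x$bin_edges), x$total_volume))
  invisible(x)
}

#' Bin-centre doses of a differential DVH (cGy)
#' @param dvh a [differential_dvh()].
#' @export
dvh_bin_centers <- function(dvh) {
  stopifnot(inherits(dvh, "dvh_diff"))
  (dvh$bin_edges[-1] + dvh$bin_edges[-length(dvh$bin_edges)]) / 2
}

#' Relative bin volumes (sum to 1)
#' @param dvh a [differential_dvh()].
#' @export
dvh_rel_volumes <- function(dvh) {
  stopifnot(inherits(dvh, "dvh_diff"))
  dvh$bin_volume / sum(dvh$bin_volume)
}

#' Cumulative dose-volume histogram
#'
#' Tabulated `volume_at_least[i]` = structure volume (cc) receiving at least
#' `dose_axis[i]` cGy. Must start at the total volume for dose 0 and be
#' monotone non-increasing.
#'
#' @param dose_axis monotone increasing dose values (cGy), starting at 0.
#' @param volume_at_least volume (cc) receiving at least each dose.
#' @param structure structure label.
#' @param total_volume total structure volume (cc).
#' @return object of class `dvh_cum`.
#' @export
cumulative_dvh <- function(dose_axis, volume_at_least, structure = "structure",
                           total_volume = max(volume_at_least)) {
  dose_axis <- as.numeric(dose_axis)
  volume_at_least <- as.numeric(volume_at_least)
  if (length(dose_axis) != length(volume_at_least))
    stop("dose_axis and volume_at_least lengths differ")
  if (is.unsorted(dose_axis, strictly = TRUE))
    stop("`dose_axis` must be strictly increasing")
  if (any(diff(volume_at_least) > 1e-9 * max(total_volume, 1)))
    stop(sprintf("cumulative volume must be non-increasing (first offence at row %d)",
                 which(diff(volume_at_least) > 1e-9 * max(total_volume, 1))[1] + 1L))
  volume_at_least <- cummin(pmax(volume_at_least, 0))
  if (abs(volume_at_least[1] - total_volume) > 1e-6 * total_volume)
    stop("volume at the lowest tabulated dose must equal the total volume")
  structure(list(dose_axis = dose_axis, volume_at_least = volume_at_least,
                 total_volume = total_volume, structure = structure),
            class = "dvh_cum")
}

#' @export
print.dvh_cum <- function(x, ...) {
  cat(sprintf("<dvh_cum> %s: %d points over [%.0f, %.0f] cGy, %.2f cc\n",
              x$structure, length(x$dose_axis),
              min(x$dose_axis), max(x$dose_axis), x$total_volume))
  invisible(x)
}

#' Differential DVH from a dose grid and structure mask
#'
#' Histograms the masked voxel doses into fixed-width bins covering
#' `[0, max dose in mask]`. The default 10 cGy width mirrors common TPS
#' export resolution.
#'
#' @param grid a [dose_grid()].
#' @param mask a [structure_mask()] congruent with `grid`.
#' @param bin_width bin width in cGy (> 0), default 10.
#' @return a [differential_dvh()].
#' @export
grid_to_differential_dvh <- function(grid, mask, bin_width = 10) {
  check_congruent(grid, mask)
  if (!is.finite(bin_width) || bin_width <= 0) stop("`bin_width` must be > 0")
  doses <- grid$values[mask$voxels]
  if (length(doses) == 0L)
    stop(sprintf("structure '%s' has no voxels: DVH undefined", mask$name))
  dmax <- max(doses)
  n_bins <- max(1L, ceiling((dmax + 1e-9) / bin_width))
  edges <- seq(0, by = bin_width, length.out = n_bins + 1L)
  # findInterval puts a dose exactly on an inner edge into the upper bin;
  # the top edge is open upward so the max dose lands in the last bin.
  idx <- findInterval(doses, edges, rightmost.closed = TRUE)
  idx[idx > n_bins] <- n_bins
  counts <- tabulate(idx, nbins = n_bins)
  differential_dvh(edges, counts * mask$voxel_volume, structure = mask$name,
                   total_volume = length(doses) * mask$voxel_volume)
}

#' Convert a differential DVH to its cumulative form
#'
#' The cumulative curve is tabulated at the bin edges: the volume receiving
#' at least a given edge dose is the suffix sum of the bins above it, so the
#' curve drops linearly across each occupied bin (uniform-within-bin
#' assumption) and reaches 0 at the top edge.
#'
#' @param dvh a [differential_dvh()].
#' @return a [cumulative_dvh()].
#' @export
differential_to_cumulative <- function(dvh) {
  stopifnot(inherits(dvh, "dvh_diff"))
  suffix <- rev(cumsum(rev(dvh$bin_volume)))          # vol >= lower edge of bin i
  dose_axis <- dvh$bin_edges
  vol <- c(suffix, 0)
  if (dose_axis[1] > 0) {                              # extend down to 0 if needed
    dose_axis <- c(0, dose_axis)
    vol <- c(vol[1], vol)
  }
  cumulative_dvh(dose_axis, vol, structure = dvh$structure,
                 total_volume = dvh$total_volume)
}

as_cumulative <- function(x) {
  if (inherits(x, "dvh_cum")) x else differential_to_cumulative(x)
}

#' Dose covering a given volume fraction (Dx%)
#'
#' Returns Dx%: the minimum dose received by the hottest `volume_percent` of
#' the structure, i.e. the largest dose D with V(D) >= `volume_percent`,
#' linearly interpolated between tabulated cumulative points. On a plateau
#' (a dose range all attaining the level) this resolves to the plateau's
#' upper boundary, which keeps the uniform-structure identity Dx% = dose for
#' every x.
#'
#' @param cdvh a [cumulative_dvh()] (a differential DVH is converted).
#' @param volume_percent volume level in (0, 100].
#' @return dose in cGy.
#' @export
dose_at_volume <- function(cdvh, volume_percent) {
  cdvh <- as_cumulative(cdvh)
  if (!is.finite(volume_percent) || volume_percent <= 0 || volume_percent > 100)
    stop("`volume_percent` must be in (0, 100]")
  target <- volume_percent / 100 * cdvh$total_volume
  d <- cdvh$dose_axis; v <- cdvh$volume_at_least
  if (target > v[1]) return(d[1])
  eps <- 1e-12 * cdvh$total_volume
  j <- which(v < target - eps)[1]     # first point strictly below the level
  if (is.na(j)) return(d[length(d)])  # curve never drops below: max dose
  if (j == 1L) return(d[1])
  if (abs(v[j - 1] - target) <= eps) return(d[j - 1])   # plateau upper edge
  d[j - 1] + (v[j - 1] - target) / (v[j - 1] - v[j]) * (d[j] - d[j - 1])
}

#' Volume fraction receiving at least a dose (Vx)
#'
#' @param cdvh a [cumulative_dvh()] (a differential DVH is converted).
#' @param dose dose threshold in cGy (>= 0).
#' @return percent of structure volume receiving at least `dose`.
#' @export
volume_at_dose <- function(cdvh, dose) {
  cdvh <- as_cumulative(cdvh)
  if (!is.finite(dose) || dose < 0) stop("`dose` must be >= 0")
  d <- cdvh$dose_axis; v <- cdvh$volume_at_least
  if (dose <= d[1]) return(100)
  if (dose >= d[length(d)]) {
    return(100 * v[length(v)] / cdvh$total_volume)    # 0 unless curve truncated
  }
  100 * stats::approx(d, v, xout = dose, ties = "ordered")$y / cdvh$total_volume
}
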