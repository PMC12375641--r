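#' Dose grid container
#'
#' A `dose_grid` holds a regular, axis-aligned 3D scalar field of absorbed
#' dose in cGy together with its voxel spacing and the physical position of
#' the first voxel centre. It is the substrate for all DVH and plan-quality
#' computations in this package.
#'
#' @param values numeric 3D array of absorbed dose (cGy); all values must be
#'   non-negative.
#' @param spacing numeric(3), voxel edge lengths in mm; strictly positive.
#' @param origin numeric(3), physical coordinate (mm) of the centre of voxel
#'   `[1,1,1]`.
#' @return An object of class `dose_grid`.
#' @examples
#' g <- dose_grid(array(100, c(4, 4, 4)), spacing = c(2, 2, 2))
#' voxel_volume_cc(g)
#' @export
dose_grid <- function(values, spacing, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  storage.mode(values) <- "double"
  if (anyNA(values)) stop("dose values must not contain NA")
  if (any(values < 0)) stop("dose values must be non-negative")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive voxel edge lengths (mm)")
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("`origin` must be numeric(3) (mm)")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<dose_grid> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(format(x$spacing), collapse = " x ")))
  cat(sprintf("  dose range [%.1f, %.1f] cGy\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' Voxel volume of a grid
#'
#' @param grid a [dose_grid()].
#' @return voxel volume in cc.
#' @export
voxel_volume_cc <- function(grid) {
  stopifnot(inherits(grid, "dose_grid"))
  prod(grid$spacing) / 1000
}

#' Voxel-centre coordinate axes of a grid
#'
#' @param grid a [dose_grid()].
#' @return list of three numeric vectors (mm), one per axis.
#' @export
grid_axes <- function(grid) {
  stopifnot(inherits(grid, "dose_grid"))
  d <- dim(grid$values)
  lapply(1:3, function(k) grid$origin[k] + (seq_len(d[k]) - 1) * grid$spacing[k])
}

#' Structure mask
#'
#' A binary voxel mask congruent with a [dose_grid()], naming one anatomical
#' structure (PTV, Lungs, Heart, Esophagus, Cord, Body, ...).
#'
#' @param name structure label.
#' @param voxels logical 3D array; `TRUE` marks voxels inside the structure.
#' @param voxel_volume volume of one voxel in cc.
#' @return An object of class `structure_mask`.
#' @export
structure_mask <- function(name, voxels, voxel_volume) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array")
  if (!is.logical(voxels)) {
    if (!all(voxels %in% c(0, 1))) stop("`voxels` must be logical or 0/1")
    voxels <- array(as.logical(voxels), dim(voxels))
  }
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("`name` must be a non-empty string")
  voxel_volume <- as.numeric(voxel_volume)
  if (!is.finite(voxel_volume) || voxel_volume <= 0)
    stop("`voxel_volume` must be positive (cc)")
  structure(list(name = name, voxels = voxels, voxel_volume = voxel_volume),
            class = "structure_mask")
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("<structure_mask> %s: %d voxels, %.2f cc\n",
              x$name, sum(x$voxels), mask_volume_cc(x)))
  invisible(x)
}

#' Total volume of a structure mask (cc)
#' @param mask a [structure_mask()].
#' @export
mask_volume_cc <- function(mask) {
  stopifnot(inherits(mask, "structure_mask"))
  sum(mask$voxels) * mask$voxel_volume
}

# Congruence guard used by every grid+mask operation.
check_congruent <- function(grid, mask) {
  stopifnot(inherits(grid, "dose_grid"), inherits(mask, "structure_mask"))
  if (!identical(dim(grid$values), dim(mask$voxels)))
    stop(sprintf("mask '%s' (%s) is not congruent with the dose grid (%s)",
                 mask$name, paste(dim(mask$voxels), collapse = "x"),
                 paste(dim(grid$values), collapse = "x")))
  invisible(TRUE)
}

#' Doses of the voxels inside a structure
#'
#' @param grid a [dose_grid()].
#' @param mask a [structure_mask()] congruent with `grid`.
#' @return numeric vector of masked voxel doses (cGy).
#' @export
masked_doses <- function(grid, mask) {
  check_congruent(grid, mask)
  grid$values[mask$voxels]
}
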