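#' Thorax phantom specification
#'
#' Parametric geometry for the synthetic thorax: an elliptic-cylinder Body,
#' two ellipsoidal lungs, an ellipsoidal heart, tubular esophagus and spinal
#' cord, and a spherical PTV sitting centrally in the right lung against the
#' mediastinum. Coordinates are mm about the grid centre: x right-left,
#' y posterior-anterior, z inferior-superior. Per-patient anatomical
#' variability (PTV radius and centre jitter) is drawn from `seed`.
#'
#' @param shape integer(3) grid shape; default `c(40, 40, 40)`.
#' @param spacing voxel spacing in mm; default 5.
#' @param ptv_radius nominal PTV radius (mm); per patient the realised
#'   radius is jittered within +/- 4 mm.
#' @param ptv_center nominal PTV centre (mm); jittered within +/- 6 mm.
#' @param seed integer seed controlling the anatomical jitter.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(40L, 40L, 40L), spacing = 5,
                         ptv_radius = 22, ptv_center = c(28, -5, 5),
                         seed = 1L) {
  shape <- as.integer(shape)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  stopifnot(length(shape) == 3L, all(shape >= 8L),
            length(spacing) == 3L, all(spacing > 0),
            ptv_radius > 5)
  structure(list(shape = shape, spacing = spacing,
                 ptv_radius = ptv_radius, ptv_center = ptv_center,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# voxel-centre coordinate arrays (mm, centred on the grid)
coord_arrays <- function(shape, spacing) {
  ax <- lapply(1:3, function(k)
    (seq_len(shape[k]) - (shape[k] + 1) / 2) * spacing[k])
  list(
    x = array(rep(ax[[1]], times = shape[2] * shape[3]), shape),
    y = array(rep(rep(ax[[2]], each = shape[1]), times = shape[3]), shape),
    z = array(rep(ax[[3]], each = shape[1] * shape[2]), shape)
  )
}

ellipsoid_mask <- function(co, center, radii) {
  ((co$x - center[1]) / radii[1])^2 +
    ((co$y - center[2]) / radii[2])^2 +
    ((co$z - center[3]) / radii[3])^2 <= 1
}

tube_mask <- function(co, center_xy, radius) {
  (co$x - center_xy[1])^2 + (co$y - center_xy[2])^2 <= radius^2
}

#' Generate a thorax phantom
#'
#' Deterministic for a fixed spec (including its seed). The PTV is checked to
#' lie strictly inside the Body, and to be disjoint from the spinal cord.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `phantom`: grid geometry, named
#'   [structure_mask()] list (PTV, Lung_L, Lung_R, Lungs, Heart, Esophagus,
#'   Cord, Body), and the realised PTV centre/radius used by the dose
#'   generator.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  rng <- local_rng(spec$seed)
  co <- coord_arrays(spec$shape, spec$spacing)
  vv <- prod(spec$spacing) / 1000

  r_ptv <- spec$ptv_radius + rng$runif(1, -4, 4)
  c_ptv <- spec$ptv_center + rng$runif(3, -6, 6)

  body_v <- (co$x / 95)^2 + (co$y / 80)^2 <= 1
  lung_r <- ellipsoid_mask(co, c(45, 0, 0), c(38, 55, 85)) & body_v
  lung_l <- ellipsoid_mask(co, c(-45, 0, 0), c(38, 55, 85)) & body_v
  heart <- ellipsoid_mask(co, c(-15, 25, -30), c(30, 30, 35)) & body_v
  eso <- tube_mask(co, c(0, -38), 7) & body_v
  cord <- tube_mask(co, c(0, -62), 5) & body_v
  r2 <- (co$x - c_ptv[1])^2 + (co$y - c_ptv[2])^2 + (co$z - c_ptv[3])^2
  ptv <- r2 <= r_ptv^2

  if (any(ptv & !body_v)) stop("PTV extends outside the Body")
  if (any(ptv & cord)) stop("PTV overlaps the spinal cord")
  mk <- function(name, v) structure_mask(name, v, vv)
  masks <- list(
    PTV = mk("PTV", ptv),
    Lung_L = mk("Lung_L", lung_l & !ptv),
    Lung_R = mk("Lung_R", lung_r & !ptv),
    Lungs = mk("Lungs", (lung_l | lung_r) & !ptv),
    Heart = mk("Heart", heart),
    Esophagus = mk("Esophagus", eso),
    Cord = mk("Cord", cord),
    Body = mk("Body", body_v)
  )
  structure(list(shape = spec$shape, spacing = spec$spacing,
                 origin = -(spec$shape - 1) / 2 * spec$spacing,
                 masks = masks, ptv_center = c_ptv, ptv_radius = r_ptv,
                 voxel_volume = vv, seed = spec$seed),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %s voxels @ %s mm, PTV r = %.1f mm (%.1f cc)\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              x$ptv_radius, mask_volume_cc(x$masks$PTV)))
  invisible(x)
}

# smooth low-frequency multiplicative heterogeneity field in [-1, 1]
smooth_field <- function(co, rng, n_modes = 3, length_scale = 120) {
  f <- 0
  for (i in seq_len(n_modes)) {
    k <- rng$runif(3, -1, 1)
    k <- k / sqrt(sum(k^2)) * 2 * pi / length_scale
    phi <- rng$runif(1, 0, 2 * pi)
    f <- f + cos(k[1] * co$x + k[2] * co$y + k[3] * co$z + phi)
  }
  f / n_modes
}

#' Generate a treatment-plan-like dose grid on a phantom
#'
#' Emulates an IMRT plan without any beam model: a slightly hot plateau
#' (default 1.04 x prescription) with smooth low-frequency heterogeneity
#' inside the PTV, an isotropic exponential falloff with scale `falloff` mm
#' outside it, and one localised Gaussian cold spot seated on the PTV
#' surface (the realistic coverage dip that makes the raw minimum dose sit
#' well below the near-minimum). The plan is verified post hoc against the
#' coverage objective (>= 95% of the PTV receiving >= 95% of prescription)
#' and the ICRU62 -5%/+7% homogeneity window; on failure the heterogeneity
#' and cold-spot amplitude are reduced and the plan regenerated, erroring
#' after 3 attempts.
#'
#' @param phantom a [generate_phantom()] result.
#' @param prescription prescription dose (cGy); default 5400.
#' @param falloff exponential dose falloff scale (mm); default 40.
#' @param plateau plateau level relative to prescription; default 1.04.
#' @param heterogeneity relative amplitude of the smooth in-target
#'   heterogeneity; default 0.01.
#' @param cold_frac cold-spot amplitude range as a fraction of prescription;
#'   default `c(0.28, 0.38)` (0 disables the cold spot). The default keeps
#'   the voxel-level dip deep enough that the plan minimum stays on the PTV
#'   surface even under several-hundred-cGy peripheral perturbations.
#' @param seed integer seed.
#' @return a [dose_grid()].
#' @export
generate_plan_dose <- function(phantom, prescription = 5400, falloff = 40,
                               plateau = 1.04, heterogeneity = 0.01,
                               cold_frac = c(0.28, 0.38), seed = 1L) {
  stopifnot(inherits(phantom, "phantom"))
  if (!(prescription > 0)) stop("`prescription` must be > 0")
  if (!(falloff > 0)) stop("`falloff` must be > 0")
  co <- coord_arrays(phantom$shape, phantom$spacing)
  r <- sqrt((co$x - phantom$ptv_center[1])^2 +
            (co$y - phantom$ptv_center[2])^2 +
            (co$z - phantom$ptv_center[3])^2)
  dist_surf <- pmax(r - phantom$ptv_radius, 0)

  het <- heterogeneity; cf <- cold_frac
  for (attempt in 1:3) {
    rng <- local_rng(seed + 7L * (attempt - 1L))
    h <- 1 + het * smooth_field(co, rng)
    dose <- prescription * plateau * exp(-dist_surf / falloff) * h
    if (length(cf) == 2L && cf[2] > 0) {
      u <- rng$runif(3, -1, 1)
      u <- u / sqrt(sum(u^2))
      cs_center <- phantom$ptv_center + u * phantom$ptv_radius
      amp <- prescription * rng$runif(1, cf[1], cf[2])
      d2cs <- (co$x - cs_center[1])^2 + (co$y - cs_center[2])^2 +
        (co$z - cs_center[3])^2
      dose <- dose - amp * exp(-d2cs / (2 * 3.5^2))
    }
    dose <- pmax(dose, 0)
    grid <- dose_grid(array(dose, phantom$shape), phantom$spacing,
                      phantom$origin)
    m <- summary_metrics(grid, phantom$masks$PTV)
    cdvh <- differential_to_cumulative(
      grid_to_differential_dvh(grid, phantom$masks$PTV))
    ok <- volume_at_dose(cdvh, 0.95 * prescription) >= 95 &&
      homogeneity_check(m, prescription)$pass
    if (ok) return(grid)
    het <- het * 0.5
    cf <- cf * 0.5
  }
  stop("plan generation failed coverage/homogeneity constraints after 3 attempts")
}

#' Calculation-condition effect
#'
#' Parametric perturbation emulating the systematic differences between dose
#' engines (AAA vs AXB), dose-reporting modes (Dm vs Dw) and the presence of
#' iodinated contrast, without recomputing any dose engine: a global
#' multiplicative bias, an extra multiplicative bias below 20% of the
#' prescription (the low-dose lung region where engine differences
#' concentrate), an additive shift confined to the PTV periphery (where the
#' minimum dose lives), and iid Gaussian voxel noise.
#'
#' @param condition condition label.
#' @param global_scale multiplicative dose bias (> 0).
#' @param target_min_shift additive bias (cGy) applied with full weight
#'   within `periphery_mm` of the PTV surface, fading over a further
#'   `periphery_mm` outside/inside.
#' @param low_dose_scale extra multiplicative bias below 20% of prescription.
#' @param noise_sd Gaussian voxel noise SD (cGy), >= 0.
#' @return object of class `condition_effect`.
#' @export
condition_effect <- function(condition, global_scale = 1, target_min_shift = 0,
                             low_dose_scale = 1, noise_sd = 15) {
  stopifnot(global_scale > 0, low_dose_scale > 0, noise_sd >= 0)
  structure(list(condition = condition, global_scale = global_scale,
                 target_min_shift = target_min_shift,
                 low_dose_scale = low_dose_scale, noise_sd = noise_sd),
            class = "condition_effect")
}

#' Default six-condition effect table
#'
#' Directions and rough magnitudes calibrated to the observed ordering of a
#' paired AAA/AXB contrast study: the convolution-superposition engine (AAA)
#' runs slightly hot globally and in the low-dose lung region and reports a
#' higher PTV minimum; contrast (`_C`) raises the peripheral minimum by
#' roughly 450-650 cGy; dose-to-medium (`Dm`) reports about 1% below
#' dose-to-water (`Dw`). `AXB_Dw` is the reference condition. These are
#' calibration knobs for the emulator, not re-derivations of engine physics.
#'
#' @param noise_sd per-voxel Gaussian noise SD (cGy) shared by all
#'   conditions.
#' @return named list of [condition_effect()] in the canonical order
#'   AAA, AAA_C, AXB_Dm, AXB_Dw, AXB_C_Dm, AXB_C_Dw.
#' @export
default_condition_effects <- function(noise_sd = 15) {
  eff <- list(
    condition_effect("AAA",      1.006, 110, 1.03, noise_sd),
    condition_effect("AAA_C",    1.009, 665, 1.03, noise_sd),
    condition_effect("AXB_Dm",   0.994, -40, 1.00, noise_sd),
    condition_effect("AXB_Dw",   1.000,   0, 1.00, noise_sd),
    condition_effect("AXB_C_Dm", 0.997, 435, 0.99, noise_sd),
    condition_effect("AXB_C_Dw", 1.003, 490, 0.99, noise_sd)
  )
  names(eff) <- vapply(eff, `[[`, character(1), "condition")
  eff
}

#' Apply a calculation-condition effect to a base dose grid
#'
#' `dose' = dose * global_scale * (low_dose_scale below 0.2 x prescription)
#' + target_min_shift * w(x) + N(0, noise_sd^2)`, where the periphery weight
#' w is 1 within `periphery_mm` of the PTV surface and decays linearly to 0
#' over a further `periphery_mm`. Deterministic for a fixed seed. Negative
#' results are clipped to zero; a warning is raised when more than 1% of
#' voxels clip.
#'
#' @param base a [dose_grid()].
#' @param effect a [condition_effect()].
#' @param phantom the [generate_phantom()] the grid was computed on (supplies
#'   the PTV surface geometry).
#' @param prescription prescription dose (cGy) defining the low-dose region.
#' @param seed integer seed for the noise draw.
#' @param periphery_mm flat-top half-width of the periphery weight; default 6.
#' @return a [dose_grid()].
#' @export
apply_condition <- function(base, effect, phantom, prescription, seed = 1L,
                            periphery_mm = 6) {
  stopifnot(inherits(base, "dose_grid"), inherits(effect, "condition_effect"),
            inherits(phantom, "phantom"))
  rng <- local_rng(seed)
  dose <- base$values * effect$global_scale
  if (effect$low_dose_scale != 1) {
    low <- base$values < 0.2 * prescription
    dose[low] <- dose[low] * effect$low_dose_scale
  }
  if (effect$target_min_shift != 0) {
    co <- coord_arrays(phantom$shape, phantom$spacing)
    r <- sqrt((co$x - phantom$ptv_center[1])^2 +
              (co$y - phantom$ptv_center[2])^2 +
              (co$z - phantom$ptv_center[3])^2)
    d_surf <- abs(r - phantom$ptv_radius)
    w <- pmin(pmax((2 * periphery_mm - d_surf) / periphery_mm, 0), 1)
    dose <- dose + effect$target_min_shift * w
  }
  if (effect$noise_sd > 0)
    dose <- dose + rng$rnorm(length(dose), 0, effect$noise_sd)
  n_clip <- sum(dose < 0)
  if (n_clip > 0.01 * length(dose))
    warning(sprintf("%.1f%% of voxels clipped to zero dose",
                    100 * n_clip / length(dose)))
  dose[dose < 0] <- 0
  dose_grid(array(dose, dim(base$values)), base$spacing, base$origin)
}

#' Cohort configuration
#'
#' @param n_patients number of patients (>= 2); default 20, a typical paired
#'   plan-comparison cohort size.
#' @param prescription prescription dose (cGy); default 5400.
#' @param n_fractions fraction count; default 30 (conventional 1.8 Gy/fx).
#' @param effects named list of [condition_effect()]s, all six conditions;
#'   default [default_condition_effects()].
#' @param master_seed integer master seed; all per-patient/per-condition
#'   seeds derive from it.
#' @param phantom_shape,phantom_spacing grid geometry passed to
#'   [phantom_spec()].
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 20, prescription = 5400,
                          n_fractions = 30,
                          effects = default_condition_effects(),
                          master_seed = 1L,
                          phantom_shape = c(40L, 40L, 40L),
                          phantom_spacing = 5) {
  n_patients <- as.integer(n_patients)
  if (is.na(n_patients) || n_patients < 2) stop("need n_patients >= 2")
  if (length(effects) < 2L) stop("need at least two conditions")
  if (is.null(names(effects)) || any(!nzchar(names(effects))))
    stop("`effects` must be a named list of condition_effect objects")
  structure(list(n_patients = n_patients, prescription = prescription,
                 n_fractions = n_fractions, effects = effects,
                 master_seed = as.integer(master_seed),
                 phantom_shape = phantom_shape,
                 phantom_spacing = phantom_spacing),
            class = "cohort_config")
}

# documented seed-derivation scheme: distinct streams per patient/purpose,
# kept below 2^31 - 1
derive_seed <- function(master, patient, stream) {
  as.integer((as.double(master) * 48271 + patient * 104729 + stream * 7919) %%
               2147483629)
}

#' Generate a full synthetic cohort
#'
#' For each patient: a jittered phantom, one base plan, and one perturbed
#' dose grid per condition. Fully deterministic under `master_seed`; the
#' returned manifest records every derived seed and effect parameter.
#'
#' @param config a [cohort_config()].
#' @return object of class `cohort`: `phantoms` (per patient), `grids`
#'   (`grids[[patient]][[condition]]`, [dose_grid()]s), `config`, and
#'   `manifest` (data.frame of patient, condition, seeds and effect
#'   parameters).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  phantoms <- list(); grids <- list(); man <- list()
  for (p in seq_len(config$n_patients)) {
    pid <- sprintf("P%02d", p)
    spec <- phantom_spec(shape = config$phantom_shape,
                         spacing = config$phantom_spacing,
                         seed = derive_seed(config$master_seed, p, 0L))
    ph <- generate_phantom(spec)
    plan_seed <- derive_seed(config$master_seed, p, 1L)
    base <- generate_plan_dose(ph, prescription = config$prescription,
                               seed = plan_seed)
    phantoms[[pid]] <- ph
    grids[[pid]] <- list()
    for (k in seq_along(config$effects)) {
      eff <- config$effects[[k]]
      cond_seed <- derive_seed(config$master_seed, p, 1L + k)
      grids[[pid]][[eff$condition]] <-
        apply_condition(base, eff, ph, config$prescription, seed = cond_seed)
      man[[length(man) + 1L]] <- data.frame(
        patient = pid, condition = eff$condition,
        phantom_seed = spec$seed, plan_seed = plan_seed,
        condition_seed = cond_seed, global_scale = eff$global_scale,
        target_min_shift = eff$target_min_shift,
        low_dose_scale = eff$low_dose_scale, noise_sd = eff$noise_sd,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(phantoms = phantoms, grids = grids, config = config,
                 manifest = do.call(rbind, man)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d patients x %d conditions (%s), Rx %.0f cGy / %d fx\n",
              x$config$n_patients, length(x$config$effects),
              paste(names(x$config$effects), collapse = ", "),
              x$config$prescription, x$config$n_fractions))
  invisible(x)
}
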