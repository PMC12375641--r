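test_that("phantom PTV voxel count matches the analytic sphere volume", {
  ph <- generate_phantom(phantom_spec(seed = 1))
  analytic_cc <- 4 / 3 * pi * ph$ptv_radius^3 / 1000
  expect_equal(mask_volume_cc(ph$masks$PTV), analytic_cc, tolerance = 0.05)
})

test_that("phantom is deterministic per seed and respects containment", {
  a <- generate_phantom(phantom_spec(seed = 42))
  b <- generate_phantom(phantom_spec(seed = 42))
  expect_identical(a$masks$PTV$voxels, b$masks$PTV$voxels)
  expect_identical(a$ptv_center, b$ptv_center)
  c <- generate_phantom(phantom_spec(seed = 43))
  expect_false(identical(a$masks$PTV$voxels, c$masks$PTV$voxels))
  # PTV strictly inside Body, disjoint from cord, all structures non-empty
  expect_true(all(a$masks$Body$voxels[a$masks$PTV$voxels]))
  expect_false(any(a$masks$PTV$voxels & a$masks$Cord$voxels))
  for (m in a$masks) expect_gt(sum(m$voxels), 0)
})

test_that("zero-heterogeneity plan is uniform prescription inside the PTV", {
  ph <- generate_phantom(phantom_spec(seed = 2))
  g <- generate_plan_dose(ph, prescription = 5400, plateau = 1,
                          heterogeneity = 0, cold_frac = c(0, 0), seed = 1)
  inside <- masked_doses(g, ph$masks$PTV)
  expect_equal(inside, rep(5400, length(inside)), tolerance = 1e-12)
  hc <- homogeneity_check(summary_metrics(g, ph$masks$PTV), 5400)
  expect_true(hc$pass)
  # margins vanish up to the DVH half-bin discretisation (10 cGy bins)
  expect_equal(hc$lower_margin_pct, 0, tolerance = 0.2)
  expect_equal(hc$upper_margin_pct, 0, tolerance = 0.2)
})

test_that("dose decays monotonically along radial rays outside the PTV", {
  ph <- generate_phantom(phantom_spec(seed = 3))
  g <- generate_plan_dose(ph, heterogeneity = 0, cold_frac = c(0, 0), seed = 1)
  # walk outward from the PTV centre along +x at voxel resolution
  ctr_idx <- round((ph$ptv_center - g$origin) / g$spacing) + 1
  ray <- g$values[ctr_idx[1]:dim(g$values)[1], ctr_idx[2], ctr_idx[3]]
  expect_true(all(diff(ray) <= 1e-9))
})

test_that("default plans satisfy coverage and homogeneity (spot check)", {
  for (seed in 1:5) {
    ph <- generate_phantom(phantom_spec(seed = seed))
    g <- generate_plan_dose(ph, seed = seed)
    cd <- differential_to_cumulative(
      grid_to_differential_dvh(g, ph$masks$PTV))
    expect_gte(volume_at_dose(cd, 0.95 * 5400), 95)
    expect_true(homogeneity_check(summary_metrics(g, ph$masks$PTV), 5400)$pass)
  }
})

test_that("apply_condition: identity effect is bit-exact, scaling is linear", {
  ph <- generate_phantom(phantom_spec(seed = 4))
  g <- generate_plan_dose(ph, seed = 2)
  ident <- condition_effect("ID", 1, 0, 1, 0)
  expect_identical(apply_condition(g, ident, ph, 5400, seed = 9)$values,
                   g$values)
  scaled <- apply_condition(g, condition_effect("S", 1.01, 0, 1, 0),
                            ph, 5400, seed = 9)
  expect_equal(mean(scaled$values), 1.01 * mean(g$values), tolerance = 1e-12)
})

test_that("periphery shift moves PTV_Min by about the injected amount", {
  diffs <- vapply(1:6, function(s) {
    ph <- generate_phantom(phantom_spec(seed = s))
    g <- generate_plan_dose(ph, seed = s)
    a <- apply_condition(g, condition_effect("A", 1, 0, 1, 10), ph, 5400,
                         seed = 100 + s)
    b <- apply_condition(g, condition_effect("B", 1, 500, 1, 10), ph, 5400,
                         seed = 200 + s)
    min(masked_doses(b, ph$masks$PTV)) - min(masked_doses(a, ph$masks$PTV))
  }, numeric(1))
  expect_equal(mean(diffs), 500, tolerance = 0.05)
})

test_that("cohort generation is reproducible and complete", {
  cfg <- cohort_config(n_patients = 3, master_seed = 11,
                       phantom_shape = c(24L, 24L, 24L), phantom_spacing = 8)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$grids$P02$AXB_C_Dw$values, b$grids$P02$AXB_C_Dw$values)
  expect_equal(length(a$grids), 3)
  expect_equal(names(a$grids$P01), names(default_condition_effects()))
  # manifest rows: patients x conditions, seeds all below 2^31
  expect_equal(nrow(a$manifest), 3 * 6)
  expect_true(all(a$manifest$condition_seed < 2^31))
  # manifest round-trips through CSV bit-exactly
  p <- tempfile(fileext = ".csv")
  write.csv(a$manifest, p, row.names = FALSE)
  back <- read.csv(p, stringsAsFactors = FALSE)
  expect_equal(back, a$manifest)
})

test_that("identity-effect cohort yields identical conditions per patient", {
  eff <- lapply(c("C1", "C2", "C3"), condition_effect,
                global_scale = 1, target_min_shift = 0,
                low_dose_scale = 1, noise_sd = 0)
  names(eff) <- c("C1", "C2", "C3")
  co <- generate_cohort(cohort_config(n_patients = 2, effects = eff,
                                      master_seed = 5,
                                      phantom_shape = c(24L, 24L, 24L),
                                      phantom_spacing = 8))
  expect_identical(co$grids$P01$C1$values, co$grids$P01$C3$values)
})
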