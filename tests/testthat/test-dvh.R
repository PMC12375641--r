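test_that("uniform field gives a single occupied bin holding the full volume", {
  cs <- make_uniform_case(n = 5, dose = 5000)   # 125 voxels is > the spec's 100
  dvh <- grid_to_differential_dvh(cs$grid, cs$mask, bin_width = 10)
  occupied <- which(dvh$bin_volume > 0)
  expect_length(occupied, 1L)
  centre <- dvh_bin_centers(dvh)[occupied]
  expect_lt(abs(centre - 5000), 10)
  expect_equal(dvh$bin_volume[occupied], mask_volume_cc(cs$mask))
})

test_that("bin volumes conserve the masked volume on random grids", {
  set.seed(42)
  for (i in 1:10) {
    n <- sample(4:12, 1)
    g <- dose_grid(array(runif(n^3, 0, 7000), c(n, n, n)), runif(3, 1, 5))
    keep <- array(runif(n^3) < 0.5, c(n, n, n))
    keep[1] <- TRUE
    m <- structure_mask("S", keep, voxel_volume_cc(g))
    dvh <- grid_to_differential_dvh(g, m, bin_width = 25)
    expect_equal(sum(dvh$bin_volume), sum(keep) * m$voxel_volume,
                 tolerance = 1e-12)
  }
})

test_that("ramp DVH matches a brute-force per-voxel histogram oracle", {
  cs <- make_ramp_case(n = 25, dmax = 6000)
  bw <- 100
  dvh <- grid_to_differential_dvh(cs$grid, cs$mask, bin_width = bw)
  doses <- masked_doses(cs$grid, cs$mask)
  # oracle: count voxels per bin directly; same right-open binning rule
  oracle <- vapply(seq_along(dvh$bin_volume), function(i) {
    lo <- dvh$bin_edges[i]; hi <- dvh$bin_edges[i + 1]
    top <- i == length(dvh$bin_volume)
    sum(doses >= lo & (doses < hi | (top & doses <= hi)))
  }, numeric(1)) * cs$mask$voxel_volume
  expect_equal(dvh$bin_volume, oracle, tolerance = 1e-12)
  # near-flat occupancy away from the end bins
  inner <- dvh$bin_volume[dvh$bin_volume > 0]
  expect_lt(diff(range(inner[2:(length(inner) - 1)])) / mean(inner), 0.2)
})

test_that("empty mask raises an error naming the structure", {
  cs <- make_uniform_case()
  empty <- structure_mask("Nothing", array(FALSE, dim(cs$grid$values)),
                          cs$mask$voxel_volume)
  expect_error(grid_to_differential_dvh(cs$grid, empty, 10), "Nothing")
})

test_that("cumulative conversion: endpoints, monotonicity, suffix-sum oracle", {
  set.seed(7)
  for (i in 1:10) {
    dvh <- random_dvh(n_bins = 30)
    cd <- differential_to_cumulative(dvh)
    expect_equal(cd$volume_at_least[1], dvh$total_volume)
    expect_equal(cd$volume_at_least[length(cd$volume_at_least)], 0)
    expect_true(all(diff(cd$volume_at_least) <= 1e-12))
    # suffix-sum oracle at every lower bin edge
    for (j in seq_along(dvh$bin_volume)) {
      expect_equal(cd$volume_at_least[cd$dose_axis == dvh$bin_edges[j]],
                   sum(dvh$bin_volume[j:length(dvh$bin_volume)]),
                   tolerance = 1e-12)
    }
  }
})

test_that("single-bin DVH converts to a step dropping at its dose", {
  dvh <- uniform_dvh(5000, volume = 12, width = 10)
  cd <- differential_to_cumulative(dvh)
  expect_equal(volume_at_dose(cd, 0), 100)
  expect_equal(volume_at_dose(cd, 4900), 100)
  expect_equal(volume_at_dose(cd, 5100), 0)
})

test_that("two equal bins plateau at 50% between them", {
  dvh <- differential_dvh(c(3995, 4005, 5995, 6005), c(5, 0, 5), "S")
  cd <- differential_to_cumulative(dvh)
  expect_equal(volume_at_dose(cd, 5000), 50)
  # plateau tie rule: D50% is the minimum dose of the hottest half, i.e. the
  # plateau's upper boundary (the hot bin's lower edge)
  expect_equal(dose_at_volume(cd, 50), 5995)
})

test_that("dose_at_volume on a uniform structure returns its dose", {
  dvh <- uniform_dvh(5000)
  for (v in c(2, 50, 98, 100))
    expect_lt(abs(dose_at_volume(dvh, v) - 5000), 1)
})

test_that("Dx ordering and argument validation", {
  set.seed(11)
  for (i in 1:5) {
    cd <- differential_to_cumulative(random_dvh())
    d2 <- dose_at_volume(cd, 2); d50 <- dose_at_volume(cd, 50)
    d98 <- dose_at_volume(cd, 98)
    expect_true(d98 <= d50 && d50 <= d2)
  }
  cd <- differential_to_cumulative(uniform_dvh(100))
  expect_error(dose_at_volume(cd, 0), "0, 100")
  expect_error(dose_at_volume(cd, 101), "0, 100")
  expect_error(volume_at_dose(cd, -1), ">= 0")
})

test_that("V20 on the linear ramp matches the analytic fraction", {
  cs <- make_ramp_case(n = 50, dmax = 6000)
  cd <- differential_to_cumulative(
    grid_to_differential_dvh(cs$grid, cs$mask, bin_width = 10))
  # doses are 50 equally likely levels 0..6000; P(D >= 2000) analytic
  expect_equal(volume_at_dose(cd, 2000),
               100 * mean(seq(0, 6000, length.out = 50) >= 2000),
               tolerance = 0.5)
  expect_equal(volume_at_dose(cd, 6500), 0)
})

test_that("dose_at_volume and volume_at_dose are mutual inverses", {
  set.seed(5)
  for (i in 1:5) {
    cd <- differential_to_cumulative(random_dvh(n_bins = 25))
    for (v in c(5, 20, 50, 80, 95)) {
      d <- dose_at_volume(cd, v)
      expect_equal(volume_at_dose(cd, d), v, tolerance = 1)
    }
  }
})

test_that("malformed DVH constructors are rejected", {
  expect_error(differential_dvh(c(0, 10, 5), c(1, 1)), "increasing")
  expect_error(differential_dvh(c(0, 10, 20), c(1, -1)), "non-negative")
  expect_error(differential_dvh(c(0, 10, 20), c(1, 1), total_volume = 3),
               "1e-06|total_volume")
  expect_error(cumulative_dvh(c(0, 10, 20), c(5, 8, 0)), "non-increasing")
})
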