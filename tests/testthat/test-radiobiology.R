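test_that("EQD2 transform: fixed point at 2 Gy/fx, identity at infinite a/b", {
  # 6000 cGy in 30 fx is exactly 2 Gy per fraction -> identity for any a/b
  dvh <- uniform_dvh(6000)
  out <- eqd2_transform(dvh, 3, fractionation(6000, 30))
  expect_equal(dvh_bin_centers(out), dvh_bin_centers(dvh), tolerance = 1e-4)
  expect_identical(out$bin_volume, dvh$bin_volume)
  # alpha/beta -> Inf: exact identity
  out2 <- eqd2_transform(dvh, Inf, fractionation(6000, 20))
  expect_identical(out2$bin_edges, dvh$bin_edges)
})

test_that("EQD2 of 6000 cGy in 20 fx at a/b = 3 Gy is 7200 cGy", {
  dvh <- uniform_dvh(6000, width = 1)
  out <- eqd2_transform(dvh, 3, fractionation(6000, 20))
  # direct LQ: 6000 * (300 + 300) / (200 + 300)
  expect_equal(dvh_bin_centers(out), 7200, tolerance = 0.01)
})

test_that("EUD identities: power mean of a constant, arithmetic mean at a=1", {
  u <- uniform_dvh(5000)
  for (a in c(1, 9, 1 / 0.34, 1000))
    expect_equal(eud(u, a), 5000, tolerance = 1e-9)
  set.seed(8)
  dvh <- random_dvh()
  v <- dvh_rel_volumes(dvh); d <- dvh_bin_centers(dvh)
  expect_equal(eud(dvh, 1), sum(v * d), tolerance = 1e-12)
  # a = 1000 approaches the maximum occupied dose
  expect_equal(eud(dvh, 1000), max(d[v > 0]), tolerance = 1e-3 * max(d))
  expect_error(eud(dvh, 0), "non-zero")
})

test_that("EUD: frozen two-bin value and scale equivariance", {
  dvh <- differential_dvh(c(3999.5, 4000.5, 5999.5, 6000.5), c(5, 0, 5), "S")
  # oracle: (0.5*4000^9 + 0.5*6000^9)^(1/9) = 5571.122...
  oracle <- (0.5 * 4000^9 + 0.5 * 6000^9)^(1 / 9)
  expect_equal(eud(dvh, 9), oracle, tolerance = 1e-6)
  expect_equal(oracle, 5571.122, tolerance = 1e-3)
  set.seed(9)
  d2 <- random_dvh()
  for (cc in c(0.5, 2)) {
    scaled <- differential_dvh(d2$bin_edges * cc, d2$bin_volume)
    expect_equal(eud(scaled, 9), cc * eud(d2, 9), tolerance = 1e-10)
  }
})

test_that("mechanistic Poisson TCP: substitution, limits, half-control dose", {
  expect_equal(tcp_mechanistic(0, 1e7, 0.003), exp(-1e7))
  expect_equal(tcp_mechanistic(1e6, 1e7, 0.003), 1)
  # alpha solving N exp(-alpha D) = ln 2 puts TCP at exactly 0.5
  D <- 5000; N <- 1e7
  alpha <- (log(N) - log(log(2))) / D
  expect_equal(tcp_mechanistic(D, N, alpha), 0.5, tolerance = 1e-12)
  # monotone in dose (away from the underflow floor at very low dose)
  d <- seq(3500, 8500, by = 500)
  expect_true(all(diff(tcp_mechanistic(d, N, alpha)) > 0))
})

test_that("phenomenological TCP: 0.5 at D50, limits, gamma50 slope", {
  expect_equal(tcp_poisson_uniform(4920, 4920, 1.5), 0.5, tolerance = 1e-15)
  expect_equal(tcp_poisson_uniform(0, 4920, 1.5),
               0.5^exp(2 * 1.5 / log(2)))
  expect_equal(tcp_poisson_uniform(1e6, 4920, 1.5), 1, tolerance = 1e-12)
  # normalized slope D * dTCP/dD at D50 recovers gamma50
  for (g50 in c(0.8, 1.5, 3)) {
    h <- 1e-3
    slope <- (tcp_poisson_uniform(4920 + h, 4920, g50) -
              tcp_poisson_uniform(4920 - h, 4920, g50)) / (2 * h)
    expect_equal(4920 * slope, g50, tolerance = 1e-3)
  }
})

test_that("DVH Poisson TCP reduces to the uniform closed form on one bin", {
  m <- ptv_model()
  m$eqd2 <- FALSE                    # compare on the physical dose scale
  dvh <- uniform_dvh(5200, width = 1e-6)
  expect_equal(tcp_poisson_dvh(dvh, m),
               tcp_poisson_uniform(5200, m$d50, m$gamma50),
               tolerance = 1e-12)
})

test_that("DVH Poisson TCP equals the literal per-bin product", {
  m <- ptv_model()
  m$eqd2 <- FALSE
  set.seed(10)
  for (i in 1:20) {
    dvh <- random_dvh(n_bins = 30)
    v <- dvh_rel_volumes(dvh); d <- dvh_bin_centers(dvh)
    oracle <- prod(tcp_poisson_uniform(d, m$d50, m$gamma50)^v)
    expect_equal(tcp_poisson_dvh(dvh, m), oracle, tolerance = 1e-12)
  }
  # zero-volume bin leaves TCP unchanged
  dvh <- differential_dvh(c(4995, 5005, 5015), c(10, 0), "S")
  expect_equal(tcp_poisson_dvh(dvh, m),
               tcp_poisson_dvh(uniform_dvh(5000, 10, 10), m),
               tolerance = 1e-12)
})

test_that("EQD2-corrected TCP needs a scheme, and raises TCP for cold plans", {
  m <- ptv_model()                    # eqd2 on by default for poisson_lq
  dvh <- uniform_dvh(4500)
  expect_error(tcp_poisson_dvh(dvh, m), "fractionation")
  sch <- fractionation(5400, 30)
  phys <- tcp_poisson_uniform(4500, m$d50, m$gamma50)
  # 150 cGy/fx with a/b = 10: EQD2 < physical dose -> lower TCP
  expect_lt(tcp_poisson_dvh(dvh, m, sch), phys)
})

test_that("LKB NTCP: 0.5 at every whole-organ TD50, probit values", {
  for (m in list(pneumonitis_model(), fibrosis_model(), esophagitis_model())) {
    dvh <- uniform_dvh(m$d50)
    expect_equal(ntcp_lkb(dvh, m), 0.5, tolerance = 1e-12)
    # EUD = TD50 (1 + m) sits one probit unit up
    dvh_hi <- uniform_dvh(m$d50 * (1 + m$m))
    expect_equal(ntcp_lkb(dvh_hi, m), pnorm(1), tolerance = 1e-9)
    # zero dose floors the response at Phi(-1/m) (0.106 for the steep
    # pneumonitis slope m = 0.8 -- the probit floor is not negligible there)
    expect_equal(ntcp_lkb(uniform_dvh(1e-9), m), pnorm(-1 / m$m),
                 tolerance = 1e-6)
  }
})

test_that("LKB probit agrees with numerical quadrature of the integral", {
  # a shallow-slope model makes every t in [-6, 6] reachable at positive dose
  shallow <- radbio_model("S", "e", "lyman", d50 = 3000, m = 0.15, n = 1)
  for (t in seq(-6, 6, by = 1.5)) {
    dvh <- uniform_dvh(shallow$d50 * (1 + shallow$m * t), width = 1e-6)
    quad <- integrate(function(x) exp(-x^2 / 2) / sqrt(2 * pi), -Inf, t,
                      rel.tol = 1e-12)$value
    expect_equal(ntcp_lkb(dvh, shallow), quad, tolerance = 1e-8)
  }
})

test_that("EUD volume-effect limits: serial (a large) and parallel (n = 1)", {
  set.seed(12)
  dvh <- random_dvh()
  d <- dvh_bin_centers(dvh); v <- dvh_rel_volumes(dvh)
  expect_equal(eud(dvh, 1000), max(d[v > 0]), tolerance = 1e-3 * max(d))
  expect_equal(eud(dvh, 1), sum(v * d), tolerance = 1e-9)
})

test_that("Poisson-LQ NTCP: 0.5 at D50 uniform, ~0 at zero dose", {
  m <- radbio_model("Esophagus", "Clinical stricture", "poisson_lq",
                    d50 = 6800, gamma50 = 1.5, alpha_beta = 3, eqd2 = FALSE)
  expect_equal(ntcp_poisson_lq(uniform_dvh(6800), m), 0.5, tolerance = 1e-12)
  expect_lt(ntcp_poisson_lq(uniform_dvh(1e-9), m), 1e-6)
  # scalar substitution oracle at 0.9 D50, gamma50 = 2
  m2 <- radbio_model("E", "stricture", "poisson_lq", d50 = 6800,
                     gamma50 = 2, eqd2 = FALSE)
  oracle <- 0.5^exp(2 * 2 * (1 - 0.9) / log(2))
  expect_equal(ntcp_poisson_lq(uniform_dvh(0.9 * 6800), m2), oracle,
               tolerance = 1e-12)
  # missing gamma50 errors with guidance
  m3 <- m2; m3$gamma50 <- NA_real_
  expect_error(ntcp_poisson_lq(uniform_dvh(5000), m3), "gamma50")
})

test_that("TCP/NTCP are monotone under pointwise dose increases", {
  set.seed(13)
  dvh <- random_dvh()
  up <- differential_dvh(dvh$bin_edges * 1.05, dvh$bin_volume)
  mt <- ptv_model(); mt$eqd2 <- FALSE
  expect_gt(tcp_poisson_dvh(up, mt), tcp_poisson_dvh(dvh, mt))
  mf <- fibrosis_model()
  expect_gt(ntcp_lkb(up, mf), ntcp_lkb(dvh, mf))
})

test_that("model registry validates families and links a = 1/n", {
  expect_error(radbio_model("S", "e", "lyman", d50 = 1000, n = 0.3), "m > 0")
  expect_error(radbio_model("S", "e", "lyman", d50 = 1000, m = 0.3), "n > 0")
  expect_error(radbio_model("S", "e", "poisson_lq", d50 = -5), "> 0")
  lm <- radbio_model("S", "e", "lyman", d50 = 1000, m = 0.3, n = 0.25)
  expect_equal(lm$a, 4)
  reg <- default_models(gamma50_ptv = 2.2)
  expect_equal(reg[["PTV:Tumor control"]]$gamma50, 2.2)
  expect_true(all(vapply(reg, inherits, logical(1), "radbio_model")))
})

test_that("evaluate_outcomes composes the unit operations over a cohort", {
  sch <- fractionation(5400, 30)
  dvhs_one <- list(
    PTV = differential_dvh(c(5195, 5205, 5395, 5405), c(5, 0, 5), "PTV"),
    Lungs = uniform_dvh(1500, structure = "Lungs"),
    Esophagus = uniform_dvh(2000, structure = "Esophagus"))
  cohort <- list(P1 = list(A = dvhs_one, B = dvhs_one))
  out <- evaluate_outcomes(cohort, default_models(), sch)
  expect_equal(nrow(out), 2 * length(default_models()))
  expect_true(all(out$probability >= 0 & out$probability <= 1))
  # identical DVHs across conditions -> zero between-condition differences
  a <- out[out$condition == "A", ]; b <- out[out$condition == "B", ]
  expect_equal(a$probability, b$probability)
  # rows match direct scalar calls
  fib <- fibrosis_model()
  expect_equal(out$probability[out$condition == "A" &
                                 out$endpoint == fib$endpoint],
               ntcp_lkb(dvhs_one$Lungs, fib), tolerance = 1e-12)
  # a missing structure is recorded, not fatal
  cohort$P1$A$Lungs <- NULL
  out2 <- evaluate_outcomes(cohort, default_models(), sch)
  miss <- out2[out2$condition == "A" & out2$structure == "Lungs", ]
  expect_true(all(grepl("missing", miss$error)))
  expect_true(all(is.na(miss$probability)))
})
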