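test_that("sphere amplitude has correct limits, bound and first zero", {
  expect_equal(sphere_amplitude(0), 1)
  expect_equal(sphere_amplitude(pi), 3 / pi^2, tolerance = 1e-12)
  x <- seq(0, 50, by = 0.01)
  expect_true(all(abs(sphere_amplitude(x)) <= 1 + 1e-12))
  # continuity across the series/direct switch at x = 1e-2
  expect_equal(sphere_amplitude(1e-2 - 1e-9), sphere_amplitude(1e-2 + 1e-9),
               tolerance = 1e-10)
  # first zero: root of tan x = x, bracketed search oracle
  root <- uniroot(function(z) sin(z) - z * cos(z), c(4, 4.6),
                  tol = 1e-12)$root
  expect_equal(root, 4.4934, tolerance = 1e-4)
  expect_equal(sphere_amplitude(root), 0, tolerance = 1e-12)
})

test_that("effective radius interpolates between polar and equatorial axes", {
  expect_equal(effective_radius(10, 1, c(0, pi / 4, pi / 2)), rep(10, 3))
  expect_equal(effective_radius(22.7, 0.60, 0), 13.62)
  expect_equal(effective_radius(10, 2, pi / 4), 10 * sqrt(0.5 + 2),
               tolerance = 1e-12)
  expect_equal(effective_radius(7, 0.5, pi / 2), 7)
})

test_that("shell-uniformity relation round-trips between core and outer surface", {
  expect_equal(eps_outer_from_core(10, 1.7, 0), 1.7)
  expect_equal(eps_outer_from_core(10, 1, 12), 1)
  # end-state complex geometry: algebraic round-trip through the forward
  # relation eps2 = (eps1 R1 - D) / (R1 - D)
  R2 <- 13.7; eps2 <- 1.8; D <- 10.1
  eps1 <- eps_outer_from_core(R2, eps2, D)
  expect_equal(eps1, (1.8 * 13.7 + 10.1) / 23.8, tolerance = 1e-12)
  R1 <- R2 + D
  expect_equal((eps1 * R1 - D) / (R1 - D), eps2, tolerance = 1e-12)
  # uniform thickness at both principal directions
  expect_equal(eps1 * R1 - eps2 * R2, D, tolerance = 1e-10)
  expect_equal(R1 - R2, D, tolerance = 1e-12)
})

test_that("displaced-core model obeys forward limit, reduction and geometry guard", {
  q <- fixture_q()
  p <- as.list(complex_preset("sds2.0"))
  cc <- complex_contrasts(p$Rcore, p$eps, p$Dhead, p$Npro)
  I0 <- displaced_core_shell_intensity(1e-10, p$Rcore, p$eps, p$Dhead, p$s,
                                       cc$k1, cc$k2)
  expect_equal(I0, (cc$k1 + cc$k2)^2, tolerance = 1e-8)
  Iq <- displaced_core_shell_intensity(q, p$Rcore, p$eps, p$Dhead, p$s,
                                       cc$k1, cc$k2)
  expect_true(all(Iq >= 0))
  # s = 0 reduces to the concentric model exactly
  Is0 <- displaced_core_shell_intensity(q, p$Rcore, p$eps, p$Dhead, 0,
                                        cc$k1, cc$k2)
  Icon <- concentric_core_shell_intensity(q, p$Rcore, p$eps, p$Dhead,
                                          cc$k1, cc$k2)
  expect_equal(Is0, Icon, tolerance = 1e-11)
  expect_error(
    displaced_core_shell_intensity(q, p$Rcore, p$eps, p$Dhead,
                                   p$Dhead + 1, cc$k1, cc$k2),
    "geometry")
})

test_that("quadrature matches Monte-Carlo orientation averages for both variants", {
  p <- as.list(complex_preset("sds2.0"))
  cc <- complex_contrasts(p$Rcore, p$eps, p$Dhead, p$Npro)
  qs <- c(0.05, 0.1, 0.2, 0.3)
  eps1 <- eps_outer_from_core(p$Rcore, p$eps, p$Dhead)
  set.seed(99)
  n <- 1e6
  theta <- acos(runif(n))                  # isotropic orientations
  r1 <- effective_radius(p$Rcore + p$Dhead, eps1, theta)
  r2 <- effective_radius(p$Rcore, p$eps, theta)

  Iamp <- displaced_core_shell_intensity(qs, p$Rcore, p$eps, p$Dhead, p$s,
                                         cc$k1, cc$k2)
  mc_amp <- vapply(qs, function(qq) {
    A <- cc$k1 * sphere_amplitude(qq * r1) +
      cc$k2 * sphere_amplitude(qq * r2) * besselJ(qq * p$s * sin(theta), 0)
    mean(A^2)
  }, numeric(1))
  expect_rel_equal(Iamp, mc_amp, 3e-3)     # MC se ~1e-3 at n = 1e6

  Iex <- displaced_core_shell_intensity(qs, p$Rcore, p$eps, p$Dhead, p$s,
                                        cc$k1, cc$k2, variant = "exact")
  phi <- runif(n, 0, 2 * pi)               # explicit two-body azimuth
  mc_ex <- vapply(qs, function(qq) {
    F1 <- sphere_amplitude(qq * r1)
    F2 <- sphere_amplitude(qq * r2)
    ph <- cos(qq * p$s * sin(theta) * cos(phi))
    mean(cc$k1^2 * F1^2 + cc$k2^2 * F2^2 + 2 * cc$k1 * cc$k2 * F1 * F2 * ph)
  }, numeric(1))
  expect_rel_equal(Iex, mc_ex, 3e-3)
})

test_that("doubling the quadrature order leaves intensities unchanged to 1e-6", {
  q <- seq(0.005, 0.5, length.out = 150)
  for (preset in complex_preset()$preset) {
    p <- as.list(complex_preset(preset))
    cc <- complex_contrasts(p$Rcore, p$eps, p$Dhead, p$Npro)
    I1 <- displaced_core_shell_intensity(q, p$Rcore, p$eps, p$Dhead, p$s,
                                         cc$k1, cc$k2, order = 76)
    I2 <- displaced_core_shell_intensity(q, p$Rcore, p$eps, p$Dhead, p$s,
                                         cc$k1, cc$k2, order = 152)
    expect_rel_equal(I1, I2, 1e-6)
  }
})

test_that("concentric model with eps = 1 matches the analytic core-shell sphere", {
  q <- fixture_q()
  R2 <- 15; D <- 8; k1 <- 2e-11; k2 <- -1e-11
  I <- concentric_core_shell_intensity(q, R2, 1, D, k1, k2)
  I_an <- (k1 * sphere_amplitude(q * (R2 + D)) +
             k2 * sphere_amplitude(q * R2))^2
  expect_rel_equal(I, I_an, 1e-9)
})

test_that("random-flight structure factor has correct limits and weighting", {
  q <- fixture_q()
  expect_equal(random_flight_sf(q, 1, 50), rep(1, length(q)))
  expect_equal(random_flight_sf(1e-10, 3, 50), 3, tolerance = 1e-6)
  expect_equal(random_flight_sf(1e-10, 2.4, 50), 2.4, tolerance = 1e-6)
  # x = sin(qD)/(qD) vanishes at qD = pi, so S(N=2) = 1 there
  expect_equal(random_flight_sf(pi / 50, 2, 50), 1, tolerance = 1e-12)
  # non-integer weighting is the linear mix of bracketing integers
  S2 <- random_flight_sf(q, 2, 50)
  S3 <- random_flight_sf(q, 3, 50)
  expect_equal(random_flight_sf(q, 2.4, 50), 0.6 * S2 + 0.4 * S3,
               tolerance = 1e-12)
  # continuity at integers
  expect_equal(random_flight_sf(q, 2 + 1e-9, 50), S2, tolerance = 1e-7)
  expect_equal(random_flight_sf(q, 3 - 1e-9, 50), S3, tolerance = 1e-7)
})

test_that("Gaussian-chain intensity has Debye limits and Guinier-recoverable Rg", {
  q <- seq(1e-4, 0.5, length.out = 400)
  I <- gaussian_chain_intensity(q, Rg = 30, I0 = 0.0244)
  expect_equal(I[1], 0.0244, tolerance = 1e-4)
  expect_equal(gaussian_chain_intensity(1 / 30, 30, 1), 2 / exp(1),
               tolerance = 1e-9)                     # x = 1 closed form
  expect_true(all(diff(I) < 0))
  # large-x asymptote I0 * 2/x
  x_big <- (0.5 * 30)^2
  expect_equal(I[length(I)], 0.0244 * 2 * (x_big - 1) / x_big^2,
               tolerance = 1e-3)
  # flexible chains need a narrower Guinier window than globular bodies
  g <- suppressWarnings(guinier_fit(saxs_curve(q, I, 0.01 * I),
                                    qrg_limit = 0.8))
  expect_equal(g$Rg, 30, tolerance = 0.03)
})
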