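test_that("aggregation numbers reproduce the micelle arithmetic", {
  expect_equal(aggregation_number(22.7, 0.60), 84.0, tolerance = 0.002)
  expect_equal(aggregation_number(21.0, 0.64), 70.9, tolerance = 0.002)
  # one chain exactly fills a sphere of its own volume
  v <- default_contrasts()$v_chain
  expect_equal(aggregation_number((3 * v / (4 * pi))^(1 / 3), 1), 1,
               tolerance = 1e-12)
})

test_that("contrast bookkeeping conserves shell volume and detects overfill", {
  cs <- default_contrasts()
  p <- as.list(complex_preset("sds10.5"))
  cc <- complex_contrasts(p$Rcore, p$eps, p$Dhead, p$Npro)
  expect_true(is.finite(cc$k1) && is.finite(cc$k2))
  expect_gt((cc$k1 + cc$k2)^2, 0)
  expect_true(cc$water_fraction >= 0 && cc$water_fraction < 1)
  # exact volume balance: shell = heads + protein + water
  eps1 <- eps_outer_from_core(p$Rcore, p$eps, p$Dhead)
  v_shell <- (4 * pi / 3) * (eps1 * (p$Rcore + p$Dhead)^3 -
                               p$eps * p$Rcore^3)
  v_parts <- cc$N_agg * cs$v_head_sds + p$Npro * cs$v_protein +
    cc$water_fraction * v_shell
  expect_equal(v_parts, v_shell, tolerance = 1e-12)

  # hand bookkeeping oracle for k1: shell excess length from components
  b_excess <- cc$N_agg * (cs$b_head_sds - cs$rho_solvent * cs$v_head_sds * 1e-24) +
    p$Npro * (cs$b_protein - cs$rho_solvent * cs$v_protein * 1e-24)
  v1 <- (4 * pi / 3) * eps1 * (p$Rcore + p$Dhead)^3 * 1e-24
  expect_equal(cc$k1, v1 * b_excess / (v_shell * 1e-24), tolerance = 1e-12)

  # a shell of pure water has zero contrast
  cs0 <- default_contrasts(b_head_sds = cs$rho_solvent * cs$v_head_sds * 1e-24)
  cc0 <- complex_contrasts(p$Rcore, p$eps, p$Dhead, 0, contrasts = cs0)
  expect_equal(cc0$k1, 0, tolerance = 1e-30)

  # more protein in the same shell raises the shell amplitude
  k1s <- vapply(c(0.5, 1, 1.5), function(np)
    complex_contrasts(p$Rcore, p$eps, p$Dhead, np)$k1, numeric(1))
  expect_true(all(diff(k1s) > 0))

  expect_error(complex_contrasts(p$Rcore, p$eps, 2, 5), "overfilled")
})

test_that("number density converts bound surfactant to absolute scale", {
  expect_equal(number_density(1, 0, 100, 1)$n, 6.022e15)
  expect_equal(number_density(5, 5, 70)$n, 0)
  nd <- number_density(10.5, 3.7, 55.4, 1, Npro = 0.98)
  expect_lt(abs(nd$c_protein_implied - 2) / 2, 0.2)
})

test_that("absolute-scale consistency: I(0) inverts back to the bound concentration", {
  mp <- micelle_preset("sds", C_total = 10, C_free = 2)
  cc <- complex_contrasts(mp$Rcore, mp$eps, mp$Dhead, 0)
  nd <- number_density(mp$C_total, mp$C_free, cc$N_agg)
  I0 <- nd$n * (cc$k1 + cc$k2)^2
  # invert: number density from I(0), then bound concentration
  n_back <- I0 / (cc$k1 + cc$k2)^2
  C_bound <- n_back * cc$N_agg / 6.022e17
  expect_equal(C_bound, 8, tolerance = 1e-12)
})

test_that("SDS mole fraction matches the refolding mixing conditions", {
  expect_equal(chi_sds(8.5, 10.4), 0.45, tolerance = 0.01)
  expect_equal(chi_sds(8.5, 19.8), 0.30, tolerance = 0.01)
  expect_equal(chi_sds(5, 0), 1)
  expect_error(chi_sds(0, 0), "zero")
})

test_that("Gaussian-chain prefactor reproduces the absolute forward scattering", {
  expect_equal(gaussian_chain_prefactor(2, 18300, 2.0e10), 0.0244,
               tolerance = 0.005)
  expect_equal(gaussian_chain_prefactor(0), 0)
  expect_equal(gaussian_chain_prefactor(4), 2 * gaussian_chain_prefactor(2),
               tolerance = 1e-12)
})

test_that("contrast table round-trips through its config file", {
  cs <- default_contrasts(v_chain = 360)
  path <- withr::local_tempfile(fileext = ".csv")
  write_contrasts(cs, path)
  back <- read_contrasts(path)
  expect_equal(back, cs)
  expect_error(default_contrasts(nonsense = 1), "unknown")
})
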