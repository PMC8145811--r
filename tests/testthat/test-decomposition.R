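# noise-free basis on a common grid, built from the package's own models
make_basis <- function(q = fixture_q(150), sigma_rel = 1e-4) {
  Ic <- complex_intensity(q, complex_preset("sds10.5"))
  mp <- micelle_preset("mixed", chi_sds = 0.45, C_total = 15)
  Im <- micelle_intensity(q, mp[c("Rcore", "eps", "Dhead", "C_total",
                                  "C_free")],
                          surfactant = "mixed", chi_sds = 0.45)
  In <- 0.9 * Ic + 0.3 * Im   # any smooth distinct positive curve works
  saxs_basis(
    complex = saxs_curve(q, Ic, sigma_rel * Ic),
    micelle = saxs_curve(q, Im, sigma_rel * Im),
    native = saxs_curve(q, In, sigma_rel * In),
    chain_I0 = gaussian_chain_prefactor(2))
}

test_that("a pure-complex frame decomposes to a1 = 1 at zero noise", {
  q <- fixture_q(150)
  basis <- make_basis(q)
  frame <- saxs_curve(q, basis$complex$I, 0.01 * basis$complex$I)
  d <- decompose_frame(frame, basis)
  est <- setNames(d$scales$estimate, d$scales$term)
  expect_equal(est[["a1"]], 1, tolerance = 1e-10)
  expect_equal(est[["a2"]], 0, tolerance = 1e-10)
  expect_equal(est[["a3"]], 0, tolerance = 1e-10)
  expect_equal(est[["a4"]], 0, tolerance = 1e-10)
  expect_lt(d$chi2_red, 1e-10)
})

test_that("constructed mixtures are recovered within uncertainty", {
  q <- fixture_q(150)
  basis <- make_basis(q)
  I4 <- gaussian_chain_intensity(q, 30, basis$chain_I0)
  I_true <- 0.5 * basis$complex$I + 0.3 * basis$native$I + 0.2 * I4 +
    0.7 * basis$micelle$I
  frame <- add_noise(saxs_curve(q, I_true, 0.01 * I_true),
                     f_rel = 0.01, seed = 4)
  d <- decompose_frame(frame, basis, Rg = 30,
                       include_measurement_sigma = TRUE)
  est <- setNames(d$scales$estimate, d$scales$term)
  sds <- setNames(d$scales$std.error, d$scales$term)
  expect_lt(abs(est[["a1"]] - 0.5), 2 * sds[["a1"]] + 0.02)
  expect_lt(abs(est[["a3"]] - 0.3), 2 * sds[["a3"]] + 0.02)
  expect_lt(abs(est[["a4"]] - 0.2), 2 * sds[["a4"]] + 0.02)
  expect_lt(abs(est[["a2"]] - 0.7), 2 * sds[["a2"]] + 0.02)
  # conservation holds exactly
  expect_equal(est[["a1"]] + est[["a3"]] + est[["a4"]], 1,
               tolerance = 1e-12)
})

test_that("a constant background is absorbed by the offset scale", {
  q <- fixture_q(150)
  basis <- make_basis(q)
  off <- 0.002
  frame <- saxs_curve(q, basis$native$I + off, 0.01 * basis$native$I)
  d <- decompose_frame(frame, basis)
  est <- setNames(d$scales$estimate, d$scales$term)
  expect_equal(est[["a3"]], 1, tolerance = 1e-6)
  expect_equal(est[["a5"]], off, tolerance = 1e-6)
})

test_that("two-step chi-squared corrects the basis-noise bias", {
  q <- fixture_q(150)
  bnoise <- 0.02
  clean <- make_basis(q)
  noisy_basis <- saxs_basis(
    complex = add_noise(saxs_curve(q, clean$complex$I,
                                   bnoise * clean$complex$I),
                        f_rel = bnoise, q_c = 10, m = 2, seed = 31),
    micelle = add_noise(saxs_curve(q, clean$micelle$I,
                                   bnoise * clean$micelle$I),
                        f_rel = bnoise, q_c = 10, m = 2, seed = 32),
    native = add_noise(saxs_curve(q, clean$native$I,
                                  bnoise * clean$native$I),
                       f_rel = bnoise, q_c = 10, m = 2, seed = 33),
    chain_I0 = clean$chain_I0)
  # frame built from the TRUE curves with small measurement noise: the
  # residual against the noisy basis is dominated by basis noise
  I_true <- 0.6 * clean$complex$I + 0.4 * clean$native$I +
    0.5 * clean$micelle$I
  frame <- add_noise(saxs_curve(q, I_true, 0.002 * I_true),
                     f_rel = 0.002, q_c = 10, seed = 35)
  d <- decompose_frame(frame, noisy_basis, include_measurement_sigma = TRUE)
  # step 1 ignores basis noise and inflates chi2; step 2 restores ~1
  expect_gt(d$chi2_red_step1, 3)
  expect_gt(d$chi2_red, 0.6)
  expect_lt(d$chi2_red, 1.6)
})

test_that("fractions are invariant under a common rescaling", {
  q <- fixture_q(120)
  basis <- make_basis(q)
  I4 <- gaussian_chain_intensity(q, 30, basis$chain_I0)
  I_true <- 0.4 * basis$complex$I + 0.6 * basis$native$I +
    0.2 * basis$micelle$I
  frame <- add_noise(saxs_curve(q, I_true, 0.01 * I_true),
                     f_rel = 0.01, seed = 9)
  d1 <- decompose_frame(frame, basis)
  fac <- 7.3
  scale_curve <- function(cv) saxs_curve(cv$q, fac * cv$I, fac * cv$sigma)
  basis2 <- saxs_basis(scale_curve(basis$complex), scale_curve(basis$micelle),
                       scale_curve(basis$native),
                       chain_I0 = fac * basis$chain_I0)
  frame2 <- scale_curve(frame)
  d2 <- decompose_frame(frame2, basis2)
  expect_equal(d2$scales$estimate[1:4], d1$scales$estimate[1:4],
               tolerance = 1e-8)
})

test_that("an all-micelle frame is flagged as degenerate", {
  q <- fixture_q(120)
  basis <- make_basis(q)
  frame <- saxs_curve(q, 0.8 * basis$micelle$I, 0.01 * basis$micelle$I)
  expect_warning(d <- decompose_frame(frame, basis), "degenerate")
  expect_true(d$degenerate)
})

test_that("series decomposition follows the chain-Rg schedule and recovers truth", {
  sc <- refolding_scenario(chi = 0.45, n_frames = 12, t_end = 2000,
                           noise = 0.005, seed = 6)
  sim <- simulate_refolding_series(sc, q = fixture_q(150))
  res <- decompose_series(sim$frames, sim$basis, Rg = 30, Rg_early = 40,
                          t_early = 0.3)
  expect_equal(nrow(res), 12L)
  expect_true(all(res$Rg_used[res$time_s < 0.3] == 40))
  expect_true(all(res$Rg_used[res$time_s >= 0.3] == 30))
  expect_equal(res$a1 + res$a3 + res$a4, rep(1, 12), tolerance = 1e-12)
  expect_lt(max(abs(res$a1 - sim$truth$a1)), 0.05)
  expect_lt(max(abs(res$a4 - sim$truth$a4)), 0.05)
})
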