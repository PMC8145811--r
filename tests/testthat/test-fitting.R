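truth_params <- function(preset) {
  p <- as.list(complex_preset(preset))
  saxs_params(
    Rcore = c(p$Rcore, 3, 30),
    eps = lock(p$eps),
    Dhead = c(p$Dhead, 4, 40),
    s_frac = c(p$s / p$Dhead, 0, 1),
    Npro = c(p$Npro, 0.05, 12),
    Nmic = lock(p$Nmic),
    Dmic = lock(p$Dmic),
    C_total = lock(p$C_total),
    C_free = lock(p$C_free))
}

test_that("fitting noise-free data from the truth is a fixed point", {
  cv <- fixture_complex_curve("sds7.3")
  fit <- fit_curve(cv, complex_model(), truth_params("sds7.3"), starts = 1)
  expect_true(fit$converged)
  expect_lt(fit$chi2_red, 1e-10)
  p <- as.list(complex_preset("sds7.3"))
  expect_equal(fitted_value(fit, "Rcore"), p$Rcore, tolerance = 1e-6)
  expect_equal(fitted_value(fit, "Npro"), p$Npro, tolerance = 1e-6)
})

test_that("locked parameters never move and all-locked fits skip optimization", {
  cv <- fixture_complex_curve("sds10.5")
  params <- truth_params("sds10.5")
  fit <- fit_curve(cv, complex_model(), params, starts = 2, seed = 3)
  expect_identical(fitted_value(fit, "eps"), 1.8)
  expect_identical(fitted_value(fit, "Dmic"), 50)
  expect_true(all(is.na(fit$params$sd[fit$params$locked])))

  locked_all <- saxs_params(
    Rcore = lock(13.7), eps = lock(1.8), Dhead = lock(10.1),
    s_frac = lock(1.9 / 10.1), Npro = lock(0.98), Nmic = lock(1),
    Dmic = lock(50), C_total = lock(10.5), C_free = lock(3.7))
  f2 <- fit_curve(cv, complex_model(), locked_all)
  expect_identical(f2$p, 0L)
  expect_identical(f2$niter, 0L)
  expect_true(is.finite(f2$chi2_red))
})

test_that("fits are deterministic given the seed", {
  cv <- add_noise(fixture_complex_curve("sds10.5"), f_rel = 0.01, seed = 11)
  params <- truth_params("sds10.5")
  params$value[params$name == "Rcore"] <- 10   # start away from truth
  f1 <- fit_curve(cv, complex_model(), params, starts = 4, seed = 5)
  f2 <- fit_curve(cv, complex_model(), params, starts = 4, seed = 5)
  expect_identical(f1$params$value, f2$params$value)
  expect_identical(f1$chi2, f2$chi2)
})

test_that("end-state parameters are recovered from noisy data within 3 sigma", {
  # saturated-complex end state with 1% noise; free geometry + stoichiometry
  cv <- add_noise(fixture_complex_curve("sds10.5"), f_rel = 0.01, seed = 21)
  params <- truth_params("sds10.5")
  params$value[!params$locked] <- c(10, 12, 0.5, 1.5)  # generic starts
  fit <- fit_curve(cv, complex_model(), params, starts = 8, seed = 1)
  expect_true(fit$converged)
  expect_gt(fit$chi2_red, 0.7)
  expect_lt(fit$chi2_red, 1.4)
  p <- as.list(complex_preset("sds10.5"))
  expect_lt(abs(fitted_value(fit, "Rcore") - p$Rcore),
            3 * fitted_sd(fit, "Rcore") + 0.05 * p$Rcore)
  expect_lt(abs(fitted_value(fit, "Npro") - p$Npro), 0.05 * p$Npro)
})

test_that("series fitting recovers generator trajectories with warm starts", {
  sc <- unfolding_scenario("sds10.5", n_frames = 25, t_end = 30, seed = 2)
  sim <- simulate_unfolding_series(sc, q = fixture_q(200))
  res <- fit_unfolding_series(sim$frames, unfold_protocol("sds10.5"),
                              starts = 6, seed = 1)
  expect_equal(nrow(res), 25L)
  expect_true(all(res$converged))
  # median relative error of the free parameters against the truth table
  rel_err <- function(est, truth) stats::median(abs(est - truth) / truth)
  expect_lt(rel_err(res$Npro, sim$truth$Npro), 0.05)
  expect_lt(rel_err(res$Nmic, sim$truth$Nmic), 0.05)
  # chi2_red near 1 for a correctly specified model
  expect_gt(stats::median(res$chi2_red), 0.7)
  expect_lt(stats::median(res$chi2_red), 1.4)
  # coverage: truth inside +-2 sd most of the time for Npro
  cover <- mean(abs(res$Npro - sim$truth$Npro) <= 2 * res$Npro_sd)
  expect_gte(cover, 0.8)
})

test_that("a series of identical frames yields identical warm-started fits", {
  cv <- fixture_complex_curve("sds7.3")
  frames <- lapply(1:3, function(i) {
    attr(cv, "time_s") <- 0.01 * i
    cv
  })
  res <- fit_unfolding_series(frames, unfold_protocol("sds7.3"),
                              starts = 4, seed = 1)
  expect_equal(res$Npro[2], res$Npro[1], tolerance = 1e-9)
  expect_equal(res$Npro[3], res$Npro[2], tolerance = 1e-9)
})
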