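test_that("noise injection is unbiased, seeded and q-dependent", {
  cv <- fixture_complex_curve("sds10.5", q = fixture_q(80))
  # f_rel = 0 is the identity
  same <- add_noise(cv, f_rel = 0, seed = 1)
  expect_equal(same$I, cv$I)
  # fixed seed reproduces bit-identically
  n1 <- add_noise(cv, seed = 42)
  n2 <- add_noise(cv, seed = 42)
  expect_identical(n1$I, n2$I)
  expect_false(identical(add_noise(cv, seed = 43)$I, n1$I))
  # sigma column carries the generating model
  expect_equal(n1$sigma, 0.01 * cv$I * (1 + (cv$q / 0.2)^2))
  # Monte-Carlo mean reverts to the input curve within 3 standard errors
  n_rep <- 2000
  acc <- matrix(0, n_rep, 3)
  idx <- c(1, 40, 80)
  for (i in seq_len(n_rep))
    acc[i, ] <- add_noise(cv, seed = 1000 + i)$I[idx]
  se <- apply(acc, 2, stats::sd) / sqrt(n_rep)
  expect_true(all(abs(colMeans(acc) - cv$I[idx]) <= 3 * se))
})

test_that("unfolding generator honors limits, truth table and determinism", {
  # all half-times ~0: every frame is the end-state curve
  sc0 <- unfolding_scenario("sds7.3", n_frames = 4, noise = 0,
                            halftimes = list(Npro = 1e-12, Nmic = 1e-12,
                                             s = 1e-12))
  sim0 <- simulate_unfolding_series(sc0, q = fixture_q(60))
  end <- fixture_complex_curve("sds7.3", q = fixture_q(60))
  for (fr in sim0$frames) expect_equal(fr$I, end$I, tolerance = 1e-10)

  sc <- unfolding_scenario("sds10.5", n_frames = 8, seed = 5)
  sim <- simulate_unfolding_series(sc, q = fixture_q(60))
  # schedule starts at the deadtime and is strictly increasing
  expect_equal(sim$truth$time_s[1], 0.004)
  expect_true(all(diff(sim$truth$time_s) > 0))
  # truth table matches the stated relaxation law
  expect_equal(sim$truth$Npro,
               sc$end$Npro + (sc$initial$Npro0 - sc$end$Npro) *
                 exp(-sim$truth$time_s * log(2) / sc$halftimes$Npro),
               tolerance = 1e-12)
  # geometry constraint holds on every frame
  expect_true(all(sim$truth$s <= sim$truth$Dhead + 1e-12))
  # determinism
  sim2 <- simulate_unfolding_series(unfolding_scenario("sds10.5",
                                                       n_frames = 8,
                                                       seed = 5),
                                    q = fixture_q(60))
  expect_identical(sim$frames[[3]]$I, sim2$frames[[3]]$I)
})

test_that("refolding generator conserves mass and satisfies the linear model", {
  sc <- refolding_scenario(chi = 0.45, n_frames = 6, t_end = 1000,
                           noise = 0, seed = 3)
  sim <- simulate_refolding_series(sc, q = fixture_q(100), basis_noise = 0)
  expect_equal(sim$truth$a1 + sim$truth$a3 + sim$truth$a4,
               rep(1, 6), tolerance = 1e-12)
  # zero-noise frames decompose to the truth scales almost exactly
  d <- decompose_frame(sim$frames[[3]], sim$basis,
                       Rg = sim$truth$Rg[3])
  est <- setNames(d$scales$estimate, d$scales$term)
  expect_equal(est[["a1"]], sim$truth$a1[3], tolerance = 1e-9)
  expect_equal(est[["a3"]], sim$truth$a3[3], tolerance = 1e-9)
  expect_equal(est[["a4"]], sim$truth$a4[3], tolerance = 1e-9)

  # static limit: no burst coil, infinite half-times
  scs <- refolding_scenario(chi = 0.45, burst_complex = 1, burst_coil = 0,
                            t_half_complex = Inf, t_half_coil = Inf,
                            n_frames = 3, noise = 0)
  sims <- simulate_refolding_series(scs, q = fixture_q(60), basis_noise = 0)
  expect_equal(sims$frames[[1]]$I, sims$frames[[3]]$I, tolerance = 1e-12)
})

test_that("kinetic trace generator is exact at zero noise and seeded", {
  t <- exp(seq(log(0.01), log(30), length.out = 100))
  sim <- simulate_kinetic_trace(c(1, -0.4), c(0.3, 3), y_inf = 2, t = t,
                                noise = 0)
  y_exact <- 2 + exp(-t * log(2) / 0.3) - 0.4 * exp(-t * log(2) / 3)
  expect_equal(sim$trace$y, y_exact, tolerance = 1e-12)
  s1 <- simulate_kinetic_trace(1, 2, noise = 0.01, seed = 9)
  s2 <- simulate_kinetic_trace(1, 2, noise = 0.01, seed = 9)
  expect_identical(s1$trace$y, s2$trace$y)
})

test_that("generators write machine-readable series and truth tables", {
  dir <- withr::local_tempdir()
  sc <- unfolding_scenario("sds2.0", n_frames = 3, seed = 1)
  simulate_unfolding_series(sc, q = fixture_q(40), dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "truth.csv")))
  back <- suppressMessages(read_series(file.path(dir, "manifest.csv")))
  expect_length(back, 3L)
  truth <- readr::read_csv(file.path(dir, "truth.csv"),
                           show_col_types = FALSE)
  expect_equal(truth$time_s,
               vapply(back, function(x) attr(x, "time_s"), numeric(1)),
               tolerance = 1e-9)
})
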