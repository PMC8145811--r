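#' Default q grid for synthetic stopped-flow frames
#' @param n Number of points.
#' @param q_min,q_max Range, 1/Angstrom.
#' @return Numeric vector.
#' @export
default_q_grid <- function(n = 300, q_min = 0.005, q_max = 0.4) {
  seq(q_min, q_max, length.out = n)
}

#' Log-spaced stopped-flow frame schedule
#'
#' Frame mid-times growing exponentially from the instrument deadtime,
#' matching a stopped-flow acquisition where most frames are taken right
#' after mixing and wait times grow toward the end of the series.
#'
#' @param n_frames Number of frames.
#' @param t_end Last frame time, seconds.
#' @param deadtime_s Instrument deadtime, seconds (default 4 ms).
#' @return Strictly increasing numeric vector starting at `deadtime_s`.
#' @export
frame_schedule <- function(n_frames = 30, t_end = 60, deadtime_s = 0.004) {
  stopifnot(n_frames >= 1, t_end > deadtime_s)
  exp(seq(log(deadtime_s), log(t_end), length.out = n_frames))
}

#' Add counting-statistics-like noise to a scattering curve
#'
#' The relative noise grows toward high q, where counts fall:
#' \eqn{\sigma(q) = f_{rel} I(q) (1 + (q/q_c)^m)}; the noisy intensity is
#' drawn Gaussian around the input curve and the sigma column carries the
#' true sigma. A multiplicative-Gaussian model is appropriate for
#' reduced absolute-scale curves (rather than Poisson on raw counts).
#'
#' @param curve A [saxs_curve()].
#' @param f_rel Relative noise at low q (default 0.01).
#' @param q_c Crossover q, 1/Angstrom (default 0.2).
#' @param m Power of the high-q growth (default 2).
#' @param seed Integer seed.
#' @return A noisy [saxs_curve()] with the same attributes.
#' @export
add_noise <- function(curve, f_rel = 0.01, q_c = 0.2, m = 2, seed = 1) {
  validate_curve(curve)
  stopifnot(all(curve$I >= 0))
  sig <- f_rel * curve$I * (1 + (curve$q / q_c)^m)
  if (f_rel == 0)
    return(saxs_curve(curve$q, curve$I, curve$sigma,
                      time_s = attr(curve, "time_s"),
                      label = attr(curve, "label")))
  noisy <- curve$I + with_seed(seed, stats::rnorm(nrow(curve), 0, sig))
  saxs_curve(curve$q, noisy, sig,
             time_s = attr(curve, "time_s"),
             label = attr(curve, "label"))
}

# exponential relaxation toward an end state
relax <- function(t, p0, p_end, t_half) {
  if (!is.finite(t_half) || t_half <= 0) return(rep(p_end, length(t)))
  p_end + (p0 - p_end) * exp(-t * log(2) / t_half)
}

#' Define an unfolding scenario
#'
#' End-state geometry/composition from a [complex_preset()] row, initial
#' overrides for the parameters that relax over the series, and
#' per-parameter relaxation half-times. Defaults mirror the measured
#' unfolding series: strong initial clustering (several proteins and
#' micelles per cluster) and a large initial core displacement, both
#' decaying exponentially; the proteins-per-complex and displacement
#' half-times default to the values recovered from the corresponding
#' measured series (0.36/1.38 s at 10.5 mM, 0.51/1.17 s at 7.3 mM,
#' 0.97/1.25 s at 4.1 mM, 0.84 s at 2.0 mM where the displacement stays
#' constant). The 4.1 mM scenario additionally relaxes the shell
#' thickness from 24.2 to 13.2 Angstrom and the core radius from 13.3 to
#' 8.8 Angstrom.
#'
#' @param preset One of the [complex_preset()] names.
#' @param n_frames,t_end,deadtime_s Frame schedule, [frame_schedule()].
#' @param noise Relative noise level passed to [add_noise()] (`f_rel`).
#' @param seed Integer seed.
#' @param initial Named list overriding initial values
#'   (`Npro0`, `Nmic0`, `s0`, `Dhead0`, `Rcore0`).
#' @param halftimes Named list overriding relaxation half-times, seconds
#'   (`Npro`, `Nmic`, `s`, `Dhead`, `Rcore`).
#' @return A list of class `unfolding_scenario`.
#' @export
unfolding_scenario <- function(preset = "sds10.5", n_frames = 30,
                               t_end = 60, deadtime_s = 0.004,
                               noise = 0.01, seed = 1,
                               initial = list(), halftimes = list()) {
  ep <- as.list(complex_preset(preset))
  t_np <- switch(preset, "sds10.5" = 0.36, "sds7.3" = 0.51,
                 "sds4.1" = 0.97, "sds2.0" = 0.84)
  t_s <- switch(preset, "sds10.5" = 1.38, "sds7.3" = 1.17,
                "sds4.1" = 1.25, "sds2.0" = Inf)
  # initial proteins-per-complex capped by what the shell can hold
  # (90% occupancy of the non-head shell volume at the initial geometry)
  cs <- default_contrasts()
  Dhead0 <- if (preset == "sds4.1") 24.2 else ep$Dhead
  Rcore0 <- if (preset == "sds4.1") 13.3 else ep$Rcore
  eps1_0 <- eps_outer_from_core(Rcore0, ep$eps, Dhead0)
  v_shell0 <- (4 * pi / 3) * (eps1_0 * (Rcore0 + Dhead0)^3 -
                                ep$eps * Rcore0^3)
  n_agg0 <- aggregation_number(Rcore0, ep$eps, cs$v_chain)
  npro_max <- 0.9 * (v_shell0 - n_agg0 * cs$v_head_sds) / cs$v_protein
  init <- list(Npro0 = min(5 * ep$Npro, npro_max), Nmic0 = 3,
               s0 = 0.8 * ep$Dhead, Dhead0 = ep$Dhead, Rcore0 = ep$Rcore)
  ht <- list(Npro = t_np, Nmic = t_np, s = t_s, Dhead = Inf, Rcore = Inf)
  if (preset == "sds2.0") init$s0 <- ep$s       # displacement stays constant
  if (preset == "sds4.1") {
    init$Dhead0 <- 24.2; init$Rcore0 <- 13.3
    ht$Dhead <- t_s; ht$Rcore <- t_s
  }
  init[names(initial)] <- initial
  ht[names(halftimes)] <- halftimes
  stopifnot(all(unlist(ht) > 0), noise >= 0)
  structure(list(preset = preset, end = ep, initial = init, halftimes = ht,
                 n_frames = n_frames, t_end = t_end,
                 deadtime_s = deadtime_s, noise = noise, seed = seed),
            class = "unfolding_scenario")
}

#' Simulate a stopped-flow unfolding frame series
#'
#' Every model parameter relaxes exponentially from its initial value to
#' the end state, \eqn{p(t) = p_{end} + (p_0 - p_{end}) e^{-t \ln 2 /
#' t_{1/2}}}; each frame is the absolute-scale displaced-core model
#' curve at the frame's parameters plus counting-statistics-like noise.
#' The core displacement is clipped to the geometric bound `s <= Dhead`.
#'
#' @param sc An [unfolding_scenario()].
#' @param q q grid (default [default_q_grid()]).
#' @param dir Optional directory: frames, manifest and truth table are
#'   written there as .dat/CSV files.
#' @return A list with `frames` (list of noisy [saxs_curve()]),
#'   `truth` (tibble of true per-frame parameters) and `manifest`.
#' @export
simulate_unfolding_series <- function(sc, q = default_q_grid(), dir = NULL) {
  stopifnot(inherits(sc, "unfolding_scenario"))
  times <- frame_schedule(sc$n_frames, sc$t_end, sc$deadtime_s)
  ep <- sc$end; init <- sc$initial; ht <- sc$halftimes
  truth <- tibble::tibble(
    frame = seq_along(times),
    time_s = times,
    Npro = relax(times, init$Npro0, ep$Npro, ht$Npro),
    Nmic = pmax(relax(times, init$Nmic0, ep$Nmic, ht$Nmic), 1),
    Dhead = relax(times, init$Dhead0, ep$Dhead, ht$Dhead),
    Rcore = relax(times, init$Rcore0, ep$Rcore, ht$Rcore),
    eps = ep$eps, Dmic = ep$Dmic,
    C_total = ep$C_total, C_free = ep$C_free)
  truth$s <- pmin(relax(times, init$s0, ep$s, ht$s), truth$Dhead)
  frames <- purrr::map(seq_along(times), function(i) {
    p <- as.list(truth[i, c("Rcore", "eps", "Dhead", "s", "Npro", "Nmic",
                            "Dmic", "C_total", "C_free")])
    I <- complex_intensity(q, p)
    cv <- saxs_curve(q, I, sigma = pmax(1e-12, 0.01 * abs(I)),
                     time_s = times[i],
                     label = sprintf("%s unfolding frame %d", sc$preset, i))
    add_noise(cv, f_rel = sc$noise, seed = sc$seed + i)
  })
  man <- tibble::tibble(file = sprintf("frame_%03d.dat", seq_along(times)),
                        time_s = times)
  if (!is.null(dir)) {
    write_series(frames, dir)
    readr::write_csv(truth, file.path(dir, "truth.csv"))
  }
  list(frames = frames, truth = truth, manifest = man, scenario = sc)
}

#' Define a refolding scenario
#'
#' Burst-phase species fractions at the first frame and conversion
#' half-times for the two refolding routes: unfolded random coil folding
#' to the native state, and residual protein-SDS complexes converting to
#' native protein. Defaults follow the measured refolding series: at an
#' SDS mole fraction of 0.45 the complex-to-native half-time is ~1110 s
#' and the coil route ~242 s; at 0.30 the conversions are faster (~385 s
#' and ~101 s) and the burst-phase disruption of complexes larger. The
#' burst fractions themselves are scenario parameters (defaults 0.55/0.45
#' complex/coil at 0.45 and 0.40/0.60 at 0.30).
#'
#' @param chi SDS mole fraction, 0.45 or 0.30 (selects defaults); other
#'   values allowed with explicit arguments.
#' @param burst_complex,burst_coil Fractions at t = 0 (sum <= 1; the
#'   remainder starts native).
#' @param t_half_complex,t_half_coil Conversion half-times, seconds.
#' @param Rg,Rg_early Chain radius of gyration schedule, Angstrom.
#' @param n_frames,t_end,deadtime_s Frame schedule.
#' @param noise Relative noise level.
#' @param seed Integer seed.
#' @return A list of class `refolding_scenario`.
#' @export
refolding_scenario <- function(chi = 0.45,
                               burst_complex = NULL, burst_coil = NULL,
                               t_half_complex = NULL, t_half_coil = NULL,
                               Rg = 30, Rg_early = 40,
                               n_frames = 60, t_end = 3000,
                               deadtime_s = 0.004, noise = 0.01, seed = 1) {
  near <- function(a, b) isTRUE(abs(a - b) < 1e-6)
  if (is.null(burst_complex)) burst_complex <- if (near(chi, 0.30)) 0.40 else 0.55
  if (is.null(burst_coil)) burst_coil <- if (near(chi, 0.30)) 0.60 else 0.45
  if (is.null(t_half_complex)) t_half_complex <- if (near(chi, 0.30)) 385 else 1110
  if (is.null(t_half_coil)) t_half_coil <- if (near(chi, 0.30)) 101 else 242
  stopifnot(burst_complex >= 0, burst_coil >= 0,
            burst_complex + burst_coil <= 1,
            t_half_complex > 0, t_half_coil > 0, noise >= 0)
  structure(list(chi = chi, burst_complex = burst_complex,
                 burst_coil = burst_coil,
                 t_half_complex = t_half_complex,
                 t_half_coil = t_half_coil,
                 Rg = Rg, Rg_early = Rg_early,
                 n_frames = n_frames, t_end = t_end,
                 deadtime_s = deadtime_s, noise = noise, seed = seed),
            class = "refolding_scenario")
}

# default basis curves for the refolding simulation: complex at the
# saturated end state, mixed micelles at the scenario's mole fraction,
# native protein from a synthetic monomer/dimer bead mixture at 2 mg/mL
refolding_basis_curves <- function(sc, q, contrasts = default_contrasts()) {
  I_complex <- complex_intensity(q, complex_preset("sds10.5"),
                                 contrasts = contrasts)
  mp <- micelle_preset("mixed", chi_sds = sc$chi, C_total = 15)
  I_micelle <- micelle_intensity(q, mp[c("Rcore", "eps", "Dhead",
                                         "C_total", "C_free")],
                                 contrasts = contrasts,
                                 surfactant = "mixed", chi_sds = sc$chi)
  mono <- synthetic_globule(162, seed = 101)
  dimer <- synthetic_dimer(mono)
  Im <- debye_intensity(mono, q, c_protein = 2,
                        mass = contrasts$protein_mass)
  Id <- debye_intensity(dimer, q, c_protein = 2,
                        mass = 2 * contrasts$protein_mass)
  I_native <- 0.23 * Im$I + 0.77 * Id$I
  list(complex = I_complex, micelle = I_micelle, native = I_native)
}

#' Simulate a stopped-flow refolding frame series with basis curves
#'
#' Species mass fractions evolve as two exponential conversions into the
#' native state: the complex fraction
#' \eqn{a_1(t) = a_{1,burst} 2^{-t/t_{1/2,complex}}}, the coil fraction
#' \eqn{a_4(t) = a_{4,burst} 2^{-t/t_{1/2,coil}}}, and
#' \eqn{a_3 = 1 - a_1 - a_4}, so the truth fractions conserve protein
#' mass exactly on every frame. Each frame is
#' \eqn{a_1 I_{complex} + a_2 I_{micelle} + a_3 I_{native} + a_4
#' I_{chain}(R_g(t))} plus noise; the basis curves are written with their
#' own (smaller) noise realizations and sigma columns, as measured basis
#' data would be.
#'
#' @param sc A [refolding_scenario()].
#' @param q q grid.
#' @param contrasts Contrast table.
#' @param basis_noise Relative noise on the basis curves (default
#'   0.005, i.e. better-averaged than the frames).
#' @param dir Optional output directory.
#' @return A list with `frames`, `basis` (a [saxs_basis()]), `truth`
#'   (per-frame fractions and chain Rg) and `manifest`.
#' @export
simulate_refolding_series <- function(sc, q = default_q_grid(),
                                      contrasts = default_contrasts(),
                                      basis_noise = 0.005, dir = NULL) {
  stopifnot(inherits(sc, "refolding_scenario"))
  times <- frame_schedule(sc$n_frames, sc$t_end, sc$deadtime_s)
  bc <- refolding_basis_curves(sc, q, contrasts)
  chain_I0 <- gaussian_chain_prefactor(2,
                                       mass = contrasts$protein_mass,
                                       drho_m = contrasts$drho_m)
  a1 <- sc$burst_complex * 2^(-times / sc$t_half_complex)
  a4 <- sc$burst_coil * 2^(-times / sc$t_half_coil)
  a3 <- 1 - a1 - a4
  a2 <- rep(1, length(times))
  rg_t <- ifelse(times < 0.3, sc$Rg_early, sc$Rg)
  truth <- tibble::tibble(frame = seq_along(times), time_s = times,
                          a1 = a1, a2 = a2, a3 = a3, a4 = a4,
                          Rg = rg_t)
  frames <- purrr::map(seq_along(times), function(i) {
    I <- a1[i] * bc$complex + a2[i] * bc$micelle + a3[i] * bc$native +
      a4[i] * gaussian_chain_intensity(q, Rg = rg_t[i], I0 = chain_I0)
    cv <- saxs_curve(q, I, sigma = pmax(1e-12, 0.01 * abs(I)),
                     time_s = times[i],
                     label = sprintf("refolding chi=%.2f frame %d", sc$chi, i))
    add_noise(cv, f_rel = sc$noise, seed = sc$seed + i)
  })
  mk_basis <- function(I, lab, off) {
    cv <- saxs_curve(q, I, sigma = pmax(1e-12, 0.005 * abs(I)), label = lab)
    add_noise(cv, f_rel = basis_noise, seed = sc$seed + 10000 + off)
  }
  basis <- saxs_basis(
    complex = mk_basis(bc$complex, "basis_complex", 1),
    micelle = mk_basis(bc$micelle, "basis_micelle", 2),
    native = mk_basis(bc$native, "basis_native", 3),
    chain_I0 = chain_I0)
  man <- tibble::tibble(file = sprintf("frame_%03d.dat", seq_along(times)),
                        time_s = times)
  if (!is.null(dir)) {
    write_series(frames, dir)
    write_curve(basis$complex, file.path(dir, "basis_complex.dat"))
    write_curve(basis$micelle, file.path(dir, "basis_micelle.dat"))
    write_curve(basis$native, file.path(dir, "basis_native.dat"))
    readr::write_csv(truth, file.path(dir, "truth.csv"))
  }
  list(frames = frames, basis = basis, truth = truth, manifest = man,
       scenario = sc)
}

#' Simulate a stopped-flow kinetic trace
#'
#' \eqn{y(t) = y_\infty + \sum_i A_i e^{-k_i t}} on a log-spaced
#' schedule, with Gaussian noise of standard deviation `noise` times the
#' peak-to-peak range of the noise-free trace.
#'
#' @param amplitudes Component amplitudes `A_i`.
#' @param halftimes Component half-times, seconds (`k_i = ln 2 / t`).
#' @param y_inf Offset.
#' @param t Time points, seconds; default 500 log-spaced points in
#'   0.005-60 s.
#' @param noise Relative noise (fraction of peak-to-peak).
#' @param seed Integer seed.
#' @return A list with `trace` (tibble `t`, `y`, `sigma`) and `truth`.
#' @export
simulate_kinetic_trace <- function(amplitudes, halftimes, y_inf = 1,
                                   t = exp(seq(log(0.005), log(60),
                                               length.out = 500)),
                                   noise = 0.01, seed = 1) {
  stopifnot(length(amplitudes) == length(halftimes), all(halftimes > 0))
  k <- log(2) / halftimes
  y0 <- y_inf + as.numeric(exp(-outer(t, k)) %*% amplitudes)
  sd <- noise * diff(range(y0))
  y <- if (sd > 0) y0 + with_seed(seed, stats::rnorm(length(t), 0, sd)) else y0
  trace <- tibble::tibble(t = t, y = y,
                          sigma = rep(max(sd, 1e-12), length(t)))
  truth <- tibble::tibble(component = seq_along(k),
                          amplitude = amplitudes, rate = k,
                          halftime = halftimes)
  list(trace = trace, truth = truth, y_inf = y_inf, noise_sd = sd)
}
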