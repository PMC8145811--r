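# Thomson scattering length of the electron, cm.
R_ELECTRON_CM <- 2.8179403e-13
# Avogadro constant, 1/mol.
N_AVOGADRO <- 6.02214076e23

#' Default molecular volumes and scattering lengths
#'
#' One documented, user-overridable table holding every contrast constant
#' used on the absolute scale; no numeric contrast constants live in the
#' model code. Scattering lengths are electron counts converted with the
#' Thomson radius (2.818e-13 cm per electron). Values follow standard
#' solution-scattering conventions: a C12 alkyl chain of 350 A^3 (Tanford),
#' an SDS sulfate head of 60 A^3 / 59 electrons, a C12E8 octa(ethylene
#' oxide) head of 520 A^3 / 201 electrons, a beta-lactoglobulin monomer of
#' 18300 Da with partial specific volume 0.735 cm^3/g, and water with
#' electron density 0.334 e/A^3. A copy of this table ships as
#' `inst/extdata/contrasts_default.csv`.
#'
#' @param ... Named overrides for any field of the table.
#' @return A list with elements `v_chain`, `v_head_sds`, `v_head_c12e8`,
#'   `v_protein` (A^3), `b_chain`, `b_head_sds`, `b_head_c12e8`,
#'   `b_protein` (cm), `rho_solvent` (1/cm^2), `protein_mass` (Da) and
#'   `drho_m` (cm/g, mass-specific excess scattering length density used
#'   for the Gaussian-chain prefactor).
#' @export
default_contrasts <- function(...) {
  e <- R_ELECTRON_CM
  vbar <- 0.735                       # cm^3/g
  mass <- 18300                       # Da
  cs <- list(
    v_chain      = 350,
    v_head_sds   = 60,
    v_head_c12e8 = 520,
    v_protein    = vbar * mass / 0.6022,   # A^3 per molecule
    b_chain      = 97  * e,                # C12H25
    b_head_sds   = 59  * e,                # SO4 Na
    b_head_c12e8 = 201 * e,                # (OCH2CH2)8 OH
    b_protein    = 9798 * e,               # ~0.5354 e/Da
    rho_solvent  = 0.334 * e / 1e-24,      # 1/cm^2
    protein_mass = mass,
    drho_m       = 2.0e10                  # cm/g
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cs))
    if (length(bad)) stop("unknown contrast field(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    cs[names(over)] <- over
  }
  cs
}

#' Read / write a contrast table as a flat config file
#'
#' @param path Path to a CSV with columns `key,value`.
#' @return For `read_contrasts()`, a contrast list as from
#'   [default_contrasts()] with the file's values applied on top of the
#'   defaults.
#' @export
read_contrasts <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("key", "value") %in% names(tab)))
  do.call(default_contrasts, stats::setNames(as.list(tab$value), tab$key))
}

#' @rdname read_contrasts
#' @param contrasts A contrast list.
#' @export
write_contrasts <- function(contrasts, path) {
  tab <- tibble::tibble(key = names(contrasts),
                        value = unlist(contrasts, use.names = FALSE))
  readr::write_csv(tab, path)
  invisible(path)
}

#' Micelle aggregation number from core volume
#'
#' The ellipsoidal core volume divided by the volume of one C12 alkyl
#' chain: \eqn{N_{agg} = (4\pi/3)\,\varepsilon R_{core}^3 / v_{chain}}.
#'
#' @param Rcore Core equatorial radius, Angstrom.
#' @param eps Core axis ratio.
#' @param v_chain Alkyl-chain volume, A^3 (default from
#'   [default_contrasts()]).
#' @return Aggregation number (surfactant molecules per micelle core).
#' @export
aggregation_number <- function(Rcore, eps, v_chain = default_contrasts()$v_chain) {
  stopifnot(all(Rcore > 0), all(eps > 0), v_chain > 0)
  (4 * pi / 3) * eps * Rcore^3 / v_chain
}

#' Absolute-scale contrast prefactors of a protein-decorated micelle
#'
#' Converts geometry plus composition to the amplitudes `k1`, `k2` of the
#' core-shell models. The core holds `N_agg` alkyl chains; the shell
#' holds the `N_agg` head groups, `Npro` protein molecules and filling
#' water (zero excess scattering length, volume only). The shell's excess
#' scattering length density is that of heads + protein distributed
#' uniformly through the shell volume, so
#' \eqn{k_1 = v_1 \Delta\rho_1} with \eqn{v_1 = (4\pi/3)\varepsilon_1 R_1^3}
#' and \eqn{k_2 = v_2(\Delta\rho_2 - \Delta\rho_1)} with
#' \eqn{v_2 = (4\pi/3)\varepsilon_2 R_2^3}.
#'
#' @param Rcore Core equatorial radius, Angstrom.
#' @param eps Core axis ratio.
#' @param Dshell Shell thickness, Angstrom.
#' @param Npro Protein molecules per complex (0 for a pure micelle).
#' @param contrasts Contrast table from [default_contrasts()].
#' @param surfactant `"sds"`, `"c12e8"`, or a mixture given by
#'   `chi_sds` in (0,1): head volume/scattering length are mole-fraction
#'   weighted.
#' @param chi_sds SDS mole fraction for `surfactant = "mixed"`.
#' @return A list with `k1`, `k2` (cm), `N_agg`, `water_fraction` (volume
#'   fraction of water in the shell, in `[0, 1)`), `drho_shell` and
#'   `drho_core` (1/cm^2).
#' @export
complex_contrasts <- function(Rcore, eps, Dshell, Npro,
                              contrasts = default_contrasts(),
                              surfactant = c("sds", "c12e8", "mixed"),
                              chi_sds = NULL) {
  surfactant <- match.arg(surfactant)
  cs <- contrasts
  if (surfactant == "sds") {
    v_head <- cs$v_head_sds; b_head <- cs$b_head_sds
  } else if (surfactant == "c12e8") {
    v_head <- cs$v_head_c12e8; b_head <- cs$b_head_c12e8
  } else {
    stopifnot(!is.null(chi_sds), chi_sds >= 0, chi_sds <= 1)
    v_head <- chi_sds * cs$v_head_sds + (1 - chi_sds) * cs$v_head_c12e8
    b_head <- chi_sds * cs$b_head_sds + (1 - chi_sds) * cs$b_head_c12e8
  }
  N_agg <- aggregation_number(Rcore, eps, cs$v_chain)
  eps1 <- eps_outer_from_core(Rcore, eps, Dshell)
  R1 <- Rcore + Dshell
  v1 <- (4 * pi / 3) * eps1 * R1^3        # A^3, whole outer ellipsoid
  v2 <- (4 * pi / 3) * eps * Rcore^3      # A^3, core
  v_shell <- v1 - v2
  v_occupied <- N_agg * v_head + Npro * cs$v_protein
  v_water <- v_shell - v_occupied
  if (v_water < 0)
    stop("geometry inconsistent with composition: shell overfilled",
         call. = FALSE)
  A3_to_cm3 <- 1e-24
  # excess scattering length of shell contents; water has zero excess
  b_excess_shell <- N_agg * (b_head - cs$rho_solvent * v_head * A3_to_cm3) +
    Npro * (cs$b_protein - cs$rho_solvent * cs$v_protein * A3_to_cm3)
  drho_shell <- b_excess_shell / (v_shell * A3_to_cm3)
  drho_core <- cs$b_chain / (cs$v_chain * A3_to_cm3) - cs$rho_solvent
  k1 <- v1 * A3_to_cm3 * drho_shell
  k2 <- v2 * A3_to_cm3 * (drho_core - drho_shell)
  list(k1 = k1, k2 = k2, N_agg = N_agg,
       water_fraction = v_water / v_shell,
       drho_shell = drho_shell, drho_core = drho_core)
}

#' Number density of complexes from the bound-surfactant concentration
#'
#' \eqn{n = (C_{tot} - C_{free})\,[\mathrm{mM}] \times 6.022\times10^{17}
#' / (N_{agg} N_{mic})} complexes per cm^3, so that the absolute
#' intensity \eqn{I(q) = n P(q) S(q)} comes out in 1/cm. The implied
#' protein concentration \eqn{n N_{mic} N_{pro} M / N_A} is returned as a
#' diagnostic to compare against the nominal protein concentration.
#'
#' @param C_total,C_free Total and free surfactant concentration, mM.
#' @param N_agg Aggregation number per complex core.
#' @param Nmic Complexes per cluster.
#' @param Npro Proteins per complex (diagnostic only).
#' @param protein_mass Protein molar mass, Da (diagnostic only).
#' @return List with `n` (clusters per cm^3; multiplying the per-complex
#'   form factor and the cluster structure factor, whose forward limit is
#'   `Nmic`, yields 1/cm), and `c_protein_implied` (mg/mL) when `Npro` is
#'   given.
#' @export
number_density <- function(C_total, C_free, N_agg, Nmic = 1,
                           Npro = NULL,
                           protein_mass = default_contrasts()$protein_mass) {
  stopifnot(N_agg > 0, Nmic >= 1, C_free >= 0, C_total >= C_free)
  n <- (C_total - C_free) * 6.022e17 / (N_agg * Nmic)
  c_implied <- if (!is.null(Npro))
    n * Nmic * Npro * protein_mass / N_AVOGADRO * 1e3  # mg/mL
  else NA_real_
  list(n = n, c_protein_implied = c_implied)
}

#' SDS mole fraction of a mixed surfactant solution
#'
#' \eqn{\chi_{SDS} = C_{SDS} / (C_{SDS} + C_{C12E8})}.
#'
#' @param C_SDS,C_C12E8 Concentrations, mM (nonnegative, not both zero).
#' @return Mole fraction in `[0, 1]`.
#' @export
chi_sds <- function(C_SDS, C_C12E8) {
  stopifnot(all(C_SDS >= 0), all(C_C12E8 >= 0))
  if (any(C_SDS + C_C12E8 == 0))
    stop("both concentrations zero", call. = FALSE)
  C_SDS / (C_SDS + C_C12E8)
}

#' Absolute forward scattering of an ideal monomeric protein solution
#'
#' \eqn{I(0) = c M \Delta\rho_m^2 / N_A} with the concentration `c` in
#' g/cm^3, molar mass `M` in Da and the mass-specific excess scattering
#' length density `drho_m` in cm/g; used as the absolute prefactor of the
#' Gaussian-chain contribution.
#'
#' @param c_protein Protein concentration, mg/mL.
#' @param mass Molar mass, Da.
#' @param drho_m Excess scattering length density per unit mass, cm/g.
#' @return Forward scattering, 1/cm.
#' @export
gaussian_chain_prefactor <- function(c_protein,
                                     mass = default_contrasts()$protein_mass,
                                     drho_m = default_contrasts()$drho_m) {
  stopifnot(c_protein >= 0, mass > 0, drho_m > 0)
  (c_protein * 1e-3) * mass * drho_m^2 / N_AVOGADRO
}
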