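#' End-state complex parameter presets for the four SDS concentrations
#'
#' Equilibrium (end-state) parameters of the displaced-core core-shell
#' model for beta-lactoglobulin unfolded with 2.0, 4.1, 7.3 and
#' 10.5 mM SDS at 2 mg/mL protein: head-group/protein shell thickness
#' `Dhead` (A), core equatorial radius `Rcore` (A), core axis ratio
#' `eps`, complexes per cluster `Nmic`, cluster spacing `Dmic` (A),
#' total and free SDS concentrations (mM), proteins per complex `Npro`,
#' and core displacement `s` (A).
#'
#' @param preset One of `"sds2.0"`, `"sds4.1"`, `"sds7.3"`, `"sds10.5"`,
#'   or `NULL` to get the whole table.
#' @return A one-row tibble (or the full four-row tibble).
#' @export
complex_preset <- function(preset = NULL) {
  tab <- tibble::tibble(
    preset    = c("sds2.0", "sds4.1", "sds7.3", "sds10.5"),
    Dhead     = c(15.0, 13.2, 10.2, 10.1),
    Rcore     = c(7.6, 8.8, 11.5, 13.7),
    eps       = c(3.4, 3.4, 2.1, 1.8),
    Nmic      = c(1.15, 1.0, 1.0, 1.0),
    Dmic      = c(50, 50, 50, 50),
    C_total   = c(2.0, 4.1, 7.3, 10.5),
    C_free    = c(0.7, 1.8, 2.6, 3.7),
    Npro      = c(1.96, 1.48, 0.97, 0.98),
    s         = c(7.4, 3.2, 2.1, 1.9),
    c_protein = 2.0
  )
  if (is.null(preset)) return(tab)
  row <- tab[tab$preset == preset, ]
  if (nrow(row) == 0L)
    stop("unknown preset: ", preset, "; use one of ",
         paste(tab$preset, collapse = ", "), call. = FALSE)
  row
}

#' Absolute-scale intensity of a solution of protein-decorated micelles
#'
#' The full chain from geometry plus chemistry to 1/cm: aggregation
#' number from the core volume ([aggregation_number()]), contrast
#' prefactors from the shell bookkeeping ([complex_contrasts()]), the
#' displaced-core form factor ([displaced_core_shell_intensity()]), the
#' random-flight cluster structure factor ([random_flight_sf()]) and the
#' number density from the bound-surfactant concentration
#' ([number_density()]):
#' \deqn{I(q) = n\, P(q)\, S(q).}
#'
#' @param q Scattering vector, 1/Angstrom.
#' @param pars Named list or one-row data frame with `Rcore`, `eps`,
#'   `Dhead`, `s`, `Npro`, `Nmic`, `Dmic`, `C_total`, `C_free` (see
#'   [complex_preset()]).
#' @param contrasts Contrast table, [default_contrasts()].
#' @param surfactant Passed to [complex_contrasts()].
#' @param chi_sds SDS mole fraction for mixed micelles.
#' @param variant,order Passed to [displaced_core_shell_intensity()].
#' @return Intensity, 1/cm.
#' @export
complex_intensity <- function(q, pars, contrasts = default_contrasts(),
                              surfactant = "sds", chi_sds = NULL,
                              variant = "amplitude", order = 76) {
  p <- as.list(pars)
  cc <- complex_contrasts(p$Rcore, p$eps, p$Dhead, p$Npro,
                          contrasts = contrasts, surfactant = surfactant,
                          chi_sds = chi_sds)
  P <- displaced_core_shell_intensity(q, R2 = p$Rcore, eps2 = p$eps,
                                      Dshell = p$Dhead, s = p$s,
                                      k1 = cc$k1, k2 = cc$k2,
                                      variant = variant, order = order)
  S <- random_flight_sf(q, Nmic = p$Nmic, Dmic = p$Dmic)
  nd <- number_density(p$C_total, p$C_free, cc$N_agg, Nmic = p$Nmic)
  nd$n * P * S
}

#' Absolute-scale intensity of a pure micelle solution
#'
#' Concentric core-shell ellipsoid of revolution on absolute scale; used
#' for SDS, C12E8 and mixed micelles (the mixed-micelle basis of the
#' refolding decomposition).
#'
#' @inheritParams complex_intensity
#' @param pars Named list with `Rcore`, `eps`, `Dhead`, `C_total`,
#'   `C_free` (mM).
#' @return Intensity, 1/cm.
#' @export
micelle_intensity <- function(q, pars, contrasts = default_contrasts(),
                              surfactant = "sds", chi_sds = NULL,
                              order = 76) {
  p <- as.list(pars)
  p$s <- 0
  p$Npro <- 0
  p$Nmic <- 1
  p$Dmic <- 50
  complex_intensity(q, p, contrasts = contrasts, surfactant = surfactant,
                    chi_sds = chi_sds, order = order)
}

#' Micelle parameter presets for the pure and mixed surfactant solutions
#'
#' Fitted micelle geometries for pure SDS (core long-axis radius 22.7 A,
#' axis ratio 0.60, head shell 5.5 A) and pure C12E8 (21.0 A, 0.64,
#' 15.0 A). The mixed preset interpolates the two geometries by the SDS
#' mole fraction and is used for the mixed-micelle basis curve.
#'
#' @param which `"sds"`, `"c12e8"` or `"mixed"`.
#' @param chi_sds SDS mole fraction (required for `"mixed"`).
#' @param C_total,C_free Total and free (monomeric) surfactant
#'   concentration, mM. Defaults: 10 mM total, free at a typical critical
#'   micelle concentration.
#' @return Named list of micelle parameters.
#' @export
micelle_preset <- function(which = c("sds", "c12e8", "mixed"),
                           chi_sds = NULL, C_total = 10, C_free = NULL) {
  which <- match.arg(which)
  if (which == "sds") {
    if (is.null(C_free)) C_free <- 2.0
    list(Rcore = 22.7, eps = 0.60, Dhead = 5.5,
         C_total = C_total, C_free = C_free,
         surfactant = "sds", chi_sds = NULL)
  } else if (which == "c12e8") {
    if (is.null(C_free)) C_free <- 0.07
    list(Rcore = 21.0, eps = 0.64, Dhead = 15.0,
         C_total = C_total, C_free = C_free,
         surfactant = "c12e8", chi_sds = NULL)
  } else {
    stopifnot(!is.null(chi_sds))
    if (is.null(C_free)) C_free <- 2.0 * chi_sds + 0.07 * (1 - chi_sds)
    list(Rcore = 22.7 * chi_sds + 21.0 * (1 - chi_sds),
         eps = 0.60 * chi_sds + 0.64 * (1 - chi_sds),
         Dhead = 5.5 * chi_sds + 15.0 * (1 - chi_sds),
         C_total = C_total, C_free = C_free,
         surfactant = "mixed", chi_sds = chi_sds)
  }
}

#' Evaluate a micelle preset on a q grid as a scattering curve
#'
#' @param q Scattering vector grid, 1/Angstrom.
#' @param preset A list from [micelle_preset()].
#' @param contrasts Contrast table.
#' @return A [saxs_curve()] (sigma set to 2% of I, flagged by a warning
#'   unless `sigma_rel` is given).
#' @param sigma_rel Relative standard error to attach to the noise-free
#'   model curve.
#' @export
micelle_curve <- function(q, preset, contrasts = default_contrasts(),
                          sigma_rel = 0.02) {
  I <- micelle_intensity(q, preset[c("Rcore", "eps", "Dhead",
                                     "C_total", "C_free")],
                         contrasts = contrasts,
                         surfactant = preset$surfactant,
                         chi_sds = preset$chi_sds)
  saxs_curve(q, I, sigma = sigma_rel * abs(I),
             label = paste0("micelle_", preset$surfactant))
}
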