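#' Normalized homogeneous-sphere/ellipsoid scattering amplitude
#'
#' \eqn{\Phi(x) = 3(\sin x - x \cos x)/x^3}, the normalized amplitude of a
#' homogeneous sphere, which also gives the ellipsoid-of-revolution
#' amplitude when evaluated at \eqn{x = q\,r(\theta)} with the effective
#' radius [effective_radius()]. A fourth-order series is used below
#' `x = 1e-2` to avoid catastrophic cancellation.
#'
#' @param x Nonnegative numeric vector (dimensionless).
#' @return \eqn{\Phi(x)}; \eqn{\Phi(0)=1}, \eqn{|\Phi| \le 1}.
#' @export
sphere_amplitude <- function(x) {
  x <- as.numeric(x)
  out <- numeric(length(x))
  small <- x < 1e-2
  xs <- x[small]
  out[small] <- 1 - xs^2 / 10 + xs^4 / 280
  xl <- x[!small]
  out[!small] <- 3 * (sin(xl) - xl * cos(xl)) / xl^3
  out
}

#' Effective radius of an ellipsoid of revolution at polar angle theta
#'
#' \eqn{r(\theta) = R \sqrt{\sin^2\theta + \varepsilon^2 \cos^2\theta}}
#' where `R` is the equatorial radius and `eps` the axis ratio
#' (polar/equatorial). At `theta = 0` this is the polar semi-axis
#' `eps * R`; at `theta = pi/2` the equatorial radius `R`.
#'
#' @param R Equatorial radius, Angstrom.
#' @param eps Axis ratio (polar/equatorial), dimensionless.
#' @param theta Polar angle from the symmetry axis, radians.
#' @return Effective radius, Angstrom.
#' @export
effective_radius <- function(R, eps, theta) {
  R * sqrt(sin(theta)^2 + eps^2 * cos(theta)^2)
}

#' Outer axis ratio that keeps the shell thickness uniform
#'
#' For a core-shell ellipsoid of revolution with core equatorial radius
#' `R2`, core axis ratio `eps2` and uniform shell thickness `Dshell`, the
#' outer surface has `R1 = R2 + Dshell` and axis ratio
#' \eqn{\varepsilon_1 = (\varepsilon_2 R_2 + D_{shell})/(R_2 + D_{shell})},
#' the inverse of the shell-uniformity relation
#' \eqn{\varepsilon_2 = (\varepsilon_1 R_1 - D_{shell})/(R_1 - D_{shell})}.
#'
#' @param R2 Core equatorial radius, Angstrom (> 0).
#' @param eps2 Core axis ratio.
#' @param Dshell Shell thickness, Angstrom (>= 0).
#' @return Outer axis ratio `eps1`.
#' @export
eps_outer_from_core <- function(R2, eps2, Dshell) {
  stopifnot(all(R2 > 0), all(Dshell >= 0))
  (eps2 * R2 + Dshell) / (R2 + Dshell)
}

# Gauss-Legendre nodes/weights on [0, pi/2], cached per order.
gl_cache <- new.env(parent = emptyenv())
gl_theta <- function(order) {
  key <- as.character(order)
  if (is.null(gl_cache[[key]])) {
    gl <- pracma::gaussLegendre(order, 0, pi / 2)
    gl_cache[[key]] <- list(x = gl$x, w = gl$w)
  }
  gl_cache[[key]]
}

#' Form factor of a core-shell ellipsoid of revolution with displaced core
#'
#' Scattering intensity per particle of a prolate/oblate core-shell
#' ellipsoid of revolution whose core center is offset by `s`
#' perpendicular to the symmetry axis, modelling a protein shell sitting
#' asymmetrically on a surfactant micelle. The orientation-dependent
#' amplitude is
#' \deqn{A(q,\theta) = k_1 \Phi(q r_1(\theta)) +
#'       k_2 \Phi(q r_2(\theta)) J_0(q s \sin\theta)}
#' with \eqn{r_i(\theta)} from [effective_radius()] (outer surface i = 1,
#' core i = 2), \eqn{J_0} the Bessel function of the first kind and zeroth
#' order, and the orientational average
#' \deqn{P(q) = \int_0^{\pi/2} A^2(q,\theta) \sin\theta \, d\theta}
#' evaluated by Gauss-Legendre quadrature. The `"amplitude"` variant
#' squares the azimuthally folded amplitude (the core self-term carries
#' \eqn{J_0^2}); `"exact"` performs the exact azimuthal average of the
#' intensity, in which \eqn{J_0} appears only in the cross term.
#'
#' @param q Scattering vector, 1/Angstrom.
#' @param R2 Core equatorial radius, Angstrom.
#' @param eps2 Core axis ratio.
#' @param Dshell Shell thickness, Angstrom; outer radius `R1 = R2 + Dshell`
#'   and outer axis ratio from [eps_outer_from_core()].
#' @param s Core center offset perpendicular to the symmetry axis,
#'   Angstrom; must satisfy `s <= R1 - R2 = Dshell`.
#' @param k1 Total excess scattering length of the outer-ellipsoid (shell)
#'   contribution, cm.
#' @param k2 Total excess scattering length of the core-minus-shell
#'   contribution, cm.
#' @param variant `"amplitude"` (default) or `"exact"` (see Details).
#' @param order Gauss-Legendre quadrature order (default 76).
#' @return Intensity per particle, cm^2; `P(0) = (k1 + k2)^2`.
#' @export
displaced_core_shell_intensity <- function(q, R2, eps2, Dshell, s, k1, k2,
                                           variant = c("amplitude", "exact"),
                                           order = 76) {
  variant <- match.arg(variant)
  stopifnot(R2 > 0, eps2 > 0, Dshell >= 0, s >= 0)
  R1 <- R2 + Dshell
  if (s > R1 - R2 + 1e-12)
    stop("core offset s exceeds R1 - R2: geometry violated", call. = FALSE)
  eps1 <- eps_outer_from_core(R2, eps2, Dshell)
  gl <- gl_theta(order)
  sin_t <- sin(gl$x)
  r1 <- effective_radius(R1, eps1, gl$x)
  r2 <- effective_radius(R2, eps2, gl$x)
  # matrices: q rows x theta cols
  F1 <- sphere_amplitude(outer(q, r1))
  F2 <- sphere_amplitude(outer(q, r2))
  J0 <- besselJ(outer(q, s * sin_t), 0)
  w <- gl$w * sin_t
  if (variant == "amplitude") {
    A <- k1 * F1 + k2 * F2 * J0
    as.numeric((A * A) %*% w)
  } else {
    I_t <- k1^2 * F1^2 + k2^2 * F2^2 + 2 * k1 * k2 * F1 * F2 * J0
    as.numeric(I_t %*% w)
  }
}

#' Form factor of a concentric core-shell ellipsoid of revolution
#'
#' The micelle model: [displaced_core_shell_intensity()] with zero core
#' offset. Used for pure SDS, pure C12E8 and mixed micelles.
#'
#' @inheritParams displaced_core_shell_intensity
#' @param Rcore Core equatorial radius, Angstrom.
#' @param eps Core axis ratio.
#' @param Dhead Head-group shell thickness, Angstrom.
#' @return Intensity per micelle, cm^2.
#' @export
concentric_core_shell_intensity <- function(q, Rcore, eps, Dhead, k1, k2,
                                            order = 76) {
  displaced_core_shell_intensity(q, Rcore, eps, Dhead, s = 0,
                                 k1 = k1, k2 = k2, order = order)
}

# Random-flight structure factor at integer N.
rf_integer <- function(q, N, Dmic, x_denom) {
  if (N <= 1) return(rep(1, length(q)))
  x <- ifelse(q * Dmic == 0, 1, sin(q * Dmic) / (q * x_denom))
  k <- seq_len(N - 1)
  xk <- outer(x, k, `^`)            # q rows, k cols
  1 + (2 / N) * as.numeric(xk %*% (N - k))
}

#' Random-flight structure factor for clusters of complexes
#'
#' Describes clustering of protein-micelle complexes as a random flight
#' of `Nmic` scatterers with center-to-center distance `Dmic`:
#' \deqn{S(q) = 1 + \frac{2}{N} \sum_{k=1}^{N-1} (N-k)\, x^k, \quad
#'       x = \sin(qD_{mic})/(qD_{mic}).}
#' For non-integer `Nmic` a linear weighting of the two bracketing integer
#' cluster sizes is used: with \eqn{w = N_{mic} - \lfloor N_{mic}\rfloor},
#' \eqn{S = (1-w) S(\lfloor N_{mic}\rfloor) + w S(\lfloor N_{mic}\rfloor+1)},
#' which is continuous in `Nmic` and satisfies \eqn{S(0) = N_{mic}}.
#'
#' @param q Scattering vector, 1/Angstrom.
#' @param Nmic Mean number of complexes per cluster (>= 1, possibly
#'   non-integer).
#' @param Dmic Center-to-center distance between complexes, Angstrom.
#' @param x_denominator Length scale in the denominator of `x`; the
#'   default `Dmic` is the only choice for which `S(0) = Nmic`. A
#'   different value can be supplied for comparison with variant
#'   conventions.
#' @return Dimensionless structure factor, same length as `q`.
#' @export
random_flight_sf <- function(q, Nmic, Dmic, x_denominator = Dmic) {
  stopifnot(Nmic >= 1, Dmic > 0)
  n_lo <- floor(Nmic)
  w <- Nmic - n_lo
  S <- rf_integer(q, n_lo, Dmic, x_denominator)
  if (w > 0)
    S <- (1 - w) * S + w * rf_integer(q, n_lo + 1, Dmic, x_denominator)
  S
}

#' Gaussian-chain (Debye) scattering of an unfolded protein
#'
#' \eqn{I(q) = I_0 \, 2(e^{-x} - 1 + x)/x^2} with \eqn{x = q^2 R_g^2},
#' the form factor of an ideal random coil, used for the transiently
#' unfolded protein during refolding. A series expansion is used for
#' small `x`.
#'
#' @param q Scattering vector, 1/Angstrom.
#' @param Rg Root-mean-square radius of gyration, Angstrom.
#' @param I0 Forward scattering, 1/cm (see
#'   [gaussian_chain_prefactor()] for the absolute-scale value).
#' @return Intensity, 1/cm.
#' @export
gaussian_chain_intensity <- function(q, Rg, I0) {
  stopifnot(Rg > 0, I0 > 0)
  x <- (q * Rg)^2
  D <- ifelse(x < 1e-4,
              1 - x / 3 + x^2 / 12,
              2 * (exp(-x) - 1 + x) / x^2)
  I0 * D
}
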