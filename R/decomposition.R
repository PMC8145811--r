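#' Assemble a basis set for refolding-frame decomposition
#'
#' The refolding frames are modelled as a linear combination of measured
#' basis curves for the protein-SDS complex, the mixed micelles and the
#' native protein, plus a parametric Gaussian-chain contribution for the
#' transiently unfolded monomer and a constant background:
#' \deqn{I_{lin}(q) = a_1 I_1 + a_2 I_2 + a_3 I_3 + a_4 I_4 + a_5.}
#' All measured bases must live on a common q-grid; curves on other grids
#' are linearly interpolated to the frame grid with sigma interpolated in
#' quadrature when a frame is decomposed.
#'
#' @param complex,micelle,native [saxs_curve()] basis curves (with
#'   measured sigma columns).
#' @param chain_I0 Forward scattering of the Gaussian-chain contribution,
#'   1/cm; default the absolute monomer prefactor at 2 mg/mL,
#'   [gaussian_chain_prefactor()].
#' @return A list of class `saxs_basis`.
#' @export
saxs_basis <- function(complex, micelle, native,
                       chain_I0 = gaussian_chain_prefactor(2)) {
  for (b in list(complex, micelle, native)) validate_curve(b)
  structure(list(complex = complex, micelle = micelle, native = native,
                 chain_I0 = chain_I0),
            class = "saxs_basis")
}

# interpolate a basis curve onto a q grid; sigma in quadrature
resample_basis <- function(curve, q) {
  if (length(curve$q) == length(q) && all(abs(curve$q - q) < 1e-12))
    return(curve)
  I <- stats::approx(curve$q, curve$I, xout = q, rule = 2)$y
  s2 <- stats::approx(curve$q, curve$sigma^2, xout = q, rule = 2)$y
  saxs_curve(q, I, sqrt(s2), time_s = attr(curve, "time_s"),
             label = attr(curve, "label"))
}

# Exact bounded weighted linear least squares by active-set enumeration.
# Minimize || w * (X b - y) ||^2 subject to G b >= h, for small problems:
# every subset of constraints is tried as an equality set via the KKT
# system and the feasible solution with smallest objective is returned.
bounded_wls <- function(X, y, w, G, h) {
  A <- X * w
  z <- y * w
  # column equilibration keeps the KKT systems well conditioned even
  # when weights span many orders of magnitude
  d <- sqrt(colSums(A^2))
  d[d == 0] <- 1
  As <- sweep(A, 2, d, `/`)
  Gs <- sweep(G, 2, d, `/`)
  AtA <- crossprod(As)
  Atz <- crossprod(As, z)
  m <- nrow(G)
  p <- ncol(X)
  best <- NULL
  best_obj <- Inf
  feas_tol <- 1e-9 * max(abs(h), 1)
  for (mask in 0:(2^m - 1)) {
    act <- which(bitwAnd(mask, bitwShiftL(1L, 0:(m - 1))) != 0L)
    Ga <- Gs[act, , drop = FALSE]
    rnorm_g <- sqrt(rowSums(Ga^2))
    rnorm_g[rnorm_g == 0] <- 1
    Ga <- Ga / rnorm_g
    k <- length(act)
    KKT <- rbind(cbind(2 * AtA, t(Ga)),
                 cbind(Ga, matrix(0, k, k)))
    rhs <- c(2 * Atz, h[act] / rnorm_g)
    sol <- tryCatch(solve(KKT, rhs, tol = 1e-30), error = function(e) NULL)
    if (is.null(sol) || anyNA(sol)) next
    b <- sol[seq_len(p)] / d
    if (any(G %*% b < h - feas_tol)) next
    obj <- sum((A %*% b - z)^2)
    if (obj < best_obj - 1e-12) {
      best_obj <- obj
      best <- b
    }
  }
  if (is.null(best))
    stop("constrained least squares failed on every active set", call. = FALSE)
  list(beta = best, obj = best_obj)
}

#' Decompose one refolding frame into species contributions
#'
#' Fits the linear combination of complex, mixed-micelle, native and
#' Gaussian-chain contributions plus a constant background to one frame,
#' with protein-mass conservation imposed exactly by eliminating the
#' complex scale, `a1 = 1 - a3 - a4`, before optimization, and
#' non-negativity of the mass fractions enforced by bounded least
#' squares. The goodness of fit is computed in two steps: first with the
#' frame's counting-statistics sigma, then with the basis noise
#' propagated into the effective variance
#' \eqn{\sigma_j^2 = a_1^2\sigma_{1,j}^2 + a_2^2\sigma_{2,j}^2 +
#' a_3^2\sigma_{3,j}^2} (replacing the measurement variance; set
#' `include_measurement_sigma = TRUE` to add it in quadrature instead)
#' and the scales re-optimized under the updated weights.
#'
#' @param frame A [saxs_curve()].
#' @param basis A [saxs_basis()].
#' @param Rg Radius of gyration of the Gaussian-chain contribution,
#'   Angstrom (default 30).
#' @param include_measurement_sigma Logical; see Details.
#' @param cond_warn Condition number of the weighted design above which a
#'   collinearity warning is raised.
#' @return A list with `scales` (tibble: a1..a5 with standard errors and
#'   the frame time), `chi2_red` (second-step reduced chi-squared),
#'   `chi2_red_step1`, and `condition`.
#' @export
decompose_frame <- function(frame, basis, Rg = 30,
                            include_measurement_sigma = FALSE,
                            cond_warn = 1e8) {
  validate_curve(frame)
  q <- frame$q
  b1 <- resample_basis(basis$complex, q)
  b2 <- resample_basis(basis$micelle, q)
  b3 <- resample_basis(basis$native, q)
  I4 <- gaussian_chain_intensity(q, Rg = Rg, I0 = basis$chain_I0)
  # eliminate a1 = 1 - a3 - a4:
  # I - I1 = a2 I2 + a3 (I3 - I1) + a4 (I4 - I1) + a5
  X <- cbind(a2 = b2$I, a3 = b3$I - b1$I, a4 = I4 - b1$I, a5 = 1)
  y <- frame$I - b1$I
  # constraints: a2 >= 0, a3 >= 0, a4 >= 0, a3 + a4 <= 1 (a1 >= 0)
  G <- rbind(c(1, 0, 0, 0),
             c(0, 1, 0, 0),
             c(0, 0, 1, 0),
             c(0, -1, -1, 0))
  h <- c(0, 0, 0, -1)

  w1 <- 1 / frame$sigma
  cond <- kappa(X * w1, exact = TRUE)
  if (cond > cond_warn)
    warning(sprintf("basis curves nearly collinear (condition number %.3g)",
                    cond), call. = FALSE)
  step1 <- bounded_wls(X, y, w1, G, h)
  chi2_red_step1 <- step1$obj / (length(q) - 4)

  a <- step1$beta
  a1 <- 1 - a[2] - a[3]
  sig2 <- a1^2 * b1$sigma^2 + a[1]^2 * b2$sigma^2 + a[2]^2 * b3$sigma^2
  if (include_measurement_sigma) sig2 <- sig2 + frame$sigma^2
  sig2 <- pmax(sig2, 1e-300)
  w2 <- 1 / sqrt(sig2)
  step2 <- bounded_wls(X, y, w2, G, h)
  a <- step2$beta
  chi2_red <- step2$obj / (length(q) - 4)

  # uncertainties from the unconstrained weighted covariance
  cv <- tryCatch(solve(crossprod(X * w2)), error = function(e) NULL)
  sds <- rep(NA_real_, 5)
  if (!is.null(cv)) {
    sds[2:5] <- sqrt(pmax(diag(cv), 0))
    # var(a1) = var(a3) + var(a4) + 2 cov(a3, a4)
    v1 <- cv[2, 2] + cv[3, 3] + 2 * cv[2, 3]
    sds[1] <- sqrt(max(v1, 0))
  }
  # degeneracy diagnostic: without the conservation constraint, does the
  # frame actually carry protein signal? (a1 free in [0, 1])
  Xu <- cbind(b1$I, b2$I, b3$I - 0, I4, 1)
  Gu <- rbind(diag(1, 4, 5), c(-1, 0, -1, -1, 0))
  hu <- c(0, 0, 0, 0, -1)
  uncon <- bounded_wls(Xu, frame$I, w1, Gu, hu)
  prot_sum <- sum(uncon$beta[c(1, 3, 4)])
  degenerate <- is.finite(prot_sum) && prot_sum < 0.1
  if (degenerate)
    warning("no appreciable protein signal: mass-conservation scales are degenerate",
            call. = FALSE)

  scales <- tibble::tibble(
    term = c("a1", "a2", "a3", "a4", "a5"),
    estimate = c(1 - a[2] - a[3], a[1], a[2], a[3], a[4]),
    std.error = sds,
    species = c("complex", "micelle", "native", "chain", "background"))
  list(scales = scales, chi2_red = chi2_red,
       chi2_red_step1 = chi2_red_step1, condition = cond,
       degenerate = degenerate, time_s = curve_time(frame))
}

#' Decompose a refolding frame series
#'
#' Runs [decompose_frame()] over a time-ordered series with a
#' configurable schedule for the chain radius of gyration (constant
#' 30 Angstrom by default, with an optional larger value for the early
#' frames, where the partly unfolded chains are more expanded).
#'
#' @param series List of time-ordered [saxs_curve()] frames.
#' @param basis A [saxs_basis()].
#' @param Rg Chain radius of gyration, Angstrom.
#' @param Rg_early Optional override used while `time_s < t_early`.
#' @param t_early Time before which `Rg_early` applies, seconds.
#' @param ... Passed to [decompose_frame()].
#' @return A tibble with one row per frame: `frame`, `time_s`, `a1`..`a5`
#'   (+ `_sd` columns), `Rg_used` and `chi2_red`.
#' @export
decompose_series <- function(series, basis, Rg = 30, Rg_early = NULL,
                             t_early = 0.3, ...) {
  times <- vapply(series, curve_time, numeric(1))
  stopifnot(!is.unsorted(times))
  rows <- purrr::imap(series, function(fr, i) {
    t <- times[[i]]
    rg <- if (!is.null(Rg_early) && is.finite(t) && t < t_early) Rg_early else Rg
    d <- decompose_frame(fr, basis, Rg = rg, ...)
    est <- stats::setNames(as.list(d$scales$estimate), d$scales$term)
    sds <- stats::setNames(as.list(d$scales$std.error),
                           paste0(d$scales$term, "_sd"))
    tibble::as_tibble(c(list(frame = i, time_s = t), est, sds,
                        list(Rg_used = rg, chi2_red = d$chi2_red)))
  })
  dplyr::bind_rows(rows)
}
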