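#' Define a parameter set for curve fitting
#'
#' A parameter table with one row per model parameter: starting `value`,
#' box bounds, and a `locked` flag. Locked parameters are held
#' bit-identical throughout the fit and excluded from the uncertainty
#' report.
#'
#' @param ... Named parameter specifications. Each is either a single
#'   number (free, with infinite bounds), or a list/vector
#'   `c(value, lower, upper)`, optionally with `locked = TRUE` via
#'   [lock()].
#' @return A tibble with columns `name`, `value`, `lower`, `upper`,
#'   `locked`.
#' @examples
#' saxs_params(Rcore = c(10, 4, 30), eps = lock(1.8), Npro = c(1, 0, 10))
#' @export
saxs_params <- function(...) {
  specs <- list(...)
  stopifnot(length(specs) > 0, !is.null(names(specs)), all(nzchar(names(specs))))
  rows <- purrr::imap(specs, function(sp, nm) {
    if (inherits(sp, "locked_param")) {
      tibble::tibble(name = nm, value = sp$value, lower = -Inf, upper = Inf,
                     locked = TRUE)
    } else {
      v <- as.numeric(sp)
      tibble::tibble(name = nm, value = v[1],
                     lower = if (length(v) >= 2) v[2] else -Inf,
                     upper = if (length(v) >= 3) v[3] else Inf,
                     locked = FALSE)
    }
  })
  out <- dplyr::bind_rows(rows)
  bad <- out$value < out$lower | out$value > out$upper
  if (any(bad)) stop("start value outside bounds for: ",
                     paste(out$name[bad], collapse = ", "), call. = FALSE)
  out
}

#' Mark a parameter as locked
#' @param value The fixed value.
#' @return An object understood by [saxs_params()].
#' @export
lock <- function(value) structure(list(value = value), class = "locked_param")

params_as_list <- function(params) {
  stats::setNames(as.list(params$value), params$name)
}

#' Weighted nonlinear least-squares fit of a model to a scattering curve
#'
#' Minimizes \eqn{\chi^2 = \sum_j [(I_j - I_{model}(q_j))/\sigma_j]^2}
#' with a trust-region Levenberg-Marquardt routine
#' ([minpack.lm::nls.lm]), box bounds, parameter locking and seeded
#' Latin-hypercube multi-start (default 8 starts) to escape the local
#' minima typical of oscillatory form factors. Uncertainties come from
#' the linearized covariance at the optimum, scaled by the reduced
#' chi-squared.
#'
#' @param data A [saxs_curve()].
#' @param model A function `function(q, pars)` returning model intensity
#'   in 1/cm, where `pars` is a named list of all parameters.
#' @param params A parameter table from [saxs_params()].
#' @param starts Number of multi-start points (the first start is the
#'   supplied `value` column; the rest are Latin-hypercube draws over the
#'   finite bounds).
#' @param seed Integer seed controlling the multi-start draws.
#' @param max_iter Maximum LM iterations per start.
#' @return An object of class `saxs_fit` with the best-fit parameter
#'   tibble (`value`, `sd`, `locked`), `chi2_red`, `N`, `p`, `converged`,
#'   and `seed`. Non-convergence is flagged, never thrown.
#' @export
fit_curve <- function(data, model, params, starts = 8, seed = 1,
                      max_iter = 200) {
  validate_curve(data)
  free <- !params$locked
  p <- sum(free)
  N <- nrow(data)
  if (p > 0 && N < p + 2)
    stop("need at least p + 2 data points", call. = FALSE)
  w <- 1 / data$sigma
  resid_fn <- function(theta) {
    pl <- params_as_list(params)
    pl[params$name[free]] <- as.list(theta)
    Im <- tryCatch(model(data$q, pl), error = function(e) NULL)
    if (is.null(Im)) return(rep(1e8, N))   # infeasible geometry/composition
    r <- (data$I - Im) * w
    r[!is.finite(r)] <- 1e8
    r
  }

  if (p == 0) {
    # all locked: report chi2, no optimization
    r <- resid_fn(numeric(0))
    chi2 <- sum(r^2)
    out_params <- dplyr::mutate(params, sd = NA_real_)
    return(structure(list(params = out_params, chi2 = chi2,
                          chi2_red = chi2 / N, N = N, p = 0L,
                          converged = TRUE, niter = 0L, seed = seed),
                     class = "saxs_fit"))
  }

  lower <- params$lower[free]
  upper <- params$upper[free]
  start0 <- params$value[free]
  start_mat <- matrix(start0, nrow = 1)
  if (starts > 1) {
    # half the extra starts jitter around the supplied values, half are
    # Latin-hypercube draws over the feasible box
    lo <- ifelse(is.finite(lower), lower, start0 - 2 * abs(start0) - 1)
    hi <- ifelse(is.finite(upper), upper, start0 + 2 * abs(start0) + 1)
    n_jit <- (starts - 1) %/% 2
    n_lhs <- starts - 1 - n_jit
    extra <- with_seed(seed, {
      jit <- if (n_jit > 0) {
        j <- matrix(start0, n_jit, p, byrow = TRUE) *
          matrix(exp(stats::rnorm(n_jit * p, 0, 0.25)), n_jit, p)
        pmin(pmax(j, matrix(lo, n_jit, p, byrow = TRUE)),
             matrix(hi, n_jit, p, byrow = TRUE))
      } else NULL
      lhsm <- if (n_lhs > 0) {
        u <- lhs::randomLHS(n_lhs, p)
        sweep(sweep(u, 2, hi - lo, `*`), 2, lo, `+`)
      } else NULL
      rbind(jit, lhsm)
    })
    start_mat <- rbind(start_mat, extra)
  }

  best <- NULL
  for (i in seq_len(nrow(start_mat))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start_mat[i, ], lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = max_iter, ftol = 1e-10, ptol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }

  if (is.null(best)) {
    out_params <- dplyr::mutate(params, sd = NA_real_)
    return(structure(list(params = out_params, chi2 = NA_real_,
                          chi2_red = NA_real_, N = N, p = p,
                          converged = FALSE, niter = 0L, seed = seed),
                     class = "saxs_fit"))
  }

  chi2 <- best$deviance
  dof <- max(N - p, 1L)
  chi2_red <- chi2 / dof
  # linearized covariance, scaled by reduced chi-squared
  sd_free <- rep(NA_real_, p)
  cv <- tryCatch(chi2_red * solve(best$hessian), error = function(e) NULL)
  if (!is.null(cv)) {
    dg <- diag(cv)
    sd_free <- ifelse(dg > 0, sqrt(dg), NA_real_)
  }
  out_params <- params
  out_params$value[free] <- best$par
  out_params$sd <- NA_real_
  out_params$sd[free] <- sd_free
  converged <- best$info %in% 1:4
  structure(list(params = out_params, chi2 = chi2, chi2_red = chi2_red,
                 N = N, p = p, converged = converged,
                 niter = best$niter, seed = seed),
            class = "saxs_fit")
}

#' @export
print.saxs_fit <- function(x, ...) {
  cat(sprintf("<saxs_fit> N = %d, free = %d, chi2_red = %.4g, %s\n",
              x$N, x$p, x$chi2_red,
              if (x$converged) "converged" else "NOT converged"))
  print(x$params)
  invisible(x)
}

fitted_value <- function(fit, name) {
  fit$params$value[fit$params$name == name]
}
fitted_sd <- function(fit, name) {
  fit$params$sd[fit$params$name == name]
}

# run code with a local RNG seed without disturbing the global stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Build the displaced-core complex model evaluator for fitting
#'
#' Returns a `function(q, pars)` suitable for [fit_curve()], evaluating
#' [complex_intensity()] with the core offset reparameterized as
#' `s_frac` in `[0, 1]` via `s = s_frac * Dhead`, which enforces the
#' geometric constraint `s <= R1 - R2` as a box bound throughout the
#' optimization.
#'
#' @inheritParams complex_intensity
#' @return A model evaluator closure.
#' @export
complex_model <- function(contrasts = default_contrasts(),
                          surfactant = "sds", chi_sds = NULL,
                          variant = "amplitude", order = 76) {
  function(q, pars) {
    pars$s <- pars$s_frac * pars$Dhead
    complex_intensity(q, pars, contrasts = contrasts,
                      surfactant = surfactant, chi_sds = chi_sds,
                      variant = variant, order = order)
  }
}

#' Fitting protocol presets for the unfolding frame series
#'
#' Mirrors the series-fitting protocol used for the four SDS
#' concentrations: cluster spacing `Dmic` locked at 50 A everywhere; the
#' axis ratio locked at its equilibrium end-state value; the head/shell
#' thickness locked at 10 A (2.0 mM) or 15 A (7.3 and 10.5 mM); proteins
#' per complex, cluster number and core displacement free. The 4.1 mM
#' preset is the named special case with `Dhead` and `Rcore` free
#' (both decrease markedly over that series).
#'
#' @param preset `"sds2.0"`, `"sds4.1"`, `"sds7.3"` or `"sds10.5"`.
#' @return A [saxs_params()] tibble.
#' @export
unfold_protocol <- function(preset) {
  ep <- complex_preset(preset)
  # Dhead locked at its equilibrium end-state value (rounded values near
  # 15 A at 2.0 mM and 10 A at 7.3/10.5 mM)
  Dhead_lock <- ep$Dhead
  if (preset == "sds4.1") {
    saxs_params(
      Rcore = c(ep$Rcore, 3, 30),
      eps = lock(ep$eps),
      Dhead = c(ep$Dhead, 5, 40),
      s_frac = c(min(ep$s / ep$Dhead, 1), 0, 1),
      Npro = c(ep$Npro, 0.05, 12),
      Nmic = c(ep$Nmic, 1, 8),
      Dmic = lock(ep$Dmic),
      C_total = lock(ep$C_total),
      C_free = lock(ep$C_free)
    )
  } else {
    saxs_params(
      Rcore = lock(ep$Rcore),
      eps = lock(ep$eps),
      Dhead = lock(Dhead_lock),
      s_frac = c(min(ep$s / Dhead_lock, 1), 0, 1),
      Npro = c(ep$Npro, 0.05, 12),
      Nmic = c(ep$Nmic, 1, 8),
      Dmic = lock(ep$Dmic),
      C_total = lock(ep$C_total),
      C_free = lock(ep$C_free)
    )
  }
}

#' Fit an unfolding frame series with warm starts
#'
#' Fits every frame of a time-ordered series with the displaced-core
#' complex model under a locking protocol; frame `i + 1` starts from
#' frame `i`'s solution (multi-start is used only for the first frame).
#' A non-converged frame is flagged in the output but does not abort the
#' series.
#'
#' @param series List of [saxs_curve()] frames, time-ordered.
#' @param params A [saxs_params()] protocol (e.g. [unfold_protocol()]).
#' @param model A model evaluator; default [complex_model()].
#' @param starts Multi-start budget for the first frame.
#' @param seed Integer seed.
#' @return A tibble with one row per frame: `frame`, `time_s`, one
#'   column per parameter (with `<name>_sd` for free parameters), the
#'   derived core offset `s` in Angstrom, `chi2_red` and `converged`.
#' @export
fit_unfolding_series <- function(series, params, model = complex_model(),
                                 starts = 8, seed = 1) {
  times <- vapply(series, curve_time, numeric(1))
  stopifnot(!is.unsorted(times))
  cur <- params
  free_names <- params$name[!params$locked]
  rows <- vector("list", length(series))
  for (i in seq_along(series)) {
    fit <- fit_curve(series[[i]], model, cur,
                     starts = if (i == 1) starts else 1,
                     seed = seed + i - 1)
    if (fit$converged) cur$value <- fit$params$value
    vals <- stats::setNames(as.list(fit$params$value), fit$params$name)
    sds <- stats::setNames(as.list(fit$params$sd[!fit$params$locked]),
                           paste0(free_names, "_sd"))
    rows[[i]] <- tibble::as_tibble(c(list(frame = i, time_s = times[i]),
                                     vals, sds,
                                     list(chi2_red = fit$chi2_red,
                                          converged = fit$converged)))
  }
  out <- dplyr::bind_rows(rows)
  if ("s_frac" %in% names(out)) {
    out$s <- out$s_frac * out$Dhead
    if ("s_frac_sd" %in% names(out)) out$s_sd <- out$s_frac_sd * out$Dhead
  }
  out
}

#' @method tidy saxs_fit
#' @export
tidy.saxs_fit <- function(x, ...) {
  dplyr::transmute(x$params,
                   term = .data$name, estimate = .data$value,
                   std.error = .data$sd, locked = .data$locked)
}

#' @method glance saxs_fit
#' @export
glance.saxs_fit <- function(x, ...) {
  tibble::tibble(chi2 = x$chi2, chi2.red = x$chi2_red, nobs = x$N,
                 n.free = x$p, converged = x$converged, niter = x$niter)
}
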