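#' Run the full unfolding analysis workflow
#'
#' Fits every frame of an unfolding series with the displaced-core model
#' under the locking protocol of the given preset (warm starts along the
#' series), fits single exponentials to the proteins-per-complex and
#' core-displacement trajectories to extract half-times, and runs a
#' Guinier analysis on every frame. With an output directory, the
#' parameter table, half-times and a JSON summary (embedding seed and
#' package version) are written to disk.
#'
#' @param series List of time-ordered [saxs_curve()] frames, or the list
#'   returned by [simulate_unfolding_series()].
#' @param preset Protocol preset name ([unfold_protocol()]).
#' @param seed Integer seed.
#' @param starts Multi-start budget for the first frame.
#' @param out_dir Optional output directory; never overwritten unless
#'   `force = TRUE`.
#' @param force Overwrite an existing non-empty `out_dir`.
#' @return A list with `params` (per-frame fit table), `kinetics`
#'   (half-time table for `Npro` and `s`), `guinier` (per-frame Rg/I0),
#'   and `summary`.
#' @export
run_unfold_analysis <- function(series, preset = "sds10.5", seed = 1,
                                starts = 8, out_dir = NULL, force = FALSE) {
  if (is.list(series) && !is.null(series$frames)) series <- series$frames
  if (length(series) == 0L) stop("empty series", call. = FALSE)
  protocol <- unfold_protocol(preset)
  params <- fit_unfolding_series(series, protocol, starts = starts,
                                 seed = seed)
  fits <- list(
    Npro = fit_exponentials(tibble::tibble(t = params$time_s,
                                           y = params$Npro), n = 1,
                            seed = seed),
    s = fit_exponentials(tibble::tibble(t = params$time_s, y = params$s),
                         n = 1, seed = seed))
  kin <- halftime_table(fits, labels = c("Npro", "s"))
  guin <- purrr::map_dfr(seq_along(series), function(i) {
    # early frames are clustered, so the aggregation upturn is expected;
    # the Rg/I0 trend itself carries that information
    g <- tryCatch(suppressWarnings(guinier_fit(series[[i]])),
                  error = function(e) NULL)
    if (is.null(g)) return(tibble::tibble(frame = i,
                                          time_s = curve_time(series[[i]]),
                                          Rg = NA_real_, I0 = NA_real_))
    tibble::tibble(frame = i, time_s = curve_time(series[[i]]),
                   Rg = g$Rg, I0 = g$I0)
  })
  summary <- list(workflow = "unfold-analysis", preset = preset,
                  seed = seed, n_frames = length(series),
                  t_half_Npro = kin$t_half_1[kin$label == "Npro"],
                  t_half_s = kin$t_half_1[kin$label == "s"],
                  median_chi2_red = stats::median(params$chi2_red),
                  package_version = as.character(utils::packageVersion("sfsaxs")))
  res <- list(params = params, kinetics = kin, guinier = guin,
              summary = summary)
  if (!is.null(out_dir)) write_report(res, out_dir, force)
  res
}

#' Run the full refolding analysis workflow
#'
#' Decomposes every frame of a refolding series into complex / micelle /
#' native / chain contributions with mass conservation, then fits single
#' exponentials to the native, coil and complex fraction trajectories to
#' extract the species half-times.
#'
#' @param series List of frames or the list returned by
#'   [simulate_refolding_series()] (whose basis is then used).
#' @param basis A [saxs_basis()]; required when `series` is a bare list
#'   of frames.
#' @param Rg,Rg_early,t_early Chain-Rg schedule, see [decompose_series()].
#' @param seed Integer seed.
#' @param out_dir,force Output directory handling as in
#'   [run_unfold_analysis()].
#' @return A list with `fractions` (per-frame scale table), `kinetics`
#'   (half-times for native/coil/complex), and `summary`.
#' @export
run_refold_analysis <- function(series, basis = NULL, Rg = 30,
                                Rg_early = 40, t_early = 0.3, seed = 1,
                                out_dir = NULL, force = FALSE) {
  if (is.list(series) && !is.null(series$frames)) {
    if (is.null(basis)) basis <- series$basis
    series <- series$frames
  }
  if (length(series) == 0L) stop("empty series", call. = FALSE)
  if (is.null(basis)) stop("basis curves required", call. = FALSE)
  fr <- decompose_series(series, basis, Rg = Rg, Rg_early = Rg_early,
                         t_early = t_early)
  fits <- list(
    native = fit_exponentials(tibble::tibble(t = fr$time_s, y = fr$a3),
                              n = 1, seed = seed),
    coil = fit_exponentials(tibble::tibble(t = fr$time_s, y = fr$a4),
                            n = 1, seed = seed),
    complex = fit_exponentials(tibble::tibble(t = fr$time_s, y = fr$a1),
                               n = 1, seed = seed))
  kin <- halftime_table(fits, labels = c("native", "coil", "complex"))
  summary <- list(workflow = "refold-analysis", seed = seed,
                  n_frames = length(series),
                  t_half_native = kin$t_half_1[kin$label == "native"],
                  t_half_coil = kin$t_half_1[kin$label == "coil"],
                  t_half_complex = kin$t_half_1[kin$label == "complex"],
                  median_chi2_red = stats::median(fr$chi2_red),
                  package_version = as.character(utils::packageVersion("sfsaxs")))
  res <- list(fractions = fr, kinetics = kin, summary = summary)
  if (!is.null(out_dir)) write_report(res, out_dir, force)
  res
}

write_report <- function(res, out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force)
    stop("output directory not empty (use force = TRUE): ", out_dir,
         call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in intersect(names(res), c("params", "fractions", "guinier",
                                     "kinetics")))
    readr::write_csv(res[[nm]], file.path(out_dir, paste0(nm, ".csv")))
  jsonlite::write_json(c(list(schema_version = 1), res$summary),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
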