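#' Construct a scattering curve
#'
#' A scattering curve is a tibble with columns `q` (scattering-vector
#' modulus, 1/Angstrom, strictly increasing), `I` (intensity on absolute
#' scale, 1/cm) and `sigma` (standard error of `I`, 1/cm), carrying an
#' optional frame mid-time since mixing (`time_s`, seconds) and a free-text
#' `label` as attributes.
#'
#' @param q Numeric vector of scattering-vector moduli, 1/Angstrom;
#'   strictly increasing, all positive.
#' @param I Intensity, 1/cm; same length as `q`.
#' @param sigma Standard error of `I`, 1/cm; positive wherever `I` is
#'   finite. If `NULL`, a documented default of 2% of `|I|` is used and a
#'   warning is raised.
#' @param time_s Optional frame mid-time since mixing, seconds.
#' @param label Optional free-text label.
#' @return A tibble of class `saxs_curve` with columns `q`, `I`, `sigma`.
#' @export
saxs_curve <- function(q, I, sigma = NULL, time_s = NULL, label = NULL) {
  if (is.null(sigma)) {
    warning("sigma missing; defaulting to 2% of |I|", call. = FALSE)
    sigma <- 0.02 * abs(I)
  }
  out <- tibble::tibble(q = as.numeric(q), I = as.numeric(I),
                        sigma = as.numeric(sigma))
  attr(out, "time_s") <- if (is.null(time_s)) NA_real_ else as.numeric(time_s)
  attr(out, "label") <- if (is.null(label)) NA_character_ else as.character(label)
  class(out) <- c("saxs_curve", class(out))
  validate_curve(out)
}

#' Validate a scattering curve
#'
#' Asserts the unit conventions enforced at every module boundary:
#' q strictly increasing and positive, equal column lengths, sigma
#' positive wherever the intensity is finite.
#'
#' @param curve A `saxs_curve` (or any data frame with columns q, I, sigma).
#' @return The validated curve, invisibly unchanged.
#' @export
validate_curve <- function(curve) {
  stopifnot(all(c("q", "I", "sigma") %in% names(curve)))
  if (nrow(curve) == 0L) stop("empty curve", call. = FALSE)
  q <- curve$q
  if (any(!is.finite(q)) || any(q <= 0)) stop("q must be finite and > 0", call. = FALSE)
  if (any(diff(q) <= 0)) stop("q not increasing", call. = FALSE)
  ok <- is.finite(curve$I)
  if (any(curve$sigma[ok] <= 0) || any(!is.finite(curve$sigma[ok])))
    stop("sigma must be > 0 wherever I is finite", call. = FALSE)
  curve
}

#' @export
print.saxs_curve <- function(x, ...) {
  t <- attr(x, "time_s")
  lab <- attr(x, "label")
  cat(sprintf("<saxs_curve> %d points, q = [%.4g, %.4g] 1/A%s%s\n",
              nrow(x), min(x$q), max(x$q),
              if (is.finite(t)) sprintf(", t = %.4g s", t) else "",
              if (!is.na(lab)) paste0(", ", lab) else ""))
  NextMethod()
}

curve_time <- function(curve) attr(curve, "time_s")

#' Read a scattering curve from an ASCII .dat file
#'
#' Whitespace-separated columns q, I and optionally sigma; comment lines
#' start with `#`. Header comments of the form `# key=value` carry
#' metadata (`time_s`, `label`). Non-numeric rows are skipped with a
#' message; a missing sigma column defaults to 2% of the intensity.
#'
#' @param path Path to an ASCII file with >= 2 columns.
#' @return A [saxs_curve()].
#' @export
read_curve <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  meta <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, invert = TRUE, value = TRUE)
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) stop("empty curve file: ", path, call. = FALSE)
  toks <- strsplit(trimws(body), "\\s+")
  ncol <- vapply(toks, length, integer(1))
  vals <- lapply(toks, function(x) suppressWarnings(as.numeric(x)))
  good <- ncol >= 2 & !vapply(vals, anyNA, logical(1))
  n_bad <- sum(!good)
  if (n_bad > 0)
    message(sprintf("read_curve: skipped %d non-numeric row(s) in %s", n_bad, path))
  vals <- vals[good]
  if (length(vals) == 0L) stop("no numeric rows in: ", path, call. = FALSE)
  q <- vapply(vals, `[`, numeric(1), 1L)
  I <- vapply(vals, `[`, numeric(1), 2L)
  has_sigma <- all(vapply(vals, length, integer(1)) >= 3L)
  sigma <- if (has_sigma) vapply(vals, `[`, numeric(1), 3L) else NULL
  get_meta <- function(key) {
    hit <- grep(paste0("^#\\s*", key, "\\s*="), meta, value = TRUE)
    if (length(hit) == 0L) return(NULL)
    trimws(sub(paste0("^#\\s*", key, "\\s*="), "", hit[[1L]]))
  }
  time_s <- get_meta("time_s")
  label <- get_meta("label")
  saxs_curve(q, I, sigma,
             time_s = if (!is.null(time_s)) as.numeric(time_s) else NULL,
             label = label)
}

#' Write a scattering curve to an ASCII .dat file
#'
#' Values are written with 15 significant digits so that
#' `read_curve(write_curve(x))` reproduces `x` to at least 12 significant
#' digits. Metadata (`time_s`, `label`) is stored in `# key=value` header
#' comments.
#'
#' @param curve A valid [saxs_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  validate_curve(curve)
  hdr <- c("# q[1/A] I[1/cm] sigma[1/cm]")
  t <- attr(curve, "time_s")
  lab <- attr(curve, "label")
  if (!is.null(t) && is.finite(t)) hdr <- c(hdr, sprintf("# time_s=%.15g", t))
  if (!is.null(lab) && !is.na(lab)) hdr <- c(hdr, paste0("# label=", lab))
  rows <- sprintf("%.15g %.15g %.15g", curve$q, curve$I, curve$sigma)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a stopped-flow frame series from a manifest
#'
#' The manifest is a CSV with header `file,time_s`; frame paths are
#' resolved relative to the manifest's directory. Frames are returned
#' ordered by time with their `time_s` attribute set from the manifest.
#'
#' @param manifest Path to the manifest CSV.
#' @return A list of [saxs_curve()] frames, ordered by time, with the
#'   manifest tibble in attribute `manifest`.
#' @export
read_series <- function(manifest) {
  if (!file.exists(manifest)) stop("no such manifest: ", manifest, call. = FALSE)
  man <- readr::read_csv(manifest, show_col_types = FALSE)
  stopifnot(all(c("file", "time_s") %in% names(man)))
  man <- dplyr::arrange(man, .data$time_s)
  dir <- dirname(manifest)
  paths <- ifelse(file.exists(man$file), man$file, file.path(dir, man$file))
  missing <- !file.exists(paths)
  if (any(missing))
    stop("missing frame file(s): ", paste(man$file[missing], collapse = ", "),
         call. = FALSE)
  frames <- purrr::map2(paths, man$time_s, function(p, t) {
    cv <- read_curve(p)
    attr(cv, "time_s") <- t
    cv
  })
  message(sprintf("read_series: %d frames, t = [%.4g, %.4g] s",
                  length(frames), min(man$time_s), max(man$time_s)))
  attr(frames, "manifest") <- man
  frames
}

#' Write a frame series and its manifest
#'
#' @param frames List of [saxs_curve()] frames, each with a finite
#'   `time_s` attribute.
#' @param dir Output directory (created if needed).
#' @param prefix Frame file name prefix.
#' @return Path to the written manifest CSV, invisibly.
#' @export
write_series <- function(frames, dir, prefix = "frame") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  times <- vapply(frames, curve_time, numeric(1))
  stopifnot(all(is.finite(times)), !is.unsorted(times, strictly = TRUE))
  files <- sprintf("%s_%03d.dat", prefix, seq_along(frames))
  purrr::walk2(frames, files, function(cv, f) write_curve(cv, file.path(dir, f)))
  man <- tibble::tibble(file = files, time_s = times)
  mpath <- file.path(dir, "manifest.csv")
  readr::write_csv(man, mpath)
  invisible(mpath)
}
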