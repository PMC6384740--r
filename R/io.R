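#' Write a titration series as spectra files plus a manifest
#'
#' Emits one CSV per point spectrum and a YAML manifest recording the
#' design: fixed-component total, per-point files with titrant totals and
#' inner-filter absorbances, excitation wavelength, window settings and
#' temperature. The manifest plus files round-trip through
#' [read_titration_series()].
#'
#' @param series a [titration_series()].
#' @param dir output directory (created if needed).
#' @param name basename for the manifest and spectra files.
#' @return Path of the manifest, invisibly.
#' @export
write_titration_series <- function(series, dir, name = "series") {
  stopifnot(inherits(series, "titration_series"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(length(series$points))
  for (j in seq_along(series$points)) {
    files[j] <- sprintf("%s_point%02d.csv", name, j)
    write_spectrum(series$points[[j]]$spectrum, file.path(dir, files[j]))
  }
  manifest <- list(
    fixed_total = series$fixed_total,
    excitation_wavelength = series$excitation_wavelength,
    window_center = series$window_center,
    window_width = series$window_width,
    temperature = series$temperature,
    label = series$label,
    points = lapply(seq_along(series$points), function(j) {
      p <- series$points[[j]]
      list(file = files[j], titrant_total = p$titrant_total,
           a_ex = p$a_ex, a_em = p$a_em)
    }))
  path <- file.path(dir, paste0(name, ".yaml"))
  yaml::write_yaml(manifest, path, precision = 17)
  invisible(path)
}

#' Read a titration series from a manifest
#'
#' @param path path to a YAML manifest written by [write_titration_series()]
#'   (or by hand in the same schema). Spectrum files are resolved relative
#'   to the manifest's directory. Missing required keys are config errors
#'   naming the key.
#' @return A [titration_series()].
#' @export
read_titration_series <- function(path) {
  m <- yaml::read_yaml(path)
  req <- c("fixed_total", "excitation_wavelength", "window_center",
           "window_width", "temperature", "points")
  missing <- setdiff(req, names(m))
  if (length(missing))
    stop("manifest ", path, " is missing required key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  dir <- dirname(path)
  pts <- lapply(seq_along(m$points), function(j) {
    e <- m$points[[j]]
    preq <- c("file", "titrant_total", "a_ex", "a_em")
    pmissing <- setdiff(preq, names(e))
    if (length(pmissing))
      stop("manifest ", path, " point ", j, " is missing key(s): ",
           paste(pmissing, collapse = ", "), call. = FALSE)
    f <- file.path(dir, e$file)
    if (!file.exists(f))
      stop("manifest ", path, " references missing spectrum file ", e$file,
           call. = FALSE)
    titration_point(e$titrant_total,
                    read_spectrum(f, kind = "emission",
                                  temperature = m$temperature),
                    a_ex = e$a_ex, a_em = e$a_em)
  })
  titration_series(m$fixed_total, pts,
                   excitation_wavelength = m$excitation_wavelength,
                   window_center = m$window_center,
                   window_width = m$window_width,
                   temperature = m$temperature,
                   label = m$label %||% "")
}
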