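#' One point of a fluorescence titration
#'
#' A titration point records the emission spectrum measured after one
#' addition of titrant, the total titrant concentration at that point, and
#' the solution absorbances at the excitation wavelength and at the centre
#' of the analysis window (needed for the inner-filter correction).
#'
#' @param titrant_total total titrant concentration, mol/L (>= 0).
#' @param spectrum an emission-kind [spectrum()].
#' @param a_ex absorbance at the excitation wavelength (>= 0).
#' @param a_em absorbance at the emission-window centre (>= 0).
#' @return An object of class `"titration_point"`.
#' @export
titration_point <- function(titrant_total, spectrum, a_ex = 0, a_em = 0) {
  stopifnot(inherits(spectrum, "spectrum"))
  if (spectrum$kind != "emission")
    stop("titration point spectra must be emission kind", call. = FALSE)
  if (titrant_total < 0) stop("titrant_total must be >= 0", call. = FALSE)
  if (a_ex < 0 || a_em < 0)
    stop("absorbances must be >= 0", call. = FALSE)
  structure(list(titrant_total = titrant_total, spectrum = spectrum,
                 a_ex = a_ex, a_em = a_em),
            class = "titration_point")
}

#' An ordered fluorescence titration series
#'
#' Holds the full design of one titration: the fixed (non-titrated)
#' component concentration, the ordered points starting from the titrant-free
#' reference (the F_0 source), and the excitation/analysis-window settings.
#'
#' @param fixed_total concentration of the fixed component, mol/L (the total
#'   protein concentration when a ligand is titrated into protein).
#' @param points list of [titration_point()]s with strictly increasing
#'   `titrant_total`, the first equal to 0.
#' @param excitation_wavelength nm.
#' @param window_center centre of the summation window, nm (typically the
#'   emission maximum).
#' @param window_width full window width, nm (default 10).
#' @param temperature kelvin.
#' @param label free text.
#' @return An object of class `"titration_series"`.
#' @export
titration_series <- function(fixed_total, points, excitation_wavelength,
                             window_center, window_width = 10,
                             temperature = 310.15, label = "") {
  if (!is.list(points) || !all(vapply(points, inherits, TRUE, "titration_point")))
    stop("points must be a list of titration_point objects", call. = FALSE)
  conc <- vapply(points, function(p) p$titrant_total, numeric(1))
  if (length(points) < 2L)
    stop("a titration series needs at least 2 points", call. = FALSE)
  if (conc[1L] != 0)
    stop("first point must be the titrant-free reference (titrant_total = 0)",
         call. = FALSE)
  if (any(diff(conc) <= 0))
    stop("titrant_total must be strictly increasing", call. = FALSE)
  if (fixed_total < 0) stop("fixed_total must be >= 0", call. = FALSE)
  structure(list(fixed_total = fixed_total, points = points,
                 excitation_wavelength = excitation_wavelength,
                 window_center = window_center, window_width = window_width,
                 temperature = temperature, label = as.character(label)[1L]),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  conc <- vapply(x$points, function(p) p$titrant_total, numeric(1))
  cat(sprintf(paste0("<titration_series> %d points, fixed %.3g M, ",
                     "titrant 0-%.3g M, ex %g nm, window %g +/- %g nm, ",
                     "T = %g K%s\n"),
              length(x$points), x$fixed_total, max(conc),
              x$excitation_wavelength, x$window_center, x$window_width / 2,
              x$temperature,
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

#' Titrant concentrations of a series
#' @param series a [titration_series()].
#' @return Numeric vector of total titrant concentrations (mol/L).
#' @export
titrant_concentrations <- function(series) {
  vapply(series$points, function(p) p$titrant_total, numeric(1))
}

#' Corrected, window-integrated intensities of a series
#'
#' Applies the requested corrections to every point (background subtraction
#' against `buffer` if enabled and supplied, then the inner-filter
#' correction with the point's recorded absorbances) and sums each corrected
#' spectrum over the series' analysis window.
#'
#' @param series a [titration_series()].
#' @param corrections a [correction_settings()].
#' @param buffer optional buffer blank [spectrum()] on the same grid.
#' @return Numeric vector of intensities, one per point.
#' @export
series_intensities <- function(series, corrections = correction_settings(),
                               buffer = NULL) {
  stopifnot(inherits(series, "titration_series"),
            inherits(corrections, "correction_settings"))
  vapply(series$points, function(p) {
    s <- p$spectrum
    if (corrections$apply_background && !is.null(buffer))
      s <- subtract_background(s, buffer)
    f <- integrate_window(s, series$window_center, series$window_width)
    if (corrections$apply_inner_filter)
      f <- inner_filter_correct(f, p$a_ex, p$a_em)
    f
  }, numeric(1))
}
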