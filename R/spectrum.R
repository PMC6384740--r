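#' Construct a spectrum
#'
#' A `spectrum` is one measured curve: a strictly increasing axis grid
#' (wavelength in nm for optical data, wavenumber in cm^-1 for IR) with one
#' signal value per grid point, tagged with the kind of measurement and the
#' solution conditions it was recorded under.
#'
#' @param axis numeric vector, strictly increasing, length >= 2. Wavelength
#'   (nm) or wavenumber (cm^-1) grid.
#' @param signal numeric vector, same length as `axis`.
#' @param kind one of `"emission"`, `"absorbance"`, `"cd_millidegrees"`,
#'   `"ir_absorbance"`.
#' @param temperature temperature in kelvin (> 0).
#' @param ph solution pH (dimensionless).
#' @param label free-text description.
#' @return An object of class `"spectrum"`: a list with fields `axis`,
#'   `signal`, `kind`, `temperature`, `ph`, `label`.
#' @examples
#' s <- spectrum(300:310, dnorm(300:310, 305, 2), kind = "emission")
#' peak_position(s)
#' @export
spectrum <- function(axis, signal, kind = c("emission", "absorbance",
                                            "cd_millidegrees", "ir_absorbance"),
                     temperature = 310.15, ph = 7.4, label = "") {
  kind <- match.arg(kind)
  axis <- as.numeric(axis)
  signal <- as.numeric(signal)
  if (length(axis) < 2L)
    stop("spectrum axis must have at least 2 points", call. = FALSE)
  if (length(axis) != length(signal))
    stop("axis and signal lengths differ (", length(axis), " vs ",
         length(signal), ")", call. = FALSE)
  if (anyNA(axis) || anyNA(signal))
    stop("spectrum axis/signal must not contain NA", call. = FALSE)
  if (any(diff(axis) <= 0))
    stop("spectrum axis must be strictly increasing", call. = FALSE)
  if (!is.numeric(temperature) || length(temperature) != 1L || temperature <= 0)
    stop("temperature must be a single positive value (kelvin)", call. = FALSE)
  structure(list(axis = axis, signal = signal, kind = kind,
                 temperature = temperature, ph = ph,
                 label = as.character(label)[1L]),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  unit <- if (x$kind == "ir_absorbance") "cm^-1" else "nm"
  cat(sprintf("<spectrum> %s, %d points, %g-%g %s, T = %g K%s\n",
              x$kind, length(x$axis), min(x$axis), max(x$axis), unit,
              x$temperature,
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

#' @export
plot.spectrum <- function(x, ...) {
  xlab <- if (x$kind == "ir_absorbance") expression(wavenumber ~ (cm^-1)) else "wavelength (nm)"
  ylab <- switch(x$kind,
                 emission = "fluorescence intensity (a.u.)",
                 absorbance = "absorbance",
                 cd_millidegrees = "ellipticity (mdeg)",
                 ir_absorbance = "absorbance")
  graphics::plot(x$axis, x$signal, type = "l", xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' @export
as.data.frame.spectrum <- function(x, ...) {
  data.frame(axis = x$axis, signal = x$signal)
}

#' Read a spectrum from delimited text
#'
#' Parses a two-column comma-separated file (axis, signal) with `'.'` decimal
#' separator, optional header row and optional `#` comment lines, and
#' validates the [spectrum()] invariants. Malformed rows and invariant
#' violations are errors, never silently repaired.
#'
#' @param path path to a CSV file.
#' @param kind spectrum kind, see [spectrum()].
#' @param temperature,ph,label metadata forwarded to [spectrum()].
#' @return A [spectrum()].
#' @seealso [write_spectrum()] for the bit-faithful inverse.
#' @export
read_spectrum <- function(path, kind = "emission", temperature = 310.15,
                          ph = 7.4, label = basename(path)) {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L)
    stop("no data rows in ", path, call. = FALSE)
  parts <- strsplit(lines, ",", fixed = TRUE)
  bad_shape <- which(lengths(parts) != 2L)
  if (length(bad_shape))
    stop("line ", lineno[bad_shape[1L]], " of ", path,
         ": expected 2 comma-separated fields", call. = FALSE)
  m <- matrix(trimws(unlist(parts)), ncol = 2L, byrow = TRUE)
  # tolerate a single header row of non-numeric column names
  first_num <- suppressWarnings(as.numeric(m[1L, ]))
  if (anyNA(first_num)) {
    m <- m[-1L, , drop = FALSE]
    lineno <- lineno[-1L]
    if (nrow(m) == 0L) stop("no data rows in ", path, call. = FALSE)
  }
  axis <- suppressWarnings(as.numeric(m[, 1L]))
  signal <- suppressWarnings(as.numeric(m[, 2L]))
  bad <- which(is.na(axis) | is.na(signal))
  if (length(bad))
    stop("line ", lineno[bad[1L]], " of ", path, ": non-numeric cell",
         call. = FALSE)
  if (any(diff(axis) <= 0)) {
    i <- which(diff(axis) <= 0)[1L]
    stop("line ", lineno[i + 1L], " of ", path,
         ": axis not strictly increasing", call. = FALSE)
  }
  spectrum(axis, signal, kind = kind, temperature = temperature, ph = ph,
           label = label)
}

#' Write a spectrum to delimited text
#'
#' Writes `axis,signal` rows with full double precision (17 significant
#' digits) so that [read_spectrum()] reproduces the values bit-identically.
#'
#' @param s a [spectrum()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "spectrum"))
  rows <- paste(formatC(s$axis, format = "g", digits = 17),
                formatC(s$signal, format = "g", digits = 17), sep = ",")
  writeLines(c("axis,signal", rows), path, useBytes = TRUE)
  invisible(path)
}

#' Subtract a buffer background spectrum
#'
#' Pointwise subtraction of a buffer blank from a sample recorded on the
#' identical axis grid. Grids must match exactly: no interpolation is ever
#' performed, because silent resampling corrupts quantitative comparisons.
#'
#' @param sample,buffer [spectrum()] objects with identical axis grids and
#'   kinds.
#' @return A [spectrum()] carrying the sample's metadata with
#'   `signal = sample$signal - buffer$signal`.
#' @export
subtract_background <- function(sample, buffer) {
  stopifnot(inherits(sample, "spectrum"), inherits(buffer, "spectrum"))
  if (sample$kind != buffer$kind)
    stop("kind mismatch: ", sample$kind, " vs ", buffer$kind, call. = FALSE)
  if (length(sample$axis) != length(buffer$axis) ||
      !isTRUE(all(sample$axis == buffer$axis)))
    stop("axis grids differ; background subtraction requires identical grids ",
         "(no interpolation is performed)", call. = FALSE)
  out <- sample
  out$signal <- sample$signal - buffer$signal
  out
}

#' Inner-filter correction of fluorescence intensity
#'
#' Corrects an observed fluorescence intensity for attenuation of the
#' excitation beam and reabsorption of emitted light by absorbing species:
#' `F_cor = F_obs * 10^((A_ex + A_em)/2)`, where `A_ex` and `A_em` are the
#' solution absorbances at the excitation and emission wavelengths.
#'
#' @param f_obs observed intensity (>= 0); vectorised.
#' @param a_ex absorbance at the excitation wavelength (>= 0).
#' @param a_em absorbance at the emission wavelength (>= 0).
#' @return Corrected intensity, same shape as `f_obs`.
#' @examples
#' inner_filter_correct(100, 0.1, 0.1)  # 100 * 10^0.1
#' @export
inner_filter_correct <- function(f_obs, a_ex, a_em) {
  if (any(f_obs < 0)) stop("f_obs must be non-negative", call. = FALSE)
  if (any(a_ex < 0) || any(a_em < 0))
    stop("absorbances must be non-negative", call. = FALSE)
  f_obs * 10^((a_ex + a_em) / 2)
}

#' Sum signal over a closed wavelength window
#'
#' Adds up the sampled signal values whose axis position lies inside the
#' closed interval `[center - width/2, center + width/2]` (both endpoints
#' inclusive). Summation over a window around the emission maximum is the
#' standard way to suppress point noise before forming intensity ratios.
#' A zero-width window returns the single sample nearest to `center`.
#'
#' @param s a [spectrum()].
#' @param center window center (axis units).
#' @param width full window width (axis units), >= 0.
#' @return Scalar sum of in-window signal samples.
#' @export
integrate_window <- function(s, center, width) {
  stopifnot(inherits(s, "spectrum"))
  if (width < 0) stop("width must be >= 0", call. = FALSE)
  lo <- center - width / 2
  hi <- center + width / 2
  if (lo < min(s$axis) || hi > max(s$axis))
    stop(sprintf("window [%g, %g] outside axis range [%g, %g]",
                 lo, hi, min(s$axis), max(s$axis)), call. = FALSE)
  if (width == 0)
    return(s$signal[which.min(abs(s$axis - center))])
  sum(s$signal[s$axis >= lo & s$axis <= hi])
}

#' Locate the emission peak
#'
#' Axis position of the global signal maximum of an emission spectrum. Ties
#' break to the smallest axis value so that blue shifts are reported
#' deterministically; an all-equal signal carries no peak and is flagged.
#'
#' @param s an emission-kind [spectrum()].
#' @return The axis value of the maximum, with attribute `ambiguous = TRUE`
#'   when more than one sample attains the maximum (always set for the
#'   flat-signal case, which additionally warns).
#' @export
peak_position <- function(s) {
  stopifnot(inherits(s, "spectrum"))
  if (s$kind != "emission")
    stop("peak_position is defined for emission spectra", call. = FALSE)
  mx <- max(s$signal)
  at <- which(s$signal == mx)
  pos <- s$axis[at[1L]]  # smallest axis value among ties
  if (length(at) == length(s$signal))
    warning("signal is constant; peak position is ambiguous", call. = FALSE)
  attr(pos, "ambiguous") <- length(at) > 1L
  pos
}

#' Donor-acceptor spectral overlap score
#'
#' Trapezoidal integral of the donor emission (normalised internally to unit
#' area) against the acceptor absorbance over their common wavelength range —
#' the qualitative overlap that gates resonance energy transfer between a
#' tryptophan donor and a bound-ligand acceptor. Disjoint ranges score zero
#' with a warning.
#'
#' @param donor_emission emission [spectrum()] of the donor.
#' @param acceptor_absorbance absorbance [spectrum()] of the acceptor.
#' @return Overlap score with attributes `range_lo`/`range_hi` giving the
#'   common-range bounds used.
#' @export
spectral_overlap <- function(donor_emission, acceptor_absorbance) {
  stopifnot(inherits(donor_emission, "spectrum"),
            inherits(acceptor_absorbance, "spectrum"))
  d <- donor_emission; a <- acceptor_absorbance
  lo <- max(min(d$axis), min(a$axis))
  hi <- min(max(d$axis), max(a$axis))
  if (lo >= hi) {
    warning("donor and acceptor ranges are disjoint; overlap is 0",
            call. = FALSE)
    out <- 0
    attr(out, "range_lo") <- NA_real_
    attr(out, "range_hi") <- NA_real_
    return(out)
  }
  # unit-area normalisation of the donor over its full range
  darea <- trapz(d$axis, d$signal)
  if (darea <= 0) stop("donor emission has non-positive area", call. = FALSE)
  di <- d$axis >= lo & d$axis <= hi
  ai <- a$axis >= lo & a$axis <= hi
  if (!isTRUE(all.equal(d$axis[di], a$axis[ai])))
    stop("donor and acceptor grids differ on the common range; ",
         "no interpolation is performed", call. = FALSE)
  out <- trapz(d$axis[di], (d$signal[di] / darea) * a$signal[ai])
  attr(out, "range_lo") <- lo
  attr(out, "range_hi") <- hi
  out
}

# trapezoidal rule on an irregular grid
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1L] + y[-n]) * diff(x)) / 2
}

#' Correction settings for titration processing
#'
#' @param apply_background subtract a buffer blank from each point spectrum
#'   (requires a buffer spectrum wherever the setting is consumed).
#' @param apply_inner_filter apply [inner_filter_correct()] with each
#'   titration point's recorded absorbances.
#' @return An object of class `"correction_settings"`.
#' @export
correction_settings <- function(apply_background = TRUE,
                                apply_inner_filter = TRUE) {
  structure(list(apply_background = isTRUE(apply_background),
                 apply_inner_filter = isTRUE(apply_inner_filter)),
            class = "correction_settings")
}
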