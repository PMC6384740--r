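#' Quenching curve (F_0/F versus quencher concentration)
#'
#' @param concentrations total quencher concentrations, mol/L, starting at 0.
#' @param ratios F_0/F intensity ratios; `ratios[1]` must be exactly 1.
#' @param temperature kelvin.
#' @return An object of class `"quenching_curve"`.
#' @export
quenching_curve <- function(concentrations, ratios, temperature = 310.15) {
  concentrations <- as.numeric(concentrations)
  ratios <- as.numeric(ratios)
  if (length(concentrations) != length(ratios))
    stop("concentrations and ratios lengths differ", call. = FALSE)
  if (concentrations[1L] != 0)
    stop("first concentration must be 0 (the reference point)", call. = FALSE)
  if (ratios[1L] != 1)
    stop("ratio at zero quencher must be exactly 1", call. = FALSE)
  if (any(diff(concentrations) <= 0))
    stop("concentrations must be strictly increasing", call. = FALSE)
  structure(list(concentrations = concentrations, ratios = ratios,
                 temperature = temperature,
                 n_points_used = length(concentrations)),
            class = "quenching_curve")
}

#' @export
print.quenching_curve <- function(x, ...) {
  cat(sprintf("<quenching_curve> %d points, [Q] 0-%.3g M, F0/F up to %.4g, T = %g K\n",
              length(x$concentrations), max(x$concentrations),
              max(x$ratios), x$temperature))
  invisible(x)
}

#' Build a quenching curve from a titration series
#'
#' Forms the Stern-Volmer ratios F_0/F from corrected, window-integrated
#' intensities. Corrections are applied before the ratios are formed, so an
#' inner-filter-affected series analysed with the correction enabled yields
#' the true quenching curve; with the correction disabled the ratios are
#' biased upward by the residual attenuation.
#'
#' @param series a [titration_series()] whose first point is ligand-free.
#' @param corrections a [correction_settings()].
#' @param buffer optional buffer blank [spectrum()].
#' @return A [quenching_curve()]; `ratios[1]` is 1 by construction.
#' @export
build_quenching_curve <- function(series, corrections = correction_settings(),
                                  buffer = NULL) {
  f <- series_intensities(series, corrections, buffer)
  if (any(f <= 0))
    stop("non-positive corrected intensity at point ",
         which(f <= 0)[1L], "; cannot form F0/F", call. = FALSE)
  quenching_curve(titrant_concentrations(series), f[1L] / f,
                  temperature = series$temperature)
}

#' Stern-Volmer fit
#'
#' Ordinary least squares of F_0/F on quencher concentration over the first
#' `n_points` of the curve: `F_0/F = intercept + K_sv * [Q]`. Truncation to
#' the low-concentration points avoids the upward curvature that appears at
#' extreme quencher concentrations, where closely spaced fluorophore-quencher
#' pairs act as dark complexes; the curvature of the *full* curve is
#' reported as a flag. The intercept is fitted freely (not pinned at 1) so
#' that correction errors remain visible.
#'
#' @param curve a [quenching_curve()].
#' @param n_points number of low-concentration points used for the linear
#'   fit; default `min(7, length)` following the usual first-seven-samples
#'   truncation rule. Must be >= 3.
#' @param tau_0 unquenched fluorophore lifetime in seconds (default 1e-8 s,
#'   the tryptophan value), used to derive the bimolecular constant.
#' @return An object of class `"sv_fit"` with fields `K_sv` (slope, 1/M),
#'   `K_sv_se`, `intercept`, `pearson_r` (on the fitted subset), `k_q`
#'   (`K_sv / tau_0`, 1/(M s)), `tau_0`, `curvature_flag` (`"linear"`,
#'   `"upward"` or `"downward"` from the sign of a quadratic term fitted to
#'   the full curve), `n_points_used`, `temperature` and the underlying data.
#' @examples
#' q <- quenching_curve(c(0, 1, 2, 3, 4) * 1e-5, 1 + 5.35e3 * c(0, 1, 2, 3, 4) * 1e-5)
#' sv_fit(q, n_points = 5)
#' @export
sv_fit <- function(curve, n_points = NULL, tau_0 = 1e-8) {
  stopifnot(inherits(curve, "quenching_curve"))
  n <- length(curve$concentrations)
  if (is.null(n_points)) n_points <- min(7L, n)
  if (n_points < 3L) stop("n_points must be >= 3", call. = FALSE)
  if (n_points > n)
    stop("n_points (", n_points, ") exceeds curve length (", n, ")",
         call. = FALSE)
  if (tau_0 <= 0) stop("tau_0 must be > 0", call. = FALSE)
  q <- curve$concentrations[seq_len(n_points)]
  r <- curve$ratios[seq_len(n_points)]
  fit <- stats::lm(r ~ q)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  # lm warns "essentially perfect fit" on exact synthetic lines; the SE is
  # still well-defined (0), so silence it here
  se <- tryCatch(suppressWarnings(unname(summary(fit)$coefficients[2L, 2L])),
                 error = function(e) NA_real_)
  pr <- if (stats::sd(r) == 0) NA_real_ else unname(stats::cor(q, r))
  structure(list(K_sv = slope, K_sv_se = se, intercept = intercept,
                 pearson_r = pr,
                 k_q = bimolecular_constant(slope, tau_0), tau_0 = tau_0,
                 curvature_flag = curvature_flag(curve),
                 n_points_used = n_points, temperature = curve$temperature,
                 curve = curve, lm = fit),
            class = "sv_fit")
}

# sign of the quadratic term fitted to the full curve, with a scale-aware
# dead band so exactly linear data reads "linear" despite rounding noise
curvature_flag <- function(curve) {
  q <- curve$concentrations
  r <- curve$ratios
  span <- diff(range(r))
  if (length(q) < 4L || span == 0) return("linear")
  c2 <- unname(stats::coef(stats::lm(r ~ q + I(q^2)))[3L])
  if (is.na(c2)) return("linear")
  # contribution of the quadratic term across the concentration range,
  # relative to the overall signal span
  rel <- abs(c2) * max(q)^2 / span
  if (rel < 1e-6) "linear" else if (c2 > 0) "upward" else "downward"
}

#' @export
print.sv_fit <- function(x, ...) {
  cat("Stern-Volmer fit\n")
  cat(sprintf("  K_sv      = %.4g 1/M (se %.3g), intercept = %.6g\n",
              x$K_sv, x$K_sv_se, x$intercept))
  cat(sprintf("  k_q       = %.4g 1/(M s)  (tau_0 = %g s)\n", x$k_q, x$tau_0))
  cat(sprintf("  Pearson r = %.6g on %d points; full-curve shape: %s\n",
              x$pearson_r, x$n_points_used, x$curvature_flag))
  cat(sprintf("  T = %g K\n", x$temperature))
  invisible(x)
}

#' @export
coef.sv_fit <- function(object, ...) {
  c(intercept = object$intercept, K_sv = object$K_sv)
}

#' @export
predict.sv_fit <- function(object, concentrations = NULL, ...) {
  if (is.null(concentrations)) concentrations <- object$curve$concentrations
  object$intercept + object$K_sv * concentrations
}

#' @export
plot.sv_fit <- function(x, ...) {
  graphics::plot(x$curve$concentrations, x$curve$ratios,
                 xlab = "[Q] (mol/L)", ylab = expression(F[0] / F), ...)
  used <- seq_len(x$n_points_used)
  graphics::points(x$curve$concentrations[used], x$curve$ratios[used],
                   pch = 19)
  graphics::abline(x$intercept, x$K_sv, lty = 2)
  invisible(x)
}

#' @export
summary.sv_fit <- function(object, ...) {
  object
}

#' Bimolecular quenching constant
#'
#' `k_q = K_sv / tau_0`: the Stern-Volmer constant divided by the
#' unquenched fluorophore lifetime. Values above the diffusion-controlled
#' limit (~2e10 1/(M s)) indicate ground-state complex formation rather than
#' purely collisional quenching.
#'
#' @param K_sv Stern-Volmer constant, 1/M.
#' @param tau_0 unquenched lifetime, s (> 0); default 1e-8 s (tryptophan).
#' @return k_q in 1/((mol/L) s).
#' @export
bimolecular_constant <- function(K_sv, tau_0 = 1e-8) {
  if (tau_0 <= 0) stop("tau_0 must be > 0", call. = FALSE)
  K_sv / tau_0
}

#' Diffusion-controlled collisional quenching limit
#'
#' The maximum scattering collision quenching constant, 2.0e10 1/(M s);
#' bimolecular constants above it imply a static (complex-forming)
#' contribution.
#' @export
DIFFUSION_LIMIT_KQ <- 2.0e10

#' Classify the quenching mechanism from a temperature series
#'
#' The temperature dependence of the Stern-Volmer constant separates the
#' mechanisms: collisional (dynamic) quenching grows with temperature as
#' diffusion speeds up, ground-state complex (static) quenching weakens as
#' complexes dissociate, and a flat trend indicates a static/dynamic
#' combination. The trend is judged by the sign of a linear fit of K_sv
#' against temperature relative to a tolerance on the relative change across
#' the temperature span (three-temperature series cannot support a formal
#' hypothesis test).
#'
#' @param results_by_temperature a list of [sv_fit()] objects (their
#'   `temperature` fields are used), or a named list/vector mapping
#'   temperatures to K_sv values.
#' @param tolerance relative K_sv change across the full temperature span
#'   below which the trend counts as flat (default 0.05).
#' @param tau_0 lifetime used for the diffusion-limit check when raw K_sv
#'   values (not `sv_fit` objects) are supplied.
#' @return An object of class `"mechanism_call"`: `label` one of `"static"`,
#'   `"dynamic"`, `"static_dynamic_combination"`; `diffusion_limit_exceeded`
#'   (is k_q at the highest temperature above [DIFFUSION_LIMIT_KQ]?);
#'   `relative_trend` (fractional K_sv change per kelvin).
#' @examples
#' classify_mechanism(c("298.15" = 20e3, "303.15" = 17e3, "310.15" = 15.23e3))
#' @export
classify_mechanism <- function(results_by_temperature, tolerance = 0.05,
                               tau_0 = 1e-8) {
  if (is.list(results_by_temperature) &&
      all(vapply(results_by_temperature, inherits, TRUE, "sv_fit"))) {
    temps <- vapply(results_by_temperature, function(f) f$temperature, numeric(1))
    ksv <- vapply(results_by_temperature, function(f) f$K_sv, numeric(1))
    kq <- vapply(results_by_temperature, function(f) f$k_q, numeric(1))
  } else {
    ksv <- as.numeric(results_by_temperature)
    temps <- as.numeric(names(results_by_temperature))
    if (anyNA(temps))
      stop("supply sv_fit objects or a temperature-named vector of K_sv",
           call. = FALSE)
    kq <- ksv / tau_0
  }
  if (length(unique(temps)) < 2L)
    stop("mechanism classification needs >= 2 distinct temperatures",
         call. = FALSE)
  ord <- order(temps)
  temps <- temps[ord]; ksv <- ksv[ord]; kq <- kq[ord]
  slope <- unname(stats::coef(stats::lm(ksv ~ temps))[2L])
  span <- diff(range(temps))
  rel_change <- slope * span / mean(ksv)      # fractional change over the span
  rel_trend <- slope / mean(ksv)              # fractional change per kelvin
  label <- if (abs(rel_change) <= tolerance) {
    "static_dynamic_combination"
  } else if (slope < 0) "static" else "dynamic"
  structure(list(label = label,
                 diffusion_limit_exceeded = kq[length(kq)] > DIFFUSION_LIMIT_KQ,
                 relative_trend = rel_trend,
                 temperatures = temps, K_sv = ksv, tolerance = tolerance),
            class = "mechanism_call")
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat(sprintf("Quenching mechanism: %s\n", x$label))
  cat(sprintf("  relative K_sv trend: %+.3g /K (tolerance %.3g over the span)\n",
              x$relative_trend, x$tolerance))
  cat(sprintf("  diffusion limit exceeded at highest T: %s\n",
              x$diffusion_limit_exceeded))
  invisible(x)
}
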