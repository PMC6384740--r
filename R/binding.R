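#' Free-ligand concentration under ligand depletion
#'
#' Closed-form non-negative root of the 1:1 mass balance. When the bound
#' ligand is a non-negligible fraction of the total (ligand depletion), the
#' free concentration is not the total: it is the root of
#' `L_free^2 + (P_t + K_D - L_t) L_free - K_D L_t = 0`, i.e.
#' `L_free = ((L_t - P_t - K_D) + sqrt((L_t - P_t - K_D)^2 + 4 K_D L_t))/2`.
#'
#' @param l_total total ligand concentration, mol/L (vectorised).
#' @param p_total total protein concentration, mol/L.
#' @param k_d dissociation constant, mol/L (> 0).
#' @return Free ligand concentration(s), mol/L. Satisfies the mass balance
#'   `L_free + PL = L_t` with `(P_t - PL) L_free / PL = K_D`.
#' @examples
#' free_ligand(10e-6, 5e-6, 6.48e-6)
#' @export
free_ligand <- function(l_total, p_total, k_d) {
  if (any(l_total < 0) || any(p_total < 0))
    stop("concentrations must be >= 0", call. = FALSE)
  if (any(k_d <= 0)) stop("k_d must be > 0", call. = FALSE)
  b <- l_total - p_total - k_d
  disc <- sqrt(b * b + 4 * k_d * l_total)
  # (+) root of the quadratic; for b < 0 the direct form (b + disc)/2 cancels
  # catastrophically when 4*K_D*L_t << b^2, so use the conjugate form there
  out <- ifelse(b > 0, (b + disc) / 2, 2 * k_d * l_total / (disc - b))
  ifelse(l_total == 0, 0, out)
}

#' Fraction of protein sites occupied
#'
#' Occupancy of a single class of 1:1 sites: `PL/P_t = L_free/(L_free + K_D)`,
#' with `L_free` from the depletion-aware mass balance. Strictly increasing
#' in `l_total`, in `[0, 1)`.
#'
#' @inheritParams free_ligand
#' @return Fraction bound in `[0, 1)` (vectorised over `l_total`).
#' @export
fraction_bound <- function(l_total, p_total, k_d) {
  if (any(p_total <= 0))
    stop("fraction_bound requires p_total > 0", call. = FALSE)
  lf <- free_ligand(l_total, p_total, k_d)
  lf / (lf + k_d)
}

#' A titration dataset for binding analysis
#'
#' Pairs total ligand concentrations with observed intensity ratios F/F_0
#' at a fixed total protein concentration — the input of the equilibrium
#' binding fit. Quenching data have ratios <= 1, enhancement data >= 1; the
#' model treats both identically.
#'
#' @param p_total total protein concentration, mol/L.
#' @param l_totals total ligand concentrations, mol/L, strictly increasing
#'   from 0.
#' @param signal_ratios F/F_0 values; `signal_ratios[1]` must be 1.
#' @param temperature kelvin.
#' @param label free text.
#' @return An object of class `"binding_system"`.
#' @export
binding_system <- function(p_total, l_totals, signal_ratios,
                           temperature = 310.15, label = "") {
  l_totals <- as.numeric(l_totals)
  signal_ratios <- as.numeric(signal_ratios)
  if (length(l_totals) != length(signal_ratios))
    stop("l_totals and signal_ratios lengths differ", call. = FALSE)
  if (l_totals[1L] != 0)
    stop("l_totals must start at 0 (the F_0 reference)", call. = FALSE)
  if (any(diff(l_totals) <= 0))
    stop("l_totals must be strictly increasing", call. = FALSE)
  if (signal_ratios[1L] != 1)
    stop("signal_ratios[1] must be exactly 1", call. = FALSE)
  if (p_total <= 0) stop("p_total must be > 0", call. = FALSE)
  structure(list(p_total = p_total, l_totals = l_totals,
                 signal_ratios = signal_ratios, temperature = temperature,
                 label = as.character(label)[1L]),
            class = "binding_system")
}

#' Convert a quenching curve to a binding system
#'
#' The binding model works on F/F_0 (the reciprocal of the Stern-Volmer
#' ratio F_0/F).
#'
#' @param curve a [quenching_curve()].
#' @param p_total total protein concentration, mol/L.
#' @param label free text.
#' @return A [binding_system()].
#' @export
as_binding_system <- function(curve, p_total, label = "") {
  stopifnot(inherits(curve, "quenching_curve"))
  binding_system(p_total, curve$concentrations, 1 / curve$ratios,
                 temperature = curve$temperature, label = label)
}

#' Fit the 1:1 equilibrium binding model
#'
#' Nonlinear least squares of the two-state signal model
#' `F/F_0 = 1 + (R_sat - 1) * fraction_bound(L_t, P_t, K_D)` over
#' `(K_D, R_sat)`, where `R_sat` is the signal ratio at full saturation and
#' occupancy uses the ligand-depletion mass balance. On the semilogarithmic
#' F/F_0 versus free-ligand axis this is the classic sigmoid whose halfway
#' point sits at `L_free = K_D`; the fit reports that interpolated halfway
#' point (`free_ligand_at_half`) as a self-check of the estimate. K_D is
#' optimised on a log scale (positivity by construction), initialised at the
#' geometric midpoint of the nonzero ligand range, Levenberg-Marquardt with
#' relative step tolerance 1e-12.
#'
#' @param system a [binding_system()] with at least 5 points.
#' @param start optional named list with elements `k_d` and/or
#'   `ratio_at_saturation` overriding the default starting values.
#' @return An object of class `"binding_fit"` with fields `k_d` (mol/L),
#'   `ratio_at_saturation`, `delta_g` (kJ/mol at the system temperature),
#'   `free_ligand_at_half`, `residual_norm`, `k_d_se`, `saturation_flag`
#'   (TRUE when the series stops short of ~90% occupancy), `fitted`,
#'   `system`, `converged`.
#' @examples
#' lt <- c(0, 2, 5, 10, 20, 40, 80) * 1e-6
#' fb <- fraction_bound(lt, 5e-6, 6.48e-6)
#' sys <- binding_system(5e-6, lt, 1 + (0.2 - 1) * fb)
#' binding_fit(sys)
#' @export
binding_fit <- function(system, start = list()) {
  stopifnot(inherits(system, "binding_system"))
  lt <- system$l_totals
  r <- system$signal_ratios
  pt <- system$p_total
  if (length(lt) < 5L)
    stop("binding fit needs at least 5 titration points", call. = FALSE)
  span <- diff(range(r))
  if (span < 1e-9)
    stop("flat signal: K_D is unidentifiable from a constant F/F_0 curve",
         call. = FALSE)
  lpos <- lt[lt > 0]
  kd0 <- start$k_d %||% exp(mean(log(range(lpos))))
  rsat0 <- start$ratio_at_saturation %||%
    (r[length(r)] + 0.1 * (r[length(r)] - 1))
  if (rsat0 == 1) rsat0 <- r[length(r)]
  resid_fun <- function(par) {
    kd <- exp(par[1L]); rsat <- par[2L]
    r - (1 + (rsat - 1) * fraction_bound(lt, pt, kd))
  }
  fit <- minpack.lm::nls.lm(
    par = c(log(kd0), rsat0), fn = resid_fun,
    control = minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-12,
                                         maxiter = 500))
  if (fit$info == 0 || fit$info == 5)
    stop("binding fit failed to converge (nls.lm info = ", fit$info, "): ",
         fit$message, call. = FALSE)
  kd <- exp(fit$par[1L])
  rsat <- fit$par[2L]
  if (abs(rsat - 1) < 1e-8)
    stop("fitted saturation ratio is 1: K_D is unidentifiable", call. = FALSE)
  fitted <- 1 + (rsat - 1) * fraction_bound(lt, pt, kd)
  res <- r - fitted
  # delta-method SE of K_D from the log-scale covariance, when available
  kd_se <- tryCatch({
    cv <- chol2inv(chol(fit$hessian)) * (fit$deviance / max(1, length(r) - 2))
    sqrt(cv[1L, 1L]) * kd
  }, error = function(e) NA_real_)
  lf_half <- half_saturation_lfree(lt, pt, kd, rsat)
  max_occ <- fraction_bound(max(lt), pt, kd)
  structure(list(k_d = kd, ratio_at_saturation = rsat,
                 delta_g = gibbs_free_energy(kd, system$temperature),
                 free_ligand_at_half = lf_half,
                 residual_norm = sqrt(sum(res^2)),
                 k_d_se = kd_se,
                 saturation_flag = max_occ < 0.9,
                 fitted = fitted, residuals = res,
                 converged = TRUE, system = system,
                 temperature = system$temperature),
            class = "binding_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# interpolated L_free at which the fitted signal change is half its span;
# a consistency check that must land on K_D for the 1:1 model
half_saturation_lfree <- function(lt, pt, kd, rsat) {
  lf_grid <- free_ligand(seq(0, max(lt), length.out = 4096L), pt, kd)
  occ <- lf_grid / (lf_grid + kd)
  if (max(occ) < 0.5) return(NA_real_)
  i <- which(occ >= 0.5)[1L]
  if (i == 1L) return(lf_grid[1L])
  # linear interpolation in occupancy between the bracketing grid points
  w <- (0.5 - occ[i - 1L]) / (occ[i] - occ[i - 1L])
  lf_grid[i - 1L] + w * (lf_grid[i] - lf_grid[i - 1L])
}

#' @export
print.binding_fit <- function(x, ...) {
  cat("1:1 equilibrium binding fit (ligand depletion)\n")
  cat(sprintf("  K_D   = %.4g M (se %.3g)   [%.4g uM]\n",
              x$k_d, x$k_d_se, x$k_d * 1e6))
  cat(sprintf("  R_sat = %.4g   residual norm = %.3g\n",
              x$ratio_at_saturation, x$residual_norm))
  cat(sprintf("  dG    = %.3f kJ/mol at %g K\n", x$delta_g, x$temperature))
  cat(sprintf("  L_free at half-saturation = %.4g M\n", x$free_ligand_at_half))
  if (isTRUE(x$saturation_flag))
    cat("  warning: series does not approach saturation (<90% occupancy)\n")
  invisible(x)
}

#' @export
coef.binding_fit <- function(object, ...) {
  c(k_d = object$k_d, ratio_at_saturation = object$ratio_at_saturation)
}

#' @export
residuals.binding_fit <- function(object, ...) object$residuals

#' @export
predict.binding_fit <- function(object, l_totals = NULL, ...) {
  if (is.null(l_totals)) return(object$fitted)
  1 + (object$ratio_at_saturation - 1) *
    fraction_bound(l_totals, object$system$p_total, object$k_d)
}

#' @export
summary.binding_fit <- function(object, ...) object

#' @export
plot.binding_fit <- function(x, ...) {
  sys <- x$system
  lf <- free_ligand(sys$l_totals, sys$p_total, x$k_d)
  ok <- lf > 0
  graphics::plot(lf[ok], sys$signal_ratios[ok], log = "x",
                 xlab = expression(L[free] ~ (mol/L)),
                 ylab = expression(F / F[0]), ...)
  grid_lt <- exp(seq(log(min(sys$l_totals[sys$l_totals > 0]) / 2),
                     log(max(sys$l_totals)), length.out = 200))
  graphics::lines(free_ligand(grid_lt, sys$p_total, x$k_d),
                  predict(x, grid_lt), lty = 2)
  graphics::abline(v = x$k_d, col = "grey60")
  invisible(x)
}

#' Gibbs free energy of binding
#'
#' `dG = -R T ln(c0 / K_D)` with the standard reference concentration
#' `c0 = 1 mol/L` and `R = 8.314 J/(mol K)`, returned in kJ/mol. Negative
#' for K_D < 1 M, i.e. for any spontaneous association.
#'
#' @param k_d dissociation constant, mol/L (> 0).
#' @param temperature kelvin (> 0).
#' @return Gibbs free energy change, kJ/mol.
#' @examples
#' gibbs_free_energy(183.77e-6, 310.15)  # -22.181
#' @export
gibbs_free_energy <- function(k_d, temperature) {
  if (any(k_d <= 0)) stop("k_d must be > 0", call. = FALSE)
  if (any(temperature <= 0)) stop("temperature must be > 0", call. = FALSE)
  R <- 8.314  # J / (mol K)
  -R * temperature * log(1 / k_d) / 1000
}

#' Compare binary and ternary binding fits
#'
#' Judges whether a competitor changed a ligand's affinity: the ternary/binary
#' K_D ratio is compared against a relative threshold. A ratio below
#' `1 - threshold` means binding is enhanced (smaller K_D, stronger binding)
#' in the ternary system; above `1 + threshold`, weakened; otherwise
#' unchanged.
#'
#' @param binary,ternary [binding_fit()] objects at the same temperature.
#' @param threshold relative change regarded as meaningful (default 0.10).
#' @return An object of class `"interaction_report"`: `kd_binary`,
#'   `kd_ternary`, `ratio` (= kd_ternary/kd_binary), `call` in
#'   `{"unchanged", "enhanced", "weakened"}`.
#' @export
compare_systems <- function(binary, ternary, threshold = 0.10) {
  stopifnot(inherits(binary, "binding_fit"), inherits(ternary, "binding_fit"))
  if (!isTRUE(all.equal(binary$temperature, ternary$temperature)))
    stop("binary and ternary fits are at different temperatures (",
         binary$temperature, " vs ", ternary$temperature, " K)",
         call. = FALSE)
  ratio <- ternary$k_d / binary$k_d
  call <- if (abs(ratio - 1) <= threshold) "unchanged"
          else if (ratio < 1) "enhanced" else "weakened"
  structure(list(kd_binary = binary$k_d, kd_ternary = ternary$k_d,
                 ratio = ratio, call = call, threshold = threshold),
            class = "interaction_report")
}

#' @export
print.interaction_report <- function(x, ...) {
  cat(sprintf("Affinity comparison: %s\n", x$call))
  cat(sprintf("  K_D binary  = %.4g M\n  K_D ternary = %.4g M\n", x$kd_binary,
              x$kd_ternary))
  cat(sprintf("  ratio = %.4g (threshold %.2g)\n", x$ratio, x$threshold))
  invisible(x)
}
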