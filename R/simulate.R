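#' Reference concentration series of the serum-albumin titration designs
#'
#' The canonical designs emulated by the generator: 5 uM protein titrated
#' with quercetin 0-83.3 uM or amlodipine 0-500 uM (the quenching
#' experiments), and 7.5 uM ligand titrated with protein 0-30 uM (the
#' enhancement experiments). Values in mol/L.
#'
#' @name reference_series
#' @export
QUERCETIN_SERIES <- c(0, 1.95, 3.9, 7.8, 10.4, 15.6, 20.8, 31.25, 41.6,
                      62.5, 83.3) * 1e-6

#' @rdname reference_series
#' @export
AMLODIPINE_SERIES <- c(0, 3.9, 7.8, 15.6, 31.25, 62.5, 125, 250, 333.3,
                       500) * 1e-6

#' @rdname reference_series
#' @export
HSA_ENHANCEMENT_SERIES <- c(0, 1.87, 3.75, 7.5, 15, 20, 30) * 1e-6

#' Titration scenario: the forward model's ground truth
#'
#' Everything the fluorescence-titration generator needs: the binding
#' parameters, the static/dynamic split of the quenching, the emission band
#' geometry, the inner-filter absorbance coefficients, and the noise model.
#' The defaults describe the canonical quenching design: 5 uM protein,
#' quercetin-like concentration series, 310.15 K.
#'
#' @param p_total total protein concentration, mol/L.
#' @param l_totals titrant totals, mol/L, strictly increasing from 0.
#' @param k_d generative dissociation constant, mol/L.
#' @param ratio_at_saturation F/F_0 at full occupancy (static ground-state
#'   complex quenching; < 1 quenches, > 1 enhances, 1 = no static effect).
#' @param dynamic_kq collisional Stern-Volmer component, 1/M (0 = none).
#' @param emission_center,emission_sigma Gaussian emission band centre and
#'   sigma, nm.
#' @param blue_shift_at_saturation band blue shift at full occupancy, nm.
#' @param absorbance_per_molar length-2 numeric `c(ex, em)`: titrant
#'   absorbance per mol/L at the excitation wavelength and the emission
#'   window centre (inner-filter terms; 0 disables the effect).
#' @param noise_sd relative (multiplicative) Gaussian noise on intensities.
#' @param seed integer RNG seed; generation is bitwise-reproducible.
#' @param temperature kelvin.
#' @param excitation_wavelength nm.
#' @param f0_scale intensity of the unquenched reference at the band peak.
#' @return An object of class `"titration_scenario"`.
#' @export
titration_scenario <- function(p_total = 5e-6,
                               l_totals = QUERCETIN_SERIES,
                               k_d = 6.48e-6,
                               ratio_at_saturation = 0.2,
                               dynamic_kq = 0,
                               emission_center = 347,
                               emission_sigma = 18,
                               blue_shift_at_saturation = 0,
                               absorbance_per_molar = c(0, 0),
                               noise_sd = 0,
                               seed = 1L,
                               temperature = 310.15,
                               excitation_wavelength = 295,
                               f0_scale = 1000) {
  if (k_d <= 0) stop("k_d must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (l_totals[1L] != 0 || any(diff(l_totals) <= 0))
    stop("l_totals must be strictly increasing from 0", call. = FALSE)
  if (length(absorbance_per_molar) != 2L || any(absorbance_per_molar < 0))
    stop("absorbance_per_molar must be two non-negative scalars c(ex, em)",
         call. = FALSE)
  structure(list(p_total = p_total, l_totals = l_totals, k_d = k_d,
                 ratio_at_saturation = ratio_at_saturation,
                 dynamic_kq = dynamic_kq,
                 emission_center = emission_center,
                 emission_sigma = emission_sigma,
                 blue_shift_at_saturation = blue_shift_at_saturation,
                 absorbance_per_molar = absorbance_per_molar,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 temperature = temperature,
                 excitation_wavelength = excitation_wavelength,
                 f0_scale = f0_scale),
            class = "titration_scenario")
}

# emission grid shared by the titration generators: 1 nm steps around the band
titration_grid <- function(sc) {
  lo <- floor(sc$emission_center - 6 * sc$emission_sigma -
                abs(sc$blue_shift_at_saturation))
  hi <- ceiling(sc$emission_center + 6 * sc$emission_sigma)
  seq(lo, hi, by = 1)
}

# shared core: build a titration_series from per-point occupancy/free-ligand
build_synthetic_series <- function(sc, occupancy, l_free, label) {
  grid <- titration_grid(sc)
  set.seed(sc$seed)
  pts <- vector("list", length(sc$l_totals))
  for (j in seq_along(sc$l_totals)) {
    occ <- occupancy[j]
    static_factor <- 1 + (sc$ratio_at_saturation - 1) * occ
    dynamic_factor <- 1 / (1 + sc$dynamic_kq * l_free[j])
    center <- sc$emission_center - sc$blue_shift_at_saturation * occ
    band <- sc$f0_scale * exp(-(grid - center)^2 / (2 * sc$emission_sigma^2))
    a_ex <- sc$absorbance_per_molar[1L] * sc$l_totals[j]
    a_em <- sc$absorbance_per_molar[2L] * sc$l_totals[j]
    signal <- band * static_factor * dynamic_factor * 10^(-(a_ex + a_em) / 2)
    if (sc$noise_sd > 0)
      signal <- signal * (1 + stats::rnorm(length(signal), 0, sc$noise_sd))
    pts[[j]] <- titration_point(
      sc$l_totals[j],
      spectrum(grid, signal, kind = "emission",
               temperature = sc$temperature,
               label = sprintf("%s point %d", label, j)),
      a_ex = a_ex, a_em = a_em)
  }
  titration_series(sc$p_total, pts,
                   excitation_wavelength = sc$excitation_wavelength,
                   window_center = sc$emission_center, window_width = 10,
                   temperature = sc$temperature, label = label)
}

#' Simulate a binary fluorescence titration
#'
#' Forward model with known ground truth. Per point: site occupancy from
#' the depletion-aware mass balance at the scenario's K_D; a static signal
#' factor `1 + (R_sat - 1) * occupancy` (ground-state complex); an optional
#' collisional factor `1/(1 + K_dyn * L_free)`; a Gaussian emission band
#' whose centre blue-shifts in proportion to occupancy; inner-filter
#' attenuation `10^(-(A_ex + A_em)/2)` with absorbances proportional to the
#' titrant total (recorded per point, so the correction is exactly
#' invertible in the noise-free case); multiplicative Gaussian noise.
#'
#' @param sc a [titration_scenario()].
#' @return A [titration_series()] with attribute `truth` (the scenario).
#' @export
simulate_titration <- function(sc) {
  stopifnot(inherits(sc, "titration_scenario"))
  lf <- free_ligand(sc$l_totals, sc$p_total, sc$k_d)
  occ <- lf / (lf + sc$k_d)
  out <- build_synthetic_series(sc, occ, lf, label = "synthetic binary")
  attr(out, "truth") <- sc
  out
}

#' Two-ligand single-site competitive equilibrium
#'
#' Solves the coupled mass balance for two ligands competing for one class
#' of sites: `PL_i = P L_i,free / K_i`, `L_i,t = L_i,free (1 + P/K_i)`,
#' `P_t = P (1 + L_1,free/K_1 + L_2,free/K_2)`. Fixed-point iteration on
#' free protein, converged to a relative residual below 1e-12.
#'
#' @param l1_total,l2_total ligand totals, mol/L (vectorised over
#'   `l1_total`).
#' @param p_total protein total, mol/L.
#' @param k1,k2 dissociation constants, mol/L.
#' @return A data frame with columns `l1_free`, `l2_free`, `p_free`,
#'   `occ1`, `occ2` (site fractions occupied by each ligand).
#' @export
competitive_equilibrium <- function(l1_total, l2_total, p_total, k1, k2) {
  if (k1 <= 0 || k2 <= 0) stop("dissociation constants must be > 0",
                               call. = FALSE)
  one <- function(l1t) {
    p <- p_total  # start from all protein free
    converged <- FALSE
    for (it in seq_len(10000L)) {
      l1f <- l1t / (1 + p / k1)
      l2f <- l2_total / (1 + p / k2)
      p_new <- p_total / (1 + l1f / k1 + l2f / k2)
      if (p_new == p || abs(p_new - p) <= 1e-15 * p_new) {
        p <- p_new
        converged <- TRUE
        break
      }
      p <- 0.5 * (p + p_new)  # damped: the raw map can oscillate
    }
    if (!converged)
      stop("competitive equilibrium failed to converge", call. = FALSE)
    l1f <- l1t / (1 + p / k1)
    l2f <- l2_total / (1 + p / k2)
    resid <- abs(p * (1 + l1f / k1 + l2f / k2) - p_total) / p_total
    if (resid > 1e-12)
      stop("competitive equilibrium residual ", format(resid),
           " exceeds 1e-12", call. = FALSE)
    c(l1f, l2f, p)
  }
  m <- t(vapply(l1_total, one, numeric(3)))
  data.frame(l1_free = m[, 1L], l2_free = m[, 2L], p_free = m[, 3L],
             occ1 = m[, 3L] * m[, 1L] / (k1 * p_total),
             occ2 = m[, 3L] * m[, 2L] / (k2 * p_total))
}

#' Simulate a ternary (competitor-preincubated) titration
#'
#' Forward model for titrating one ligand into protein preincubated with a
#' second ligand. `mode = "competitive"` solves the two-ligand one-site
#' equilibrium exactly ([competitive_equilibrium()]); the competitor is
#' spectroscopically silent unless `competitor_ratio_at_saturation` differs
#' from 1. `mode = "cooperative"` models allosteric facilitation
#' phenomenologically: the titrant's K_D is multiplied by
#' `cooperative_factor` whenever competitor is present (the competitor does
#' not occupy the titrant's site). With `competitor_total = 0` both modes
#' reduce bitwise to [simulate_titration()] under the same seed.
#'
#' @param binary_sc the titrant's [titration_scenario()].
#' @param competitor_kd competitor dissociation constant, mol/L.
#' @param competitor_total competitor total concentration, mol/L.
#' @param mode `"competitive"` or `"cooperative"`.
#' @param cooperative_factor multiplier applied to the titrant K_D in
#'   cooperative mode (< 1 strengthens binding).
#' @param competitor_ratio_at_saturation F/F_0 at full competitor occupancy
#'   (competitive mode only; 1 = competitor does not affect the signal).
#' @param reference F_0 convention: `"complex"` normalises to the
#'   preincubated binary mixture (the titrant-free point of this series),
#'   `"free_protein"` to ligand-free protein.
#' @return A [titration_series()] with attribute `truth`.
#' @export
simulate_ternary <- function(binary_sc, competitor_kd, competitor_total,
                             mode = c("competitive", "cooperative"),
                             cooperative_factor = 1,
                             competitor_ratio_at_saturation = 1,
                             reference = c("complex", "free_protein")) {
  stopifnot(inherits(binary_sc, "titration_scenario"))
  mode <- match.arg(mode)
  reference <- match.arg(reference)
  if (competitor_kd <= 0) stop("competitor_kd must be > 0", call. = FALSE)
  if (competitor_total < 0) stop("competitor_total must be >= 0", call. = FALSE)
  sc <- binary_sc

  if (competitor_total == 0)
    return(simulate_titration(sc))

  if (mode == "cooperative") {
    sc$k_d <- sc$k_d * cooperative_factor
    out <- simulate_titration(sc)
    attr(out, "truth") <- c(attr(out, "truth"),
                            list(mode = "cooperative",
                                 cooperative_factor = cooperative_factor))
    out$label <- "synthetic ternary (cooperative)"
    return(out)
  }

  eq <- competitive_equilibrium(sc$l_totals, competitor_total, sc$p_total,
                                sc$k_d, competitor_kd)
  # competitor's static factor modulates every point; with the "complex"
  # reference it cancels against the titrant-free point on ratio formation
  comp_factor <- 1 + (competitor_ratio_at_saturation - 1) * eq$occ2
  sc2 <- sc
  out <- build_synthetic_series(sc2, eq$occ1, eq$l1_free,
                                label = "synthetic ternary (competitive)")
  for (j in seq_along(out$points)) {
    f <- comp_factor[j]
    if (reference == "complex") f <- f / comp_factor[1L]
    out$points[[j]]$spectrum$signal <- out$points[[j]]$spectrum$signal * f
  }
  attr(out, "truth") <- c(unclass(sc),
                          list(mode = "competitive",
                               competitor_kd = competitor_kd,
                               competitor_total = competitor_total,
                               reference = reference,
                               equilibrium = eq))
  out
}

#' CD scenario: ground truth for the synthetic CD generator
#'
#' @param helix_percent_truth generative helix content, percent.
#' @param conditions a [cd_conditions()] (defaults to the far-UV design:
#'   1 uM protein, 1 mm path, 585 residues).
#' @param near_uv_perturbation named numeric `c(tyr = ..., trp = ...)`:
#'   amplitudes (mdeg) of Gaussian perturbations centred in the tyrosine
#'   and tryptophan windows of the near-UV difference spectrum.
#' @param noise_sd additive Gaussian noise, mdeg.
#' @param seed integer RNG seed.
#' @return An object of class `"cd_scenario"`.
#' @export
cd_scenario <- function(helix_percent_truth = 59.1,
                        conditions = cd_conditions(1e-6, 0.1, 585L),
                        near_uv_perturbation = c(tyr = 0, trp = 0),
                        noise_sd = 0, seed = 1L) {
  stopifnot(inherits(conditions, "cd_conditions"))
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(helix_percent_truth = helix_percent_truth,
                 conditions = conditions,
                 near_uv_perturbation = near_uv_perturbation,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cd_scenario")
}

#' Simulate far- and near-UV CD spectra
#'
#' The far-UV spectrum is the canonical two-negative-band alpha-helix
#' template (minima at 208 and 222 nm) scaled so that the MRE at exactly
#' 208 nm is the closed-form inverse of the helix equation at the
#' scenario's generative helix content, then converted to millidegrees via
#' the MRE convention. The near-UV output is a smooth aromatic-region
#' baseline plus Gaussian perturbations in the Tyr (centre 281 nm) and Trp
#' (centre 295 nm) windows; the unperturbed baseline is returned as the
#' pure-protein reference for difference spectra.
#'
#' @param sc a [cd_scenario()].
#' @return A list with elements `far_uv`, `near_uv`, `near_uv_reference`
#'   (all `cd_millidegrees` [spectrum()]s) and `truth` (the scenario).
#' @export
simulate_cd <- function(sc) {
  stopifnot(inherits(sc, "cd_scenario"))
  set.seed(sc$seed)
  cond <- sc$conditions
  to_mdeg <- function(mre_vals)
    mre_vals * 10 * cond$n_residues * cond$protein_concentration *
      cond$path_length

  # far UV: 200-260 nm on a 0.5 nm grid (208 is a grid point)
  far_grid <- seq(200, 260, by = 0.5)
  template <- exp(-(far_grid - 208)^2 / (2 * 6^2)) +
    0.9 * exp(-(far_grid - 222)^2 / (2 * 7^2))
  t208 <- template[far_grid == 208]
  mre_far <- mre_208_for_helix(sc$helix_percent_truth) * template / t208
  theta_far <- to_mdeg(mre_far)
  if (sc$noise_sd > 0)
    theta_far <- theta_far + stats::rnorm(length(theta_far), 0, sc$noise_sd)
  far_uv <- spectrum(far_grid, theta_far, kind = "cd_millidegrees",
                     label = "synthetic far-UV CD")

  # near UV: 250-340 nm, smooth baseline + windowed perturbations
  near_grid <- seq(250, 340, by = 0.5)
  base <- 0.5 * exp(-(near_grid - 268)^2 / (2 * 12^2)) -
    0.3 * exp(-(near_grid - 290)^2 / (2 * 15^2))
  pert <- sc$near_uv_perturbation[["tyr"]] *
    exp(-(near_grid - 281)^2 / (2 * 2.5^2)) +
    sc$near_uv_perturbation[["trp"]] *
    exp(-(near_grid - 295)^2 / (2 * 3.5^2))
  noise <- if (sc$noise_sd > 0)
    stats::rnorm(length(near_grid), 0, sc$noise_sd) else 0
  near_uv <- spectrum(near_grid, base + pert + noise,
                      kind = "cd_millidegrees",
                      label = "synthetic near-UV CD (sample)")
  near_ref <- spectrum(near_grid, base, kind = "cd_millidegrees",
                       label = "synthetic near-UV CD (protein reference)")
  list(far_uv = far_uv, near_uv = near_uv, near_uv_reference = near_ref,
       truth = sc)
}

#' Simulate an amide-region IR spectrum
#'
#' Sum of Gaussian component bands on a wavenumber grid, plus optional
#' additive noise. The generative band list travels with the spectrum so
#' round-trip tests can compare fitted against true parameters.
#'
#' @param bands a non-empty list of [amide_band()]s.
#' @param grid wavenumber grid, cm^-1 (default 1480-1720 at 0.5 cm^-1).
#' @param noise_sd additive Gaussian noise, absorbance units.
#' @param seed integer RNG seed.
#' @return An `ir_absorbance` [spectrum()] with attribute `truth` (the band
#'   list).
#' @export
simulate_ir <- function(bands, grid = seq(1480, 1720, by = 0.5),
                        noise_sd = 0, seed = 1L) {
  if (length(bands) == 0L)
    stop("simulate_ir needs at least one band", call. = FALSE)
  stopifnot(all(vapply(bands, inherits, TRUE, "amide_band")))
  y <- 0
  for (b in bands)
    y <- y + b$amplitude * exp(-(grid - b$center)^2 / (2 * b$width^2))
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    y <- y + stats::rnorm(length(grid), 0, noise_sd)
  }
  out <- spectrum(grid, y, kind = "ir_absorbance", temperature = 298,
                  label = "synthetic amide-region IR")
  attr(out, "truth") <- bands
  out
}

#' Free-HSA amide I reference bands
#'
#' The three-component description of the free-protein amide I envelope
#' used as the default IR simulation target: 1651 cm^-1 (random coil,
#' strongest), 1660 cm^-1 (alpha-helix), 1667 cm^-1 (beta-turn), in
#' decreasing intensity order.
#'
#' @return A list of three [amide_band()]s.
#' @export
free_hsa_amide_bands <- function() {
  list(amide_band(1651, 4.5, 0.50),
       amide_band(1660, 4.0, 0.35),
       amide_band(1667, 3.5, 0.22))
}
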