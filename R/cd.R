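#' Circular dichroism measurement conditions
#'
#' @param protein_concentration mol/L (> 0).
#' @param path_length cuvette path length, cm (> 0).
#' @param n_residues number of amino-acid residues of the protein (> 0);
#'   585 for human serum albumin.
#' @return An object of class `"cd_conditions"`.
#' @export
cd_conditions <- function(protein_concentration, path_length = 0.1,
                          n_residues = 585L) {
  if (protein_concentration <= 0 || path_length <= 0 || n_residues <= 0)
    stop("cd_conditions fields must all be > 0", call. = FALSE)
  structure(list(protein_concentration = protein_concentration,
                 path_length = path_length,
                 n_residues = as.integer(n_residues)),
            class = "cd_conditions")
}

#' Mean residue ellipticity
#'
#' Normalises a raw ellipticity reading (millidegrees) per residue, molar
#' concentration and path length: `MRE = theta / (10 n c l)` with `theta` in
#' mdeg, `c` in mol/L and `l` in cm, giving deg cm^2/dmol.
#'
#' @param theta ellipticity in millidegrees (vectorised).
#' @param conditions a [cd_conditions()].
#' @return Mean residue ellipticity, deg cm^2/dmol.
#' @export
mre <- function(theta, conditions) {
  stopifnot(inherits(conditions, "cd_conditions"))
  theta / (10 * conditions$n_residues * conditions$protein_concentration *
             conditions$path_length)
}

# standardised 100%-content MRE values used by the alpha-helix equation
MRE_ALPHA_HELIX <- 33000
MRE_BETA_SHEET <- 4000

#' Alpha-helix content from MRE at 208 nm
#'
#' The single-wavelength helix estimate
#' `helix% = -(MRE_208 - MRE_beta) / (MRE_alpha - MRE_beta) * 100` with the
#' standardised values `MRE_alpha = 33000` (100% helix) and
#' `MRE_beta = 4000` (100% beta-sheet), evaluated exactly in this form.
#' Note the convention gives 100% at `MRE_208 = -25000`; estimates outside
#' `[0, 100]` are returned with a plausibility warning, not an error.
#'
#' @param mre_208 mean residue ellipticity at 208 nm, deg cm^2/dmol.
#' @return Helix content in percent.
#' @examples
#' helix_percent(-13139)  # 59.1
#' @export
helix_percent <- function(mre_208) {
  h <- -(mre_208 - MRE_BETA_SHEET) / (MRE_ALPHA_HELIX - MRE_BETA_SHEET) * 100
  if (any(h < 0 | h > 100))
    warning("helix percentage outside [0, 100]; check units and baseline",
            call. = FALSE)
  h
}

#' Inverse of the alpha-helix equation
#'
#' MRE at 208 nm that yields a given helix percentage; exact closed-form
#' inverse of [helix_percent()], used by the synthetic CD generator.
#'
#' @param helix helix content in percent.
#' @return MRE at 208 nm, deg cm^2/dmol.
#' @export
mre_208_for_helix <- function(helix) {
  MRE_BETA_SHEET - helix / 100 * (MRE_ALPHA_HELIX - MRE_BETA_SHEET)
}

#' Helix content for a titration of CD spectra
#'
#' Samples each far-UV spectrum at the grid point nearest 208 nm, converts
#' to MRE, and applies [helix_percent()]. When replicicate spectra are given
#' per molar ratio, the mean and standard deviation across replicates are
#' reported.
#'
#' @param series a list whose elements are either a single
#'   `cd_millidegrees` [spectrum()] or a list of replicate spectra; element
#'   names (or the `molar_ratio` argument) give the ligand:protein molar
#'   ratios.
#' @param conditions a [cd_conditions()].
#' @param molar_ratio optional numeric vector of molar ratios overriding the
#'   element names.
#' @return A data frame with columns `molar_ratio`, `mre_208`,
#'   `helix_percent`, `helix_sd` (NA for single spectra), `n_replicates`,
#'   ordered as supplied.
#' @export
helix_table <- function(series, conditions, molar_ratio = NULL) {
  stopifnot(inherits(conditions, "cd_conditions"))
  if (is.null(molar_ratio)) molar_ratio <- as.numeric(names(series))
  if (length(molar_ratio) != length(series) || anyNA(molar_ratio))
    stop("supply one molar ratio per series element", call. = FALSE)
  rows <- lapply(seq_along(series), function(i) {
    reps <- series[[i]]
    if (inherits(reps, "spectrum")) reps <- list(reps)
    h <- vapply(reps, function(s) {
      stopifnot(inherits(s, "spectrum"))
      if (208 < min(s$axis) || 208 > max(s$axis))
        stop("spectrum does not cover 208 nm", call. = FALSE)
      theta <- s$signal[which.min(abs(s$axis - 208))]
      helix_percent(mre(theta, conditions))
    }, numeric(1))
    m <- vapply(reps, function(s)
      mre(s$signal[which.min(abs(s$axis - 208))], conditions), numeric(1))
    data.frame(molar_ratio = molar_ratio[i],
               mre_208 = mean(m),
               helix_percent = mean(h),
               helix_sd = if (length(h) > 1L) stats::sd(h) else NA_real_,
               n_replicates = length(h))
  })
  do.call(rbind, rows)
}

# closed wavelength windows for aromatic-residue tertiary-structure reporting
TYR_WINDOW <- c(275, 287)
TRP_WINDOW <- c(285, 305)

#' Near-UV CD difference spectrum
#'
#' Brings a sample spectrum to the common baseline by subtracting the pure
#' protein reference recorded on the identical grid, and reports the mean
#' signed change in the tyrosine (275-287 nm) and tryptophan (285-305 nm)
#' windows — the standard empirical readout of tertiary-structure
#' perturbation around the aromatic residues. The 285-287 nm overlap is
#' counted in both windows.
#'
#' @param sample,reference_hsa `cd_millidegrees` [spectrum()]s on identical
#'   grids within 250-340 nm.
#' @return The difference [spectrum()] with attributes `tyr_mean` and
#'   `trp_mean` (mean signed signal change in each closed window).
#' @export
near_uv_difference <- function(sample, reference_hsa) {
  stopifnot(inherits(sample, "spectrum"), inherits(reference_hsa, "spectrum"))
  if (min(sample$axis) < 250 || max(sample$axis) > 340)
    stop("near-UV spectra must lie within 250-340 nm", call. = FALSE)
  d <- subtract_background(sample, reference_hsa)
  win_mean <- function(w) {
    i <- d$axis >= w[1L] & d$axis <= w[2L]
    if (!any(i)) NA_real_ else mean(d$signal[i])
  }
  attr(d, "tyr_mean") <- win_mean(TYR_WINDOW)
  attr(d, "trp_mean") <- win_mean(TRP_WINDOW)
  d
}
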