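---
title: "Models and methods behind spectrobind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spectrobind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectrobind)
```

spectrobind implements the quantitative core of a solution-spectroscopy
binding study: how a fluorescent protein's emission responds to a ligand
that binds one class of sites, and what that response says about affinity,
quenching mechanism, and protein conformation. This vignette states the
models, the assumptions behind them, the tunable parameters, and the
numerical choices, so that results can be interpreted — and distrusted —
for the right reasons.

## Signal corrections

Two corrections precede every quantitative step.

**Background.** Buffer blanks are subtracted pointwise
(`subtract_background()`). Grids must match exactly; the package never
interpolates or resamples, because silent resampling corrupts ratio-based
quantities downstream. Mismatched grids are errors by design.

**Inner filter.** Absorbing species attenuate both the excitation beam and
the emitted light. The standard first-order correction is

$$F_\mathrm{cor} = F_\mathrm{obs}\cdot 10^{(A_\mathrm{ex}+A_\mathrm{em})/2},$$

with $A_\mathrm{ex}$, $A_\mathrm{em}$ the absorbances at the excitation
wavelength and at the centre of the emission analysis window
(`inner_filter_correct()`). The correction uses scalar per-point
absorbances rather than per-sample values: the manifest format therefore
requires $A_\mathrm{ex}$/$A_\mathrm{em}$ for every titration point, and the
synthetic generator records them so the correction is exactly invertible on
noise-free data. Intensities are summed over a closed 10 nm window around
the emission maximum (`integrate_window()`; both endpoints inclusive, a
deterministic reading of "the 10 nm section, added up") to suppress point
noise before ratios are formed.

## Stern–Volmer analysis

Quenching curves are $F_0/F$ against total quencher concentration, with
$F_0$ the corrected, window-integrated intensity of the titrant-free
reference. The Stern–Volmer model

$$F_0/F = 1 + K_\mathrm{SV}[Q]$$

is fitted by ordinary least squares over the first `n_points` points
(default: the first seven, the usual guard against the upward curvature
that extreme quencher concentrations produce when closely spaced
fluorophore–quencher pairs act as dark complexes). Choices worth knowing:

* **The intercept is fitted freely**, not pinned at 1. A correct correction
  chain gives an intercept statistically indistinguishable from 1; pinning
  it would hide correction errors.
* **Curvature** of the *full* curve is reported as a flag (`linear`,
  `upward`, `downward`) from the sign of a quadratic term, with a relative
  dead band of 10⁻⁶ of the signal span so exactly linear data never flags.
  Upward curvature is the dark-complex signature; downward curvature is what
  a saturating static-binding curve produces.
* **$k_q = K_\mathrm{SV}/\tau_0$** with $\tau_0 = 10^{-8}$ s (the
  unquenched tryptophan lifetime) by default. The identity is enforced in
  the result object. Values above the diffusion-controlled limit
  $2\times10^{10}\ \mathrm{M^{-1}s^{-1}}$ flag static (complex-forming)
  quenching.
* **Mechanism classification** (`classify_mechanism()`) fits $K_\mathrm{SV}$
  linearly against temperature: a relative change across the span below a
  5% tolerance (configurable) reads as a static/dynamic combination,
  significantly negative as static, significantly positive as dynamic. With
  only two or three temperatures a formal hypothesis test would be theatre;
  the sign-plus-tolerance rule is explicit and configurable instead. The
  reported uncertainty on $K_\mathrm{SV}$ is the least-squares standard
  error of the slope.

## The equilibrium binding model

At the micromolar concentrations of these experiments, bound ligand is a
substantial fraction of total ligand — the free≈total approximation fails.
The package therefore always solves the 1:1 mass balance ("ligand
depletion"):

$$L_\mathrm{free} = \tfrac12\left[(L_t - P_t - K_D) +
\sqrt{(L_t - P_t - K_D)^2 + 4K_D L_t}\right].$$

Numerically, when $L_t - P_t - K_D < 0$ this textbook form cancels
catastrophically (protein excess, tight binding), so the conjugate form
$2K_DL_t/(\sqrt{\cdot} - b)$ is used on that branch; the implementation is
tested against a bisection oracle at $10^{-10}$ relative error over random
parameter triplets spanning six decades.

The signal model is the minimal two-state one: the fluorophore is either
free or in complex, so the observed ratio is affine in occupancy,

$$F/F_0 = 1 + (R_\mathrm{sat}-1)\cdot
\frac{L_\mathrm{free}}{L_\mathrm{free}+K_D},$$

with $R_\mathrm{sat}$ the ratio at full saturation. This treats quenching
($R_\mathrm{sat}<1$) and enhancement ($R_\mathrm{sat}>1$) identically, and
it is exactly the model under which "the halfway point of the sigmoid on a
semilog free-ligand axis" equals $K_D$ — the fit reports that interpolated
halfway point (`free_ligand_at_half`) as an internal consistency check.
One class of independent sites with stoichiometry 1 is assumed throughout;
no Hill exponent or Scatchard transformation is offered, deliberately —
linearising transforms of binding data obscure exactly the nonlinearities
that matter, and a fitted "n" from a single titration is not interpretable
as a site count.

**Optimisation.** Levenberg–Marquardt least squares (`minpack.lm`) over
$(\log K_D, R_\mathrm{sat})$: the log-parameterisation enforces positivity
without constraints, $K_D$ starts at the geometric midpoint of the sampled
nonzero ligand range, and the relative step tolerance is $10^{-12}$.
Degenerate inputs fail loudly: a flat signal is an unidentifiability error,
fewer than five points is an input error, and a series whose maximum
occupancy stays below 90% sets `saturation_flag` (the fit extrapolates
$R_\mathrm{sat}$ there, and $K_D$ inherits that uncertainty).

**Thermodynamics.** $\Delta G = -RT\ln(c^\ominus/K_D)$ with
$c^\ominus = 1$ mol/L and $R = 8.314$ J mol⁻¹ K⁻¹, reported in kJ/mol.
Note that recomputing $\Delta G$ from a $K_D$ printed to three significant
digits carries an intrinsic uncertainty of roughly
$RT\,\delta K/K \approx 0.002$ kJ/mol — third-decimal agreement with
published tables is only reachable when the unrounded $K_D$ is used, which
is why the package's checks of this closure allow exactly that input-precision
margin.

**Binary vs ternary.** `compare_systems()` reports the ternary/binary
$K_D$ ratio and a three-way call with a default 10% threshold. The
threshold is a judgment call made explicit: published narratives say
"unchanged" or "significantly increased" without a criterion, and the
propagated uncertainty of two nonlinear fits rarely supports a sharper
default.

## Circular dichroism

Mean residue ellipticity uses the standard convention
$\mathrm{MRE} = \theta/(10\,n\,c\,l)$ ($\theta$ in mdeg, $c$ in mol/L, $l$
in cm, $n$ residues; 585 for human serum albumin). Helix content comes from
the single-wavelength estimate at 208 nm,

$$\alpha\% = -\frac{\mathrm{MRE}_{208} - 4000}{33000 - 4000}\times 100,$$

implemented sign-for-sign in this printed form. The convention is odd — it
returns 100% at $\mathrm{MRE}_{208} = -25000$, not $-33000$ — so estimates
outside $[0, 100]$ raise a plausibility warning rather than an error; the
equation, not the package, is the source of the excursion. Only the 208 nm
estimate is produced: full basis-set deconvolution (CONTIN/CDSSTR-style)
is a different tool with different data demands and is out of scope.

Near-UV spectra are baselined by subtracting the pure-protein reference on
an identical grid, and the difference is summarised as mean signed change
in the closed Tyr (275–287 nm) and Trp (285–305 nm) windows; the 2 nm
overlap is counted in both, matching how the windows are quoted in
practice.

## FT-IR amide I decomposition

Band positions are found as the highest interior local maximum within
1600–1700 cm⁻¹ (amide I) and 1500–1600 cm⁻¹ (amide II). Decomposition fits
the amide I region as a sum of 2–6 Gaussians. Initial centres are the
deepest minima of a Savitzky–Golay smoothed second derivative (cubic,
~7 cm⁻¹ window) — the classical band-narrowing trick, and the reason the
procedure survives realistic noise: raw second differences on a fine grid
are noise-dominated. Widths and amplitudes are log-parameterised for
positivity, and the fit is Levenberg–Marquardt with deterministic jittered
restarts under the caller's seed. Bands are reported amplitude-descending.

This Gaussian band-fitting procedure deliberately replaces proprietary
Fourier self-deconvolution workflows: FSD's resolution-enhancement
parameters are instrument-software-specific and rarely reported, whereas a
Gaussian decomposition with stated initialisation is reproducible anywhere
and testable against synthetic truth. Gaussian (not Voigt or Lorentzian)
line shapes are the simplest adequate for assignment-level conclusions;
quantitative secondary-structure percentages from band areas are not
offered.

Assignment maps rounded band centres through closed wavenumber intervals
(defaults: 1645–1652 random coil, 1652.01–1662 α-helix, 1663–1672 β-turn;
boundaries take the interval whose lower bound they equal). Published
assignments of the 1650–1655 cm⁻¹ region genuinely conflict between
samples, so the rules are a visible, per-run input rather than a constant.

## The synthetic-data generator

The generator exists so that every analysis stage can be validated against
known truth. Its defaults are the canonical study conditions: 5 µM protein;
quercetin-like (0–83.3 µM, 11 points) and amlodipine-like (0–500 µM, 10
points) titrant series; 7.5 µM ligand with 0–30 µM protein for enhancement
designs; temperatures 298.15/303.15/310.15 K; an emission band at 347 nm
(σ = 18 nm) excited at 295 nm.

`simulate_titration()` composes, per point: occupancy from the same mass
balance the analysis uses (but the analysis refits $K_D$ — the round trip
is a genuine recovery, not an echo); a static factor
$1 + (R_\mathrm{sat}-1)\cdot\mathrm{occ}$; an optional collisional factor
$1/(1 + K_\mathrm{dyn}L_\mathrm{free})$; a blue shift proportional to
occupancy; inner-filter attenuation $10^{-(A_\mathrm{ex}+A_\mathrm{em})/2}$
with absorbances proportional to titrant total; and multiplicative Gaussian
noise. Noise is multiplicative because shot-noise-dominated fluorimetry at
these signal levels scales with intensity; the level is configurable and
defaults to zero so that deterministic tests are exact.

`simulate_ternary()` offers two mechanisms: *competitive* (the exact
two-ligand one-site equilibrium, solved by damped fixed-point iteration on
free protein, mass balances conserved to 10⁻¹² relative; the competitor is
spectroscopically silent by default) and *cooperative* (a phenomenological
$K_D$ multiplier applied when competitor is present — allosteric narratives
come without a mechanistic model, and a multiplier is the honest minimal
encoding). Both $F_0$ conventions for ternary series are available:
normalising to the preincubated complex (default, the operational choice
when the competitor is added first) or to free protein.

`simulate_cd()` inverts the helix equation exactly at 208 nm and shapes the
far-UV curve with the characteristic double minimum (208/222 nm);
`simulate_ir()` sums Gaussian bands. All generators are bitwise-reproducible
under a fixed seed.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: wavelength-dependent instrument response,
photobleaching and drift, Raman scatter, polarisation effects, pipetting
error correlated across points, deviations from the two-state signal model
(multiple binding classes, partial quenching of a second fluorophore), CD
basis-set mixing beyond the helix template, and non-Gaussian IR line
shapes. Recovery of generative parameters shows the estimators are correct
under the stated model; it cannot show the model fits a given instrument's
systematics.

## Problem sizes and determinism

The validation suite runs at desk scale by choice: titrations of 10–11
points (the canonical designs), 20-replicate noise studies at 1%
multiplicative noise, 10⁴ random triplets for the mass-balance oracle, and
0.5-unit grids for CD/IR spectra. These sizes keep the full suite under a
few seconds while leaving every estimate's error orders of magnitude from
its tolerance. Every stochastic test and generator call takes an explicit
seed; reports embed their settings and seeds so a rerun reproduces them
byte-for-byte.

## Known limitations

* Single-site 1:1 binding only; no Hill/multi-site or global
  multi-temperature (van 't Hoff) decomposition.
* The 208 nm helix estimate is a one-wavelength heuristic with a skewed
  convention (see above); treat absolute percentages with more caution than
  differences between conditions.
* The Stern–Volmer mechanism call is a trend heuristic over 2–3
  temperatures, not an inferential statement.
* FT-IR band assignment depends on the rule table; the defaults encode one
  reasonable convention for serum albumin, not a universal truth.
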