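# spectrobind

Quantitative analysis of protein–ligand binding from solution spectroscopy,
built around the drug-binding workflow for serum albumin: fluorescence
titration correction, Stern–Volmer quenching analysis, equilibrium
dissociation-constant estimation under ligand depletion, binary-versus-ternary
(competitive/cooperative) affinity comparison, circular-dichroism helix
content, and Gaussian decomposition of the FT-IR amide I band. A synthetic
data generator with known ground truth backs every analysis stage, so the
whole pipeline is testable end to end without instrument data.

## Who it is for

Anyone running fluorescence/CD/FT-IR binding studies of a fluorescent
protein (one class of 1:1 sites — human serum albumin and its single Trp214
reporter is the canonical case) who wants the standard spectroscopic
estimates computed reproducibly from plain-text spectra:

* **Corrections.** Buffer background subtraction and the inner-filter
  correction `F_cor = F_obs · 10^((A_ex + A_em)/2)`.
* **Stern–Volmer.** `F₀/F = 1 + K_SV·[Q]` fitted by OLS over the first
  seven (configurable) low-concentration points; bimolecular constant
  `k_q = K_SV/τ₀` (τ₀ = 10⁻⁸ s for Trp); mechanism classification from the
  temperature trend of K_SV (static / dynamic / combination) and the
  diffusion-limit check `k_q > 2×10¹⁰ M⁻¹s⁻¹`.
* **Binding.** The ligand-depletion 1:1 model: free ligand from the
  mass-balance quadratic
  `L_free = ½[(L_t−P_t−K_D) + √((L_t−P_t−K_D)² + 4K_D·L_t)]`, signal model
  `F/F₀ = 1 + (R_sat−1)·L_free/(L_free+K_D)` fitted by Levenberg–Marquardt
  with K_D log-parameterised; `ΔG = −RT·ln(c⁰/K_D)`; binary/ternary K_D
  comparison with an explicit threshold.
* **CD.** Mean residue ellipticity `MRE = θ/(10·n·c·l)`; helix content
  `α% = −(MRE₂₀₈ − 4000)/(33000 − 4000)·100`; near-UV difference spectra
  with Tyr (275–287 nm) and Trp (285–305 nm) window means.
* **FT-IR.** Amide I/II maxima location and sum-of-Gaussians decomposition
  of the amide I region (second-derivative initialisation), with
  configurable wavenumber→secondary-structure assignment rules.

## Worked example

Simulate a quercetin-like titration (5 µM protein, ligand 0–83.3 µM,
generative K_D = 6.48 µM, static quenching to 20% of F₀), then run the full
analysis:

```r
library(spectrobind)

sc  <- titration_scenario(p_total = 5e-6, l_totals = QUERCETIN_SERIES,
                          k_d = 6.48e-6, ratio_at_saturation = 0.2)
ser <- simulate_titration(sc)
report <- run_binary_analysis(run_config(ser))
report
#> == Binary titration analysis ==
#>
#> Stern-Volmer fits:
#>  temperature     K_sv  K_sv_se intercept pearson_r          k_q curvature
#>       310.15 67541.39 1843.661  1.025761 0.9981424 6.754139e+12  downward
#>  n_points_used
#>              7
#>
#> 1:1 equilibrium binding fit (ligand depletion)
#>   K_D   = 6.48e-06 M (se 1.86e-21)   [6.48 uM]
#>   R_sat = 0.2   residual norm = 1.76e-16
#>   dG    = -30.806 kJ/mol at 310.15 K
#>   L_free at half-saturation = 6.48e-06 M
#>
#> Emission peak shift (last vs first point): +0 nm
```

Reading it: the Stern–Volmer slope (≈6.8×10⁴ M⁻¹) is the initial quenching
sensitivity; its k_q (≈6.8×10¹² M⁻¹s⁻¹) exceeds the diffusion limit, as
expected for ground-state-complex quenching; the equilibrium fit recovers
the generative K_D = 6.48 µM exactly (noise-free data), with
ΔG ≈ −30.8 kJ/mol at 310.15 K; and the half-saturation free-ligand
concentration equals K_D, confirming the halfway-point construction. The
`downward` curvature flag records that a saturating static-quenching curve
bends below the initial Stern–Volmer line at high occupancy.

The CD and FT-IR paths work the same way:

```r
cond <- cd_conditions(1e-6, 0.1, 585L)          # 1 uM HSA, 1 mm path
sim  <- simulate_cd(cd_scenario(59.1, cond))
helix_percent(mre(sim$far_uv$signal[sim$far_uv$axis == 208], cond))
#> [1] 59.1

bands <- assign_bands(fit_amide_bands(simulate_ir(free_hsa_amide_bands()), 3))
bands_table(bands)
#>   center width amplitude       label
#> 1   1651   4.5      0.50 random_coil
#> 2   1660   4.0      0.35 alpha_helix
#> 3   1667   3.5      0.22   beta_turn
```

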