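# Independent oracles used across tests. These deliberately avoid the
# package's own code paths for the quantities they check.

# Vectorised bisection on the 1:1 mass-balance residual
#   g(Lf) = Lf + Pt * Lf / (Lf + Kd) - Lt
# Root bracketed in [0, Lt]; 200 halvings take the bracket below 1e-60*Lt.
bisect_free_ligand <- function(l_total, p_total, k_d, iters = 200L) {
  lo <- rep(0, length(l_total))
  hi <- l_total
  g <- function(lf) lf + p_total * lf / (lf + k_d) - l_total
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    pos <- g(mid) > 0
    hi <- ifelse(pos, mid, hi)
    lo <- ifelse(pos, lo, mid)
  }
  (lo + hi) / 2
}

# A Gaussian emission band on an integer-nm grid
gaussian_spectrum <- function(center = 347, sigma = 15, lo = 250, hi = 450,
                              amp = 1000, kind = "emission") {
  x <- seq(lo, hi, by = 1)
  spectrum(x, amp * exp(-(x - center)^2 / (2 * sigma^2)), kind = kind)
}

# Table of printed reference constants used by several tests: the four
# binary/ternary systems at 310.15 K (K_sv in 1/M, K_D in mol/L, dG kJ/mol)
reference_systems <- data.frame(
  system = c("AML+HSA", "Q+HSA", "(Q+HSA)+AML", "(AML+HSA)+Q"),
  K_sv = c(5.35e3, 15.23e3, 5.07e3, 76.02e3),
  k_q = c(5.35e11, 15.23e11, 5.07e11, 76.02e11),
  K_D = c(183.77e-6, 6.48e-6, 192.81e-6, 2.39e-6),
  delta_g = c(-22.181, -30.807, -22.057, -33.379))
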