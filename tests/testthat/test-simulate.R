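test_that("generators are bitwise-deterministic under a fixed seed", {
  sc <- titration_scenario(noise_sd = 0.01, seed = 7L)
  s1 <- simulate_titration(sc)
  s2 <- simulate_titration(sc)
  expect_identical(lapply(s1$points, function(p) p$spectrum$signal),
                   lapply(s2$points, function(p) p$spectrum$signal))

  c1 <- simulate_cd(cd_scenario(60, noise_sd = 0.3, seed = 3L))
  c2 <- simulate_cd(cd_scenario(60, noise_sd = 0.3, seed = 3L))
  expect_identical(c1$far_uv$signal, c2$far_uv$signal)
  expect_identical(c1$near_uv$signal, c2$near_uv$signal)

  i1 <- simulate_ir(free_hsa_amide_bands(), noise_sd = 0.01, seed = 5L)
  i2 <- simulate_ir(free_hsa_amide_bands(), noise_sd = 0.01, seed = 5L)
  expect_identical(i1$signal, i2$signal)
})

test_that("scenario invariants are enforced", {
  expect_error(titration_scenario(k_d = 0), "k_d")
  expect_error(titration_scenario(noise_sd = -1), "noise_sd")
  expect_error(titration_scenario(l_totals = c(1e-6, 2e-6)), "from 0")
  expect_error(titration_scenario(absorbance_per_molar = c(-1, 0)),
               "non-negative")
  expect_error(simulate_ir(list()), "at least one band")
})

test_that("noise-free generation with inner filter is exactly invertible", {
  sc <- titration_scenario(k_d = 6.48e-6, ratio_at_saturation = 0.2,
                           absorbance_per_molar = c(2000, 800))
  ser <- simulate_titration(sc)
  cur <- build_quenching_curve(ser, correction_settings())
  fb <- fraction_bound(sc$l_totals, sc$p_total, sc$k_d)
  expect_equal(1 / cur$ratios, 1 + (0.2 - 1) * fb, tolerance = 1e-12)
  fit <- binding_fit(as_binding_system(cur, sc$p_total))
  expect_lt(abs(fit$k_d - sc$k_d) / sc$k_d, 1e-3)
})

test_that("blue shift moves the emission peak by the occupancy-scaled amount", {
  sc <- titration_scenario(k_d = 6.48e-6, blue_shift_at_saturation = 8,
                           ratio_at_saturation = 0.5)
  ser <- simulate_titration(sc)
  p0 <- as.numeric(peak_position(ser$points[[1]]$spectrum))
  pN <- as.numeric(peak_position(ser$points[[length(ser$points)]]$spectrum))
  occN <- fraction_bound(max(sc$l_totals), sc$p_total, sc$k_d)
  expect_equal(p0 - pN, 8 * occN, tolerance = 0.15)  # one 1-nm grid step
})

test_that("pure dynamic temperature series classifies as dynamic", {
  fits <- lapply(c(298.15, 303.15, 310.15), function(temp) {
    kdyn <- 5e3 * (1 + (temp - 298.15) / 20)  # diffusion speeds up with T
    sc <- titration_scenario(ratio_at_saturation = 1, dynamic_kq = kdyn,
                             p_total = 1e-12, k_d = 1, temperature = temp)
    sv_fit(build_quenching_curve(simulate_titration(sc)))
  })
  expect_equal(classify_mechanism(fits)$label, "dynamic")
})

test_that("competitive equilibrium conserves mass to 1e-12", {
  set.seed(21)
  for (i in 1:25) {
    pt <- 10^runif(1, -7, -4)
    k1 <- 10^runif(1, -7, -4); k2 <- 10^runif(1, -7, -4)
    l1 <- 10^runif(1, -7, -3); l2 <- 10^runif(1, -7, -3)
    eq <- competitive_equilibrium(l1, l2, pt, k1, k2)
    pl1 <- eq$p_free * eq$l1_free / k1
    pl2 <- eq$p_free * eq$l2_free / k2
    expect_lt(abs(eq$p_free + pl1 + pl2 - pt) / pt, 1e-12)
    expect_lt(abs(eq$l1_free + pl1 - l1) / l1, 1e-12)
    expect_lt(abs(eq$l2_free + pl2 - l2) / l2, 1e-12)
  }
})

test_that("competitive equilibrium matches a brute-force grid refinement", {
  # independent check: solve for free protein by exhaustive bisection on the
  # monotone protein mass-balance residual
  pt <- 5e-6; k1 <- 6.48e-6; k2 <- 183.77e-6; l1 <- 2e-5; l2 <- 1e-4
  g <- function(p) p * (1 + (l1 / (1 + p / k1)) / k1 +
                          (l2 / (1 + p / k2)) / k2) - pt
  lo <- 0; hi <- pt
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
  }
  eq <- competitive_equilibrium(l1, l2, pt, k1, k2)
  expect_equal(eq$p_free, (lo + hi) / 2, tolerance = 1e-10)
})

test_that("ternary reduces bitwise to binary when no competitor is present", {
  sc <- titration_scenario(noise_sd = 0.01, seed = 9L)
  bin <- simulate_titration(sc)
  ter <- simulate_ternary(sc, competitor_kd = 1e-5, competitor_total = 0)
  expect_identical(lapply(bin$points, function(p) p$spectrum$signal),
                   lapply(ter$points, function(p) p$spectrum$signal))
})

test_that("a tight competitor right-shifts the apparent affinity", {
  sc <- titration_scenario(k_d = 6.48e-6, ratio_at_saturation = 0.2,
                           l_totals = QUERCETIN_SERIES)
  bin_fit <- binding_fit(as_binding_system(
    build_quenching_curve(simulate_titration(sc)), sc$p_total))
  ter <- simulate_ternary(sc, competitor_kd = 1e-6, competitor_total = 2e-5,
                          mode = "competitive")
  ter_fit <- binding_fit(as_binding_system(
    build_quenching_curve(ter), sc$p_total))
  expect_gt(ter_fit$k_d, 1.5 * bin_fit$k_d)
})

test_that("the cooperative factor reproduces the enhanced ternary affinity", {
  sc <- titration_scenario(k_d = 6.48e-6, ratio_at_saturation = 0.2,
                           l_totals = QUERCETIN_SERIES)
  ter <- simulate_ternary(sc, competitor_kd = 183.77e-6,
                          competitor_total = 5e-6, mode = "cooperative",
                          cooperative_factor = 2.39 / 6.48)
  fit <- binding_fit(as_binding_system(build_quenching_curve(ter), sc$p_total))
  expect_lt(abs(fit$k_d - 2.39e-6) / 2.39e-6, 1e-3)
})

test_that("CD generator round-trips the helix truth and the window design", {
  cond <- cd_conditions(1e-6, 0.1, 585L)
  sim <- simulate_cd(cd_scenario(0, cond))
  # zero-helix template scales to MRE_208 = 4000 exactly
  th208 <- sim$far_uv$signal[sim$far_uv$axis == 208]
  expect_equal(mre(th208, cond), 4000, tolerance = 1e-12)
  sim2 <- simulate_cd(cd_scenario(59.1, cond))
  th208 <- sim2$far_uv$signal[sim2$far_uv$axis == 208]
  expect_equal(helix_percent(mre(th208, cond)), 59.1, tolerance = 1e-10)
  # far-UV template carries the two characteristic negative minima
  expect_lt(sim2$far_uv$signal[sim2$far_uv$axis == 208], 0)
  expect_lt(sim2$far_uv$signal[sim2$far_uv$axis == 222], 0)
})
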