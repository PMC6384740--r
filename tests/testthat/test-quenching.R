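test_that("quenching curve construction enforces the reference point", {
  expect_error(quenching_curve(c(1e-6, 2e-6), c(1, 1.1)), "must be 0")
  expect_error(quenching_curve(c(0, 1e-6), c(1.01, 1.1)), "exactly 1")
  expect_error(quenching_curve(c(0, 2e-6, 1e-6), c(1, 1.1, 1.2)),
               "strictly increasing")
})

test_that("ratios from an unquenched series are all 1", {
  sc <- titration_scenario(ratio_at_saturation = 1, dynamic_kq = 0)
  ser <- simulate_titration(sc)
  cur <- build_quenching_curve(ser)
  expect_equal(cur$ratios, rep(1, length(cur$ratios)))
})

test_that("pure dynamic quenching reproduces the Stern-Volmer line exactly", {
  kdyn <- 1e4
  sc <- titration_scenario(ratio_at_saturation = 1, dynamic_kq = kdyn,
                           p_total = 1e-12, k_d = 1)
  # negligible binding: L_free == L_total, so F0/F = 1 + kdyn * [Q] exactly
  ser <- simulate_titration(sc)
  cur <- build_quenching_curve(ser)
  expect_equal(cur$ratios, 1 + kdyn * cur$concentrations, tolerance = 1e-10)
  fit <- sv_fit(cur)
  expect_equal(fit$K_sv, kdyn, tolerance = 1e-9)
  expect_equal(fit$intercept, 1, tolerance = 1e-9)
})

test_that("disabling the inner-filter correction biases the ratios upward", {
  sc <- titration_scenario(ratio_at_saturation = 0.3,
                           absorbance_per_molar = c(2000, 800))
  ser <- simulate_titration(sc)
  corrected <- build_quenching_curve(ser, correction_settings())
  uncorrected <- build_quenching_curve(
    ser, correction_settings(apply_inner_filter = FALSE))
  expect_true(all(uncorrected$ratios[-1] > corrected$ratios[-1]))
})

test_that("Stern-Volmer fit recovers an exact generative line", {
  conc <- c(0, 1.95, 3.9, 7.8, 10.4, 15.6, 20.8) * 1e-6
  cur <- quenching_curve(conc, 1 + 5.35e3 * conc)
  fit <- sv_fit(cur)
  expect_equal(fit$K_sv, 5.35e3, tolerance = 1e-10)
  expect_equal(fit$intercept, 1, tolerance = 1e-10)
  expect_equal(fit$pearson_r, 1, tolerance = 1e-12)
  expect_equal(fit$curvature_flag, "linear")
  expect_equal(fit$k_q, fit$K_sv / fit$tau_0)  # exact constructor identity
})

test_that("a constant curve fits slope zero", {
  conc <- c(0, 1, 2, 3, 4) * 1e-6
  cur <- quenching_curve(conc, rep(1, 5))
  fit <- sv_fit(cur, n_points = 5)
  expect_equal(fit$K_sv, 0)
  expect_true(is.na(fit$pearson_r))
})

test_that("dark-complex upward curvature is flagged on the full curve", {
  # combined static+dynamic series: product of two linear-in-[Q] factors
  conc <- seq(0, 5e-4, length.out = 12)
  ratios <- (1 + 5e3 * conc) * (1 + 4e3 * conc)
  cur <- quenching_curve(conc, ratios)
  fit <- sv_fit(cur, n_points = 7)
  expect_equal(fit$curvature_flag, "upward")
  # truncated estimate sits above the true initial slope (dark-complex bias)
  # but well below the full-curve secant slope
  expect_gt(fit$K_sv, 9e3)
  expect_lt(fit$K_sv, 2 * 9e3)
})

test_that("fit guards: n_points bounds", {
  cur <- quenching_curve(c(0, 1e-6, 2e-6, 3e-6), 1 + 1e3 * c(0, 1e-6, 2e-6, 3e-6))
  expect_error(sv_fit(cur, n_points = 2), ">= 3")
  expect_error(sv_fit(cur, n_points = 9), "exceeds curve length")
  expect_error(sv_fit(cur, tau_0 = 0), "tau_0")
})

test_that("bimolecular constant reproduces printed closures", {
  expect_equal(bimolecular_constant(5.35e3, 1e-8), 5.35e11)
  expect_equal(bimolecular_constant(15.23e3, 1e-8), 15.23e11)
  expect_equal(bimolecular_constant(0, 1e-8), 0)
  expect_error(bimolecular_constant(1e3, 0), "> 0")
})

test_that("mechanism classification follows the temperature trend", {
  dec <- c("298.15" = 20e3, "303.15" = 17e3, "310.15" = 15.23e3)
  m <- classify_mechanism(dec)
  expect_equal(m$label, "static")
  expect_true(m$diffusion_limit_exceeded)  # 15.23e3 / 1e-8 >> 2e10

  flat <- c("298.15" = 5e3, "303.15" = 5e3, "310.15" = 5e3)
  expect_equal(classify_mechanism(flat)$label, "static_dynamic_combination")

  inc <- c("298.15" = 5e3, "303.15" = 6e3, "310.15" = 7.5e3)
  expect_equal(classify_mechanism(inc)$label, "dynamic")

  expect_error(classify_mechanism(c("310.15" = 5e3)), "2 distinct")
})

test_that("classification is invariant to temperature-list ordering", {
  v <- c("310.15" = 15.23e3, "298.15" = 20e3, "303.15" = 17e3)
  perm <- c("298.15" = 20e3, "303.15" = 17e3, "310.15" = 15.23e3)
  m1 <- classify_mechanism(v)
  m2 <- classify_mechanism(perm)
  expect_equal(m1$label, m2$label)
  expect_equal(m1$relative_trend, m2$relative_trend)
})

test_that("diffusion-limit flag trips exactly at the threshold", {
  # K_sv chosen so k_q at the highest temperature straddles 2e10 with tau_0 = 1e-8
  below <- c("298.15" = 150, "310.15" = 199.9)
  above <- c("298.15" = 150, "310.15" = 200.1)
  expect_false(classify_mechanism(below)$diffusion_limit_exceeded)
  expect_true(classify_mechanism(above)$diffusion_limit_exceeded)
})
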