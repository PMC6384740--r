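test_that("free ligand has the right limits and satisfies the mass balance", {
  expect_equal(free_ligand(1e-5, 0, 1e-6), 1e-5)   # no protein
  expect_equal(free_ligand(0, 1e-5, 1e-6), 0)      # no ligand
  expect_error(free_ligand(-1, 1e-5, 1e-6), ">= 0")
  expect_error(free_ligand(1e-5, 1e-5, 0), "> 0")
  lf <- free_ligand(10e-6, 5e-6, 6.48e-6)
  pl <- 10e-6 - lf
  expect_equal((5e-6 - pl) * lf / pl, 6.48e-6, tolerance = 1e-12)
})

test_that("free ligand matches the bisection oracle", {
  expect_equal(free_ligand(10e-6, 5e-6, 6.48e-6),
               bisect_free_ligand(10e-6, 5e-6, 6.48e-6),
               tolerance = 1e-12)
  set.seed(11)
  n <- 500
  lt <- 10^runif(n, -8, -2)
  pt <- 10^runif(n, -8, -3)
  kd <- 10^runif(n, -9, -2)
  got <- free_ligand(lt, pt, kd)
  want <- mapply(function(a, b, c) bisect_free_ligand(a, b, c), lt, pt, kd)
  expect_lt(max(abs(got - want) / pmax(want, 1e-300)), 1e-10)
})

test_that("fraction bound is a proper monotone occupancy", {
  expect_equal(fraction_bound(0, 5e-6, 1e-6), 0)
  # L_free == K_D is half saturation by definition: choose L_t so that
  # the mass balance puts L_free exactly at K_D
  kd <- 2e-6; pt <- 5e-6
  lt <- kd + pt * kd / (kd + kd)  # L_t = L_free + PL at L_free = K_D
  expect_equal(fraction_bound(lt, pt, kd), 0.5, tolerance = 1e-12)
  # approaches 1 monotonically
  lt_grid <- c(1, 10, 100, 1e4) * 1e-6
  fb <- fraction_bound(lt_grid, 5e-6, 1e-6)
  expect_true(all(diff(fb) > 0))
  expect_gt(fraction_bound(1e4 * 1e-6, 5e-6, 1e-6), 0.999)
  expect_true(all(fb < 1))
  # decreasing in k_d
  expect_gt(fraction_bound(1e-5, 5e-6, 1e-6), fraction_bound(1e-5, 5e-6, 1e-5))
  expect_error(fraction_bound(1e-5, 0, 1e-6), "p_total")
})

test_that("binding fit recovers generative constants from noise-free data", {
  for (row in list(list(kd = 6.48e-6, lt = QUERCETIN_SERIES),
                   list(kd = 183.77e-6, lt = AMLODIPINE_SERIES))) {
    fb <- fraction_bound(row$lt, 5e-6, row$kd)
    sys <- binding_system(5e-6, row$lt, 1 + (0.2 - 1) * fb)
    fit <- binding_fit(sys)
    expect_lt(abs(fit$k_d - row$kd) / row$kd, 1e-3)
    expect_equal(fit$ratio_at_saturation, 0.2, tolerance = 1e-6)
    # halfway-point construction agrees with the least-squares K_D
    expect_equal(fit$free_ligand_at_half, fit$k_d, tolerance = 1e-3)
  }
})

test_that("flat signal is an unidentifiability error", {
  lt <- c(0, 1, 2, 4, 8, 16) * 1e-6
  expect_error(binding_fit(binding_system(5e-6, lt, rep(1, 6))), "flat signal")
})

test_that("binding fit needs enough points", {
  lt <- c(0, 1, 2, 4) * 1e-6
  expect_error(binding_fit(binding_system(5e-6, lt, c(1, 0.9, 0.8, 0.7))),
               "at least 5")
})

test_that("saturation shortfall is flagged", {
  kd <- 1e-4
  lt <- c(0, 1, 2, 3, 4, 5) * 1e-6  # far below half saturation
  fb <- fraction_bound(lt, 5e-6, kd)
  sys <- binding_system(5e-6, lt, 1 + (0.2 - 1) * fb)
  fit <- binding_fit(sys)
  expect_true(fit$saturation_flag)
})

test_that("Gibbs free energy reproduces printed values within input precision", {
  got <- gibbs_free_energy(reference_systems$K_D, 310.15)
  # printed K_D carries ~3 significant digits; half a unit in its last digit
  # propagates to ~0.002 kJ/mol in dG
  expect_true(all(abs(got - reference_systems$delta_g) < 0.002))
  expect_equal(gibbs_free_energy(1, 298.15), 0)
  expect_error(gibbs_free_energy(0, 300), "> 0")
  expect_error(gibbs_free_energy(1e-6, -1), "> 0")
  # strictly increasing in k_d; negative iff K_D < 1 M
  kds <- c(1e-9, 1e-6, 1e-3, 0.999999, 1, 1.5)
  g <- gibbs_free_energy(kds, 310.15)
  expect_true(all(diff(g) > 0))
  expect_true(all((g < 0) == (kds < 1)))
})

test_that("system comparison classifies affinity changes", {
  mk <- function(kd) {
    lt <- sort(unique(c(0, kd * c(0.2, 0.5, 1, 2, 5, 10, 30))))
    fb <- fraction_bound(lt, 5e-6, kd)
    binding_fit(binding_system(5e-6, lt, 1 + (0.25 - 1) * fb))
  }
  unchanged <- compare_systems(mk(183.77e-6), mk(192.81e-6), threshold = 0.10)
  expect_equal(unchanged$call, "unchanged")
  enhanced <- compare_systems(mk(6.48e-6), mk(2.39e-6), threshold = 0.10)
  expect_equal(enhanced$call, "enhanced")
  same <- compare_systems(mk(6.48e-6), mk(6.48e-6))
  expect_equal(same$call, "unchanged")
  expect_equal(same$ratio, 1, tolerance = 1e-9)
  weakened <- compare_systems(mk(6.48e-6), mk(60e-6), threshold = 0.10)
  expect_equal(weakened$call, "weakened")
})

test_that("comparison refuses mismatched temperatures", {
  lt <- QUERCETIN_SERIES
  fb <- fraction_bound(lt, 5e-6, 6.48e-6)
  f1 <- binding_fit(binding_system(5e-6, lt, 1 + (0.2 - 1) * fb,
                                   temperature = 310.15))
  f2 <- binding_fit(binding_system(5e-6, lt, 1 + (0.2 - 1) * fb,
                                   temperature = 298.15))
  expect_error(compare_systems(f1, f2), "different temperatures")
})

test_that("noisy replicates keep median K_D bias small", {
  kd <- 6.48e-6
  biases <- vapply(1:20, function(seed) {
    sc <- titration_scenario(k_d = kd, l_totals = QUERCETIN_SERIES,
                             ratio_at_saturation = 0.2, noise_sd = 0.01,
                             seed = seed)
    ser <- simulate_titration(sc)
    cur <- build_quenching_curve(ser)
    fit <- binding_fit(as_binding_system(cur, 5e-6))
    (fit$k_d - kd) / kd
  }, numeric(1))
  expect_lt(abs(stats::median(biases)), 0.05)
})
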