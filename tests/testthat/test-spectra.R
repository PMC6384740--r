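test_that("spectrum constructor enforces its invariants", {
  expect_s3_class(spectrum(1:3, c(0, 1.5, 0.9)), "spectrum")
  expect_error(spectrum(c(300, 301, 301), 1:3), "strictly increasing")
  expect_error(spectrum(c(302, 301, 300), 1:3), "strictly increasing")
  expect_error(spectrum(1:3, 1:2), "lengths differ")
  expect_error(spectrum(1, 1), "at least 2")
  expect_error(spectrum(1:3, 1:3, temperature = 0), "positive")
})

test_that("read_spectrum parses delimited text and rejects bad input", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# comment", "300,0.0", "301,1.5", "302,0.9"), f)
  s <- read_spectrum(f, "emission")
  expect_equal(s$axis, c(300, 301, 302))
  expect_equal(s$signal, c(0, 1.5, 0.9))

  writeLines(c("300,1", "301,2", "301,3"), f)
  expect_error(read_spectrum(f), "not strictly increasing")

  writeLines(c("300,1", "301,abc"), f)
  expect_error(read_spectrum(f), "line 2.*non-numeric")

  writeLines(c("300,1,9", "301,2"), f)
  expect_error(read_spectrum(f), "2 comma-separated")
})

test_that("write/read round-trip is bit-identical", {
  set.seed(42)
  x <- sort(runif(50, 200, 400))
  x <- x[c(TRUE, diff(x) > 0)]
  s <- spectrum(x, rnorm(length(x)) * 1e3, kind = "absorbance")
  f <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(s, f)
  s2 <- read_spectrum(f, "absorbance")
  expect_identical(s2$axis, s$axis)
  expect_identical(s2$signal, s$signal)
})

test_that("background subtraction is exact pointwise and refuses grid mismatch", {
  a <- spectrum(1:3, c(5, 3, 1))
  b <- spectrum(1:3, c(1, 1, 1))
  expect_equal(subtract_background(a, b)$signal, c(4, 2, 0))
  expect_equal(subtract_background(a, a)$signal, c(0, 0, 0))
  z <- spectrum(1:3, c(0, 0, 0))
  expect_equal(subtract_background(a, z)$signal, a$signal)
  expect_error(subtract_background(a, spectrum(2:4, 1:3)), "identical grids")
  expect_error(subtract_background(a, spectrum(1:3, 1:3, kind = "absorbance")),
               "kind mismatch")
  # subtract then add back restores the signal exactly
  d <- subtract_background(a, b)
  expect_identical(d$signal + b$signal, a$signal)
})

test_that("inner-filter correction matches the closed form and is multiplicative", {
  expect_identical(inner_filter_correct(100, 0, 0), 100)
  expect_identical(inner_filter_correct(0, 0.5, 0.5), 0)
  # independent high-precision evaluation of 100 * 10^0.1
  expect_equal(inner_filter_correct(100, 0.1, 0.1), 125.89254117941672,
               tolerance = 1e-14)
  expect_error(inner_filter_correct(100, -0.1, 0), "non-negative")
  expect_error(inner_filter_correct(-1, 0, 0), "non-negative")
  # multiplicativity in absorbance: correct(f, a1+a2, 0) == correct(correct(f, a1, 0), a2, 0)
  for (a in list(c(0.1, 0.3), c(0.02, 0.5), c(1, 1))) {
    expect_equal(inner_filter_correct(50, a[1] + a[2], 0),
                 inner_filter_correct(inner_filter_correct(50, a[1], 0), a[2], 0))
  }
})

test_that("window integration counts closed-interval samples", {
  s <- spectrum(340:360, rep(1, 21))
  expect_equal(integrate_window(s, 350, 10), 11)  # inclusive endpoints
  expect_equal(integrate_window(s, 350, 0), 1)    # nearest sample
  expect_error(integrate_window(s, 345, 20), "outside axis range")
  # brute-force property on random spectra
  set.seed(7)
  for (i in 1:20) {
    x <- seq(300, 400, by = 0.7)
    y <- rnorm(length(x))
    sp <- spectrum(x, y)
    ctr <- runif(1, 320, 380)
    w <- runif(1, 0.5, 30)
    brute <- sum(y[x >= ctr - w / 2 & x <= ctr + w / 2])
    expect_equal(integrate_window(sp, ctr, w), brute)
  }
})

test_that("peak position finds the maximum with a blue-shift tie rule", {
  g <- gaussian_spectrum(center = 347)
  expect_equal(as.numeric(peak_position(g)), 347)
  two <- spectrum(c(400, 450, 500, 525, 550), c(0, 5, 0, 5, 0))
  p <- peak_position(two)
  expect_equal(as.numeric(p), 450)
  expect_true(attr(p, "ambiguous"))
  flat <- spectrum(1:5, rep(2, 5))
  expect_warning(pf <- peak_position(flat), "ambiguous")
  expect_true(attr(pf, "ambiguous"))
  expect_error(peak_position(spectrum(1:3, 1:3, kind = "absorbance")),
               "emission")
})

test_that("spectral overlap matches the rectangle closed form and is linear", {
  # donor: rectangle of height 2 on [300, 400]; unit-area density = 2/200
  x <- seq(300, 400, by = 1)
  donor <- spectrum(x, rep(2, length(x)))
  acceptor <- spectrum(x, rep(0.5, length(x)), kind = "absorbance")
  # integral of (1/100) * 0.5 over 100 nm = 0.5
  ov <- spectral_overlap(donor, acceptor)
  expect_equal(as.numeric(ov), 0.5, tolerance = 1e-12)
  expect_equal(attr(ov, "range_lo"), 300)
  expect_equal(attr(ov, "range_hi"), 400)
  # doubling the acceptor doubles the score
  acceptor2 <- spectrum(x, rep(1.0, length(x)), kind = "absorbance")
  expect_equal(as.numeric(spectral_overlap(donor, acceptor2)),
               2 * as.numeric(ov), tolerance = 1e-12)
  # disjoint ranges -> zero with warning
  far <- spectrum(seq(500, 600), rep(1, 101), kind = "absorbance")
  expect_warning(z <- spectral_overlap(donor, far), "disjoint")
  expect_equal(as.numeric(z), 0)
})
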