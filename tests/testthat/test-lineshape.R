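test_that("HN loss matches direct complex arithmetic and the Debye limits", {
  # Debye closed forms
  expect_equal(hn_loss(1, hn_params(1, 1, 1, 1)), 0.5)
  expect_equal(hn_loss(10, hn_params(2, 1, 1, 1)), 2 * 10 / 101)
  # derived value: Im of 1/[1 + i^0.8]^0.6 by complex arithmetic
  p <- hn_params(1, 1, 0.8, 0.6)
  expect_equal(hn_loss(1, p), -Im(1 / (1 + (1i)^0.8)^0.6), tolerance = 1e-12)
  # property: 1000 random draws vs the complex route
  set.seed(101)
  for (i in 1:1000) {
    a <- runif(1, 0.2, 1); g <- runif(1, 0.1, 1)
    wt <- 10^runif(1, -4, 4); de <- 10^runif(1, -1, 1)
    pr <- hn_params(de, 1, a, g)
    expect_equal(hn_loss(wt, pr), -Im(de / (1 + (1i * wt)^a)^g),
                 tolerance = 1e-10)
  }
})

test_that("HN loss rejects invalid input and invalid parameters", {
  p <- hn_params(1, 1, 0.8, 0.6)
  expect_error(hn_loss(0, p))
  expect_error(hn_loss(-1, p))
  expect_error(hn_loss(NaN, p))
  expect_error(hn_params(1, 1, 1.2, 0.5))
  expect_error(hn_params(1, 1, 0.5, 0))
  expect_error(hn_params(-1, 1, 0.5, 0.5))
  expect_error(hn_params(1, 0, 0.5, 0.5))
})

test_that("HN limiting log-log slopes are alpha and -alpha*gamma", {
  for (pars in list(c(0.6, 0.9), c(0.87, 0.496), c(0.45, 1))) {
    p <- hn_params(1, 1, pars[1], pars[2])
    lo <- (log10(hn_loss(1e-4 * 10^0.01, p)) - log10(hn_loss(1e-4, p))) / 0.01
    hi <- (log10(hn_loss(1e4 * 10^0.01, p)) - log10(hn_loss(1e4, p))) / 0.01
    expect_lt(abs(lo - pars[1]), 0.02)
    expect_lt(abs(hi + pars[1] * pars[2]), 0.02)
  }
})

test_that("dc loss follows sigma/(eps0 omega) with the S/cm conversion", {
  expect_equal(dc_loss(123, 0), 0)
  # doubling omega halves the value
  expect_equal(dc_loss(2, 1e-10), dc_loss(1, 1e-10) / 2)
  # hand unit conversion: 1e-12 S/cm = 1e-10 S/m at f = 1 Hz
  expect_equal(dc_loss(2 * pi * 1, 1e-12),
               1e-10 / (8.8541878128e-12 * 2 * pi), tolerance = 1e-12)
  expect_error(dc_loss(1, -1e-12))
})

test_that("model loss superposes dc and processes additively", {
  f <- test_fgrid()
  debye <- hn_params(2, 1 / (2 * pi * 100), 1, 1)
  one <- process_set(sigma_dc = 0, processes = list(debye))
  two <- process_set(sigma_dc = 0, processes = list(debye, debye))
  y1 <- model_loss(f, one)
  expect_equal(model_loss(f, two), 2 * y1, tolerance = 1e-14)
  # single Debye: peak height delta_eps/2 exactly at f = 1/(2 pi tau)
  expect_equal(model_loss(100, one), 1)
  withdc <- process_set(sigma_dc = 1e-12, processes = list(debye))
  expect_equal(model_loss(f, withdc), y1 + dc_loss(2 * pi * f, 1e-12))
  expect_error(model_loss(numeric(0), one))
  expect_error(model_loss(c(2, 1), one))
})

test_that("hn_peak_time matches the numerical argmax of the loss", {
  # Debye: tau_max = tau_HN
  expect_equal(hn_peak_time(hn_params(1, 2.5, 1, 1)), 2.5)
  # scale invariance in tau
  p1 <- hn_params(1, 1, 0.8, 0.6); p2 <- hn_params(1, 2, 0.8, 0.6)
  expect_equal(hn_peak_time(p2), 2 * hn_peak_time(p1))
  # derived: numerical argmax oracle
  expect_equal(hn_peak_time(p1), hn_argmax_oracle(p1), tolerance = 1e-3)
  # property: 100 random draws within 0.1%
  set.seed(77)
  for (i in 1:100) {
    p <- hn_params(1, 10^runif(1, -6, 0), runif(1, 0.3, 1), runif(1, 0.2, 1))
    expect_equal(hn_peak_time(p), hn_argmax_oracle(p), tolerance = 1e-3)
  }
  # inverse round-trips
  expect_equal(hn_peak_time(hn_params(1, hn_tau_from_peak(3e-4, 0.7, 0.4),
                                      0.7, 0.4)), 3e-4, tolerance = 1e-12)
})

test_that("peak_stats reduces a Debye peak to its textbook geometry", {
  f <- 10^seq(-3, 3, by = 0.1)
  sp <- loss_spectrum(300, 0.1, f,
                      hn_loss(2 * pi * f, hn_params(1, 1 / (2 * pi), 1, 1)))
  st <- peak_stats(sp)
  expect_true(st$reliable)
  expect_equal(st$f_max, 1, tolerance = 1e-6)
  expect_equal(st$eps2_max, 0.5, tolerance = 0.02)
  # Debye full width at half maximum: log10((2+sqrt(3))/(2-sqrt(3))) decades
  expect_equal(st$fwhm_decades, log10((2 + sqrt(3)) / (2 - sqrt(3))),
               tolerance = 0.02)
})

test_that("peak_stats is symmetric for symmetric peaks and flags edge maxima", {
  f <- 10^seq(-3, 3, by = 0.1)
  sp <- loss_spectrum(300, 0.1, f,
                      hn_loss(2 * pi * f, hn_params(1, 1 / (2 * pi), 0.6, 1)))
  st <- peak_stats(sp)
  ly <- log10(sp$eps2)
  half <- which(sp$eps2 > st$eps2_max / 2)
  left <- log10(st$f_max) - log10(f[min(half)])
  right <- log10(f[max(half)]) - log10(st$f_max)
  expect_equal(left, right, tolerance = 0.06)
  # broad HN width against a dense-grid evaluation
  fd <- 10^seq(-4, 4, by = 1e-4)
  yd <- hn_loss(2 * pi * fd, hn_params(1, 1 / (2 * pi), 0.8, 0.6))
  above <- range(which(yd > max(yd) / 2))
  fwhm_dense <- log10(fd[above[2]]) - log10(fd[above[1]])
  sp2 <- loss_spectrum(300, 0.1, f,
                       hn_loss(2 * pi * f, hn_params(1, 1 / (2 * pi), 0.8, 0.6)))
  expect_equal(peak_stats(sp2)$fwhm_decades, fwhm_dense, tolerance = 0.02)
  # rising flank only: maximum on the grid edge
  sp3 <- loss_spectrum(300, 0.1, f, dc_loss(2 * pi * rev(f), 1e-10))
  expect_false(peak_stats(sp3)$reliable)
})
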