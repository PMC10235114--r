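test_that("deconvolution recovers a noise-free alpha + conductivity spectrum", {
  f <- test_fgrid()
  truth <- process_set(sigma_dc = 3e-12,
                       processes = list(hn_params(6, 2e-3, 0.87, 0.496)))
  sp <- loss_spectrum(347, 0.1, f, model_loss(f, truth))
  ft <- fit_spectrum(sp, n_processes = 1, fit_dc = TRUE)
  expect_true(ft$converged)
  expect_lt(ft$residual, 1e-10)
  expect_equal(ft$sigma_dc, 3e-12, tolerance = 1e-3)
  expect_equal(ft$processes$delta_eps, 6, tolerance = 1e-3)
  expect_equal(ft$processes$tau_hn, 2e-3, tolerance = 1e-3)
  expect_equal(ft$processes$alpha, 0.87, tolerance = 1e-3)
  expect_equal(ft$processes$gamma, 0.496, tolerance = 1e-3)
  expect_equal(ft$processes$tau_max,
               hn_peak_time(truth$processes[[1]]), tolerance = 1e-3)
})

test_that("deconvolution recovers a noise-free two-secondary glassy spectrum", {
  f <- test_fgrid()
  truth <- process_set(0, processes = list(
    hn_params(0.3, hn_tau_from_peak(1e-1, 0.5, 1), 0.5, 1),
    hn_params(0.25, hn_tau_from_peak(3e-5, 0.55, 1), 0.55, 1)))
  sp <- loss_spectrum(233, 0.1, f, model_loss(f, truth))
  ft <- fit_spectrum(sp, n_processes = 2, fit_dc = FALSE,
                     labels = c("beta", "gamma"))
  expect_lt(ft$residual, 1e-10)
  expect_equal(ft$processes$tau_max, c(1e-1, 3e-5), tolerance = 0.01)
  expect_equal(ft$processes$label, c("beta", "gamma"))
})

test_that("a spectrum without conductivity yields an effectively zero sigma", {
  f <- test_fgrid()
  sp <- loss_spectrum(347, 0.1, f, model_loss(f, process_set(
    0, processes = list(hn_params(6, 2e-3, 0.87, 0.496)))))
  ft <- fit_spectrum(sp, n_processes = 1, fit_dc = TRUE)
  expect_lt(ft$sigma_dc, 1e-15)
})

test_that("round-trip is the identity on parameters for random draws", {
  f <- test_fgrid()
  set.seed(202)
  for (i in 1:25) {
    de <- 10^runif(1, -0.5, 1)
    tm <- 10^runif(1, -5, -1)
    a <- runif(1, 0.5, 1); g <- runif(1, 0.3, 1)
    sig <- 10^runif(1, -13, -11)
    truth <- process_set(sig, processes = list(
      hn_params(de, hn_tau_from_peak(tm, a, g), a, g)))
    sp <- loss_spectrum(347, 0.1, f, model_loss(f, truth))
    ft <- fit_spectrum(sp, 1, fit_dc = TRUE, restarts = 4)
    expect_equal(ft$processes$delta_eps, de, tolerance = 5e-3)
    expect_equal(ft$processes$tau_max, tm, tolerance = 5e-3)
    expect_equal(ft$processes$alpha, a, tolerance = 5e-3)
    expect_equal(ft$processes$gamma, g, tolerance = 5e-3)
    expect_equal(ft$sigma_dc, sig, tolerance = 5e-3)
  }
})

test_that("recovered peak times are unbiased under 1 percent noise", {
  f <- test_fgrid()
  truth <- process_set(1e-12, processes = list(
    hn_params(6, hn_tau_from_peak(1e-3, 0.87, 0.496), 0.87, 0.496)))
  y0 <- model_loss(f, truth)
  set.seed(303)
  errs <- replicate(40, {
    y <- y0 * 10^rnorm(length(f), 0, 0.0043)  # 1 percent multiplicative
    ft <- fit_spectrum(loss_spectrum(347, 0.1, f, y), 1,
                       fit_dc = TRUE, restarts = 2)
    log10(ft$processes$tau_max) - log10(1e-3)
  })
  expect_lt(abs(mean(errs)), 0.02)
})

test_that("dc subtraction is exact and clips at the floor", {
  f <- test_fgrid()
  alpha <- hn_params(6, 2e-3, 0.87, 0.496)
  y_alpha <- hn_loss(2 * pi * f, alpha)
  full <- y_alpha + dc_loss(2 * pi * f, 5e-12)
  sp <- loss_spectrum(347, 0.1, f, full)
  # identity at sigma = 0
  expect_equal(subtract_dc(sp, 0)$eps2, full)
  # constructed decomposition
  res <- subtract_dc(sp, 5e-12)
  expect_equal(res$eps2, y_alpha, tolerance = 1e-10)
  # pure dc minus its own sigma: every point at the floor
  dconly <- loss_spectrum(347, 0.1, f, dc_loss(2 * pi * f, 5e-12))
  res2 <- subtract_dc(dconly, 5e-12, floor = 1e-8)
  expect_true(all(res2$eps2 == 1e-8))
  expect_equal(attr(res2, "n_clipped"), length(f))
})

test_that("KWW shape fit identifies Debye and round-trips beta = 0.51", {
  f <- 10^seq(-2, 4, by = 0.1)
  # Debye input
  spD <- loss_spectrum(330, 0.1, f,
                       hn_loss(2 * pi * f, hn_params(4, 1 / (2 * pi * 10), 1, 1)))
  fD <- fit_kww_shape(normalize_spectrum(spD))
  expect_equal(fD$beta_kww, 1, tolerance = 0.01)
  # spectrum generated from the KWW loss itself
  yk <- kww_loss(2 * pi * f, kww_params(1 / (2 * pi * 10), 0.51))
  fK <- fit_kww_shape(normalize_spectrum(loss_spectrum(330, 0.1, f, yk)))
  expect_equal(fK$beta_kww, 0.51, tolerance = 0.01)
  # recovered characteristic time matches the generating one
  expect_equal(fK$tau_alpha, 1 / (2 * pi * 10), tolerance = 0.02)
  # monotonicity: broader input gives smaller fitted beta
  y4 <- kww_loss(2 * pi * f, kww_params(1 / (2 * pi * 10), 0.4))
  y7 <- kww_loss(2 * pi * f, kww_params(1 / (2 * pi * 10), 0.7))
  b4 <- fit_kww_shape(normalize_spectrum(loss_spectrum(330, 0.1, f, y4)))$beta_kww
  b7 <- fit_kww_shape(normalize_spectrum(loss_spectrum(330, 0.1, f, y7)))$beta_kww
  expect_lt(b4, b7)
})

test_that("KWW shape fit is invariant under rescaling f and eps2", {
  f <- 10^seq(-2, 4, by = 0.1)
  y <- kww_loss(2 * pi * f, kww_params(1 / (2 * pi * 10), 0.6))
  b1 <- fit_kww_shape(normalize_spectrum(loss_spectrum(330, 0.1, f, y)))$beta_kww
  b2 <- fit_kww_shape(normalize_spectrum(
    loss_spectrum(330, 0.1, f * 37, y * 0.013)))$beta_kww
  expect_equal(b1, b2, tolerance = 1e-4)
})

test_that("superpositioning diagnostic separates constant from varying shape", {
  f <- 10^seq(-2, 4, by = 0.1)
  mk <- function(a, g, fmax) {
    y <- hn_loss(2 * pi * f, hn_params(3, hn_tau_from_peak(1 / (2 * pi * fmax), a, g), a, g))
    normalize_spectrum(loss_spectrum(330, 0.1, f, y))
  }
  same <- list(mk(0.87, 0.496, 5), mk(0.87, 0.496, 5), mk(0.87, 0.496, 5))
  res <- tps_residual(same)
  expect_equal(res$max_deviation, 0, tolerance = 1e-9)
  expect_equal(res$beta_spread, 0, tolerance = 1e-9)
  expect_true(res$holds)
  # one spectrum with the breadth exponent reduced by 0.15 breaks the verdict
  mixed <- c(same, list(mk(0.72, 0.496, 5)))
  res2 <- suppressWarnings(tps_residual(mixed))
  expect_false(res2$holds)
  expect_gt(res2$max_deviation, 0.01)
})
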