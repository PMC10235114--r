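test_that("scenario validation names every offending field", {
  cfg <- default_scenario()
  expect_silent(validate_scenario(cfg))
  bad <- cfg
  bad$fdse$s_exponent <- 2
  bad$strengths$deps_alpha <- -1
  expect_error(validate_scenario(bad), "fdse\\$s_exponent")
  expect_error(validate_scenario(bad), "strengths\\$deps_alpha")
})

test_that("the ground-truth map encodes the generating laws exactly", {
  cfg <- default_scenario()
  truth <- make_relaxation_truth(cfg)
  m <- truth$map
  # re-fitting the ambient beta branch returns the configured energy
  b <- m[m$process == "beta" & m$p == 0.1, ]
  ft <- arrhenius_fit(b$T, b$log10_tau)
  expect_equal(ft$E_act, cfg$beta_process$E_at_p0, tolerance = 1e-10)
  expect_equal(ft$log10_tau_inf, cfg$beta_process$log10_tau_inf,
               tolerance = 1e-10)
  # gamma times identical across pressures at fixed temperature
  g273 <- m[m$process == "gamma" & m$T == 273, ]
  expect_gt(nrow(g273), 5)
  expect_equal(diff(range(g273$log10_tau)), 0)
  # conductivity ties to tau_alpha through the fractional law exactly
  a <- m[m$process == "alpha", ]
  expect_lt(max(abs(cfg$fdse$s_exponent * a$log10_sigma_dc + a$log10_tau -
                      cfg$fdse$log10_const)), 1e-12)
  # Tg curve consistent with the surface parameters
  expect_equal(truth$tg_curve$Tg[truth$tg_curve$p == 0], 325)
})

test_that("spectrum generation is seeded, reproducible and noise-exact", {
  cfg <- default_scenario()
  s1 <- make_spectra(cfg, seed = 42, which = "supercooled")
  s2 <- make_spectra(cfg, seed = 42, which = "supercooled")
  expect_identical(s1[[1]]$eps2, s2[[1]]$eps2)
  s3 <- make_spectra(cfg, seed = 43, which = "supercooled")
  expect_false(identical(s1[[1]]$eps2, s3[[1]]$eps2))
  # zero noise reproduces the model exactly
  cfg0 <- default_scenario(noise_sd_decades = 0)
  sp <- make_spectra(cfg0, which = "supercooled")[[1]]
  ps <- bdsfit:::.state_process_set(sp$T, sp$p, cfg0, TRUE)
  expect_identical(sp$eps2, model_loss(sp$f, ps))
})

test_that("the glassy window shows two secondary peaks at ambient pressure only", {
  cfg <- default_scenario(noise_sd_decades = 0)
  f <- cfg$grids$f
  two <- model_loss(f, bdsfit:::.state_process_set(205, 0.1, cfg, FALSE))
  one <- model_loss(f, bdsfit:::.state_process_set(313, 340, cfg, FALSE))
  expect_equal(length(bdsfit:::.find_peaks(f, two)), 2)
  expect_equal(length(bdsfit:::.find_peaks(f, one)), 1)
  # the gamma mode is pushed beyond the window, not removed: its strength
  # still enters the model
  ps <- bdsfit:::.state_process_set(313, 340, cfg, FALSE)
  expect_equal(length(ps$processes), 2)
  expect_lt(hn_peak_time(ps$processes[[2]]), 1e-6 / (2 * pi))
})

test_that("the synthetic DSC trace round-trips its generating values", {
  cfg <- default_scenario()
  tr <- make_dsc(cfg, noise_sd = 0)
  tr2 <- make_dsc(cfg, noise_sd = 0)
  expect_identical(tr$heat_flow, tr2$heat_flow)
  mp <- melting_peak(tr, c(390, 430))
  gs <- glass_step(tr, c(300, 350))
  expect_equal(mp$Tm, 413, tolerance = 1e-4)
  expect_equal(gs$Tg, 325, tolerance = 1e-3)
  expect_equal(gs$dCp, 0.464, tolerance = 1e-2)
})

test_that("isochronal state points sit on the requested isochrone", {
  cfg <- default_scenario()
  ip <- isochronal_state_points(cfg$avramov, -2, c(0.1, 120, 170))
  lt <- avramov_tau(ip$T, ip$p, cfg$avramov)
  expect_equal(lt, rep(-2, 3), tolerance = 1e-9)
  expect_true(all(diff(ip$T) > 0))
})
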