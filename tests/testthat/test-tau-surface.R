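ref_params <- function() avramov_params(
  log10_tau0 = -14, C = log(10) * 16, Tg0 = 325, alpha0 = 5,
  beta_av = 0.6269, Pi = 250, c_over_cp = 0.075)

test_that("the surface honours its defining isochrone", {
  p <- ref_params()
  # at T = Tg0, p = 0: log tau = log tau0 + C/ln 10
  expect_equal(avramov_tau(325, 0, p), -14 + 16)
  # same value anywhere along Tg(p)
  expect_equal(avramov_tau(tg_of_p(200, p), 200, p), 2, tolerance = 1e-12)
  # isochrone-consistency invariant over 0..400 MPa
  pg <- seq(0, 400, by = 5)
  vals <- avramov_tau(tg_of_p(pg, p), pg, p)
  expect_lt(max(abs(vals - avramov_tau(325, 0, p))), 1e-9)
  # monotone in T at fixed p
  Tg <- seq(330, 400, by = 1)
  expect_true(all(diff(avramov_tau(Tg, 120, p)) < 0))
})

test_that("Tg(p) closed form, limits and derivative agree with oracles", {
  p <- ref_params()
  expect_equal(tg_of_p(0, p), 325)
  # c_over_cp = 0: pure power law
  p0 <- avramov_params(-14, log(10) * 16, 325, 5, 0.6269, 250, 0)
  expect_equal(tg_of_p(c(100, 300), p0),
               325 * (1 + c(100, 300) / 250)^(0.6269 / 5))
  # closed-form isochrone equals the numerical root of the surface
  set.seed(404)
  for (pp in runif(20, 0, 400)) {
    root <- uniroot(function(T) avramov_tau(T, pp, p) - 2,
                    c(250, 600), tol = 1e-9)$root
    expect_equal(tg_of_p(pp, p, tau_g_criterion = 2), root, tolerance = 1e-8)
  }
  # dTg/dp closed form vs centred finite difference at p -> 0
  h <- 1e-3
  fd <- (tg_of_p(h, p) - tg_of_p(0, p)) / h * 1000
  expect_equal(dtg_dp(p), fd, tolerance = 1e-3)
  # worked arithmetic: Tg0 = 325, beta/alpha0 = 0.1, Pi = 200 -> 162.5 K/GPa
  pw <- avramov_params(-14, log(10) * 16, 325, 5, 0.5, 200, 0.05)
  expect_equal(dtg_dp(pw), 0.1 * 325 / 200 * 1000)
  # doubling Pi halves the coefficient
  pw2 <- avramov_params(-14, log(10) * 16, 325, 5, 0.5, 400, 0.05)
  expect_equal(dtg_dp(pw2), dtg_dp(pw) / 2)
})

test_that("Tg(p) grows monotonically and sublinearly for positive C/Cp0", {
  p <- ref_params()
  pg <- seq(0, 400, by = 2)
  tg <- tg_of_p(pg, p)
  expect_true(all(diff(tg) > 0))
  expect_true(all(diff(diff(tg)) < 0))
})

test_that("parameter validation enforces the surface invariants", {
  expect_error(avramov_params(-14, 30, 325, 5, 0.6, -10, 0.05))
  expect_error(avramov_params(-14, 30, 325, -5, 0.6, 250, 0.05))
  # c ln(1 + p/Pi) must stay below 1 over the fitted range
  expect_error(avramov_params(-14, 30, 325, 5, 0.6, 10, 0.3, p_max = 400))
  expect_error(avramov_tau(300, -5, ref_params()))
})

test_that("surface fitting round-trips noise-free data within 1 percent", {
  truth <- make_relaxation_truth(default_scenario())
  fit <- fit_avramov_surface(truth$map)
  expect_true(fit$converged)
  expect_false(fit$ill_conditioned)
  expect_lt(fit$residual, 1e-8)
  p <- fit$params
  expect_equal(p$Tg0, 325, tolerance = 0.01)
  expect_equal(p$alpha0, 5, tolerance = 0.01)
  expect_equal(p$beta_av, 0.6269, tolerance = 0.01)
  expect_equal(p$Pi, 250, tolerance = 0.01)
  expect_equal(p$c_over_cp, 0.075, tolerance = 0.01)
  expect_equal(p$log10_tau0, -14, tolerance = 0.01)
})

test_that("a single isobar leaves the pressure scale unidentified", {
  truth <- make_relaxation_truth(default_scenario())
  m <- truth$map
  amb <- m[m$process == "alpha" & m$p == 0.1, , drop = FALSE]
  fit <- fit_avramov_surface(amb)
  expect_true(fit$ill_conditioned)
})

test_that("relaxation_map rejects duplicates and out-of-window times", {
  expect_error(relaxation_map(c(300, 300), c(0.1, 0.1), c("alpha", "alpha"),
                              c(-3, -4)))
  expect_error(relaxation_map(300, 0.1, "alpha", -15))
})
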