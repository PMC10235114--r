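R_GAS <- bds_constants$R

arr_tau <- function(T, E_kJ, log10_tau_inf)
  log10_tau_inf + E_kJ * 1000 / (R_GAS * log(10) * T)

test_that("Arrhenius fitting is exact on Arrhenius data", {
  T <- seq(180, 290, by = 10)
  ft <- arrhenius_fit(T, arr_tau(T, 50, -14), process = "beta", p = 0.1)
  expect_equal(ft$E_act, 50, tolerance = 1e-10)
  expect_equal(ft$log10_tau_inf, -14, tolerance = 1e-10)
  expect_lt(ft$residual_rms, 1e-12)
  expect_false(ft$non_arrhenius)
  # isothermal shift: scaling all tau by 10 changes the prefactor only
  ft10 <- arrhenius_fit(T, arr_tau(T, 50, -14) + 1)
  expect_equal(ft10$E_act, 50, tolerance = 1e-10)
  expect_equal(ft10$log10_tau_inf, -13, tolerance = 1e-10)
})

test_that("curvature in an Arrhenius plot raises the non-Arrhenius flag", {
  T <- seq(180, 290, by = 5)
  curved <- arr_tau(T, 50, -14) + 0.5 * ((1 / T - mean(1 / T)) * 1e3)^2
  expect_true(arrhenius_fit(T, curved)$non_arrhenius)
  expect_error(arrhenius_fit(c(200, 210), c(-1, -2)))
  expect_error(arrhenius_fit(c(200, 205, 210), c(-1, -2, -3)))
})

test_that("activation volume carries its units and worked values", {
  # unit identity guarding MPa and ln/log10 factors
  expect_equal(log(10) * R_GAS * 273 * 1, 5227, tolerance = 1e-4 * 5227)
  # zero slope -> zero volume
  p <- seq(60, 340, by = 40)
  expect_equal(activation_volume(p, rep(-4, length(p)), T = 273)$dV, 0)
  # linear in temperature at fixed slope
  lt <- -6 + 2.30 * (p - 60) / 280
  expect_equal(activation_volume(p, lt, T = 546)$dV,
               2 * activation_volume(p, lt, T = 273)$dV, tolerance = 1e-12)
  expect_error(activation_volume(c(0, 50), c(-1, -2), 273))
})

test_that("Eyring fitting round-trips its own model exactly", {
  T <- seq(190, 290, by = 10)
  dH <- 70; dS <- 100
  lnTauT <- dH * 1000 / R_GAS / T + log(bds_constants$h / bds_constants$kB) -
    dS / R_GAS
  lt <- (lnTauT - log(T)) / log(10)
  ft <- eyring_fit(T, lt)
  expect_equal(ft$dH, 70, tolerance = 1e-10)
  expect_equal(ft$dS, 100, tolerance = 1e-10)
})

test_that("Eyring enthalpy brackets the Arrhenius energy minus RT", {
  T <- seq(190, 290, by = 5)
  E <- 66
  ft <- eyring_fit(T, arr_tau(T, E, -18.6))
  expect_gt(ft$dH, E - R_GAS * max(T) / 1000)
  expect_lt(ft$dH, E - R_GAS * min(T) / 1000)
  # tau_inf up by 10x lowers dS by R ln 10
  ft10 <- eyring_fit(T, arr_tau(T, E, -17.6))
  expect_equal(ft$dS - ft10$dS, R_GAS * log(10), tolerance = 1e-9)
})

test_that("Tg-scaled collapse separates built-in collapse from violation", {
  tgc <- data.frame(p = c(0.1, 170, 340), Tg = c(325, 348, 365))
  mk_map <- function(E_fun) {
    rows <- NULL
    for (i in 1:3) {
      p <- tgc$p[i]
      T <- seq(0.78, 0.92, by = 0.02) * tgc$Tg[i]
      rows <- rbind(rows, data.frame(T = T, p = p, process = "beta",
                                     log10_tau = arr_tau(T, E_fun(i), -18.6)))
    }
    relaxation_map(rows$T, rows$p, rows$process, rows$log10_tau)
  }
  # activation energy proportional to Tg(p): branches collapse
  col1 <- tg_scaled_collapse(mk_map(function(i) 66 * tgc$Tg[i] / 325), tgc)
  expect_lt(col1$spread, 0.05)
  expect_true(col1$collapses)
  # pressure-independent energy with rising Tg: no collapse
  col2 <- tg_scaled_collapse(mk_map(function(i) 66), tgc)
  expect_false(col2$collapses)
  # single pressure: trivial collapse
  m1 <- mk_map(function(i) 66)
  col3 <- tg_scaled_collapse(m1[m1$p == 0.1, ], tgc)
  expect_equal(col3$spread, 0)
})

test_that("isochronal ratio detects superposition and its violation", {
  tg <- c(`0.1` = 325, `170` = 348)
  mk <- function(offset_by_p) {
    rows <- NULL
    for (pp in c(0.1, 170)) {
      Tgp <- tg[[as.character(pp)]]
      T <- seq(0.95, 1.1, by = 0.01) * Tgp
      # alpha branch crossing 1 s within range
      lta <- 2 - 120 * (1 - Tgp / T)
      rows <- rbind(rows,
                    data.frame(T = T, p = pp, process = "alpha",
                               log10_tau = pmax(pmin(lta, 5.9), -11.9)),
                    data.frame(T = T, p = pp, process = "beta",
                               log10_tau = pmax(pmin(
                                 lta - 7 - offset_by_p * (pp > 1), 5.9), -11.9)))
    }
    relaxation_map(rows$T, rows$p, rows$process, rows$log10_tau)
  }
  # identical alpha and beta maps: ratio zero everywhere
  m <- mk(0)
  a <- m[m$process == "alpha", ]
  ident <- isochronal_ratio(m, relaxation_map(a$T, a$p, rep("beta", nrow(a)),
                                              a$log10_tau),
                            tau_alpha_ref = 1)
  expect_equal(ident$table$ratio_decades, rep(0, 2), tolerance = 1e-9)
  # constant alpha-beta offset: spread under 0.05 decades
  res <- isochronal_ratio(m, m, tau_alpha_ref = 1)
  expect_lt(res$spread, 0.05)
  expect_equal(res$table$ratio_decades, rep(7, 2), tolerance = 1e-6)
  # pressure-dependent offset: spread reflects it
  res2 <- isochronal_ratio(mk(0.8), mk(0.8), tau_alpha_ref = 1)
  expect_gt(res2$spread, 0.5)
  # reference unreachable at every pressure: informative failure
  expect_error(isochronal_ratio(m, m, tau_alpha_ref = 1e12), "unreachable")
})
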