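#' Default synthetic study scenario
#'
#' Ground-truth configuration emulating a high-pressure dielectric study of a
#' hydrogen-bonded amorphous pharmaceutical: a structural (alpha) relaxation on
#' a pressure-extended Avramov surface, a pressure-sensitive Johari-Goldstein
#' (beta) relaxation, a pressure-insensitive intramolecular (gamma) relaxation,
#' dc conductivity tied to the structural time by a fractional
#' Debye-Stokes-Einstein law, and the measurement grids of a combined
#' isobaric/isothermal campaign.
#'
#' Default numbers reproduce the headline scale of such a study: Tg0 = 325 K
#' with tau(Tg) = 100 s, dTg/dp = 163 K/GPa at ambient pressure, beta-process
#' activation energy 66 kJ/mol at ambient pressure rising linearly with
#' pressure by 0.043 kJ/(mol MPa) -- equivalently an activation volume of
#' 43 cm3/mol at any isotherm -- a gamma-process energy of 38 kJ/mol, FDSE
#' exponent s = 0.65, and an alpha-peak shape corresponding to a stretching
#' exponent beta_KWW = 0.51. The beta pre-exponential (log10 tau_inf = -18.6)
#' follows from pairing E_beta = 66 kJ/mol with an Eyring activation entropy
#' of ~105 J/(mol K) over the ambient glassy range.
#'
#' @param noise_sd_decades multiplicative loss noise, standard deviation in
#'   decades (log-normal); 0.01 decades is ~2.3 percent, typical of dielectric
#'   loss data.
#' @param seed integer seed recorded in the scenario and used by the
#'   generators unless overridden.
#' @param deps_curie logical; if TRUE the relaxation strengths follow a 1/T
#'   Curie law referenced to Tg0 instead of being constant.
#' @return A list of class `scenario_config`.
#' @export
default_scenario <- function(noise_sd_decades = 0.01, seed = 20260901,
                          deps_curie = FALSE) {
  avr <- avramov_params(
    log10_tau0 = -14,
    C = .LN10 * 16,          # tau(Tg) = 100 s isochrone
    Tg0 = 325,
    alpha0 = 5,
    beta_av = 0.6269,        # with Pi and alpha0: dTg/dp|0 = 163 K/GPa
    Pi = 250,
    c_over_cp = 0.075)
  # alpha-peak HN shape matched to the KWW stretching exponent 0.51
  # (least-squares HN representation of the normalised KWW loss curve)
  cfg <- list(
    avramov = avr,
    alpha_shape = list(alpha = 0.870, gamma = 0.496),
    beta_process = list(E_at_p0 = 66, dE_dp = 0.043,   # kJ/mol, kJ/(mol MPa)
                        log10_tau_inf = -18.6,
                        shape = list(alpha = 0.50, gamma = 1)),
    gamma_process = list(E = 38, log10_tau_inf = -15,
                         pressure_sensitive = FALSE,
                         shape = list(alpha = 0.55, gamma = 1)),
    strengths = list(deps_alpha = 6,
                     deps_beta = 0.3,    # small-amplitude secondary modes
                     deps_gamma = 0.25,  # sharper, comparable to beta: the
                                         # two glassy peaks resolve clearly
                     curie = deps_curie),
    fdse = list(s_exponent = 0.65,
                # sigma anchored to 10^-11.5 S/cm at tau = 10 ms, which keeps
                # the simulated dc flanks in realistic proportion to the
                # alpha-peak across the measured window
                log10_const = 0.65 * (-11.5) - 2),
    noise = list(sd_decades = noise_sd_decades, seed = seed),
    grids = list(
      f = 10^seq(-1, 6, by = 0.1),
      supercooled = rbind(
        expand.grid(T = seq(333, 363, by = 3), p = 0.1),
        expand.grid(T = seq(350, 383, by = 3), p = 120),
        expand.grid(T = seq(357, 381, by = 3), p = 170),
        expand.grid(T = 347, p = c(0.1, seq(10, 120, by = 10))),
        expand.grid(T = 381, p = seq(120, 300, by = 15))),
      glassy = rbind(
        expand.grid(T = seq(190, 290, by = 5), p = 0.1),
        expand.grid(T = seq(273, 321, by = 4), p = 170),
        expand.grid(T = seq(273, 353, by = 5), p = 340),
        expand.grid(T = 273, p = seq(60, 340, by = 20)))))
  structure(cfg, class = "scenario_config")
}

#' Validate a scenario configuration
#'
#' Checks every sub-parameter of a [default_scenario()]-style configuration and
#' stops with a message listing all offending fields.
#'
#' @param config a `scenario_config` list.
#' @return `config`, invisibly, on success.
#' @export
validate_scenario <- function(config) {
  bad <- character(0)
  chk <- function(ok, field) if (!isTRUE(ok)) bad <<- c(bad, field)
  chk(inherits(config$avramov, "avramov_params"), "avramov")
  sh <- config$alpha_shape
  chk(is.numeric(sh$alpha) && sh$alpha > 0 && sh$alpha <= 1, "alpha_shape$alpha")
  chk(is.numeric(sh$gamma) && sh$gamma > 0 && sh$gamma <= 1, "alpha_shape$gamma")
  bp <- config$beta_process
  chk(is.numeric(bp$E_at_p0) && bp$E_at_p0 > 0, "beta_process$E_at_p0")
  chk(is.numeric(bp$dE_dp) && is.finite(bp$dE_dp), "beta_process$dE_dp")
  chk(is.numeric(bp$log10_tau_inf), "beta_process$log10_tau_inf")
  gp <- config$gamma_process
  chk(is.numeric(gp$E) && gp$E > 0, "gamma_process$E")
  chk(isFALSE(gp$pressure_sensitive), "gamma_process$pressure_sensitive")
  st <- config$strengths
  chk(is.numeric(st$deps_alpha) && st$deps_alpha > 0, "strengths$deps_alpha")
  chk(is.numeric(st$deps_beta) && st$deps_beta > 0, "strengths$deps_beta")
  chk(is.numeric(st$deps_gamma) && st$deps_gamma > 0, "strengths$deps_gamma")
  fd <- config$fdse
  chk(is.numeric(fd$s_exponent) && fd$s_exponent > 0 && fd$s_exponent <= 1,
      "fdse$s_exponent")
  chk(is.numeric(fd$log10_const), "fdse$log10_const")
  chk(is.numeric(config$noise$sd_decades) && config$noise$sd_decades >= 0,
      "noise$sd_decades")
  f <- config$grids$f
  chk(is.numeric(f) && !is.unsorted(f, strictly = TRUE) && all(f > 0),
      "grids$f")
  chk(is.data.frame(config$grids$supercooled), "grids$supercooled")
  chk(is.data.frame(config$grids$glassy), "grids$glassy")
  if (length(bad))
    stop("invalid scenario fields: ", paste(bad, collapse = ", "))
  invisible(config)
}

# ground-truth log10 tau of the secondary processes
.beta_log10_tau <- function(T, p, config) {
  E <- (config$beta_process$E_at_p0 + config$beta_process$dE_dp * (p - 0.1)) * 1000
  config$beta_process$log10_tau_inf + E / (bds_constants$R * .LN10 * T)
}
.gamma_log10_tau <- function(T, p, config) {
  config$gamma_process$log10_tau_inf +
    config$gamma_process$E * 1000 / (bds_constants$R * .LN10 * T)
}

#' Ground-truth relaxation map of a scenario
#'
#' Evaluates, noise free, the generating models at every state point of the
#' scenario grids: alpha times from the Avramov surface (with dc
#' conductivities from the FDSE law) on the supercooled grid, beta and gamma
#' times from their Arrhenius laws on the glassy grid. Also returns the
#' generating Tg(p) curve.
#'
#' @param config a validated `scenario_config`.
#' @return A list: `map` (a [relaxation_map()]), `tg_curve` (data.frame p,
#'   Tg), `config`.
#' @export
make_relaxation_truth <- function(config) {
  validate_scenario(config)
  sc <- unique(config$grids$supercooled)
  lt_a <- avramov_tau(sc$T, sc$p, config$avramov)
  ls_a <- (config$fdse$log10_const - lt_a) / config$fdse$s_exponent
  gl <- unique(config$grids$glassy)
  lt_b <- .beta_log10_tau(gl$T, gl$p, config)
  lt_g <- .gamma_log10_tau(gl$T, gl$p, config)
  map <- relaxation_map(
    T = c(sc$T, gl$T, gl$T),
    p = c(sc$p, gl$p, gl$p),
    process = c(rep("alpha", nrow(sc)), rep("beta", nrow(gl)),
                rep("gamma", nrow(gl))),
    log10_tau = c(lt_a, lt_b, lt_g),
    log10_sigma_dc = c(ls_a, rep(NA_real_, 2 * nrow(gl))))
  pg <- seq(0, 400, by = 5)
  list(map = map, tg_curve = data.frame(p = pg,
                                        Tg = tg_of_p(pg, config$avramov)),
       config = config)
}

# relaxation strength, optionally Curie 1/T referenced to Tg0
.strength <- function(deps0, T, config) {
  if (isTRUE(config$strengths$curie)) deps0 * config$avramov$Tg0 / T else deps0
}

# noise-free process set of one state point
.state_process_set <- function(T, p, config, supercooled) {
  procs <- list()
  if (supercooled) {
    lt_a <- avramov_tau(T, p, config$avramov)
    sh <- config$alpha_shape
    procs <- c(procs, list(hn_params(
      delta_eps = .strength(config$strengths$deps_alpha, T, config),
      tau_hn = hn_tau_from_peak(10^lt_a, sh$alpha, sh$gamma),
      alpha = sh$alpha, gamma = sh$gamma)))
    sigma <- 10^((config$fdse$log10_const - lt_a) / config$fdse$s_exponent)
  } else sigma <- 0
  shb <- config$beta_process$shape
  procs <- c(procs, list(hn_params(
    delta_eps = .strength(config$strengths$deps_beta, T, config),
    tau_hn = hn_tau_from_peak(10^.beta_log10_tau(T, p, config),
                              shb$alpha, shb$gamma),
    alpha = shb$alpha, gamma = shb$gamma)))
  shg <- config$gamma_process$shape
  procs <- c(procs, list(hn_params(
    delta_eps = .strength(config$strengths$deps_gamma, T, config),
    tau_hn = hn_tau_from_peak(10^.gamma_log10_tau(T, p, config),
                              shg$alpha, shg$gamma),
    alpha = shg$alpha, gamma = shg$gamma)))
  process_set(sigma_dc = sigma, processes = procs)
}

#' Generate synthetic loss spectra for a scenario
#'
#' Evaluates the full spectral model (dc conductivity + alpha + beta + gamma,
#' all processes always present; visibility in the frequency window is
#' emergent) at every state point of the scenario grids and applies
#' multiplicative log-normal noise. The alpha-peak shape is constant in T and
#' p -- the temperature-pressure superpositioning premise of the generator.
#'
#' @param config a validated `scenario_config`.
#' @param truth optional result of [make_relaxation_truth()] (recomputed if
#'   missing; accepted for interface symmetry).
#' @param seed overrides `config$noise$seed`.
#' @param which "all", "supercooled" or "glassy".
#' @return A list of [loss_spectrum()] objects; each carries attributes
#'   `regime` and `seed`.
#' @export
make_spectra <- function(config, truth = NULL, seed = NULL, which = "all") {
  validate_scenario(config)
  if (is.null(seed)) seed <- config$noise$seed
  grids <- switch(which,
    all = rbind(cbind(unique(config$grids$supercooled), regime = "supercooled"),
                cbind(unique(config$grids$glassy), regime = "glassy")),
    supercooled = cbind(unique(config$grids$supercooled), regime = "supercooled"),
    glassy = cbind(unique(config$grids$glassy), regime = "glassy"),
    stop("which must be all, supercooled or glassy"))
  f <- config$grids$f
  sd_dec <- config$noise$sd_decades
  .with_local_seed(seed, {
    lapply(seq_len(nrow(grids)), function(i) {
      ps <- .state_process_set(grids$T[i], grids$p[i], config,
                               grids$regime[i] == "supercooled")
      y <- model_loss(f, ps)
      if (sd_dec > 0) y <- y * 10^stats::rnorm(length(y), 0, sd_dec)
      sp <- loss_spectrum(grids$T[i], grids$p[i], f, y)
      attr(sp, "regime") <- grids$regime[i]
      attr(sp, "seed") <- seed
      sp
    })
  })
}

#' Generate a synthetic DSC trace
#'
#' Linear baseline + logistic heat-capacity step at the glass transition +
#' Gaussian melting endotherm + Gaussian noise, with the step and peak
#' parameters taken from the scenario-scale defaults (Tg = Tg0 of the Avramov
#' set, step 0.464 J/(g K), melting at 413 K).
#'
#' @param config a validated `scenario_config`.
#' @param Tm melting temperature, K.
#' @param dCp heat-capacity step at Tg, J/(g K).
#' @param melt_height,melt_width Gaussian endotherm amplitude (J/(g K)) and
#'   standard deviation (K).
#' @param step_width logistic step width, K.
#' @param baseline c(intercept, slope) of the linear baseline.
#' @param noise_sd Gaussian signal noise, J/(g K).
#' @param seed overrides `config$noise$seed`.
#' @return A [dsc_trace()] carrying attribute `truth` (list of the generating
#'   values).
#' @export
make_dsc <- function(config, Tm = 413, dCp = 0.464, melt_height = 8,
                     melt_width = 2.5, step_width = 2,
                     baseline = c(0.8, 0.002), noise_sd = 0.002,
                     seed = NULL) {
  validate_scenario(config)
  if (is.null(seed)) seed <- config$noise$seed
  Tg <- config$avramov$Tg0
  T <- seq(170, 430, by = 0.2)
  y <- baseline[1] + baseline[2] * T +
    dCp * stats::plogis((T - Tg) / step_width) +
    melt_height * exp(-(T - Tm)^2 / (2 * melt_width^2))
  if (noise_sd > 0)
    y <- .with_local_seed(seed + 1L, y + stats::rnorm(length(T), 0, noise_sd))
  tr <- dsc_trace(T, y, heating_rate = 10)
  attr(tr, "truth") <- list(Tg = Tg, dCp = dCp, Tm = Tm)
  tr
}

#' Isochronal state points of a scenario
#'
#' Finds, for each requested pressure, the temperature at which the
#' generating Avramov surface reaches a target structural relaxation time --
#' the construction used to assemble isochronal spectra sets for shape
#' (superpositioning) analysis.
#'
#' @param params an [avramov_params()] object.
#' @param log10_tau_target target log10 tau_alpha, seconds.
#' @param pressures pressures, MPa.
#' @return data.frame with columns p and T.
#' @export
isochronal_state_points <- function(params, log10_tau_target, pressures) {
  T <- vapply(pressures, function(pp)
    tg_of_p(pp, params, tau_g_criterion = log10_tau_target), numeric(1))
  data.frame(p = pressures, T = T)
}
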