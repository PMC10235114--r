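#' Pressure-extended Avramov parameter set
#'
#' Parameters of the entropy-based Avramov equation of state for the
#' structural relaxation time under temperature and pressure,
#' \deqn{\log_{10}\tau(T,p) = \log_{10}\tau_0 +
#'   \frac{C}{\ln 10}\left(\frac{T_g(p)}{T}\right)^{a(p)},\qquad
#'   a(p) = \alpha_0\left[1 - \frac{C}{C_{p_0}}\ln(1+p/\Pi)\right],}
#' with the glass-transition curve
#' \deqn{T_g(p) = T_{g0}\,(1+p/\Pi)^{\beta /
#'   \{\alpha_0[1-(C/C_{p_0})\ln(1+p/\Pi)]\}}.}
#' By construction \eqn{\tau(T_g(p), p)} is pressure independent (the
#' isochrone defining Tg), with value \eqn{\log_{10}\tau_0 + C/\ln 10}.
#'
#' @param log10_tau0 limiting high-temperature time, log10 seconds.
#' @param C strength coefficient (dimensionless). Under the conventional
#'   tau(Tg) = 100 s criterion, C = ln10 * (2 - log10_tau0).
#' @param Tg0 ambient-pressure glass-transition temperature, K.
#' @param alpha0 ambient fragility exponent (> 0).
#' @param beta_av pressure exponent (> 0).
#' @param Pi pressure scale, MPa (> 0).
#' @param c_over_cp heat-capacity ratio C/C_p0 (>= 0) controlling how the
#'   apparent fragility exponent decreases with pressure.
#' @param p_max pressure up to which the parameter set must stay valid
#'   (c_over_cp * ln(1 + p/Pi) < 1), MPa.
#' @return An object of class `avramov_params`.
#' @export
avramov_params <- function(log10_tau0, C, Tg0, alpha0, beta_av, Pi,
                           c_over_cp, p_max = 400) {
  vals <- c(log10_tau0, C, Tg0, alpha0, beta_av, Pi, c_over_cp)
  if (any(!is.finite(vals))) stop("all parameters must be finite")
  if (Pi <= 0) stop("Pi must be > 0")
  if (alpha0 <= 0 || beta_av <= 0 || Tg0 <= 0)
    stop("alpha0, beta_av and Tg0 must be > 0")
  if (c_over_cp < 0) stop("c_over_cp must be >= 0")
  if (c_over_cp * log(1 + p_max / Pi) >= 1)
    stop("c_over_cp * ln(1 + p/Pi) must stay below 1 over the fitted p-range")
  structure(list(log10_tau0 = log10_tau0, C = C, Tg0 = Tg0, alpha0 = alpha0,
                 beta_av = beta_av, Pi = Pi, c_over_cp = c_over_cp),
            class = "avramov_params")
}

#' @export
print.avramov_params <- function(x, ...) {
  cat(sprintf(paste0(
    "<avramov_params> log10(tau0/s) = %.3f, C = %.3f, Tg0 = %.2f K,\n",
    "  alpha0 = %.3f, beta = %.4f, Pi = %.1f MPa, C/Cp0 = %.4f\n",
    "  dTg/dp|0 = %.1f K/GPa, isochrone log10(tau/s) = %.3f\n"),
    x$log10_tau0, x$C, x$Tg0, x$alpha0, x$beta_av, x$Pi, x$c_over_cp,
    dtg_dp(x), x$log10_tau0 + x$C / .LN10))
  invisible(x)
}

.avramov_exponent <- function(p, params) {
  u <- 1 - params$c_over_cp * log(1 + p / params$Pi)
  if (any(u <= 0)) stop("a(p) <= 0: parameter invariant violated at this p")
  params$alpha0 * u
}

#' Structural relaxation time on the Avramov surface
#'
#' @param T temperature, K; vectorised (recycled against `p`).
#' @param p pressure, MPa; vectorised.
#' @param params an [avramov_params()] object.
#' @return log10 of tau_alpha in seconds.
#' @export
avramov_tau <- function(T, p, params) {
  stopifnot(inherits(params, "avramov_params"))
  if (any(!is.finite(T)) || any(T <= 0)) stop("T must be > 0")
  if (any(!is.finite(p)) || any(p < 0)) stop("p must be >= 0")
  a_p <- .avramov_exponent(p, params)
  tg_p <- tg_of_p(p, params)
  params$log10_tau0 + (params$C / .LN10) * (tg_p / T)^a_p
}

#' Glass-transition temperature versus pressure
#'
#' Closed-form Tg(p) of the Avramov equation of state. With the default
#' `tau_g_criterion = NULL` this is the natural isochrone of the surface (the
#' curve along which tau equals its value at `Tg0` and ambient pressure). A
#' numeric criterion instead returns the isochrone of [avramov_tau()] at that
#' log10 tau level, still in closed form.
#'
#' @param p pressure, MPa (>= 0); vectorised.
#' @param params an [avramov_params()] object.
#' @param tau_g_criterion optional isochrone level, log10 seconds.
#' @return Tg in K.
#' @export
tg_of_p <- function(p, params, tau_g_criterion = NULL) {
  stopifnot(inherits(params, "avramov_params"))
  if (any(!is.finite(p)) || any(p < 0)) stop("p must be >= 0 MPa")
  lp <- log(1 + p / params$Pi)
  denom <- params$alpha0 * (1 - params$c_over_cp * lp)
  if (any(denom <= 0)) stop("Tg(p) undefined: exponent denominator <= 0")
  tg <- params$Tg0 * (1 + p / params$Pi)^(params$beta_av / denom)
  if (is.null(tau_g_criterion)) return(tg)
  # isochrone at an arbitrary level: (Tg(p)/T)^a(p) = ln10 (crit - log tau0)/C
  rhs <- .LN10 * (tau_g_criterion - params$log10_tau0) / params$C
  if (rhs <= 0) stop("tau_g_criterion must exceed log10_tau0")
  a_p <- .avramov_exponent(p, params)
  tg * rhs^(-1 / a_p)
}

#' Pressure coefficient of the glass transition at ambient pressure
#'
#' Closed form of dTg/dp in the p -> 0 limit,
#' \eqn{T_{g0}\,\beta/(\alpha_0 \Pi)} (K/MPa), reported in K/GPa.
#'
#' @param params an [avramov_params()] object.
#' @return dTg/dp at p = 0, K/GPa.
#' @export
dtg_dp <- function(params) {
  stopifnot(inherits(params, "avramov_params"))
  1000 * params$Tg0 * params$beta_av / (params$alpha0 * params$Pi)
}

#' Relaxation map constructor
#'
#' Long-format table of relaxation times (and optionally dc conductivities)
#' versus state point, the bridge between spectral fitting and equation-of-state
#' fitting.
#'
#' @param T,p state point vectors (K, MPa).
#' @param process character vector of process labels ("alpha", "beta", "gamma").
#' @param log10_tau log10 relaxation times, seconds.
#' @param log10_sigma_dc optional log10 dc conductivities, S/cm (NA where not
#'   measured).
#' @return A data.frame of class `relaxation_map`.
#' @export
relaxation_map <- function(T, p, process, log10_tau, log10_sigma_dc = NA_real_) {
  df <- data.frame(T = T, p = p, process = as.character(process),
                   log10_tau = log10_tau,
                   log10_sigma_dc = log10_sigma_dc,
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df[c("T", "p", "process")]))
    stop("duplicate (T, p, process) records")
  if (any(df$log10_tau < -12 | df$log10_tau > 6))
    stop("log10_tau outside the sanity window [-12, 6]")
  class(df) <- c("relaxation_map", "data.frame")
  df
}

#' Fit the Avramov surface to an alpha-relaxation map
#'
#' Joint least squares of [avramov_tau()] over all (T, p) records (one
#' parameter set describing the whole surface). The strength coefficient C is
#' constrained by the isochrone convention C = ln10 (tau_g_criterion -
#' log10 tau0) -- i.e. tau(Tg) equals the criterion, conventionally 100 s --
#' which is what makes Tg0 an identified parameter: at fixed pressure the
#' surface is otherwise invariant under Tg0 -> k Tg0, C -> C k^(-alpha0).
#'
#' @param map a [relaxation_map()]; only `process == "alpha"` records are used.
#' @param tau_g_criterion isochrone level defining Tg, log10 seconds
#'   (default 2, i.e. 100 s).
#' @param restarts jittered multi-starts (fixed seed).
#' @param seed integer seed for the restart jitter.
#' @return A list of class `avramov_fit`: `params` ([avramov_params()]),
#'   `residual` (RMS decades), `converged`, `ill_conditioned`, `se`
#'   (approximate standard errors), `n`.
#' @export
fit_avramov_surface <- function(map, tau_g_criterion = 2, restarts = 6,
                                seed = 421) {
  stopifnot(inherits(map, "relaxation_map") || is.data.frame(map))
  rec <- map[map$process == "alpha", , drop = FALSE]
  if (nrow(rec) < 8) stop("need at least 8 alpha records")
  Tv <- rec$T; pv <- rec$p; lt <- rec$log10_tau
  n_pressures <- length(unique(round(pv)))
  single_pressure <- n_pressures < 2

  # theta = (log10_tau0, Tg0, log(alpha0), beta_av, log(Pi), c_over_cp)
  build <- function(theta) {
    lt0 <- theta[1]
    avramov_params(log10_tau0 = lt0,
                   C = .LN10 * (tau_g_criterion - lt0),
                   Tg0 = theta[2], alpha0 = exp(theta[3]),
                   beta_av = theta[4], Pi = exp(theta[5]),
                   c_over_cp = theta[6], p_max = max(pv))
  }
  resid_fn <- function(theta) {
    par <- try(build(theta), silent = TRUE)
    if (inherits(par, "try-error")) return(rep(1e6, length(lt)))
    out <- try(avramov_tau(Tv, pv, par) - lt, silent = TRUE)
    if (inherits(out, "try-error") || any(!is.finite(out)))
      return(rep(1e6, length(lt)))
    out
  }

  # data-driven Tg0 start: quadratic-in-1/T extrapolation of the lowest-p
  # records to the isochrone level
  p0 <- min(pv)
  amb <- rec[abs(pv - p0) < 1e-9, , drop = FALSE]
  tg0_init <- if (nrow(amb) >= 4) {
    x <- 1 / amb$T
    cf <- stats::lm(amb$log10_tau ~ x + I(x^2))$coefficients
    rt <- try({
      r <- Re(polyroot(c(cf[1] - tau_g_criterion, cf[2], cf[3])))
      cand <- 1 / r[r > 0]
      # the isochrone sits just below the coldest measured temperature
      cand <- cand[cand < 1.02 * min(amb$T)]
      max(cand)
    }, silent = TRUE)
    if (inherits(rt, "try-error") || !is.finite(rt) || length(rt) == 0)
      0.9 * min(amb$T) else rt
  } else 0.9 * min(Tv)

  theta0 <- c(-13, tg0_init, log(5), 0.6, log(300), 0.05)
  lower <- c(-20, 0.5 * tg0_init, log(0.5), 0.01, log(10), 0)
  upper <- c(-6, 1.5 * tg0_init, log(25), 10, log(5000), 0.49)

  run_one <- function(th) {
    th <- pmin(pmax(th, lower), upper)
    fit <- try(minpack.lm::nls.lm(
      par = th, lower = lower, upper = upper, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)), silent = TRUE)
    if (inherits(fit, "try-error")) NULL else fit
  }
  fits <- .with_local_seed(seed, {
    out <- list(run_one(theta0))
    for (r in seq_len(max(0, restarts - 1))) {
      jit <- theta0 + stats::rnorm(6, 0, c(1, 3, 0.3, 0.2, 0.5, 0.02))
      out <- c(out, list(run_one(jit)))
    }
    out
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) stop("all restarts of the surface fit failed")
  rss <- vapply(fits, function(fit) sum(fit$fvec^2), numeric(1))
  best <- fits[[which.min(rss)]]
  params <- build(best$par)
  residual <- sqrt(min(rss) / length(lt))

  # approximate standard errors from the Jacobian at the optimum
  se <- rep(NA_real_, 6)
  cov_ok <- TRUE
  hv <- try(chol2inv(chol(best$hessian)), silent = TRUE)
  if (!inherits(hv, "try-error")) {
    s2 <- min(rss) / max(1, length(lt) - 6)
    se <- sqrt(pmax(diag(hv), 0) * s2)
  } else cov_ok <- FALSE
  scale_ref <- abs(best$par); scale_ref[scale_ref < 1e-3] <- 1
  ill <- single_pressure || !cov_ok ||
    any(!is.finite(se)) || any(se / scale_ref > 10)

  structure(list(params = params, residual = residual,
                 converged = best$info %in% 1:4,
                 ill_conditioned = ill, se = se, n = length(lt),
                 tau_g_criterion = tau_g_criterion),
            class = "avramov_fit")
}

#' @export
print.avramov_fit <- function(x, ...) {
  cat(sprintf("<avramov_fit> n = %d, RMS = %.4g decades%s\n", x$n, x$residual,
              if (x$ill_conditioned) " [ill-conditioned]" else ""))
  print(x$params)
  invisible(x)
}
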