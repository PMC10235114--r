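# Wald-Wolfowitz runs test on residual signs: too few runs means systematic
# curvature, i.e. the data are not described by the straight line.
.curvature_flag <- function(resid, alpha_level = 0.01) {
  s <- sign(resid)
  s <- s[s != 0]
  n <- length(s)
  if (n < 8) return(FALSE)
  n1 <- sum(s > 0); n2 <- sum(s < 0)
  if (n1 == 0 || n2 == 0) return(TRUE)
  runs <- 1 + sum(diff(s) != 0)
  mu <- 1 + 2 * n1 * n2 / n
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  if (v <= 0) return(FALSE)
  stats::pnorm((runs - mu) / sqrt(v)) < alpha_level
}

#' Arrhenius fit of a relaxation-time branch
#'
#' Linear least squares of \eqn{\ln\tau} versus 1/T for a thermally activated
#' process \eqn{\tau = \tau_\infty \exp(E/RT)}; the activation energy follows
#' from the slope.
#'
#' @param T temperatures, K (>= 3 points spanning >= 20 K).
#' @param log10_tau log10 relaxation times, s.
#' @param process label carried through to the result ("beta", "gamma", ...).
#' @param p pressure label, MPa.
#' @return A list of class `arrhenius_fit`: `E_act` (kJ/mol),
#'   `log10_tau_inf`, standard errors `se_E` and `se_log10_tau_inf`,
#'   `residual_rms` (decades), `non_arrhenius` (runs-test curvature flag),
#'   `condition`.
#' @export
arrhenius_fit <- function(T, log10_tau, process = "beta", p = NA_real_) {
  if (length(T) < 3) stop("need at least 3 points")
  if (diff(range(T)) < 20) stop("temperature span must be >= 20 K")
  x <- 1 / T
  fit <- stats::lm(log10_tau ~ x)
  cf <- suppressWarnings(summary(fit)$coefficients)
  R <- bds_constants$R
  E <- unname(cf[2, 1]) * R * .LN10 / 1000          # kJ/mol
  se_E <- unname(cf[2, 2]) * R * .LN10 / 1000
  structure(list(E_act = E, log10_tau_inf = unname(cf[1, 1]),
                 se_E = se_E, se_log10_tau_inf = unname(cf[1, 2]),
                 residual_rms = sqrt(mean(stats::resid(fit)^2)),
                 non_arrhenius = .curvature_flag(stats::resid(fit)),
                 condition = list(process = process, p = p)),
            class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("<arrhenius_fit> %s (p = %s MPa): E = %.2f kJ/mol, log10(tau_inf/s) = %.2f%s\n",
              x$condition$process, format(x$condition$p), x$E_act,
              x$log10_tau_inf,
              if (x$non_arrhenius) " [non-Arrhenius]" else ""))
  invisible(x)
}

#' Activation volume from an isothermal pressure scan
#'
#' \deqn{\Delta V = 2.303\,R\,T\,(d\log_{10}\tau/dp)_T,} with the slope in
#' 1/MPa and R in J/(mol K); J/(mol MPa) is identically cm3/mol.
#'
#' @param p pressures, MPa (>= 3 points spanning >= 100 MPa).
#' @param log10_tau log10 relaxation times, s.
#' @param T temperature of the isotherm, K.
#' @return A list of class `activation_volume`: `dV` (cm3/mol), `se_dV`,
#'   `slope` (decades/MPa), `nonlinear` flag, `T`.
#' @export
activation_volume <- function(p, log10_tau, T) {
  if (length(p) < 3) stop("need at least 3 points")
  if (diff(range(p)) < 100) stop("pressure span must be >= 100 MPa")
  fit <- stats::lm(log10_tau ~ p)
  cf <- suppressWarnings(summary(fit)$coefficients)
  fac <- .LN10 * bds_constants$R * T        # (J/(mol K) * K) = J/mol per decade
  structure(list(dV = fac * unname(cf[2, 1]), se_dV = fac * unname(cf[2, 2]),
                 slope = unname(cf[2, 1]),
                 nonlinear = .curvature_flag(stats::resid(fit)), T = T),
            class = "activation_volume")
}

#' @export
print.activation_volume <- function(x, ...) {
  cat(sprintf("<activation_volume> T = %.1f K: dV = %.2f cm3/mol (slope %.3g dec/MPa)%s\n",
              x$T, x$dV, x$slope, if (x$nonlinear) " [nonlinear]" else ""))
  invisible(x)
}

#' Eyring reduction of a relaxation-time branch
#'
#' Transition-state analysis: linear least squares of \eqn{\ln(\tau T)} versus
#' 1/T,
#' \deqn{\ln(\tau T) = \frac{\Delta H}{R}\frac{1}{T} +
#'   \left[\ln\frac{h}{k_B} - \frac{\Delta S}{R}\right],}
#' giving the activation enthalpy from the slope and the activation entropy
#' from the intercept.
#'
#' @inheritParams arrhenius_fit
#' @return A list of class `eyring_fit`: `dH` (kJ/mol), `dS` (J/(mol K)),
#'   standard errors, `non_arrhenius` flag, `condition`.
#' @export
eyring_fit <- function(T, log10_tau, process = "beta", p = NA_real_) {
  if (length(T) < 3) stop("need at least 3 points")
  if (diff(range(T)) < 20) stop("temperature span must be >= 20 K")
  x <- 1 / T
  y <- log10_tau * .LN10 + log(T)           # ln(tau*T)
  fit <- stats::lm(y ~ x)
  cf <- suppressWarnings(summary(fit)$coefficients)
  R <- bds_constants$R
  dH <- R * unname(cf[2, 1]) / 1000
  dS <- R * (log(bds_constants$h / bds_constants$kB) - unname(cf[1, 1]))
  structure(list(dH = dH, dS = dS,
                 se_dH = R * unname(cf[2, 2]) / 1000,
                 se_dS = R * unname(cf[1, 2]),
                 non_arrhenius = .curvature_flag(stats::resid(fit)),
                 condition = list(process = process, p = p)),
            class = "eyring_fit")
}

#' @export
print.eyring_fit <- function(x, ...) {
  cat(sprintf("<eyring_fit> %s (p = %s MPa): dH = %.2f kJ/mol, dS = %.2f J/(mol K)\n",
              x$condition$process, format(x$condition$p), x$dH, x$dS))
  invisible(x)
}

#' Tg-scaled master plot of a secondary relaxation
#'
#' Rescales log10 tau of a secondary process against Tg(p)/T for every
#' pressure and measures how well the branches collapse onto a single curve:
#' the metric is the maximal vertical spread (decades) over the overlapping
#' range of the scaled abscissa.
#'
#' @param map a [relaxation_map()] holding the secondary-process records.
#' @param tg_curve data.frame with columns `p` (MPa) and `Tg` (K), or a
#'   function p -> Tg.
#' @param process which process label to collapse (default "beta").
#' @param threshold spread below which the branches are declared collapsed,
#'   decades.
#' @return A list of class `collapse_metric`: `spread` (decades; 0 with a
#'   single pressure), `collapses`, `overlap` (scaled-abscissa range compared),
#'   `branches` (data.frame of p, Tg, x = Tg/T, log10_tau).
#' @export
tg_scaled_collapse <- function(map, tg_curve, process = "beta",
                               threshold = 0.2) {
  rec <- map[map$process == process, , drop = FALSE]
  if (nrow(rec) == 0) stop("map has no records for this process")
  tg_fun <- if (is.function(tg_curve)) tg_curve else {
    stopifnot(all(c("p", "Tg") %in% names(tg_curve)))
    function(p) stats::approx(tg_curve$p, tg_curve$Tg, xout = p,
                              rule = 2)$y
  }
  rec$Tg <- vapply(rec$p, tg_fun, numeric(1))
  rec$x <- rec$Tg / rec$T
  # only pressures with enough points to trace a branch take part in the
  # comparison (isothermal scans contribute one point per pressure)
  counts <- table(rec$p)
  rec <- rec[rec$p %in% as.numeric(names(counts)[counts >= 3]), , drop = FALSE]
  if (nrow(rec) == 0) stop("no pressure has >= 3 records for this process")
  pressures <- sort(unique(rec$p))
  branches <- rec[order(rec$p, rec$x), c("p", "Tg", "x", "log10_tau", "T")]
  if (length(pressures) < 2)
    return(structure(list(spread = 0, collapses = TRUE, overlap = NULL,
                          branches = branches), class = "collapse_metric"))
  lo <- max(vapply(pressures, function(pp) min(rec$x[rec$p == pp]), numeric(1)))
  hi <- min(vapply(pressures, function(pp) max(rec$x[rec$p == pp]), numeric(1)))
  if (!(hi > lo))
    return(structure(list(spread = NA_real_, collapses = NA, overlap = NULL,
                          branches = branches, flag = "no_overlap"),
                     class = "collapse_metric"))
  xg <- seq(lo, hi, length.out = 101)
  ymat <- vapply(pressures, function(pp) {
    sub <- rec[rec$p == pp, ]
    stats::approx(sub$x, sub$log10_tau, xout = xg)$y
  }, numeric(length(xg)))
  spread <- max(apply(ymat, 1, max) - apply(ymat, 1, min))
  structure(list(spread = spread, collapses = spread < threshold,
                 overlap = c(lo, hi), branches = branches),
            class = "collapse_metric")
}

#' @export
print.collapse_metric <- function(x, ...) {
  cat(sprintf("<collapse_metric> spread = %.3f decades -> %s\n", x$spread,
              if (isTRUE(x$collapses)) "collapses" else "does not collapse"))
  invisible(x)
}

#' Isochronal ratio of structural and secondary relaxation times
#'
#' For every pressure, finds the temperature at which the structural
#' relaxation time equals a reference value (linear interpolation of log10 tau
#' in 1/T) and evaluates the secondary relaxation time there. A
#' pressure-independent ratio log10(tau_alpha/tau_beta) at fixed tau_alpha is
#' the isochronal-superpositioning signature.
#'
#' @param alpha_map,beta_map [relaxation_map()] objects carrying the alpha and
#'   the secondary branch (labels "alpha" and `process`).
#' @param tau_alpha_ref reference structural time, seconds.
#' @param process secondary label in `beta_map`.
#' @param extrapolate allow linear extrapolation of the branches in 1/T beyond
#'   their data range (the reading near Tg usually requires extrapolating the
#'   secondary Arrhenius branch).
#' @return A list of class `isochronal_ratio`: `table` (p, T_iso,
#'   log10_tau_beta, ratio_decades), `spread` (max - min ratio), `skipped`.
#' @export
isochronal_ratio <- function(alpha_map, beta_map, tau_alpha_ref,
                             process = "beta", extrapolate = FALSE) {
  a <- alpha_map[alpha_map$process == "alpha", , drop = FALSE]
  b <- beta_map[beta_map$process == process, , drop = FALSE]
  if (nrow(a) == 0 || nrow(b) == 0) stop("maps lack required records")
  lref <- log10(tau_alpha_ref)
  pressures <- sort(intersect(unique(a$p), unique(b$p)))
  if (length(pressures) == 0) stop("no common pressures in the two maps")
  rows <- NULL; skipped <- numeric(0)
  for (pp in pressures) {
    sa <- a[a$p == pp, ]; sb <- b[b$p == pp, ]
    if (nrow(sa) < 2 || nrow(sb) < 2) { skipped <- c(skipped, pp); next }
    # invert log10 tau_alpha(1/T) at the reference level
    o <- order(sa$log10_tau)
    lt <- sa$log10_tau[o]; invT <- (1 / sa$T)[o]
    in_range <- lref >= min(lt) && lref <= max(lt)
    if (!in_range && !extrapolate) { skipped <- c(skipped, pp); next }
    invT_ref <- stats::approx(lt, invT, xout = lref, rule = 2, ties = mean)$y
    if (!in_range) {
      # linear extension of the alpha branch in (log tau, 1/T)
      cf <- stats::coef(stats::lm(invT ~ lt))
      invT_ref <- unname(cf[1] + cf[2] * lref)
    }
    T_iso <- 1 / invT_ref
    bx <- (1 / sb$T); by <- sb$log10_tau
    b_in <- 1 / T_iso >= min(bx) && 1 / T_iso <= max(bx)
    if (!b_in && !extrapolate) { skipped <- c(skipped, pp); next }
    lt_b <- if (b_in) stats::approx(bx, by, xout = 1 / T_iso, ties = mean)$y else {
      cf <- stats::coef(stats::lm(by ~ bx))
      unname(cf[1] + cf[2] / T_iso)
    }
    rows <- rbind(rows, data.frame(p = pp, T_iso = T_iso,
                                   log10_tau_beta = lt_b,
                                   ratio_decades = lref - lt_b))
  }
  if (is.null(rows)) stop("tau_alpha_ref unreachable at every pressure")
  structure(list(table = rows,
                 spread = max(rows$ratio_decades) - min(rows$ratio_decades),
                 skipped = skipped, tau_alpha_ref = tau_alpha_ref),
            class = "isochronal_ratio")
}

#' @export
print.isochronal_ratio <- function(x, ...) {
  cat(sprintf("<isochronal_ratio> tau_alpha = %.3g s: spread = %.3f decades\n",
              x$tau_alpha_ref, x$spread))
  print(x$table, row.names = FALSE)
  invisible(x)
}
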