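#' Fractional Debye-Stokes-Einstein exponent
#'
#' Quantifies the coupling between charge transport and structural relaxation
#' through \eqn{\sigma_{dc}^{\,s}\,\tau_\alpha = const}: in log space
#' \eqn{\log_{10}\tau_\alpha = const - s\,\log_{10}\sigma_{dc}}. The exponent
#' is estimated by ordinary least squares of log10 tau on log10 sigma (sigma
#' as abscissa); s = 1 is the fully coupled Debye-Stokes-Einstein limit and
#' lower values measure the decoupling typical of proton-conducting H-bonded
#' liquids.
#'
#' @param log10_sigma log10 dc conductivities (S/cm).
#' @param log10_tau log10 structural relaxation times (s).
#' @param condition label of the thermodynamic condition (e.g. "p = 0.1 MPa").
#' @return A list of class `fdse_fit`: `s_exponent`, `intercept` (the log10
#'   constant of sigma^s tau), `r_squared`, `condition`, `n`, `flags`
#'   ("degenerate_span" when tau spans less than one decade, "unphysical" when
#'   s falls outside (0, 1]).
#' @export
fdse_exponent <- function(log10_sigma, log10_tau, condition = "") {
  if (length(log10_sigma) != length(log10_tau))
    stop("input lengths differ")
  keep <- is.finite(log10_sigma) & is.finite(log10_tau)
  x <- log10_sigma[keep]; y <- log10_tau[keep]
  if (length(x) < 3) stop("need at least 3 (sigma, tau) pairs")
  flags <- character(0)
  if (diff(range(y)) < 1) flags <- c(flags, "degenerate_span")
  fit <- stats::lm(y ~ x)
  s <- -unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  # noise-free closures are legitimately perfect fits
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (!is.finite(s) || s <= 0 || s > 1) flags <- c(flags, "unphysical")
  structure(list(s_exponent = s, intercept = intercept, r_squared = r2,
                 condition = condition, n = length(x), flags = flags),
            class = "fdse_fit")
}

#' @export
print.fdse_fit <- function(x, ...) {
  cat(sprintf("<fdse_fit> %s: s = %.4f (n = %d, R^2 = %.5f)%s\n",
              x$condition, x$s_exponent, x$n, x$r_squared,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

#' FDSE exponents across isobars and isotherms
#'
#' Groups the alpha records of a relaxation map that carry conductivities into
#' isobaric (shared p) and isothermal (shared T) conditions and fits
#' [fdse_exponent()] on each condition with at least three state points.
#'
#' @param map a [relaxation_map()] with `log10_sigma_dc` on alpha records.
#' @param T_tol,p_tol grouping tolerances (K, MPa) for float state values.
#' @return A list: `fits` (list of `fdse_fit`), `table` (data.frame with
#'   condition, kind, value, s, r_squared, n), `s_spread` (max - min s),
#'   `skipped` (conditions dropped for missing sigma or too few points).
#' @export
fdse_map <- function(map, T_tol = 0.1, p_tol = 1) {
  rec <- map[map$process == "alpha" & is.finite(map$log10_sigma_dc), ,
             drop = FALSE]
  if (nrow(rec) == 0) stop("map carries no alpha records with sigma_dc")
  group_key <- function(v, tol) round(v / tol) * tol
  fits <- list(); skipped <- character(0); rows <- NULL
  # isobars: shared pressure, varying temperature
  for (pk in unique(group_key(rec$p, p_tol))) {
    sub <- rec[abs(group_key(rec$p, p_tol) - pk) < half_tol(p_tol), ]
    lbl <- sprintf("isobar p = %.1f MPa", pk)
    if (length(unique(sub$T)) < 3) {
      if (nrow(sub) >= 3) skipped <- c(skipped, lbl)
      next
    }
    ft <- fdse_exponent(sub$log10_sigma_dc, sub$log10_tau, lbl)
    fits <- c(fits, list(ft))
    rows <- rbind(rows, data.frame(condition = lbl, kind = "isobar",
                                   value = pk, s = ft$s_exponent,
                                   r_squared = ft$r_squared, n = ft$n))
  }
  # isotherms: shared temperature, varying pressure
  for (tk in unique(group_key(rec$T, T_tol))) {
    sub <- rec[abs(group_key(rec$T, T_tol) - tk) < half_tol(T_tol), ]
    if (length(unique(sub$p)) < 3) next
    lbl <- sprintf("isotherm T = %.1f K", tk)
    ft <- fdse_exponent(sub$log10_sigma_dc, sub$log10_tau, lbl)
    fits <- c(fits, list(ft))
    rows <- rbind(rows, data.frame(condition = lbl, kind = "isotherm",
                                   value = tk, s = ft$s_exponent,
                                   r_squared = ft$r_squared, n = ft$n))
  }
  if (length(fits) == 0) stop("no condition has >= 3 usable state points")
  svals <- vapply(fits, function(f) f$s_exponent, numeric(1))
  list(fits = fits, table = rows, s_spread = max(svals) - min(svals),
       skipped = skipped)
}

half_tol <- function(tol) tol / 2 + 1e-9
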