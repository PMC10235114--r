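#' Havriliak-Negami parameter set
#'
#' Parameters of one Havriliak-Negami (HN) relaxation process,
#' \deqn{\varepsilon^*(\omega) = \Delta\varepsilon /
#'   [1 + (i\omega\tau_{HN})^\alpha]^\gamma,}
#' where `alpha` controls the symmetric breadth and `gamma` the high-frequency
#' asymmetry of the loss peak. `alpha = gamma = 1` is the Debye limit.
#'
#' @param delta_eps dielectric relaxation strength (> 0).
#' @param tau_hn HN relaxation time in seconds (> 0). Note this is not the
#'   loss-peak time; see [hn_peak_time()].
#' @param alpha breadth exponent, in (0, 1].
#' @param gamma asymmetry exponent, in (0, 1].
#' @return An object of class `hn_params`.
#' @seealso [hn_loss()], [hn_peak_time()]
#' @export
hn_params <- function(delta_eps, tau_hn, alpha, gamma) {
  stopifnot(is.numeric(delta_eps), is.numeric(tau_hn),
            is.numeric(alpha), is.numeric(gamma))
  if (!is.finite(delta_eps) || delta_eps <= 0)
    stop("delta_eps must be finite and > 0")
  if (!is.finite(tau_hn) || tau_hn <= 0) stop("tau_hn must be finite and > 0")
  if (!is.finite(alpha) || alpha <= 0 || alpha > 1)
    stop("alpha must be in (0, 1]")
  if (!is.finite(gamma) || gamma <= 0 || gamma > 1)
    stop("gamma must be in (0, 1]")
  structure(list(delta_eps = delta_eps, tau_hn = tau_hn,
                 alpha = alpha, gamma = gamma),
            class = "hn_params")
}

#' @export
print.hn_params <- function(x, ...) {
  cat(sprintf(
    "<hn_params> delta_eps = %.4g, tau_HN = %.4g s, alpha = %.3f, gamma = %.3f\n",
    x$delta_eps, x$tau_hn, x$alpha, x$gamma))
  invisible(x)
}

#' Kohlrausch-Williams-Watts parameter set
#'
#' Parameters of the stretched-exponential relaxation function
#' \eqn{\Phi(t) = \exp[-(t/\tau)^{\beta}]}. `beta_kww = 1` is exponential
#' (Debye) relaxation; smaller values give broader, more dispersive loss peaks.
#'
#' @param tau_kww characteristic relaxation time, seconds (> 0).
#' @param beta_kww stretching exponent, in (0, 1].
#' @return An object of class `kww_params`.
#' @export
kww_params <- function(tau_kww, beta_kww) {
  if (!is.finite(tau_kww) || tau_kww <= 0) stop("tau_kww must be > 0")
  if (!is.finite(beta_kww) || beta_kww <= 0 || beta_kww > 1)
    stop("beta_kww must be in (0, 1]")
  structure(list(tau_kww = tau_kww, beta_kww = beta_kww), class = "kww_params")
}

#' Full spectral model: conductivity plus a set of HN processes
#'
#' @param sigma_dc dc conductivity in S/cm (>= 0).
#' @param eps_inf high-frequency limit permittivity (enters only the real part
#'   of the permittivity, kept for completeness of the model record).
#' @param processes list of [hn_params()] objects, conventionally ordered
#'   slowest first (alpha, then beta, then gamma).
#' @return An object of class `process_set`.
#' @export
process_set <- function(sigma_dc = 0, eps_inf = 1, processes = list()) {
  if (!is.finite(sigma_dc) || sigma_dc < 0) stop("sigma_dc must be >= 0")
  if (!is.list(processes) || (length(processes) > 0 &&
      !all(vapply(processes, inherits, logical(1), "hn_params"))))
    stop("processes must be a list of hn_params objects")
  structure(list(sigma_dc = sigma_dc, eps_inf = eps_inf,
                 processes = processes),
            class = "process_set")
}

#' Havriliak-Negami dielectric loss
#'
#' Imaginary part (loss convention, positive) of the HN relaxation term
#' \eqn{\Delta\varepsilon/[1+(i\omega\tau_{HN})^\alpha]^\gamma}, evaluated in
#' closed trigonometric form.
#'
#' @param omega angular frequency in rad/s (> 0); vectorised.
#' @param params an [hn_params()] object.
#' @return Loss values (dimensionless), same length as `omega`.
#' @examples
#' p <- hn_params(1, 1, 1, 1)
#' hn_loss(1, p)  # Debye loss at the peak: 0.5
#' @export
hn_loss <- function(omega, params) {
  stopifnot(inherits(params, "hn_params"))
  if (length(omega) == 0 || any(!is.finite(omega)) || any(omega <= 0))
    stop("omega must be finite and > 0")
  wt_a <- (omega * params$tau_hn)^params$alpha
  ca <- cos(pi * params$alpha / 2)
  sa <- sin(pi * params$alpha / 2)
  re <- 1 + wt_a * ca
  im <- wt_a * sa
  theta <- atan2(im, re)
  params$delta_eps * sin(params$gamma * theta) /
    (re^2 + im^2)^(params$gamma / 2)
}

#' dc-conductivity contribution to the dielectric loss
#'
#' \eqn{\sigma_{dc}/(\varepsilon_0\omega)} with `sigma_dc` in S/cm (converted
#' to S/m internally; the vacuum permittivity is in F/m).
#'
#' @param omega angular frequency in rad/s (> 0); vectorised.
#' @param sigma_dc dc conductivity, S/cm (>= 0).
#' @return Loss values (dimensionless).
#' @export
dc_loss <- function(omega, sigma_dc) {
  if (any(!is.finite(omega)) || any(omega <= 0))
    stop("omega must be finite and > 0")
  if (!is.finite(sigma_dc) || sigma_dc < 0) stop("sigma_dc must be >= 0")
  .sigma_cgs_to_si(sigma_dc) / (bds_constants$eps0 * omega)
}

#' Model dielectric loss spectrum
#'
#' Superposition of the dc-conductivity term and all HN processes of a
#' [process_set()], evaluated at ordinary frequencies. All stored frequency
#' grids are in Hz; the conversion to angular frequency happens here only.
#'
#' @param freq frequency grid in Hz, strictly increasing, positive.
#' @param model a [process_set()] object.
#' @return Loss values, same length as `freq`.
#' @export
model_loss <- function(freq, model) {
  stopifnot(inherits(model, "process_set"))
  if (length(freq) == 0) stop("frequency grid is empty")
  if (any(!is.finite(freq)) || any(freq <= 0) || is.unsorted(freq, strictly = TRUE))
    stop("freq must be positive and strictly increasing")
  omega <- 2 * pi * freq
  out <- dc_loss(omega, model$sigma_dc)
  for (pr in model$processes) out <- out + hn_loss(omega, pr)
  out
}

#' KWW relaxation function
#'
#' \eqn{\Phi(t)=\exp[-(t/\tau)^\beta]}.
#'
#' @param t time in seconds (>= 0); vectorised.
#' @param params a [kww_params()] object.
#' @return Correlation values in (0, 1].
#' @export
kww_decay <- function(t, params) {
  stopifnot(inherits(params, "kww_params"))
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be finite and >= 0")
  exp(-(t / params$tau_kww)^params$beta_kww)
}

# Normalised KWW loss at reduced frequency wt = omega*tau, by the one-sided
# Fourier transform of (-dPhi/dt):
#   eps''(wt) = Int_0^Inf (-Phi'(t)) sin(wt t) dt   (tau = 1 units).
# Substituting v = t^beta and rotating the integration path onto the ray
# t = s exp(-i pi/4) (allowed: the integrand is entire, decays in the sector)
# gives a non-oscillatory absolutely convergent integral,
#   F(wt) = e^{-i b th} Int_0^Inf exp(-v e^{-i b th} - i wt v^{1/b} e^{-i th}) dv
# with th = pi/4, b = beta, and eps'' = -Im F.
.int_quiet <- function(f, lo, hi, rel.tol) {
  r <- stats::integrate(f, lo, hi, rel.tol = rel.tol, abs.tol = 1e-300,
                        subdivisions = 500L, stop.on.error = FALSE)
  if (!is.finite(r$value))
    stop("quadrature failed: ", r$message)
  r$value
}

.kww_loss_scalar <- function(wt, beta, rel.tol = 1e-10) {
  th <- pi / 4
  eb <- complex(modulus = 1, argument = -th * beta)
  e1 <- complex(modulus = 1, argument = -th)
  f_im <- function(v) Im(eb * exp(-v * eb - 1i * wt * v^(1 / beta) * e1))
  # the modulus decays like exp(-v cos(beta*pi/4) - wt v^(1/beta) sin(pi/4));
  # integrate in two pieces split at the faster of the two decay scales so the
  # adaptive rule cannot overlook a narrow high-frequency support
  upper <- 60 / cos(th * beta)
  v1 <- min(upper / 2, max((40 / (wt * sin(th)))^beta, 1e-8))
  im <- .int_quiet(f_im, 0, v1, rel.tol)
  # beyond v1 the modulus is below exp(-40) of the peak scale; only integrate
  # the tail when the split was set by the thermal (v) decay, not the omega one
  if (v1 >= upper / 2 - 1e-12)
    im <- im + .int_quiet(f_im, v1, upper, rel.tol)
  -im
}

#' Normalised KWW dielectric loss (one-sided Fourier transform)
#'
#' Imaginary part of the one-sided Fourier transform of \eqn{-d\Phi/dt} for the
#' stretched exponential, normalised to unit relaxation strength. For
#' `beta_kww = 1` this reduces to the Debye loss
#' \eqn{\omega\tau/(1+\omega^2\tau^2)}. Evaluated by quadrature along a rotated
#' integration path on which the Fourier kernel does not oscillate.
#'
#' @param omega angular frequency in rad/s (> 0); vectorised.
#' @param params a [kww_params()] object.
#' @return Loss values (dimensionless, relaxation strength 1).
#' @export
kww_loss <- function(omega, params) {
  stopifnot(inherits(params, "kww_params"))
  if (any(!is.finite(omega)) || any(omega <= 0))
    stop("omega must be finite and > 0")
  wt <- omega * params$tau_kww
  b <- params$beta_kww
  if (b == 1) return(wt / (1 + wt^2))
  vapply(wt, .kww_loss_scalar, numeric(1), beta = b)
}

# Reduced peak frequency (omega*tau at the loss maximum) of the normalised KWW
# loss. Debye: 1; decreasing beta pushes the maximum to slightly higher wt.
.kww_peak_omega <- function(beta) {
  if (beta == 1) return(1)
  opt <- stats::optimize(function(lw) -.kww_loss_scalar(10^lw, beta),
                         interval = c(-1, 1.5), tol = 1e-7)
  10^opt$minimum
}

#' Loss-peak relaxation time of an HN process
#'
#' Converts the HN time to the model-free relaxation time
#' \eqn{\tau_{max} = 1/\omega_{max}} at the analytic maximum of the HN loss:
#' \deqn{\tau_{max} = \tau_{HN}\,
#'  \left[\sin\frac{\pi\alpha}{2(\gamma+1)}\right]^{-1/\alpha}
#'  \left[\sin\frac{\pi\alpha\gamma}{2(\gamma+1)}\right]^{1/\alpha}.}
#'
#' @param params an [hn_params()] object.
#' @return tau_max in seconds.
#' @export
hn_peak_time <- function(params) {
  stopifnot(inherits(params, "hn_params"))
  a <- params$alpha; g <- params$gamma
  params$tau_hn * sin(pi * a / (2 * (g + 1)))^(-1 / a) *
    sin(pi * a * g / (2 * (g + 1)))^(1 / a)
}

#' HN relaxation time from a loss-peak time
#'
#' Inverse of [hn_peak_time()]: the HN time whose loss maximum sits at
#' `tau_max` for the given shape exponents.
#'
#' @param tau_max loss-peak relaxation time, seconds.
#' @param alpha,gamma HN shape exponents.
#' @return tau_HN in seconds.
#' @export
hn_tau_from_peak <- function(tau_max, alpha, gamma) {
  ratio <- sin(pi * alpha / (2 * (gamma + 1)))^(-1 / alpha) *
    sin(pi * alpha * gamma / (2 * (gamma + 1)))^(1 / alpha)
  tau_max / ratio
}

#' Peak geometry of a loss spectrum
#'
#' Locates the loss maximum by parabolic interpolation in
#' (log10 f, log10 eps'') around the discrete argmax, and measures the full
#' width at half maximum in decades of frequency from linearly interpolated
#' half-height crossings. A Debye peak has fwhm ~ 1.144 decades; any broader
#' dispersion widens it.
#'
#' @param spectrum a [loss_spectrum()] object.
#' @return A list of class `peak_stats`: `f_max` (Hz), `eps2_max`,
#'   `fwhm_decades` (NA when a half-height crossing is outside the grid), and
#'   `reliable` (FALSE when the maximum sits on the grid edge).
#' @export
peak_stats <- function(spectrum) {
  stopifnot(inherits(spectrum, "loss_spectrum"))
  f <- spectrum$f; y <- spectrum$eps2
  i <- which.max(y)
  reliable <- i > 1 && i < length(y)
  lf <- log10(f); ly <- log10(y)
  if (reliable) {
    # parabola y = a + b (x-x1) + c (x-x1)^2 fitted over the points within
    # half a decade of the discrete maximum (at least the adjacent ones);
    # its vertex refines position and height while averaging down point noise
    j <- which(abs(lf - lf[i]) <= 0.5)
    if (length(j) < 3) j <- (i - 1):(i + 1)
    x <- lf[j] - lf[i]
    cfs <- stats::lm.fit(cbind(1, x, x^2), ly[j])$coefficients
    if (is.finite(cfs[3]) && cfs[3] < 0) {
      lx_max <- lf[i] - cfs[2] / (2 * cfs[3])
      ly_max <- cfs[1] - cfs[2]^2 / (4 * cfs[3])
    } else {
      lx_max <- lf[i]; ly_max <- ly[i]
    }
  } else {
    lx_max <- lf[i]; ly_max <- ly[i]
  }
  f_max <- 10^lx_max; eps2_max <- 10^ly_max
  # half-height crossings, linear interpolation in (log f, log eps2)
  lhalf <- ly_max - log10(2)
  fwhm <- NA_real_
  if (reliable) {
    left <- right <- NA_real_
    for (j in seq(i, 2)) {
      if (ly[j - 1] <= lhalf && ly[j] > lhalf) {
        left <- lf[j - 1] + (lhalf - ly[j - 1]) * (lf[j] - lf[j - 1]) /
          (ly[j] - ly[j - 1])
        break
      }
    }
    for (j in seq(i, length(y) - 1)) {
      if (ly[j + 1] <= lhalf && ly[j] > lhalf) {
        right <- lf[j] + (lhalf - ly[j]) * (lf[j + 1] - lf[j]) /
          (ly[j + 1] - ly[j])
        break
      }
    }
    if (is.finite(left) && is.finite(right)) fwhm <- right - left
  }
  structure(list(f_max = unname(f_max), eps2_max = unname(eps2_max),
                 fwhm_decades = unname(fwhm), reliable = reliable),
            class = "peak_stats")
}
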