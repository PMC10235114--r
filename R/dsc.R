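#' DSC trace container
#'
#' @param T temperature grid, K, strictly increasing.
#' @param heat_flow signal versus T: heat flow (W/g) or apparent heat capacity
#'   (J/(g K)).
#' @param heating_rate heating rate, K/min (> 0).
#' @return An object of class `dsc_trace`.
#' @export
dsc_trace <- function(T, heat_flow, heating_rate = 10) {
  if (length(T) != length(heat_flow)) stop("T and heat_flow lengths differ")
  if (is.unsorted(T, strictly = TRUE)) stop("T must be strictly increasing")
  if (!is.finite(heating_rate) || heating_rate <= 0)
    stop("heating_rate must be > 0")
  structure(list(T = T, heat_flow = heat_flow, heating_rate = heating_rate),
            class = "dsc_trace")
}

#' @export
print.dsc_trace <- function(x, ...) {
  cat(sprintf("<dsc_trace> %d points, T = %.1f..%.1f K, rate %.1f K/min\n",
              length(x$T), min(x$T), max(x$T), x$heating_rate))
  invisible(x)
}

#' Melting point from a DSC endotherm
#'
#' The melting temperature is taken as the maximum of the endothermic peak:
#' local maxima of the baseline-detrended signal inside the window are
#' located, the largest is refined by parabolic interpolation, and any
#' additional peaks are reported.
#'
#' @param trace a [dsc_trace()].
#' @param window temperature window c(lo, hi), K, expected to bracket the
#'   endotherm.
#' @return A list of class `melting_peak`: `Tm` (K, NA when flagged),
#'   `height` (detrended peak amplitude), `all_peaks` (data.frame of every
#'   detected peak), `flagged` (TRUE when no interior extremum exists).
#' @export
melting_peak <- function(trace, window) {
  stopifnot(inherits(trace, "dsc_trace"), length(window) == 2)
  sel <- trace$T >= window[1] & trace$T <= window[2]
  if (sum(sel) < 5) stop("window contains too few points")
  T <- trace$T[sel]; y <- trace$heat_flow[sel]
  # straight baseline through the window endpoints; peaks measured above it
  base <- y[1] + (y[length(y)] - y[1]) * (T - T[1]) / (T[length(T)] - T[1])
  d <- y - base
  idx <- which(diff(sign(diff(d))) == -2) + 1L
  idx <- idx[d[idx] > 0.05 * max(d)]
  # a window holding no endotherm leaves only numerical dust above baseline
  if (max(d) <= 1e-9 * max(abs(y))) idx <- integer(0)
  if (length(idx) == 0)
    return(structure(list(Tm = NA_real_, height = NA_real_,
                          all_peaks = NULL, flagged = TRUE),
                     class = "melting_peak"))
  refine <- function(i) {
    if (i == 1 || i == length(T)) return(c(T[i], d[i]))
    x <- T[(i - 1):(i + 1)] - T[i]
    cf <- stats::lm.fit(cbind(1, x, x^2), d[(i - 1):(i + 1)])$coefficients
    if (!is.finite(cf[3]) || cf[3] >= 0) return(c(T[i], d[i]))
    c(T[i] - cf[2] / (2 * cf[3]), cf[1] - cf[2]^2 / (4 * cf[3]))
  }
  pk <- t(vapply(idx, refine, numeric(2)))
  all_peaks <- data.frame(Tm = pk[, 1], height = pk[, 2])
  all_peaks <- all_peaks[order(-all_peaks$height), , drop = FALSE]
  structure(list(Tm = all_peaks$Tm[1], height = all_peaks$height[1],
                 all_peaks = all_peaks, flagged = FALSE),
            class = "melting_peak")
}

#' @export
print.melting_peak <- function(x, ...) {
  if (x$flagged) cat("<melting_peak> no peak found\n")
  else cat(sprintf("<melting_peak> Tm = %.2f K (height %.3g, %d peak(s))\n",
                   x$Tm, x$height, nrow(x$all_peaks)))
  invisible(x)
}

#' Glass-transition step from a DSC trace
#'
#' Fits a logistic step on a linear baseline,
#' \eqn{y(T) = a + bT + \Delta C_p/(1+e^{-(T-T_g)/w})}, inside the window.
#' The glass-transition temperature is the midpoint of the fitted heat
#' capacity increment and \eqn{\Delta C_p} its amplitude; defining the
#' midpoint on the fitted sigmoid rather than on raw half-height crossings
#' makes the reduction robust to noise and to sloped baselines.
#'
#' @param trace a [dsc_trace()] whose signal is an apparent heat capacity.
#' @param window temperature window c(lo, hi), K, bracketing the step.
#' @param min_snr minimal step amplitude in units of the fit residual
#'   standard deviation; below it the result is flagged and Tg set to NA.
#' @return A list of class `glass_step`: `Tg` (K), `dCp` (signal units),
#'   `width` (K), `flagged`, `residual_sd`.
#' @export
glass_step <- function(trace, window, min_snr = 5) {
  stopifnot(inherits(trace, "dsc_trace"), length(window) == 2)
  sel <- trace$T >= window[1] & trace$T <= window[2]
  if (sum(sel) < 10) stop("window contains too few points")
  T <- trace$T[sel]; y <- trace$heat_flow[sel]
  n <- length(T)
  k <- max(4L, n %/% 5)
  # baseline slope/intercept from the pre-step quarter of the window
  pre <- stats::coef(stats::lm(y[1:k] ~ T[1:k]))
  a0 <- unname(pre[1]); b0 <- unname(pre[2])
  if (!is.finite(b0)) { a0 <- y[1]; b0 <- 0 }
  d0 <- max(mean(y[(n - k + 1):n]) - (a0 + b0 * mean(T[(n - k + 1):n])), 1e-6)
  # midpoint start: steepest slope of a lightly smoothed signal
  ys <- as.numeric(stats::filter(y, rep(1 / 5, 5), sides = 2))
  dy <- diff(ys)
  dy[!is.finite(dy)] <- -Inf
  tg0 <- T[which.max(dy)]
  if (!is.finite(tg0)) tg0 <- mean(window)
  theta0 <- c(a = a0, b = b0, d = d0, Tg = tg0, lw = log(2))
  model <- function(th) th[1] + th[2] * T + th[3] * stats::plogis((T - th[4]) / exp(th[5]))
  fit <- minpack.lm::nls.lm(
    par = theta0, fn = function(th) model(th) - y,
    lower = c(-Inf, -Inf, 0, window[1], log(0.05)),
    upper = c(Inf, Inf, Inf, window[2], log(diff(window))),
    control = minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-13,
                                         ptol = 1e-13))
  th <- fit$par
  res_sd <- sqrt(mean(fit$fvec^2))
  flagged <- !(fit$info %in% 1:4) || th[3] < min_snr * res_sd
  structure(list(Tg = if (flagged) NA_real_ else unname(th[4]),
                 dCp = if (flagged) NA_real_ else unname(th[3]),
                 width = unname(exp(th[5])), flagged = flagged,
                 residual_sd = res_sd),
            class = "glass_step")
}

#' @export
print.glass_step <- function(x, ...) {
  if (x$flagged) cat("<glass_step> no reliable step found\n")
  else cat(sprintf("<glass_step> Tg = %.2f K, dCp = %.4g (width %.2f K)\n",
                   x$Tg, x$dCp, x$width))
  invisible(x)
}
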