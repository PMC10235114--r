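#' Dielectric loss spectrum at one state point
#'
#' Atomic data object of the pipeline: a loss spectrum \eqn{\varepsilon''(f)}
#' tagged with its thermodynamic state (temperature, pressure).
#'
#' @param T temperature, K (> 0).
#' @param p pressure, MPa (>= 0.1; 0.1 MPa is ambient).
#' @param f frequency grid, Hz, strictly increasing, within 1e-3..1e9.
#' @param eps2 dielectric loss values (> 0), same length as `f`.
#' @return An object of class `loss_spectrum`.
#' @export
loss_spectrum <- function(T, p, f, eps2) {
  if (!is.finite(T) || T <= 0) stop("T must be > 0 (kelvin)")
  if (!is.finite(p) || p < 0.1) stop("p must be >= 0.1 MPa")
  if (length(f) != length(eps2)) stop("f and eps2 lengths differ")
  if (any(!is.finite(f)) || any(f < 1e-3) || any(f > 1e9))
    stop("f outside the sanity window [1e-3, 1e9] Hz")
  if (is.unsorted(f, strictly = TRUE)) stop("f must be strictly increasing")
  if (any(!is.finite(eps2)) || any(eps2 <= 0)) stop("eps2 must be > 0")
  structure(list(T = T, p = p, f = f, eps2 = eps2), class = "loss_spectrum")
}

#' @export
print.loss_spectrum <- function(x, ...) {
  cat(sprintf("<loss_spectrum> T = %.1f K, p = %.1f MPa, %d points, f = %.3g..%.3g Hz\n",
              x$T, x$p, length(x$f), min(x$f), max(x$f)))
  invisible(x)
}

# deterministic restarts without disturbing the caller's RNG stream
.with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Interior local maxima of a loss spectrum (indices), found on median+mean
# smoothed log-loss with a topographic-prominence criterion so that
# grid-level noise does not spawn spurious peaks.
.find_peaks <- function(f, eps2, min_prominence = 0.05,
                        min_sep_decades = 0.4) {
  ly <- log10(eps2)
  n <- length(ly)
  ly_s <- ly
  if (n >= 9) {
    for (pass in 1:2) {
      k <- as.numeric(stats::filter(ly_s, rep(1 / 3, 3), sides = 2))
      k[is.na(k)] <- ly_s[is.na(k)]
      ly_s <- k
    }
  }
  idx <- which(diff(sign(diff(ly_s))) == -2) + 1L
  if (length(idx) == 0) return(integer(0))
  # topographic prominence: height above the higher of the two valley floors
  # reaching to the nearest higher ground (or the grid edge)
  prom <- vapply(idx, function(i) {
    hl <- which(ly_s[seq_len(i - 1)] > ly_s[i])
    left <- min(ly_s[(if (length(hl)) max(hl) else 1):i])
    hr <- which(ly_s[(i + 1):n] > ly_s[i]) + i
    right <- min(ly_s[i:(if (length(hr)) min(hr) else n)])
    ly_s[i] - max(left, right)
  }, numeric(1))
  idx <- idx[prom >= min_prominence]
  prom <- prom[prom >= min_prominence]
  if (length(idx) <= 1) return(idx)
  # greedy de-duplication: keep the most prominent peak of any cluster closer
  # than min_sep_decades in log f
  o <- order(-prom)
  kept <- integer(0)
  for (i in idx[o]) {
    if (all(abs(log10(f[i]) - log10(f[kept])) >= min_sep_decades))
      kept <- c(kept, i)
  }
  sort(kept)
}

# parameter vector <-> model helpers for the HN deconvolution; with
# symmetric = TRUE the asymmetry exponent is pinned to 1 (Cole-Cole), the
# conventional description of secondary relaxations
.unpack_theta <- function(theta, n_proc, fit_dc, symmetric = FALSE) {
  sigma <- if (fit_dc) 10^theta[1] else 0
  off <- if (fit_dc) 1L else 0L
  npar <- if (symmetric) 3L else 4L
  procs <- vector("list", n_proc)
  for (k in seq_len(n_proc)) {
    i <- off + (k - 1) * npar
    procs[[k]] <- hn_params(delta_eps = 10^theta[i + 1],
                            tau_hn = 10^theta[i + 2],
                            alpha = theta[i + 3],
                            gamma = if (symmetric) 1 else theta[i + 4])
  }
  process_set(sigma_dc = sigma, processes = procs)
}

#' Deconvolve a loss spectrum into conductivity plus HN processes
#'
#' Least-squares fit of [model_loss()] to a measured or synthetic spectrum in
#' log10-loss space (so that the conductivity flank and the peaks are weighted
#' evenly across decades). Initial relaxation times are seeded from detected
#' peaks; a fixed-seed set of jittered multi-starts guards against local
#' minima, and the best residual wins.
#'
#' @param spec a [loss_spectrum()].
#' @param n_processes number of HN processes to fit (1..3).
#' @param fit_dc logical, include a dc-conductivity term.
#' @param labels optional character labels for the processes after sorting by
#'   decreasing tau_max; default `c("alpha","beta","gamma")` truncated, i.e.
#'   processes named by slowness.
#' @param guesses optional list with elements `log10_tau` (vector of peak-time
#'   guesses, log10 s), `log10_sigma`, `alpha`, `gamma` overriding the
#'   automatic seeding.
#' @param symmetric logical; fix every asymmetry exponent at gamma = 1
#'   (Cole-Cole lineshapes), the conventional constraint when deconvolving
#'   secondary relaxations whose peaks are symmetric on the log-frequency
#'   axis.
#' @param restarts number of jittered restarts (>= 1).
#' @param seed integer seed for the restart jitter (restored afterwards).
#' @return An object of class `process_fit`: state, `sigma_dc` (S/cm),
#'   `processes` (data.frame with label, delta_eps, tau_hn, alpha, gamma,
#'   tau_max), `residual` (RMS of the log10 misfit), `converged`, and `flags`
#'   (may contain "unresolved" when two fitted peak times are closer than a
#'   decade, or "ill_posed" when more processes were requested than peaks are
#'   visible).
#' @export
fit_spectrum <- function(spec, n_processes = 1, fit_dc = TRUE, labels = NULL,
                         guesses = NULL, symmetric = FALSE, restarts = 8,
                         seed = 1734) {
  stopifnot(inherits(spec, "loss_spectrum"))
  if (!n_processes %in% 1:3) stop("n_processes must be 1, 2 or 3")
  if (log10(max(spec$f) / min(spec$f)) < 3)
    stop("spectrum must cover at least 3 decades of frequency")
  f <- spec$f; y <- spec$eps2
  ly <- log10(y)
  flags <- character(0)

  peaks <- .find_peaks(f, y)
  if (length(peaks) > 0 && length(peaks) < n_processes)
    flags <- c(flags, "ill_posed")

  # --- automatic seeding -------------------------------------------------
  tau_guess <- if (!is.null(guesses$log10_tau)) {
    10^guesses$log10_tau
  } else if (length(peaks) > 0) {
    tg <- 1 / (2 * pi * f[peaks])
    tg <- sort(tg, decreasing = TRUE)
    if (length(tg) >= n_processes) tg[seq_len(n_processes)]
    else c(tg, 1 / (2 * pi * 10^(log10(max(f)) -
                                   seq_len(n_processes - length(tg)))))
  } else {
    # no interior peak: spread guesses over the window
    10^(seq(log10(1 / (2 * pi * min(f))) - 0.5,
            log10(1 / (2 * pi * max(f))) + 0.5,
            length.out = n_processes + 2)[2:(n_processes + 1)])
  }
  tau_guess <- sort(tau_guess, decreasing = TRUE)[seq_len(n_processes)]
  deps_guess <- vapply(tau_guess, function(tg) {
    fm <- 1 / (2 * pi * tg)
    2.5 * y[which.min(abs(log10(f) - log10(fm)))]
  }, numeric(1))
  a0 <- if (!is.null(guesses$alpha)) rep_len(guesses$alpha, n_processes)
        else rep(0.8, n_processes)
  g0 <- if (!is.null(guesses$gamma)) rep_len(guesses$gamma, n_processes)
        else rep(0.6, n_processes)
  sig0 <- if (!is.null(guesses$log10_sigma)) guesses$log10_sigma
          else log10(max(y[1] * 2 * pi * f[1] * bds_constants$eps0 / 100,
                         1e-19))

  theta0 <- c(if (fit_dc) sig0,
              if (symmetric)
                as.vector(rbind(log10(deps_guess), log10(tau_guess), a0))
              else
                as.vector(rbind(log10(deps_guess), log10(tau_guess), a0, g0)))
  lt_lo <- log10(1 / (2 * pi * max(f))) - 4
  lt_hi <- log10(1 / (2 * pi * min(f))) + 4
  per_lo <- if (symmetric) c(-5, lt_lo, 0.15) else c(-5, lt_lo, 0.15, 0.05)
  per_hi <- if (symmetric) c(4, lt_hi, 1) else c(4, lt_hi, 1, 1)
  lower <- c(if (fit_dc) -20, rep(per_lo, n_processes))
  upper <- c(if (fit_dc) -1, rep(per_hi, n_processes))

  resid_fn <- function(theta) {
    m <- model_loss(f, .unpack_theta(theta, n_processes, fit_dc, symmetric))
    log10(pmax(m, 1e-300)) - ly
  }

  run_one <- function(th) {
    th <- pmin(pmax(th, lower), upper)
    fit <- try(minpack.lm::nls.lm(
      par = th, lower = lower, upper = upper, fn = resid_fn,
      control = minpack.lm::nls.lm.control(
        maxiter = 400, ftol = 1e-15, ptol = 1e-15)), silent = TRUE)
    if (inherits(fit, "try-error")) return(NULL)
    fit
  }

  # fixed shape-space corners visited before random restarts: the narrow
  # curved valley in (alpha, gamma) needs starts on both sides of it, each
  # made self-consistent (tau_HN and delta_eps converted with its own shape)
  corners <- list(c(0.95, 0.95), c(0.95, 0.5), c(0.65, 0.95), c(0.65, 0.45))
  corner_theta <- function(shape) {
    a <- shape[1]; g <- if (symmetric) 1 else shape[2]
    th <- theta0
    idx <- if (fit_dc) 1L else 0L
    npar <- if (symmetric) 3L else 4L
    unit_pk <- hn_loss(1 / hn_peak_time(hn_params(1, 1, a, g)),
                       hn_params(1, 1, a, g))
    for (k in seq_len(n_processes)) {
      i <- idx + (k - 1) * npar
      y_pk <- deps_guess[k] / 2.5
      th[i + 1] <- log10(max(y_pk / unit_pk, 1e-4))
      th[i + 2] <- log10(hn_tau_from_peak(tau_guess[k], a, g))
      th[i + 3] <- a
      if (!symmetric) th[i + 4] <- g
    }
    th
  }
  # when no peak is detectable (buried under the conductivity flank), sweep
  # the window with a deterministic ladder of peak-time seeds; the start
  # nearest the true peak descends into its basin
  ladder <- list()
  if (length(peaks) == 0) {
    for (lt_seed in seq(log10(1 / (2 * pi * max(f))),
                        log10(1 / (2 * pi * min(f))), by = 1)) {
      th <- theta0
      idx0 <- if (fit_dc) 1L else 0L
      npar0 <- if (symmetric) 3L else 4L
      for (k in seq_len(n_processes)) {
        i <- idx0 + (k - 1) * npar0
        y_here <- y[which.min(abs(log10(f) - (-lt_seed - log10(2 * pi))))]
        th[i + 1] <- log10(max(2.5 * y_here, 1e-3))
        th[i + 2] <- lt_seed + (k - 1)  # stagger multiple processes
      }
      ladder <- c(ladder, list(th))
    }
  }
  fits <- .with_local_seed(seed, {
    out <- c(list(run_one(theta0)), lapply(ladder, run_one))
    for (r in seq_len(max(0, restarts - 1))) {
      jit <- theta0
      if (r <= length(corners)) {
        out <- c(out, list(run_one(corner_theta(corners[[r]]))))
        next
      }
      idx <- if (fit_dc) 1L else 0L
      npar <- if (symmetric) 3L else 4L
      if (fit_dc) jit[1] <- jit[1] + stats::rnorm(1, 0, 0.5)
      for (k in seq_len(n_processes)) {
        i <- idx + (k - 1) * npar
        jit[i + 1] <- jit[i + 1] + stats::rnorm(1, 0, 0.3)
        jit[i + 2] <- jit[i + 2] + stats::rnorm(1, 0, 0.4)
        # shape exponents resampled over their whole range: the least-squares
        # valley is narrow and strongly curved in (alpha, gamma), and local
        # jitter cannot cross between competing basins
        jit[i + 3] <- stats::runif(1, 0.3, 1)
        if (!symmetric) jit[i + 4] <- stats::runif(1, 0.2, 1)
      }
      out <- c(out, list(run_one(jit)))
    }
    out
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) stop("all restarts of the HN fit failed")
  rss <- vapply(fits, function(fit) sum(fit$fvec^2), numeric(1))
  # a relaxation time pinned at its box bound is a degenerate solution (a
  # power-law mimic of the conductivity flank, not a peak); prefer interior
  # solutions whenever any converged
  npar <- if (symmetric) 3L else 4L
  off <- if (fit_dc) 1L else 0L
  tau_slots <- off + (seq_len(n_processes) - 1L) * npar + 2L
  pinned <- vapply(fits, function(fit)
    any(fit$par[tau_slots] > lt_hi - 0.1 | fit$par[tau_slots] < lt_lo + 0.1),
    logical(1))
  best <- if (any(!pinned)) {
    fits[!pinned][[which.min(rss[!pinned])]]
  } else fits[[which.min(rss)]]
  residual <- sqrt(min(rss) / length(f))
  converged <- best$info %in% 1:4 && is.finite(residual)
  if (!converged) flags <- c(flags, "non_converged")

  ps <- .unpack_theta(best$par, n_processes, fit_dc, symmetric)
  tmax <- vapply(ps$processes, hn_peak_time, numeric(1))
  ord <- order(tmax, decreasing = TRUE)
  if (is.null(labels)) labels <- c("alpha", "beta", "gamma")[seq_len(n_processes)]
  procs <- do.call(rbind, lapply(seq_along(ord), function(j) {
    pr <- ps$processes[[ord[j]]]
    data.frame(label = labels[j], delta_eps = pr$delta_eps,
               tau_hn = pr$tau_hn, alpha = pr$alpha, gamma = pr$gamma,
               tau_max = tmax[ord[j]], stringsAsFactors = FALSE)
  }))
  if (n_processes > 1 &&
      any(procs$tau_max[-n_processes] / procs$tau_max[-1] < 10))
    flags <- c(flags, "unresolved")

  structure(list(state = c(T = spec$T, p = spec$p),
                 sigma_dc = ps$sigma_dc, processes = procs,
                 residual = residual, converged = converged, flags = flags),
            class = "process_fit")
}

#' @export
print.process_fit <- function(x, ...) {
  cat(sprintf("<process_fit> T = %.1f K, p = %.1f MPa, sigma_dc = %.3g S/cm, RMS(log10) = %.3g%s\n",
              x$state["T"], x$state["p"], x$sigma_dc, x$residual,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  print(x$processes, row.names = FALSE)
  invisible(x)
}

#' Subtract the dc-conductivity contribution from a spectrum
#'
#' Pointwise \eqn{\varepsilon'' - \sigma_{dc}/(\varepsilon_0\omega)}; residual
#' points that fall at or below zero are clipped to `floor` and counted.
#'
#' @param spec a [loss_spectrum()].
#' @param sigma_dc dc conductivity, S/cm (typically from a prior fit).
#' @param floor clipping floor for non-positive residual loss.
#' @return A [loss_spectrum()] with attribute `n_clipped`.
#' @export
subtract_dc <- function(spec, sigma_dc, floor = 1e-8) {
  stopifnot(inherits(spec, "loss_spectrum"))
  res <- spec$eps2 - dc_loss(2 * pi * spec$f, sigma_dc)
  n_clip <- sum(res <= floor)
  res <- pmax(res, floor)
  out <- loss_spectrum(spec$T, spec$p, spec$f, res)
  attr(out, "n_clipped") <- n_clip
  out
}

#' Normalise a spectrum to its loss maximum
#'
#' Rescales frequency by the interpolated peak frequency and the loss by the
#' interpolated peak height, the representation used for shape comparison of
#' alpha-peaks across state points.
#'
#' @param spec a dc-subtracted [loss_spectrum()] with an interior maximum.
#' @return An object of class `normalized_spectrum` with fields `x` (f/f_max),
#'   `y` (eps2/eps2_max), `T`, `p`, `f_max`, `eps2_max`.
#' @export
normalize_spectrum <- function(spec) {
  st <- peak_stats(spec)
  if (!st$reliable)
    warning("loss maximum at the grid edge; normalisation unreliable")
  structure(list(x = spec$f / st$f_max, y = spec$eps2 / st$eps2_max,
                 T = spec$T, p = spec$p,
                 f_max = st$f_max, eps2_max = st$eps2_max),
            class = "normalized_spectrum")
}

#' Fit the KWW shape to a normalised alpha-peak
#'
#' Fits the one-sided Fourier transform of the stretched exponential to a
#' normalised, dc-subtracted loss peak. The peak position and height of the
#' model are pinned to (1, 1) in reduced coordinates, so the stretching
#' exponent is the only free parameter; the characteristic time follows from
#' the reduced peak frequency of the fitted shape.
#'
#' @param nspec a [normalize_spectrum()] object.
#' @param y_min points with normalised loss below this are excluded: decades
#'   below the maximum the measured loss is dominated by secondary-process
#'   tails and dc-subtraction residuals rather than by the structural peak.
#' @return A list: `beta_kww`, `tau_alpha` (s; NA when the source peak
#'   frequency is unknown), `rms` of the log10 misfit, `converged`.
#' @export
fit_kww_shape <- function(nspec, y_min = 0.05) {
  stopifnot(inherits(nspec, "normalized_spectrum"))
  keep <- nspec$y > y_min & is.finite(nspec$y)
  x <- nspec$x[keep]; y <- nspec$y[keep]
  if (length(x) < 5) stop("too few points above y_min for a shape fit")
  ly <- log10(y)

  model_curve <- function(beta) {
    wp <- .kww_peak_omega(beta)
    # master curve sampled where the data live, then spline-interpolated
    lx_grid <- seq(min(log10(x)) - 0.05, max(log10(x)) + 0.05,
                   length.out = 45)
    lv <- log10(vapply(10^lx_grid * wp, .kww_loss_scalar, numeric(1),
                       beta = beta, rel.tol = 1e-8))
    pk <- log10(.kww_loss_scalar(wp, beta, rel.tol = 1e-8))
    fun <- stats::splinefun(lx_grid, lv - pk, method = "natural")
    fun(log10(x))
  }
  obj <- function(beta) sum((model_curve(beta) - ly)^2)
  opt <- stats::optimize(obj, interval = c(0.25, 1), tol = 1e-5)
  beta <- opt$minimum
  # boundary handling: Debye data drive the optimum to the upper bound
  if (obj(1) <= opt$objective) beta <- 1
  rms <- sqrt(min(obj(beta), opt$objective) / length(x))
  tau_alpha <- if (is.finite(nspec$f_max))
    .kww_peak_omega(beta) / (2 * pi * nspec$f_max) else NA_real_
  list(beta_kww = beta, tau_alpha = tau_alpha, rms = rms,
       converged = is.finite(beta) && is.finite(rms))
}

#' Temperature-pressure superpositioning diagnostic
#'
#' Compares normalised alpha-peaks recorded at different state points sharing
#' the same relaxation time (an isochronal set). Superpositioning (TPS) holds
#' when the peak shape is invariant: the spread of fitted KWW exponents stays
#' below a threshold and the pointwise deviation between curves is small.
#'
#' @param nspecs list of [normalize_spectrum()] objects (>= 2).
#' @param spread_threshold maximal allowed spread (max - min) of fitted
#'   beta_KWW for the "holds" verdict.
#' @return A list: `max_deviation` (max over spectrum pairs of the max
#'   pointwise |y_i - y_j| on the common reduced-frequency support),
#'   `beta_kww` (per-spectrum fits), `beta_spread`, `holds`.
#' @export
tps_residual <- function(nspecs, spread_threshold = 0.02) {
  if (!is.list(nspecs) || length(nspecs) < 2)
    stop("need at least two normalised spectra")
  stopifnot(all(vapply(nspecs, inherits, logical(1), "normalized_spectrum")))
  lo <- max(vapply(nspecs, function(s) min(s$x), numeric(1)))
  hi <- min(vapply(nspecs, function(s) max(s$x), numeric(1)))
  if (!(hi > lo)) stop("normalised spectra have no common x support")
  full_lo <- min(vapply(nspecs, function(s) min(s$x), numeric(1)))
  full_hi <- max(vapply(nspecs, function(s) max(s$x), numeric(1)))
  if (lo / full_lo > 1.0001 || full_hi / hi > 1.0001)
    warning("comparison restricted to the common reduced-frequency support")
  lx <- seq(log10(lo), log10(hi), length.out = 201)
  ys <- vapply(nspecs, function(s) {
    stats::splinefun(log10(s$x), log10(s$y), method = "natural")(lx)
  }, numeric(length(lx)))
  ylin <- 10^ys
  max_dev <- 0
  for (i in seq_len(ncol(ylin) - 1))
    for (j in seq((i + 1), ncol(ylin)))
      max_dev <- max(max_dev, max(abs(ylin[, i] - ylin[, j])))
  betas <- vapply(nspecs, function(s) fit_kww_shape(s)$beta_kww, numeric(1))
  spread <- max(betas) - min(betas)
  list(max_deviation = max_dev, beta_kww = betas, beta_spread = spread,
       holds = spread <= spread_threshold)
}
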