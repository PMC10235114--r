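# Independent oracles used across the suite. They share no code with the
# package internals they check.

# Brute-force quadrature for the one-sided Fourier transform of the KWW
# relaxation: substituting v = (t/tau)^beta gives
#   eps''(wt) = Int_0^Inf exp(-v) sin(wt v^(1/beta)) dv,
# evaluated by composite Simpson on a dense grid (valid up to moderate wt,
# where the integrand oscillates slowly enough for the grid).
kww_oracle_simpson <- function(wt, beta, V = 60, n = 2^21) {
  v <- seq(0, V, length.out = n + 1)
  h <- V / n
  fv <- exp(-v) * sin(wt * v^(1 / beta))
  h / 3 * sum(fv * c(1, rep(c(4, 2), length.out = n - 1), 1))
}

# Convergent high-frequency series of the same transform (beta < 1):
#   eps''(wt) = sum_n (-1)^(n+1) Gamma(n beta + 1)/n! sin(n pi beta/2) wt^(-n beta)
kww_oracle_series <- function(wt, beta, N = 400) {
  n <- seq_len(N)
  sum((-1)^(n + 1) * exp(lgamma(n * beta + 1) - lgamma(n + 1)) *
        sin(n * pi * beta / 2) * wt^(-n * beta))
}

kww_oracle <- function(wt, beta) {
  if (beta == 1) return(wt / (1 + wt^2))
  if (wt <= 10) kww_oracle_simpson(wt, beta) else kww_oracle_series(wt, beta)
}

# Numerical argmax of the HN loss over log reduced frequency (golden-section
# refinement of a coarse grid scan), independent of the analytic peak formula.
hn_argmax_oracle <- function(params) {
  lw <- seq(-6, 6, by = 0.05) - log10(params$tau_hn)
  i <- which.max(hn_loss(10^lw, params))
  opt <- stats::optimize(function(x) -hn_loss(10^x, params),
                         interval = c(lw[max(1, i - 1)], lw[min(length(lw), i + 1)]),
                         tol = 1e-10)
  1 / 10^opt$minimum
}

# Default frequency grid of the study window
test_fgrid <- function() 10^seq(-1, 6, by = 0.1)

# Normalised, dc-cleaned alpha peak of one state point of a scenario,
# following the shape-analysis protocol (mask dc-dominated frequencies,
# subtract the fitted conductivity, normalise to the maximum).
make_normalized_alpha <- function(T, p, config, seed, shape = NULL) {
  cfg <- config
  if (!is.null(shape)) cfg$alpha_shape <- shape
  ps <- bdsfit:::.state_process_set(T, p, cfg, TRUE)
  f <- cfg$grids$f
  y <- model_loss(f, ps)
  if (cfg$noise$sd_decades > 0) {
    y <- bdsfit:::.with_local_seed(seed,
      y * 10^stats::rnorm(length(y), 0, cfg$noise$sd_decades))
  }
  sp <- loss_spectrum(T, p, f, y)
  ft <- fit_spectrum(sp, n_processes = 1, fit_dc = TRUE, labels = "alpha")
  keep <- dc_loss(2 * pi * sp$f, ft$sigma_dc) < 0.5 * sp$eps2
  sub <- loss_spectrum(sp$T, sp$p, sp$f[keep], sp$eps2[keep])
  normalize_spectrum(subtract_dc(sub, ft$sigma_dc))
}
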