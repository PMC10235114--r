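#!/usr/bin/env Rscript
# Generate the synthetic high-pressure dielectric study: loss spectra on the
# supercooled and glassy measurement grids, the ground-truth relaxation map,
# and a DSC trace. Everything downstream reads results/.

library(bdsfit)

cfg <- default_scenario()
out <- run_pipeline(cfg, out_dir = "results", stages = "simulate")
truth <- make_relaxation_truth(cfg)
write_relaxation_map(truth$map, "results/truth_map.csv")
utils::write.csv(truth$tg_curve, "results/truth_tg_curve.csv", row.names = FALSE)
write_dsc(make_dsc(cfg), "results/dsc_trace.csv")

regimes <- table(vapply(out$spectra, function(s) attr(s, "regime"), character(1)))
cat(sprintf(
  "Simulated %d loss spectra (%d supercooled, %d glassy) on f = %.2g..%.2g Hz\n",
  length(out$spectra), regimes[["supercooled"]], regimes[["glassy"]],
  min(cfg$grids$f), max(cfg$grids$f)))
cat(sprintf("Ground truth: Tg0 = %.1f K, dTg/dp = %.1f K/GPa, E_beta(0.1 MPa) = %.0f kJ/mol,\n",
            cfg$avramov$Tg0, dtg_dp(cfg$avramov), cfg$beta_process$E_at_p0))
cat(sprintf("E_gamma = %.0f kJ/mol, FDSE s = %.2f, noise = %.3f decades, seed = %d\n",
            cfg$gamma_process$E, cfg$fdse$s_exponent,
            cfg$noise$sd_decades, cfg$noise$seed))
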