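#!/usr/bin/env Rscript
# Conductivity-relaxation coupling: fractional Debye-Stokes-Einstein exponent
# per isobar and isotherm from the fitted (sigma_dc, tau_alpha) pairs.

library(bdsfit)

out <- run_pipeline(default_scenario(), out_dir = "results",
                    stages = c("simulate", "fit-spectra", "map", "fdse"))
tab <- out$fdse$table
print(tab, row.names = FALSE)
cat(sprintf("\ns ranges over [%.2f, %.2f] (spread %.3f): clear decoupling (s < 1),\n",
            min(tab$s), max(tab$s), out$fdse$s_spread))
cat("essentially invariant across the examined isobars and isotherms.\n")
cat("Table written to results/fdse.csv\n")
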