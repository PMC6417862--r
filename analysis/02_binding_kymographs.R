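#!/usr/bin/env Rscript
# Initial ADF/Cofilin binding: kymograph material paths and the C0*A
# correlation.
#
# Generates bound-cofilin kymographs with and without local depletion of the
# free pool, measures initial binding slopes along material paths starting at
# different times, and reproduces the moderate correlation between the
# initial slope and the product C0*A on a calibrated synthetic table.

suppressPackageStartupMessages(library(actintread))
outdir <- "results/02_binding"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

starts <- c(300, 600, 900, 1200)

kymD <- gen_kymograph(cofilin_kinetics(), network_geometry(),
                      actin_profile(50), t_end = 2400, noise_sd = 0,
                      depletion = TRUE, domain = c(160, 160), h = 2)
slD <- estimate_initial_slopes(kymD, starts, window = 240, normalize = TRUE)
kymN <- gen_kymograph(cofilin_kinetics(), network_geometry(),
                      actin_profile(50), t_end = 2400, noise_sd = 0,
                      depletion = FALSE)
slN <- estimate_initial_slopes(kymN, starts, window = 240, normalize = TRUE)
slopes <- rbind(cbind(model = "depletion", slD),
                cbind(model = "no_depletion", slN))
write.csv(slopes, file.path(outdir, "initial_slopes.csv"), row.names = FALSE)
cat("Normalized initial slopes vs start time:\n")
cat("  with depletion   :", sprintf("%.3f", slD$slope), "(decreasing)\n")
cat("  without depletion:", sprintf("%.3f", slN$slope), "(flat)\n")

tab <- gen_binding_table(n = 60, seed = 1)
write.csv(tab, file.path(outdir, "binding_table.csv"), row.names = FALSE)
write_provenance(tab, file.path(outdir, "binding_table_provenance.json"))
ct <- correlate_binding_rate(tab)
cat(sprintf("Pearson correlation of slope with C0*A: R = %.2f (p = %.2g, n = %d)\n",
            ct$R, ct$p, ct$n))
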