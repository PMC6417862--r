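#!/usr/bin/env Rscript
# Exponent recovery on synthetic equilibrium-length tables.
#
# Generates length records obeying L = c*V*A0^2/CB with 10% lognormal noise,
# fits the exponents freely, evaluates the fixed-exponent R^2 over the
# (alpha, beta) grid, and runs the negative-control permutation.

suppressPackageStartupMessages(library(actintread))
outdir <- "results/06_inference"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

tab <- gen_length_table(n = 50, alpha = 2, beta = 1, noise_sd = 0.1, seed = 1)
write.csv(tab, file.path(outdir, "length_table.csv"), row.names = FALSE)
write_provenance(tab, file.path(outdir, "length_table_provenance.json"))

fit <- fit_exponents(tab)
cat(sprintf("Free fit: alpha = %.2f [%.2f, %.2f], beta = %.2f [%.2f, %.2f], R2 = %.3f\n",
            fit$alpha_hat, fit$alpha_ci[1], fit$alpha_ci[2],
            fit$beta_hat, fit$beta_ci[1], fit$beta_ci[2], fit$R2))

surf <- exponent_r2_surface(tab)
write.csv(cbind(alpha = seq(1, 3, by = 0.25), as.data.frame(surf)),
          file.path(outdir, "r2_surface.csv"), row.names = FALSE)
cat(sprintf("Fixed-exponent R2 at (2, 1): %.3f; minimum over the grid alpha in [1,3], beta in [0.5,1.2]: %.3f\n",
            fit_exponents(tab, fixed = c(2, 1))$R2, min(surf)))

set.seed(2)
shuf <- tab; shuf$CB <- sample(shuf$CB)
cat(sprintf("Negative control (CB shuffled): fixed-exponent R2 = %.2f\n",
            fit_exponents(shuf, fixed = c(2, 1))$R2))

hits <- sapply(1:100, function(s) {
  f <- fit_exponents(gen_length_table(n = 50, noise_sd = 0.1, seed = 1000 + s))
  c(f$alpha_hat, f$beta_hat)
})
cat(sprintf("Over 100 seeds: alpha in [1.7, 2.3] %.0f%% of the time, beta in [0.8, 1.2] %.0f%%\n",
            100 * mean(hits[1, ] >= 1.7 & hits[1, ] <= 2.3),
            100 * mean(hits[2, ] >= 0.8 & hits[2, ] <= 1.2)))
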