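#!/usr/bin/env Rscript
# Equilibrium network length from the two-feedback model and its phase maps.
#
# Solves the coupled disassembly/binding-depletion system, writes the two
# feedback curves, the (C0, A0) and (W, A0) phase maps of the equilibrium
# length, and demonstrates the compensation workflow (recovering a target
# length after a density drop by lowering C0 or widening the network).

suppressPackageStartupMessages(library(actintread))
outdir <- "results/04_equilibrium"

run_scenario(list(scenario = "feedback_curves", seed = 1,
                  outdir = file.path(outdir, "curves")))
run_scenario(list(scenario = "phase_map_C0_A0", seed = 1,
                  outdir = file.path(outdir, "map_C0_A0")))
run_scenario(list(scenario = "phase_map_W_A0", seed = 1,
                  outdir = file.path(outdir, "map_W_A0")))

s <- solve_equilibrium(50, per_min(1.16), 0.25, 30)
cat(sprintf("Reference solution (A0 = 50 uM, C0 = 250 nM, W = 30 um): L* = %.1f um, CB* = %.2f uM, depletion factor %.3f\n",
            s$L_star, s$CB_star, s$depletion_factor))
cat(sprintf("Depletion number at the solution: %.0f (strong depletion)\n",
            depletion_number(cofilin_kinetics()$rB, 50, 30, s$L_star, 10)))

# compensation: a density drop from 50 to 40 uM shortens the network; find
# the C0 or W restoring the original length
target <- s$L_star
C0c <- compensate_length(target, A0 = 40, V = per_min(1.16), W = 30,
                         solve_for = "C0")
Wc <- compensate_length(target, A0 = 40, V = per_min(1.16), C0 = 0.25,
                        solve_for = "W")
cat(sprintf("After a density drop to 40 uM, L* = %.1f um; restoring %.1f um needs C0 = %.0f nM or W = %.0f um\n",
            solve_equilibrium(40, per_min(1.16), 0.25, 30)$L_star,
            target, 1000 * C0c, Wc))
write.csv(data.frame(target_L = target, C0_compensating = C0c,
                     W_compensating = Wc),
          file.path(outdir, "compensation.csv"), row.names = FALSE)
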