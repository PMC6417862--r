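# Shared fixtures: the figure-caption parameter set and small, fast model runs.

fig3_kinetics <- function() {
  cofilin_kinetics(C0 = 0.125, D = 10, rB = per_min(0.5), rU = per_min(0.31))
}

fig3_geometry <- function(W = 30) network_geometry(W = W, V = per_min(1.16))

# a quick, small-domain chamber run for qualitative checks
small_chamber <- function(t_end = 1200, W = 30, A = 50, rB = per_min(0.5),
                          domain = c(120, 120), h = 2, dt = 2,
                          output_times = NULL, ...) {
  kin <- cofilin_kinetics(C0 = 0.125, D = 10, rB = rB, rU = per_min(0.31))
  simulate_chamber(kin, network_geometry(W = W, V = per_min(1.16)),
                   actin_profile(A), t_end = t_end, domain = domain, h = h,
                   dt = dt, output_times = output_times, ...)
}

# a static (non-growing) network: tiny V with a large elapsed time gives a
# fixed initial length while keeping advection negligible
static_geometry <- function(W, L0) network_geometry(W = W, V = 1e-9, t = L0 / 1e-9)

# internal lattice helpers exercised directly in the fragmentation tests
reachable_from_edge <- actintread:::reachable_from_edge
component_sizes <- actintread:::component_sizes
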