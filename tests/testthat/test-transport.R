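test_that("simple constant-rate model: closed forms and scaling", {
  kin <- fig3_kinetics()
  geo <- network_geometry(W = 30, V = per_min(1.16), t = 40 * 60)
  act <- actin_profile(50)

  # fresh actin at the leading edge carries no cofilin
  expect_identical(simple_bound_profile(kin, act, geo, 0), 0)
  # direct evaluation with the figure-caption parameters at y = V * 1 min
  expect_equal(simple_bound_profile(kin, act, geo, 1.16), 3.125)
  # linear and homogeneous in C0
  kin2 <- cofilin_kinetics(C0 = 0.25, D = 10, rB = per_min(0.5),
                           rU = per_min(0.31))
  expect_equal(simple_bound_profile(kin2, act, geo, 10),
               2 * simple_bound_profile(kin, act, geo, 10))
  expect_error(simple_bound_profile(kin, act, network_geometry(30, 0, 10), 1),
               "positive")
  expect_error(simple_bound_profile(kin, act, geo, geo$L + 5), "within")

  # L* = gamma*V/(kB*C0): direct value and inverse scaling with C0
  th <- threshold_model(1)
  geo1 <- network_geometry(W = 30, V = 1)
  kin1 <- cofilin_kinetics(C0 = 1, D = 10, rB = 0.1, rU = 0)
  expect_equal(simple_equilibrium_length(th, kin1, geo1), 10)
  kin_half <- cofilin_kinetics(C0 = 0.5, D = 10, rB = 0.1, rU = 0)
  expect_equal(simple_equilibrium_length(th, kin_half, geo1),
               2 * simple_equilibrium_length(th, kin1, geo1))
  expect_warning(
    expect_identical(
      simple_equilibrium_length(th, cofilin_kinetics(C0 = 0, rB = 0.1), geo1),
      Inf),
    "no finite")

  # independent oracle: invert CB(y)/A = gamma with a root finder
  th2 <- threshold_model(0.05)
  geo2 <- network_geometry(W = 30, V = per_min(1.16), t = 3600 * 10)
  root <- uniroot(function(y)
    simple_bound_profile(kin, act, geo2, y) - th2$gamma * act$A0,
    c(1e-6, geo2$L), tol = 1e-12)$root
  expect_equal(simple_equilibrium_length(th2, kin, geo2), root,
               tolerance = 1e-9)
})

test_that("quasi-steady depletion estimates behave as flux balance demands", {
  kin <- cofilin_kinetics(C0 = 0.125, D = 10, rB = 0.00833, rU = per_min(0.31))
  # no network, no depletion
  expect_equal(quasi_steady_estimate(kin, network_geometry(30, 1, 0), 50)$CF,
               kin$C0)
  # fast diffusion restores the bulk concentration
  kinD <- cofilin_kinetics(C0 = 0.125, D = 1e9, rB = 0.00833)
  geo <- network_geometry(W = 30, V = 1, t = 10)
  expect_equal(quasi_steady_estimate(kinD, geo, 50)$CF, kin$C0,
               tolerance = 1e-6)
  # direct evaluation: CF/C0 = 10/135 at W=30, L=10, A=50
  est <- quasi_steady_estimate(kin, geo, 50, CB = 0)
  expect_equal(est$CF / kin$C0, 10 / 135, tolerance = 1e-3)
  # both estimates decrease as the network lengthens
  ls <- c(5, 10, 20, 40)
  cf <- sapply(ls, function(L)
    quasi_steady_estimate(kin, network_geometry(30, 1, L), 50)$CF)
  bd <- sapply(ls, function(L)
    quasi_steady_estimate(kin, network_geometry(30, 1, L), 50)$binding_rate)
  expect_true(all(diff(cf) < 0) && all(diff(bd) < 0))
})

test_that("zero-reaction chamber stays uniform; closed domain conserves cofilin", {
  kin0 <- cofilin_kinetics(C0 = 0.125, D = 10, rB = 0, rU = 0)
  sim <- simulate_chamber(kin0, fig3_geometry(), actin_profile(50),
                          t_end = 600, domain = c(120, 120), h = 2, dt = 2,
                          output_times = c(300, 600))
  for (s in sim$snapshots) {
    expect_equal(max(abs(s$CF - kin0$C0)), 0, tolerance = 1e-12)
    expect_identical(max(s$CB), 0)
  }

  simc <- small_chamber(t_end = 1200, domain = c(120, 120), boundary = "closed",
                        output_times = seq(120, 1200, by = 120))
  tot <- total_cofilin(simc)
  expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-6)
  # nonnegativity everywhere
  expect_true(all(vapply(simc$snapshots,
                         function(s) min(s$CF) >= 0 && min(s$CB) >= 0,
                         logical(1))))
})

test_that("well-mixed closed chamber relaxes to two-state detailed balance", {
  kin <- cofilin_kinetics(C0 = 0.125, D = 500, rB = per_min(0.5),
                          rU = per_min(0.31))
  sim <- simulate_chamber(kin, static_geometry(W = 20, L0 = 10),
                          actin_profile(50), t_end = 2000,
                          domain = c(20, 20), h = 1, dt = 1,
                          boundary = "closed", leading_edge = 5)
  last <- sim$snapshots[[length(sim$snapshots)]]
  ratio <- mean(last$CB[last$mask]) / mean(last$CF[last$mask])
  expect_equal(ratio, kin$rB * 50 / kin$rU, tolerance = 0.02)
})

test_that("pure diffusion spreads a point perturbation like a Gaussian", {
  kin0 <- cofilin_kinetics(C0 = 0, D = 5, rB = 0, rU = 0)
  n <- 100; h <- 2
  init <- matrix(0, n, n); init[n / 2, n / 2] <- 1
  sim <- simulate_chamber(kin0, network_geometry(W = 30, V = 0),
                          actin_profile(0), t_end = 50,
                          domain = c(200, 200), h = h, dt = 1,
                          boundary = "closed", leading_edge = 90,
                          init_CF = init)
  last <- sim$snapshots[[length(sim$snapshots)]]
  xc <- sum(sweep(last$CF, 2, sim$x, "*")) / sum(last$CF)
  m2x <- sum(sweep(last$CF, 2, (sim$x - xc)^2, "*")) / sum(last$CF)
  # second moment grows exactly at 2*D*t per axis on the discrete Laplacian
  expect_equal(m2x, 2 * kin0$D * 50, tolerance = 1e-3)
  # profile matches the analytic Gaussian shape
  mid <- last$CF[, n / 2]
  g <- dnorm(sim$y, mean = sim$y[n / 2], sd = sqrt(2 * kin0$D * 50))
  expect_gt(cor(mid, g), 0.999)
})

test_that("leading-edge inflow is cofilin-free and depletion deepens in time", {
  sim <- small_chamber(t_end = 1800, output_times = seq(300, 1800, by = 300))
  last <- sim$snapshots[[length(sim$snapshots)]]
  ydist <- sim$y - sim$leading_edge
  row_up <- max(which(ydist < 0))          # fresh-side row, outside network
  row_dn <- which.min(abs(ydist - 2))      # ~2 um downstream
  cb_up <- mean(last$CB[row_up, sim$cols])
  cb_dn <- mean(last$CB[row_dn, sim$cols])
  expect_lt(cb_up, 0.01 * cb_dn)

  tc <- depletion_timecourse(sim)
  expect_true(all(diff(tc$CF_mean) < 0))
  expect_error(depletion_timecourse(sim, region = list(x = c(-50, -40),
                                                       y = c(0, 10))),
               "empty")
})

test_that("mean free cofilin decreases with width, density and binding rate", {
  region <- list(x = c(45, 75), y = c(30, 90))   # fixed observation window
  base <- small_chamber(t_end = 1200, W = 30, output_times = 1200)
  narrow <- small_chamber(t_end = 1200, W = 20, output_times = 1200)
  sparse <- small_chamber(t_end = 1200, A = 25, output_times = 1200)
  slow <- small_chamber(t_end = 1200, rB = per_min(0.25), output_times = 1200)
  m <- function(s) depletion_timecourse(s, region)$CF_mean
  expect_lt(m(base), m(narrow))
  expect_lt(m(base), m(sparse))
  expect_lt(m(base), m(slow))
})

test_that("steady-state PDE depletion is within a factor 2 of the quasi-steady estimate", {
  cases <- list(c(W = 20, L = 10, A = 30), c(W = 30, L = 20, A = 50),
                c(W = 20, L = 30, A = 80))
  for (cs in cases) {
    kin <- cofilin_kinetics(C0 = 0.125, D = 10, rB = per_min(0.5),
                            rU = per_min(0.31))
    sim <- simulate_chamber(kin, static_geometry(cs[["W"]], cs[["L"]]),
                            actin_profile(cs[["A"]]), t_end = 2400,
                            domain = c(160, 160), h = 2, dt = 2)
    last <- sim$snapshots[[length(sim$snapshots)]]
    cf_pde <- mean(last$CF[last$mask])
    cb_pde <- mean(last$CB[last$mask])
    est <- quasi_steady_estimate(kin,
                                 network_geometry(cs[["W"]], 1, cs[["L"]]),
                                 cs[["A"]], CB = cb_pde)
    expect_gt(cf_pde / est$CF, 0.5)
    expect_lt(cf_pde / est$CF, 2)
  }
})

test_that("a tabulated actin profile feeds through the solver", {
  prof <- gen_density_profiles(A0 = 50, L = 30, noise_sd = 0, n = 1)
  act <- as_actin_profile(prof)
  sim <- simulate_chamber(fig3_kinetics(), fig3_geometry(), act,
                          t_end = 2400, domain = c(150, 150), h = 2, dt = 2)
  last <- sim$snapshots[[length(sim$snapshots)]]
  ydist <- sim$y - sim$leading_edge
  cb_line <- rowMeans(last$CB[, sim$cols])
  # bound cofilin accumulates along the dense plateau ...
  on_plateau <- ydist > 2 & ydist < 25
  expect_gt(mean(diff(cb_line[on_plateau])), 0)
  # ... but stops accumulating past the trailing-edge density collapse
  beyond <- ydist > 32 & ydist < 44
  expect_lte(mean(diff(cb_line[beyond])), 1e-9)
})
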