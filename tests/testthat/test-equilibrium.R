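# inline bracketing oracle, independent of the closed form in the package
bracket_root <- function(A0, V, C0, W, kin, par) {
  f <- function(L) {
    fc <- feedback_curves(L, A0, V, C0, W, kin, par)
    fc$CB_disassembly - fc$CB_binding
  }
  hi <- 1
  while (f(hi) > 0) hi <- hi * 2
  uniroot(f, c(hi / 2, hi), tol = 1e-14)$root
}

test_that("closed-form equilibrium equals the numeric intersection", {
  set.seed(1)
  kin <- cofilin_kinetics(rB = 0.01, D = 10)
  par <- equilibrium_params()
  for (i in 1:100) {
    A0 <- runif(1, 10, 100); V <- runif(1, 0.005, 0.05)
    C0 <- runif(1, 0.05, 0.6); W <- runif(1, 5, 100)
    s <- solve_equilibrium(A0, V, C0, W, kin, par)
    expect_equal(s$L_star, bracket_root(A0, V, C0, W, kin, par),
                 tolerance = 1e-10)
    # both feedback relations hold at the solution
    fc <- feedback_curves(s$L_star, A0, V, C0, W, kin, par)
    expect_equal(fc$CB_disassembly, s$CB_star, tolerance = 1e-9)
    expect_equal(fc$CB_binding, s$CB_star, tolerance = 1e-9)
  }
})

test_that("feedback curves have the stated limits and a single crossing", {
  kin <- cofilin_kinetics(rB = 0.01, D = 10)
  par <- equilibrium_params()
  L <- exp(seq(log(0.01), log(5000), length.out = 400))
  fc <- feedback_curves(L, 50, 0.02, 0.25, 30, kin, par)
  expect_lt(fc$CB_disassembly[400], 1e-2)
  # binding curve vanishes proportionally as L -> 0
  expect_equal(fc$CB_binding[1],
               par$k2 * 0.01 * 50 * 0.25 * L[1] / 0.02, tolerance = 0.02)
  expect_true(all(diff(fc$CB_disassembly) < 0))
  expect_true(all(diff(fc$CB_binding) > 0))
  # exactly one sign change of the difference
  d <- sign(fc$CB_disassembly - fc$CB_binding)
  expect_equal(sum(diff(d) != 0), 1)
  # no-depletion reduction: D -> Inf gives the linear binding law
  kinD <- cofilin_kinetics(rB = 0.01, D = 1e12)
  fcD <- feedback_curves(L, 50, 0.02, 0.25, 30, kinD, par)
  expect_equal(fcD$CB_binding, par$k2 * 0.01 * 50 * 0.25 * L / 0.02,
               tolerance = 1e-6)
  # dimensional sanity: both curves in uM at a known point
  expect_equal(feedback_curves(10, 50, 0.02, 0.25, 30, kin, par)$CB_disassembly,
               1 * 50^2 * 0.02 / 10)
})

test_that("equilibrium length is monotone in concentration, density and width", {
  kin <- cofilin_kinetics(rB = 0.01, D = 10)
  Ls_C0 <- sapply(seq(0.05, 0.5, length.out = 8), function(C0)
    solve_equilibrium(50, 0.02, C0, 30, kin)$L_star)
  expect_true(all(diff(Ls_C0) < 0))
  Ls_A0 <- sapply(seq(20, 90, length.out = 8), function(A0)
    solve_equilibrium(A0, 0.02, 0.25, 30, kin)$L_star)
  expect_true(all(diff(Ls_A0) > 0))
  Ls_W <- sapply(seq(5, 90, length.out = 8), function(W)
    solve_equilibrium(50, 0.02, 0.25, W, kin)$L_star)
  expect_true(all(diff(Ls_W) > 0))
})

test_that("depletion number reproduces the published tail and cell estimates", {
  # actin tails: rB*A0 ~ 10/s, W = 1 um, L = 3 um, D = 10 -> 3
  expect_equal(depletion_number(10, 1, 1, 3, 10), 3)
  # keratocyte lamellipodium: W = L = 10 um -> 100
  expect_equal(depletion_number(10, 1, 10, 10, 10), 100)
  expect_equal(depletion_number(10, 1, 0, 3, 10), 0)
  expect_error(depletion_number(10, 1, 1, 3, 0), "positive")
})

test_that("strong-depletion limit: structure and asymptotic agreement", {
  kin <- cofilin_kinetics(rB = 0.01, D = 10)
  L1 <- suppressWarnings(depletion_limit_length(50, 0.02, 0.25, 30, kin))
  expect_equal(suppressWarnings(depletion_limit_length(50, 0.02, 0.25, 60, kin)),
               2 * L1)
  expect_equal(suppressWarnings(depletion_limit_length(100, 0.02, 0.25, 30, kin)),
               4 * L1)
  # deep-depletion regime: limit within 10% of the full solution
  s <- solve_equilibrium(100, 0.05, 0.4, 90, kin)
  expect_gt(depletion_number(0.01, 100, 90, s$L_star, 10), 50)
  lim <- depletion_limit_length(100, 0.05, 0.4, 90, kin)
  expect_lt(abs(lim - s$L_star) / s$L_star, 0.1)
  # negative control: wrong regime diverges from the full solution
  kin_fast <- cofilin_kinetics(rB = 1e-5, D = 1000)
  s2 <- solve_equilibrium(20, 0.02, 0.25, 5, kin_fast)
  expect_lt(depletion_number(1e-5, 20, 5, s2$L_star, 1000), 1)
  lim2 <- suppressWarnings(depletion_limit_length(20, 0.02, 0.25, 5, kin_fast))
  expect_gt(abs(lim2 - s2$L_star) / s2$L_star, 0.5)
})

test_that("no-depletion analytic limit of the full solver", {
  kin <- cofilin_kinetics(rB = 0.01, D = 1e12)
  par <- equilibrium_params()
  s <- solve_equilibrium(50, 0.02, 0.25, 30, kin, par)
  expect_equal(s$L_star,
               0.02 * sqrt(par$k1 * 50 / (par$k2 * 0.01 * 0.25)),
               tolerance = 1e-4)
  expect_equal(s$depletion_factor, 1, tolerance = 1e-4)
})

test_that("generalized exponents agree with the closed form at (2, 1)", {
  kin <- cofilin_kinetics(rB = 0.01, D = 10)
  s_closed <- solve_equilibrium(50, 0.02, 0.25, 30, kin, equilibrium_params())
  s_gen <- solve_equilibrium(50, 0.02, 0.25, 30, kin,
                             equilibrium_params(alpha = 2, beta = 1 + 1e-12))
  expect_equal(s_gen$L_star, s_closed$L_star, tolerance = 1e-8)
})

test_that("phase maps inherit monotonicity and support compensation", {
  m <- length_phase_map("C0_A0", seq(0.1, 0.5, length.out = 6),
                        seq(25, 80, length.out = 6))
  expect_true(all(apply(m, 2, diff) < 0))   # down each C0 column of rows
  expect_true(all(apply(m, 1, diff) > 0))   # up each A0 row
  m2 <- length_phase_map("W_A0", seq(10, 90, length.out = 6),
                         seq(25, 80, length.out = 6))
  expect_true(all(apply(m2, 2, diff) > 0))

  # compensation round trips through the solver
  kin <- cofilin_kinetics(rB = 0.01, D = 10)
  target <- solve_equilibrium(50, 0.02, 0.25, 30, kin)$L_star
  C0c <- compensate_length(target, A0 = 40, V = 0.02, W = 30,
                           solve_for = "C0", kinetics = kin)
  expect_equal(solve_equilibrium(40, 0.02, C0c, 30, kin)$L_star, target,
               tolerance = 1e-6)
  Wc <- compensate_length(target, A0 = 40, V = 0.02, C0 = 0.25,
                          solve_for = "W", kinetics = kin)
  expect_equal(solve_equilibrium(40, 0.02, 0.25, Wc, kin)$L_star, target,
               tolerance = 1e-6)
})

test_that("feedback solver is consistent with the continuum fragmentation law", {
  # with k1 mapped to c*ln(1/(1-q_c))/k_break the disassembly feedback at
  # fixed CB reproduces the mean-field length
  fp <- fragmentation_params(k_break = 2.5)
  cp <- continuum_params(q_c = 0.4, c = 1)
  k1_eq <- cp$c * log(1 / (1 - cp$q_c)) / fp$k_break
  CB <- 0.5; A0 <- 50; V <- 0.02
  L_feedback <- k1_eq * A0^2 * V / CB
  expect_equal(continuum_prediction(V, A0, CB, fp, cp)$L, L_feedback)
})
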