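## Equilibrium network length from two coupled feedbacks.
##
## Feedback 1 (disassembly): the treadmilling length shortens with bound
## cofilin, L = k1 * A0^2 * V / CB (generalized L = k1 * A0^alpha * V / CB^beta).
## Feedback 2 (binding with local depletion): bound cofilin accumulates with
## length, CB = k2 * rB * A0 * C0 * (L/V) * D / (rB * A0 * W * L + D); the
## second factor is the depletion factor in (0, 1]. The intersection of the
## two CB(L) curves is the equilibrium (L*, CB*); for alpha = 2, beta = 1 it
## is the positive root of a quadratic.

#' Feedback-model parameters
#'
#' @param k1 disassembly-magnitude parameter (s/uM); default 1
#' @param k2 dimensionless binding parameter; default 0.5
#' @param alpha actin-density exponent of the disassembly law (default 2)
#' @param beta bound-cofilin exponent (default 1)
#' @export
equilibrium_params <- function(k1 = 1, k2 = 0.5, alpha = 2, beta = 1) {
  if (k1 <= 0 || k2 <= 0) stop("k1 and k2 must be positive", call. = FALSE)
  stop_if_negative(alpha = alpha, beta = beta)
  structure(list(k1 = k1, k2 = k2, alpha = alpha, beta = beta),
            class = "equilibrium_params")
}

#' The two feedback curves CB(L)
#'
#' @param L vector of lengths (um), positive
#' @param A0 leading-edge actin density (uM)
#' @param V growth speed (um/s)
#' @param C0 solution ADF/Cofilin concentration (uM)
#' @param W network width (um)
#' @param kinetics [cofilin_kinetics()] supplying rB and D
#' @param params [equilibrium_params()]
#' @return data.frame with columns L, CB_disassembly (decreasing),
#'   CB_binding (increasing, saturating), depletion_factor
#' @export
feedback_curves <- function(L, A0, V, C0, W, kinetics = cofilin_kinetics(),
                            params = equilibrium_params()) {
  stopifnot(all(L > 0))
  rB <- kinetics$rB; D <- kinetics$D
  dis <- (params$k1 * A0^params$alpha * V / L)^(1 / params$beta)
  dep <- D / (rB * A0 * W * L + D)
  bind <- params$k2 * rB * A0 * C0 * (L / V) * dep
  data.frame(L = L, CB_disassembly = dis, CB_binding = bind,
             depletion_factor = dep)
}

#' Solve the coupled feedback system for the equilibrium length
#'
#' For alpha = 2, beta = 1 returns the unique positive root of
#' (k2*rB*A0*C0*D/V) L^2 - k1*A0^2*V*rB*A0*W L - k1*A0^2*V*D = 0 in closed
#' form; for other exponents a bracketing root search on the curve difference
#' is used.
#'
#' @inheritParams feedback_curves
#' @return list of class `equilibrium_solution`: `L_star` (um), `CB_star`
#'   (uM), `depletion_factor` in (0,1]
#' @export
solve_equilibrium <- function(A0, V, C0, W, kinetics = cofilin_kinetics(),
                              params = equilibrium_params()) {
  if (any(c(A0, V, C0, W) <= 0))
    stop("A0, V, C0 and W must all be positive", call. = FALSE)
  rB <- kinetics$rB; D <- kinetics$D
  k1 <- params$k1; k2 <- params$k2
  if (params$alpha == 2 && params$beta == 1) {
    qa <- k2 * rB * A0 * C0 * D / V
    qb <- -k1 * A0^2 * V * rB * A0 * W
    qc <- -k1 * A0^2 * V * D
    L_star <- (-qb + sqrt(qb^2 - 4 * qa * qc)) / (2 * qa)
  } else {
    diff_fun <- function(L) {
      fc <- feedback_curves(L, A0, V, C0, W, kinetics, params)
      fc$CB_disassembly - fc$CB_binding
    }
    hi <- 1
    while (diff_fun(hi) > 0) hi <- hi * 4
    L_star <- stats::uniroot(diff_fun, c(hi / 8, hi), tol = 1e-12)$root
  }
  dep <- D / (rB * A0 * W * L_star + D)
  CB_star <- k2 * rB * A0 * C0 * (L_star / V) * dep
  structure(list(L_star = L_star, CB_star = CB_star, depletion_factor = dep),
            class = "equilibrium_solution")
}

#' Dimensionless depletion number rB*A0*W*L/D
#'
#' Values well below 1 mean negligible local depletion of ADF/Cofilin;
#' values of 10-100 mean very significant depletion.
#'
#' @param rB binding rate constant (1/(s*uM)), or the product rB*A0 (1/s) if
#'   `A0 = 1`
#' @param A0 actin density (uM)
#' @param W,L network width and length (um)
#' @param D diffusion coefficient (um^2/s), > 0
#' @export
depletion_number <- function(rB, A0, W, L, D) {
  stop_if_negative(rB = rB, A0 = A0, W = W, L = L)
  if (D <= 0) stop("D must be positive", call. = FALSE)
  rB * A0 * W * L / D
}

#' Strong-depletion limiting length
#'
#' When the depletion number is large, CB saturates at k2*D*C0/(V*W) and the
#' length approaches (k1/k2) * A0^2 * V^2 * W / (D * C0): linear in width,
#' quadratic in density.
#'
#' @inheritParams feedback_curves
#' @return length (um); warns when evaluated outside the strong-depletion
#'   regime (depletion number < 10 at the limiting length)
#' @export
depletion_limit_length <- function(A0, V, C0, W,
                                   kinetics = cofilin_kinetics(),
                                   params = equilibrium_params()) {
  L <- (params$k1 / params$k2) * A0^2 * V^2 * W / (kinetics$D * C0)
  dn <- depletion_number(kinetics$rB, A0, W, L, kinetics$D)
  if (dn < 10)
    warning(sprintf(
      "depletion number %.2g at the limiting length: outside the strong-depletion regime",
      dn), call. = FALSE)
  L
}

#' Phase map of equilibrium lengths over a two-parameter grid
#'
#' @param vary which pair varies: "C0_A0" or "W_A0"
#' @param grid1 grid for the first parameter (C0 in uM, or W in um)
#' @param grid2 grid for A0 (uM)
#' @param A0,V,C0,W fixed values for the parameters not varied
#' @param kinetics,params model parameters
#' @return matrix of L_star (um), rows indexed by `grid1`, columns by `grid2`
#' @export
length_phase_map <- function(vary = c("C0_A0", "W_A0"), grid1, grid2,
                             A0 = 50, V = per_min(1.16), C0 = 0.25, W = 30,
                             kinetics = cofilin_kinetics(),
                             params = equilibrium_params()) {
  vary <- match.arg(vary)
  out <- matrix(NA_real_, length(grid1), length(grid2),
                dimnames = list(signif(grid1, 6), signif(grid2, 6)))
  for (i in seq_along(grid1)) {
    for (j in seq_along(grid2)) {
      out[i, j] <- if (vary == "C0_A0") {
        solve_equilibrium(grid2[j], V, grid1[i], W, kinetics, params)$L_star
      } else {
        solve_equilibrium(grid2[j], V, C0, grid1[i], kinetics, params)$L_star
      }
    }
  }
  out
}

#' Compensating parameter for a target equilibrium length
#'
#' Given a (perturbed) density A0 and a target length, inverts the closed-form
#' equilibrium condition for the ADF/Cofilin concentration C0 (or the width W)
#' that restores the target — the compensation workflow on the phase map.
#'
#' @param target_L desired equilibrium length (um)
#' @param A0 actin density (uM)
#' @param V growth speed (um/s)
#' @param W width (um), fixed when solving for C0
#' @param C0 concentration (uM), fixed when solving for W
#' @param solve_for "C0" or "W"
#' @param kinetics,params model parameters (alpha = 2, beta = 1 required)
#' @return the compensating parameter value
#' @export
compensate_length <- function(target_L, A0, V, W = 30, C0 = 0.25,
                              solve_for = c("C0", "W"),
                              kinetics = cofilin_kinetics(),
                              params = equilibrium_params()) {
  solve_for <- match.arg(solve_for)
  stopifnot(params$alpha == 2, params$beta == 1, target_L > 0)
  rB <- kinetics$rB; D <- kinetics$D
  k1 <- params$k1; k2 <- params$k2
  L <- target_L
  if (solve_for == "C0") {
    ## from (k2 rB A0 C0 D / V) L^2 = k1 A0^2 V (rB A0 W L + D)
    k1 * A0^2 * V^2 * (rB * A0 * W * L + D) / (k2 * rB * A0 * D * L^2)
  } else {
    ## solve the same relation for W
    (k2 * rB * A0 * C0 * D * L^2 / V - k1 * A0^2 * V * D) /
      (k1 * A0^2 * V * rB * A0 * L)
  }
}
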