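## Steering of heterogeneous networks: two elastic beams growing side-by-side.
##
## Two sub-networks of common single-lane width W grow at speeds V1 and V2
## with elastic moduli E1 and E2 (sigma = E2/E1, with E scaling with actin
## density as E ~ A^tau). In mechanical equilibrium the pair bends into an arc
## whose radius and combined growth speed are closed forms in (W, V1, V2,
## sigma); the network always steers toward the slower lane. ADF/Cofilin
## shortens the sparser lane, so sigma varies with distance from the leading
## edge and the arc straightens beyond the shorter lane's trailing edge.

#' Elasticity ratio from the density-modulus scaling E ~ A^tau
#'
#' @param A1,A2 lane densities (uM), positive
#' @param tau elasticity-density exponent; ~2.5 for random isotropic networks,
#'   with ~0.5 reported for branched arrays (predictions are insensitive)
#' @return sigma = E2/E1 = (A2/A1)^tau
#' @export
elasticity_ratio <- function(A1, A2, tau = 2.5) {
  if (A1 <= 0 || any(A2 <= 0)) stop("densities must be positive", call. = FALSE)
  (A2 / A1)^tau
}

#' Curvature radius of the coupled two-lane network
#'
#' R = W * [ (V1+V2)/(V1-V2) + (sigma-1)(V1*sigma - V2)/(4*sigma*(V1-V2)) ],
#' reducing to W*(V1+V2)/(V1-V2) at sigma = 1. Equal speeds give straight
#' growth (infinite radius).
#'
#' @param W single-lane width (um)
#' @param V1,V2 lane growth speeds (um/s)
#' @param sigma elasticity ratio E2/E1 (> 0)
#' @return list with `R` (um, positive magnitude; `Inf` when straight) and
#'   `direction` ("lane1"/"lane2": the slower lane steered toward, or
#'   "straight")
#' @export
curvature_radius <- function(W, V1, V2, sigma = 1) {
  stopifnot(W > 0, V1 > 0, V2 > 0, sigma > 0)
  if (V1 == V2) return(list(R = Inf, direction = "straight"))
  R <- W * ((V1 + V2) / (V1 - V2) +
              (sigma - 1) * (V1 * sigma - V2) / (4 * sigma * (V1 - V2)))
  list(R = abs(R), direction = if (V1 > V2) "lane2" else "lane1")
}

#' Combined growth speed of the coupled pair
#'
#' Vh = (V1+V2)/2 - (V1-V2)(V1^2 sigma^2 - V2^2) /
#'      (2 (V1^2 sigma^2 + 6 V1 V2 sigma + V2^2));
#' equal lanes grow at V for any sigma, and Vh is invariant under swapping
#' the lanes together with sigma -> 1/sigma.
#'
#' @inheritParams curvature_radius
#' @return combined speed (um/s)
#' @export
combined_speed <- function(V1, V2, sigma = 1) {
  stopifnot(V1 > 0, V2 > 0, sigma > 0)
  (V1 + V2) / 2 - (V1 - V2) * (V1^2 * sigma^2 - V2^2) /
    (2 * (V1^2 * sigma^2 + 6 * V1 * V2 * sigma + V2^2))
}

#' Joint equilibrium lengths of two lanes sharing one cofilin pool
#'
#' The lanes compete for the same free ADF/Cofilin, so the depletion factor is
#' shared: D / (rB*(A1*W1*L1 + A2*W2*L2) + D). Each lane's disassembly
#' feedback L_i = k1*A_i^2*V_i/CB_i then couples through it; the joint system
#' is solved by damped fixed-point iteration on the shared factor. Both lanes
#' come out at least as long as in isolation, the sparser lane gaining more.
#'
#' @param A1,A2 lane leading-edge densities (uM)
#' @param V1,V2 lane growth speeds (um/s)
#' @param C0 shared solution concentration (uM)
#' @param W1,W2 lane widths (um)
#' @param kinetics [cofilin_kinetics()]
#' @param params [equilibrium_params()] (alpha = 2, beta = 1)
#' @return list with `L1`, `L2` (um), `CB1`, `CB2` (uM), shared
#'   `depletion_factor`, and the isolated lengths `L1_isolated`,
#'   `L2_isolated`
#' @export
coupled_equilibrium_lengths <- function(A1, A2, V1, V2, C0, W1 = 15, W2 = 15,
                                        kinetics = cofilin_kinetics(),
                                        params = equilibrium_params()) {
  stopifnot(params$alpha == 2, params$beta == 1)
  if (any(c(A1, A2, V1, V2, C0, W1, W2) <= 0))
    stop("all parameters must be positive", call. = FALSE)
  rB <- kinetics$rB; D <- kinetics$D
  k1 <- params$k1; k2 <- params$k2
  ## with shared factor F: L_i = V_i * sqrt(k1 * A_i / (k2 * rB * C0 * F))
  len <- function(F) c(V1 * sqrt(k1 * A1 / (k2 * rB * C0 * F)),
                       V2 * sqrt(k1 * A2 / (k2 * rB * C0 * F)))
  F <- 1
  for (it in 1:200) {
    L <- len(F)
    F_new <- D / (rB * (A1 * W1 * L[1] + A2 * W2 * L[2]) + D)
    if (abs(F_new - F) < 1e-14) { F <- F_new; break }
    F <- 0.5 * F + 0.5 * F_new
  }
  L <- len(F)
  CB <- c(k2 * rB * A1 * C0 * (L[1] / V1) * F,
          k2 * rB * A2 * C0 * (L[2] / V2) * F)
  iso1 <- solve_equilibrium(A1, V1, C0, W1, kinetics, params)$L_star
  iso2 <- solve_equilibrium(A2, V2, C0, W2, kinetics, params)$L_star
  list(L1 = L[1], L2 = L[2], CB1 = CB[1], CB2 = CB[2],
       depletion_factor = F, L1_isolated = iso1, L2_isolated = iso2)
}

#' Integrate the centerline shape of a heterogeneous network
#'
#' The local curvature at distance y behind the leading edge is
#' 1/R(sigma(y)) with sigma(y) = (A2(y)/A1(y))^tau evaluated pointwise from
#' the lane density profiles; beyond the shorter lane's trailing edge the
#' survivor grows straight (curvature exactly 0, sharp transition).
#'
#' @param A1,A2 lane density profiles: constants or functions of y (um -> uM)
#' @param V1,V2 lane growth speeds (um/s)
#' @param W single-lane width (um)
#' @param L1,L2 lane lengths (um); `Inf` for no-cofilin (ungraded) lanes
#' @param L_total arclength to integrate (um); default max(L1, L2) (finite)
#' @param tau elasticity exponent
#' @param ds integration step (um)
#' @return object of class `shape_curve`: data.frame centerline (s, x, y,
#'   kappa), `direction`, `Vh`, and `avg_curvature_radius` — the inverse of
#'   the arclength-weighted mean curvature over the curved portion (Inf if
#'   fully straight)
#' @export
heterogeneous_shape <- function(A1, A2, V1, V2, W, L1 = Inf, L2 = Inf,
                                L_total = NULL, tau = 2.5, ds = 0.1) {
  a1f <- if (is.function(A1)) A1 else function(y) rep(A1, length(y))
  a2f <- if (is.function(A2)) A2 else function(y) rep(A2, length(y))
  if (is.null(L_total)) {
    L_total <- max(L1[is.finite(L1)], L2[is.finite(L2)], 40)
  }
  L_short <- min(L1, L2)
  s <- seq(0, L_total, by = ds)
  a1 <- a1f(s); a2 <- a2f(s)
  if (any(!is.finite(a1)) || any(a1 <= 0) || any(!is.finite(a2)) || any(a2 <= 0))
    stop("density profiles must be positive over the integrated length",
         call. = FALSE)
  kap <- numeric(length(s))
  live <- s <= L_short
  if (V1 != V2 && any(live)) {
    sig <- (a2[live] / a1[live])^tau
    kap[live] <- vapply(sig, function(sg) {
      1 / curvature_radius(W, V1, V2, sg)$R
    }, numeric(1))
  }
  direction <- if (V1 == V2) "straight" else if (V1 > V2) "lane2" else "lane1"
  sgn <- if (direction == "lane2") -1 else 1   # bend sign convention
  theta <- cumsum(c(0, sgn * kap[-length(kap)] * ds))
  xx <- cumsum(c(0, cos(theta[-length(theta)] + pi / 2) * ds))
  yy <- cumsum(c(0, sin(theta[-length(theta)] + pi / 2) * ds))
  curved <- kap > 0
  avg_R <- if (any(curved)) 1 / mean(kap[curved]) else Inf
  avg_R_full <- if (any(curved)) 1 / mean(kap) else Inf
  structure(list(
    centerline = data.frame(s = s, x = xx, y = yy, kappa = kap),
    direction = direction,
    Vh = combined_speed(V1, V2, (a2f(0) / a1f(0))^tau),
    avg_curvature_radius = avg_R,
    avg_curvature_radius_full = avg_R_full,
    average_definition = paste(
      "avg_curvature_radius: inverse arclength-weighted mean curvature over",
      "the curved portion; _full: over the whole integrated shape")),
    class = "shape_curve")
}
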