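## Parameter containers and unit conventions.
##
## Canonical internal units throughout the package: concentrations in uM,
## lengths in um, time in s. Rates quoted per minute in the literature must be
## converted at the boundary; `per_min()` does that.

#' Convert a per-minute rate to the canonical per-second unit
#'
#' @param x rate in 1/min (or um/min for speeds)
#' @return the same rate in 1/s (or um/s)
#' @export
per_min <- function(x) x / 60

stop_if_negative <- function(...) {
  vals <- list(...)
  nms <- names(vals)
  for (i in seq_along(vals)) {
    v <- vals[[i]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      stop(sprintf("`%s` must be a single nonnegative number", nms[i]),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' ADF/Cofilin kinetic parameters
#'
#' Bundles the biochemical constants governing ADF/Cofilin exchange between
#' solution and the actin network.
#'
#' @param C0 initial free ADF/Cofilin concentration in solution (uM)
#' @param D  diffusion coefficient of free ADF/Cofilin (um^2/s)
#' @param rB binding rate constant (1/(s*uM)); the simple closed-form model
#'   calls the same quantity kB
#' @param rU unbinding rate (1/s)
#' @param diffusion_correction dimensionless factor in (0, 1] applied to D
#'   inside the network; the steric effect of even a dense network is a
#'   few-percent reduction, so the default is 1
#' @return object of class `cofilin_kinetics`
#' @export
cofilin_kinetics <- function(C0 = 0.125, D = 10, rB = per_min(0.5),
                             rU = per_min(0.31), diffusion_correction = 1) {
  stop_if_negative(C0 = C0, D = D, rB = rB, rU = rU)
  if (diffusion_correction <= 0 || diffusion_correction > 1)
    stop("`diffusion_correction` must lie in (0, 1]", call. = FALSE)
  structure(list(C0 = C0, D = D, rB = rB, rU = rU,
                 diffusion_correction = diffusion_correction),
            class = "cofilin_kinetics")
}

#' Network geometry and growth
#'
#' @param W network width (um), > 0
#' @param V leading-edge growth speed (um/s), >= 0
#' @param t elapsed time (s); the current network length is L(t) = V*t
#' @return object of class `network_geometry` with fields W, V, t and L
#' @export
network_geometry <- function(W = 30, V = per_min(1.16), t = 0) {
  stop_if_negative(W = W, V = V, t = t)
  if (W <= 0) stop("`W` must be positive", call. = FALSE)
  structure(list(W = W, V = V, t = t, L = V * t), class = "network_geometry")
}

#' Filamentous actin density profile
#'
#' Either a constant density (rough estimates) or a tabulated function of the
#' distance y from the leading edge (comparison with measured profiles).
#'
#' @param A0 leading-edge filamentous actin density (uM)
#' @param profile optional function of y (um) returning density (uM); must
#'   satisfy profile(0) == A0 within 1e-6 relative
#' @return object of class `actin_profile`; calling `density_at(obj, y)`
#'   evaluates it
#' @export
actin_profile <- function(A0 = 50, profile = NULL) {
  stop_if_negative(A0 = A0)
  if (!is.null(profile)) {
    stopifnot(is.function(profile))
    p0 <- profile(0)
    if (abs(p0 - A0) > 1e-6 * max(A0, 1))
      stop("profile(0) must equal A0", call. = FALSE)
  }
  structure(list(A0 = A0, profile = profile), class = "actin_profile")
}

#' Evaluate an actin profile at distances y from the leading edge
#' @param actin an `actin_profile`
#' @param y distances (um)
#' @return densities (uM), constant A0 if no profile function was given
#' @export
density_at <- function(actin, y) {
  stopifnot(inherits(actin, "actin_profile"))
  if (is.null(actin$profile)) rep(actin$A0, length(y)) else {
    a <- actin$profile(y)
    if (any(a < -1e-12)) stop("actin profile must be nonnegative", call. = FALSE)
    pmax(a, 0)
  }
}

#' Critical bound-cofilin threshold of the simple disassembly model
#'
#' @param gamma critical bound-ADF/Cofilin-per-actin ratio (dimensionless, > 0)
#' @export
threshold_model <- function(gamma = 0.1) {
  stop_if_negative(gamma = gamma)
  if (gamma <= 0) stop("`gamma` must be positive", call. = FALSE)
  structure(list(gamma = gamma), class = "threshold_model")
}
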