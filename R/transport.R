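## Transport of ADF/Cofilin around a growing branched actin network.
##
## Two coupled fields on a 2D chamber: free cofilin CF(x,y,t) diffusing in
## solution, and bound cofilin CB(x,y,t) advected with the network material at
## the growth speed V (leading edge held at a fixed station, material drifting
## in +y):
##
##   dCB/dt = -V dCB/dy + rB * A * CF - rU * CB      (on the network)
##   dCF/dt =  D Lap(CF) - rB * A * CF + rU * CB
##
## Numerics: Lie operator splitting per step — backward-Euler diffusion with a
## prefactored sparse Cholesky solve, exact pointwise relaxation of the linear
## binding/unbinding exchange (unconditionally stable, positivity preserving),
## and first-order upwind advection of CB (CFL <= 0.5 enforced). Newly
## polymerized actin is cofilin-free: the advection inflow at the leading edge
## is exactly zero.

#' Bound-cofilin profile of the simple constant-rate binding model
#'
#' Closed form CB(y) = kB*C0*A*y/V: material a distance y behind the leading
#' edge has aged y/V seconds while binding at the constant rate kB*C0*A.
#'
#' @param kinetics [cofilin_kinetics()]; `rB` plays the role of kB
#' @param actin [actin_profile()] with constant density
#' @param geometry [network_geometry()]; V must be positive
#' @param y distance from the leading edge (um), within [0, L(t)]
#' @return bound ADF/Cofilin concentration (uM)
#' @export
simple_bound_profile <- function(kinetics, actin, geometry, y) {
  stopifnot(inherits(kinetics, "cofilin_kinetics"),
            inherits(actin, "actin_profile"),
            inherits(geometry, "network_geometry"))
  if (geometry$V <= 0) stop("growth speed V must be positive", call. = FALSE)
  if (any(y < 0) || any(y > geometry$L + 1e-9))
    stop("y must lie within [0, L(t)]", call. = FALSE)
  kinetics$rB * kinetics$C0 * actin$A0 * y / geometry$V
}

#' Equilibrium length of the simple threshold model
#'
#' The network falls apart where the bound-per-actin ratio CB/A reaches the
#' critical value gamma, giving L* = gamma*V/(kB*C0) — independent of width
#' and density.
#'
#' @param threshold [threshold_model()]
#' @param kinetics [cofilin_kinetics()]
#' @param geometry [network_geometry()]
#' @return length (um); `Inf` with a warning when kB*C0 = 0 (no finite
#'   equilibrium)
#' @export
simple_equilibrium_length <- function(threshold, kinetics, geometry) {
  stopifnot(inherits(threshold, "threshold_model"))
  if (kinetics$rB * kinetics$C0 <= 0) {
    warning("kB*C0 = 0: no finite equilibrium length", call. = FALSE)
    return(Inf)
  }
  threshold$gamma * geometry$V / (kinetics$rB * kinetics$C0)
}

#' Quasi-steady estimates of depletion near the network
#'
#' Flux-balance estimates for the local free concentration and the
#' leading-edge binding rate once a network of area W x L has built up:
#' CF ~ (C0*D + W*L*CB*rU)/(D + A*W*L*rB) and
#' dCB/dt ~ rB*A*C0*D/(D + A*W*L*rB). Both fall as the network grows.
#'
#' @param kinetics [cofilin_kinetics()]
#' @param geometry [network_geometry()] supplying W and L
#' @param A constant actin density (uM)
#' @param CB current mean bound concentration (uM)
#' @return list with `CF` (uM) and `binding_rate` (uM/s)
#' @export
quasi_steady_estimate <- function(kinetics, geometry, A, CB = 0) {
  stop_if_negative(A = A, CB = CB)
  W <- geometry$W; L <- geometry$L
  D <- kinetics$D; rB <- kinetics$rB; rU <- kinetics$rU; C0 <- kinetics$C0
  denom <- D + A * W * L * rB
  list(CF = (C0 * D + W * L * CB * rU) / denom,
       binding_rate = rB * A * C0 * D / denom)
}

## ---- grid helpers -----------------------------------------------------------

## Backward-Euler diffusion operator (I + dt*D/h^2 * Lneg) on a cell-centred
## grid. "far-field": outermost cell ring held at C0 (Dirichlet); "closed":
## no-flux Neumann, mass conserving. Returns a solver closure.
make_diffusion_solver <- function(nx, ny, h, dt, D, boundary, C0) {
  lam <- dt * D / h^2
  if (boundary == "closed") {
    idx <- function(j, i) (i - 1L) * ny + j
    n <- nx * ny
    ii <- jj <- xx <- vector("list", 5L)
    jg <- rep(seq_len(ny), nx)
    ig <- rep(seq_len(nx), each = ny)
    ## neighbour counts give the Neumann diagonal
    nb <- (jg > 1L) + (jg < ny) + (ig > 1L) + (ig < nx)
    diag_i <- idx(jg, ig)
    ii[[1]] <- diag_i; jj[[1]] <- diag_i; xx[[1]] <- 1 + lam * nb
    k <- 2L
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      jn <- jg + d[1]; in_ <- ig + d[2]
      ok <- jn >= 1L & jn <= ny & in_ >= 1L & in_ <= nx
      ii[[k]] <- diag_i[ok]; jj[[k]] <- idx(jn[ok], in_[ok])
      xx[[k]] <- rep(-lam, sum(ok)); k <- k + 1L
    }
    A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                              dims = c(n, n))
    ch <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE)
    function(CF) {
      sol <- Matrix::solve(ch, as.vector(CF))
      matrix(as.numeric(sol), nrow = ny, ncol = nx)
    }
  } else {
    ## unknowns: interior cells; boundary ring fixed at C0
    interior <- matrix(FALSE, ny, nx)
    interior[2:(ny - 1L), 2:(nx - 1L)] <- TRUE
    uidx <- matrix(0L, ny, nx)
    uidx[interior] <- seq_len(sum(interior))
    n <- sum(interior)
    jg <- rep(seq_len(ny), nx); ig <- rep(seq_len(nx), each = ny)
    keep <- interior[cbind(jg, ig)]
    jg <- jg[keep]; ig <- ig[keep]
    diag_i <- uidx[cbind(jg, ig)]
    ii <- list(diag_i); jj <- list(diag_i)
    xx <- list(rep(1 + 4 * lam, n))
    bnd_contrib <- numeric(n)   # constant RHS term from the fixed ring
    k <- 2L
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      jn <- jg + d[1]; in_ <- ig + d[2]
      nb_int <- interior[cbind(jn, in_)]
      ii[[k]] <- diag_i[nb_int]; jj[[k]] <- uidx[cbind(jn, in_)][nb_int]
      xx[[k]] <- rep(-lam, sum(nb_int))
      bnd_contrib[diag_i[!nb_int]] <- bnd_contrib[diag_i[!nb_int]] + lam * C0
      k <- k + 1L
    }
    A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                              dims = c(n, n))
    ch <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE)
    function(CF) {
      b <- CF[interior] + bnd_contrib
      sol <- Matrix::solve(ch, b)
      out <- CF
      out[interior] <- as.numeric(sol)
      out[!interior] <- C0
      out
    }
  }
}

## ---- main solver ------------------------------------------------------------

#' Simulate the 2D chamber model of cofilin transport around a growing network
#'
#' @param kinetics [cofilin_kinetics()]
#' @param geometry [network_geometry()]; W is the network width, V the growth
#'   speed. The initial network length is `V * geometry$t` (usually 0).
#' @param actin [actin_profile()]; constant density or tabulated A(y)
#' @param t_end simulated duration (s)
#' @param domain chamber extents c(Lx, Ly) in um; the far-field boundary
#'   should be several network dimensions away
#' @param h grid spacing (um); must resolve the width (>= 10 cells across W)
#' @param dt time step (s); default satisfies the advection CFL (<= 0.5) and
#'   keeps splitting error small
#' @param boundary "far-field" (CF = C0 on the chamber edge, emulating a vast
#'   chamber) or "closed" (no-flux, conserves total cofilin; for tests)
#' @param saturation if TRUE the binding term is multiplied by
#'   max(0, 1 - CB/(s_max*A)); default FALSE, the plain mass-action law
#' @param s_max saturation stoichiometry (bound cofilin per actin), used only
#'   when `saturation = TRUE`
#' @param output_times times (s) at which fields are stored; default `t_end`
#' @param leading_edge y-position of the (stationary) leading edge (um);
#'   default places the final network centred in the chamber
#' @param init_CF optional initial free-cofilin field (matrix ny x nx), for
#'   verification runs; default uniform C0
#' @return object of class `chamber_sim`: snapshots of CF/CB with grid
#'   metadata and the network mask at each stored time
#' @export
simulate_chamber <- function(kinetics, geometry, actin = actin_profile(),
                             t_end, domain = c(300, 300), h = 1, dt = NULL,
                             boundary = c("far-field", "closed"),
                             saturation = FALSE, s_max = 1,
                             output_times = NULL, leading_edge = NULL,
                             init_CF = NULL) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(kinetics, "cofilin_kinetics"),
            inherits(geometry, "network_geometry"),
            inherits(actin, "actin_profile"), t_end > 0)
  W <- geometry$W; V <- geometry$V
  if (W / h < 10) stop("grid too coarse: need >= 10 cells across W", call. = FALSE)
  nx <- as.integer(round(domain[1] / h))
  ny <- as.integer(round(domain[2] / h))
  x <- (seq_len(nx) - 0.5) * h
  y <- (seq_len(ny) - 0.5) * h
  L0 <- geometry$L
  L_end <- L0 + V * t_end
  if (is.null(leading_edge)) leading_edge <- (domain[2] - L_end) / 2
  if (leading_edge < 0 || leading_edge + L_end > domain[2])
    stop("network outgrows the chamber; enlarge `domain`", call. = FALSE)
  if (is.null(dt)) {
    dt <- min(2, if (V > 0) 0.5 * h / V else Inf, t_end)
  }
  if (V * dt / h > 0.5)
    stop("advection CFL V*dt/h exceeds 0.5; reduce dt", call. = FALSE)
  cfl <- V * dt / h

  ## network columns (width W centred in x)
  cols <- which(abs(x - domain[1] / 2) <= W / 2 + 1e-9)
  ## distance of each row centre downstream of the leading edge
  ydist <- y - leading_edge
  mask_rows <- function(L) which(ydist >= 0 & ydist <= L + 1e-9)

  A_rows <- density_at(actin, pmax(ydist, 0))   # density per row (network cols)

  Dmat <- kinetics$D
  diffuse <- make_diffusion_solver(nx, ny, h, dt, Dmat, boundary, kinetics$C0)

  CF <- if (is.null(init_CF)) matrix(kinetics$C0, ny, nx) else {
    stopifnot(all(dim(init_CF) == c(ny, nx)))
    init_CF
  }
  CB <- matrix(0, ny, nx)

  if (is.null(output_times)) output_times <- t_end
  output_times <- sort(unique(pmin(output_times, t_end)))
  nsteps <- ceiling(t_end / dt - 1e-9)
  out_step <- pmax(1L, as.integer(round(output_times / dt)))

  rB <- kinetics$rB; rU <- kinetics$rU
  snapshots <- list(); si <- 1L
  adv_rows <- which(ydist >= 0)      # advection acts downstream of the edge
  first_adv <- adv_rows[1]

  for (step in seq_len(nsteps)) {
    t_now <- step * dt
    L_now <- L0 + V * t_now
    rows <- mask_rows(L_now)

    ## 1) diffusion of CF (implicit)
    CF <- diffuse(CF)

    ## 2) upwind advection of CB toward the trailing edge (+y), inflow 0
    if (V > 0 && length(adv_rows) > 1) {
      blk <- CB[adv_rows, cols, drop = FALSE]
      up <- rbind(0, blk[-nrow(blk), , drop = FALSE])
      CB[adv_rows, cols] <- blk - cfl * (blk - up)
    }

    ## 3) binding/unbinding inside the network (exact linear relaxation)
    if (length(rows) > 0 && length(cols) > 0) {
      a <- A_rows[rows] * rB                  # per-row binding rate (1/s)
      cfb <- CF[rows, cols, drop = FALSE]
      cbb <- CB[rows, cols, drop = FALSE]
      if (!saturation) {
        tot <- cfb + cbb
        rate <- a + rU
        f_eq <- if (rU > 0 || any(a > 0)) rU / rate else 1
        dec <- exp(-rate * dt)
        cf_eq <- tot * f_eq
        cf_new <- cf_eq + (cfb - cf_eq) * dec
        CF[rows, cols] <- cf_new
        CB[rows, cols] <- tot - cf_new
      } else {
        Aloc <- A_rows[rows]
        nsub <- max(1L, ceiling(dt * (max(a) + rU) / 0.5))
        sdt <- dt / nsub
        for (s in seq_len(nsub)) {
          sat <- pmax(0, 1 - cbb / (s_max * Aloc))
          flux <- (a * cfb * sat - rU * cbb) * sdt
          cfb <- cfb - flux; cbb <- cbb + flux
        }
        CF[rows, cols] <- cfb; CB[rows, cols] <- cbb
      }
    }

    if (min(CF) < -1e-8 || min(CB) < -1e-8)
      stop("solver produced negative concentrations beyond tolerance",
           call. = FALSE)

    while (si <= length(out_step) && step == out_step[si]) {
      msk <- matrix(FALSE, ny, nx); msk[rows, cols] <- TRUE
      snapshots[[si]] <- list(t = t_now, CF = CF, CB = CB, mask = msk,
                              L = L_now)
      si <- si + 1L
    }
  }

  structure(list(snapshots = snapshots,
                 times = vapply(snapshots, `[[`, numeric(1), "t"),
                 x = x, y = y, h = h, dt = dt,
                 leading_edge = leading_edge, cols = cols,
                 boundary = boundary,
                 kinetics = kinetics, geometry = geometry, actin = actin),
            class = "chamber_sim")
}

#' Total cofilin (free + bound) in a simulation snapshot
#'
#' Area integral of CF + CB; constant in time on a closed domain.
#' @param sim a `chamber_sim`
#' @return numeric vector, one total (uM*um^2) per stored snapshot
#' @export
total_cofilin <- function(sim) {
  stopifnot(inherits(sim, "chamber_sim"))
  vapply(sim$snapshots,
         function(s) (sum(s$CF) + sum(s$CB)) * sim$h^2, numeric(1))
}

#' Mean free-cofilin time course in an observation region
#'
#' Average CF over a rectangular region, one value per stored snapshot — the
#' depletion diagnostic. Default region: the chamber area covered by the
#' network at the final stored time.
#'
#' @param sim a `chamber_sim` with several stored times
#' @param region optional list(x = c(x0, x1), y = c(y0, y1)) in um
#' @return data.frame with columns `t` (s) and `CF_mean` (uM)
#' @export
depletion_timecourse <- function(sim, region = NULL) {
  stopifnot(inherits(sim, "chamber_sim"))
  if (is.null(region)) {
    last <- sim$snapshots[[length(sim$snapshots)]]
    region <- list(x = range(sim$x[sim$cols]),
                   y = c(sim$leading_edge, sim$leading_edge + last$L))
  }
  ix <- which(sim$x >= region$x[1] - 1e-9 & sim$x <= region$x[2] + 1e-9)
  iy <- which(sim$y >= region$y[1] - 1e-9 & sim$y <= region$y[2] + 1e-9)
  if (length(ix) == 0 || length(iy) == 0)
    stop("observation region is empty", call. = FALSE)
  data.frame(
    t = sim$times,
    CF_mean = vapply(sim$snapshots,
                     function(s) mean(s$CF[iy, ix]), numeric(1)))
}

#' Maximum relative depletion of free cofilin
#'
#' 100 * (1 - min(CF)/C0) over the whole domain at the final stored time.
#' @param sim a `chamber_sim`
#' @return percentage in [0, 100]
#' @export
max_depletion <- function(sim) {
  stopifnot(inherits(sim, "chamber_sim"))
  last <- sim$snapshots[[length(sim$snapshots)]]
  100 * (1 - min(last$CF) / sim$kinetics$C0)
}
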