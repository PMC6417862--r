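## Stochastic fragmentation of the network at the trailing edge.
##
## The branched network is idealized as a square lattice: nodes are effective
## crosslinking/branching points, edges are actin-filament arrays between
## them. Bound ADF/Cofilin removes nodes at rate P = k_break * CB^beta /
## A_local^alpha, where A_local is the local network density measured from the
## intact edges in a disc around the node. Pieces disconnected from the
## leading edge diffuse away and are deleted, which yields macroscopic
## fragmentation: node removal "primes" the network, and the positive feedback
## between density loss and breakage produces an avalanche at the trailing
## edge.
##
## Row 1 of the node matrix is the leading edge; growth prepends fully intact
## rows as the cumulative advance V*t crosses multiples of the lattice
## spacing.

#' Fragmentation model parameters
#'
#' @param alpha actin-density exponent (>= 0); default 2, the value the
#'   equilibrium-length fit selects
#' @param beta bound-cofilin exponent (>= 0); default 1
#' @param k_break rate prefactor, units uM^(alpha-beta)/s so that P is 1/s
#'   with CB and A in uM. The default reproduces experiment-scale equilibrium
#'   lengths (tens of um) at A0 = 50 uM, CB = 0.5 uM, V ~ 1 um/min.
#' @param kernel_radius radius (um) of the uniform disc over which intact
#'   edges are counted for the local density; must be >= the lattice spacing
#' @return object of class `fragmentation_params`
#' @export
fragmentation_params <- function(alpha = 2, beta = 1, k_break = 2.5,
                                 kernel_radius = 1) {
  stop_if_negative(alpha = alpha, beta = beta, k_break = k_break,
                   kernel_radius = kernel_radius)
  structure(list(alpha = alpha, beta = beta, k_break = k_break,
                 kernel_radius = kernel_radius),
            class = "fragmentation_params")
}

#' Continuum (mean-field) parameters
#'
#' @param q_c critical broken-node fraction in (0,1) at which the lattice
#'   falls apart (percolation-like threshold); default 0.4
#' @param c calibration prefactor linking the mean-field length to the
#'   stochastic mean (default 1; see [calibrate_continuum()])
#' @export
continuum_params <- function(q_c = 0.4, c = 1) {
  if (q_c <= 0 || q_c >= 1) stop("`q_c` must lie in (0,1)", call. = FALSE)
  stop_if_negative(c = c)
  structure(list(q_c = q_c, c = c), class = "continuum_params")
}

#' Build a fully intact lattice network
#'
#' @param W network width (um)
#' @param L initial network length (um); may be 0
#' @param a lattice spacing (um); the edges represent sub-micron filament
#'   arrays, default 0.5
#' @param A0 leading-edge actin density (uM) that a fully intact region maps to
#' @return object of class `lattice_network`
#' @export
build_lattice <- function(W, L = 0, a = 0.5, A0 = 50) {
  if (W <= 0 || a <= 0) stop("W and a must be positive", call. = FALSE)
  if (W / a < 4) stop("lattice too narrow: need W/a >= 4", call. = FALSE)
  stop_if_negative(L = L, A0 = A0)
  nc <- as.integer(round(W / a))
  nr <- max(1L, as.integer(round(L / a)))
  structure(list(intact = matrix(TRUE, nr, nc), a = a, A0 = A0,
                 growth_accum = 0, time = 0),
            class = "lattice_network")
}

## edge occupancy implied by adjacent intact nodes
h_edges <- function(M) M[, -ncol(M), drop = FALSE] & M[, -1L, drop = FALSE]
v_edges <- function(M) M[-nrow(M), , drop = FALSE] & M[-1L, , drop = FALSE]

## kernel offsets: midpoints of horizontal/vertical edges within `r` lattice
## units of a node. H edge (je,ke) has midpoint offset (dy, dx+0.5) from node
## (je-dy, ke-dx); V edges by symmetry.
kernel_offsets <- function(r) {
  off_h <- NULL
  for (dy in seq(-floor(r), floor(r))) {
    for (dx in seq(-ceiling(r) - 1L, ceiling(r))) {
      if (dy^2 + (dx + 0.5)^2 <= r^2 + 1e-12)
        off_h <- rbind(off_h, c(dy, dx))
    }
  }
  list(h = off_h, v = off_h[, 2:1, drop = FALSE])  # V = transpose symmetry
}

## accumulate E (edge matrix) shifted by (dj, di) into an acc of dim (nr, nc)
add_shifted <- function(acc, E, dj, di) {
  nr <- nrow(acc); nc <- ncol(acc)
  re <- nrow(E); ce <- ncol(E)
  j0 <- max(1L, 1L - dj); j1 <- min(nr, re - dj)
  i0 <- max(1L, 1L - di); i1 <- min(nc, ce - di)
  if (j0 > j1 || i0 > i1) return(acc)
  acc[j0:j1, i0:i1] <- acc[j0:j1, i0:i1] +
    E[(j0 + dj):(j1 + dj), (i0 + di):(i1 + di)]
  acc
}

count_kernel_edges <- function(M, off) {
  nr <- nrow(M); nc <- ncol(M)
  acc <- matrix(0, nr, nc)
  if (nc >= 2) {
    H <- h_edges(M)
    for (k in seq_len(nrow(off$h)))
      acc <- add_shifted(acc, H, off$h[k, 1], off$h[k, 2])
  }
  if (nr >= 2) {
    V <- v_edges(M)
    for (k in seq_len(nrow(off$v)))
      acc <- add_shifted(acc, V, off$v[k, 1], off$v[k, 2])
  }
  acc
}

#' Local network density at every node
#'
#' Weighted (uniform-disc) count of intact edges around each node, normalized
#' so that a fully intact lattice maps to A0 everywhere (boundary-corrected).
#'
#' @param lattice a `lattice_network`
#' @param kernel_radius disc radius in um (default 2 lattice spacings)
#' @return matrix of densities (uM), dim = lattice node grid
#' @export
local_density <- function(lattice, kernel_radius = 2 * lattice$a) {
  stopifnot(inherits(lattice, "lattice_network"))
  M <- lattice$intact
  off <- kernel_offsets(kernel_radius / lattice$a)
  full <- matrix(TRUE, nrow(M), ncol(M))
  norm <- count_kernel_edges(full, off)
  cnt <- count_kernel_edges(M, off)
  lattice$A0 * cnt / pmax(norm, 1)
}

#' Node breakage rate
#'
#' P = k_break * CB^beta / A_local^alpha. Nodes whose neighbourhood has lost
#' all edges (A_local = 0) are treated as instantaneously breakable (infinite
#' rate, i.e. breakage probability 1 in the next step).
#'
#' @param A_local local actin density (uM), vector or matrix
#' @param CB bound ADF/Cofilin concentration (uM), scalar or conformable
#' @param params [fragmentation_params()]
#' @return rate (1/s), same shape as `A_local`
#' @export
node_breakage_rate <- function(A_local, CB, params) {
  stopifnot(inherits(params, "fragmentation_params"))
  rate <- params$k_break * CB^params$beta / A_local^params$alpha
  rate[A_local <= 0 & params$alpha > 0] <- Inf
  rate
}

## BFS from the leading-edge row over 4-adjacent intact nodes; returns logical
## matrix of reachable nodes. Column-major integer encoding id = (i-1)*nr + j.
reachable_from_edge <- function(M) {
  nr <- nrow(M); nc <- ncol(M)
  visited <- logical(nr * nc)
  frontier <- (which(M[1L, ]) - 1L) * nr + 1L
  visited[frontier] <- TRUE
  intact <- as.vector(M)
  while (length(frontier) > 0) {
    j <- (frontier - 1L) %% nr + 1L
    nb <- c(frontier[j > 1L] - 1L, frontier[j < nr] + 1L,
            frontier[frontier > nr] - nr, frontier[frontier <= nr * (nc - 1L)] - 0L + nr)
    nb <- nb[intact[nb] & !visited[nb]]
    nb <- unique(nb)
    visited[nb] <- TRUE
    frontier <- nb
  }
  matrix(visited, nr, nc)
}

## component sizes of a set of node ids in an nr x nc grid
component_sizes <- function(ids, nr, nc) {
  if (length(ids) == 0) return(integer(0))
  inset <- logical(nr * nc); inset[ids] <- TRUE
  seen <- logical(nr * nc)
  sizes <- integer(0)
  for (s in ids) {
    if (seen[s]) next
    seen[s] <- TRUE
    frontier <- s; size <- 1L
    while (length(frontier) > 0) {
      j <- (frontier - 1L) %% nr + 1L
      nb <- c(frontier[j > 1L] - 1L, frontier[j < nr] + 1L,
              frontier[frontier > nr] - nr,
              frontier[frontier <= nr * (nc - 1L)] + nr)
      nb <- nb[inset[nb] & !seen[nb]]
      nb <- unique(nb)
      seen[nb] <- TRUE
      size <- size + length(nb)
      frontier <- nb
    }
    sizes <- c(sizes, size)
  }
  sizes
}

#' Advance the lattice network by one time step
#'
#' Appends intact rows at the leading edge as cumulative growth crosses lattice
#' rows, breaks each intact node independently with probability
#' 1 - exp(-P*dt), then prunes (and records) every piece disconnected from the
#' leading-edge row.
#'
#' @param lattice a `lattice_network`
#' @param params [fragmentation_params()]
#' @param CB bound-cofilin input: a scalar (uM, the model's default spatially
#'   constant simplification) or a function of the distance y (um) from the
#'   leading edge
#' @param V growth speed (um/s)
#' @param dt time step (s); must satisfy dt * P(A0, CB) <= 0.2 at full density
#' @return list with elements `lattice` (updated), `removed_sizes` (node
#'   counts of pruned fragments), `n_broken`, `n_zero_density` (nodes flagged
#'   as instantaneously breakable)
#' @export
advance_network <- function(lattice, params, CB, V, dt) {
  stopifnot(inherits(lattice, "lattice_network"),
            inherits(params, "fragmentation_params"))
  a <- lattice$a
  M <- lattice$intact
  nc <- ncol(M)

  ## growth: new fully intact, fully dense rows at the leading edge
  lattice$growth_accum <- lattice$growth_accum + V * dt
  while (lattice$growth_accum >= a - 1e-12) {
    M <- rbind(rep(TRUE, nc), M)
    lattice$growth_accum <- lattice$growth_accum - a
  }
  nr <- nrow(M)

  cb_row <- if (is.function(CB)) CB((seq_len(nr) - 1) * a) else rep(CB, nr)
  p_ref <- params$k_break * max(cb_row)^params$beta / lattice$A0^params$alpha
  if (dt * p_ref > 0.2)
    stop("dt too large: dt * P(A0, CB) must be <= 0.2", call. = FALSE)

  lattice$intact <- M
  dens <- local_density(lattice, params$kernel_radius)
  rate <- node_breakage_rate(dens, matrix(rep(cb_row, nc), nr, nc), params)
  n_zero <- sum(is.infinite(rate) & M)
  p <- 1 - exp(-rate * dt)
  brk <- M & (matrix(stats::runif(nr * nc), nr, nc) < p)
  M[brk] <- FALSE

  ## prune pieces disconnected from the leading edge
  removed_sizes <- integer(0)
  if (any(brk)) {
    keep <- reachable_from_edge(M)
    lost <- which(as.vector(M & !keep))
    if (length(lost) > 0) {
      removed_sizes <- component_sizes(lost, nr, nc)
      M[M & !keep] <- FALSE
    }
  }

  ## trim empty trailing rows
  occ <- which(rowSums(M) > 0)
  last <- if (length(occ) > 0) max(occ) else 1L
  M <- M[seq_len(last), , drop = FALSE]

  lattice$intact <- M
  lattice$time <- lattice$time + dt
  list(lattice = lattice, removed_sizes = removed_sizes,
       n_broken = sum(brk), n_zero_density = n_zero)
}

#' Network length of a lattice (um)
#' @param lattice a `lattice_network`
#' @return distance from the leading edge to the farthest occupied row (um)
#' @export
lattice_length <- function(lattice) {
  occ <- which(rowSums(lattice$intact) > 0)
  if (length(occ) == 0) 0 else max(occ) * lattice$a
}

#' Run the stochastic fragmentation model to its treadmilling equilibrium
#'
#' Grows a lattice from zero length at speed V while nodes break at
#' P = k_break*CB^beta/A_local^alpha, until time T. The post-transient window
#' (diagnosed as the first time the length reaches the median of its last
#' quarter) yields the equilibrium mean and standard deviation of the length.
#'
#' @param W network width (um)
#' @param V growth speed (um/s)
#' @param A0 leading-edge actin density (uM)
#' @param CB bound cofilin (uM), scalar or function of y
#' @param params [fragmentation_params()]
#' @param T total simulated time (s)
#' @param seed RNG seed (integer)
#' @param a lattice spacing (um)
#' @param dt time step (s); default 0.2/P(A0, CB) capped at half the
#'   row-crossing time a/V
#' @return object of class `fragmentation_run`: length time series, mean
#'   post-transient density profile, removed-fragment sizes, equilibrium
#'   summary (`L_mean`, `L_sd`, `reached_equilibrium`)
#' @export
run_to_equilibrium <- function(W, V, A0, CB, params = fragmentation_params(),
                               T = 6000, seed = 1, a = 0.5, dt = NULL) {
  set.seed(seed)
  cb_max <- if (is.function(CB)) max(CB(seq(0, 200, by = a))) else CB
  p0 <- params$k_break * cb_max^params$beta / A0^params$alpha
  if (is.null(dt)) dt <- min(0.2 / p0, 0.5 * a / V)
  lattice <- build_lattice(W, L = 0, a = a, A0 = A0)
  nsteps <- ceiling(T / dt)
  Ls <- numeric(nsteps); ts <- numeric(nsteps)
  frag_sizes <- integer(0)
  prof_sum <- numeric(0); prof_n <- 0L
  profile_from <- floor(nsteps / 2)
  for (s in seq_len(nsteps)) {
    st <- advance_network(lattice, params, CB, V, dt)
    lattice <- st$lattice
    frag_sizes <- c(frag_sizes, st$removed_sizes)
    Ls[s] <- lattice_length(lattice); ts[s] <- lattice$time
    if (s >= profile_from) {
      dens <- rowMeans(local_density(lattice, params$kernel_radius) *
                         lattice$intact)
      if (length(dens) > length(prof_sum))
        prof_sum <- c(prof_sum, numeric(length(dens) - length(prof_sum)))
      prof_sum[seq_along(dens)] <- prof_sum[seq_along(dens)] + dens
      prof_n <- prof_n + 1L
    }
  }
  ## transient diagnosis: first time the length reaches the median of the
  ## last quarter of the run
  m <- stats::median(Ls[max(1, floor(0.75 * nsteps)):nsteps])
  i_eq <- which(Ls >= m)[1]
  reached <- !is.na(i_eq) && i_eq < 0.6 * nsteps
  win <- if (reached) seq.int(i_eq, nsteps) else seq_len(nsteps)
  structure(list(
    t = ts, L = Ls,
    profile = if (prof_n > 0)
      data.frame(y = (seq_along(prof_sum) - 1) * a,
                 A = prof_sum / prof_n) else NULL,
    fragment_sizes = frag_sizes,
    L_mean = mean(Ls[win]), L_sd = stats::sd(Ls[win]),
    reached_equilibrium = reached, window_start = ts[win[1]],
    W = W, V = V, A0 = A0, CB = cb_max, a = a, dt = dt,
    params = params, seed = seed),
    class = "fragmentation_run")
}

#' Continuum mean-field prediction of the equilibrium length
#'
#' Broken-node fraction q(y) accumulates along the drift, V dq/dy =
#' P(A0,CB)(1-q); the network ends where q reaches the percolation-like
#' threshold q_c, giving L = c * ln(1/(1-q_c)) * V * A0^alpha /
#' (k_break * CB^beta) — the advertised scaling L ~ V A0^alpha / CB^beta.
#'
#' @param V growth speed (um/s)
#' @param A0 actin density (uM)
#' @param CB bound cofilin (uM), > 0
#' @param params [fragmentation_params()]
#' @param continuum [continuum_params()]
#' @return list with `L` (um) and `profile`, a function of y giving the
#'   mean-field density A0*(1-q(y)) (near-flat, collapsing at y ~ L)
#' @export
continuum_prediction <- function(V, A0, CB, params = fragmentation_params(),
                                 continuum = continuum_params()) {
  stopifnot(inherits(params, "fragmentation_params"),
            inherits(continuum, "continuum_params"))
  if (CB <= 0) stop("CB = 0: no finite equilibrium", call. = FALSE)
  p0 <- params$k_break * CB^params$beta / A0^params$alpha
  L <- continuum$c * log(1 / (1 - continuum$q_c)) * V / p0
  profile <- function(y) ifelse(y <= L, A0 * exp(-p0 * y / V), 0)
  list(L = L, profile = profile)
}

#' Calibrate the continuum prefactor against one stochastic run
#'
#' @param run a `fragmentation_run` at a reference parameter point
#' @param params,continuum the model parameters used for the run
#' @return a `continuum_params` with `c` set so the mean-field length matches
#'   the stochastic equilibrium mean at the reference point
#' @export
calibrate_continuum <- function(run, params = run$params,
                                continuum = continuum_params()) {
  stopifnot(inherits(run, "fragmentation_run"))
  base <- continuum_prediction(run$V, run$A0, run$CB, params,
                               continuum_params(q_c = continuum$q_c, c = 1))
  continuum_params(q_c = continuum$q_c, c = run$L_mean / base$L)
}
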