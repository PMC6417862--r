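## Synthetic observables with the statistical structure the analysis assumes.
##
## These generators stand in for the raw imaging data: bound-cofilin
## kymographs (with or without local depletion of the free pool), actin
## density profiles that are near-flat with an abrupt trailing-edge drop,
## equilibrium-length tables obeying L = c * V * A0^alpha / CB^beta, and
## initial-binding-slope tables proportional to C0*A. Noise models: additive
## Gaussian for kymographs (clipped at zero), multiplicative lognormal for
## lengths and slopes (positive, scale-free error). Every generator is
## deterministic under a fixed seed and carries provenance metadata.

gen_version <- function() as.character(utils::packageVersion("actintread"))

with_provenance <- function(x, generator, params, seed) {
  attr(x, "provenance") <- list(generator = generator, params = params,
                                seed = seed, version = gen_version())
  x
}

#' Synthetic bound-cofilin kymograph
#'
#' CB(y, t) on a regular grid. With `depletion = TRUE` the field comes from
#' the full chamber simulation (free-pool depletion makes later-starting
#' material paths bind slower); with `depletion = FALSE` it is the constant-
#' rate closed form CB = rB*C0*A*y/V (every material path has the same slope
#' rB*C0*A).
#'
#' @param kinetics [cofilin_kinetics()]
#' @param geometry [network_geometry()]
#' @param actin [actin_profile()]
#' @param t_end duration (s)
#' @param frame_interval kymograph frame spacing (s)
#' @param pixel_size y-sampling (um)
#' @param noise_sd additive Gaussian noise (uM-equivalent a.u.), >= 0
#' @param seed RNG seed
#' @param depletion simulate the free pool (TRUE) or use the no-depletion
#'   closed form (FALSE)
#' @param domain,h chamber size and grid spacing for the depletion simulation
#' @return object of class `kymograph`: matrix CB (rows = y, cols = t), with
#'   `y`, `t`, `V`, pixel/frame metadata
#' @export
gen_kymograph <- function(kinetics = cofilin_kinetics(),
                          geometry = network_geometry(),
                          actin = actin_profile(),
                          t_end = 2400, frame_interval = 60, pixel_size = 1,
                          noise_sd = 0, seed = 1, depletion = TRUE,
                          domain = c(160, 160), h = 2) {
  if (noise_sd < 0) stop("noise sd must be nonnegative", call. = FALSE)
  times <- seq(frame_interval, t_end, by = frame_interval)
  L_end <- geometry$V * t_end
  ys <- seq(0, L_end, by = pixel_size)
  if (depletion) {
    sim <- simulate_chamber(kinetics, geometry, actin, t_end = t_end,
                            domain = domain, h = h, output_times = times)
    ic <- which.min(abs(sim$x - domain[1] / 2))   # center column
    ydist <- sim$y - sim$leading_edge
    CByt <- vapply(sim$snapshots, function(s) {
      stats::approx(ydist, s$CB[, ic], xout = ys, rule = 2)$y
    }, numeric(length(ys)))
  } else {
    ## closed form: material present where y <= V*t, loaded linearly in age
    CByt <- outer(ys, times, function(y, t) {
      ifelse(y <= geometry$V * t + 1e-9,
             kinetics$rB * kinetics$C0 * density_at(actin, y) * y / geometry$V,
             0)
    })
  }
  set.seed(seed)
  if (noise_sd > 0)
    CByt <- pmax(CByt + matrix(stats::rnorm(length(CByt), 0, noise_sd),
                               nrow(CByt)), 0)
  out <- structure(list(CB = CByt, y = ys, t = times, V = geometry$V,
                        pixel_size = pixel_size,
                        frame_interval = frame_interval,
                        noise_sd = noise_sd),
                   class = "kymograph")
  with_provenance(out, "gen_kymograph",
                  list(kinetics = unclass(kinetics),
                       geometry = unclass(geometry), t_end = t_end,
                       noise_sd = noise_sd, depletion = depletion), seed)
}

#' Extract a material path from a kymograph
#'
#' Material born at the leading edge at time t0 sits at y = V*(t - t0).
#'
#' @param kym a `kymograph`
#' @param t0 start time (s)
#' @return data.frame (t, y, CB) for frames with 0 <= y <= max(y)
#' @export
kymo_path <- function(kym, t0) {
  stopifnot(inherits(kym, "kymograph"))
  tt <- kym$t[kym$t >= t0]
  yy <- kym$V * (tt - t0)
  keep <- yy <= max(kym$y) + 1e-9
  tt <- tt[keep]; yy <- yy[keep]
  it <- match(tt, kym$t)
  cb <- vapply(seq_along(tt), function(k) {
    stats::approx(kym$y, kym$CB[, it[k]], xout = yy[k], rule = 2)$y
  }, numeric(1))
  data.frame(t = tt, y = yy, CB = cb)
}

#' Synthetic actin density profiles (plateau + trailing-edge collapse)
#'
#' A(y) = A0 * logistic plateau collapsing over a width `drop_width` ending at
#' y = L, times multiplicative lognormal noise; A = 0 beyond L. The noiseless
#' profile stays within 1% of A0 over the first 80% of the length.
#'
#' @param A0 plateau density (uM)
#' @param L profile length (um)
#' @param drop_width width of the trailing-edge collapse (um); default 10% of L
#' @param noise_sd lognormal sdlog of the multiplicative noise
#' @param n number of profiles
#' @param seed RNG seed
#' @param dy sampling step (um)
#' @return object of class `density_profiles`: grid `y` and matrix `A`
#'   (n rows)
#' @export
gen_density_profiles <- function(A0 = 50, L = 40, drop_width = 0.1 * L,
                                 noise_sd = 0, n = 1, seed = 1, dy = 0.5) {
  if (drop_width >= L) stop("drop width must be smaller than L", call. = FALSE)
  set.seed(seed)
  y <- seq(0, 1.2 * L, by = dy)
  yc <- L - drop_width / 2
  sc <- drop_width / 8
  base <- A0 * (1 - stats::plogis((y - yc) / sc))
  base[y > L] <- 0
  A <- t(vapply(seq_len(n), function(i) {
    if (noise_sd > 0)
      base * stats::rlnorm(length(base), 0, noise_sd) else base
  }, numeric(length(y))))
  out <- structure(list(y = y, A = A, A0 = A0, L = L,
                        drop_width = drop_width, noise_sd = noise_sd),
                   class = "density_profiles")
  with_provenance(out, "gen_density_profiles",
                  list(A0 = A0, L = L, drop_width = drop_width,
                       noise_sd = noise_sd, n = n), seed)
}

#' Turn one generated density profile into an `actin_profile`
#' @param profiles a `density_profiles`
#' @param i row index
#' @return an [actin_profile()] with a tabulated interpolating function
#' @export
as_actin_profile <- function(profiles, i = 1) {
  stopifnot(inherits(profiles, "density_profiles"))
  f <- stats::approxfun(profiles$y, profiles$A[i, ], rule = 2)
  actin_profile(A0 = profiles$A[i, 1], profile = f)
}

#' Synthetic equilibrium-length records
#'
#' Records (L, V, A0, CB) obeying L = cL * V * A0^alpha / CB^beta times
#' multiplicative lognormal noise, with condition labels spanning the
#' experimental design: C0 in {125, 250, 400, 500} nM, widths {15, 30, 90}
#' um, and three density classes (low/medium/high, A0 ~ 30/50/80 uM with
#' 10% spread). Growth speeds increase weakly with density (~1 um/min scale);
#' CB is log-uniform on [0.1, 2] uM, matching the measured spread of
#' network-averaged bound cofilin.
#'
#' @param n number of records (>= 10)
#' @param alpha,beta true exponents
#' @param noise_sd lognormal sdlog of the length noise (0.1 = "10% noise")
#' @param cL prefactor (units so L is in um); default 0.2 puts lengths in the
#'   observed tens-of-um range
#' @param seed RNG seed
#' @return data.frame of class `length_table`: L, V, A0, CB, C0, W,
#'   density_class
#' @export
gen_length_table <- function(n = 50, alpha = 2, beta = 1, noise_sd = 0.1,
                             cL = 0.2, seed = 1) {
  if (n < 10) stop("need n >= 10 records", call. = FALSE)
  set.seed(seed)
  classes <- c(low = 30, medium = 50, high = 80)
  cls <- sample(names(classes), n, replace = TRUE)
  A0 <- classes[cls] * stats::rlnorm(n, 0, 0.1)
  V <- per_min(0.8 + 0.008 * A0) * stats::rlnorm(n, 0, 0.05)
  CB <- exp(stats::runif(n, log(0.1), log(2)))
  C0 <- sample(c(0.125, 0.25, 0.4, 0.5), n, replace = TRUE)
  W <- sample(c(15, 30, 90), n, replace = TRUE)
  L <- cL * V * A0^alpha / CB^beta *
    (if (noise_sd > 0) stats::rlnorm(n, 0, noise_sd) else 1)
  out <- data.frame(L = L, V = V, A0 = A0, CB = CB, C0 = C0, W = W,
                    density_class = cls)
  class(out) <- c("length_table", "data.frame")
  with_provenance(out, "gen_length_table",
                  list(n = n, alpha = alpha, beta = beta,
                       noise_sd = noise_sd, cL = cL), seed)
}

#' Synthetic initial-binding-slope records
#'
#' Initial kymograph slopes rB*C0*A times multiplicative lognormal noise,
#' over the experimental spread of concentrations and density classes. The
#' default noise level is calibrated (see [calibrate_binding_noise()]) so the
#' Pearson correlation between slope and the product C0*A sits in the
#' moderate-correlation regime (~0.5) the measurements show.
#'
#' @param n number of records (>= 10)
#' @param rB binding rate constant (1/(s*uM))
#' @param noise_sd lognormal sdlog of the slope noise
#' @param seed RNG seed
#' @return data.frame of class `binding_table`: slope (uM/s), C0 (uM), A (uM)
#' @export
gen_binding_table <- function(n = 60, rB = per_min(0.5), noise_sd = 0.82,
                              seed = 1) {
  if (n < 10) stop("need n >= 10 records", call. = FALSE)
  if (noise_sd < 0) stop("noise sd must be nonnegative", call. = FALSE)
  set.seed(seed)
  classes <- c(low = 30, medium = 50, high = 80)
  A <- classes[sample(3, n, replace = TRUE)] * stats::rlnorm(n, 0, 0.1)
  C0 <- sample(c(0.125, 0.25, 0.4, 0.5), n, replace = TRUE)
  slope <- rB * C0 * A *
    (if (noise_sd > 0) stats::rlnorm(n, 0, noise_sd) else 1)
  out <- data.frame(slope = slope, C0 = C0, A = A)
  class(out) <- c("binding_table", "data.frame")
  with_provenance(out, "gen_binding_table",
                  list(n = n, rB = rB, noise_sd = noise_sd), seed)
}

#' Calibrate the binding-slope noise level to a target correlation
#'
#' Finds the lognormal sdlog at which the mean (over seeds) Pearson
#' correlation between slope and C0*A equals `target_R`.
#'
#' @param target_R target correlation
#' @param n records per table
#' @param n_seeds seeds averaged per candidate noise level
#' @return calibrated sdlog
#' @export
calibrate_binding_noise <- function(target_R = 0.51, n = 60, n_seeds = 40) {
  mean_R <- function(sd) {
    mean(vapply(seq_len(n_seeds), function(s) {
      tab <- gen_binding_table(n = n, noise_sd = sd, seed = 10000 + s)
      stats::cor(tab$slope, tab$C0 * tab$A)
    }, numeric(1)))
  }
  stats::uniroot(function(sd) mean_R(sd) - target_R,
                 lower = 0.2, upper = 4, tol = 1e-3)$root
}

#' Write a generated object's provenance sidecar
#' @param x object carrying a provenance attribute
#' @param path output JSON path
#' @export
write_provenance <- function(x, path) {
  pv <- attr(x, "provenance")
  if (is.null(pv)) stop("object carries no provenance", call. = FALSE)
  jsonlite::write_json(pv, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
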