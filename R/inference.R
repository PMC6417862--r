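## Inference procedures mirroring the data analysis: initial-binding-slope
## estimation along kymograph material paths, the slope-vs-(C0*A)
## correlation, and exponent fitting of the equilibrium-length power law.

#' Initial binding slopes along kymograph material paths
#'
#' For each start time t0, extracts the material path y = V*(t - t0) and fits
#' an ordinary least-squares line to CB over the initial window. Under local
#' depletion the slopes decrease with start time; without depletion they are
#' flat.
#'
#' @param kym a `kymograph`
#' @param start_times vector of t0 (s)
#' @param window initial-window length (s); default the first 20% of each
#'   path's duration
#' @param normalize divide slopes by their mean (the "mean one" convention)
#' @return data.frame: t0, slope (uM/s or normalized), se, n_points
#' @export
estimate_initial_slopes <- function(kym, start_times, window = NULL,
                                    normalize = FALSE) {
  stopifnot(inherits(kym, "kymograph"))
  res <- lapply(start_times, function(t0) {
    p <- kymo_path(kym, t0)
    if (nrow(p) < 3) stop("path starting at ", t0, " has fewer than 3 frames",
                          call. = FALSE)
    w <- if (is.null(window)) 0.2 * (max(p$t) - min(p$t)) else window
    p <- p[p$t <= min(p$t) + w + 1e-9, , drop = FALSE]
    if (nrow(p) < 3)
      stop("initial window shorter than 3 samples for t0 = ", t0,
           call. = FALSE)
    fit <- stats::lm(CB ~ t, data = p)
    ## slope SE computed directly (summary.lm warns on noiseless fits)
    rss <- sum(stats::residuals(fit)^2)
    sxx <- sum((p$t - mean(p$t))^2)
    se <- sqrt(rss / (nrow(p) - 2) / sxx)
    data.frame(t0 = t0, slope = stats::coef(fit)[["t"]], se = se,
               n_points = nrow(p))
  })
  out <- do.call(rbind, res)
  if (normalize) {
    m <- mean(out$slope)
    out$slope <- out$slope / m
    out$se <- out$se / m
  }
  rownames(out) <- NULL
  out
}

#' Correlation between initial binding slope and C0*A
#'
#' @param table data.frame with columns slope, C0, A (e.g. from
#'   [gen_binding_table()] or read from file)
#' @return list with `R` (Pearson), `p` (two-sided), `n`
#' @export
correlate_binding_rate <- function(table) {
  stopifnot(all(c("slope", "C0", "A") %in% names(table)), nrow(table) >= 3)
  x <- table$C0 * table$A
  if (stats::sd(x) == 0 || stats::sd(table$slope) == 0)
    stop("zero-variance input", call. = FALSE)
  ct <- stats::cor.test(table$slope, x)
  list(R = unname(ct$estimate), p = ct$p.value, n = nrow(table))
}

#' Fit the equilibrium-length power law L = c * V * A0^alpha / CB^beta
#'
#' Least squares in log space: log(L/V) regressed on log A0 and log CB.
#' `alpha_hat` is the A0 coefficient, `beta_hat` the negated CB coefficient.
#' With `fixed = c(alpha, beta)` only the prefactor is fitted and R-squared of
#' the predicted vs observed (log) lengths is reported — the robustness check
#' over the exponent grid.
#'
#' @param table data.frame with positive columns L, V, A0, CB (>= 5 rows)
#' @param fixed optional c(alpha, beta) for fixed-exponent mode
#' @return object of class `exponent_fit`: alpha_hat, beta_hat, their 95%
#'   confidence intervals, prefactor, R2, p_value, condition-number
#'   diagnostic
#' @export
fit_exponents <- function(table, fixed = NULL) {
  stopifnot(all(c("L", "V", "A0", "CB") %in% names(table)))
  if (nrow(table) < 5) stop("need at least 5 records", call. = FALSE)
  if (any(table$L <= 0 | table$V <= 0 | table$A0 <= 0 | table$CB <= 0))
    stop("all of L, V, A0, CB must be positive", call. = FALSE)
  y <- log(table$L / table$V)
  la <- log(table$A0); lc <- log(table$CB)
  if (is.null(fixed)) {
    X <- cbind(1, la, lc)
    kap <- kappa(scale(X[, -1], scale = FALSE), exact = TRUE)
    collinear <- !is.finite(kap) || kap > 1e6
    fit <- stats::lm(y ~ la + lc)
    ci <- stats::confint(fit)
    sm <- summary(fit)
    fstat <- sm$fstatistic
    structure(list(
      alpha_hat = unname(stats::coef(fit)["la"]),
      beta_hat = -unname(stats::coef(fit)["lc"]),
      alpha_ci = unname(ci["la", ]),
      beta_ci = -unname(ci["lc", c(2, 1)]),
      prefactor = exp(unname(stats::coef(fit)[1])),
      R2 = sm$r.squared,
      p_value = stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
      collinear = collinear, condition_number = kap,
      fixed = FALSE), class = "exponent_fit")
  } else {
    stopifnot(length(fixed) == 2)
    x <- fixed[1] * la - fixed[2] * lc
    logc <- mean(y - x)
    resid <- y - x - logc
    R2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
    structure(list(alpha_hat = fixed[1], beta_hat = fixed[2],
                   prefactor = exp(logc), R2 = R2, fixed = TRUE),
              class = "exponent_fit")
  }
}

#' R-squared surface of the fixed-exponent length law over an exponent grid
#'
#' @param table a length table
#' @param alphas,betas grids of exponents
#' @return matrix of fixed-exponent R2, rows = alphas, cols = betas
#' @export
exponent_r2_surface <- function(table, alphas = seq(1, 3, by = 0.25),
                                betas = seq(0.5, 1.2, by = 0.1)) {
  outer(alphas, betas, Vectorize(function(a, b)
    fit_exponents(table, fixed = c(a, b))$R2))
}
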