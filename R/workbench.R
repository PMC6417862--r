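## Configuration, scenario runner and run comparison.
##
## Canonical units everywhere: uM, um, s. Scenario configs that quote rates
## per minute (as the figure captions do) must convert with per_min() before
## they reach the models; `run_scenario()` configs are already canonical.

.scenarios <- c("fig3c", "kymograph", "fragmentation_sweep", "feedback_curves",
                "phase_map_C0_A0", "phase_map_W_A0", "steering_shapes",
                "binding_table", "length_table")

#' Read and validate a run configuration
#'
#' @param config a named list, or path to a YAML/JSON file with fields
#'   `scenario` (one of the known scenarios), `seed` (integer), `outdir`,
#'   and optional `params` (scenario parameters, canonical units). Unknown
#'   top-level keys are rejected.
#' @return validated config list of class `run_config`
#' @export
read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  allowed <- c("scenario", "seed", "outdir", "params")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(config$scenario) || !config$scenario %in% .scenarios)
    stop("`scenario` must be one of: ", paste(.scenarios, collapse = ", "),
         call. = FALSE)
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$outdir)) stop("`outdir` is required", call. = FALSE)
  if (is.null(config$params)) config$params <- list()
  structure(config, class = "run_config")
}

write_csv0 <- function(df, path) utils::write.csv(df, path, row.names = FALSE)

#' Execute a named scenario and write its result bundle
#'
#' Runs the stage(s) named by the config and writes CSV outputs plus a
#' `provenance.json` sidecar (scenario, parameters, seed, package version)
#' sufficient to re-execute the run. Reruns with the same config reproduce
#' all CSV outputs byte-for-byte.
#'
#' @param config a `run_config`, list, or path (see [read_run_config()])
#' @return invisibly, the vector of files written
#' @export
run_scenario <- function(config) {
  cfg <- read_run_config(config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  p <- cfg$params
  gp <- function(name, default) if (is.null(p[[name]])) default else p[[name]]
  files <- character(0)
  out <- function(name) {
    f <- file.path(cfg$outdir, name); files <<- c(files, f); f
  }
  set.seed(cfg$seed)

  if (cfg$scenario == "fig3c") {
    kin <- cofilin_kinetics(C0 = gp("C0", 0.125), D = gp("D", 10),
                            rB = gp("rB", per_min(0.5)),
                            rU = gp("rU", per_min(0.31)))
    geo <- network_geometry(W = gp("W", 30), V = gp("V", per_min(1.16)))
    sim <- simulate_chamber(kin, geo, actin_profile(gp("A", 50)),
                            t_end = gp("t_end", 2400),
                            domain = gp("domain", c(300, 300)),
                            h = gp("h", 2), dt = gp("dt", 0.5),
                            output_times = gp("output_times",
                                              seq(300, 2400, by = 300)))
    last <- sim$snapshots[[length(sim$snapshots)]]
    write_csv0(as.data.frame(last$CF), out("CF_final.csv"))
    write_csv0(as.data.frame(last$CB), out("CB_final.csv"))
    write_csv0(depletion_timecourse(sim), out("depletion_timecourse.csv"))
    write_csv0(data.frame(max_depletion_pct = max_depletion(sim)),
               out("summary.csv"))
  } else if (cfg$scenario == "kymograph") {
    kym <- gen_kymograph(t_end = gp("t_end", 2400),
                         noise_sd = gp("noise_sd", 0),
                         seed = cfg$seed, depletion = gp("depletion", TRUE))
    write_csv0(data.frame(y = kym$y, kym$CB), out("kymograph.csv"))
  } else if (cfg$scenario == "fragmentation_sweep") {
    A0s <- gp("A0", c(35, 50, 70))
    res <- lapply(A0s, function(A) {
      run_to_equilibrium(gp("W", 30), gp("V", per_min(1.16)), A,
                         gp("CB", 0.5), T = gp("T", 8000), seed = cfg$seed)
    })
    write_csv0(data.frame(
      A0 = A0s,
      L_mean = vapply(res, `[[`, numeric(1), "L_mean"),
      L_sd = vapply(res, `[[`, numeric(1), "L_sd")), out("sweep.csv"))
  } else if (cfg$scenario == "feedback_curves") {
    L <- gp("L", seq(1, 120, by = 1))
    fc <- feedback_curves(L, gp("A0", 50), gp("V", per_min(1.16)),
                          gp("C0", 0.25), gp("W", 30))
    write_csv0(fc, out("curves.csv"))
  } else if (cfg$scenario %in% c("phase_map_C0_A0", "phase_map_W_A0")) {
    vary <- if (cfg$scenario == "phase_map_C0_A0") "C0_A0" else "W_A0"
    g1 <- gp("grid1", if (vary == "C0_A0")
      seq(0.05, 0.5, length.out = 20) else seq(10, 90, length.out = 20))
    g2 <- gp("grid2", seq(20, 90, length.out = 20))
    m <- length_phase_map(vary, g1, g2)
    write_csv0(cbind(data.frame(p1 = g1), as.data.frame(m)),
               out("phase_map.csv"))
  } else if (cfg$scenario == "steering_shapes") {
    sh <- heterogeneous_shape(gp("A1", 30), gp("A2", 60),
                              gp("V1", per_min(0.8)), gp("V2", per_min(1.6)),
                              W = gp("W", 15), L1 = gp("L1", Inf),
                              L2 = gp("L2", Inf),
                              L_total = gp("L_total", 60),
                              tau = gp("tau", 2.5))
    write_csv0(sh$centerline, out("centerline.csv"))
    write_csv0(data.frame(direction = sh$direction, Vh = sh$Vh,
                          avg_curvature_radius = sh$avg_curvature_radius),
               out("summary.csv"))
  } else if (cfg$scenario == "binding_table") {
    tab <- gen_binding_table(n = gp("n", 60), seed = cfg$seed)
    write_csv0(tab, out("binding_table.csv"))
    ct <- correlate_binding_rate(tab)
    write_csv0(data.frame(R = ct$R, p = ct$p, n = ct$n), out("correlation.csv"))
  } else if (cfg$scenario == "length_table") {
    tab <- gen_length_table(n = gp("n", 50), noise_sd = gp("noise_sd", 0.1),
                            seed = cfg$seed)
    write_csv0(tab, out("length_table.csv"))
    fit <- fit_exponents(tab)
    write_csv0(data.frame(alpha_hat = fit$alpha_hat, beta_hat = fit$beta_hat,
                          R2 = fit$R2), out("fit.csv"))
  }

  jsonlite::write_json(
    list(scenario = cfg$scenario, params = p, seed = cfg$seed,
         version = gen_version()),
    file.path(cfg$outdir, "provenance.json"),
    auto_unbox = TRUE, digits = NA, null = "null")
  files <- c(files, file.path(cfg$outdir, "provenance.json"))
  invisible(files)
}

#' Compare two scenario result bundles numerically
#'
#' @param dir_a,dir_b bundle directories sharing a scenario
#' @param tol absolute numeric tolerance per value
#' @return data.frame: file, max_abs_diff, within_tol; files present in only
#'   one bundle raise an error (schema mismatch)
#' @export
compare_runs <- function(dir_a, dir_b, tol = 0) {
  fa <- sort(list.files(dir_a, pattern = "\\.csv$"))
  fb <- sort(list.files(dir_b, pattern = "\\.csv$"))
  if (!identical(fa, fb))
    stop("schema mismatch: bundles contain different files", call. = FALSE)
  pa <- jsonlite::read_json(file.path(dir_a, "provenance.json"))
  pb <- jsonlite::read_json(file.path(dir_b, "provenance.json"))
  if (!identical(pa$scenario, pb$scenario))
    stop("bundles come from different scenarios", call. = FALSE)
  res <- lapply(fa, function(f) {
    a <- utils::read.csv(file.path(dir_a, f))
    b <- utils::read.csv(file.path(dir_b, f))
    if (!identical(dim(a), dim(b)) || !identical(names(a), names(b)))
      stop("schema mismatch in ", f, call. = FALSE)
    num <- vapply(a, is.numeric, logical(1))
    d <- if (any(num)) {
      max(abs(as.matrix(a[, num, drop = FALSE]) -
                as.matrix(b[, num, drop = FALSE])), 0)
    } else 0
    same_chr <- identical(a[, !num, drop = FALSE], b[, !num, drop = FALSE])
    data.frame(file = f, max_abs_diff = d,
               within_tol = d <= tol && same_chr)
  })
  do.call(rbind, res)
}
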