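#' Global growth parameters of the four reference conditions
#'
#' The inferred global diffusion-model parameters for the four growth
#' environments of the reference yeast colony-array experiment (glucose or
#' galactose, with or without 1 M NaCl): maximum growth rate `r0` and
#' physiological-state change rate `m` per 20-minute step, diffusivity in
#' cm^2/s, consumption rates `nu1`, `nu2` and coupling shape `K`, `kappa`
#' (resource units are arbitrary, with `s0 = 1`).
#'
#' @return Data frame with columns `condition`, `r0`, `m`, `D_cm2_s`, `nu1`,
#'   `nu2`, `K`, `kappa`.
#' @export
growth_param_table <- function() {
  data.frame(
    condition = c("Glc", "Glc+NaCl", "Gal", "Gal+NaCl"),
    r0 = c(0.119, 0.052, 0.078, 0.040),
    m = c(0.417, 0.288, 0.229, 0.138),
    D_cm2_s = c(3.60e-6, 4.33e-6, 5.15e-6, 3.79e-6),
    nu1 = c(1.16e-5, 7.63e-6, 5.56e-6, 2.65e-6),
    nu2 = c(7.05e-8, 1.46e-7, 4.09e-8, 2.39e-8),
    K = c(16.781, 16.599, 6.158, 4.774),
    kappa = c(0.007, 0.007, 0.032, 0.083))
}

#' Scenario configuration for synthetic plates
#'
#' Describes one synthetic growth experiment: the reference condition whose
#' global parameters drive the forward simulator, the statistical structure of
#' the initial population sizes and physiological states (log-normal with
#' row/column pre-culture effects, emulating plates pinned from a shared
#' pre-culture), the occupancy pattern, and optional observation noise.
#'
#' @param condition One of the [growth_param_table()] conditions.
#' @param n_rows,n_cols,pad_layers,n_times Grid and series dimensions
#'   (defaults: full 32 x 48 plate, 3 padding layers, 218 samples).
#' @param N0_mean Mean initial population size (default 1e4, arbitrary
#'   calibrated units).
#' @param N0_cv Coefficient of variation of the i.i.d. component of `N0`
#'   (default 0.15).
#' @param N0_row_amp,N0_col_amp Standard deviation of log-scale row/column
#'   effects on `N0` (default 0.2 each).
#' @param c_mean Mean physiological state (default 0.01, i.e. a lag of
#'   roughly `log(1/c)/m` steps).
#' @param c_cv Coefficient of variation of the smooth spatial component of
#'   `c` (default 0.5).
#' @param c_row_amp,c_col_amp Log-scale row/column effects on `c`
#'   (default 0.3 each).
#' @param c_smoothness Half-width (cells) of the box smoothing applied to the
#'   spatial noise of `c` (default 2).
#' @param c_model `"spatial"` (default) or `"plate_mean"` (all colonies share
#'   the plate-mean state, removing state-driven variability).
#' @param occupancy `"full"`, `"every_fourth"` (only the bottom-right cell of
#'   each 2 x 2 block carries a colony), or a logical matrix.
#' @param noise_sd Multiplicative log-normal observation noise s.d. on `N`
#'   (default 0: inference targets noiseless recovery).
#' @param fine_substeps Euler substeps per sample in the simulator
#'   (default 10, i.e. 2-minute integration steps).
#' @param coupling Coupling form passed to the simulator.
#' @param overrides Named list of global-parameter overrides (e.g.
#'   `list(D = 0)`), applied after the condition lookup.
#' @param seed Integer RNG seed; a fixed seed reproduces the dataset exactly.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(condition = "Glc", n_rows = 32L, n_cols = 48L,
                            pad_layers = 3L, n_times = 218L,
                            N0_mean = 1e4, N0_cv = 0.15,
                            N0_row_amp = 0.2, N0_col_amp = 0.2,
                            c_mean = 0.01, c_cv = 0.5,
                            c_row_amp = 0.3, c_col_amp = 0.3,
                            c_smoothness = 2L, c_model = "spatial",
                            occupancy = "full", noise_sd = 0,
                            fine_substeps = 10L, coupling = "sigmoid",
                            overrides = list(), seed = 0L) {
  if (!condition %in% growth_param_table()$condition)
    stop("unknown condition: ", condition)
  if (N0_cv < 0 || c_cv < 0 || noise_sd < 0) stop("dispersions must be >= 0")
  if (!(is.matrix(occupancy) || occupancy %in% c("full", "every_fourth")))
    stop("occupancy must be 'full', 'every_fourth' or a logical matrix")
  structure(as.list(environment()), class = "scenario_config")
}

# Box-smooth a matrix (normalised by local counts), `times` passes.
.smooth_matrix <- function(m, times = 1L) {
  if (times < 1L) return(m)
  ones <- matrix(1, nrow(m), ncol(m))
  box <- function(x) {
    nr <- nrow(x); nc <- ncol(x)
    v <- x + rbind(0, x[-nr, , drop = FALSE]) + rbind(x[-1, , drop = FALSE], 0)
    v + cbind(0, v[, -nc, drop = FALSE]) + cbind(v[, -1, drop = FALSE], 0)
  }
  num <- m; den <- ones
  for (i in seq_len(times)) { num <- box(num); den <- box(den) }
  num / den
}

#' Generate initial-condition fields for a synthetic plate
#'
#' Draws the initial population sizes and physiological states with the
#' structure the analysis assumes: log-normal values with additive log-scale
#' row and column effects (pre-culture structure shared along rows/columns)
#' plus i.i.d. (for `N0`) or spatially smoothed (for `c`) noise. Setting all
#' dispersion parameters to zero yields uniform fields.
#'
#' @param config A [scenario_config()].
#' @return List with matrices `N0` (0 on unoccupied cells), `c` (`NA` on
#'   unoccupied cells) and logical `occupancy`.
#' @export
generate_initial_fields <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  nr <- config$n_rows; nc <- config$n_cols
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)
  occ <- if (is.matrix(config$occupancy)) {
    if (!all(dim(config$occupancy) == c(nr, nc)))
      stop("occupancy mask does not match the grid")
    config$occupancy
  } else if (config$occupancy == "every_fourth") {
    outer(seq_len(nr) %% 2L == 0L, seq_len(nc) %% 2L == 0L, `&`)
  } else matrix(TRUE, nr, nc)

  lognorm_field <- function(mean, cv, row_amp, col_amp, smooth = 0L) {
    sdlog <- sqrt(log(1 + cv^2))
    z <- matrix(stats::rnorm(nr * nc), nr, nc)
    if (smooth > 0L) {
      z <- .smooth_matrix(z, smooth)
      zsd <- stats::sd(z)
      if (zsd > 0) z <- z / zsd
    }
    re <- stats::rnorm(nr, 0, row_amp)
    ce <- stats::rnorm(nc, 0, col_amp)
    mean * exp(sdlog * z - sdlog^2 / 2 + outer(re, ce, `+`))
  }

  N0 <- lognorm_field(config$N0_mean, config$N0_cv,
                      config$N0_row_amp, config$N0_col_amp)
  cfield <- if (identical(config$c_model, "plate_mean")) {
    matrix(config$c_mean, nr, nc)
  } else {
    lognorm_field(config$c_mean, config$c_cv, config$c_row_amp,
                  config$c_col_amp, smooth = config$c_smoothness)
  }
  N0[!occ] <- 0
  cfield[!occ] <- NA_real_
  list(N0 = N0, c = cfield, occupancy = occ)
}

#' Generate a synthetic plate from a reference condition
#'
#' Looks up the condition's global parameters, draws the initial fields, runs
#' the forward simulator on the padded lattice, and (optionally) applies
#' multiplicative log-normal observation noise. The ground-truth record
#' returned alongside the plate suffices to regenerate the dataset exactly.
#'
#' @param config A [scenario_config()].
#' @return List with `plate` (a [plate_series()]), `truth` (list with the
#'   `diffusion_params` used, `N0`, `c`, `occupancy`, `config`) and
#'   `resource` (the simulated `resource_field`).
#' @export
generate_plate <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  geometry <- plate_geometry(config$n_rows, config$n_cols,
                             pad_layers = config$pad_layers)
  tab <- growth_param_table()
  row <- tab[tab$condition == config$condition, ]
  pars <- list(r0 = row$r0, m = row$m,
               D = lattice_diffusivity(row$D_cm2_s, geometry),
               nu1 = row$nu1, nu2 = row$nu2, K = row$K, kappa = row$kappa)
  for (nm in names(config$overrides)) pars[[nm]] <- config$overrides[[nm]]
  fields <- generate_initial_fields(config)
  params <- diffusion_params(pars$r0, pars$m, fields$c, pars$D, pars$nu1,
                             pars$nu2, pars$K, pars$kappa)
  sim <- simulate_plate(params, fields$N0, geometry,
                        n_times = config$n_times,
                        fine_substeps = config$fine_substeps,
                        coupling = config$coupling,
                        condition = config$condition,
                        return_resource = TRUE)
  plate <- sim$plate
  if (config$noise_sd > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(config$seed + 1L)
    noise <- array(stats::rnorm(length(plate$N), 0, config$noise_sd),
                   dim = dim(plate$N))
    plate$N <- plate$N * exp(noise)
  }
  list(plate = plate,
       truth = list(params = params, N0 = fields$N0, c = fields$c,
                    occupancy = fields$occupancy, config = config),
       resource = sim$resource)
}

#' Generate the standard 4-condition plate bundle
#'
#' Simulates one plate per condition in the canonical stacking order
#' (galactose + NaCl, glucose, glucose + NaCl, galactose) and returns them as
#' a rank-4 array `[4 x rows x cols x T]`, the layout of the reference
#' platform's exported data.
#'
#' @param seed Base seed; plate `i` uses `seed + i - 1`.
#' @param ... Further arguments passed to [scenario_config()].
#' @return List with `array` (rank-4) and `conditions`.
#' @export
generate_condition_bundle <- function(seed = 0L, ...) {
  conds <- default_conditions()
  plates <- lapply(seq_along(conds), function(i) {
    cfg <- scenario_config(condition = conds[i], seed = seed + i - 1L, ...)
    generate_plate(cfg)$plate
  })
  d <- dim(plates[[1]]$N)
  arr <- array(NA_real_, dim = c(length(conds), d))
  for (i in seq_along(plates)) arr[i, , , ] <- plates[[i]]$N
  list(array = arr, conditions = conds)
}

#' Write a suite of small synthetic fixtures
#'
#' Produces a set of mini-plate scenarios covering the behaviours the
#' analysis suite exercises: a baseline glucose mini-plate, a plate-mean
#' physiological-state variant, an every-fourth occupancy variant, a
#' zero-diffusivity variant, and a logistic-limit variant (constant
#' adjustment, linear coupling, no diffusion or maintenance). Each scenario
#' is written as a plate-array CSV plus a JSON ground-truth record.
#'
#' @param outdir Output directory (created if needed).
#' @param n_rows,n_cols,pad_layers Mini-plate dimensions (default 8 x 12,
#'   2 padding layers).
#' @param n_times Samples per curve (default 120 for fast fixtures).
#' @param seed Base seed.
#' @return Invisibly, a data frame listing scenario names and file paths.
#' @export
generate_fixture_suite <- function(outdir, n_rows = 8L, n_cols = 12L,
                                   pad_layers = 2L, n_times = 120L,
                                   seed = 0L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  base <- list(n_rows = n_rows, n_cols = n_cols, pad_layers = pad_layers,
               n_times = n_times, seed = seed)
  scen <- list(
    glc = base,
    glc_plate_mean_c = utils::modifyList(base, list(c_model = "plate_mean")),
    glc_every_fourth = utils::modifyList(base, list(occupancy = "every_fourth")),
    glc_no_diffusion = utils::modifyList(base, list(overrides = list(D = 0))),
    logistic_limit = utils::modifyList(base, list(
      coupling = "linear", c_mean = 1e8, c_cv = 0, c_row_amp = 0, c_col_amp = 0,
      N0_cv = 0, N0_row_amp = 0, N0_col_amp = 0,
      overrides = list(D = 0, nu2 = 0, kappa = 0))))
  files <- lapply(names(scen), function(nm) {
    cfg <- do.call(scenario_config, c(list(condition = "Glc"), scen[[nm]]))
    out <- generate_plate(cfg)
    plate_path <- file.path(outdir, paste0(nm, "_plate.csv"))
    arr <- array(out$plate$N, dim = c(1L, dim(out$plate$N)))
    write_plate_array(arr, plate_path, conditions = out$plate$condition)
    truth_path <- file.path(outdir, paste0(nm, "_truth.json"))
    tr <- out$truth
    jsonlite::write_json(
      list(condition = tr$config$condition, seed = tr$config$seed,
           r0 = tr$params$r0, m = tr$params$m, D = tr$params$D,
           nu1 = tr$params$nu1, nu2 = tr$params$nu2, K = tr$params$K,
           kappa = tr$params$kappa,
           N0 = tr$N0, c = tr$c, occupancy = tr$occupancy * 1L),
      truth_path, auto_unbox = TRUE, digits = NA)
    data.frame(scenario = nm, plate = plate_path, truth = truth_path)
  })
  invisible(do.call(rbind, files))
}
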