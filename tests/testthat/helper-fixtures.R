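# Shared synthetic fixtures, built once per test session and cached.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Baseline glucose mini-plate (8 x 12, 2 padding layers, heterogeneous states).
mini_config <- function(...) {
  args <- utils::modifyList(
    list(condition = "Glc", n_rows = 8L, n_cols = 12L,
         pad_layers = 2L, n_times = 120L, seed = 42L),
    list(...))
  do.call(scenario_config, args)
}

mini_plate <- function() cached("mini", generate_plate(mini_config()))

# Variant with all physiological states set to the plate mean.
mini_plate_mean_c <- function() {
  cached("mini_mean_c", generate_plate(mini_config(c_model = "plate_mean")))
}

# Variant without diffusion.
mini_plate_no_d <- function() {
  cached("mini_no_d", generate_plate(mini_config(overrides = list(D = 0))))
}

# Fully homogeneous colonies (no initial-condition variability).
mini_plate_homog <- function() {
  cached("mini_homog", generate_plate(mini_config(
    N0_cv = 0, N0_row_amp = 0, N0_col_amp = 0,
    c_cv = 0, c_row_amp = 0, c_col_amp = 0)))
}

# Preprocessed rates for the baseline mini-plate (light smoothing: the
# fixtures are noiseless).
mini_rates <- function() {
  cached("mini_rates", {
    out <- mini_plate()
    compute_rates(smooth_series(out$plate, window = 2, drop_tail = 10))
  })
}

mini_alpha <- function() cached("mini_alpha", fit_alpha_two_stage(mini_rates()))

# Synthetic rates drawn directly from the adjustment function (no simulator):
# rho_i(t) = alpha(t; r0, m, c_i), the exact generative model of the
# two-stage fit.
alpha_only_rates <- function(r0 = 0.119, m = 0.417, cvals, n_times = 60L,
                             geometry = plate_geometry(length(cvals), 1L,
                                                       pad_layers = 1L)) {
  tt <- seq_len(n_times)
  rho <- array(NA_real_, dim = c(length(cvals), 1L, n_times))
  for (i in seq_along(cvals))
    rho[i, 1, ] <- baranyi_alpha(tt, r0, m, cvals[i])
  structure(list(dN = rho, rho = rho, N = array(1, dim = dim(rho)),
                 times = tt, geometry = geometry, condition = "synthetic"),
            class = "rate_series", n_masked = 0L)
}
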