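test_that("consumption term combines growth and maintenance linearly", {
  expect_equal(consumption(123, 456, 0, 0), 0)
  expect_equal(consumption(0, 200, 0.5, 0.01), 2)          # constant N
  # glucose parameter set: nu1 dN + nu2 N
  expect_equal(consumption(100, 1e5, 1.16e-5, 7.05e-8),
               1.16e-3 + 7.05e-3, tolerance = 1e-12)
  expect_equal(consumption(100, 1e5, 1.16e-5, 7.05e-8), 8.21e-3,
               tolerance = 1e-4)
})

test_that("coupling function has the stated limits and is numerically stable", {
  expect_equal(coupling_f(c(-3, 0, 2), 5, 0), c(1, 1, 1))      # kappa = 0
  expect_equal(coupling_f(0, 7, 0.4), 2^-0.4, tolerance = 1e-12)
  # glucose shape parameters at the initial concentration: f is ~1
  expect_equal(coupling_f(1, 16.781, 0.007), (1 + exp(-16.781))^-0.007,
               tolerance = 1e-15)
  expect_lt(abs(coupling_f(1, 16.781, 0.007) - 1), 1e-9)
  # monotone increasing in s, bounded by 1, no overflow at extreme arguments
  s <- c(-1e6, -100, -5, 0, 1, 100, 1e6)
  f <- coupling_f(s, 16.781, 0.007)
  expect_true(all(is.finite(f)))
  expect_true(all(diff(f) >= 0))
  expect_true(all(f <= 1 & f >= 0))
  # deep-starvation regime decays like exp(kappa K s)
  expect_equal(log(coupling_f(-20, 16.781, 0.007)),
               0.007 * 16.781 * -20, tolerance = 1e-6)
  expect_equal(coupling_f(0.3, 1, 1, form = "linear"), 0.3)
})

test_that("Moore-neighbourhood mean handles uniform fields, spikes and borders", {
  u <- matrix(4.2, 6, 7)
  expect_equal(mean_field_neighbors(u), u)
  spike <- matrix(0, 5, 5); spike[3, 3] <- 8
  sb <- mean_field_neighbors(spike)
  expect_equal(sb[2:4, 2:4][-5], rep(1, 8))   # the 8 neighbours see h/8
  expect_equal(sb[3, 3], 0)
  # corner cell averages over its 3 existing neighbours
  corner <- matrix(0, 4, 4); corner[1, 2] <- 3
  expect_equal(mean_field_neighbors(corner)[1, 1], 1)
  # torus wrap: averaging is doubly stochastic, total mass is conserved
  set.seed(2)
  z <- matrix(rnorm(30), 5, 6)
  expect_equal(sum(mean_field_neighbors(z, wrap = TRUE)), sum(z),
               tolerance = 1e-12)
})

test_that("Euler resource step: identity, linear decay and stability guard", {
  s <- matrix(runif(12), 3, 4)
  expect_equal(step_resource(s, s * 0, D = 0, dt = 1), s)
  # D = 0, constant consumption g: clipped linear decay
  s1 <- matrix(1, 3, 4)
  for (i in 1:8) s1 <- step_resource(s1, matrix(0.2, 3, 4), D = 0, dt = 1,
                                     clip = TRUE)
  expect_equal(s1, matrix(pmax(0, 1 - 0.2 * 8), 3, 4))
  expect_error(step_resource(s, s * 0, D = 2, dt = 1), "unstable")
})

test_that("fine-step Euler relaxes a cell to its neighbour mean exponentially", {
  # one cell coupled to a frozen neighbour mean: ds/dt = D (sbar - s)
  D <- 0.4; sbar0 <- 2; s0 <- 0.5; dt <- 1e-3
  s <- matrix(s0, 1, 1)
  for (i in seq_len(5 / dt))
    s <- step_resource(s, matrix(0, 1, 1), D, dt = dt,
                       sbar = matrix(sbar0, 1, 1))
  expect_equal(s[1, 1], sbar0 + (s0 - sbar0) * exp(-D * 5), tolerance = 1e-4)
})

test_that("sweep iteration reaches the direct Euler fixed point", {
  rt <- mini_rates()
  par <- list(D = 0.08, nu1 = 1.16e-5, nu2 = 7.05e-8)
  f_direct <- integrate_resource(rt, par, method = "direct")
  f_sweep <- integrate_resource(rt, par, method = "sweep")
  expect_lt(max(abs(f_direct$s - f_sweep$s)), 1e-8)
})

test_that("diffusion-model predictions reduce correctly", {
  rt <- mini_rates()
  ap <- mini_alpha()
  par <- list(D = 0.08, nu1 = 1.16e-5, nu2 = 7.05e-8)
  sf <- integrate_resource(rt, par)
  A <- alpha_field(ap, rt$times)
  # kappa = 0: coupling is 1, prediction is the bare adjustment
  expect_equal(predict_rho_diffusion(ap, sf, K = 5, kappa = 0), A)
  # saturated coupling at s ~ 1: prediction ~ adjustment at early times
  sf0 <- integrate_resource(rt, list(D = 0, nu1 = 0, nu2 = 0))
  pred <- predict_rho_diffusion(ap, sf0, K = 50, kappa = 0.05)
  expect_equal(pred, A, tolerance = 1e-8)
})

test_that("linear coupling with D = 0, nu2 = 0 reduces to the telescoped resource", {
  rt <- mini_rates()
  ap <- mini_alpha()
  nu1 <- 2e-6
  sf <- integrate_resource(rt, list(D = 0, nu1 = nu1, nu2 = 0))
  pred <- predict_rho_diffusion(ap, sf, K = 0, kappa = 0, form = "linear")
  # s telescopes: s(t_k) = 1 - nu1 * sum_{j<k} dN_j, the density-style
  # linear-in-N resource under the observed trajectory
  d <- dim(rt$rho)
  cum <- array(0, dim = d)
  for (k in 2:d[3]) cum[, , k] <- cum[, , k - 1] + rt$dN[, , k - 1]
  expect_equal(pred, alpha_field(ap, rt$times) * (1 - nu1 * cum),
               tolerance = 1e-10)
})

test_that("predictions are gauge invariant under a latent-resource shift", {
  rt <- mini_rates()
  ap <- mini_alpha()
  par <- list(D = 0.08, nu1 = 1.16e-5, nu2 = 7.05e-8)
  base <- predict_rho_diffusion(ap, integrate_resource(rt, par, s0 = 1),
                                K = 16.781, kappa = 0.007)
  for (s_star in c(-2.5, 0.7, 10)) {
    shifted <- predict_rho_diffusion(
      ap, integrate_resource(rt, par, s0 = 1 + s_star),
      K = 16.781, kappa = 0.007, s_star = s_star)
    expect_lt(max(abs(shifted - base), na.rm = TRUE), 1e-12)
  }
})

test_that("torus diffusion conserves total resource without consumption", {
  set.seed(4)
  s <- matrix(rexp(48), 6, 8)
  tot <- sum(s)
  for (i in 1:25) s <- step_resource(s, s * 0, D = 0.6, dt = 1, wrap = TRUE,
                                     sbar = mean_field_neighbors(s, wrap = TRUE))
  expect_equal(sum(s), tot, tolerance = 1e-12)
})

test_that("resource is non-increasing when D = 0 and consumption is non-negative", {
  rt <- mini_rates()
  sf <- integrate_resource(rt, list(D = 0, nu1 = 1e-5, nu2 = 1e-7))
  diffs <- apply(sf$s, c(1, 2), diff)
  expect_true(all(diffs <= 1e-12))
})

test_that("simulator emits the platform series length and padded lattice", {
  out <- mini_plate()
  expect_equal(dim(out$plate$N)[3], 120L)            # configured length
  pd <- padded_dims(out$plate$geometry)
  expect_equal(dim(out$resource$s)[1:2], pd)
  expect_equal(pd, c(8L + 4L, 12L + 4L))
  # default series length matches the 72 h / 20 min protocol
  geom <- plate_geometry(2L, 2L, pad_layers = 1L)
  par <- diffusion_params(0.119, 0.417, matrix(0.01, 2, 2),
                          D = 0.085, nu1 = 1.16e-5, nu2 = 7.05e-8,
                          K = 16.781, kappa = 0.007)
  pl <- simulate_plate(par, matrix(1e4, 2, 2), geom)
  expect_equal(dim(pl$N)[3], 218L)
  expect_equal(pl$times, 0:217)
  # structural check for the full-plate lattice
  expect_equal(padded_dims(plate_geometry()), c(38L, 54L))
})

test_that("without consumption or coupling the simulator is pure lag-adjusted growth", {
  geom <- plate_geometry(2L, 2L, pad_layers = 1L)
  par <- diffusion_params(0.119, 0.417, matrix(0.02, 2, 2),
                          D = 0.085, nu1 = 0, nu2 = 0, K = 16.781, kappa = 0)
  pl <- simulate_plate(par, matrix(1e4, 2, 2), geom, n_times = 80,
                       fine_substeps = 100)
  lnN <- log(pl$N[1, 1, ])
  late_slope <- diff(lnN)[70:79]
  expect_equal(late_slope, rep(0.119, 10), tolerance = 1e-3)
})

test_that("constant adjustment with linear coupling follows the logistic closed form", {
  geom <- plate_geometry(1L, 1L, pad_layers = 1L)
  r0 <- 0.1; nu1 <- 1e-6; N0 <- 1e4
  par <- diffusion_params(r0, 1, matrix(1e12, 1, 1),
                          D = 0, nu1 = nu1, nu2 = 0, K = 0, kappa = 0)
  pl <- simulate_plate(par, matrix(N0, 1, 1), geom, n_times = 150,
                       fine_substeps = 100, coupling = "linear")
  # dN/dt = r0 (1 - nu1 (N - N0)) N: logistic with capacity N0 + 1/nu1
  A <- 1 + nu1 * N0
  tt <- pl$times
  closed <- A * N0 * exp(r0 * A * tt) / (A + nu1 * N0 * (exp(r0 * A * tt) - 1))
  expect_equal(pl$N[1, 1, ], closed, tolerance = 2e-3)
})

test_that("diffusivity unit conversion matches the plate geometry and round-trips", {
  geom <- plate_geometry()
  expect_equal(convert_diffusivity(0.0853, geom), 3.6e-6, tolerance = 1e-3)
  expect_equal(convert_diffusivity(0, geom), 0)
  D <- 0.123
  expect_equal(lattice_diffusivity(convert_diffusivity(D, geom), geom), D,
               tolerance = 1e-12)
})

test_that("fitting a no-diffusion plate drives the fitted diffusivity to zero", {
  out <- mini_plate_no_d()
  rt <- compute_rates(smooth_series(out$plate, window = 2, drop_tail = 10))
  fit <- fit_diffusion(rt, control = list(nm_maxit = 300L, n_starts = 2L,
                                          outer_rounds = 3L))
  expect_lt(fit$params$D, 0.01)
  expect_lt(fit$report$sse_total, 1e-3 * sum(rt$rho^2, na.rm = TRUE))
})
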