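test_that("single Euler step: neutral zero state, exact fixed point, pure leak", {
  w <- weight_profile(b = 3, c = 2)
  cfg <- sim_config(dt = 0.1)
  ## u = 0 with H(0) = 1/2: the drive is the convolution of a constant, 0
  g0 <- ring_grid(256)
  s0 <- state_profile(g0, rep(0, 256))
  expect_equal(ring_step(s0, w, step_gain, 0, cfg)$u, rep(0, 256))
  ## the continuum single-peak equilibrium moves only by the O(1/n)
  ## jump-cell quadrature error of the discrete map, scaled by dt
  disp <- vapply(c(512L, 4096L), function(n) {
    g <- ring_grid(n)
    u_eq <- (3 / pi) * cos(g$theta)
    max(abs(ring_step(state_profile(g, u_eq), w, step_gain, 0, cfg)$u - u_eq))
  }, numeric(1))
  expect_lt(disp[1], 0.1 * 5 / 512)      # dt * max|w| / n
  expect_lt(disp[2], 0.1 * 5 / 4096)
  expect_equal(disp[1] / disp[2], 8, tolerance = 0.2)  # ~1/n scaling
  ## zero kernel: per-step decay by (1 - dt/tau)
  set.seed(1)
  u0 <- rnorm(256)
  s <- state_profile(g0, u0)
  out <- ring_step(s, weight_profile(b = 0, c = 0), step_gain, 0,
                   sim_config(dt = 0.25, tau = 2))
  expect_equal(out$u, u0 * (1 - 0.25 / 2), tolerance = 1e-14)
  expect_equal(out$t, 0.25)
})

test_that("compiled integrator agrees with the pure-R oracle step by step", {
  w <- weight_profile(b = 2, c = -1, a = 0.3, alpha = 0.1)
  gl <- gain_function("logistic", k = 3, u0 = 0.1)
  grid <- ring_grid(64)
  set.seed(2)
  u <- runif(64, -1, 1)
  cfg <- sim_config(dt = 0.05, max_steps = 25L, conv_tol = 1e-15)
  tr <- ring_integrate(state_profile(grid, u), w, gl, 0.2, cfg,
                       record_every = 1L)
  wfun <- function(x) evaluate_weight(w, x)
  gfun <- function(x) evaluate_gain(gl, x)
  for (i in 1:25)
    u <- euler_oracle_step(u, wfun, gfun, 0.05, 1, grid$theta, 0.2)
  expect_equal(tr$states[nrow(tr$states), ], u, tolerance = 1e-11)
  expect_equal(nrow(tr$states), 26L)
  expect_equal(diff(tr$times), rep(0.05, 25), tolerance = 1e-12)
})

test_that("trajectories converge to the bump equilibria from scaled noisy starts", {
  w <- weight_profile(b = 3, c = 2)
  grid <- ring_grid(500)
  cfg <- sim_config(dt = 0.1, max_steps = 5000L)
  s1 <- construct_family("single_peak", 3, 2, theta0 = pi)
  u0 <- make_initial("scaled_equilibrium", grid, scale = 0.1,
                     noise_sigma = 0.01, seed = 42, equilibrium = s1)
  tr <- ring_integrate(u0, w, step_gain, 0, cfg)
  expect_true(tr$converged)
  expect_lt(fitted_family_error(tr$final$u, "single_peak", 3, 2, m = 1), 1e-2)
  ## the bump stays near the seeded phase pi
  expect_lt(abs(fitted_phase(tr$final$u, 1) - pi), 0.1)

  s2 <- construct_family("double_peak", 3, 2, theta0 = pi / 2)
  u0 <- make_initial("scaled_equilibrium", grid, scale = 0.1,
                     noise_sigma = 0.01, seed = 7, equilibrium = s2)
  tr2 <- ring_integrate(u0, w, step_gain, 0, cfg)
  expect_true(tr2$converged)
  expect_lt(fitted_family_error(tr2$final$u, "double_peak", 3, 2, m = 2), 1e-2)
})

test_that("inhibitory kernel (b, c < 0) collapses to the flat state up to the O(dt) band", {
  grid <- ring_grid(500)
  u0 <- make_initial("random", grid, seed = 3)
  tr <- ring_integrate(u0, weight_profile(b = -1, c = -1), step_gain, 0,
                       sim_config(dt = 0.01, max_steps = 20000L))
  ## step-gain chattering leaves an O(dt) band around u = 0
  expect_lt(max(abs(tr$final$u)), 5e-3)
})

test_that("Lyapunov energy: closed-form value at the flat state and argument checks", {
  gl <- gain_function("logistic", k = 2)
  w <- weight_profile(b = 3.5, c = 3.5)
  grid <- ring_grid(128)
  s0 <- state_profile(grid, rep(0, 128))
  expect_equal(lyapunov_energy(s0, w, gl, 0), -pi * log(2), tolerance = 1e-12)
  ## zero kernel: only the entropy term remains, independent of a constant a
  expect_equal(lyapunov_energy(s0, weight_profile(b = 0, c = 0), gl, 0),
               -pi * log(2), tolerance = 1e-12)
  expect_error(lyapunov_energy(s0, w, step_gain, 0),
               class = "hdring_step_energy_error")
  expect_error(lyapunov_energy(s0, weight_profile(b = 1, c = 1, alpha = 0.2),
                               gl, 0), class = "hdring_odd_kernel_error")
})

test_that("energy descends along logistic trajectories and is stationary at fixed points", {
  gl <- gain_function("logistic", k = 2)
  w <- weight_profile(b = 4.5, c = 3.5)
  grid <- ring_grid(50)
  for (seed in 1:3) {
    u0 <- make_initial("random", grid, seed = seed)
    tr <- ring_integrate(u0, w, gl, 0,
                         sim_config(dt = 0.001, max_steps = 8000L),
                         record_every = 1L)
    E <- trajectory_energy(tr, w, gl, 0)
    expect_lte(max(diff(E)), 1e-9)
  }
  ## stationarity: a converged state moves the energy by ~0
  u0 <- make_initial("cosine", grid, seed = 1)
  tr <- ring_integrate(u0, w, gl, 0,
                       sim_config(dt = 0.01, max_steps = 60000L,
                                  conv_tol = 1e-11), record_every = 0L)
  expect_true(tr$converged)
  e1 <- lyapunov_energy(tr$final, w, gl, 0)
  tr2 <- ring_integrate(tr$final, w, gl, 0,
                        sim_config(dt = 0.01, max_steps = 1L,
                                   conv_tol = 1e-30))
  e2 <- lyapunov_energy(tr2$final, w, gl, 0)
  expect_lt(abs(e2 - e1), 1e-15)
})

test_that("asymptotic bound certifies |u| after transients", {
  expect_equal(asymptotic_bound(weight_profile(b = 3, c = 2), step_gain, 0), 5)
  expect_equal(asymptotic_bound(weight_profile(b = 0, c = 0), step_gain, -0.7),
               0.7)
  expect_equal(asymptotic_bound(weight_profile(b = 1, c = 1.5), step_gain, 0),
               2.5)
  ## property: 50 random kernels, random starts up to 10 M, 50 tau of flow
  set.seed(6)
  grid <- ring_grid(64)
  cfg <- sim_config(dt = 0.1, max_steps = 500L, conv_tol = 1e-30)
  for (i in 1:50) {
    b <- runif(1, -5, 5); c <- runif(1, -5, 5)
    w <- weight_profile(b = b, c = c)
    M <- asymptotic_bound(w, step_gain, 0)
    u0 <- state_profile(grid, runif(64, -10 * M, 10 * M))
    tr <- ring_integrate(u0, w, step_gain, 0, cfg)
    expect_lte(max(abs(tr$final$u)), M + 0.05)
  }
})

test_that("harmonics above the kernel order decay as exp(-t/tau)", {
  w <- weight_profile(b = 3, c = 2)
  grid <- ring_grid(64)
  u0 <- 0.5 * cos(grid$theta) + 0.3 * cos(5 * grid$theta)
  a0 <- harmonics(u0, 6)[["5"]]
  tr <- ring_integrate(state_profile(grid, u0), w, step_gain, 0,
                       sim_config(dt = 1e-3, max_steps = 5000L,
                                  conv_tol = 1e-30))
  a5 <- harmonics(tr$final$u, 6)[["5"]]
  expect_equal(Mod(a5) / Mod(a0), exp(-5), tolerance = 0.01)
})

test_that("integration is equivariant under integer-cell rotations", {
  w <- weight_profile(b = 3, c = 2)
  grid <- ring_grid(120)
  u0 <- make_initial("random", grid, seed = 9)$u
  shift <- 17L
  rot <- function(u) u[((seq_along(u) - 1L - shift) %% length(u)) + 1L]
  cfg <- sim_config(dt = 0.1, max_steps = 300L, conv_tol = 1e-30)
  t1 <- ring_integrate(state_profile(grid, u0), w, step_gain, 0, cfg)
  t2 <- ring_integrate(state_profile(grid, rot(u0)), w, step_gain, 0, cfg)
  expect_equal(t2$final$u, rot(t1$final$u), tolerance = 1e-10)
})

test_that("converged states are exact degree-2 trig polynomials (form closure)", {
  w <- weight_profile(b = 3, c = 2)
  grid <- ring_grid(200)
  u0 <- make_initial("random", grid, seed = 10)
  tr <- ring_integrate(u0, w, step_gain, 0,
                       sim_config(dt = 0.1, max_steps = 10000L,
                                  conv_tol = 1e-12))
  expect_true(tr$converged)
  h <- harmonics(tr$final$u, 10)
  high <- h[abs(as.integer(names(h))) > 2]
  expect_lt(max(Mod(high)), 1e-10)
})

test_that("sim_config validates the explicit-Euler constraints", {
  expect_error(sim_config(dt = 1.5, tau = 1), "dt < tau")
  expect_error(sim_config(conv_tol = 0))
  expect_silent(sim_config(dt = 0.5, tau = 1))
})
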