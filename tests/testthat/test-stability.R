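test_that("circulant weight eigenvalues: closed form, discrete sum, dense eigen", {
  w <- weight_profile(b = 3, c = 2)
  expect_equal(unname(weight_mode_eigenvalues(w, 0:3)), c(0, 1.5, 1, 0))
  expect_equal(unname(weight_mode_eigenvalues(w, 0:3, n = 500)),
               c(0, 1.5, 1, 0), tolerance = 1e-10)
  expect_equal(unname(weight_mode_eigenvalues(weight_profile(b = 0, c = 0),
                                              0:4)), rep(0, 5))
  expect_equal(unname(weight_mode_eigenvalues(weight_profile(a = 2, b = 0,
                                                             c = 0), 0:3)),
               c(2, 0, 0, 0))
  ## dense eigen-decomposition: each harmonic eigenvalue is doubly degenerate
  grid <- ring_grid(500)
  W <- hdring:::weight_matrix(w, grid) / 500
  ev <- sort(Re(eigen(W, only.values = TRUE)$values), decreasing = TRUE)
  expect_equal(ev[1:4], c(1.5, 1.5, 1, 1), tolerance = 1e-10)
  expect_lt(max(abs(ev[-(1:4)])), 1e-10)
  expect_error(weight_mode_eigenvalues(weight_profile(b = 1, c = 1,
                                                      alpha = 0.1), 0:2),
               class = "hdring_odd_kernel_error")
})

test_that("delta-sum g-coefficients match the closed-form values", {
  gs <- g_coefficients(construct_family("single_peak", 3, 2))
  expect_equal(Re(gs$g22), -1 / 3, tolerance = 1e-12)
  expect_equal(Re(gs$g33), 1 / 3, tolerance = 1e-12)
  expect_lt(Mod(gs$g23), 1e-12)

  gd <- g_coefficients(construct_family("double_peak", 3, 2))
  expect_equal(Re(gd$g22), 0, tolerance = 1e-12)
  expect_equal(Re(gd$g33), -1 / 2, tolerance = 1e-12)
  expect_lt(Mod(gd$g23), 1e-12)

  ## mixed family rational forms at (b, c) = (1, 1.5):
  ## g22 = -2b/(2c^2+bc-b^2), g33 = (4b^2-2c^2)/((2c^2+bc-b^2) c)
  b <- 1; c <- 1.5
  den <- 2 * c^2 + b * c - b^2
  gm <- g_coefficients(construct_family("mixed_plus", b, c))
  expect_equal(Re(gm$g22), -2 * b / den, tolerance = 1e-8)
  expect_equal(Re(gm$g33), (4 * b^2 - 2 * c^2) / (den * c), tolerance = 1e-8)

  expect_error(g_coefficients(construct_family("flat", 3, 2)),
               class = "hdring_flat_state_error")
})

test_that("delta sums are the steep-sigmoid limit of the quadrature path", {
  for (fam in c("single_peak", "double_peak")) {
    sol <- construct_family(fam, 3, 2)
    gd <- g_coefficients(sol)
    gq <- g_coefficients(sol, gain_function("logistic", k = 1e4))
    for (nm in c("g22", "g33")) {
      ref <- Re(gd[[nm]])
      if (abs(ref) > 1e-9)
        expect_lt(abs(Re(gq[[nm]]) - ref) / abs(ref), 0.01)
      else expect_lt(abs(Re(gq[[nm]])), 1e-3)
    }
  }
})

test_that("characteristic-polynomial reduction reproduces the closed-form spectra", {
  gs <- g_coefficients(construct_family("single_peak", 3, 2))
  sp <- jacobian_spectrum(3, 2, gs, n = 500)
  expect_equal(sort(Re(sp$special)), sort(c(-1.5, -1 + 2 / 6)),
               tolerance = 1e-10)
  expect_equal(sp$bulk, -1)
  expect_equal(sp$bulk_multiplicity, 498L)

  gd <- g_coefficients(construct_family("double_peak", 3, 2))
  spd <- jacobian_spectrum(3, 2, gd, n = 500)
  expect_equal(sort(Re(spd$special)), c(-1.5, -1), tolerance = 1e-10)

  ## mixed family: the two-root closed form in k = c/b
  k <- 1.5
  num <- -1 + 2 * k + k^2 - 2 * k^3
  disc <- 1 - 4 * k + 4 * k^2 + 2 * k^3 - 7 * k^4 + 4 * k^5 + 4 * k^6
  den <- 2 * (1 - 3 * k + 4 * k^3)
  lam_ref <- -1 + (num + c(1, -1) * sqrt(disc)) / den
  gm <- g_coefficients(construct_family("mixed_plus", 1, 1.5))
  spm <- jacobian_spectrum(1, 1.5, gm)
  expect_equal(sort(Re(spm$special)), sort(lam_ref), tolerance = 1e-6)
})

test_that("symmetric families have real two-root spectra", {
  for (spec in list(c("single_peak", 3, 2), c("double_peak", 3, 2),
                    c("mixed_plus", 1, 1.5), c("mixed_minus", 1, 1.5),
                    c("two_domain_0", 3, 2), c("two_domain_pi", 3, 2))) {
    b <- as.numeric(spec[2]); c <- as.numeric(spec[3])
    g <- g_coefficients(construct_family(spec[1], b, c))
    disc <- (b * g$g22 - c * g$g33)^2 + 4 * b * c * g$g23^2
    expect_gte(Re(disc), 0)
    expect_lt(abs(Im(disc)), 1e-10)
    sp <- jacobian_spectrum(b, c, g)
    expect_lt(max(abs(Im(sp$special))), 1e-10)
  }
})

test_that("mode-coupling spectrum carries the rotation zero mode and decides stability", {
  mc <- mode_coupling_spectrum(construct_family("single_peak", 3, 2))
  ev <- sort(Re(mc$eigenvalues), decreasing = TRUE)
  expect_equal(ev, c(0, -1 + 2 / 3, -1, -1), tolerance = 1e-10)
  expect_true(mc$stable)

  mcd <- mode_coupling_spectrum(construct_family("double_peak", 3, 2))
  expect_equal(sort(Re(mcd$eigenvalues), decreasing = TRUE),
               c(0, -1 + 3 / 4, -1 + 3 / 4, -1), tolerance = 1e-10)
  expect_true(mcd$stable)

  ## at (1, 1.5) the single peak loses stability to the second harmonic
  mc2 <- mode_coupling_spectrum(construct_family("single_peak", 1, 1.5))
  expect_equal(mc2$lambda_max, 0.5, tolerance = 1e-10)
  expect_false(mc2$stable)

  mca <- mode_coupling_spectrum(construct_family("asym_plus", 3, 2))
  expect_gt(mca$lambda_max, 0.5)
  expect_false(mca$stable)

  mct <- mode_coupling_spectrum(solve_two_domain(3, 2, "0"))
  expect_gt(mct$lambda_max, 0.5)
  expect_false(mct$stable)
})

test_that("mode-coupling eigenvalues match the dense Jacobian for logistic gains", {
  w <- weight_profile(b = 4.5, c = 3.5)
  grid <- ring_grid(256)
  for (k in c(2, 8, 32)) {
    gl <- gain_function("logistic", k = k)
    u0 <- make_initial("cosine", grid, seed = 1)
    tr <- ring_integrate(u0, w, gl, 0,
                         sim_config(dt = 0.02, max_steps = 300000L,
                                    conv_tol = 1e-13))
    expect_true(tr$converged)
    sol <- as_equilibrium(tr$final, 4.5, 3.5)
    mc <- mode_coupling_spectrum(sol, gl)
    ## the dense grid must resolve the g' window (width ~ 1/k), so the
    ## oracle resolution grows with the gain slope
    nj <- numeric_jacobian_spectrum(sol, gl, n = if (k > 8) 1024L else 256L)
    expect_equal(sort(Re(mc$eigenvalues)), sort(Re(nj[1:4])),
                 tolerance = 1e-6)
  }
})

test_that("flat-state stability: logistic closed form and step-gain rules", {
  gl <- gain_function("logistic", k = 2)
  sp <- flat_stability(3.5, 3.5, gl)
  expect_equal(Re(sp$special), c(-0.125, -0.125))
  expect_true(sp$stable)
  sp2 <- flat_stability(4.5, 3.5, gl)
  expect_equal(sort(Re(sp2$special)), c(-0.125, 0.125))
  expect_false(sp2$stable)
  ## exact crossing at b = 8/k
  expect_equal(max(Re(flat_stability(8 / 2, 1, gl)$special)), 0)
  expect_equal(max(Re(flat_stability(8 / 5, 1,
                                     gain_function("logistic", k = 5))$special)),
               0)
  ## step gain: categorical
  expect_true(flat_stability(-1, -2, step_gain)$stable)
  expect_false(flat_stability(0.1, -2, step_gain)$stable)
  expect_equal(flat_stability(3, -2, step_gain)$special[1], Inf)
})

test_that("dense Jacobian oracle: trivial cases and the degenerate flat pairs", {
  gl <- gain_function("logistic", k = 2)
  grid <- ring_grid(200)
  ## zero kernel: J = -I
  ev <- numeric_jacobian_spectrum(state_profile(grid, rnorm(200)), gl,
                                  w = weight_profile(b = 0, c = 0))
  expect_equal(Re(ev), rep(-1, 200), tolerance = 1e-12)
  ## flat state at b = c = 3.5: two doubly degenerate pairs at -0.125
  flat <- hdring:::new_equilibrium(numeric(5), "flat", 3.5, 3.5)
  ev2 <- numeric_jacobian_spectrum(flat, gl, n = 200)
  expect_equal(Re(ev2[1:4]), rep(-0.125, 4), tolerance = 1e-8)
  expect_equal(Re(ev2[5:200]), rep(-1, 196), tolerance = 1e-8)
  expect_error(numeric_jacobian_spectrum(flat, step_gain),
               class = "hdring_step_derivative_error")
})

test_that("linear stability is consistent with the nonlinear dynamics", {
  ## n large enough that 1%-of-amplitude noise can flip threshold cells of
  ## the unstable profiles (the flip threshold scales like |u'| 2 pi / n)
  grid <- ring_grid(1000)
  cfg <- sim_config(dt = 0.05, max_steps = 20000L)
  cases <- list(list("single_peak", 3, 2), list("double_peak", 3, 2),
                list("mixed_plus", 1, 1.5), list("asym_plus", 3, 2),
                list("single_peak", 1, 1.5))
  for (cs in cases) {
    fam <- cs[[1]]; b <- cs[[2]]; c <- cs[[3]]
    sol <- construct_family(fam, b, c)
    mc <- mode_coupling_spectrum(sol)
    second <- sort(Re(mc$eigenvalues), decreasing = TRUE)[2]
    u_eq <- predict(sol, grid$theta)
    amp <- max(abs(u_eq))
    set.seed(31)
    ## 1% perturbation along the leading eigendirection plus noise: on a
    ## finite grid a perturbation must move the Heaviside jump set to act,
    ## and the leading eigenvector is maximal exactly at the zeros of u
    v <- mode_eigenvector_profile(mc, grid$theta, which = 1L)
    if (mc$lambda_max <= 0.01)
      v <- mode_eigenvector_profile(mc, grid$theta, which = 2L)
    u0 <- u_eq + 0.01 * amp * v + rnorm(1000, 0, 0.002 * amp)
    tr <- ring_integrate(state_profile(grid, u0),
                         weight_profile(b = b, c = c), step_gain, 0, cfg)
    dist <- max(abs(tr$final$u - u_eq))
    if (mc$lambda_max > 0.01) {
      expect_gt(dist, 10 * 0.01 * amp)     # abandoned
    } else if (second < -0.01) {
      ## recovered up to rotation (the zero mode lets the phase drift)
      m <- if (fam == "double_peak") 2L else 1L
      expect_lt(fitted_family_error(tr$final$u, fam, b, c, m = m),
                0.05 * amp)
    }
  }
})
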