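## Shared fixtures and independent oracles used across the suite.

step_gain <- gain_function("step")

## independent Riemann-sum convolution oracle: plain double loop over the
## kernel function, no FFT, no circulant matrix
conv_oracle <- function(wfun, rates, theta) {
  n <- length(theta)
  vapply(seq_len(n), function(j) {
    sum(wfun(theta[j] - theta) * rates) / n
  }, numeric(1))
}

## fitted phase of the dominant harmonic m
fitted_phase <- function(u, m) {
  f <- fft(u) / length(u)
  (-Arg(f[m + 1L]) / m) %% (2 * pi)
}

## max-abs error between a state and the closed-form family at the fitted
## rotation phase (the family is a rotation orbit; convergence is to the
## orbit, not to one fixed phase)
fitted_family_error <- function(u, family, b, c, m = 1L) {
  th0 <- fitted_phase(u, m)
  sol <- construct_family(family, b, c, theta0 = th0)
  grid <- ring_grid(length(u))
  max(abs(u - predict(sol, grid$theta)))
}

## families that exist at (b, c) according to the catalog conditions
families_at <- function(b, c) {
  all_f <- c("flat", "single_peak", "double_peak", "mixed_plus",
             "mixed_minus", "two_domain_0", "two_domain_pi", "asym_plus",
             "asym_minus")
  Filter(function(f) hdring:::family_exists(f, b, c), all_f)
}

## pure-R Euler reference step (independent of the compiled path)
euler_oracle_step <- function(u, wfun, gfun, dt, tau, theta, input = 0) {
  drive <- conv_oracle(wfun, gfun(u), theta)
  u + (dt / tau) * (-u + drive + input)
}
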