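## Time integration of the discretized network, Lyapunov energy, and the
## asymptotic boundedness certificate.

#' Simulation configuration
#'
#' Parameters of the explicit-Euler integrator. The scheme matches the
#' discretized network exactly (dense circulant weight matrix, fixed step);
#' no adaptive stepping is used so that runs are bit-reproducible given a
#' seed.
#'
#' @param tau Membrane time constant (> 0), default 1.
#' @param dt Euler time step (> 0, must satisfy `dt < tau`), default 0.1.
#' @param max_steps Maximum number of Euler updates.
#' @param conv_tol Convergence tolerance on `max_j |du_j/dt|`, default 1e-9.
#' @param seed Optional integer seed recorded with the run (used by helpers
#'   that draw initial conditions).
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(tau = 1, dt = 0.1, max_steps = 10000L,
                       conv_tol = 1e-9, seed = NULL) {
  stopifnot(is.numeric(tau), tau > 0, is.numeric(dt), dt > 0,
            is.numeric(max_steps), max_steps >= 1, is.numeric(conv_tol),
            conv_tol > 0)
  if (dt >= tau)
    stop("explicit Euler needs dt < tau for the leak term")
  structure(list(tau = tau, dt = dt, max_steps = as.integer(max_steps),
                 conv_tol = conv_tol, seed = seed), class = "sim_config")
}

#' Single Euler step of the ring dynamics
#'
#' Advances `u <- u + (dt/tau) * (-u + (w * g(u))_ring + I)` by one step.
#' This is the pure-R reference path; [ring_integrate()] uses an equivalent
#' compiled loop.
#'
#' @param state A [state_profile()].
#' @param w A [weight_profile()].
#' @param gain A [gain_function()].
#' @param input Constant external input (scalar or [external_input()]).
#' @param cfg A [sim_config()].
#' @return The advanced [state_profile()].
#' @export
ring_step <- function(state, w, gain, input = 0, cfg = sim_config()) {
  stopifnot(inherits(state, "state_profile"))
  I <- input_value(input)
  g <- evaluate_gain(gain, state$u)
  drive <- ring_convolution(w, g, state$grid)
  du <- (-state$u + drive + I) / cfg$tau
  u_new <- state$u + cfg$dt * du
  if (!all(is.finite(u_new)))
    hd_stop("Euler step produced a non-finite state", "hdring_nonfinite_error")
  state_profile(state$grid, u_new, state$t + cfg$dt)
}

#' Integrate the ring network to convergence
#'
#' Repeats Euler steps until `max_j |du_j/dt| < conv_tol` or `max_steps` is
#' reached, optionally recording intermediate states.
#'
#' @inheritParams ring_step
#' @param state0 Initial [state_profile()].
#' @param record_every Record a snapshot every this many steps (0 records
#'   only the initial and final states).
#' @return An object of class `"ring_trajectory"`: a list with `times`
#'   (snapshot times), `states` (snapshot-by-cell matrix), `grid`, `steps`,
#'   `converged`, `final_residual`, and the final [state_profile()] in
#'   `$final`.
#' @export
ring_integrate <- function(state0, w, gain, input = 0, cfg = sim_config(),
                           record_every = 0L) {
  stopifnot(inherits(state0, "state_profile"), inherits(w, "weight_profile"),
            inherits(gain, "gain_function"), inherits(cfg, "sim_config"))
  I <- input_value(input)
  grid <- state0$grid
  W <- weight_matrix(w, grid)
  res <- euler_ring_cpp(state0$u, W, cfg$dt, cfg$tau, cfg$max_steps,
                        cfg$conv_tol,
                        if (gain$kind == "step") 0L else 1L,
                        if (gain$kind == "step") 0 else gain$k,
                        gain$u0, I, as.integer(record_every))
  final <- state_profile(grid, res$states[nrow(res$states), ],
                         state0$t + res$t_final)
  structure(list(times = state0$t + res$times, states = res$states,
                 grid = grid, steps = res$steps, converged = res$converged,
                 final_residual = res$final_residual, final = final,
                 cfg = cfg),
            class = "ring_trajectory")
}

#' @export
print.ring_trajectory <- function(x, ...) {
  cat(sprintf("Ring trajectory: %d steps (dt = %g), %s, max|du/dt| = %.3g\n",
              x$steps, x$cfg$dt,
              if (x$converged) "converged" else "max_steps reached",
              x$final_residual))
  invisible(x)
}

#' @export
plot.ring_trajectory <- function(x, n_curves = 8, ...) {
  idx <- unique(round(seq(1, nrow(x$states), length.out = n_curves)))
  matplot(x$grid$theta, t(x$states[idx, , drop = FALSE]), type = "l",
          lty = 1, xlab = expression(theta), ylab = expression(u(theta)),
          col = hcl.colors(length(idx), "viridis"), ...)
  invisible(x)
}

#' Lyapunov energy of a network state
#'
#' Evaluates the discretized energy
#' \deqn{E = \int_0^{2\pi}\!\!\int_0^{g(u(\theta))} (g^{-1}(V) - I)\,dV d\theta
#'  - \frac{1}{4\pi}\int_0^{2\pi}\!\!\int_0^{2\pi}
#'    w(\theta-\phi) g(u(\phi)) g(u(\theta))\, d\phi\, d\theta}
#' using the same uniform-grid Riemann sums as the convolution, so that the
#' discrete dynamics descend the discrete energy up to Euler truncation
#' error. For the logistic gain the inner integral has the closed form
#' `u0 x + (1/k) (x log x + (1-x) log(1-x))` at `x = g(u)`. Requires an
#' invertible gain (logistic) and an even kernel (`alpha = 0`). Users who
#' want a Heaviside-limit energy should pass a steep logistic gain
#' (k of order 1e3).
#'
#' @inheritParams ring_step
#' @return The scalar energy.
#' @export
lyapunov_energy <- function(state, w, gain, input = 0) {
  stopifnot(inherits(state, "state_profile"))
  check_energy_args(w, gain)
  I <- input_value(input)
  drop(trajectory_energy_matrix(matrix(state$u, 1L), state$grid, w, gain, I))
}

check_energy_args <- function(w, gain) {
  stopifnot(inherits(w, "weight_profile"), inherits(gain, "gain_function"))
  if (gain$kind == "step")
    hd_stop(paste("the Lyapunov energy needs an invertible gain;",
                  "use a steep logistic gain (k >= 1e3) for the",
                  "Heaviside limit"), "hdring_step_energy_error")
  if (w$alpha != 0)
    hd_stop("the Lyapunov argument requires an even kernel (alpha = 0)",
            "hdring_odd_kernel_error")
  invisible(TRUE)
}

## vectorized energy for a matrix of states (rows = snapshots)
trajectory_energy_matrix <- function(states, grid, w, gain, I) {
  n <- grid$n
  h <- 2 * pi / n
  G <- matrix(evaluate_gain(gain, states), nrow(states), n)
  ## entropy-like inner integral of g^{-1}: u0 x + (1/k)(x log x + (1-x) log(1-x))
  xlx <- function(x) ifelse(x <= 0 | x >= 1, 0, x * log(x))
  Fg <- gain$u0 * G + (1 / gain$k) * (xlx(G) + xlx(1 - G))
  term1 <- rowSums(Fg - I * G) * h
  W <- weight_matrix(w, grid)
  term2 <- -(1 / (4 * pi)) * h^2 * rowSums((G %*% W) * G)
  term1 + term2
}

#' Energy along a trajectory
#'
#' Applies [lyapunov_energy()] to every recorded snapshot of a trajectory
#' (vectorized; integrate with `record_every = 1` to check per-step descent).
#'
#' @param traj A [ring_trajectory][ring_integrate()].
#' @inheritParams ring_step
#' @return Numeric vector of energies, one per snapshot.
#' @export
trajectory_energy <- function(traj, w, gain, input = 0) {
  stopifnot(inherits(traj, "ring_trajectory"))
  check_energy_args(w, gain)
  trajectory_energy_matrix(traj$states, traj$grid, w, gain,
                           input_value(input))
}

#' Asymptotic bound on the network state
#'
#' After transients, `|u(theta, t)|` is bounded by
#' `max_theta |w(theta)| * max g + |I|` (with `max g = 1`): the drive term is
#' a mean of kernel values weighted by rates in `[0, 1]`, and the leak
#' contracts the state toward it. The kernel maximum is located by a fine
#' grid scan polished with local optimization.
#'
#' @inheritParams ring_step
#' @return The certified bound `M`.
#' @export
asymptotic_bound <- function(w, gain, input = 0) {
  stopifnot(inherits(w, "weight_profile"), inherits(gain, "gain_function"))
  I <- input_value(input)
  th <- seq(0, 2 * pi, length.out = 4097L)[-4097L]
  v <- abs(evaluate_weight(w, th))
  j <- which.max(v)
  h <- 2 * pi / 4096
  opt <- optimize(function(x) -abs(evaluate_weight(w, x)),
                  interval = c(th[j] - h, th[j] + h), tol = 1e-12)
  max(v[j], -opt$objective) * 1 + abs(I)
}
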