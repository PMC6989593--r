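## The user-facing model object: a ring network bundles the weight kernel,
## the gain function, the constant input and the discretization, with
## print/summary/coef/plot/simulate methods in the classic modelling idiom.

#' Head-direction ring attractor network
#'
#' Bundles the two-harmonic kernel `w = a + b cos + c cos2` (plus optional
#' shift term), the gain nonlinearity, a constant input and the grid size
#' into a model object. `summary()` catalogs the equilibrium families that
#' exist at `(b, c)` with their stability; `simulate()` integrates the
#' dynamics from standard initial conditions.
#'
#' @param b,c First- and second-harmonic kernel coefficients.
#' @param a Constant kernel coefficient (default 0).
#' @param alpha Shift-gain of the odd derivative term (default 0).
#' @param gain A [gain_function()] (default: Heaviside step).
#' @param input Constant external input (default 0).
#' @param n Number of cells for simulations (default 500).
#' @param tau Membrane time constant (default 1).
#' @return An object of class `"ring_network"`.
#' @examples
#' net <- ring_network(b = 3, c = 2)
#' summary(net)
#' @export
ring_network <- function(b, c, a = 0, alpha = 0,
                         gain = gain_function("step"), input = 0,
                         n = 500L, tau = 1) {
  structure(list(w = weight_profile(b = b, c = c, a = a, alpha = alpha),
                 gain = gain, input = input_value(input),
                 n = as.integer(n), tau = tau),
            class = "ring_network")
}

#' @export
print.ring_network <- function(x, ...) {
  cat("Head-direction ring attractor network\n")
  print(x$w)
  print(x$gain)
  cat(sprintf("  constant input I = %g, n = %d cells, tau = %g\n",
              x$input, x$n, x$tau))
  invisible(x)
}

#' @export
coef.ring_network <- function(object, ...) {
  c(a = object$w$a, b = object$w$b, c = object$w$c, alpha = object$w$alpha)
}

#' @export
plot.ring_network <- function(x, n = 512, ...) {
  th <- seq(0, 2 * pi, length.out = n)
  plot(th, evaluate_weight(x$w, th), type = "l", xlab = expression(theta),
       ylab = expression(w(theta)), ...)
  abline(h = 0, lty = 3)
  invisible(x)
}

#' @export
summary.ring_network <- function(object, n_resid = 2048L, ...) {
  b <- object$w$b; c <- object$w$c
  fams <- setdiff(FAMILIES, "numeric")
  rows <- lapply(fams, function(fam) {
    ex <- family_exists(fam, b, c)
    if (!ex)
      return(data.frame(family = fam, exists = FALSE, residual = NA_real_,
                        lambda_max = NA_real_, stable = NA))
    sol <- tryCatch(construct_family(fam, b, c), error = function(e) NULL)
    if (is.null(sol))
      return(data.frame(family = fam, exists = TRUE, residual = NA_real_,
                        lambda_max = NA_real_, stable = NA))
    r <- as.numeric(equilibrium_residual(sol, n = n_resid, method = "exact"))
    st <- analytic_family_stability(fam, b, c)
    data.frame(family = fam, exists = TRUE, residual = r,
               lambda_max = st$lambda_max, stable = st$stable)
  })
  out <- list(b = b, c = c, gain = object$gain,
              table = do.call(rbind, rows))
  class(out) <- "summary.ring_network"
  out
}

#' @export
print.summary.ring_network <- function(x, ...) {
  cat(sprintf("Equilibrium catalog at (b = %g, c = %g), step-gain analysis\n",
              x$b, x$c))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Simulate a ring network
#'
#' Integrates the network from a chosen initial condition (see
#' [make_initial()]); with `nsim > 1`, returns a list of trajectories with
#' derived seeds.
#'
#' @param object A [ring_network()].
#' @param nsim Number of trajectories.
#' @param seed Base seed for the initial conditions.
#' @param init Initial-condition kind passed to [make_initial()].
#' @param scale,noise_sigma Passed to [make_initial()].
#' @param equilibrium Optional equilibrium for `init = "scaled_equilibrium"`.
#' @param cfg A [sim_config()].
#' @param record_every Snapshot stride (0: first/last only).
#' @param ... Unused.
#' @return A `"ring_trajectory"` (or a list of them when `nsim > 1`).
#' @export
simulate.ring_network <- function(object, nsim = 1, seed = NULL,
                                  init = "random", scale = 1,
                                  noise_sigma = 0, equilibrium = NULL,
                                  cfg = sim_config(tau = object$tau),
                                  record_every = 0L, ...) {
  grid <- ring_grid(object$n)
  one <- function(s) {
    u0 <- make_initial(init, grid, scale = scale, noise_sigma = noise_sigma,
                       seed = s, equilibrium = equilibrium)
    ring_integrate(u0, object$w, object$gain, object$input, cfg,
                   record_every = record_every)
  }
  if (nsim == 1) return(one(seed))
  seeds <- if (is.null(seed)) rep(list(NULL), nsim)
           else as.list(seed + seq_len(nsim) - 1L)
  lapply(seeds, one)
}
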