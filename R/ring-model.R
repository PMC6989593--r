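## Core data types of the ring network: synaptic weight kernel, gain function,
## periodic grid, activity profile, and the spectral utilities they share.

#' Two-harmonic synaptic weight kernel
#'
#' Constructs the synaptic weight profile
#' \deqn{w(\theta) = a + b\cos\theta + c\cos 2\theta +
#'       \alpha\,(-b\sin\theta - 2c\sin 2\theta),}
#' i.e. a truncated Fourier series plus an optional odd derivative term
#' \eqn{\alpha\, dw/d\theta} used by the bump-shifting mechanism. With
#' `alpha = 0` the kernel is even and 2\eqn{\pi}-periodic; connections are
#' then symmetric and a Lyapunov energy exists for sigmoid gains.
#'
#' @param b First-harmonic cosine coefficient. Controls the existence of
#'   single-peaked equilibria.
#' @param c Second-harmonic cosine coefficient. Controls the existence of
#'   double-peaked equilibria.
#' @param a Constant Fourier coefficient (default 0). A constant external
#'   input can be absorbed into `a`; the closed-form equilibrium catalog
#'   assumes `a = 0`.
#' @param alpha Gain of the odd derivative component (default 0), the speed
#'   parameter of the shifting mechanism.
#' @return An object of class `"weight_profile"`.
#' @seealso [evaluate_weight()], [ring_convolution()], [shift_experiment()]
#' @examples
#' w <- weight_profile(b = 3, c = 2)
#' evaluate_weight(w, 0)      # 5, the kernel maximum
#' @export
weight_profile <- function(b, c, a = 0, alpha = 0) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c), is.numeric(alpha),
            length(a) == 1L, length(b) == 1L, length(c) == 1L,
            length(alpha) == 1L, is.finite(c(a, b, c, alpha)))
  structure(list(a = a, b = b, c = c, alpha = alpha),
            class = "weight_profile")
}

#' @export
print.weight_profile <- function(x, ...) {
  cat(sprintf("Ring weight kernel: w(theta) = %g + %g cos(theta) + %g cos(2 theta)\n",
              x$a, x$b, x$c))
  if (x$alpha != 0)
    cat(sprintf("  + shift term alpha * dw/dtheta with alpha = %g\n", x$alpha))
  invisible(x)
}

#' Gain (activation) function of the ring units
#'
#' Either the Heaviside step `H(u - u0)` (with the symmetric convention
#' `H(0) = 1/2`) or the logistic sigmoid `1 / (1 + exp(-k (u - u0)))`.
#' The step gain is the infinite-slope limit of the logistic one.
#'
#' @param kind `"step"` or `"logistic"`.
#' @param k Logistic slope (required for `kind = "logistic"`, must be > 0).
#' @param u0 Threshold (default 0).
#' @return An object of class `"gain_function"`.
#' @examples
#' g <- gain_function("logistic", k = 2)
#' evaluate_gain(g, 0)  # 0.5
#' @export
gain_function <- function(kind = c("step", "logistic"), k = NULL, u0 = 0) {
  kind <- match.arg(kind)
  if (kind == "logistic") {
    if (is.null(k) || !is.finite(k) || k <= 0)
      stop("logistic gain requires a finite positive slope `k`")
  } else {
    k <- Inf
  }
  stopifnot(is.numeric(u0), length(u0) == 1L, is.finite(u0))
  structure(list(kind = kind, k = k, u0 = u0), class = "gain_function")
}

#' @export
print.gain_function <- function(x, ...) {
  if (x$kind == "step")
    cat(sprintf("Heaviside step gain, threshold u0 = %g (H(u0) = 1/2)\n", x$u0))
  else
    cat(sprintf("Logistic gain, slope k = %g, threshold u0 = %g\n", x$k, x$u0))
  invisible(x)
}

#' Uniform periodic grid on the ring
#'
#' `n` preferred directions `theta_j = 2*pi*j/n`, `j = 0, ..., n-1`, sampling
#' the half-open circle `[0, 2*pi)` with exact spacing `2*pi/n`.
#'
#' @param n Number of cells (integer, at least 8).
#' @return An object of class `"ring_grid"` with fields `n` and `theta`.
#' @export
ring_grid <- function(n) {
  n <- as.integer(n)
  stopifnot(length(n) == 1L, !is.na(n), n >= 8L)
  structure(list(n = n, theta = 2 * pi * (0:(n - 1L)) / n), class = "ring_grid")
}

#' @export
print.ring_grid <- function(x, ...) {
  cat(sprintf("Ring grid: %d cells, theta_j = 2 pi j / %d on [0, 2 pi)\n",
              x$n, x$n))
  invisible(x)
}

#' Sampled activity profile
#'
#' The membrane state `u(theta_j)` of the `n` cells at time `t` (in units of
#' the membrane time constant tau).
#'
#' @param grid A [ring_grid()].
#' @param u Numeric vector of length `grid$n`; must be finite.
#' @param t Time stamp (default 0).
#' @return An object of class `"state_profile"`.
#' @export
state_profile <- function(grid, u, t = 0) {
  stopifnot(inherits(grid, "ring_grid"), is.numeric(u),
            length(u) == grid$n, length(t) == 1L, is.finite(t))
  if (!all(is.finite(u)))
    hd_stop("state profile contains non-finite activity values",
            "hdring_nonfinite_error")
  structure(list(grid = grid, u = as.numeric(u), t = as.numeric(t)),
            class = "state_profile")
}

#' @export
print.state_profile <- function(x, ...) {
  cat(sprintf("Activity profile on %d cells at t = %g: range [%.4g, %.4g]\n",
              x$grid$n, x$t, min(x$u), max(x$u)))
  invisible(x)
}

#' @export
plot.state_profile <- function(x, ..., add = FALSE) {
  if (add) lines(x$grid$theta, x$u, ...)
  else plot(x$grid$theta, x$u, type = "l", xlab = expression(theta),
            ylab = expression(u(theta)), ...)
  invisible(x)
}

#' Constant external input
#'
#' A spatially and temporally constant input current `I`. Structured input
#' `I(theta, t)` is outside the scope of the closed-form analysis; a constant
#' can always be absorbed into the kernel coefficient `a`.
#'
#' @param value The input current (default 0).
#' @return An object of class `"external_input"`.
#' @export
external_input <- function(value = 0) {
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  structure(list(value = value), class = "external_input")
}

## accept either an external_input or a bare number everywhere
input_value <- function(input) {
  if (inherits(input, "external_input")) input$value
  else if (is.numeric(input) && length(input) == 1L && is.finite(input)) input
  else stop("`input` must be an external_input object or a finite scalar")
}

## Operations ------------------------------------------------------------------

#' Evaluate the weight kernel
#'
#' @param profile A [weight_profile()].
#' @param theta Angle(s) in radians (any real; the kernel is 2 pi periodic).
#' @return Numeric vector `w(theta)`.
#' @export
evaluate_weight <- function(profile, theta) {
  stopifnot(inherits(profile, "weight_profile"), is.numeric(theta))
  profile$a + profile$b * cos(theta) + profile$c * cos(2 * theta) +
    profile$alpha * (-profile$b * sin(theta) - 2 * profile$c * sin(2 * theta))
}

#' Evaluate the gain function
#'
#' Step gain: 0 below threshold, 1 above, 1/2 exactly at threshold.
#' Logistic gain: `plogis(k * (u - u0))`. Output always lies in `[0, 1]`
#' and is non-decreasing in `u`.
#'
#' @param gain A [gain_function()].
#' @param u Activity value(s).
#' @return Firing rates in `[0, 1]`.
#' @export
evaluate_gain <- function(gain, u) {
  stopifnot(inherits(gain, "gain_function"), is.numeric(u))
  if (gain$kind == "step") {
    r <- as.numeric(u > gain$u0)
    r[u == gain$u0] <- 0.5
    r
  } else {
    plogis(gain$k * (u - gain$u0))
  }
}

#' Derivative of the gain function
#'
#' Closed form `k g(u) (1 - g(u))` for the logistic gain. The step gain has a
#' Dirac-delta derivative which cannot be evaluated pointwise; stability
#' calculations handle it analytically through delta sums over the zeros of
#' the equilibrium profile (see [g_coefficients()]).
#'
#' @inheritParams evaluate_gain
#' @return `g'(u)` for the logistic gain.
#' @export
gain_derivative <- function(gain, u) {
  stopifnot(inherits(gain, "gain_function"), is.numeric(u))
  if (gain$kind == "step")
    hd_stop(paste("the step gain has a Dirac-delta derivative;",
                  "use the analytic delta-sum path (g_coefficients)"),
            "hdring_step_derivative_error")
  gain$k * dlogis(gain$k * (u - gain$u0))
}

#' Circular convolution of the kernel with a rate profile
#'
#' Computes the discretized ring convolution
#' \deqn{(w * r)_j = \frac{1}{n} \sum_k w(\theta_j - \theta_k)\, r_k,}
#' the uniform Riemann sum of \eqn{(1/2\pi)\int_0^{2\pi} w(\theta-\phi)
#' r(\phi)\,d\phi} on the periodic grid. The quadrature is spectrally
#' accurate for trigonometric polynomials; the FFT and direct circulant
#' paths agree to machine precision.
#'
#' @param profile A [weight_profile()].
#' @param rates Numeric vector of firing rates, one per grid cell.
#' @param grid A [ring_grid()] with `grid$n == length(rates)`.
#' @param method `"fft"` (default) or `"direct"` (O(n^2) reference path).
#' @return Numeric vector of length `n`.
#' @export
ring_convolution <- function(profile, rates, grid, method = c("fft", "direct")) {
  method <- match.arg(method)
  stopifnot(inherits(profile, "weight_profile"), inherits(grid, "ring_grid"))
  if (length(rates) != grid$n)
    stop("length(rates) must equal grid$n")
  wv <- evaluate_weight(profile, grid$theta)
  n <- grid$n
  if (method == "fft") {
    Re(fft(fft(wv) * fft(as.numeric(rates)), inverse = TRUE)) / n^2
  } else {
    idx <- outer(0:(n - 1L), 0:(n - 1L), function(j, k) (j - k) %% n)
    as.numeric((matrix(wv[idx + 1L], n, n) %*% rates) / n)
  }
}

#' Fourier coefficients of an activity profile
#'
#' Discrete Fourier coefficients `u_m` normalized so that
#' `u(theta) = sum_m u_m exp(i m theta)`; equivalently `u_m = fft(u)[m+1]/n`
#' for `m >= 0` and the conjugate-symmetric top entries for `m < 0`.
#' Reconstruction is exact for trigonometric polynomials of degree at most
#' `order` when `order < n/2`.
#'
#' @param state A [state_profile()] or a bare numeric vector.
#' @param order Highest harmonic to return; must satisfy `order < n/2`.
#' @return Complex vector of length `2*order + 1`, named `-order ... order`.
#' @export
harmonics <- function(state, order) {
  u <- if (inherits(state, "state_profile")) state$u else as.numeric(state)
  n <- length(u)
  order <- as.integer(order)
  if (order >= n / 2)
    hd_stop(sprintf("order %d aliases on a %d-point grid (need order < n/2)",
                    order, n), "hdring_aliasing_error")
  f <- fft(u) / n
  m <- (-order):order
  out <- f[ifelse(m >= 0, m + 1L, n + m + 1L)]
  names(out) <- m
  out
}

#' Rebuild a profile from Fourier coefficients
#'
#' Inverse of [harmonics()]: evaluates `sum_m u_m exp(i m theta)` on a grid.
#'
#' @param coeffs Complex coefficients named as returned by [harmonics()].
#' @param grid A [ring_grid()].
#' @return Numeric vector of length `grid$n`.
#' @export
reconstruct_profile <- function(coeffs, grid) {
  stopifnot(inherits(grid, "ring_grid"))
  m <- as.integer(names(coeffs))
  v <- rep(0 + 0i, grid$n)
  for (i in seq_along(m))
    v <- v + coeffs[i] * exp(1i * m[i] * grid$theta)
  Re(v)
}

## amplitude of harmonic m (2*|u_m| for m > 0, |u_0| for m = 0)
harmonic_amplitude <- function(u, m) {
  f <- fft(as.numeric(u)) / length(u)
  if (m == 0) abs(f[1L]) else 2 * abs(f[m + 1L])
}

## dense circulant weight matrix W_{jk} = w(theta_j - theta_k)
weight_matrix <- function(profile, grid) {
  wv <- evaluate_weight(profile, grid$theta)
  n <- grid$n
  idx <- outer(0:(n - 1L), 0:(n - 1L), function(j, k) (j - k) %% n)
  matrix(wv[idx + 1L], n, n)
}
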