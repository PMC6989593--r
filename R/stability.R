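## Linear stability of equilibria. Perturbations epsilon(theta, t) about an
## equilibrium obey tau d eps/dt = -eps + w * (g'(u) eps). In the Fourier
## basis the convolution keeps only the kernel modes (+-1, +-2 for a = 0),
## so the non-trivial part of the spectrum is the eigenvalue set of a small
## mode-coupling matrix built from Fourier coefficients of g'(u(theta)).
##
## Two analytic reductions are provided:
##  * jacobian_spectrum(): the classical two-root characteristic-polynomial
##    reduction with coefficients (g22, g33, g23); it treats the coupling of
##    harmonics 1 and 2 through the e^{3 i theta} moment of g'(u) and yields
##    a quadratic factor with two special roots.
##  * mode_coupling_spectrum(): the full coupling matrix over the four
##    Fourier modes +-1, +-2, whose eigenvalues match the dense finite-n
##    Jacobian (numeric_jacobian_spectrum) to quadrature accuracy, including
##    the rotation zero mode that every non-flat equilibrium carries.
## The two reductions do not agree in general; see the package vignette for
## the analysis. Phase-diagram stability flags use the mode-coupling path.

#' Eigenvalues of the scaled circulant weight matrix
#'
#' For the even kernel the circulant `(1/n) W` is diagonalized by Fourier
#' modes with eigenvalues `lambda_j = (1/n) sum_k w(theta_k) cos(j theta_k)`,
#' which converge to `(1/2pi) int w(phi) cos(j phi) dphi`. For
#' `w = a + b cos + c cos2` this gives `a, b/2, c/2, 0, 0, ...` for
#' `j = 0, 1, 2, 3, ...` (each nonzero harmonic eigenvalue is doubly
#' degenerate on the discrete ring, carried by the cos and sin
#' eigenvectors).
#'
#' @param w A [weight_profile()] with `alpha = 0`.
#' @param modes Integer vector of mode numbers `j >= 0`.
#' @param n If `NULL` (default), the continuum integrals (closed form);
#'   otherwise the discrete sum on an `n`-point grid.
#' @return Named numeric vector of eigenvalues, one per mode.
#' @export
weight_mode_eigenvalues <- function(w, modes, n = NULL) {
  stopifnot(inherits(w, "weight_profile"))
  if (w$alpha != 0)
    hd_stop("mode eigenvalues require an even kernel (alpha = 0)",
            "hdring_odd_kernel_error")
  modes <- as.integer(modes)
  stopifnot(all(modes >= 0L))
  out <- if (is.null(n)) {
    vapply(modes, function(j)
      switch(as.character(j), "0" = w$a, "1" = w$b / 2, "2" = w$c / 2, 0),
      numeric(1))
  } else {
    th <- 2 * pi * (0:(n - 1L)) / n
    wv <- evaluate_weight(w, th)
    vapply(modes, function(j) sum(wv * cos(j * th)) / n, numeric(1))
  }
  names(out) <- modes
  out
}

## Fourier moments of g'(u(theta)): gamma(q) = (1/2pi) int g'(u) e^{-i q theta}
## step gain: Dirac delta sum over the simple zeros of u
gain_moment <- function(sol, gain, q, zeros = NULL) {
  co <- if (inherits(sol, "ring_equilibrium")) sol$coeffs else sol
  if (gain$kind == "step") {
    if (is.null(zeros)) zeros <- step_zero_set(co)
    sum(exp(-1i * q * zeros) / abs(trig_deriv(co, zeros))) / (2 * pi)
  } else {
    N <- quad_points(gain$k)
    th <- 2 * pi * (0:(N - 1L)) / N
    gp <- gain_derivative(gain, trig_eval(co, th))
    mean(gp * exp(-1i * q * th))
  }
}

quad_points <- function(k) min(2L^20L, max(8192L, 2L^ceiling(log2(64 * k))))

## zeros of the profile for delta sums, with degeneracy checks
step_zero_set <- function(co) {
  if (max(abs(co)) < 1e-12)
    hd_stop(paste("the flat state has no simple zeros; use flat_stability()",
                  "for the dedicated flat-state analysis"),
            "hdring_flat_state_error")
  z <- trig_zeros(co, n_scan = 8192L)
  if (!length(z))
    hd_stop("profile has no zeros; delta-sum coefficients undefined",
            "hdring_flat_state_error")
  ## merge zeros closer than 1e-6 rad and flag them degenerate
  if (length(z) > 1L) {
    gaps <- diff(c(z, z[1] + 2 * pi))
    if (any(gaps < 1e-6))
      hd_stop("profile has (near-)double zeros; degenerate equilibrium",
              "hdring_degenerate_error")
  }
  d <- abs(trig_deriv(co, z))
  if (any(d <= 1e-8))
    hd_stop("profile has a non-simple zero (|u'| <= 1e-8); degenerate",
            "hdring_degenerate_error")
  z
}

#' g-coefficients of the linearization
#'
#' The Fourier-weighted moments of `g'(u(theta))` that enter the
#' characteristic polynomial:
#' \deqn{g_{22} = \frac{1}{2\pi}\int_0^{2\pi} g'(u(\theta)) e^{2i\theta} d\theta,\quad
#'       g_{33} = \frac{1}{2\pi}\int g'(u) e^{4i\theta} d\theta,\quad
#'       g_{23} = g_{32} = \frac{1}{2\pi}\int g'(u) e^{3i\theta} d\theta.}
#' For the step gain, `g'` is a Dirac comb on the zeros of `u` and the
#' integrals reduce to the delta sums
#' `(1/2pi) sum_i exp(i m theta_i) / |u'(theta_i)|`; zeros are located by an
#' 8192-point sign scan plus bisection and must be simple. For the logistic
#' gain a trapezoid quadrature with resolution adapted to the slope `k` is
#' used. The equilibrium is canonicalized first (first-harmonic phase
#' rotated to zero) because the moments are frame-dependent.
#'
#' @param sol A `"ring_equilibrium"` (certified; see
#'   [equilibrium_residual()]).
#' @param gain A [gain_function()].
#' @return An object of class `"g_coeffs"`: list with complex `g22`,
#'   `g33`, `g23`.
#' @examples
#' g <- g_coefficients(construct_family("single_peak", 3, 2),
#'                     gain_function("step"))
#' c(g$g22, g$g33, g$g23)  # -1/3, 1/3, 0
#' @export
g_coefficients <- function(sol, gain = gain_function("step")) {
  stopifnot(inherits(sol, "ring_equilibrium"), inherits(gain, "gain_function"))
  sol <- canonicalize_equilibrium(sol)
  zeros <- if (gain$kind == "step") step_zero_set(sol$coeffs) else NULL
  g <- lapply(c(g22 = 2, g33 = 4, g23 = 3), function(m) {
    ## positive-exponent convention: conjugate of the gamma moment at +m
    Conj(gain_moment(sol, gain, m, zeros))
  })
  structure(list(g22 = g$g22, g33 = g$g33, g23 = g$g23,
                 family = sol$family), class = "g_coeffs")
}

#' @export
print.g_coeffs <- function(x, ...) {
  fmt <- function(z) if (abs(Im(z)) < 1e-12) sprintf("%.6g", Re(z))
                     else sprintf("%.6g%+.6gi", Re(z), Im(z))
  cat(sprintf("g-coefficients (%s): g22 = %s, g33 = %s, g23 = %s\n",
              x$family %||% "?", fmt(x$g22), fmt(x$g33), fmt(x$g23)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_spectrum <- function(family, b, c, special, n, method,
                         eigenvalues = NULL, zero_tol = 1e-7) {
  lam_max <- max(-1, Re(special))
  if (!is.null(eigenvalues)) lam_max <- max(-1, Re(eigenvalues))
  structure(list(family = family, b = b, c = c, bulk = -1,
                 bulk_multiplicity = if (is.null(n)) NA_integer_
                                     else as.integer(max(n - 2L, 0L)),
                 special = special, eigenvalues = eigenvalues,
                 lambda_max = lam_max, stable = lam_max < zero_tol,
                 method = method),
            class = "ring_spectrum")
}

#' @export
print.ring_spectrum <- function(x, ...) {
  cat(sprintf("Linear spectrum [%s] at (b = %g, c = %g), method = %s\n",
              x$family %||% "?", x$b, x$c, x$method))
  sp <- if (is.null(x$eigenvalues)) x$special else x$eigenvalues
  fmt <- function(z) if (abs(Im(z)) < 1e-12) sprintf("%.4g", Re(z))
                     else sprintf("%.4g%+.4gi", Re(z), Im(z))
  cat("  non-bulk eigenvalues:",
      paste(vapply(sp, fmt, character(1)), collapse = ", "), "\n")
  cat(sprintf("  bulk = -1, lambda_max = %.4g, %s\n", x$lambda_max,
              if (x$stable) "stable" else "unstable"))
  invisible(x)
}

#' Characteristic-polynomial spectrum (two-root reduction)
#'
#' Solves the quadratic factor of the characteristic polynomial
#' \deqn{(\lambda+1)^2 - \left(\tfrac{b}{2}g_{22} + \tfrac{c}{2}g_{33}\right)
#'       (\lambda+1) + \tfrac{bc}{4}\left(g_{22}g_{33} - g_{23}g_{32}\right) = 0}
#' (with `g32 = g23`) in complex arithmetic, together with the
#' `(n-2)`-fold bulk eigenvalue `-1`. All eigenvalues are in units of
#' `1/tau`. This is the classical two-root reduction; its roots coincide
#' with the true non-bulk spectrum only in special cases -- see
#' [mode_coupling_spectrum()] for the full coupling matrix and the vignette
#' for the comparison.
#'
#' @param b,c Weight coefficients.
#' @param g A `"g_coeffs"` object from [g_coefficients()].
#' @param n Network size used to report the bulk multiplicity.
#' @return A `"ring_spectrum"` with the two `special` roots,
#'   `lambda_max = max(-1, Re(special))` and the stability flag.
#' @examples
#' g <- g_coefficients(construct_family("single_peak", 3, 2))
#' jacobian_spectrum(3, 2, g)$special  # -3/2 and -1 + c/(2b) = -2/3
#' @export
jacobian_spectrum <- function(b, c, g, n = 500L) {
  stopifnot(inherits(g, "g_coeffs"), n >= 4L)
  S <- (b / 2) * g$g22 + (c / 2) * g$g33
  P <- (b * c / 4) * (g$g22 * g$g33 - g$g23^2)
  mu <- polyroot(c(P, -S, 1))
  special <- mu - 1
  special <- special[order(-Re(special))]
  new_spectrum(g$family, b, c, special, n, "characteristic_polynomial")
}

#' Full mode-coupling spectrum of the linearization
#'
#' Builds the coupling matrix of the perturbation dynamics over the Fourier
#' modes `m = +1, -1, +2, -2` (the only modes the two-harmonic kernel
#' transmits when `a = 0`),
#' \deqn{A_{ml} = w_m\,\gamma_{m-l},\qquad
#'       \gamma_q = \frac{1}{2\pi}\int_0^{2\pi} g'(u(\theta))
#'       e^{-iq\theta}\,d\theta,}
#' with `w_1 = w_{-1} = b/2`, `w_2 = w_{-2} = c/2`. All remaining modes
#' decay at the bulk rate `-1`, so the non-bulk spectrum is
#' `eig(A) - 1`. Every non-flat equilibrium has a rotation zero mode
#' (derivative of the family with respect to its phase), so "stable" means
#' orbitally stable: `lambda_max <= zero_tol` with the zero mode the only
#' non-negative eigenvalue. Matches [numeric_jacobian_spectrum()] to
#' quadrature accuracy.
#'
#' @inheritParams g_coefficients
#' @param zero_tol Tolerance below which the largest real part is treated
#'   as the neutral rotation mode.
#' @return A `"ring_spectrum"` with all four non-bulk `eigenvalues`.
#' @export
mode_coupling_spectrum <- function(sol, gain = gain_function("step"),
                                   zero_tol = 1e-7) {
  stopifnot(inherits(sol, "ring_equilibrium"), inherits(gain, "gain_function"))
  if (max(abs(sol$coeffs)) < 1e-12 && gain$kind == "step")
    hd_stop("use flat_stability() for the flat state under step gain",
            "hdring_flat_state_error")
  zeros <- if (gain$kind == "step") step_zero_set(sol$coeffs) else NULL
  gam <- new.env()
  gq <- function(q) {
    key <- as.character(q)
    if (is.null(gam[[key]]))
      gam[[key]] <- gain_moment(sol, gain, q, zeros)
    gam[[key]]
  }
  ms <- c(1L, -1L, 2L, -2L)
  wm <- c(sol$b / 2, sol$b / 2, sol$c / 2, sol$c / 2)
  A <- matrix(0 + 0i, 4L, 4L)
  for (i in 1:4) for (j in 1:4) A[i, j] <- wm[i] * gq(ms[i] - ms[j])
  ed <- eigen(A)
  ord <- order(-Re(ed$values))
  ev <- ed$values[ord] - 1
  sp <- new_spectrum(sol$family, sol$b, sol$c, special = ev[1:2], n = NULL,
                     method = "mode_coupling", eigenvalues = ev,
                     zero_tol = zero_tol)
  sp$modes <- ms
  sp$vectors <- ed$vectors[, ord, drop = FALSE]
  sp
}

#' Evaluate a mode-coupling eigenvector as a profile
#'
#' Reconstructs the real spatial perturbation pattern of the `which`-th
#' eigenvalue of a [mode_coupling_spectrum()] (eigenvalues are sorted by
#' decreasing real part), normalized to unit maximum amplitude. Useful for
#' perturbing an equilibrium along a specific (e.g. the most unstable)
#' direction.
#'
#' @param spectrum A `"ring_spectrum"` from [mode_coupling_spectrum()].
#' @param theta Angles at which to evaluate.
#' @param which Eigenvalue index (default 1, the largest real part).
#' @return Numeric vector of the perturbation profile.
#' @export
mode_eigenvector_profile <- function(spectrum, theta, which = 1L) {
  stopifnot(inherits(spectrum, "ring_spectrum"),
            !is.null(spectrum$vectors))
  v <- spectrum$vectors[, which]
  prof <- Re(colSums(v * exp(1i * outer(spectrum$modes, theta))))
  m <- max(abs(prof))
  if (m < 1e-14) {
    ## degenerate complex pairing can cancel the real part: use imaginary
    prof <- Im(colSums(v * exp(1i * outer(spectrum$modes, theta))))
    m <- max(abs(prof))
  }
  prof / m
}

#' Stability of the flat state
#'
#' The flat equilibrium `u = 0` (threshold `u0 = 0`) has a diagonal
#' linearization: modes 1 and 2 carry eigenvalues
#' `-1 + g'(0) b/2` and `-1 + g'(0) c/2` (each doubly degenerate on the
#' ring), all other modes `-1`. For the logistic gain `g'(0) = k/4`, so the
#' flat state is stable iff `b < 8/k` and `c < 8/k`. For the step gain
#' `g'(0)` diverges and stability is categorical: stable iff `b < 0` and
#' `c < 0`; the corresponding special entries are reported as `-Inf`/`+Inf`
#' sentinels (`-1` when the coefficient is exactly 0).
#'
#' @param b,c Weight coefficients.
#' @param gain A [gain_function()].
#' @param n Network size for the bulk multiplicity report.
#' @return A `"ring_spectrum"`.
#' @export
flat_stability <- function(b, c, gain, n = 500L) {
  stopifnot(inherits(gain, "gain_function"))
  if (gain$kind == "logistic") {
    gp0 <- gain_derivative(gain, gain$u0)  # k/4 at threshold
    special <- c(-1 + gp0 * b / 2, -1 + gp0 * c / 2)
  } else {
    sentinel <- function(x) if (x > 0) Inf else if (x < 0) -Inf else -1
    special <- c(sentinel(b), sentinel(c))
  }
  special <- special[order(-special)]
  sp <- new_spectrum("flat", b, c, special, n, "flat_closed_form")
  if (gain$kind == "step") {
    sp$stable <- (b < 0 && c < 0)
    sp$lambda_max <- if (sp$stable) -1 else Inf
  }
  sp
}

#' Dense finite-n Jacobian spectrum (numeric oracle)
#'
#' Builds the full `n x n` Jacobian `J = -I + (1/n) W diag(g'(u))` of the
#' discretized network about a state and returns all its eigenvalues.
#' Serves as the independent oracle for the analytic reductions; requires a
#' finite-slope (logistic) gain.
#'
#' @param sol A `"ring_equilibrium"`, a [state_profile()], or a bare
#'   activity vector.
#' @param gain A logistic [gain_function()].
#' @param n Grid size (>= 64) when `sol` is an equilibrium object.
#' @param w Optional kernel; defaults to `weight_profile(b, c)` taken from
#'   `sol` when it is an equilibrium.
#' @return Complex eigenvalues sorted by decreasing real part.
#' @export
numeric_jacobian_spectrum <- function(sol, gain, n = 256L, w = NULL) {
  stopifnot(inherits(gain, "gain_function"))
  if (gain$kind == "step")
    hd_stop("the dense Jacobian needs a finite g'; use the analytic path",
            "hdring_step_derivative_error")
  if (inherits(sol, "ring_equilibrium")) {
    stopifnot(n >= 64L)
    grid <- ring_grid(n)
    u <- predict(sol, grid$theta)
    if (is.null(w)) w <- weight_profile(b = sol$b, c = sol$c)
  } else {
    u <- if (inherits(sol, "state_profile")) sol$u else as.numeric(sol)
    grid <- ring_grid(length(u))
    if (is.null(w)) stop("supply `w` when `sol` is a raw state")
  }
  W <- weight_matrix(w, grid)
  J <- -diag(grid$n) + W %*% diag(gain_derivative(gain, u)) / grid$n
  ev <- eigen(J, only.values = TRUE)$values
  ev[order(-Re(ev))]
}
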