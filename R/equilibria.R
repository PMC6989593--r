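## Closed-form equilibrium catalog of the step-gain, two-harmonic ring
## network, the self-consistency residual that certifies each solution, a
## numeric root solver for the two-domain families, and a multi-start
## fixed-point oracle over the trig-polynomial coefficient space.
##
## Every equilibrium is a trig polynomial
##   u(theta) = a0 + b1 cos(theta) + b2 sin(theta) + c1 cos(2 theta) + c2 sin(2 theta)
## because convolution with the two-harmonic kernel annihilates all higher
## harmonics. The module fixes a = 0 and I = 0 (a constant input only moves
## the profile up and down).

FAMILIES <- c("flat", "single_peak", "double_peak", "mixed_plus",
              "mixed_minus", "two_domain_0", "two_domain_pi",
              "asym_plus", "asym_minus", "numeric")

## trig-polynomial evaluation, coeffs = c(a0, b1, b2, c1, c2)
trig_eval <- function(co, th)
  co[1] + co[2] * cos(th) + co[3] * sin(th) + co[4] * cos(2 * th) +
    co[5] * sin(2 * th)

trig_deriv <- function(co, th)
  -co[2] * sin(th) + co[3] * cos(th) - 2 * co[4] * sin(2 * th) +
    2 * co[5] * cos(2 * th)

## all zeros of the trig polynomial on [0, 2pi). Default path: the zeros are
## the unit-circle roots of the degree-4 complex polynomial
##   p(w) = u_{-2} + u_{-1} w + u_0 w^2 + u_1 w^3 + u_2 w^4,  w = e^{i theta},
## found by polyroot and polished by Newton. Fallback: sign-change scan plus
## vectorized bisection.
trig_zeros <- function(co, n_scan = 8192L, iters = 60L,
                       method = c("poly", "scan")) {
  method <- match.arg(method)
  scale <- max(abs(co))
  if (scale < 1e-300) return(numeric(0))
  if (method == "poly") {
    p <- c(complex(real = co[4], imaginary = co[5]) / 2,
           complex(real = co[2], imaginary = co[3]) / 2,
           complex(real = co[1]),
           complex(real = co[2], imaginary = -co[3]) / 2,
           complex(real = co[4], imaginary = -co[5]) / 2)
    nz <- which(abs(p) > 1e-14 * scale)
    if (length(nz) < 2L) return(numeric(0))  # constant: no sign structure
    p <- p[min(nz):max(nz)]
    r <- tryCatch(polyroot(p), error = function(e) NULL)
    if (!is.null(r)) {
      th <- Arg(r[abs(Mod(r) - 1) < 1e-6]) %% (2 * pi)
      if (length(th)) {
        for (it in 1:4) {  # Newton polish on the real profile
          d <- trig_deriv(co, th)
          ok <- abs(d) > 1e-12 * scale
          th[ok] <- th[ok] - trig_eval(co, th[ok]) / d[ok]
        }
        th <- th %% (2 * pi)
        th <- th[abs(trig_eval(co, th)) < 1e-7 * scale]
        th <- sort(th)
        if (length(th) > 1L) th <- th[c(TRUE, diff(th) > 1e-10)]
        ## count must be even for a continuous periodic profile with simple
        ## zeros; fall back to the scan on suspicion of a missed root
        if (length(th) %% 2L == 0L) return(th)
      } else return(numeric(0))
    }
  }
  th_s <- 2 * pi * (0:(n_scan - 1L)) / n_scan
  v <- trig_eval(co, th_s)
  vn <- c(v[-1L], v[1L])
  hit <- which(v * vn < 0)
  exact <- th_s[v == 0]
  if (!length(hit)) return(sort(exact))
  lo <- th_s[hit]
  hi <- lo + 2 * pi / n_scan
  flo <- v[hit]
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    fm <- trig_eval(co, mid)
    left <- flo * fm <= 0
    hi[left] <- mid[left]
    lo[!left] <- mid[!left]
    flo[!left] <- fm[!left]
  }
  sort(c(exact, (lo + hi) / 2)) %% (2 * pi)
}

## positive arcs {u > 0} as a 2-column matrix (lo, hi), hi possibly > 2pi
positive_arcs <- function(co, zeros = trig_zeros(co)) {
  if (!length(zeros)) {
    if (trig_eval(co, 0) > 0) return(matrix(c(0, 2 * pi), 1L))
    return(matrix(numeric(0), 0L, 2L))
  }
  z <- sort(zeros)
  k <- length(z)
  lo <- z
  hi <- c(z[-1L], z[1L] + 2 * pi)
  mid <- (lo + hi) / 2
  pos <- trig_eval(co, mid) > 0
  cbind(lo, hi)[pos, , drop = FALSE]
}

## exact Fourier coefficients of (1/2pi) * int_arcs w(theta - phi) d phi for
## w = a + b cos + c cos2 (alpha = 0); returns c(a0, b1, b2, c1, c2)
arc_convolution_coeffs <- function(a, b, c, arcs) {
  if (!nrow(arcs)) return(numeric(5L))
  lo <- arcs[, 1L]; hi <- arcs[, 2L]
  c(a * sum(hi - lo) / (2 * pi),
    (b / (2 * pi)) * sum(sin(hi) - sin(lo)),
    (b / (2 * pi)) * sum(cos(lo) - cos(hi)),
    (c / (4 * pi)) * sum(sin(2 * hi) - sin(2 * lo)),
    (c / (4 * pi)) * sum(cos(2 * lo) - cos(2 * hi)))
}

## the self-consistency map for step gain: coefficients of w * H(u)
step_image_coeffs <- function(co, b, c, a = 0, n_scan = 2048L) {
  z <- trig_zeros(co, n_scan)
  if (!length(z) && all(abs(co) < 1e-14)) {
    ## flat state: H(0) = 1/2 everywhere, zero-mean harmonics drop out
    return(c(a / 2, 0, 0, 0, 0))
  }
  arc_convolution_coeffs(a, b, c, positive_arcs(co, z))
}

new_equilibrium <- function(coeffs, family, b, c, theta0 = 0, aux = list()) {
  names(coeffs) <- c("a0", "b1", "b2", "c1", "c2")
  structure(list(coeffs = coeffs, family = family, b = b, c = c,
                 theta0 = theta0, aux = aux), class = "ring_equilibrium")
}

#' @export
print.ring_equilibrium <- function(x, ...) {
  co <- x$coeffs
  cat(sprintf("Ring equilibrium [%s] at (b = %g, c = %g), theta0 = %g\n",
              x$family, x$b, x$c, x$theta0))
  cat(sprintf("  u(theta) = %+.5f %+.5f cos(t) %+.5f sin(t) %+.5f cos(2t) %+.5f sin(2t)\n",
              co[1], co[2], co[3], co[4], co[5]))
  if (!is.null(x$aux$B))
    cat(sprintf("  amplitudes B = %.5f, C = %.5f\n", x$aux$B, x$aux$C))
  invisible(x)
}

#' @export
coef.ring_equilibrium <- function(object, ...) object$coeffs

#' @export
predict.ring_equilibrium <- function(object, theta, ...) {
  trig_eval(object$coeffs, theta)
}

#' @export
plot.ring_equilibrium <- function(x, n = 512, ...) {
  th <- seq(0, 2 * pi, length.out = n)
  plot(th, predict(x, th), type = "l", xlab = expression(theta),
       ylab = expression(u(theta)), main = x$family, ...)
  abline(h = 0, lty = 3)
  invisible(x)
}

#' @export
residuals.ring_equilibrium <- function(object, ...) {
  equilibrium_residual(object, ...)
}

## which closed-form families exist at (b, c)?
family_exists <- function(family, b, c) {
  switch(family,
         flat = TRUE,
         single_peak = b > 0,
         double_peak = c > 0,
         mixed_plus = ,
         mixed_minus = b > 0 && b < c && c <= 2 * b,
         asym_plus = ,
         asym_minus = b > 0 && b < 2 * c,
         ## the two-domain root system is solvable only for c/2 < b < 2c
         ## (root pairs are born at b/c = 1/2 and merge in a fold at
         ## b/c = 2); this is narrower than the single-ended condition
         ## 0 < b < 2c that suffices for the asymmetric family
         two_domain_0 = ,
         two_domain_pi = b > 0 && c > 0 && b > c / 2 && b < 2 * c &&
           abs(b / c - 0.5) > 1e-10,
         FALSE)
}

existence_error <- function(family, b, c) {
  hd_stop(sprintf("family '%s' does not exist at (b = %g, c = %g)",
                  family, b, c), "hdring_existence_error")
}

#' Construct a closed-form equilibrium family
#'
#' Builds the requested equilibrium of the step-gain network with kernel
#' `w = b cos(theta) + c cos(2 theta)` (a = 0), rotated by `theta0`:
#' \describe{
#'   \item{`flat`}{`u = 0`, the unique constant solution (always exists).}
#'   \item{`single_peak`}{`(b/pi) cos(theta - theta0)`, requires `b > 0`.}
#'   \item{`double_peak`}{`(c/pi) cos 2(theta - theta0)`, requires `c > 0`.}
#'   \item{`mixed_plus` / `mixed_minus`}{
#'     `(b/pi) sqrt((c+b)/(2c)) cos(theta-theta0) +/-
#'      (sqrt(c^2-b^2)/(2 pi)) cos 2(theta-theta0)`,
#'     requires `0 < b < c <= 2b` (one positive domain; the boundary
#'     `c = 2b`, where the profile grazes zero, is flagged in `aux`).}
#'   \item{`asym_plus` / `asym_minus`}{
#'     `(b/pi) sqrt((2c-b)/(2c)) cos(theta-theta0) +/-
#'      (b/(2 pi)) sin 2(theta-theta0)`, requires `0 < b < 2c`; the two are
#'     mirror images of each other.}
#'   \item{`two_domain_0` / `two_domain_pi`}{profiles with two positive
#'     domains per period, obtained numerically by [solve_two_domain()];
#'     the defining root system is solvable exactly for `c/2 < b < 2c`
#'     (see the vignette -- the single-ended condition `0 < b < 2c` that
#'     suffices for the asymmetric family is not enough here).}
#' }
#'
#' @param family One of the family labels above.
#' @param b,c Weight coefficients the solution solves.
#' @param theta0 Rotation phase (radians); the whole family is the orbit of
#'   the canonical solution under rotation.
#' @return A `"ring_equilibrium"` object.
#' @examples
#' sol <- construct_family("single_peak", b = 3, c = 2, theta0 = pi)
#' max(abs(predict(sol, pi) - 3 / pi))  # peak value b/pi at theta0
#' @export
construct_family <- function(family, b, c, theta0 = 0) {
  family <- match.arg(family, setdiff(FAMILIES, "numeric"))
  if (!family_exists(family, b, c)) existence_error(family, b, c)
  sol <- switch(family,
    flat = new_equilibrium(numeric(5L), "flat", b, c,
                           aux = list(B = 0, C = 0)),
    single_peak = new_equilibrium(c(0, b / pi, 0, 0, 0), family, b, c,
                                  aux = list(B = b / pi, C = 0)),
    double_peak = new_equilibrium(c(0, 0, 0, c / pi, 0), family, b, c,
                                  aux = list(B = 0, C = c / pi)),
    mixed_plus = ,
    mixed_minus = {
      B <- (b / pi) * sqrt((c + b) / (2 * c))
      C <- sqrt(c^2 - b^2) / (2 * pi)
      s <- if (family == "mixed_plus") 1 else -1
      new_equilibrium(c(0, B, 0, s * C, 0), family, b, c,
                      aux = list(B = B, C = C,
                                 boundary = isTRUE(all.equal(c, 2 * b))))
    },
    asym_plus = ,
    asym_minus = {
      B <- (b / pi) * sqrt((2 * c - b) / (2 * c))
      C <- b / (2 * pi)
      s <- if (family == "asym_plus") 1 else -1
      new_equilibrium(c(0, B, 0, 0, s * C), family, b, c,
                      aux = list(B = B, C = C))
    },
    two_domain_0 = solve_two_domain(b, c, "0"),
    two_domain_pi = solve_two_domain(b, c, "pi"))
  if (theta0 != 0) sol <- rotate(sol, theta0) else sol$theta0 <- 0
  sol$theta0 <- theta0
  sol
}

#' Self-consistency residual of an equilibrium
#'
#' Measures `max_theta |u(theta) - (w * g(u))(theta) - I|`, which vanishes
#' exactly at an equilibrium. Two evaluation paths are provided:
#' \describe{
#'   \item{`method = "exact"`}{for the step gain, the convolution of the
#'     kernel with the indicator of the positive set of `u` is evaluated in
#'     closed form from the zeros of `u` (located by bisection to ~1e-14),
#'     so the residual is limited only by root finding. This is the
#'     certification path. For a logistic gain a fine quadrature
#'     (>= 2^15 points) is used instead.}
#'   \item{`method = "grid"`}{the Riemann-sum path through
#'     [ring_convolution()] on an `n`-point grid. For the step gain its
#'     error is O(1/n) from the jumps of the Heaviside output, so it
#'     certifies only down to that level; it is useful for convergence
#'     studies in `n`.}
#' }
#'
#' @param sol A `"ring_equilibrium"`.
#' @param w Kernel (defaults to `weight_profile(b = sol$b, c = sol$c)`).
#' @param gain Gain (defaults to the step gain).
#' @param n Grid size for `method = "grid"` (and the evaluation grid for
#'   the max in both methods). At least 256.
#' @param method `"exact"` or `"grid"`.
#' @return The max-abs residual, with attribute `"n"` giving the grid used.
#' @export
equilibrium_residual <- function(sol, w = NULL, gain = gain_function("step"),
                                 n = 2048L, method = c("exact", "grid")) {
  method <- match.arg(method)
  stopifnot(inherits(sol, "ring_equilibrium"), n >= 256L)
  if (is.null(w)) w <- weight_profile(b = sol$b, c = sol$c)
  stopifnot(inherits(w, "weight_profile"), inherits(gain, "gain_function"))
  co <- sol$coeffs
  if (method == "exact" && gain$kind == "step") {
    img <- step_image_coeffs(co, w$b, w$c, w$a, n_scan = 8192L)
    th <- 2 * pi * (0:(n - 1L)) / n
    r <- max(abs(trig_eval(co - img, th)))
    return(structure(r, n = as.integer(n)))
  }
  if (method == "exact") n <- max(n, 32768L)
  grid <- ring_grid(n)
  u <- trig_eval(co, grid$theta)
  drive <- ring_convolution(w, evaluate_gain(gain, u), grid)
  structure(max(abs(u - drive)), n = as.integer(n))
}

#' Rotate an equilibrium
#'
#' Rotation invariance: if `u(theta)` solves the equilibrium equation then
#' so does `u(theta - shift)`. The first harmonic is rotated by `shift`,
#' the second by `2 * shift`; the residual is unchanged.
#'
#' @param x A `"ring_equilibrium"`.
#' @param shift Rotation angle in radians.
#' @param ... Unused.
#' @return The rotated equilibrium.
#' @export
rotate <- function(x, shift, ...) UseMethod("rotate")

#' @rdname rotate
#' @export
rotate.ring_equilibrium <- function(x, shift, ...) {
  co <- x$coeffs
  cs <- cos(shift); sn <- sin(shift)
  c2 <- cos(2 * shift); s2 <- sin(2 * shift)
  x$coeffs <- c(co[1],
                co[2] * cs - co[3] * sn,
                co[2] * sn + co[3] * cs,
                co[4] * c2 - co[5] * s2,
                co[4] * s2 + co[5] * c2)
  names(x$coeffs) <- c("a0", "b1", "b2", "c1", "c2")
  x$theta0 <- x$theta0 + shift
  x
}

## rotate so the first-harmonic phase is 0 (b2 = 0, b1 >= 0); if the first
## harmonic vanishes, zero the second-harmonic phase instead
canonicalize_equilibrium <- function(sol, tol = 1e-10) {
  co <- sol$coeffs
  B <- sqrt(co[2]^2 + co[3]^2)
  if (B > tol) return(rotate(sol, -atan2(co[3], co[2])))
  C <- sqrt(co[4]^2 + co[5]^2)
  if (C > tol) return(rotate(sol, -atan2(co[5], co[4]) / 2))
  sol
}

## Two-domain solver -----------------------------------------------------------

## Root system for equilibria with two positive domains per period.
## An even candidate u = B cos(phi) + C cos(2 phi) with zeros at
## {-al, al, be, 2pi - be} and positive set (-al, al) u (be, 2pi - be)
## self-consistently requires (convolution over the two arcs)
##   B = (b/pi)  (sin al - sin be),  C = (c/2pi) (sin 2al - sin 2be),
## and al, be must be zeros of the resulting u. The two equations
## u(al) = u(be) = 0 in (al, be) are solved by damped Newton seeded from a
## coarse scan. Sign-flipping the candidate (u -> -u, an equilibrium again
## since the kernel has zero mean and H(-u) = 1 - H(u)) exchanges the two
## phase classes: C > 0 is the cos-2 aligned class ("0"), C < 0 the
## anti-aligned class ("pi").
two_domain_candidate <- function(al, be, b, c) {
  c(B = (b / pi) * (sin(al) - sin(be)),
    C = (c / (2 * pi)) * (sin(2 * al) - sin(2 * be)))
}

two_domain_eqs <- function(x, b, c) {
  bc <- two_domain_candidate(x[1], x[2], b, c)
  c(bc[1] * cos(x[1]) + bc[2] * cos(2 * x[1]),
    bc[1] * cos(x[2]) + bc[2] * cos(2 * x[2]))
}

#' Solve for the two-domain equilibria
#'
#' Equilibria whose activity is positive on two separate arcs per period.
#' Their defining root system (the arc endpoints must be zeros of the
#' profile reconstructed from the arc convolution) is solved numerically by
#' damped Newton iterations seeded on a coarse scan; closed-form
#' coefficient expressions for these families are fragile to transcribe,
#' so the solver is the authoritative construction and every solution is certified by its
#' self-consistency residual (< 1e-6 required, typically ~1e-12) and by its
#' sign pattern (exactly two positive arcs).
#'
#' @param b,c Weight coefficients; require `0 < b < 2c` and `b/c != 1/2`.
#' @param phase_class `"0"` (second harmonic aligned with the first,
#'   `C > 0`) or `"pi"` (anti-aligned, `C < 0`).
#' @return A `"ring_equilibrium"` with `aux` carrying the root angles
#'   `alpha`, `beta` and amplitudes `B`, `C`.
#' @export
solve_two_domain <- function(b, c, phase_class = c("0", "pi")) {
  phase_class <- match.arg(as.character(phase_class), c("0", "pi"))
  fam <- if (phase_class == "0") "two_domain_0" else "two_domain_pi"
  if (!family_exists(fam, b, c)) existence_error(fam, b, c)

  ## coarse scan for Newton seeds (vectorized over the (alpha, beta) grid)
  gseq <- seq(0.02, pi - 0.02, length.out = 96L)
  AL <- rep(gseq, times = length(gseq))
  BE <- rep(gseq, each = length(gseq))
  keep <- BE > AL + 0.05
  AL <- AL[keep]; BE <- BE[keep]
  Bv <- (b / pi) * (sin(AL) - sin(BE))
  Cv <- (c / (2 * pi)) * (sin(2 * AL) - sin(2 * BE))
  fmax <- pmax(abs(Bv * cos(AL) + Cv * cos(2 * AL)),
               abs(Bv * cos(BE) + Cv * cos(2 * BE)))
  ord <- order(fmax)
  ok <- ord[fmax[ord] < 0.08]
  if (length(ok) > 60L) ok <- ok[seq_len(60L)]
  seeds <- lapply(ok, function(i) c(AL[i], BE[i]))
  roots <- list()
  for (x0 in seeds) {
    x <- x0
    ok <- FALSE
    for (it in 1:60) {
      f <- two_domain_eqs(x, b, c)
      if (max(abs(f)) < 1e-13) { ok <- TRUE; break }
      J <- matrix(0, 2, 2)
      for (j in 1:2) {
        h <- 1e-7
        xp <- x; xp[j] <- xp[j] + h
        J[, j] <- (two_domain_eqs(xp, b, c) - f) / h
      }
      dx <- tryCatch(solve(J, f), error = function(e) NULL)
      if (is.null(dx)) break
      ## dampen to stay in the ordered domain
      lam <- 1
      repeat {
        xn <- x - lam * dx
        if (xn[1] > 1e-6 && xn[2] < pi - 1e-6 && xn[2] > xn[1] + 1e-6) break
        lam <- lam / 2
        if (lam < 1e-4) break
      }
      x <- x - lam * dx
    }
    if (!ok) next
    bc2 <- two_domain_candidate(x[1], x[2], b, c)
    if (abs(bc2[1]) < 1e-8 || abs(bc2[2]) < 1e-8) next  # degenerate / pure-harmonic
    roots[[length(roots) + 1L]] <- c(x, bc2)
  }
  if (!length(roots))
    hd_stop(sprintf(paste("two-domain root solver found no solution at",
                          "(b = %g, c = %g); scanned (alpha, beta) in",
                          "(0, pi)^2 with 96 x 96 seeds"), b, c),
            "hdring_solver_error")
  ## canonicalize candidates to B > 0 (u and -u are both equilibria; -u is
  ## the pi-rotation of the opposite phase class) and pick the class
  want_sign <- if (phase_class == "0") 1 else -1
  picked <- NULL
  for (r in roots) {
    Bv <- r[3]; Cv <- r[4]
    for (s in c(1, -1)) {
      Bs <- s * Bv; Cs <- s * Cv
      if (Bs < 0) { Bs <- -Bs } # rotation by pi flips cos, keeps cos2
      if (sign(Cs) == want_sign) picked <- c(r[1], r[2], Bs, Cs)
    }
  }
  if (is.null(picked))
    hd_stop(sprintf("no two-domain root of phase class %s at (b = %g, c = %g)",
                    phase_class, b, c), "hdring_solver_error")
  co <- c(0, picked[3], 0, picked[4], 0)
  sol <- new_equilibrium(co, fam, b, c,
                         aux = list(B = picked[3], C = abs(picked[4]),
                                    alpha = picked[1], beta = picked[2]))
  ## certification
  r <- equilibrium_residual(sol, n = 2048L, method = "exact")
  if (r > 1e-6)
    hd_stop(sprintf("two-domain solution failed certification (residual %.2e)",
                    r), "hdring_solver_error")
  if (nrow(positive_arcs(co)) != 2L)
    hd_stop("two-domain solution does not have two positive arcs",
            "hdring_solver_error")
  sol$aux$residual <- as.numeric(r)
  sol
}

## Generic multi-start fixed-point oracle --------------------------------------

## rotation-invariant signature of a trig-polynomial equilibrium:
## (B, C, relative phase of the second harmonic in the frame of the first)
equilibrium_signature <- function(co, tol = 1e-8) {
  B <- sqrt(co[2]^2 + co[3]^2)
  C <- sqrt(co[4]^2 + co[5]^2)
  psi <- if (B > tol && C > tol)
    (atan2(co[5], co[4]) - 2 * atan2(co[3], co[2])) %% (2 * pi)
  else NA_real_
  c(B = unname(B), C = unname(C), psi = unname(psi))
}

signature_match <- function(s1, s2, tol = 1e-4) {
  if (abs(s1[1] - s2[1]) > tol || abs(s1[2] - s2[2]) > tol) return(FALSE)
  ## the relative phase only discriminates when both harmonics are present
  ## in both profiles beyond the matching tolerance
  if (is.na(s1[3]) || is.na(s2[3])) return(TRUE)
  if (min(s1[1:2], s2[1:2]) <= tol) return(TRUE)
  d <- abs(s1[3] - s2[3]) %% (2 * pi)
  min(d, 2 * pi - d) < 1e-3 + tol
}

#' Multi-start search for all fixed points
#'
#' Brute-force oracle for the closed-form catalog: damped-Newton root
#' finding on the four-dimensional self-consistency map
#' `F(b1, b2, c1, c2) = coefficients of w * H(u) - (b1, b2, c1, c2)`
#' (the constant coefficient is pinned to 0 since a = 0), started from
#' seeded random coefficient vectors. Converged roots are deduplicated up
#' to rotation using the invariant signature (B, C, relative phase) and
#' labeled by matching against the closed-form catalog.
#'
#' @param b,c Weight coefficients.
#' @param n_starts Number of random starts (>= 20).
#' @param seed Integer seed for the start points.
#' @param match_tol Signature tolerance for deduplication and labeling.
#' @param lattice Also seed Newton from a deterministic lattice of
#'   amplitude/phase combinations (recommended: the basins of the
#'   asymmetric and two-domain roots under the coefficient-space map are
#'   small, so purely random starts need thousands of draws to hit them).
#' @return A list of canonicalized `"ring_equilibrium"` objects (the flat
#'   solution always included), each with `aux$residual`, `aux$n_found`
#'   (how many starts reached it) and a `family` label (`"numeric"` if no
#'   closed form matches).
#' @export
generic_fixed_points <- function(b, c, n_starts = 200L, seed = 1L,
                                 match_tol = 1e-4, lattice = TRUE) {
  stopifnot(n_starts >= 20L)
  Fmap <- function(x) {
    img <- step_image_coeffs(c(0, x), b, c, a = 0, n_scan = 2048L)
    img[2:5] - x
  }
  A <- max(0.3, 1.3 * max(b, c, 0) / pi)
  starts <- with_seed(seed, matrix(runif(4L * n_starts, -A, A), ncol = 4L))
  if (lattice) {
    amp <- max(abs(b), abs(c), 0.5) / pi
    lat <- expand.grid(B = amp * c(0.1, 0.2, 0.4, 0.7, 1),
                       C = amp * c(0.1, 0.2, 0.4, 0.7, 1),
                       psi = (0:7) * pi / 4)
    starts <- rbind(starts,
                    cbind(lat$B, 0, lat$C * cos(lat$psi),
                          lat$C * sin(lat$psi)))
  }
  n_starts <- nrow(starts)
  roots <- list()
  sigs <- list()
  counts <- integer(0)
  add_root <- function(x) {
    co <- c(0, x)
    s <- equilibrium_signature(co)
    for (i in seq_along(sigs)) {
      if (signature_match(s, sigs[[i]], match_tol)) {
        counts[i] <<- counts[i] + 1L
        return(invisible(NULL))
      }
    }
    roots[[length(roots) + 1L]] <<- co
    sigs[[length(sigs) + 1L]] <<- s
    counts[length(counts) + 1L] <<- 1L
    invisible(NULL)
  }
  add_root(numeric(4L))  # the flat solution is always a root of the map
  for (i in seq_len(n_starts)) {
    x <- starts[i, ]
    ok <- FALSE
    f <- Fmap(x)
    best <- Inf
    stall <- 0L
    for (it in 1:50) {
      nf <- max(abs(f))
      if (nf < 1e-11) { ok <- TRUE; break }
      ## abandon stagnating starts early (barren regions have no roots to find)
      if (nf > 0.5 * best) stall <- stall + 1L else stall <- 0L
      if (stall >= 5L) break
      best <- min(best, nf)
      ## central differences: keeps the iteration equivariant under the
      ## mirror symmetry (b2, c2) -> (-b2, -c2) up to O(h^2)
      J <- matrix(0, 4, 4)
      for (j in 1:4) {
        h <- 1e-6 * max(1, abs(x[j]))
        xp <- x; xp[j] <- xp[j] + h
        xm <- x; xm[j] <- xm[j] - h
        J[, j] <- (Fmap(xp) - Fmap(xm)) / (2 * h)
      }
      ## the map is rotation-equivariant, so J is singular along the orbit
      ## direction at every non-flat root: use a pseudo-inverse step
      dx <- tryCatch({
        sv <- svd(J)
        keep <- sv$d > 1e-10 * max(sv$d)
        drop(sv$v[, keep, drop = FALSE] %*%
               ((t(sv$u[, keep, drop = FALSE]) %*% f) / sv$d[keep]))
      }, error = function(e) NULL)
      if (is.null(dx) || !all(is.finite(dx))) break
      lam <- 1
      repeat {
        xn <- x - lam * dx
        fn <- Fmap(xn)
        if (max(abs(fn)) < nf || lam < 1e-3) break
        lam <- lam / 2
      }
      x <- xn; f <- fn
    }
    if (ok && all(is.finite(x))) add_root(x)
  }
  ## reflection theta -> -theta is a symmetry of the even-kernel network,
  ## so the mirror image of every root is a root: complete the set
  for (co in roots) {
    m <- c(co[2], -co[3], co[4], -co[5])
    if (max(abs(Fmap(m))) < 1e-10) add_root(m)
  }
  ## label against the closed-form catalog
  catalog <- lapply(setdiff(FAMILIES, c("numeric", "flat")), function(fam) {
    if (!family_exists(fam, b, c)) return(NULL)
    tryCatch(construct_family(fam, b, c), error = function(e) NULL)
  })
  catalog <- Filter(Negate(is.null), catalog)
  cat_sigs <- lapply(catalog, function(s) equilibrium_signature(s$coeffs))
  out <- vector("list", length(roots))
  for (i in seq_along(roots)) {
    co <- roots[[i]]
    fam <- if (max(abs(co)) < 1e-9) "flat" else "numeric"
    if (fam != "flat") {
      for (j in seq_along(catalog)) {
        if (signature_match(sigs[[i]], cat_sigs[[j]], match_tol)) {
          fam <- catalog[[j]]$family
          break
        }
      }
    }
    sol <- canonicalize_equilibrium(new_equilibrium(co, fam, b, c))
    sol$aux$residual <- as.numeric(equilibrium_residual(sol, method = "exact"))
    sol$aux$n_found <- counts[i]
    sol$aux$signature <- sigs[[i]]
    out[[i]] <- sol
  }
  out
}

#' Coerce a converged state to an equilibrium object
#'
#' Any fixed point of the two-harmonic network is exactly a trigonometric
#' polynomial of degree 2 (the convolution annihilates all higher
#' harmonics), so a converged simulation state is fully described by its
#' five leading Fourier coefficients. Labeled `"numeric"` unless a
#' closed-form signature matches within `match_tol`.
#'
#' @param state A [state_profile()] (or bare numeric vector).
#' @param b,c The weight coefficients of the network that produced it.
#' @param match_tol Signature tolerance for family labeling.
#' @return A `"ring_equilibrium"`.
#' @export
as_equilibrium <- function(state, b, c, match_tol = 1e-4) {
  u <- if (inherits(state, "state_profile")) state$u else as.numeric(state)
  f <- fft(u) / length(u)
  co <- c(Re(f[1L]), 2 * Re(f[2L]), -2 * Im(f[2L]),
          2 * Re(f[3L]), -2 * Im(f[3L]))
  sig <- equilibrium_signature(co)
  fam <- "numeric"
  for (cand in setdiff(FAMILIES, c("numeric", "flat"))) {
    if (!family_exists(cand, b, c)) next
    sol <- tryCatch(construct_family(cand, b, c), error = function(e) NULL)
    if (is.null(sol)) next
    if (signature_match(sig, equilibrium_signature(sol$coeffs), match_tol)) {
      fam <- cand
      break
    }
  }
  if (max(abs(co)) < 1e-9) fam <- "flat"
  new_equilibrium(co, fam, b, c, aux = list(signature = sig))
}

#' Equilibrium catalog at a parameter point
#'
#' Constructs every closed-form family that exists at `(b, c)` (including
#' the numerically solved two-domain families) and certifies each by its
#' self-consistency residual.
#'
#' @param b,c Weight coefficients.
#' @param n Certification grid size reported with each residual.
#' @return A data frame with one row per family: coefficients, residual and
#'   the grid size used; the equilibrium objects are attached as the
#'   `"solutions"` attribute.
#' @export
equilibrium_catalog <- function(b, c, n = 2048L) {
  sols <- list()
  for (fam in setdiff(FAMILIES, "numeric")) {
    if (!family_exists(fam, b, c)) next
    sol <- tryCatch(construct_family(fam, b, c), error = function(e) NULL)
    if (is.null(sol)) next
    sol$aux$residual <- as.numeric(equilibrium_residual(sol, n = n,
                                                        method = "exact"))
    sols[[fam]] <- sol
  }
  df <- do.call(rbind, lapply(sols, function(s) {
    data.frame(family = s$family, b = b, c = c,
               a0 = s$coeffs[1], b1 = s$coeffs[2], b2 = s$coeffs[3],
               c1 = s$coeffs[4], c2 = s$coeffs[5],
               residual = s$aux$residual, n_grid = as.integer(n),
               row.names = NULL)
  }))
  attr(df, "solutions") <- sols
  df
}
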