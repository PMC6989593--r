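---
title: "Equilibria and stability of the head-direction ring network: methods"
author: "hdring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equilibria and stability of the head-direction ring network: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdring)
```

## The model

Head-direction cells fire maximally when the animal faces one allocentric
direction. The classic mechanistic account is a ring attractor: a
continuum of units labelled by preferred direction $\theta \in [0, 2\pi)$,
coupled through a rotation-invariant kernel, whose stable states are
localized activity bumps. `hdring` analyzes the standard neural-field
dynamics

$$\tau\,\partial_t u(\theta, t) = -u(\theta, t) +
  \frac{1}{2\pi}\int_0^{2\pi} w(\theta - \phi)\, g(u(\phi, t))\, d\phi + I,$$

with the two-harmonic kernel $w(\theta) = a + b\cos\theta + c\cos 2\theta$
and a gain $g$ that is either the Heaviside step $H$ (with the symmetric
convention $H(0) = 1/2$) or the logistic sigmoid
$1/(1 + e^{-k(u - u_0)})$. A constant input $I$ only shifts profiles
vertically and can be absorbed into $a$; the closed-form catalog therefore
fixes $a = I = 0$ and $u_0 = 0$.

Three structural facts organize everything the package does:

1. **Boundedness.** Because $g \in [0, 1]$, after transients
   $|u| \le \max_\theta |w(\theta)| \cdot \max g + |I|$
   (`asymptotic_bound()`), so trajectories live in a compact set.
2. **Harmonic closure.** Convolution with a degree-2 trigonometric kernel
   annihilates every harmonic above order 2, and those harmonics decay
   freely as $e^{-t/\tau}$. Consequently *every* fixed point — including
   numerically converged sigmoid states — is exactly
   $u(\theta) = a_0 + b_1\cos\theta + b_2\sin\theta + c_1\cos 2\theta +
   c_2\sin 2\theta$, which is why `as_equilibrium()` can represent any
   converged state by five coefficients.
3. **Rotation invariance.** If $u(\theta)$ is an equilibrium so is
   $u(\theta - \theta_0)$: equilibria come in rotation orbits, and every
   non-flat equilibrium carries a neutral (zero-eigenvalue) rotation mode
   in its linearization.

## The equilibrium catalog (step gain)

Substituting the trig-polynomial form into the fixed-point equation
reduces equilibrium finding to finitely many families. `construct_family()`
builds, and `equilibrium_residual()` certifies:

| family | profile (canonical phase) | existence |
|---|---|---|
| `flat` | $u = 0$ | always (unique constant solution for $a=0$) |
| `single_peak` | $(b/\pi)\cos\theta$ | $b > 0$ |
| `double_peak` | $(c/\pi)\cos 2\theta$ | $c > 0$ |
| `mixed_plus/minus` | $(b/\pi)\sqrt{\tfrac{c+b}{2c}}\cos\theta \pm \tfrac{\sqrt{c^2-b^2}}{2\pi}\cos 2\theta$ | $0 < b < c \le 2b$ |
| `asym_plus/minus` | $(b/\pi)\sqrt{\tfrac{2c-b}{2c}}\cos\theta \pm \tfrac{b}{2\pi}\sin 2\theta$ | $0 < b < 2c$ |
| `two_domain_0/pi` | $B\cos\theta \pm C\cos 2\theta$, two positive arcs | $c/2 < b < 2c$ |

The asymmetric pair is noteworthy: mirror-image activity profiles that are
not reflection-symmetric even though the connectivity is.

**Two-domain construction.** For profiles positive on two arcs per period,
closed-form coefficient expressions are fragile to transcribe, so
`solve_two_domain()` treats the defining root system as authoritative: with zeros at $\pm\alpha,\ \pm\beta$ the arc convolution
gives $B = (b/\pi)(\sin\alpha - \sin\beta)$,
$C = (c/2\pi)(\sin 2\alpha - \sin 2\beta)$, and $\alpha, \beta$ must be
zeros of the reconstructed profile. Vieta applied to the resulting
quadratic in $\cos\phi$ forces $\cos\alpha\,\cos\beta = -1/2$ (which the
solver reproduces to $10^{-12}$). Damped Newton from a coarse
$96 \times 96$ seed scan solves the pair of equations; each solution is
certified by residual ($< 10^{-6}$ required, $\sim 10^{-12}$ typical) and
by its sign pattern. Because $u \mapsto -u$ maps equilibria to equilibria
when the kernel has zero mean, the two phase classes are sign images of
one another.

**Existence region of the two-domain pair.** Scanning the root system
densely over $(\alpha, \beta)$ shows solutions exist exactly for
$1/2 < b/c < 2$: the root pair is born at $b/c = 1/2$ (the degenerate
ratio) and merges in a fold at $b/c = 2$. The single-ended condition
$0 < b < 2c$ that governs the asymmetric family is *not* sufficient here —
at $(b, c) = (0.8, 3)$, for example, the system has no two-domain root and
the multi-start oracle finds no such class either. `family_exists()`
encodes the corrected region.

**Residual certification.** Two paths, deliberately different:

* `method = "exact"`: for the step gain the convolution of the kernel
  against the indicator of the positive set is an explicit arc integral;
  zeros of the trig polynomial are found as unit-circle roots of a
  degree-4 complex polynomial (`polyroot`) polished by Newton. The
  residual of a true equilibrium is then limited only by root-finding,
  $\sim 10^{-12}$. This is the certification path.
* `method = "grid"`: the Riemann sum through `ring_convolution()` on an
  $n$-point grid. The Heaviside jumps make this path $O(1/n)$ (about
  $7\times 10^{-4}$ at $n = 4096$), which the tests verify as a
  convergence study. It cannot certify below that level and is not asked
  to.

**The fixed-point oracle.** `generic_fixed_points()` runs damped Newton
with an SVD pseudo-inverse (the map is rotation-equivariant, so its
Jacobian is exactly singular along the orbit direction at every non-flat
root) on the 4-dimensional coefficient map
$F(b_1, b_2, c_1, c_2) = \text{coeffs}(w * H(u)) - (b_1, b_2, c_1, c_2)$.
Roots are deduplicated by the rotation-invariant signature
$(B, C, \psi)$ where $\psi$ is the relative phase $2\theta_2 - 2\theta_1$
— kept as an angle, not its cosine, because the mirror-image asymmetric
families differ only in the sign of $\psi$. Under uniform random starts
the asymmetric and two-domain basins are tiny (a few per mille), so the
default adds a deterministic amplitude/phase lattice of starts; the
deduplicated result is unchanged, only the hit rate improves.

## Linear stability

Perturbations obey $\tau\,\dot\varepsilon = -\varepsilon +
w * (g'(u)\,\varepsilon)$. In the Fourier basis the kernel transmits only
modes $\pm 1, \pm 2$ (for $a = 0$), so the Jacobian is block-triangular:
all other modes sit at the bulk rate $-1$, and the non-trivial spectrum is
$\mathrm{eig}(A) - 1$ for the $4\times 4$ coupling matrix
$A_{m\ell} = w_m\,\gamma_{m-\ell}$, where
$\gamma_q = \frac{1}{2\pi}\int g'(u(\theta))\,e^{-iq\theta}\,d\theta$.
For the step gain $g'$ is a Dirac comb on the zeros of $u$ and the
$\gamma_q$ are delta sums $\frac{1}{2\pi}\sum_i e^{-iq\theta_i}/|u'(\theta_i)|$;
for the logistic gain they are computed by trapezoid quadrature with
resolution adapted to the slope $k$ (at least $64k$ points), because the
integrand concentrates in windows of width $\sim 1/(k|u'|)$.

The package exposes **two analytic reductions side by side**:

* `mode_coupling_spectrum()` — the full $4\times4$ matrix above. Its
  eigenvalues match the dense finite-$n$ Jacobian
  (`numeric_jacobian_spectrum()`) to $10^{-6}$ and below for logistic
  gains, including the rotation zero mode. This is the path used for all
  stability *decisions* (phase diagrams, dynamics-consistency checks).
* `jacobian_spectrum()` — the classical two-root reduction: the quadratic
  factor $(\lambda+1)^2 - (\tfrac{b}{2}g_{22} + \tfrac{c}{2}g_{33})
  (\lambda+1) + \tfrac{bc}{4}(g_{22}g_{33} - g_{23}^2)$ built from the
  moments $g_{22}, g_{33}, g_{23}$ of $g'(u)$ at $e^{2i\theta}$,
  $e^{4i\theta}$, $e^{3i\theta}$ (`g_coefficients()`).

The two do not agree in general, and the discrepancy is not a numerical
subtlety. The two-root reduction couples modes $+1$ and $+2$ through the
$e^{3i\theta}$ moment; in the correct linearization modes couple through
the *difference* of their indices ($\gamma_{\pm 1}$ for modes 1 and 2) and
every mode also carries the diagonal moment $\gamma_0$, which the
reduction omits. Concretely, for the single peak at $(b, c) = (3, 2)$ the
reduction yields special roots $\{-3/2,\ -1 + c/2b\}$, while the dense
Jacobian of a steep-sigmoid single-peak equilibrium (resolved at
$n = 2000$, $k = 40$) has non-bulk spectrum
$\{0,\ -1 + c/b,\ \approx\!-1,\ \approx\!-1\}$ — a rotation zero mode the
reduction cannot produce, and a second-harmonic eigenvalue differing by a
factor of two in the coupling. The same comparison for the double peak
gives $\{0,\ -1 + b/2c\ (\times 2),\ -1\}$ against the reduction's
$\{-1, -3/2\}$.

The dynamical consequences are testable and the package tests them:

* single peak: orbitally stable iff $c < b$ (not $c < 2b$). At
  $(b, c) = (1, 1.5)$ a trajectory started near the single peak abandons
  it for the mixed solution.
* double peak: stable iff $b < 2c$ (not unconditionally).
* mixed pair: stable throughout its existence region (both reductions
  agree qualitatively here).
* asymmetric pair: unstable, $\lambda_{\max} = 7/9$ at $(3, 2)$ by the
  coupling matrix. The two-root formula evaluated with the delta-sum
  moments gives a *negative* top root for this family, so the coupling
  matrix is also what confirms the escape seen in simulation.
* two-domain pair: unstable ($\lambda_{\max} \approx 0.73$ at $(3, 2)$).

The flat state is diagonal in every treatment: eigenvalues
$-1 + g'(0)b/2$ and $-1 + g'(0)c/2$, each doubly degenerate
(`flat_stability()`). For the logistic gain $g'(0) = k/4$, giving the
stability rectangle $b < 8/k$ and $c < 8/k$; for the step gain stability
is categorical ($b < 0$ and $c < 0$).

Because of the neutral rotation mode, "stable" for non-flat equilibria
always means *orbitally* stable: $\lambda_{\max}$ at most a zero
tolerance ($10^{-7}$ by default), with the zero mode the only
non-negative eigenvalue.

## Dynamics and energy

Integration is explicit Euler with fixed $\Delta t$ on the dense circulant
weight matrix (compiled core), matching the discretized system
$\tau \dot u = -u + \frac{1}{n} W g(u) + I$ exactly; no adaptive stepping,
so a run is bit-reproducible from its config and seed. Convergence is
declared at $\max_j |du_j/dt| < 10^{-9}$ by default.

For invertible gains and even kernels the discretized energy
$$E = \frac{2\pi}{n}\sum_j \Big[\int_0^{g(u_j)} g^{-1}(V)\,dV - I g(u_j)\Big]
  - \frac{1}{4\pi}\Big(\frac{2\pi}{n}\Big)^2 \sum_{j,k} W_{jk}\, g(u_j) g(u_k)$$
uses the same quadrature as the dynamics, so discrete descent holds up to
Euler truncation error; at $\Delta t = 10^{-3}$ the tests see strict
descent to $10^{-9}$ per step across seeded random starts. The inner
integral has the closed form $u_0 x + k^{-1}[x\ln x + (1-x)\ln(1-x)]$ at
$x = g(u)$. The step gain is excluded (its inverse does not exist); a
steep logistic ($k \ge 10^3$) is the documented stand-in for a
Heaviside-limit energy.

Two discretization artifacts worth knowing about:

* With the step gain and $b, c < 0$, trajectories approach the flat state
  only up to an $O(\Delta t)$ chattering band — cells at threshold flip
  their Heaviside output each step. The tests assert the band at
  $\Delta t = 0.01$ rather than exact convergence.
* On an $n$-cell grid an unstable equilibrium is escaped only if the
  perturbation actually flips a cell's sign: the flip threshold scales
  like $|u'| \cdot 2\pi/n$. The instability-escape test therefore uses
  $n = 1000$ with noise $\sigma = 10^{-3}$, where the two scales cross.
* The same quantization pins the step-gain fixed points: each continuum
  equilibrium is represented by a discrete set of pinned states whose
  distance from the continuum family is $O(1/n)$ with a pinning-dependent
  spread — for the two-bump state at $n = 500$ between $2\times 10^{-5}$
  (balanced arcs) and $\sim\!2\times 10^{-2}$ (arcs unbalanced by one
  cell). Which pinning a noisy start selects depends on the seed, so
  convergence comparisons at fixed $n$ carry this floor.

Convergence tests compare a final state against the *rotation orbit* of
the target family (phase fitted from the dominant harmonic's complex
argument), because random perturbations leave the final bump phase
slightly off the nominal one — the rotation mode is neutral, so the phase
is inherited from noise, not restored.

## Phase diagrams and shifting

`analytic_phase_diagram()` evaluates existence from the catalog conditions
and stability from the coupling matrix (closed forms for flat, single and
double; delta sums for the rest). `numerical_phase_diagram()` follows the
simulation protocol — per cell, seeded uniform random, $\cos\theta$ and
$\cos 2\theta$ initial states at $N = 50$ cells; a cell is `bistable` when
both one- and two-peak outcomes occur. The default scan configuration is
$\Delta t = 0.01$ with a budget of $8\times 10^4$ steps and tolerance
$10^{-6}$: relaxation slows as $1/|b - 8/k|$ near the flat boundary, and
this budget lets cells one step (0.1) from the boundary settle; the
reference points from the sigmoid analysis ($k = 2$: flat at (3.5, 3.5),
one-peaked at (4.5, 3.5), two-peaked at (3.5, 4.5)) are verified at
$\Delta t = 10^{-3}$ as well. The flatness threshold is
$10^{-3} \times$ the asymptotic bound. For the steep-gain comparison
($k = 64$) the simulated labels agree with the catalog prediction — one
peak below $c = b/2$, two peaks above $c = 2b$, bistable between — on
well over 90% of off-boundary cells.

`shift_experiment()` adds the odd component $\alpha\, dw/d\theta$ to the
kernel. A traveling-wave substitution shows the equilibrium profile then
translates rigidly at angular velocity $-\alpha/\tau$: the drift is
*toward decreasing* $\theta$ for $\alpha > 0$ with this sign convention,
a direction the experiment reports signed (the speed is $|\alpha|/\tau$,
linear in $\alpha$, which the tests check to 10%). The bump position is
tracked sub-grid as $-\arg(u_m)/m$ for the dominant harmonic $m$,
unwrapped; the harmonic amplitude vector stays within a fraction of a
percent of its initial value, confirming rigid translation.

## Problem sizes and numerical defaults

* Certification grid $n = 2048$ (reported alongside each residual);
  convergence studies use the dyadic ladder 512–4096.
* Simulations: $n = 500$ for bump convergence (the protocol of the
  convergence figures), $n = 1000$ for the instability escape, $n = 50$
  for sigmoid scans, $n = 64$–256 for property checks.
* Step-gain zero finding: `polyroot` + Newton polish (fallback: 8192-point
  sign scan + bisection); zeros closer than $10^{-6}$ rad or with
  $|u'| \le 10^{-8}$ raise a degenerate-equilibrium error rather than a
  silent answer — the mixed family at its boundary $c = 2b$ grazes zero
  and is flagged this way.
* Logistic quadrature for $\gamma_q$: $\max(8192, 64k)$ points, capped at
  $2^{20}$.
* Rotation-class deduplication tolerance $10^{-4}$ on $(B, C, \psi)$,
  chosen above the solver tolerance ($10^{-11}$ on the coefficient map).

## What the synthetic protocols do and do not show

All inputs here are generated by the model itself — there is no recorded
neural data. Passing tests demonstrate internal consistency of the
analysis (closed forms vs. oracle, analytic spectra vs. dense Jacobian,
linear stability vs. nonlinear escape) under the stated kernel family and
gains. They say nothing about whether real head-direction circuits
realize a two-harmonic kernel, whether double-peaked tuning observed in
retrosplenial cortex reflects a genuinely double-peaked attractor, or how
noise and heterogeneity — absent from this idealized ring — reshape the
phase diagram. The kernel is limited to two harmonics by construction;
`ring_convolution()` and `harmonics()` accept general profiles, but the
catalog and stability reductions are specific to the two-harmonic case.
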