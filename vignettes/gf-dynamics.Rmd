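---
title: "Classifying the embedded dynamics of the Gyorgyi-Field model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying the embedded dynamics of the Gyorgyi-Field model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

The Belousov-Zhabotinsky (BZ) reaction is the canonical oscillating
chemical reaction: bromate oxidizes malonic acid, catalyzed by cerium,
far from equilibrium.  Run in a continuous-flow stirred-tank reactor
(CSTR), the reaction sustains regimes ranging from simple limit cycles
through period-doubling cascades to chemical chaos, controlled by the
flow rate $k_f$ (the inverse residence time, in s$^{-1}$).

The Gyorgyi-Field (GF) reduction condenses the BZ mechanism to three
dimensionless state variables
$x \propto [\mathrm{HBrO_2}]$, $z \propto [\mathrm{Ce^{4+}}]$,
$v \propto [\mathrm{BrMA}]$, with bromide eliminated algebraically
through its quasi-steady value

$$\tilde y = \frac{\alpha k_6 Z_0 V_0\, z v}
  {(k_1 H X_0 x + k_2 A H^2 + k_f)\, Y_0}.$$

The vector field (implemented in `gf_rhs()`, with an analytic Jacobian
in `gf_jacobian()` and an equivalent compiled version used by the
integrators) contains the seven elementary rate constants $k_1..k_7$,
the reactor concentrations $A$ (bromate), $H$ (protons), $M$ (malonic
acid), $C$ (total cerium), stoichiometric factors $\alpha, \beta$, and
the flow rate $k_f$, all with published default values
(`gf_parameters()`).

### Scaling constants

The dimensionless form requires five scaling constants
($\tau = t/T_0$, $x = X/X_0$, and so on).  The package adopts the
scalings of the original GF reduction,

$$X_0 = \frac{k_2 A H^2}{k_5},\quad
  Z_0 = \frac{C A}{40 M},\quad
  V_0 = \frac{4 A H C}{M^2},\quad
  T_0 = \frac{1}{10 k_2 A H C},$$

with $Y_0 = k_2 A H^2/(k_1 H)$ for the bromide scale.  $Y_0$ cancels
identically from the vector field (every occurrence of $\tilde y$ is
multiplied by $Y_0$), so its value is a reporting convention only.  Two
observations validate this choice end to end:

* the kept-window state ranges are $O(1)$ in all three coordinates, as
  a scaling set is designed to achieve; and
* the regime map over $k_f$ reproduces the published structure in
  detail (see below), which is a sharp test because the attractor
  depends on $T_0$ and $k_f$ essentially through their product: a
  different $T_0$ would translate and stretch every bifurcation
  boundary on the $k_f$ axis.

## Simulation protocol

`integrate_gf()` integrates with adaptive solvers and interpolates onto
a uniform grid (`dt_out`, default $10^{-4}\,\tau$) up to
$\tau_{\mathrm{final}} = 100$ from the initial state $(1,1,1)$; the
first 80% of samples are discarded (`discard_transient()`) so that all
statistics describe the attractor.  The default solver is the
Dormand-Prince 4(5) pair; a Radau IIA stiff solver with the analytic
Jacobian is available for cross-checking (`solver_crosscheck()`).
Tolerances default to $10^{-8}$ (relative) and $10^{-10}$ (absolute),
tighter than typical defaults, because positive Lyapunov exponents
amplify local error exponentially.  Note that pointwise agreement
between two solvers degrades linearly with the horizon even in periodic
regimes (accumulated phase error over hundreds of oscillation periods
-- the kept window contains roughly 1,400 of them), so the cross-check
is run on a short window with tightened tolerances; in chaotic regimes
only the downstream classification is comparable.

The indicators consume the scalar observable
$s(t) = \sqrt{x^2 + z^2 + v^2}$ (`norm_signal()`), resampled with
stride 100 (`resample_signal()`), giving $N \approx 2{,}000$ samples at
$\Delta\tau = 10^{-2}$ on the kept window.  The oscillation period is
$\approx 0.015\,\tau$, so the strided series samples the flow at
map-like intervals; feeding the heavily oversampled raw series to the
0-1 test biases its statistic toward zero, and the quadratic-cost ApEn
on 200,001 samples would be prohibitive.

## Indicators

**0-1 test for chaos** (`k_test()`).  The observation $\phi(j)$ is
mapped to translation variables
$p_c(n) = \sum_{j\le n} \phi(j)\cos(jc)$,
$q_c(n) = \sum_{j\le n} \phi(j)\sin(jc)$.  Regular dynamics leave the
$(p,q)$ orbit bounded; chaos makes it diffusive.  The mean-square
displacement over lags $n \le n_{\mathrm{cut}} = \lfloor N/10 \rfloor$
(finite-sample average over the $N-n$ available displacements) is
corrected by the mean term
$E(\phi)^2 (1-\cos nc)/(1-\cos c)$, and $K_c$ is the Pearson
correlation between lag and corrected displacement.  The statistic
$K$ is the median of $K_c$ over `n_c = 100` angles drawn uniformly
from $(\pi/5, 4\pi/5)$ -- an interval that avoids the resonance
artifacts near $c = 0$ and $\pi$ and contains the published
illustration angle $c = 1.569853$.  A zero-variance displacement
vector (constant signal) is assigned $K_c = 0$: the correlation is
undefined and regularity is the only consistent verdict.  `k_test()`
evaluates all lags at once through the autocorrelation of the complex
orbit $p + iq$ by FFT; the estimator is numerically identical to the
direct sum (tested) and an order of magnitude faster.

**Approximate entropy** (`apen()`).  $\mathrm{ApEn}(m, r, N) =
\Phi^m(r) - \Phi^{m+1}(r)$, where $\Phi^m(r)$ averages the
log-frequency of Chebyshev-distance matches of $m$-length embedded
vectors within threshold $r$.  Self-matches are included, so every
count is positive and ApEn is non-negative in practice.  Defaults:
$m = 2$ (the canonical choice), $r = 0.1$ interpreted on the signal
rescaled to unit standard deviation, which makes the statistic
invariant under affine transformations of the observable; a raw-scale
threshold is available (`r_scale = "raw"`).

**Lyapunov spectrum** (`lyapunov_spectrum()`).  Benettin's method: the
flow is integrated together with three tangent vectors driven by the
analytic Jacobian, re-orthonormalized by QR factorization every
`renorm_interval`; exponents are time-averaged log stretching factors
over $\tau \in [80, 500]$.  The horizon is deliberately several times
the simulation protocol's $\tau = 100$ because the running estimates
are still settling there.  The default interval of $0.25\,\tau$ keeps
the two leading exponents clean.  The third exponent is a very strong
contraction (order $-5{,}000$ per $\tau$; the flow is stiff), and over
intervals of a few tenths the tangent frame collapses below double
precision, so the reported $L_3$ saturates at a rounding floor.
Resolving it -- verified by the sum rule
$L_1 + L_2 + L_3 = \langle \mathrm{tr}\, J \rangle$, which the test
suite checks to 5% -- requires `renorm_interval = 5e-4` with
`rel_tol = 1e-13`.  The regime verdict only needs the signs of $L_1$
and $L_2$, which are insensitive to this.

**Geometry** (`signal_geometry` functions).  Bifurcation data are the
local maxima of each state variable
($s_{k-1} < s_k \ge s_{k+1}$, plateaus counted once at their first
sample).  Poincare sections interpolate plane crossings linearly; the
package convention is the centroid plane $v = \bar v$ of the kept
window, crossed in both directions.  The section plane is a free
convention (any transversal plane is valid); the $v$ coordinate varies
smoothly around the orbit, and its centroid plane separates all four
crossings of the period-doubled loop cleanly, whereas the $x$ centroid
plane leaves two of them closer than the cluster radius.  Crossing
points are counted by single-linkage clustering with radius `tol`
times the point-set diameter (default $10^{-3}$; periodic counts are
stable over $[10^{-3}, 10^{-2}]$).  Fourier amplitude spectra use a
Hann taper on the mean-removed signal (the kept window holds a
non-integer number of periods) with coherent-gain correction, so a
sinusoid of amplitude $a$ shows a peak of height $a$;
`peak_amplitude_fraction()` turns "harmonic comb vs broadband" into a
number.

## Sweep pipeline

`run_sweep()` computes one `indicator_record()` per grid point:
$K$, ApEn, local maxima, Poincare count, and optionally $L_1$
(expensive, off by default in sweeps).  Records are independent; each
draws its 0-1-test angles with a seed derived deterministically from
the global seed and the grid index, so results do not depend on
evaluation order, and a partial table can be resumed (`previous`).
Classification uses the midpoint cut $K \ge 0.5$ (the statistic is
bimodal near $\{0, 1\}$); values in $(0.2, 0.8)$ are flagged as
unsettled/intermittent.  `nested_zoom()` runs strictly nested
flow-rate intervals and reports the mixture of verdicts per level;
`k_apen_correlation()` quantifies the coupling between the two
indicators across a sweep.

Desk-scale defaults: 201 points over
$k_f \in (3\times 10^{-4}, 5\times 10^{-4})$ for the single sweep and
101 points per zoom level -- the regime structure is already clear at
this resolution, and a full $10^{-7}$-step (2,001-point) grid remains
available behind the CLI's `--full` flag.

## Validation signals

`generate_signal()` produces series of known dynamical class so every
indicator is testable without the GF model: offset sines and
multi-harmonic sums (regular; the nonzero mean exercises the 0-1
test's mean-correction term), logistic-map series (period-2 at
$r = 3.2$, chaotic at $r = 4$; 1,000 burn-in iterates discarded), and
seeded uniform white noise.  Each spec carries its expected verdict,
asserted in the test suite.  These fixtures emulate the *dynamical
classes* the indicators must separate -- they do not emulate
measurement noise, drift, or transients of real reactor data, so
passing them shows the indicators are implemented correctly, not that
they are robust to laboratory artifacts.

## Numerical choices and limitations

* The $x^{0.5}$ autocatalysis terms make negative $x$ a domain error;
  the right-hand side clamps $x$ at 0 within solver round-off
  ($|x| < 10^{-14}$) and treats anything below $-10^{-12}$ as an
  error.
* The Jacobian diverges at $x = 0$ ($\partial x^{0.5}$); the attractor
  stays well inside the positive octant, so this only constrains
  hypothetical sections through the axes.
* The middle Lyapunov exponent of the chaotic regime is $O(10^{-1})$
  away from zero at coarse renormalization; halving checks in the
  suite apply to $L_1$.
* On this clock (per unit $\tau$, with the scalings above) the package
  obtains $L_1 \approx 26$ for the chaotic showcase at
  $k_f = 3.5\times 10^{-4}$ -- consistent between the tangent-space
  spectrum, an independent two-trajectory divergence estimate, and the
  divergence sum rule.  Per second this is
  $L_1/T_0 \approx 1.1\times 10^{-2}$.  Reported Lyapunov magnitudes
  for this system vary with the time normalization of the estimator
  used, so cross-study comparisons should be made through the sign
  pattern and the regime map rather than raw magnitudes.
* ApEn and the 0-1 test are computed on the strided observable; their
  absolute values (not just verdicts) depend on the stride, which is
  exposed in `indicator_record()` and covered by a sensitivity test.

## Worked example

```{r}
library(gfchaos)

p <- gf_parameters(kf = 3.5e-4)
traj <- integrate_gf(p, sim_config())
kept <- discard_transient(traj)
sig <- resample_signal(norm_signal(kept), 100)

k_test(sig)$K                      # ~1: chaotic
apen(sig)                          # high entropy
count_distinct_points(poincare_points(kept))  # a band, not a finite set
maximal_lyapunov(lyapunov_spectrum(p))        # positive

tab <- run_sweep(sweep_grid(3e-4, 5e-4, n_points = 41), seed = 1)
k_apen_correlation(tab)
```
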