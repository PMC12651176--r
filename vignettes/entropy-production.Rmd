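---
title: "Entropy production in a stochastic linearized neural field: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy production in a stochastic linearized neural field: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amariepr)
```

## The model and its assumptions

The package works with a scalar neural activity field on a periodic
one-dimensional domain (a ring of length $L$ with $N$ sites, spacing
$\Delta x = L/N$). The nonlinear field equation

$$\partial_t u = -\frac{u}{\tau} + \frac{1}{\tau}\int_\Omega w(x,y)\,
f[u(y,t)]\,dy + \xi(x,t)$$

combines membrane leak ($\tau$, units of time), synaptic transmission
through the coupling kernel $w(x,y)$, a sigmoid firing-rate function
$f[u] = (e^{\beta(u^\ast-u)}+1)^{-1}$ with gain $\beta>0$ and threshold
$u^\ast>0$, and additive Gaussian forcing, white in time, with symmetric
positive-definite spatial covariance $\gamma(x,y)$. The nonlinear equation
is used **only** to locate the homogeneous fixed point $u_0$, the solution
of $f[u_0] = u_0/\tilde w$ with $\tilde w = \int w(x,y)\,dy$; all dynamical
analysis concerns the strictly linear fluctuation equation

$$\dot\eta = \Lambda\eta + \xi, \qquad
\lambda(x,y) = -\frac{\delta(x-y)}{\tau} + \frac{f'(u_0)}{\tau}\,w(x,y).$$

This presumes small fluctuations around a *stable* homogeneous state; the
package refuses to linearize at an unstable root (e.g. the middle root of a
bistable steep-gain sigmoid) because no stationary Gaussian state exists
there. A homogeneous fixed point requires constant kernel row integrals;
kernels violating this (checked to relative $10^{-8}$) are rejected rather
than silently solved for an inhomogeneous state.

Working in one dimension is a deliberate restriction: every matrix-level
formula below is dimension-agnostic, and the ring keeps the spectral route
exact and all problem sizes desk-scale. Higher-dimensional grids,
non-sigmoid activations, heterogeneous $\tau$, time-dependent kernels, and
multiplicative/colored noise are out of scope.

## Discretization convention

A single convention is used everywhere so the three entropy-production
routes agree to rounding on the *same* discrete system:

* Operators act as matrices with quadrature weight $\Delta x$ on smooth
  kernels; a Dirac delta becomes $\delta_{ij}/\Delta x$ at the values level,
  i.e. contributes $-1/\tau$ on the diagonal of the drift *matrix* with no
  $\Delta x$ factor: $\Lambda_{ij} = -\delta_{ij}/\tau +
  (f'(u_0)/\tau)\,W_{ij}\,\Delta x$.
* Spatially white noise $\gamma = T\,\delta(x-y)$ becomes
  $(T/\Delta x)\,I$.
* With these choices all $\Delta x$ factors cancel in the Lyapunov equation
  $\Lambda C + C\Lambda^{\mathsf T} = -\Gamma$, the trace formula, the
  Onsager–Machlup action and the $h$-kernel $h = \Lambda\Gamma$, which are
  therefore evaluated as plain matrix expressions.
* Noise convention: $\langle\xi\xi'\rangle = \Gamma\,\delta(t-t')$, so the
  diffusion matrix is $\Gamma/2$. Comparisons with textbook Lyapunov forms
  written as $\Lambda C + C\Lambda^{\mathsf T} = -2D$ must respect this
  factor.

## The three routes and their numerics

**Trace formula.** $\sigma = \mathrm{Tr}[(\Lambda^{\mathsf T}\Gamma^{-1} -
\Gamma^{-1}\Lambda)\Lambda C]$. The stationary covariance is obtained from
the eigendecomposition $\Lambda = VDV^{-1}$ (the transformed equation is
entrywise: $Y_{ij} = -\tilde G_{ij}/(d_i+d_j)$), then symmetrized; the
residual $\|\Lambda C + C\Lambda^{\mathsf T} + \Gamma\|_F$ must be below
$10^{-10}\|\Gamma\|_F$, with a dense vectorized (Kronecker) solve as
fallback for numerically defective drifts. $\Gamma^{-1}$ is applied via
Cholesky-based inversion of the well-conditioned covariances used here,
never by naive inversion of an ill-conditioned matrix. The antisymmetric
factor is formed as $M - M^{\mathsf T}$ with $M =
\Lambda^{\mathsf T}\Gamma^{-1}$, which makes $\sigma$ *exactly* zero in
floating point for symmetric drift with white noise. The algebraically
equivalent form $\mathrm{Tr}[2\Lambda^{\mathsf T}\Gamma^{-1}\Lambda C +
\Lambda]$ is computed alongside and must agree to $10^{-8}$ relative —
a self-check of the trace-identity chain, not a tunable.

**Path estimator.** Trajectories come from Euler–Maruyama,
$\eta_{n+1} = (I + \Lambda\,dt)\eta_n + \sqrt{dt}\,Bz_n$ with
$BB^{\mathsf T} = \Gamma$ (Cholesky factor; additive noise means the SDE
itself has no Itô/Stratonovich ambiguity). The integrator enforces
$dt\,\max|\lambda| \le 0.5$ (error) and warns above $0.1$. The entropy
functional is computed two algebraically identical ways: the
backward-minus-forward Onsager–Machlup action and the Stratonovich sum
$2\sum_n \Delta\eta_n^{\mathsf T}\Gamma^{-1}\Lambda\bar\eta_n$ with the
**midpoint** field $\bar\eta_n = (\eta_n + \eta_{n+1})/2$. The midpoint is
what makes the equal-time noise–field correlation $\Gamma/2$ emerge in the
stationary average; no Itô-form estimator is offered. The action difference
is accumulated per time step, where the quadratic terms cancel at per-step
scale; accumulating the two global actions first and subtracting loses
$\sim\!8$ digits on $10^6$-step runs and would spuriously violate the
identity gap bound $10^{-9}(1+|\Sigma|)$. Standard errors use
non-overlapping block means with block length
$\max(10/\min|\mathrm{Re}\,\lambda|,\,100\,dt)$, resampled by a 200-replicate
block bootstrap; runs shorter than 20 blocks are refused. The estimator
carries $O(dt)$ discretization bias and $O(e^{-2|\mathrm{Re}\lambda|t})$
finite-run bias, which are documented rather than corrected.

**Spectral route.** For circulant $W$ (checked: max row-roll deviation
$\le 10^{-10}$ relative) the discrete transform
$\hat w_k = \Delta x\sum_j w(x_j)e^{-ikx_j}$, $k_m = 2\pi m/L$,
$m \in [-N/2, N/2)$, makes $\lambda_k = (-1 + f'(u_0)\hat w_k)/\tau$
*exactly* the eigenvalues of the circulant drift matrix. The continuum
transform convention (with its $(2\pi)^{-d/2}$) differs only by a
normalization of $\hat w_k$ that never enters $\sigma_k =
-\mathrm{Im}^2\lambda_k/\mathrm{Re}\,\lambda_k$, which depends on the
eigenvalues alone; our convention is chosen to make the cross-route test
exact. Mode amplitudes are normalized as $\eta_k = \sqrt{\Delta x/N}\,
\sum_j \eta_j e^{-ikx_j}$, under which the mode noise amplitude equals the
transform $\gamma_k = \Delta x\sum_j \gamma(x_j)e^{-ikx_j}$ of the noise
profile (white noise: $\gamma_k = T$ for every $k$) and the stationary
variance is $\gamma_k/(-2\mathrm{Re}\,\lambda_k)$.

One grouping ambiguity had to be resolved for the stationary mode
correlators: we define
$\langle\dot\eta_k\eta_k^*\rangle = \gamma_k(\lambda_k^* -
\lambda_k)/(4\,\mathrm{Re}\,\lambda_k)$, the grouping under which
$\lambda_k\langle\dot\eta_k^*\eta_k\rangle/\gamma_k +
\lambda_k^*\langle\dot\eta_k\eta_k^*\rangle/\gamma_k$ reduces *exactly* to
$\sigma_k$, and which matches both the direct Ornstein–Uhlenbeck
computation ($\langle\dot\eta\eta^*\rangle = \lambda\langle|\eta|^2\rangle
+ \gamma/2$) and the simulation estimator in the test suite. For
$\lambda = -1+i$, $\gamma = 2$ this gives $+i$.

Note the total $\sigma$ of a kernel whose transform does not decay (the
pure-shift family) grows with $N$: the per-mode formula is the meaningful
continuum object there, and the spectrum print method flags spectra whose
highest-$|k|$ mode still contributes more than 1% of the total.

**Equilibrium diagnostics.** Detailed balance is equivalent to the symmetry
of $h(x,y) = \int\lambda(x,z)\gamma(z,y)\,dz$; at the matrix level
$h = \Lambda\Gamma$ (a convention-independent composition). The default
verdict threshold on $\|h - h^{\mathsf T}\|_F/\|h\|_F$ is $10^{-8}$
(configurable): the continuum condition is exact, floating point needs a
threshold. Symmetry of $w$ is sufficient only for white noise; the
construction $\Lambda = H\Gamma^{-1}$ with symmetric negative-definite $H$
shows asymmetric drift in equilibrium with matched correlated noise.

**Shannon route.** For the stationary Gaussian with density kernel
$C^{-1}$, the total and reservoir entropy rates are exact traces: with
$v = A\eta$, $A = \Lambda + \tfrac12\Gamma C^{-1}$ (the probability-current
coefficient), $\dot S_{tot} = 2\,\mathrm{Tr}[A^{\mathsf T}\Gamma^{-1}AC]$
and $\dot S_{res} = 2\,\mathrm{Tr}[A^{\mathsf T}\Gamma^{-1}\Lambda C]$.
Their difference telescopes to $\mathrm{Tr}\,\Lambda + \tfrac12
\mathrm{Tr}[\Gamma C^{-1}]$, which the Lyapunov equation makes vanish — the
system entropy is constant at stationarity and everything produced is
dissipated to the reservoir. A Monte-Carlo version samples
$\eta\sim N(0,C)$ and averages $2v^{\mathsf T}\Gamma^{-1}\Lambda\eta$,
serving as an independent stochastic cross-check of the same quantity.

## Tunable parameters

| parameter | meaning | default | rationale |
|---|---|---|---|
| `tau` | relaxation time (time units) | user | sets the overall rate scale; $\sigma \propto 1/\tau$ at fixed kernel |
| `beta`, `u_star` | sigmoid gain, threshold | user | `beta * w_tilde / 4 > 1` makes the fixed-point equation bistable |
| `width` | kernel length scale (space units) | user | sets how fast $\hat w_k$ decays |
| `shift` | kernel displacement | 0 | the sole source of irreversibility under white noise |
| `normalization` | target row integral $\tilde w$ | none | pins $u_0$ and the $k=0$ eigenvalue |
| `amplitude` (noise `T`) | noise strength | 1 | provably absent from $\sigma$; tested, not assumed |
| `dt` | integration step | user | guard at $0.1/\max|\lambda|$ (warn), $0.5$ (error); estimator bias $O(dt)$ |
| stability tolerance | $\max\mathrm{Re}\,\lambda < -10^{-10}$ | fixed | Lyapunov solve and $t\to\infty$ limits need strict stability |
| equilibrium tolerance | relative $h$-asymmetry | $10^{-8}$ | see above |

## What the generators emulate — and what they do not

The parametric kernels (Gaussian, shifted Gaussian, mexican hat, pure
shift) and noise families (white, squared-exponential correlated) span the
qualitative regimes the theory distinguishes: reversible symmetric
coupling, irreversible asymmetric coupling, and noise with or without
spatial structure. They are translation-invariant profiles on a ring —
deliberately idealized. Real cortical connectivity is heterogeneous,
bounded, delayed and plastic; real fluctuations are non-Gaussian,
multiplicative and non-Markovian in part. Passing tests therefore
demonstrate the correctness of the computational machinery on the model
class it implements, not the adequacy of that class for any particular
dataset. In particular, the noise-independence of $\sigma$ is a theorem
*for additive Gaussian noise with a time-independent kernel* and should not
be extrapolated beyond it.

## Problem sizes and numerical choices in the shipped checks

The test suite and the acceptance script run at $N \le 64$ sites,
trajectories up to $2\times10^6$ steps ($dt$ between $10^{-3}$ and
$5\times10^{-3}$, horizons up to $10^4$ time units), and $10^5$ Monte-Carlo
samples — sizes chosen so every stochastic check resolves its target within
the quoted 3-standard-error bands in seconds on one CPU. Stationary
covariance recovery uses horizons of $\gtrsim 5\times10^3$ slowest
relaxation times, where the sampling error of the empirical covariance sits
near 3% in relative Frobenius norm, comfortably inside the 5% contract.
Degenerate inputs are errors, not warnings: non-PD covariances, unstable
drifts, non-circulant inputs to the spectral route, trajectories too short
to block, and model/trajectory fingerprint mismatches in the path
estimator.

## Known limitations

* Dense linear algebra throughout: intended for $N \lesssim 256$.
* The Lyapunov eigendecomposition route assumes a diagonalizable drift; the
  Kronecker fallback covers defective cases at $O(N^6)$ cost.
* No entropy-production inference from data with unknown drift/diffusion,
  no coarse-grained or partial-observation bounds, and no treatment of
  non-stationary transients: every $\sigma$ here is a stationary quantity.
* The path estimator requires consecutive saved steps (`save_stride = 1`);
  strided trajectories bias the Stratonovich sum by $O(\mathrm{stride}\cdot
  dt)$.
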