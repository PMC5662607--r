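---
title: "The bout-structured random acceleration model: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The bout-structured random acceleration model: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boutmotion)
```

## The model

An animal foraging in a statistically stationary environment receives cues
(visual, auditory, olfactory, tactile) at random times and responds by
changing the force it exerts. `boutmotion` models one spatial coordinate of
this movement by Newton's second law with linear (Stokes) drag,

$$\ddot x = -\gamma \dot x + a(t),$$

where $\gamma = c/m$ is the drag per unit body mass and $a(t)$ is the force
per unit mass ("acceleration") exerted by the animal. The stochastic
structure of $a(t)$ is the model's defining feature:

* time is partitioned into *bouts* by cue arrivals, a Poisson process of
  rate $\omega$, so bout durations are exponential with mean $1/\omega$;
* within a bout the acceleration is constant; at each cue it is redrawn
  independently from a distribution $\phi(a)$ with zero mean (isotropic
  environment) and finite variance $\nu_a^2$ (finite energy expenditure).

The resulting forcing is exponentially correlated,
$\langle a(t)a(t+\Delta)\rangle = \nu_a^2 e^{-\omega\Delta}$, and
discontinuous — a Langevin equation with a *non-Wiener* process. Two
classical movement models are recovered as limits: the standard
Wiener-driven Langevin equation at low drag ($\zeta = \gamma/\omega \ll 1$,
with matched forcing variance $q^2 = 2\sigma^2/\omega$), and the velocity
jump process at high drag ($\zeta \gg 1$, where velocity relaxes to the
within-bout terminal value $a/\gamma$ between cues).

All analysis is done in the dimensionless variables $\tau = \omega t$,
$\zeta = \gamma/\omega$, $\eta = \sigma/\omega^2$ (with
$\sigma = \nu_a$); physical units enter only through `model_params()` and
`rescale_parameters()`. Because the mean squared displacement (MSD) depends
on $\phi(a)$ only through its variance, the package ships three families
(`gaussian`, `uniform`, `two_point`) spanning bounded and unbounded
support, and the test suite checks that their simulated MSDs are
statistically indistinguishable.

## Exact MSD and its regimes

For the process started at rest the MSD has a closed form
$\langle x^2(\zeta,\tau)\rangle$ (`msd_exact()`), valid for every
$\zeta > 0$; the apparent $1/(\zeta-1)$ singularity is removable. Although
its derivation assumed $\zeta > 1$, the expression agrees with simulation
for all $\zeta$, and the package treats it as valid throughout (results for
$\zeta < 1$ are derivation-extended but simulation-confirmed). Its limits,
each exposed as a function:

* $\tau \to 0$: $\langle x^2\rangle \sim (\eta^2/4)\tau^4$ — superballistic
  onset, independent of drag (`msd_small_time()`);
* $\zeta \to 0$: the drag-free envelope
  $\langle z^2(\tau)\rangle = (\eta^2/3)[\tau^2(2\tau-3)+6-6(1+\tau)e^{-\tau}]$,
  an upper bound for every $\zeta$ (`msd_zero_drag()`);
* $\zeta \ll 1$, $\tau \gg 1$: the Wiener-limit MSD with its $t^3$
  superdiffusive onset (`msd_low_drag()`);
* $\zeta \gg 1$, $\zeta\tau \gg 1$: the velocity-jump MSD with its $t^2$
  ballistic onset (`msd_high_drag()`);
* $\tau \to \infty$: the diffusive asymptote
  $\Delta_d^2(\zeta,\tau) = (2\eta^2/\zeta^2)\tau -
  \eta^2[1+2(1+\zeta)^2]/[\zeta^3(1+\zeta)]$ with diffusion coefficient
  $D = \nu_a^2/(\gamma^2\omega)$ (`diffusive_asymptote()`,
  `diffusion_coefficient()`), where the dispersal kernel becomes Gaussian
  with variance $\Delta_d^2$ (`gaussian_kernel()`).

The effective small-time exponent depends on the drag ratio: $t^3$ for
$\zeta \ll 1$, $t^4$ at intermediate drag, $t^2$ for $\zeta \gg 1$
(`classify_drag_regime()`; the decade thresholds 0.1 and 10 are a reporting
convention only).

### Numerical evaluation

The closed form is numerically treacherous: at small $\tau$ its terms
cancel to $O(\tau^4)$, at small $\zeta$ to $O(\zeta)$, and near $\zeta = 1$
the bracketed factor itself vanishes. `msd_exact()` therefore evaluates by
region, using exact series generated symbolically from the closed form:

* $\tau \le 0.5$ and $\zeta\tau \le 0.5$ (extended to $\zeta\tau \le 1$ for
  $\zeta \ge 32$): power series in $\tau$, orders 4–18, coefficients
  polynomial in $\zeta$;
* small $\zeta$ at larger $\tau$: power series in $\zeta$, orders 0–10,
  chosen over the direct formula only when a cancellation-error estimate
  favours it;
* otherwise the direct formula, with a 5-term Taylor expansion of the
  bracket about $\zeta = 1$ when $|\zeta - 1| < 10^{-3}$.

Against a 120-digit reference the hybrid is accurate to about $10^{-13}$
relative in routine use and never worse than $3\times10^{-10}$ (an extreme
high-drag corner, $\zeta \ge 10^3$ with $\zeta\tau$ near 1). All
exponentials appear with non-positive arguments, so underflow to zero is
exact in the limit; the terms $1-e^{-g}$ and $g + e^{-g} - 1$ are computed
via `expm1` and a short series to preserve ~15 digits at small $g$.

## Transition times

Two times summarise the transient structure at drag $\zeta$ and confidence
$\varepsilon \in (0,1)$:

* $\tau_{sd}$, the end of the superdiffusive stage: the first $\tau$ at
  which $\langle x^2\rangle/\langle z^2\rangle$ falls to
  $\varepsilon_{sd}$ (`tau_sd_exact()`), with the small-$\tau$ closed form
  $\tau_{sd} \approx 3(1-\varepsilon_{sd})/(2\zeta)$ (`tau_sd_approx()`);
* $\tau_d$, convergence to diffusion. The exact MSD approaches
  $\Delta_d^2$ *from above* (the dropped exponential terms are positive at
  small and moderate $\zeta$ — the package verifies this numerically), so
  the proximity condition is applied to the magnitude of the deviation,
  $|\langle x^2\rangle/\Delta_d^2 - 1| = 1 - \varepsilon_d$
  (`tau_d_exact()`). At leading order in small $\zeta$ this is solved by
  $\tau_d \approx \zeta^{-1}\{3/2 + W[2/(e^{3/2}(1-\varepsilon_d))]\}$
  with $W$ the principal Lambert branch (`tau_d_approx()`,
  `lambert_w0()`).

Both exact solvers use geometric bracket expansion from the valid end of
the domain followed by bisection to $10^{-12}$ relative width, and verify
the defining relation at the root to $10^{-8}$; `tau_d_exact()` also checks
on a diagnostic grid up to $10\tau_d$ that the deviation stays inside the
band, warning otherwise.

**Where the closed forms are good.** The Lambert form of $\tau_d$ converges
to the exact crossing as $\zeta \to 0$ (below 0.5% for $\zeta \le 10^{-2}$).
The $\tau_{sd}$ closed form was derived for small $\tau$; when the crossing
happens late ($\tau_{sd} \gtrsim 10$, i.e. small $\zeta$ at fixed
$\varepsilon$) the proximity deficit is governed by the large-$\tau$ branch
of the envelope ($\propto 3\zeta\tau/4$ instead of $2\zeta\tau/3$), and the
closed-form-to-exact ratio tends to $9/8$ rather than 1. Agreement is
therefore best as $\varepsilon \to 1$ at fixed $\zeta$ — e.g. 2.4%, 1.6%,
0.2% at $\zeta = 10^{-2}$ for $\varepsilon = 0.9, 0.99, 0.999$ — but
reaches 5–8% at $\zeta = 10^{-3}$ for $\varepsilon \le 0.99$. The test
suite asserts the first behaviour and (deliberately) records the second as
a failing expectation at its stated 5% band rather than widening it: the
discrepancy is a property of the approximation itself, verified against
independent 50-digit root-finding.

Halley iteration for $W_0$ runs until the iterate converges to machine
precision; the achievable residual $|we^w - x|$ is $(1+w)x\epsilon$, i.e.
below $10^{-12}$ in absolute terms for arguments up to a few hundred
(covering the $\varepsilon$ grids used here) and below
$10^{-12}\max(1,x)$ always.

`loglog_slope()` quantifies the $t^\alpha$ statements: a centred finite
difference of $\ln \mathrm{MSD}$ vs $\ln\tau$ with multiplicative step
$1 \pm 10^{-3}$ (callables), or the derivative of a natural cubic spline
through $(\ln\tau, \ln \mathrm{MSD})$ (tabulated curves). Note the exact
slope at finite $\tau$ carries a correction
$-\tau(4/15 + 2\zeta/3) + O(\tau^2)$, which is why slope checks at
$\tau = 10^{-4}$ across $\zeta \le 64$ are asserted around the corrected
value rather than exactly 4.

## The simulator

Within a bout the dynamics are linear with constant forcing, so velocity
and position have exact closed forms; the simulator (`simulate_positions()`
in R, the same algorithm compiled for ensembles) advances bout to bout with
*no time-discretisation error* — the only randomness is in the bout
durations and accelerations, and the only numerical error is round-off.
Design choices:

* a sample time inside a bout reads the state without ending the bout (the
  bout keeps its residual duration) — observation does not perturb the
  process;
* $\gamma = 0$ uses the drag-free forms $v + a\,dt$,
  $y + v\,dt + a\,dt^2/2$ (removable singularity of the general solution);
* every stochastic function takes an explicit seed; an ensemble call
  consumes a single seeded RNG stream sequentially, so results are
  bit-reproducible given `(seed, sample_times, n)`. The pure-R and compiled
  engines consume identical streams, which the tests verify path by path
  for all three acceleration families;
* trajectories can also be evaluated through the explicit bout-sum solution
  (`positions_closed_form()`), an independent route used for
  cross-checking and fixtures.

Ensemble estimators: `ensemble_msd()` (mean of $x^2$ with standard errors
from the across-trajectory variance of $x^2$), `ensemble_pdf()` (histogram
dispersal kernel on symmetric bins centred at 0, default extent
$\pm6\sqrt{\Delta_d^2}$, plus the renormalised form
$\tilde\rho(x) = \rho(x)/\rho(0)$; a warning is issued when the central bin
holds fewer than 10 samples), and `empirical_acc_autocov()` (time-average
forcing autocovariance from one long realization, standard errors from
block means over blocks much longer than the correlation time $1/\omega$).

### What the simulations emulate — and what they do not

The generator reproduces the model's study conditions: trajectories start
at rest, bouts are exponential, accelerations i.i.d. with variance
$\nu_a^2$. Reference ensembles use $10^5$ trajectories for MSD curves
(against $10^7$ at full scale) and $10^6$ for the large-time kernel
(against $10^9$), with acceptance bands widened accordingly (Monte Carlo
agreement within 4 standard errors at $\ge 95\%$ of grid points;
Kolmogorov–Smirnov distance to the Gaussian kernel below 0.01 at
$\tau = 1024$). The kernel reproduction uses $\zeta = 1$ as its default
setting. Passing tests show the implementation is internally consistent
and matches the closed-form theory at these sizes; they do not show that
real animals follow the model — no fitting to empirical tracking data is
provided, movement is 1D (the isotropic 2D case follows as
$\langle r^2\rangle = 2\langle x^2\rangle$, which the tests verify), drag
is strictly linear (no Oseen corrections, so Reynolds numbers above
$\sim10^3$–$10^4$ are outside scope), and rest periods / intermittent
movement are not modelled.

## Problem sizes and runtime

Default test-suite sizes: $10^5$ trajectories per drag value for the MSD
grid (seven $\zeta$ values, $\tau \le 10^2$, ~15 s total), $10^6$
trajectories for the $\tau = 1024$ Gaussianity check (~2 min), $10^6$
draws for distribution-moment checks, $10^5/\omega$ of realization for the
autocovariance. The whole suite runs in about two minutes on one CPU; the
acceptance script is deterministic and runs in seconds.

## Known limitations

* `msd_exact()` loses accuracy (to ~$10^{-9}$ relative) only in the extreme
  high-drag corner $\zeta \gtrsim 10^3$ with $\zeta\tau$ of order 1–10;
  regime analysis there is unaffected at the tolerances used.
* `tau_d_exact()` requires the deviation band to be reached within
  $\tau \le 10^9 \max(1, 1/\zeta)$ and reports the first crossing if the
  deviation re-enters the band (it warns if that happens).
* The dispersal kernel is exposed only through simulation and its Gaussian
  large-time limit; the full time-dependent kernel has no closed form here.
* Heavy-tailed acceleration distributions (infinite variance) are outside
  the model class by assumption.
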