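---
title: "Topologically protected steady states in driven Markov networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topologically protected steady states in driven Markov networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stochtopo)
```

## The model

stochtopo works with continuous-time Markov chains on networks whose states
carry an integer horizontal coordinate $x$. The occupancy vector evolves by
the master equation
$$\frac{d\mathbf p}{dt} = W \mathbf p,$$
with $W_{ij}$ the rate of the jump $j \to i$ and diagonal entries equal to
minus the total outflow, so columns sum to zero. We study networks built
from two *bulks* — translationally invariant repetitions of a unit cell of
$B$ internal states per column — joined at interfaces where the rates
interpolate between the bulks.

The central object is the tilted current matrix
$$W(\lambda)_{ij} = W_{ij}\, e^{\lambda d_{j\to i}}, \qquad i \neq j,$$
where $d \in \{-1, 0, +1\}$ is the displacement of the jump along the axis
(a hop across a periodic seam counts $\pm 1$, never the raw coordinate
difference). The largest eigenvalue $e(\lambda)$ of $W(\lambda)$ is the
scaled cumulant generating function of the time-integrated current;
$e(0) = 0$, and $e'(0)$ is the mean current $J$.

### Bulk winding numbers

In a translationally invariant bulk the tilted generator block-diagonalizes
into Bloch matrices
$$W(k, \lambda) = \mathrm{intra} + \mathrm{hop}_+ e^{ik+\lambda}
  + \mathrm{hop}_- e^{-ik-\lambda} + D,$$
with $D$ the untilted outflow diagonal. Writing the determinant as
$\det W(k,\lambda) = |D| e^{i\theta(k,\lambda)}$, the winding number
$$w(\lambda) = \frac{\theta(2\pi,\lambda) - \theta(0,\lambda)}{2\pi}$$
is an integer whenever the determinant does not vanish on the
$k$-circle. Our sign convention is fixed so that a rightward-biased
single-row bulk at $\lambda > 0$ has $w = +1$; only differences and the
signs of mismatches carry physical content, and with this orientation the
proofreading bulks get the labels $+1$ (product-localized) and $-1$
(reactant-localized). $\lambda = 0$ is excluded — conservation forces
$\det W(0, 0) = 0$ — so window membership is always assessed on both sides
of zero.

When the two bulks disagree, $\delta w = w_L - w_R \neq 0$ on an interval
$\lambda^- < 0 < \lambda^+$, the composite network is guaranteed a zero
mode of $W(\lambda)$ localized at the interface throughout that window. At
$\lambda = 0$ this is the steady state itself: it is exponentially
localized at the seam, carries zero net current, and its localization is
insensitive to disorder in the rates — only the bulk invariants matter.

### Two independent routes to $w$

`winding_number()` integrates the unwrapped determinant phase over a
$k$-grid (default 512 points, with a per-step jump guard and a
band-touching check). `winding_oracle_roots()` is an algebraically
independent oracle: substituting $z = e^{ik}$ makes $\det W(z,\lambda)$ a
Laurent polynomial; clearing the order-$B$ pole leaves a polynomial whose
roots inside the unit circle count the winding by the argument principle,
$w = \#\{|z| < 1\} - B$. The test-suite checks the two routes agree on
hundreds of seeded random cells ($B \le 3$, rates log-uniform on
$[0.1, 10]$).

The same polynomial at $\lambda = 0$ yields the bulk localization data:
roots with $|z^*| < 1$ give decay rates $\kappa = -\log|z^*|$ for profiles
decaying leftward, roots with $|z^*| > 1$ rates for profiles decaying
rightward, and localization lengths $\eta = 1/\kappa$. On the solvable
single-row pair (rates 2/1 against 1/2) everything is available in closed
form: the window is exactly $(-\log 2, \log 2)$, the decay rate in either
bulk is $\log 2$, and the window endpoints coincide with the decay rates —
the relation between $\lambda^\pm$ and $\eta^{L/R}$ that we verify
explicitly rather than assume in general.

```{r solvable}
win <- lambda_window(bulk_cell_1d(2, 1), bulk_cell_1d(1, 2))
tidy(win)
bulk_decay_rates(bulk_cell_1d(2, 1))$decay
```

### The interface index

`zero_modes()` finds right and left null vectors of $W(\lambda)$ from the
smallest singular values; `local_index()` counts right minus left modes
whose 1-norm mass is majority-localized in a chosen interface region. By
bulk–boundary correspondence this equals $\delta w$ of the flanking bulks.
Two numerical choices deserve comment:

* **Relative zero tolerance.** On a finite network the topological zero
  mode is split by an amount $\sim e^{-N/\eta}$ in the bulk width $N$. The
  default tolerance $10^{-6}$ (relative to the largest singular value)
  presumes roughly $N \ge 30$ columns per bulk at $\kappa \approx \log 2$.
* **Where to evaluate $\lambda$.** The conjugate (left) zero mode has
  localization length $\approx 1/\lambda$: at $\lambda = 0$ it is the
  exactly uniform vector, and it sharpens only deeper into the window. An
  index probe of the $\delta w = -1$ seam therefore needs $\lambda$ large
  enough that $1/\lambda$ is a few columns (we use $\lambda = 0.3$ with a
  $\pm 3$-column region), while the $\delta w = +1$ seam already works at
  $\lambda = 0.05$ because the steady-state-like right mode decays at
  $\approx \log 2$ per column. Mode-to-region assignment uses majority
  mass (`frac = 0.5`) with ties broken toward "not in region".

The literal composed-matrix reading $\dim\ker \rho W(\lambda)$ is exposed
as `local_kernel_dim()` for diagnosis, but at finite size it returns the
generic dimension $n - |\mathrm{region}|$: an extra kernel dimension would
require a conjugate mode *strictly supported* in the region, which
exponential tails preclude. Localized-mode counting is the operative
definition.

## Steady states: why GTH elimination

`steady_state()` uses Grassmann–Taksar–Heyman state elimination rather
than a dense null-space solve. GTH performs only additions,
multiplications and divisions of non-negative rates, so each entry of the
stationary vector carries small *relative* error regardless of
conditioning. This matters here: the reversed-driving adaptation lattice
is bimodal with wells coupled by fluxes as small as $e^{-2S}$; a generic
eigen- or SVD-based solve sees a numerically two-dimensional kernel and
cannot apportion mass between the wells, while GTH resolves both the
$10^{-21}$-scale interior marginals and the well weights. Reducible
networks are still detected (a state with zero outflow into the remaining
states during elimination) and reported with the strongly connected
components at validation time.

Eigenvalue quantities ($e(\lambda)$, spectral gaps, scans of the smallest
singular value of $W(\lambda)$) use dense `eigen()`/`svd()`. All study
networks here are small (at most a few hundred states), where dense
factorizations are faster and more robust than iterative sparse solvers;
nothing in the interface assumes density, so a sparse backend could be
swapped in for larger lattices.

## The biophysical models

### Chemosensory adaptation

The adaptation lattice has activity $a \in \{0, 1\}$ (rows) and
methylation $m \in 0..M-1$ (columns). Activity flips derive from the free
energy $f(a, m) = a E (S - m)$ through Glauber-form rates
$\omega_a\,\sigma(E(m - S))$ for $0 \to 1$ and $\omega_a\,\sigma(E(S - m))$
for $1 \to 0$: sigmoid in $m$ with crossover at $m = S$ (the log
chemoattractant concentration), saturating far from the crossover — which
is precisely what makes the two halves of the lattice translationally
invariant bulks. Methylation implements the feedback: inactive receptors
methylate ($m \to m+1$ at $\omega_m$), active ones demethylate
($m \to m-1$ at $\omega_m$), with the reverse moves suppressed by
$e^{-G}$. Boundaries at $m = 0, M-1$ are reflecting (probability is
conserved without auxiliary states). Defaults $M = 48$, $E = 6$,
$\omega_a = \omega_m = 1$, $G = \pm 2$ are the study conditions used
throughout the tests.

Because $\sigma(x)/\sigma(-x) = e^x$ exactly, every elementary plaquette
of this lattice has cycle affinity $2G + E$: the lattice is equilibrium
only at $G = -E/2$, and the flip rates themselves contribute $E$ per
cycle. `plaquette_affinities()` verifies the affinity is uniform — the
Kolmogorov-criterion fingerprint of this rate scheme. (Flip rates are
floored at $\omega_a e^{-|E| \cdot 10}$ so that remote columns stay
connected to both rows; the floor matches the saturated cells returned by
`bulk_limits()` and is irrelevant at the $10^{-26}$ level elsewhere. Pass
`floor_distance = Inf` to disable it.)

For $G = +2$ both bulk drifts point at the crossover, $\delta w = +1$, and
the steady state is a localized pulse that tracks $S$: across
$S \in [12, 36]$ the mean activity stays at its set point to within a
fraction of a percent and $\langle m\rangle - S$ is constant to well under
half a methylation level, clean or disordered. For $G = -2$ the drifts
reverse, $\delta w = -1$, the distribution is bimodal at the lattice
edges, and activity switches with $S$ — no adaptation. `adaptation_sweep()`
reports both regimes; its flank fits use columns 2–12 away from the
profile peak.

### Kinetic proofreading

A proofreading cascade is modelled as the minimal single-row chain from
reactants to products with uniform forward/backward rates — one bulk
against vacuum at both ends. The single label for that geometry is
`topological_charge()`, the sum $w(+\epsilon) + w(-\epsilon)$, which we
justify on the solvable model: correct-substrate kinetics (forward >
backward) give $+1$ and product-end localization with end-to-end occupancy
ratio $(f/b)^n$; wrong-substrate kinetics give $-1$ and reactant-end
localization.

## Kinetic Monte Carlo cross-validation

`gillespie_run()` is the direct stochastic simulation algorithm (single
seeded RNG stream, exponential waiting times, rate-proportional jump
choice); `occupancy()` turns a trajectory into time-weighted occupancies
and an empirical current, discarding a 10% burn-in and reporting
batch-mean standard errors over 10 equal time batches. The tests confirm
total-variation convergence to the exact steady state (below 0.02 by
$T = 10^5$ on the open two-bulk chain) and currents consistent with
$J = e'(0)$ within 3 standard errors on the biased ring and the driven
adaptation lattice.

## What the synthetic fixtures do and do not show

All inputs are generated in code: the solvable two-bulk pair and its open,
periodic, identical-bulk and disordered variants, the adaptation lattices
at $G \in \{-2, 0, 2\}$, the proofreading chains, and seeded random unit
cells. They exercise exactly the regime the theory addresses —
quasi-one-dimensional lattices with saturating interfaces and
log-uniform quenched disorder. They do not emulate broken translational
invariance inside a bulk, hops beyond nearest-neighbour columns
(`disp` beyond $\pm 1$ is reserved but unimplemented), multi-bulk
composites, or rate distributions with heavy tails; passing tests say
nothing about those cases.

Problem sizes were chosen once as the smallest that separate the
asymptotic regimes cleanly: rings of 10/20/40 columns per bulk for the
size series (the numerical window read off $s_{\min}^2 > 10^{-8}$ on a
$\lambda$-grid of step 0.025 moves monotonically toward $\pm\log 2$ across
those sizes, with the $N=40$ plateau below $10^{-10}$), 20 disorder seeds
at strength 0.3 for the index theorem, and $T = 10^5$ for the simulation
checks.

## Numerical choices and limitations

* Winding grids: 512 $k$-points by default, with failure (not silent
  acceptance) when a phase step approaches $\pi$ or $|\det|$ falls below
  $10^{-10}$ of its maximum (band touching). Windings are grid-independent
  in the tested families.
* Window endpoints: bisection on the integer-valued winding to $10^{-6}$
  in $\lambda$; evaluation offsets $\pm 0.05$ for reporting $\delta w$.
* Zero thresholds: $10^{-10}$ absolute residual at $\lambda = 0$;
  relative $10^{-6}$ singular-value tolerance for finite-size split modes.
* The canonical JSON serialization (fixed key order, full-precision
  floats) makes write–read–write byte-identical, which the tests enforce.
* Degenerate inputs: reducible networks, duplicate edges, zero rates,
  `disp` outside $\{-1,0,1\}$, non-saturating adaptation specs and
  all-marginal bulks are rejected with named errors rather than coerced.
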