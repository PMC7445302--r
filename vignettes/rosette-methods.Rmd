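---
title: "Size ratios of ideal rosette polymers: models, estimators and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Size ratios of ideal rosette polymers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rosette)
```

## The physical problem

A *rosette polymer* is a branched macromolecule in which $f^c$ linear arms
and $f^r$ closed loops (rings) radiate from a single branch point, the core.
Its overall size is characterised by two experimentally accessible length
scales: the radius of gyration,
$$\langle R_g^2\rangle = \frac{1}{2M^2}\sum_{n,m}
  \langle(\vec r_n - \vec r_m)^2\rangle,$$
measured by static scattering, and the Kirkwood hydrodynamic radius,
$$\langle R_H^{-1}\rangle = \frac{1}{M^2}\sum_{n \ne m}
  \left\langle\frac{1}{|\vec r_n - \vec r_m|}\right\rangle,$$
measured by dynamic light scattering. Their dimensionless combination
$$\rho = \sqrt{\langle R_g^2\rangle}\,\langle R_H^{-1}\rangle$$
is *universal*: in the long-chain limit it depends only on architecture, not
on chemical microstructure. This package computes $\rho$ for ideal
(Gaussian) rosettes — flexible chains with no excluded volume, the
$\theta$-solvent idealisation — four independent ways: a general closed
form, a numerically quadratured pair-contact ("diagram") assembly, exact
direct sampling of conformations, and Langevin bead-spring molecular
dynamics, the last two joined by a correction-to-scaling extrapolation.
Because the model is Gaussian, every route must agree; the package's test
suite is built around those cross-checks.

Benchmarks worth keeping in mind: $\rho_{\text{chain}} = 8/(3\sqrt\pi)
\approx 1.5045$, $\rho_{\text{ring}} = \sqrt{2\pi}/2 \approx 1.2533$, and a
monotone decrease of $\rho$ towards 1 as arms are added, rings compacting
more efficiently than chains. One detail the closed form reveals that a
casual reading of the family curves misses: at equal total functionality
$f$ the symmetric rosette ($f^c = f^r = f/2$) lies below the pure chain
star only up to $f = 6$; by $f = 8$ the many-arm chain star has become the
more compact of the two ($\rho(4,4) = 1.2273$ vs $\rho(8,0) = 1.2161$),
a crossover confirmed independently by the quadrature oracle and asserted
in the tests.

## Conventions that matter

**Bead counting.** An arm carries $n$ bond steps. A ring's last bead *is*
the core (no duplicated zero-length pair), so a rosette has
$M = 1 + f^c n + f^r(n-1)$ distinct beads. The alternative (duplicating the
ring's endpoint) would place two beads at distance zero and make the
Kirkwood sum singular. The $O(1)$ bead-count ambiguity is irrelevant
asymptotically and is absorbed by the finite-size fit.

**Step variance.** `step_var` is the *per-component* variance of one bond
step, so a bond vector has mean-square length `dim * step_var` and the
discrete chain matches the continuum normalisation
$\langle(\vec r(s_2)-\vec r(s_1))^2\rangle = d\,|s_2 - s_1|$ at
`step_var = 1`. $\rho$ is exactly invariant to `step_var` (it is a scale),
which the tests assert bitwise by reusing the same seed across variances.

**Kirkwood diagonal.** The defining double sum includes divergent $n = m$
terms; we exclude the diagonal but keep the $1/M^2$ normalisation, the
standard Kirkwood practice. The resulting $O(1/M)$ bias is part of the
finite-size correction the extrapolation removes.

**The $\rho$ estimator.** $\rho$ combines *ensemble means*,
$\sqrt{\overline{R_g^2}}\cdot\overline{R_H^{-1}}$, not per-conformation
ratios, matching the definitions above. Its standard error comes from a
delete-one-block jackknife over conformations, which automatically carries
the strong within-conformation correlation of $R_g^2$ and $R_H^{-1}$ into
the error of the combination.

## Closed form and quadrature oracle

The general $d$-dimensional closed form for $\rho(f^c, f^r)$ (implemented
in `rho_rosette()`) was verified against every special case we can compute
independently: the chain, the ring, the star family, the tadpole and the
double ring, and the ten-architecture benchmark table. A further, fully
independent numerical route (`rho_from_oracle()`) assembles
$\langle R_H^{-1}\rangle$ from the five distinct pair-geometry integrals —
same linear arm, two linear arms, same ring, two rings, ring–chain — each
reduced analytically to a one-dimensional integral and evaluated by
adaptive quadrature (`stats::integrate`, default tolerance $10^{-8}$; the
inverse-square-root edge singularities are integrable and handled by the
adaptive rule). Four of the five integrals also have elementary closed
forms ($4/3$, $(8\sqrt2-8)/3$, $\pi/2$, $1 + \tfrac52\arcsin(1/\sqrt5) -
\pi/4$); these are frozen in the tests as oracle values, never used by the
implementation.

One subtlety is combinatorial: the ordered-region integrals must be counted
with *ordered-pair* prefactors $\{2f^c,\ f^c(f^c{-}1),\ 2f^r,\
f^r(f^r{-}1),\ 2f^cf^r\}$ when expanding the unrestricted double sum over
arm pairs. This convention reproduces every printed special value; the
half-counting alternative reproduces none, which is how we fixed it. A
separately published closed form for $R_H$ alone is inconsistent with the
chain limit by a constant factor close to $4/\pi$ and is deliberately not
used; the theory-layer `rh_rosette()` is defined as
$\sqrt{\langle R_g^2\rangle}/\rho$ from the two verified expressions.

The quadrature oracle is three-dimensional only (it hard-codes the Gaussian
$\langle 1/r\rangle = \sqrt{2/\pi}/\sigma$ factor); the closed form covers
general $d \ge 2$.

## Exact conformation sampling

Because the model is Gaussian, conformations can be drawn *exactly*:
linear arms are cumulative sums of i.i.d. Gaussian steps; ring arms are
Brownian bridges $r_k = W_k - (k/n)W_n$, which close on the core exactly
(to floating-point addition) and have the bridge variance profile
$k(n-k)/n$. Arms are independent — there are no interactions in the ideal
model — so a rosette is assembled arm by arm at a common origin. Compared
with molecular dynamics this has no equilibration transient, no integrator
bias and no autocorrelation; it is the workhorse for ensemble statistics,
with MD retained separately as a protocol check.

Reproducibility: `simulate(topology, nsim, seed)` gives every conformation
its own L'Ecuyer-CMRG substream derived from the root seed, so ensembles
are reproducible regardless of how they are partitioned, and the caller's
RNG state is restored afterwards.

What the generator does *not* emulate: excluded volume (good-solvent
swelling), bending stiffness, hydrodynamic interactions beyond the
Kirkwood pair approximation, and solvent. Passing tests therefore validate
the ideal-chain machinery, not predictions for swollen or semiflexible
polymers.

## Langevin molecular dynamics

The bead-spring model connects beads by harmonic bonds
$V(r) = \tfrac{k}{2}(r - r_0)^2$ with $k = 200\,k_BT/b^2$ and $r_0 = b$,
evolved by the Langevin equation with friction $\zeta = 0.5\,m/\tau$ and
timestep $\Delta t = 0.0025\,\tau$, $\tau = \sqrt{mb^2/k_BT}$
(`md_params()` defaults). The integrator wraps velocity half-kicks around
an *analytically exact* joint position–velocity Ornstein–Uhlenbeck substep.
Exactness of the substep means the free particle equilibrates to velocity
variance $k_BT/m$ at any timestep, and the high-friction limit reproduces
the overdamped displacement law $\mathrm{Var}(\Delta x) = 2k_BT\Delta
t/\zeta$; both are asserted in the tests. The OU coefficients are computed
with `expm1` to avoid catastrophic cancellation at the small
$\zeta\Delta t/m = 1.25\times10^{-3}$ of the default parameters. The inner
loop is compiled (Rcpp) and draws its noise from R's RNG, so trajectories
are reproducible from `set.seed()`.

Protocol defaults are scaled to the slowest Rouse relaxation time
$t_R = \zeta n^2 r_0^2/(3\pi^2 k_BT)$: equilibration $4\,t_R$ from an
exact Gaussian initial coil, production $40\,t_R$, one frame per $t_R/20$
(about 800 correlated frames), jackknife blocks of $2\,t_R$. Stationarity
is checked by comparing the two production halves through their $2\,t_R$
block means (within 3 combined SE); a failure warns rather than errors.
With these defaults the jackknife errors were validated against the
seed-to-seed spread of independent runs and found slightly conservative.

**A known, physical finite-size offset.** A stiff harmonic-bond chain is a
freely jointed chain, not a Gaussian-step chain: at bond separation $j = 1$
the exact mean reciprocal distance is $1/b$, whereas Gaussian steps give
$\sqrt{6/\pi}/b \approx 1.382/b$. Using the identity
$\langle 1/r_j\rangle_{\mathrm{FJC}} = (2/\pi)\int_0^\infty
(\sin k/k)^j\,dk$ one finds $\rho_{\mathrm{FJC}}/\rho_{\mathrm{Gauss}} - 1
= -4.6\%$ at $M = 51$, $-3.3\%$ at $M = 101$, $-2.4\%$ at $M = 201$. This
is *not* an integrator artefact; it is short-range microstructure that
vanishes as $N^{-1/2}$ and is exactly what the correction-to-scaling fit
removes. The MD tests therefore validate $\rho$ against the exact
freely-jointed finite-$M$ value (a sharp test of the dynamics), while the
MD-vs-sampler universality comparison at matched $M$ is a 3-combined-SE
check at $N = 100$, where the residual offset sits well inside the
resolution of a desk-scale run.

## Finite-size extrapolation

Measured ratios approach their asymptote from below as
$$\rho(N) = \rho_\infty\!\left(1 + a\,N^{-\Delta}\right),\qquad
\Delta = \tfrac12$$
for ideal ($\theta$-state) chains; $\Delta$ is a *fixed input*, never
fitted (`fit_finite_size()` is a two-parameter fit, and the good-solvent
value $\Delta \approx 0.53$ is out of scope since the model has no excluded
volume). `N` is beads *per arm*, held consistent across all outputs. The
fit is weighted least squares in the linearised variable $x = N^{-\Delta}$
(intercept $\rho_\infty$, slope $\rho_\infty a$), the convex formulation
that matches how such data are conventionally plotted; when measurement
errors are supplied they are taken at face value, so the parameter
covariance is $(X^TWX)^{-1}$ and the quoted $\chi^2$ is the weighted
residual sum. Points are weighted by their errors by default (an
unweighted option exists, since published fits do not always state their
weighting); a nonlinear refit (`method = "nls"`) agrees with the linear
route to $10^{-6}$ on clean data and is available as a robustness check.
The ratio $a = \mathrm{slope}/\mathrm{intercept}$ carries a delta-method
error.

How good is the $\Delta = 1/2$ law at desk scales? Fitting the *exact*
discrete-chain series over $N \in \{100, \dots, 1600\}$ gives
$\rho_\infty = 1.5041$ (true $1.5045$; curvature bias $-0.03\%$), and the
exact ring series gives $1.25338$ (true $1.25331$). Those biases set the
floor on what the stochastic pipeline can resolve and are far inside the
quoted fit errors at 400 conformations per point.

## Problem sizes and numerical choices

The package's standard study grid — five chain lengths
$N \in \{100, 200, 400, 800, 1600\}$ with 400 exact conformations per
length, exact Kirkwood pair sums — gives $\rho_\infty$ to about $\pm
0.003$–$0.004$ for a single-arm architecture, a resolution chosen to
separate the chain and ring asymptotes by two orders of magnitude more
than their distance. Pair subsampling (`pairs = K`) exists for much larger
molecules; it is unbiased by construction, degenerates to the exact sum at
full coverage, and is unnecessary below $M \sim 10^3$ where `dist()` is
cheap. MD validation runs use $n \le 100$ beads per arm, where a full
default-protocol trajectory takes minutes on one core; quantitative MD
conclusions at these sizes rest on the block jackknife plus the
finite-size fit, exactly as for the sampler.

Degenerate inputs are rejected early: an armless topology, $n < 2$,
non-positive contour lengths, coincident beads in an exact pair sum (the
offending bead indices are named), zero-length bonds in the force field,
fits with fewer than three distinct $N$. `step_var = 0` is allowed (a
point molecule; useful as a degenerate limit in tests), as is `dim != 3`
everywhere except the quadrature oracle and XYZ output.

## Limitations

Ideal chains only: no excluded volume, no bending rigidity, no
hydrodynamic tensor beyond the Kirkwood pair approximation, no solvent
quality interpolation. Arms are equal length by construction. The MD
module reproduces the canonical ensemble of the bead-spring model, not any
particular simulation engine's trajectories. The closed form covers
general dimension, but all numerical benchmarks in the package are
three-dimensional.
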