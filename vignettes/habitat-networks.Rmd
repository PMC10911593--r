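---
title: "Predicting Wolbachia invasion on networks of coupled mosquito habitats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting Wolbachia invasion on networks of coupled mosquito habitats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wolbanet)
```

## The modeling problem

Releasing *Wolbachia*-carrying *Aedes aegypti* is an established route to
suppressing dengue transmission: carriers transmit the virus poorly, and
cytoplasmic incompatibility (CI) — the inviability of embryos from
carrier-male x non-carrier-female matings — gives carriers a frequency-
dependent reproductive advantage once they are common.  The practical
questions are quantitative.  How many carriers must a one-time release
contain?  If the release succeeds near the release site, will carriers
spread to neighboring breeding sites, and what determines whether they do?

`wolbanet` treats the landscape not as a continuum but as a network of
discrete *habitats* — pockets of high mosquito density such as stagnant
ponds — exchanging adult mosquitoes by diffusive coupling: the net flux of
any motile compartment $C$ from habitat $k$ into habitat $j$ is
$m_{jk}(C^{(k)} - C^{(j)})$, with a symmetric coefficient matrix $m_{jk}$
(day$^{-1}$).  This sidesteps the fine-grained ecological mapping that
spatially explicit PDE models require: a crude survey of habitat sizes and
pairwise distances is enough to parameterise the network.

## The two population models

### The two-compartment model

The minimal model tracks only carriers $x$ and non-carriers $y$ in one
well-mixed habitat:

$$\frac{dx}{dt} = (b_I - \delta_I)\,x - d\,x(x+y), \qquad
  \frac{dy}{dt} = b_U \frac{y^2}{x+y} - \delta_U\,y - d\,y(x+y).$$

The CI mechanism is the quadratic birth term: a non-carrier female's brood
survives only if her mate is also a non-carrier, an event of probability
$y/(x+y)$ under random mating.  We require
$b_I > d + \delta_I$, $b_U > d + \delta_U$, $b_U \ge b_I$ and
$\delta_I \ge \delta_U$ (`validate_params()`): both strains are viable in
isolation and carrying *Wolbachia* exacts a mild fitness cost.  Under these
restrictions the model is bistable.  Its three equilibria
(`model1_equilibria()`) are a stable carrier-only state
$((b_I-\delta_I)/d,\,0)$, a stable non-carrier-only state
$(0,\,(b_U-\delta_U)/d)$, and a coexistence saddle whose stable manifold is
the straight line

$$y = \frac{b_I - \delta_I + \delta_U}{b_U - b_I + \delta_I - \delta_U}\,x$$

(`stable_manifold_slope()`).  That line *is* the release-planning tool:
initial conditions with $y/x$ below the slope end in carrier fixation,
those above it in carrier loss.  With the baseline field rates
($b_I = 0.285$, $b_U = 0.300$, $\delta_I = 0.079$, $\delta_U = 0.071$
day$^{-1}$) the slope is $0.277/0.023 \approx 12.04$: carriers need to be
released at only about 1/12th of the standing non-carrier population.

On a network, each habitat $j$ runs these dynamics with its own
density-dependent death rate $d_j$ plus the coupling sums
(`vector_field_Nhab()`).  Two structural facts carry over from the single
habitat.  First, the same slope acts as a *critical ratio*
(`critical_ratio()`): if every habitat starts exactly on the ratio, all
ratios $y_j(t)/x_j(t)$ stay constant forever, and starting every habitat
strictly below it is a sufficient condition for fixation everywhere.
Second, specifying habitats by carrying capacity is more natural than
specifying $d_j$, so `death_rates_from_capacities()` inverts the
all-non-carrier equilibrium:

$$d_j = \frac{1}{K_j}\Big(b_U - \delta_U +
        \sum_k m_{jk}(K_k/K_j - 1)\Big),$$

which makes "non-carriers at capacity" an exact equilibrium of the coupled
system by construction (the package verifies the residual is at numerical
zero).  The conversion can fail: migration out of a small habitat towards a
large neighbour can outrun local births, driving $d_j \le 0$.  For a pair
with capacity ratio $a = \min K/\max K$ the admissible range is
$m < (b_U - \delta_U)/(1-a)$ (`migration_upper_bound()`); the constructor
enforces positivity of every derived $d_j$ directly for $N > 2$, where no
closed-form bound is available.  User-supplied $d$ bypasses the check,
because in that case no capacity profile is being asserted.

### The nine-compartment model

The detailed model (`vector_field_model2()`) splits the population by life
stage (aquatic vs adult), sex, and carrier status: $A_u, A_w$ (aquatic),
$F_u, F_w$ (unmated females), $F_{pu}, F_{pw}$ (pregnant females),
$M_u, M_w$ (males), and $F_{ps}$ (sterile pregnant females — non-carrier
females that mated a carrier male and fell to CI).  Aquatic recruitment is
logistic with capacity $K$; the CI split sends a maturing non-carrier
female to $F_{pu}$ with probability $M_u/(M_u+M_w)$ and to $F_{ps}$
otherwise.  Three conventions in this implementation deserve note:

* **Mating at zero males.** Both mating fractions are defined as 0 when
  $M_u + M_w = 0$: no males, no mating.
* **Carrier-female maturation.** The $F_{pw}$ recruitment is
  $\sigma F_w$ with no male-availability factor, unlike the non-carrier
  side.  This asymmetry is implemented verbatim from the source model; it
  amounts to assuming carrier females always find mates and none of their
  matings are sterile.
* **Carrier proportion.** The published experiments plot the "proportion
  of infected mosquitoes" without defining the denominator.
  `carrier_proportion()` uses $(F_w + F_{pw} + M_w)$ over all seven adult
  compartments, counting $F_{ps}$ in the denominator as non-carrier-lineage
  adults; `include_sterile = FALSE` drops it.  For the fixation statistics
  reported here the two conventions never straddle the 0.5 cutoff.

The baseline rates (`model2_params_baseline()`) leave the carrier
egg-laying rate ambiguous between reduced fecundity ($\phi_w = 11$) and
parity with non-carriers ($\phi_w = 13$); the argument is therefore
mandatory.  The shipped sweep fixtures use $\phi_w = 11$, under which the
two-habitat migration threshold lands where the published experiments place
it (just below $m = 0.002$).

On a network (`vector_field_model2_Nhab()`), every *adult* compartment of
every habitat receives the diffusive coupling term with a single
coefficient per habitat pair; the aquatic compartments receive none, since
larvae cannot fly.  Sterile and pregnant females migrate like everyone
else.

## From geometry to migration coefficients

Mark-release-recapture (MRR) studies summarise mosquito dispersal as a
radial kernel: the probability density $p(r)$ of the distance travelled
over an experimental period of $t$ days, with mean distance travelled $\xi$
(and standard deviation $\sigma$ for the log-normal family).  A habitat is
modelled as the disk enclosing a fraction $q$ of that mass, so its radius
$r^*$ is the $q$-quantile of $p$ (`habitat_radius()`):
$r^* = -\xi\ln(1-q)$ for the exponential kernel, the log-normal quantile
otherwise.

The migration coefficient between two habitats with centers $x^*$ apart is
the kernel mass that lands in the destination disk, per unit time:

$$m(x^*) = \frac{1}{2\pi t}\int_0^{2\pi}\!\!\int_0^{r^*}
  \frac{p(D(r,\theta))}{D(r,\theta)}\, r\, dr\, d\theta, \qquad
  D = \sqrt{(r\cos\theta + x^*)^2 + (r\sin\theta)^2}.$$

The $1/D$ factor converts the 1-D radial density into an isotropic planar
density (up to the $1/2\pi$), so new kernel families need only a radial pdf
and a quantile.

### Numerical treatment

`migration_rate()` does not evaluate the double integral directly.  In
polar coordinates about the **source** center, the circle of radius $\rho$
meets the destination disk in an arc of angle
$\alpha(\rho) = 2\arccos\!\big((\rho^2 + x^{*2} - r^{*2})/(2\rho
x^*)\big)$ (clamped), which collapses the computation to the
one-dimensional integral
$m = \tfrac{1}{2\pi t}\int p(\rho)\,\alpha(\rho)\,d\rho$ over
$[\,|x^* - r^*|,\ x^* + r^*]$.  The reduction is exact, and it matters:
whenever $x^* < r^*$ the source center lies inside the destination disk and
the $1/D$ integrand is singular (integrably so).  Direct 2-D quadrature
loses two to three digits there — for the Singapore exponential kernel at
$x^* = 100$ m it returns 0.1148 against the true 0.1160 — while the
1-D form is bounded and cheap.  The 2-D route is retained as
`method = "quad2d"` and as an independent cross-check in the test suite,
alongside a Monte-Carlo oracle: $m\,t$ must equal the probability that a
random kernel draw (radius from $p$, angle uniform) lands in the
destination disk, to within three standard errors at $10^6$ draws.
Overlapping habitats ($x^* < 2r^*$) produce a warning, not an error — the
published coefficient tables themselves include such geometries — and only
$x^* \le 0$ is refused.

### The log-normal parameterisation

Converting MRR summaries $(\xi, \sigma)$ into log-scale parameters
$(M, S)$ admits two conventions, and the package exposes both.  The strict
moment match is
$M = \ln\!\big(\xi^2/\sqrt{\xi^2+\sigma^2}\big)$,
$S = \sqrt{\ln(1 + (\sigma/\xi)^2)}$, under which the distribution's mean
and standard deviation equal $\xi$ and $\sigma$ exactly
(`ms_convention = "moment"`).  The default, `ms_convention = "table"`,
keeps the same $M$ but uses $S = \sqrt{\ln(1 + (\xi/\sigma)^2)}$.  The
default is the convention under which this package reproduces the published
migration-coefficient tables for the Singapore MRR estimates to their
printed precision (all eight log-normal entries across both $\sigma$
values); the strict moment match reproduces none of them.  Note the
behavioural difference: under the table convention a *larger* $\sigma$
yields a *narrower* log-scale spread and hence smaller far-field migration.
Users fitting their own MRR data should choose the convention that matches
how their $(\xi,\sigma)$ were estimated; the quantile and all downstream
machinery honour either choice.

## Simulation, classification, and the experiment drivers

All models integrate through `deSolve::ode` (lsoda — adaptive and
stiff-capable) with tolerances $10^{-10}$ by default; states are clipped to
zero on evaluation and output, so trajectories respect the closed positive
orthant up to integrator tolerance.  `steady_state()` reports the terminal
state plus a convergence flag (max derivative below $10^{-8}$ relative to
state scale) — non-convergence is informative, not fatal, because
trajectories near the coexistence saddle settle slowly.

`classify_outcome()` labels each habitat.  For the two-compartment model a
population is extinct below $\epsilon_j = 10^{-3} \times$ (the habitat's
non-carrier-only equilibrium): equilibria are of order the carrying
capacity and numerical decay leaves trace amounts, so an absolute cutoff
would misfire across capacity scales.  The label is insensitive to that
fraction across $[10^{-4}, 10^{-1}]$ in every shipped scenario — the
attracting states are well separated.  One caveat is inherent to diffusive
coupling: a habitat adjacent to a non-carrier reservoir receives a
perpetual trickle, so strict extinction never occurs there and mixed
chains are labelled `coexistence`; for "did the release take the habitat"
questions the carrier proportion with a 0.5 cutoff (the nine-compartment
fixation rule) is the robust statistic, and the experiment drivers report
it alongside the labels.

The drivers under `R/experiments.R` package the standard study designs:

* `minimal_release()` — integer bisection for the smallest single-habitat
  release that fixes carriers in every habitat.  It reports the smallest
  *succeeding* integer: for the basin scenario (capacities 400/600,
  $m = 0.006$, baseline rates) releases of 51 into the smaller habitat or
  60 into the larger succeed, while 50 and 59 fail — robust to pushing the
  horizon from 4\,000 to 60\,000 days and tolerances to $10^{-12}$.
* `basin_boundary()` — the joint-release success frontier; its axis
  intercepts must and do equal the `minimal_release()` outputs (two
  independent code paths).
* `migration_sweep()` — steady states across an $m$ grid with bisection
  brackets on every qualitative change.  For the equal-death-rate pair
  ($b_I = 0.42$, $b_U = 0.57$, $d_A = d_B = 0.001$) it brackets the loss
  of the all-positive coexistence state at $m \approx 0.0128$.
* `model2_migration_sweep()`, `model2_capacity_map()`,
  `model2_release_map()` — the nine-compartment analogues, all evaluated
  at exactly $t = 2500$ days (the published protocol reads proportions at
  that time, not at the converged flag).

Every driver is a pure function of its scenario; re-running any fixture
reproduces its output bit for bit, and no randomness exists outside the
Monte-Carlo test oracle (which carries an explicit seed).

## The reaction-diffusion limit

For a homogeneous 1-D landscape the package also ships the
continuous-space adaptation (`solve_pde()`): the two-compartment reactions
plus $D\,\partial_s^2$ terms, discretised by a second-order central
Laplacian on a uniform grid (method of lines, zero-flux boundaries by
default) and integrated by the same stiff solver, so no CFL restriction
applies.  Because the reaction is bistable, invasion fronts are *pushed*
waves: a localized release ignites only if its amplitude survives
diffusive spreading long enough for the local dynamics to lock in.  The
demonstration profile $x(s,0) = 40e^{-s^2}$ over a non-carrier background
of 200 is about a metre wide, which dictates the scale of the default
grid: with $D = 1$ m$^2$/day the pulse dilutes below threshold within a
day and dies, and any $D \gtrsim 0.05$ quenches it.  The defaults are
therefore $D = 0.01$ m$^2$/day on $[-10, 30]$ m with 200 nodes, under
which the pulse ignites a clean left-to-right front (measured speed
0.027 m/day, linear fit $R^2 > 0.999$ via `wave_speed()`) that overtakes
the domain, while the same profile at amplitude 0.4 dissolves — the
wave/no-wave dichotomy the framework predicts.  Both $D$ and the domain
are configurable; wave existence is robust to these choices, transit times
are not, so the package asserts only the dichotomy and the exact
$\sqrt{D}$ speed scaling (a similarity property of the bistable system,
verified numerically to within 10% with the fixed-width initial pulse).

## Scenarios and fixtures

Scenarios are strict YAML documents (`load_scenario()`): unknown keys are
rejected, a habitat block carries exactly one of `K` or `d` (mixing the
two would silently change the non-carrier equilibrium), and migration is
either explicit or geometric (kernel + distances), the explicit matrix
winning with a warning if both appear.  Initial populations use keys
`x0`/`y0` and the PDE grid uses `nodes`, because YAML 1.1 readers parse
bare `y` and `n` as booleans.  The shipped fixtures
(`list_fixtures()`) reproduce every printed parameter set of the
published experiments — rate tables, kernel estimates, capacities, initial
conditions — and double as schema documentation.  Two carry choices of
this package rather than printed values: `fig7_chain` fixes the release at
150 carriers (half the habitat capacity; the source states no size, and
the qualitative outcome — fixation in the first two habitats, not the
third — holds for any release that takes the first habitat), and
`fig8_synthetic` is labelled synthetic because the published geometry for
the placement-dependence demonstration is corrupted in the source; its
collinear large–small–large arrangement (capacities 400/100/400, 150 m
gaps) was chosen once to exhibit the claim that a release able to conquer
a large habitat cascades system-wide, while the identical release into the
small middle habitat fails everywhere.

## What the synthetic scenarios do and do not show

The fixtures emulate the published study conditions: deterministic
dynamics, habitat-independent rate constants, symmetric migration with a
single coefficient per habitat pair, and circular habitats of a common
kernel-derived radius.  Real landscapes violate all four —
demographic noise matters at the release sizes in question (a 51-mosquito
threshold is well inside stochastic territory), wind imposes directional
bias, habitat quality varies, and MRR-derived kernels are themselves
uncertain.  Passing tests therefore certify the mathematical framework and
its numerics, not field-level predictions; the package's value is in
ranking strategies (which habitat to seed, how release size trades against
distance) rather than in absolute release counts.

## Problem sizes

The test suite and the acceptance script run the study designs at their
published sizes: two- and three-habitat networks, horizons of 2\,000–10\,000
days (2\,500 for the nine-compartment sweeps), a 200-node PDE grid, and a
$10^6$-draw Monte-Carlo oracle.  The whole suite completes in well under a
minute on one core.
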