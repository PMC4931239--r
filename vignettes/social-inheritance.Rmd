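---
title: "Social inheritance as a generative model of animal social networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Social inheritance as a generative model of animal social networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socinherit)
```

## The model and its assumptions

`socinherit` models a social group of constant size $N$ as a binary,
undirected network changing by birth–death events. Per event, one
individual dies uniformly at random and loses all bonds; a mother is
then drawn uniformly among the $N-1$ survivors and a newborn takes the
vacant place, bonding

* the mother with probability $p_b$,
* each of the mother's contacts independently with probability $p_n$, and
* each remaining survivor independently with probability $p_r$.

The order of operations matters and is fixed throughout the package:
death first, then the mother is drawn among survivors (so the mother
can never be the dying individual, and the newborn cannot die in the
step it is born). Bonds never dissolve once formed and never change
weight — turnover happens only through death. Demography is neutral:
no age or stage structure, no heterogeneity in mortality or fertility.
These are deliberate simplifications; the point of the model is that
clustering, modularity, apparent heritability of position and
assortativity all emerge from bond inheritance alone.

When $p_b < 1$ the $p_n$/$p_r$ rule is still applied to the mother's
contacts and non-contacts regardless of whether the mother link itself
formed; a conditional variant (weaker inheritance when the mother link
fails) has no defined functional form and is not implemented.

### Parameters

| parameter | meaning | default | units |
|---|---|---|---|
| `n` | group size | 100 | individuals |
| `p_b` | newborn–mother bond probability | 1 | probability |
| `p_n` | social inheritance per maternal contact | — | probability |
| `p_r` | random bonding per non-contact | — | probability |
| `steps` | birth–death events | `10 * n` | events |

Ten full population turnovers (`steps = 10 * n`) is the rule of thumb
for reaching stationarity; `simulate_network()` warns below it.
Convergence is slower for $p_n$ close to 1 and $p_r$ very close to 0.
The initial graph is Erdős–Rényi; its default edge probability is set
so the expected degree equals the analytic stationary mean degree,
which removes most of the burn-in transient. All randomness flows
through R's RNG, so a seed makes runs bit-reproducible across the R
and compiled layers.

## Stationarity approximations

**Mean degree.** At stationarity the bonds destroyed by a death must
equal those created by a birth. A random death removes $\bar d$ bonds
and leaves survivors with mean degree $\bar d' = \bar d (N-2)/(N-1)$;
the newborn creates $p_b + p_n \bar d' + p_r (N - 2 - \bar d')$ bonds
in expectation. Solving the balance gives the closed form implemented
in `expected_mean_degree()`:

$$\bar d = \frac{p_b + p_r (N-2)}{1 - (p_n - p_r)\frac{N-2}{N-1}}.$$

The denominator is strictly positive for all valid probabilities, so
the solution always exists (it approaches $N-1$ as $p_n - p_r \to 1$).

**Mean local clustering.** The same balance idea applies to the sum of
local clustering coefficients: a random death removes $\bar c$ (the
typical neighbour of the dead individual experiences no net change),
and a birth (i) perturbs the coefficient of every individual the
newborn bonds and (ii) adds the newborn's own coefficient. For a
focal individual of degree $d$ and coefficient $c$ that gains the
newborn as a neighbour, the new coefficient is
$(c\binom{d}{2} + c_t)/\binom{d+1}{2}$ where $c_t$ counts the closed
triangles the newborn creates at that focal: $p_n d_p$ at the mother,
and class-specific mixtures of $p_b$, $p_n$, $p_r$ with the expected
within/between-class edge densities at a mother's contact or
non-contact. The newborn's own coefficient is the ratio
$T_c/T_t$ of closed to total pairs among its bonds, with the bond
counts per class independent Bernoulli($p_b$), Binomial($d_p, p_n$)
and Binomial($N - d_p - 2, p_r$) variables. We approximate
$E[T_c/T_t]$ by the second-order expansion
$E[T_c]/E[T_t] - \mathrm{Cov}(T_c,T_t)/E[T_t]^2 + E[T_c]\mathrm{Var}(T_t)/E[T_t]^3$;
all required moments are exact, computed from factorial moments (which
extend to the non-integer typical mother degree $d_p = \bar d'$) via a
small polynomial-expectation engine, and the approximation is tested
against Monte-Carlo evaluation. Treating the mother as a typical
post-death individual ($d_p = \bar d'$, $c_p = \bar c$) closes the
equation, which `expected_mean_clustering()` solves for
$\bar c \in [0,1]$ by bracketed root finding (tolerance $10^{-10}$;
if no sign change exists the residual is minimised and a warning
flags the known breakdown region, low $p_n$ with very low $p_r$).
When $E[T_t]$ is numerically zero the newborn's expected coefficient
is 0, matching the degree-below-2 convention.

**Degree distribution.** `stationary_degree_distribution()` solves the
mean-field rate equation for $\phi_d$. Per event a degree-$d$
individual gains a bond with probability
$\frac{N-1-d}{N}\cdot\frac{p_b + p_n d + p_r(N-2-d)}{N-1}$ (the dying
individual is neither itself nor a neighbour, and the newborn bonds
it, by conditioning on the mother being the focal, one of its
neighbours, or neither) and loses one with probability
$\frac{d}{N}(1 - w(d-1))$ (a neighbour dies and the newborn does not
bond it, evaluated at the post-death degree). Individuals are replaced
at rate $1/N$ by newborns whose degree follows the birth distribution
$b_d$: the convolution of the mother bond with
Binomial($l, p_n$) + Binomial($N-2-l, p_r$), mixed over mothers drawn
from the post-death distribution
$\tilde\phi_l = \phi_l(1 - l/N) + \phi_{l+1}(l+1)/N$. The stationary
distribution is found by damped fixed-point iteration of the per-event
map (damping 0.5, start: binomial with the analytic mean, convergence:
total-variation change $< 10^{-10}$, cap $2\times10^5$ iterations).
The per-event map preserves the probability simplex, so the iteration
is unconditionally stable; no closed form is available. Internal
consistency: the distribution's mean agrees with the closed-form mean
degree within 2% across the working parameter grid.

## Network measures

Density, global/local clustering, unnormalised betweenness, walktrap
communities cut at maximal modularity (walk length 4), and Newman's
continuous-trait assortativity are computed through igraph, with
exhaustive brute-force oracles in the test suite (triplet enumeration,
simple-path enumeration, all set partitions on small graphs).
Individuals with fewer than two bonds have no neighbour pair; their
local coefficient is defined as 0 and included in the mean by default
(`isolates = "exclude"` drops them instead — in sparse networks the
choice measurably shifts the mean, so it is explicit configuration and
recorded in fit results).

## Traits, heritability and assortativity

`simulate_with_traits()` assigns every individual a trait in $[0,1]$:
founders draw Uniform(0,1); a newborn mutates to a fresh uniform draw
with probability $\mu$ and otherwise takes
Normal(mother, $\sigma^2$). Gaussian draws leaving $[0,1]$ are
*reflected* into the interval (clipping is available); reflection
preserves density mass near the boundaries instead of piling it onto
the endpoints. Defaults $\mu = 0.05$, $\sigma = 0.05$ follow the
reference experiments. Traits never influence bonding in the core
model, so any assortativity in the result is emergent.

`heritability_experiment()` pairs every living individual with its
living mother through the lineage log and regresses offspring
centrality on mother centrality (OLS slope; the correlation is
reported alongside, since both summaries are in circulation).
Replicates with fewer than 3 pairs are dropped with a warning. One
subtlety the experiments exposed: with $p_b = 1$ the guaranteed
mother bond alone correlates the betweenness of adjacent nodes, so the
slope does not vanish at $p_n = p_r$; the clean no-signal control is
$p_b = 0$ with $p_n = p_r$, which the tests use.

Two preference-based alternatives serve as contrasts. The
explicit-assortativity model bonds the newborn to survivors with
probability $c\,e^{-x/s}$ in the absolute trait difference $x$
(mother bond $p_b$ as usual); the generalized-preference model gives
each individual display and preference traits on the circle $[0,1)$,
inherited with wrapped Gaussian deviations, and bonds newborn $j$ to
survivor $i$ with probability $k\,e^{-d_{ij}/s}$ in the circular
distance between $j$'s preference and $i$'s display. The exact kernel
shapes are configuration (any monotone-decreasing kernel supports the
same qualitative contrasts); their scale is calibrated by log-scale
bisection (`calibrate_kernel()`) so the stationary density matches a
target, 0.123 by default — the mean density of the four observed
networks used as anchors. Both alternatives reproduce high
assortativity but fall far short of the social-inheritance model's
clustering and modularity at matched density, which is the
discriminating comparison the package asserts.

## Parameter estimation

**Analytical inversion** (`fit_analytical()`) solves
$\{\bar d(p_n, p_r) = \hat d,\ \bar c(p_n, p_r) = \hat c\}$ assuming
$p_b = 1$. The degree balance inverts exactly for $p_n$ as a function
of $p_r$, reducing the problem to a one-dimensional root search on the
clustering residual over the feasible $p_r$ range (201-point
sign-change scan, `uniroot` polish to $10^{-10}$, smallest-residual
root wins, estimates clipped to $[0,1]$ with the clip flagged). On its
own forward map the inversion is exact to $10^{-6}$; on simulated
networks it inherits the approximation's bias structure —
overestimating $p_r$ at low $p_n$ with very low $p_r$, underestimating
it (and $p_n$) at high $p_n$ with moderately high $p_r$.

**PLS regression** (`fit_pls()`) simulates an ensemble of networks at
the observed size with $(p_n, p_r)$ uniform on the unit square,
summarises each network by the descending-sorted degree and local
clustering sequences (length $2N$, label-invariant), and regresses the
parameters on the features by partial least squares (centred and
unit-scaled). A single global linear fit turned out to be misspecified
over the full prior: its bias at sparse, clustered corners *grows*
with ensemble size, while a nearest-neighbour readout of the same
features recovers the truth — the information is in the features, the
global linear map is at fault. The default therefore localises the
regression: the 100 training networks nearest the observation in
standardised feature space are selected and the PLS fit (2 components,
the parameter dimension) linearises the map around the observation —
the regression-adjustment idea familiar from simulation-based
inference. `local = FALSE` restores the plain global regression, with
its component count chosen by 5-fold cross-validation on the training
ensemble. Training ensembles are reusable across fits
(`build_pls_training()`), and `validate_recovery()` reports
truth-vs-estimate tables under either method.

## Numerical and design choices

* Seeds: every stochastic entry point takes `seed`; replicate
  ensembles inside experiment helpers draw from one seeded stream.
* Degenerate graphs (empty, complete) are legal simulator states;
  metrics define 0/0 cases as 0 where the field convention does
  (clustering), and error where the quantity is genuinely undefined
  (assortativity without trait variance).
* Varying-size simulations draw deaths as independent Bernoulli
  trials per individual; in the shrinking regime the death count in
  the final step is capped so the trajectory ends exactly on the
  target size.
* Two-sex variants: sexes are fair Bernoulli draws (initial
  composition included, overridable via `init_sex`); in the two-parent
  variants the newborn bonds each parent with probability $p_b$ and
  applies $p_n$ to the union of both parents' contacts. Restricting
  reproduction to females is *not* neutral: mothers are drawn from
  half the population, accumulate guaranteed newborn bonds, and are
  then copied more — mean degree runs a few percent above the basic
  model. The two-parent variants densify the network and lose the
  clustering *excess over density* that distinguishes social
  inheritance from random connectivity.
* Association matrices are thresholded at the upper quartile of the
  positive unordered-pair values (linear-interpolation quantile,
  strict `>`); zero associations are excluded from the quantile by
  default, with a flag to include them.

## What the synthetic data does and does not show

The fixture generator and the experiment defaults emulate the study
conditions ($N = 100$, 2000 events, uniform founder traits, noisy
association overlays with stronger indices on true bonds). Passing
tests show the implementation is faithful to the model and its
analytic structure under those conditions. They do not show that real
association indices are binary-thresholdable without information loss,
that real groups have constant size or neutral demography, or that
observed assortativity in any particular species is socially rather
than genetically inherited — the model is a null against which such
claims can be tested, not evidence for them. Problem sizes in the test
suite (down to $N = 40$–$60$ and hundreds of events for unit tests;
full $N = 100$, 2000-event ensembles in the acceptance suite) were
chosen to keep replicate counts high at interactive runtimes.

## Known limitations

* Weighted, directed and multilayer networks are out of scope, as is
  bond dissolution after formation.
* The clustering approximation degrades for low $p_n$ combined with
  very low $p_r$ (it can lose its root in $[0,1]$; the solver then
  minimises the residual and warns).
* The mean-field degree distribution assumes $p_b = 1$ in its birth
  distribution's standard use ($b_0 = 0$); the $p_b < 1$ extension is
  the obvious Bernoulli convolution and is implemented, but was not
  validated against ensembles.
* Analytical fitting requires the observed mean degree to be
  reproducible under $p_b = 1$; networks sparser than one bond per
  individual on average fall outside its domain.
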