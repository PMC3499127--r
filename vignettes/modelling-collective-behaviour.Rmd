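---
title: "Models, likelihoods and design choices in swarmfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, likelihoods and design choices in swarmfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swarmfit)
```

# Scope

`swarmfit` implements a modelling cycle for collective animal behaviour:
simulate local interaction rules forward to group-level patterns
(simulators), and invert group-level recordings back to local rules
(likelihood-based model selection). Four study systems are covered, each as
a self-contained module behind a shared data model:

* **Ring arena direction switching** — small groups circulating in an
  annular arena, where the observable is each animal's binary travel sense
  (clockwise vs counter-clockwise) and the question is which switching rule
  explains the observed reversals.
* **Alignment-in-radius collective motion** — the classic self-propelled
  particle model with angular noise, used as the theory-driven reference for
  the order-parameter phase transition.
* **Pheromone trail following** — a Weber's-law turning response on a
  shared, evaporating pheromone field, with the double-bridge choice
  dynamics as its mean-field counterpart.
* **Route mixtures for paired journeys** — repeated solo homing paths
  summarised as station-wise Gaussian route distributions, with paired
  journeys modelled as a weighted mixture of the two partners'
  distributions.

# Data model

Trajectories are agents-by-timepoints matrices wrapped in
`SummarizedExperiment` containers: a `RingTrajectory` carries assays
`theta` (angular position, radians in $[0, 2\pi)$, counter-clockwise
positive) and `dir` ($+1$ counter-clockwise, $-1$ clockwise); a
`PlanarTrajectory` carries `x`, `y`, `heading` and optionally `speed`.
Timestamps must be evenly spaced; the default timestep is 0.4 s, the length
of one sensing window in the ant observations, and is configurable
everywhere. The annular arena is reduced to its angular coordinate: every
ring-arena quantity in the package depends only on angle and travel sense,
so the radial coordinate carries no information for these models.

Angular conventions are fixed once: positions live in $[0, 2\pi)$,
separations are measured *forward along the focal agent's direction of
travel* and reported in $(-\pi, \pi]$, positive ahead. Clockwise motion
codes to $-1$.

# The switching-model family

For a focal agent at time $t$, each candidate rule maps the configuration
of the other agents to a probability of reversing direction during
$[t, t+1)$. Only opposite-direction neighbours enter any rule. The context
is summarised by three sufficient statistics, computed per record by the
pluggable context builder `ringContext()`:

* `f_opp` — fraction of the other agents travelling opposite to the focal
  agent (0 for a lone agent);
* `s_fwd` — smallest forward separation to an opposite-direction agent
  ahead (`Inf` if none);
* `s_near` — signed separation of the nearest opposite-direction agent.

The registered rules are:

| name | parameters | form |
|------|------------|------|
| `bernoulli` | $p_0$ | constant rate |
| `meanfield` | $p_0, k$ | $p_0 + k f_{\mathrm{opp}}$ |
| `zone` | $p_0, p_1, w$ | $p_1$ if an opposite agent lies within $[0, w]$ ahead, else $p_0$ |
| `d1` | $p_0, p_1, w, \tau$ | refractory memory: an encounter sets a counter to $\tau$; $p_1$ while it is positive |
| `d2` | $p_0, k, w, \lambda$ | decaying trace $M \leftarrow (1-\lambda) M + \mathbf{1}\{\text{encounter}\}$; $p_0 + k M$ |

All probabilities are clipped to $[10^{-9}, 1 - 10^{-9}]$ so that sequence
log-likelihoods stay finite; the clip bound is a package constant and is
documented rather than configurable per call, because every consumer (the
simulator, the likelihood, the fitters) must agree on it.

Two genuinely open design points were resolved as follows. First, the
memory mechanisms: the refractory window (`d1`) and the exponentially
decaying encounter trace (`d2`) were chosen as the two simplest
non-Markovian mechanisms consistent with "memory of previous encounters";
the registry is pluggable so alternatives can be added without touching the
fitting engine. With $\lambda = 1$ the trace model collapses onto the
Markovian zone rule with $p_1 = p_0 + k$, which the tests exploit as an
exact cross-check. Second, zone geometry: the interaction zone extends
*ahead only* ($[0, w]$), because oncoming animals approach from the front;
a `symmetric` switch selects a $\pm w$ zone instead. For opposite-direction
pairs the forward separation is symmetric (if B is $x$ ahead of A, A is $x$
ahead of B), so the forward-only choice does not privilege either member of
an encounter.

# Simulators

`simulateRing()` uses a synchronous update: all switch decisions at step
$t$ read the configuration at step $t$, then positions advance by
$\mathrm{dir} \cdot \omega \, \Delta t$. This matches the factorisation of
the sequence likelihood exactly — the likelihood engine scores the same
conditional probabilities the simulator draws from. Agents are points and
pass through one another; the interaction acts only through the switch
probability. Defaults: $N = 8$ (the small-group regime), $\Delta t =
0.4$ s, and $\omega$ such that a lap takes about 200 steps.

`simulateVicsek()` implements the standard angular-noise variant of the
alignment model: each particle adopts the circular mean heading of all
particles within radius $r$ (itself included) plus uniform noise on
$[-\eta/2, \eta/2]$, then moves at constant speed on a periodic square;
ties in the circular mean (zero resultant) retain the previous heading.
The polar order parameter is
$\phi = |\sum_i (\cos\theta_i, \sin\theta_i)| / N$; for $N$ independent
uniform headings $E[\phi] \approx \sqrt{\pi} / (2\sqrt{N})$, the null
value the transition scan is compared against.

`simulateTrail()` advances ants one step per sensing window: integrate the
pheromone field over front-left and front-right sectors, turn by the
Weber's-law response plus Gaussian noise, advance one step length, deposit
on the occupied cell; the whole field decays by the evaporation fraction
each step (decay precedes deposition, so the total mass after $T$ steps
with gain zero is exactly $d \, n_{\mathrm{ants}} (1 - (1-e)^T)/e$, a
closed form the tests assert to $10^{-9}$). Sector defaults — radius 5
cells, half-angle $\pi/4$, the two sectors tiling the frontal half-plane
split at the heading line — parameterise geometry the source system leaves
unspecified. Walls reflect. Deposit-only mode (evaporation 0) reproduces
the passage-count map construction of `buildPheromoneMap()`.

# The Weber's-law response

The turning angle per sensing window is

$$\alpha = A \, \frac{L - R}{L + R + T_0},$$

in degrees, positive toward the left sector, where $L$ and $R$ are the
pheromone masses in the two frontal sectors, $A = 30.80$ is the turning
gain and $T_0 = 10.53$ (pheromone units) is the detection threshold below
which the contrast is effectively damped. $|\alpha| \le A$ always, the
response is antisymmetric in $L \leftrightarrow R$, and lowering $T_0$ can
only strengthen it. $T_0$ enters as a denominator offset (a soft
threshold), not a hard cutoff: this is the unique reading on which the
response is proportional to $(L-R)/(L+R)$ at high concentrations yet
suppressed when both concentrations are below threshold. The degenerate
case $T_0 = 0, L = R = 0$ is defined as $\alpha = 0$. `weberTurn()` is the
single point of truth for this form; everything downstream treats it as a
black box.

The double-bridge dynamics integrate
$\dot c_A = f P_A - \rho c_A$ with the choice function
$P_A = (k + c_A)^n / ((k + c_A)^n + (k + c_B)^n)$ (defaults $n = 2$,
$k = 20$, following the standard choice-function tradition). Symmetry is an
exact invariant from symmetric initial conditions at any $n$; for $n \ge 2$
the symmetric state loses stability above a flow threshold, which the test
suite verifies against a numerically computed Jacobian eigenvalue rather
than a hand-derived formula. `effectiveChoiceCurve()` closes the loop
between levels: a single Weber response is nearly linear in the contrast,
but accumulating `nCrossings` sensing steps before commitment sharpens the
branch choice — the effective nonlinearity that the mean-field model needs.

# The inference engine

The sequence log-likelihood of a rule is
$\sum_r [y_r \log p_r + (1 - y_r) \log(1 - p_r)]$ over all (agent, step)
records, with memory states threaded per agent in time order and
initialised to zero at each trajectory's start (no pre-history).

**Optimisation.** Smooth models use a multi-start bound-constrained
simplex search on logit-transformed coordinates. Threshold parameters
(zone width, memory duration) make the likelihood piecewise constant, so
generic hill-climbing is unreliable there; instead the fitters exploit
profile structure: for a fixed trigger partition the two rates have
closed-form maximum-likelihood estimates, and the likelihood depends on
$w$ only through the partition, so scanning the observed separations gives
the exact maximum for the zone model (the smallest maximising threshold is
reported). The refractory model adds an exhaustive scan over integer
$\tau$; the trace model profiles $w$ over separation quantiles with a
simplex search inside. Parameter boxes are declared per model in the
registry and double as the support of independent uniform priors.

**Model selection.** The default criterion is the Laplace-approximate log
marginal likelihood
$\log p(D \mid M) \approx \ell(\hat\theta) + \tfrac{d}{2}\log 2\pi -
\tfrac12 \log \det \mathcal{I}(\hat\theta) + \log \pi(\hat\theta)$,
with the observed information from central finite differences, so that
ranking realises Bayes-factor selection with an automatic penalty for
unnecessary parameters. Integer parameters are excluded from the curvature
term and contribute their uniform prior mass. When the fit sits on a bound
or the information matrix is not positive definite, the value falls back
to the BIC form $\ell - \tfrac{d}{2}\log n$ and the fit is flagged; this
is the honest regime for threshold parameters whose likelihood is locally
flat. On a Bernoulli subproblem with $n = 1000$ the Laplace value is
within 0.1 nat of the exact Beta integral, and log-likelihood, AIC and BIC
orderings are available alongside. Ranking output includes log Bayes
factors against the mean-field baseline, and per-model seeds are derived
from the master seed so the ranking is invariant to candidate order.

`forceMatchingFit()` restricts candidate planar interaction laws to forms
linear in their parameters (alignment toward the neighbourhood mean
heading, attraction toward the neighbour centroid), so fitting is exact
linear algebra: rank-deficient designs are solved minimum-norm and
flagged. This is deliberately the least-squares, few-observation regime:
the tests show the generating law beats a wrong alternative in at least
95% of noisy replicates and that estimator spread shrinks as
$1/\sqrt{n}$.

# Route mixtures

Solo paths are resampled to a fixed number of arc-length stations (default
100, linear interpolation) and summarised by the station-wise mean path
and cross-track standard deviation, floored at a configurable minimum
(default $10^{-3}$ arena units) so identical paths still define a proper
distribution. The divide-by-$n$ standard deviation is used, so two paths
offset $\pm d$ give sd exactly $d$. A path that already has one point per
station is scored against the stations directly; only paths with a
different sampling are re-interpolated. The station-wise Gaussian
cross-track model was chosen as the simplest representation that supports
likelihoods, fidelity and mixtures; a full spatial process model of route
uncertainty is out of scope.

Paired journeys are scored as the station-wise mixture
$\sum_j \log[w \phi_{1j} + (1 - w)\phi_{2j}]$, which is concave in $w$
(the 1-D fit is a grid plus golden-section refinement and provably
unimodal). *Route fidelity* — how loyal a bird is to its own route — is
operationalised as the reciprocal of the mean cross-track sd of its solo
paths; the fidelity-dependent weight model sets
$w_i = \mathrm{logit}^{-1}(a + b f_i)$, and BIC comparison against the
constant-weight model asks whether loyalty predicts influence.

# What the synthetic generators do and do not emulate

Every test input is produced by the package's own generators, which stand
in for arena recordings of real animals. They reproduce the *structure*
the models care about — binary travel senses with context-dependent
reversal rates, alignment with angular noise, stigmergic deposition with
evaporation, station-wise route variability — under exactly the
assumptions the models make (independent decisions given the context,
Gaussian noise, no body size, no collisions, no radial excursions). A
passing suite therefore demonstrates internal consistency of the modelling
cycle (simulate, then recover what was simulated) and the qualitative
group-level phenomena; it cannot certify that any rule describes a real
species, nor reproduce the empirical likelihood values of recorded
animals, which would require the original recordings.

Problem sizes were chosen once as the package's study conditions: Weber
recovery uses 50,000 turning observations (gain 30.80, threshold 10.53,
noise sd 20 degrees, concentrations log-uniform on $[1, 1000]$); zone-width
recovery uses $N = 8$, $T = 5000$, 10 replicates at the non-local width
$\pi$; memory-model selection uses $N = 8$, $T = 1500$, 20 replicates at
the local width $\pi/5$ with $p_0 = 0.02$, $p_1 = 0.2$, $\tau = 5$. The
strong-coupling alignment demonstration uses $p_0 = 0.002$, $p_1 = 0.3$,
$w = \pi/5$: with a local zone, minority animals meet opposite-direction
neighbours far more often than majority animals do, so the group locks
into one rotational sense and the late-time clockwise-count distribution
is bimodal; with a saturating *global* forward zone the asymmetry
inverts and the group stays mixed, which is why the non-local width is a
recovery target but not the alignment demonstration.

# Numerical choices and degenerate inputs

* Probability clip $10^{-9}$; timestamps checked to a relative tolerance
  of $10^{-9}$; trajectory CSV written with 17 significant digits so round
  trips are bit-exact.
* A lone agent has `f_opp = 0` and never triggers a zone; an event table
  with a single timepoint is an error ("no transitions observable").
* Zone-profile ties are broken toward the smallest threshold; circular-mean
  ties in the alignment model retain the previous heading.
* The loop metric thresholds at the 90th percentile of cell values
  (falling back to the occupied cells when the top decile is flat, as in a
  drawn uniform ring), connects cells by 8-neighbour adjacency so diagonal
  trails stay connected, and takes the 2-core as the set of cells lying on
  cycles.
* Master seeds are expanded into per-component sub-seeds with
  `deriveSeed()`, a small counter-based hash, so adding a component to a
  pipeline does not perturb the draws of the others; all derived seeds stay
  below $2^{31}$.

# Known limitations

* Ring agents are points: no exclusion, no contact mechanics, no radial
  degree of freedom.
* The trail simulation deliberately omits path integration and direct
  ant-ant interactions; the re-walked reinforcing loops it builds (measured
  by `loopMetric()` against the gain-zero control) are the observable
  consequence of that omission, not a defect to be tuned away.
* Marginal likelihoods are Laplace/BIC approximations; no posterior
  sampling is provided.
* The candidate force-matching laws must be linear in their parameters.
* Custom memory models can be registered for fitting, but the ring
  simulator only threads the two built-in memory mechanisms.
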