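# swarmfit

Simulation and likelihood-based model selection for collective animal
behaviour.

Animal groups — circulating prawns, marching locusts, ant colonies laying
pheromone trails, pairs of homing pigeons — produce group-level patterns
from local interaction rules. `swarmfit` implements both directions of that
modelling cycle for researchers in quantitative ethology:

* **local → global**: stochastic simulators for ring-arena direction
  switching, alignment-in-radius collective motion (with its order-parameter
  phase transition), and Weber's-law pheromone trail following with
  deposition, evaporation, and double-bridge choice dynamics;
* **global → local**: a model-selection engine that scores candidate
  interaction rules by the probability of the complete observed event
  sequence — maximum-likelihood fits, AIC/BIC, Laplace-approximate marginal
  likelihoods and Bayes factors, least-squares force matching for planar
  models — plus a route-mixture predictor for paired journeys built from
  repeated solo paths.

## The models at the core

**Direction switching.** Agents circulate a ring with travel sense
$d_i \in \{+1, -1\}$. Each timestep a focal agent reverses with a
probability set by its rule: mean-field $p_0 + k f_{\mathrm{opp}}$;
an interaction zone ($p_1$ when an opposite-direction agent lies within
$[0, w]$ ahead, else $p_0$); or non-Markovian memory — a refractory window
of length $\tau$ (D1) or a decaying encounter trace
$M \leftarrow (1-\lambda)M + \mathbf 1\{\text{encounter}\}$ (D2). The
sequence likelihood $\sum_r [y_r \log p_r + (1-y_r)\log(1-p_r)]$ threads
memory per agent, and models are ranked by approximate marginal likelihood
(Bayes factors against the mean-field baseline).

**Weber's-law trail following.** An ant turns by
$\alpha = A\,(L - R)/(L + R + T_0)$ degrees per 0.4 s sensing window,
where $L, R$ are the pheromone masses in its front-left/front-right
sectors, $A$ the gain and $T_0$ the detection threshold. The spatially
explicit simulator couples this response to a shared evaporating field;
`effectiveChoiceCurve()` shows how repeated interactions sharpen an almost
linear response into the nonlinearity that double-bridge dynamics
$\dot c_A = f P_A - \rho c_A$, $P_A \propto (k + c_A)^n$, require.

**Route mixtures.** Repeated solo paths are summarised as a station-wise
Gaussian cross-track distribution; a paired journey is scored under the
mixture $w\,\phi_1 + (1-w)\,\phi_2$ of the two partners' distributions,
with $w$ constant or a logistic function of route fidelity (inverse mean
cross-track spread).

## Worked example: recover a switching rule from simulated groups

```r
library(swarmfit)

# simulate 8 agents for 2000 steps under the non-local zone rule
cfg <- ringSimConfig(N = 8, T = 2000, model = "zone",
                     params = c(p0 = 0.02, p1 = 0.2, w = pi), seed = 11)
traj <- simulateRing(cfg)
ev   <- extractEvents(traj)
ev
#> SwitchEvents: 15992 records, 8 agents, 2444 switches (dt = 0.4 s)

# fit the generating rule by maximum likelihood
fitMLE("zone", ev, seed = 1)
#> ModelFitResult 'zone': logLik -6330.343 on 15992 events (3 params)
#>   params: p0 = 0.01735, p1 = 0.1968, w = 3.141
#>   AIC 12666.69 | BIC 12689.73 | log marginal NA | converged: TRUE
```

The fitted parameters sit on the generating values: baseline rate 0.017
(truth 0.02), in-zone rate 0.197 (truth 0.2), zone width 3.141 rad (truth
$\pi$). Ranking a candidate set on the same events orders the true model
first and reports its log Bayes factor against the mean-field baseline:

```r
rankModels(c("meanfield", "zone", "bernoulli"), ev, seed = 5)@table[, c("model", "logMarginal", "logBF")]
#>       model logMarginal     logBF
#> 1      zone   -6350.258  291.4222
#> 2 meanfield   -6641.680    0.0000
#> 3 bernoulli   -6842.812 -201.1321
```

The same engine runs the ant analysis: `simulateWeberObservations()` draws
(L, R, turning-angle) triples, and `fitWeber()` recovers the gain and
threshold by nonlinear least squares:

```r
d <- simulateWeberObservations(50000, weberParams(A = 30.80, T0 = 10.53,
                                                  noiseSd = 20), seed = 5)
fitWeber(d)$coef
#>        A       T0
#> 30.92203 11.61726
```

## Command line

A thin wrapper over the same functions is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts", "swarmfit", package = "swarmfit"))') \
    simulate-ring --config cfg.yaml --seed 9 --out traj.csv
```

Subcommands: `simulate-ring`, `simulate-vicsek`, `simulate-ants`,
`pheromone-map`, `double-bridge`, `choice-curve`, `events`, `profile`,
`fit`, `rank`, `recover`, `routes-fit`, `pair-fit`, `cycle-demo`,
`make-fixtures`. Every output gets a JSON manifest (config echo, seed,
version) from which the run can be reproduced.

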