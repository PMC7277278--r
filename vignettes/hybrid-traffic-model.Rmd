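---
title: "Estimating long-distance vector traffic from roadside surveys"
author: "gravroute"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating long-distance vector traffic from roadside surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gravroute)
```

## The problem

Trailered boats, firewood, bait buckets and other human-moved goods carry
invasive species and pathogens over distances no natural dispersal could
cover.  The agents of interest — here, medium-to-large motorized boats that
could be fouled by dreissenid mussels — are rare among general traffic, and
their origins (whole provinces and states) and destinations (thousands of
lakes) have far too many access points to survey directly.  What *can* be
surveyed cheaply is the long-distance traffic funnelled through a handful of
highways: roadside inspection stations record, per survey shift, how many
agents passed and where each was travelling from and to.

`gravroute` fits a gravity model — the classical trip-distribution model in
which the mean flow between origin $i$ and destination $j$ is proportional
to an origin *repulsiveness* $m_i$, a destination *attractiveness* $a_j$ and
a negative power of the travel time $d_{ij}$ — to exactly this kind of
roadside count data, by chaining it with three observation submodels:

1. **Gravity**: the daily number of agents $N_{ij}$ travelling $i \to j$ is
   negative binomial with mean
   $\mu_{ij} = c\, m_i a_j d_{ij}^{-\alpha_d}$ and a mean-to-variance ratio
   $p$ shared by all pairs.
2. **Route choice**: an agent passes survey station $k$ with probability
   $\rho_{ijk}$, built from a set of *admissible* paths and a length-based
   choice rule.
3. **Temporal pattern**: the agent passes during the shift window with
   probability $\tau$, the integral of a daily (von Mises) traffic density
   over the window.
4. **Compliance**: the agent stops and yields complete, consistent data
   with probability $\xi$.

The surveyed count for a (shift, origin-destination) cell is the daily
count thinned by $\rho$, $\tau$ and $\xi$ in turn.

## The count law and why the parametrization matters

We parametrize the negative binomial by its mean $\mu$ and the
mean-to-variance ratio $p \in (0, 1]$, i.e. size $\mu p/(1-p)$ and success
probability $p$.  Two closure properties make this the right choice:

* **Pooling.** Sums of independent counts with common $p$ are again
  negative binomial with the same $p$: predictions are invariant to whether
  individual lakes or origin jurisdictions are merged into regions.
* **Thinning.** Binomially thinning a negative binomial count with
  retention $t$ preserves the *size* parameter and moves the success
  parameter to $p/(p + t(1-p))$.  The surveyed count is therefore exactly
  negative binomial with mean $t\mu$, $t = \rho\,\tau\,\xi$.

Note the thinned count's mean-to-variance ratio is *not* $p$; it approaches
1 (Poisson) as the thinning gets strong.  The package implements this exact
law.  One measurable consequence: with $p < 1$ the composite likelihood can
in principle separate the overall scale $c$ from the compliance rate $\xi$
through the variance structure, while in the Poisson limit only the product
$c\,\xi$ is identified.  In practice the separation is extremely weak, which
is why compliance is estimated from its own dedicated counts rather than
from the count likelihood.

## Covariate structure

Repulsiveness and attractiveness are compositions of one-covariate
*building blocks*, either a power $f_0(x) = x^{\alpha_1}$ or a saturating
function $f_1(x) = (x/(x + \alpha_0))^{\alpha_1}$; blocks multiply when
covariates act jointly ("and") and add when they substitute for one another
("or").  The applied model shipped with the package is

$$\mu_{ij} = c \left(\tfrac{pop_i}{pop_i + pop_0}\right)^{\alpha_{pop}}
  \beta_{CA}^{CA_i}
  \left(\tfrac{A_j}{A_j + A_0}\right)^{\alpha_A}
  \big(1 + \beta_{camp}\,camp_j + \beta_{fac}\,fac_j + \beta_{mar}\,mar_j
      + \beta_{lpop} f_1(lpop_j)\big)\, d_{ij}^{-\alpha_d},$$

with populations in $10^6$ persons, near-lake populations in $10^3$
persons, lake areas in km$^2$ and travel times in $10^4$ minutes — the
parameter values are only meaningful on these scales.
`bc_boater_params()` returns the reference estimates for the British
Columbia boater system (e.g. $\beta_{fac} = 4.51$: facilities alone make a
lake 5.51 times as attractive).  The exponents $\alpha_{pop}, \alpha_A,
\alpha_{lpop}$ default to 1 and stay fixed unless explicitly freed.  Rather
than a fully general covariate algebra, candidate models for AIC selection
are expressed as fixed/free masks over this structure (`aic_select()`),
which covers the practical model search while keeping every candidate
identifiable by construction.

## Route admissibility and choice

Enumerating all paths between thousands of pairs is hopeless; following the
locally-optimal-path idea, a path is *admissible* if

* it is a **single-via path** — a shortest path constrained through one
  intermediate vertex (this is what keeps enumeration tractable and rules
  out zigzags);
* its length is at most $\gamma$ times the shortest ($\gamma = 1.4$ by
  default);
* it contains **no local detour**: every along-path subpath shorter than
  $\delta$ times the path length ($\delta = 0.2$) must itself be a shortest
  path, tested for all vertex pairs on the path with relative tolerance
  $10^{-9}$.

Shortest-path ties are broken lexicographically by vertex name so that
enumerated path sets are reproducible; correctness is contract-tested
against a brute-force filter on small random graphs.  An admissible path
$P$ is chosen with probability $\propto l_P^{-\lambda}$; with the reference
$\lambda = 7.4$, a route 10% longer than the best attracts half the
traffic.  A fraction $\eta_c$ of agents drives inadmissible routes instead
and passes any given station with probability $\eta_o$; since traffic on
never-monitored inadmissible routes is unobservable, $\eta_c$ is not
estimable and is constrained to $[0, 0.05]$, with boundary-touching
confidence intervals reported as such.  Inadmissible-route flow is never
mapped to specific edges — predictions report it as an unallocated total.

## Staged fitting

The submodels are fitted in the order inverse to the observation
hierarchy; `fit_gravity()` refuses to run without the upstream fits.

* **Compliance** is two pooled ratios (stopped / passed, complete /
  stopped) with Clopper–Pearson intervals; shifts without bypass counts
  contribute only to the second ratio.
* **Temporal pattern** maximizes the *conditional* likelihood
  $\sum \log[f(t_i)/\tau(\text{shift}_i)]$, which removes the bias from
  surveys concentrated at particular times of day.  Because all windows may
  sit on one side of the day this surface can be multimodal in the peak
  time, so the optimizer starts from several peak offsets.  The
  concentration is capped at $\kappa = 50$ (a degenerate one-instant
  sample would otherwise diverge).
* **Route choice** maximizes the likelihood of *which monitored station*
  each surveyed agent was seen at, conditional on monitoring effort:
  station $k$ has probability $\rho_{ijk} w_k / \sum_{k'} \rho_{ijk'}
  w_{k'}$ with $w_k$ the $\tau$-weighted monitored time of station $k$
  (duration-weighting is a one-line change in the caller).  If every
  surveyed pair has a single admissible route, $\lambda$ is flagged
  unidentifiable.
* **Gravity** maximizes the composite likelihood over all (shift, pair)
  cells — including the overwhelmingly many implicit zeros — treating
  cells as independent.  Zero-count blocks are evaluated in closed form
  and grouped by identical (station, window probability), which makes the
  cost linear in the number of distinct survey configurations rather than
  shifts.  Positivity-constrained parameters are log-transformed ($p$
  logit-transformed), and multi-start Nelder–Mead (default 10 jittered
  restarts, deterministic seed) guards against local optima.

Confidence intervals throughout are profile-likelihood intervals: the
endpoints where the profiled log-likelihood drops by
$\chi^2_{1,0.95}/2 = 1.92$, found by stepping out and bisection while
re-optimizing the remaining parameters.  A side that never crosses the
threshold before a finite box bound is reported at the bound (as happens
for $\eta_c$); an infinite bound yields an open endpoint.  Because the
composite likelihood ignores dependencies between cells that share a day,
its intervals can undercover on real data; in the synthetic test bench each
shift runs on its own day, so cells are genuinely independent there and
coverage is nominal.

## Model assessment

Two metrics mirror common practice for this model class:

* **Variance-corrected $R^2$** compares observed and predicted mean counts
  per station over shifts lying inside a common midday window (11.00–16.00
  by default, so per-station counts are comparably distributed), after
  dividing both by the model-predicted standard deviation of the station
  mean (per-shift variances summed over cells, i.e.
  $\mathrm{sd} = \sqrt{\sum_s \sigma^2_s}/m$).  Aggregation is per station;
  per-shift normalization without aggregation would be dominated by the
  many zero-count shifts.
* **Nagelkerke's pseudo-$R^2$** compares the composite likelihood against
  a null model with uniform temporal pattern, no route information
  ($\eta_c = 1$, so the station passage probability is a constant that
  folds into the mean) and one constant mean and ratio for all pairs,
  fitted by its own maximum likelihood.  The cell count $n$ in the formula
  is the number of (shift, pair) likelihood cells — a convention choice,
  documented rather than hidden.

## The synthetic test bench

`generate_scenario()` + `simulate_surveys()` emulate the whole data
pipeline: a connected planar-ish road network (k-nearest-neighbour graph
plus its Euclidean minimum spanning tree) whose destination region spans a
few hundred minutes of driving; origin jurisdictions attached by long
feeder roads (300–1500 minutes) so origin–destination trips sit in the
multi-hour long-distance band; heavy-tailed lake areas and populations on
the reference covariate scales; stations on the highest-betweenness
junctions, which is where inspection stations are in fact placed.  True
parameters default to the reference (British Columbia) estimates.  The
simulation is event-level: each agent samples an actual route, passage
time and compliance outcome, so the marginal count law of the likelihood
is *derived*, not built in — matching the two is a real test.

Survey shifts start on a half-hour grid between 07.00 and 12.00 and last
4–8 hours, all in daytime as in the motivating survey programme; each shift
runs on its own day.  Two deliberate departures from real data follow from
this: there is no weekly or seasonal structure (the model ignores it too,
and the negative binomial absorbs the resulting overdispersion), and
counts from different shifts are truly independent, which real same-day
shifts are not.  Passing tests therefore validate the estimators under the
model's own assumptions — they do not show that real traffic satisfies
those assumptions.

Default sizes are chosen so the full test bench runs in minutes on one
CPU: 20 origins, 100 destinations, 300 network vertices, 12 stations, 500
shifts for the study-scale scenario; parameter-recovery experiments use
smaller, denser "busy subsystem" scenarios (few dozen vertices, large
popular lakes, shorter feeders) because at 10-lake scale realistic sparse
covariates yield almost no long-distance traffic and nothing to fit.
Recovery experiments free ($c$, $p$, $\alpha_d$) with the remaining
parameters held at truth; freeing all eleven parameters per replicate
would add nothing to the coverage question while multiplying the cost.
The out-of-sample validation experiment runs at survey-programme volumes
(on the order of a thousand daytime shifts over eight stations, a few
surveyed agents per shift): the variance-corrected $R^2$ compares
*station means*, and its own central-limit premise requires many midday
shifts per station — at sparser volumes the metric measures noise, not
model quality.

## Numerical choices

* Von Mises densities use exponentially scaled Bessel functions, so large
  concentrations do not overflow.  Window probabilities integrate the
  density adaptively to $10^{-10}$ in `window_probability()`; likelihood
  loops use a fixed 64-node Gauss–Legendre rule (agrees to $\sim 10^{-9}$,
  property-tested) because the adaptive integrator is too slow inside an
  optimizer.  Midnight-wrapping windows are split at 0 h and summed.
* Zero-cell grouping keys quantize the window probability at 12
  significant digits; two cells group only if station and window
  probability agree to that precision.
* $\mu = 0$ cells (zero attractiveness, unreachable pairs) are treated as
  a point mass at zero, not an error; an observed count there yields
  $-\infty$ log-likelihood, which the optimizer treats as a hard wall.
* Profile bisection solves CI endpoints to $10^{-3}$ relative precision —
  far below any scientific use of an interval endpoint, and each extra
  digit costs a full inner re-optimization per bisection step.

## Known limitations

* The composite independence assumption is exact only in the synthetic
  bench; on real data, confidence intervals and AIC differences should be
  read qualitatively.
* Path-overlap corrections are not implemented: two admissible routes
  sharing most edges are treated as distinct alternatives.
* The inadmissible-route model is location-free by construction; edge-flow
  maps omit that share (reported as an unallocated total).
* Compliance is a single global rate; per-station rates are an interface
  slot but no estimator is provided.
* The temporal model is a single daily cycle; an optional step-function
  density would be a drop-in replacement for the von Mises density in the
  same conditional likelihood, and is left out of the default pipeline.
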