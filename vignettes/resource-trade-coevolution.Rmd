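---
title: "Modelling the co-evolution of plant-mycorrhizal resource trade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the co-evolution of plant-mycorrhizal resource trade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycotrade)
```

## The model

`mycotrade` simulates a plant and a mycorrhizal fungus locked into repeated
one-to-one resource trade over a shared lifetime, and asks what trading
strategies evolve when the strategy itself is heritable. The model
deliberately excludes partner choice, sanctions, proportional rewards and
every other proposed mutualism-stabilising mechanism: the only coupling
between the partners is that each one's growth feeds back on the resources
available to the other.

Each lifecycle runs for `steps = 10` timesteps from founding biomasses
$X_0 = Y_0 = 1$. In every timestep three things happen:

1. **Gather.** The plant acquires carbon equal to its biomass (it is the C
   specialist) and phosphorus $\alpha X_n$; the fungus acquires P equal to
   its biomass and C $\beta Y_n$. The uptake efficiencies
   $\alpha, \beta \in [0, 1]$ are fixed properties of the environment/organism
   pair and absorb both nutrient availability and acquisition ability.
2. **Exchange.** The heritable strategy is the pair
   $(\gamma, \varepsilon) \in [-1, 1]^2$: the plant moves $\gamma X_n$ of its
   gathered C to the fungus and the fungus moves $\varepsilon Y_n$ of its
   gathered P to the plant. A negative share means the organism *takes* its
   specialised resource back from its partner; a taker's claim is clamped to
   what the partner gathered that step (it can take all the available
   resource, but no more). Exactly one transfer happens per resource, so the
   two clamps cannot interact within a step.
3. **Grow.** Each organism grows by the smaller of its two post-exchange
   pools -- Liebig's law of the minimum:
   $$X_{n+1} = X_n + \min(\alpha X_n + \varepsilon Y_n,\; X_n(1-\gamma)),
     \qquad
     Y_{n+1} = Y_n + \min(Y_n(1-\varepsilon),\; \beta Y_n + \gamma X_n),$$
   for non-negative shares, with the clamped analogue otherwise. Pools are
   discarded between steps (no storage), and the final biomasses $X_{10},
   Y_{10}$ are the pair's fitness values.

Two parameter families have closed-form solutions used as analytic oracles
throughout the test suite: with no exchange, fitness is $(1+\alpha)^{10}$ and
$(1+\beta)^{10}$; with no nonspecialised uptake and symmetric giving
$\gamma=\varepsilon=g \ge 0$, both fitnesses are $(1+\min(g, 1-g))^{10}$.

```{r}
simulate_lifecycle(alpha = 0.1, beta = 0.3, gamma = 0, epsilon = 0)
```

## Landscapes

`compute_landscape()` evaluates the lifecycle over a grid of strategies
(500 points per axis by default; the sweep
uses 201 so the `(0, 0)` baseline cell is on-grid) and derives:

* the **coupled fitness landscapes** -- plant and fungus fitness surfaces,
  interdependent because each organism's growth feeds back on the other's
  resources;
* the **interaction-type partition** relative to the no-exchange baseline at
  `(0, 0)`: mutualism (both gain), parasitism (one gains, one loses; named
  for the beneficiary), competition (both lose). We add an explicit
  **neutral** class for ties within a relative tolerance of `1e-9`: unlike
  in continuous models, ties occur on sets of positive measure here (a plant
  with $\alpha = 0$ that receives no P is pinned exactly at baseline), and
  silently merging them into a gain/loss class would misstate the biology;
* the **extinction zones** (an organism's biomass never exceeds 1, which
  disqualifies it from reproduction) and their complement, the **viable
  resource exchange range**;
* the **resources received** layers: net signed lifetime transfer totals,
  with given/taken magnitude splits.

## The individual-based evolution model

`run_evolution()` evolves populations of 200 plants (carrying $\gamma$) and
200 fungi (carrying $\varepsilon$). Each generation: a uniform random
one-to-one pairing; one full lifecycle per pair; reproductive weight equal
to final biomass for individuals that grew and zero otherwise (a switch
selects biomass gain instead); offspring sampled with replacement
proportionally to weight, every offspring mutated by a Gaussian step of sd
0.02 and clipped to $[-1, 1]$; monomorphic founding. A species in which no
individual grew is extinct and the run stops. Runs are capped at 2000
generations.

The reproduction internals admit many reasonable variants, so all of them
are exposed in `evolution_config()`. The defaults were fixed once: small mutation steps (0.02) reproduce smooth
mean-strategy trajectories; one-to-one random pairing is the model's core
premise of repeated individual-level interaction; fitness-proportional
sampling is the simplest scheme consistent with "final biomass is the
fitness value". The same generation step is implemented twice -- a compiled
production loop and an R-level reference that consume the random stream
identically -- and the suite asserts they produce bit-identical
trajectories.

## Stable strategy areas

`characterize_uptake()` reconstructs, for one $(\alpha, \beta)$ pair, the
full stability pipeline:

1. **Exploration.** Evolution runs start from a 5 x 5 grid of founding
   strategies spanning $[-0.8, 0.8]^2$, filtered to viable founders (a
   monomorphic population founded at a no-growth strategy is extinct at
   generation 0, so nothing is learned from it). For runs that reach the
   generation cap, the population mean strategies of the final 500
   generations are pooled.
2. **Candidate areas.** Pooled points are clustered by single linkage at a
   distance threshold of 0.1 strategy units (run on a deterministic
   subsample of at most 800 points for speed, with all points assigned to
   the nearest subsampled point's cluster) and each cluster receives a
   covariance ellipse scaled to cover 95% of its points (empirical
   Mahalanobis quantile).
3. **The stable area.** The fitted 95% ellipse describes a stationary
   cloud's *tail*; the stable resource exchange strategy **area** is defined
   as that ellipse scaled 3-fold on both semi-axes -- the region a
   stationary population actually roams. One definition is used everywhere:
   for the membership rule, the zone classification, the fitness maxima and
   the reported geometry. The factor matters: a strict membership test
   against the unscaled 95% ellipse would reject even a perfectly stationary
   replicate (about 5% of its generations fall outside that ellipse by
   construction), while classifying zones on a smaller ellipse than the
   tested one can call an area "parasitism-only" even though the tested
   populations demonstrably roam into the mutualism wedge.
4. **Stability test.** 36 independently seeded runs are founded at the area
   centre; a replicate *remains* if its per-generation mean strategy (what
   the trajectories plot) stays inside the area for 500 consecutive
   generations from generation 0 without extinction. All 36 remaining is
   *stable*; at least one remaining is *semi-stable*; none is *no stable
   strategy*.
5. **Classification.** The landscape cells inside the area determine the
   category: at least 99% mutualism (of non-neutral interior cells) is
   `mutualism_stable`; mutualism present plus more than 1% parasitic cells
   is `mutualism_parasitism_stable`. Neutral cells are reported but excluded
   from the denominators -- ties live exactly on zone boundaries (e.g. the
   single $\varepsilon = 0$ grid column where giving costs a still-P-limited
   plant nothing), and a one-column boundary touch must not flip the
   category of an otherwise unambiguous area. Any other combination raises
   a `novel` flag rather than being forced into a category.

`run_sweep()` repeats this for the full grid of 21 plant P uptake
efficiencies (0 to 1 by 0.05) crossed with 11 fungus C uptake efficiencies
(0 to 1 by 0.1) -- 231 combinations -- and aggregates the category shares.
Every level of the pipeline derives independent child seeds from one master
seed, so any replicate, combination or the whole sweep can be reproduced in
isolation.

## What the simulations show

Running the pipeline reproduces the qualitative regimes the model was built
to explore (none of the numbers below are hard-coded anywhere; the
acceptance script under `scripts/` recomputes them from scratch):

* **Stable mutualism** wherever both organisms depend substantially on
  their partner: a single compact area in the first quadrant attracts
  trajectories from most viable founding strategies, and none of 36
  replicates leave it.
* **Mutualistic-parasitic areas** appear when one uptake efficiency is high
  (the roaming region straddles the mutualism/parasitism boundary, so the
  population's average interaction type switches back and forth).
* **Transient parasitism**: trajectories founded in the first-quadrant
  competition zone cross a parasitic zone on their way into mutualism.
* **Darwinian extinction**: founders in or near the third quadrant enter a
  mutual-taking feedback loop -- each organism gains short-term relative
  fitness by damaging the partner that is damaging it -- and the strategies
  race toward $(-1, -1)$ until one or both populations collapse. At extreme
  uptake efficiencies (95-100%) this is the only outcome and no stable
  strategy exists.
* **Maximum fitness, maximum resource received and the stable area
  generally do not coincide**; they do only when both uptake efficiencies
  are low and equal.

## Numerical choices and degenerate inputs

* All arithmetic is double precision; transfers are never rounded. An
  organism "grew" if its final biomass exceeds 1 by more than `1e-12`
  (guarding float noise only).
* $\gamma = 1$ is legal: the plant may give all its gathered C and forfeit
  growth that step.
* Covariance ellipses get a `1e-12` diagonal ridge so monomorphic or
  near-degenerate clouds remain invertible; a zero-axis ellipse contains
  only points on the complementary axis.
* Ties in grid argmaxima are broken lexicographically by $(\gamma,
  \varepsilon)$ and all tied cells are reported.
* An ellipse so small it contains no grid cell is evaluated at the nearest
  cell and flagged.

## What the generator emulates, and limitations

The synthetic fixtures (`generate_fixtures()`) encode hand-derived exchange
ledgers, closed-form lifecycles, the exactly-known structure of the
$\alpha=\beta=0$ landscape, and a two-genotype selection scenario with its
analytic expectation; they validate machinery, not biology. The
individual-based model's default study conditions (population 200 per
species, 2000-generation cap, 36-replicate stability testing over the
231-combination grid) are simulation settings, not field data: real plants and
fungi have multiple simultaneous partners, can disengage from harmful ones,
store resources between episodes, and trade more than two currencies. Tests
passing here therefore support the internal logic of the fitness-feedback
argument, not quantitative predictions about any real symbiosis.

Two caveats deserve note. First, the reproduction scheme and the
stable-area geometry involve genuinely open design choices (mutation
kernel, selection scheme, ellipse scaling, zone thresholds); plausible
alternatives shift the headline percentage shares of the sweep by a few
points. Second, at the extreme corner $\alpha = \beta = 1$ the model has a
structural stalemate: a population racing to mutual full taking stalls just
short of $(-1, -1)$, because an individual's growth is zeroed only when its
partner's trait is *exactly* $-1$, and a finite mutating population never
reaches that state collectively, so the all-individuals-failed extinction
rule cannot trigger. The pipeline reports this corner as a (novel,
flagged) stable strategy inside the competition zone; every neighbouring
high-uptake combination (95%, or one efficiency at 100% with the other
below it) ends in extinction-only, as the mutual-taking feedback argument
predicts.
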