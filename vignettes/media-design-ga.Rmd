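---
title: "Designing growth media for microbial communities with a genetic algorithm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing growth media for microbial communities with a genetic algorithm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MediaGA)
```

## The problem

The phenotype of a multispecies microbial community — which organisms
dominate, how evenly taxa are represented, how much metabolic cross-feeding
occurs — depends sensitively on which limiting nutrients the medium supplies.
Screening all nutrient combinations is hopeless: all subsets of a 20-carbon-
source panel already span $2^{20} \approx 1.05$ million media. MediaGA treats
the medium composition (the set of limiting carbon sources added to a fixed,
otherwise non-limiting base medium) as the unit of optimization and searches
the combinatorial space with an elitist genetic algorithm (GA), using either a
precomputed environment-to-phenotype lookup table or an on-demand community
simulator as the evaluator.

## Environments and media

An *environment* is a set of at most $N$ nutrient ids drawn from a
`NutrientPool`; equality is order-free. Admissible-set counting is closed-form
(`countEnvironments()`), so even spaces far too large to enumerate can be
sized instantly; `enumerateEnvironments()` materializes small spaces in a
canonical order (by subset size, then lexicographically on pool indices) and
refuses, behind an explicit cap, to expand large ones. Both size rules are
exposed because both occur in practice: panels of "up to $k$" nutrients
(including the base-medium-only empty set) and exact-$k$ designs.

`buildMedium()` converts an environment into amounts. In the default
equimolar-carbon mode all nutrients share one molar amount $x$ with
$x \sum_i c_i = 0.02$ mmol C (50 mM C in 400 µl), where $c_i$ is carbon atoms
per molecule; in override mode each nutrient gets a fixed amount (e.g.
$5\times10^{-4}$ mmol), the convention for large exploratory spaces where the
growth phase is deliberately kept short.

## The community simulator

The evaluator contract only requires per-organism final biomass, exchange
records, secretion totals and the derived summary statistics. Behind that
contract MediaGA ships a deterministic Monod consumer–resource model rather
than genome-scale dynamic FBA: it is seedable, runs in milliseconds, and
preserves every downstream interface.

Per explicit-Euler step of length $\Delta t$ (default 0.01 h over 24 h):

* each organism $i$ demands substrate $s$ at
  $v^{max}_{is}\, B_i\, \frac{S_s/V}{K_{is} + S_s/V}\,\Delta t$ mmol
  ($B_i$ biomass in gDW, $S_s$ the substrate pool in mmol, $V$ the culture
  volume);
* when total demand exceeds availability, all consumers are rationed
  proportionally, so pools never go negative;
* consumed carbon splits into biomass ($y_{is}$ gDW/mmol) and secreted
  byproducts (per-substrate carbon fractions); any remainder is booked as
  respired;
* organisms with a missing required cofactor metabolite (auxotrophy gate,
  presence tolerance $10^{-12}$ mmol) neither grow nor take anything up;
* death removes biomass at a first-order rate (default 0.1 h⁻¹; 0 in the
  short-horizon target-composition setting).

Byproduct absorption is attributed to donor organisms proportionally to their
cumulative secretion of that metabolite up to the previous step — the
extracellular pool is shared, so donor identity must be reconstructed — and
self-transfers are not counted as exchanges. A carbon audit (biomass, medium,
byproducts, death-removed, respired; biomass converted at a configurable 40
mmol C/gDW) closes to machine precision when yields are carbon-complete, and
is asserted to $10^{-6}$ relative tolerance in the tests. Halving the
timestep changes fixture outcomes by under 1%, which is why the 0.01 h
default is considered converged.

The growth-cessation test follows the two-clause rule: the discrete
growth-curve derivative was positive at least once (the organism grew at all)
and is at or below zero (tolerance $10^{-12}$ gDW/step) at the end. The rule
deliberately excludes organisms that never grew; `everGrew()` reports those
separately rather than folding them into one flag.

## Objectives

Six families map a `PhenotypeSummary` to a scalar: Shannon entropy
$H = -\sum_i p_i \log_2 p_i$ of the relative abundances (taxonomic balance),
the abundance of a focal organism, the number of distinct directed
(donor, receiver, metabolite) exchanges, total flux directed at a focal
organism, community-wide secretion of a focal metabolite, and the sum squared
error to a target abundance profile such as $[0.90, 0.05, 0.05]$ (minimized).
Internally fitness is always maximize — minimize families are negated, with
raw values preserved in logs — so the engine is objective-agnostic. Fitness
ties are broken by the canonical environment order, keeping runs reproducible.

## The search engine

One GA generation: evaluate and rank the $P$ environments (default
$P = 10$, an experimentally tractable batch size), carry the top $\sigma$
(default 2) over as parents, create $P - \sigma$ offspring, and mutate
everything except the top-ranked environment. Offspring are, with probability
$p_C$, random assortments drawn from the linearized multiset of parent
nutrients — parental slots are drawn without replacement until the target
size (uniform on $1..N$) in distinct nutrients is reached, so nutrients shared
by several parents are proportionally more likely to be inherited — and
otherwise fresh random environments, which keeps exploration alive at low
$p_C$. Mutation replaces each nutrient of a non-top environment independently
with probability $p_M$ by a uniformly chosen nutrient not currently in that
environment ("not currently" is scoped to the environment, not the
population, whose nutrient set would often be exhausted). $p_M$ is kept below
0.5 so mutation cannot dominate the signal. The shipped operating point is
$[p_C, p_M] = [0.9, 0.35]$.

Repeat proposals are served from a memo, so `uniqueEvaluations()` counts
distinct experiments — the cost that matters when each evaluation is a wet-lab
or genome-scale simulation run. Duplicate environments within a population
are permitted; an evaluator failure demotes that environment to worst fitness
and the run continues.

Convergence requires all three of: (1) best-minus-mean within 10% of the mean
fitness of the generation; (2) the scaled gap between the generation's best
and the best ever found below 0.01; (3) no statistically significant fitness
increase over the predecessor generation — one-tailed two-sample Welch t-test
at $\alpha = 0.05$ — for 10 consecutive generations. Scores touching zero or
negative values (negated SSE at its optimum) are shifted by $|\min| + 1$
before the ratio criteria; constant generations fall back to a deterministic
mean comparison instead of a degenerate t-test.

The random-search baseline keeps the bookkeeping identical but removes
selection and recombination: each generation retains $\sigma$ environments
drawn uniformly (with replacement) from everything proposed so far and fills
the rest with fresh random draws — the same carry-over/novelty split as the
GA, which makes the comparison about selection pressure rather than proposal
budget.

## Benchmarking against a known optimum

On an exhaustively mapped space the full fitness distribution is known, so a
run can be scored absolutely: `G99` is the first generation whose best
fitness strictly exceeds the distribution's 99th percentile (linear
interpolation over the sorted values; `Inf` if never crossed), `Prend` the
percentile rank of the final best-ever fitness, and
$S = (1 - \widetilde{G99}) + \widetilde{P}_{rend} \in [0, 2]$ combines them
after min–max normalization across a parameter grid. Percentile rank uses the
at-or-below convention so a run that attains the enumerated maximum sits at
exactly 100 (a midrank variant is available for tie-heavy distributions, but
it can never reach 100, which would contradict the score's intended span).
Never-crossed runs are mapped to the generation cap before normalization and
counted separately in aggregates. The grid search spans $p_C \in \{0, 0.1,
\dots, 1\}$ and $p_M \in \{0, 0.05, \dots, 0.45\}$ with shared seed sets per
cell, reports the best cell per objective, and averages best pairs across
objectives — the origin of the shipped $[0.9, 0.35]$ default.

## The synthetic benchmark community

`communityFixture()` builds the packaged benchmark: 13 organisms on a
10-nutrient pool (sugars, a sugar alcohol, organic acids; 3–12 carbons),
searched over up-to-3-nutrient environments — 176 in total, small enough that
the exhaustive mapping takes seconds and 50-seed benchmarking minutes on one
CPU, while preserving search-against-known-optimum logic. Organisms are drawn
from four archetypes chosen to emulate the statistical structure of genome-
scale community datasets: *specialists* (2–3 nutrients, high uptake,
heavy byproduct secretion), *generalists* (60–80% of the pool at modest
rates), *cross-feeders* (mostly byproduct-fed), and *auxotrophs*
(competitive growers gated on a cofactor that only other members secrete).
Byproducts are six common fermentation products (acetate, formate, lactate,
succinate, glycine, ethanol). Yields are derived from the secretion fractions
so consumed carbon partitions exactly into biomass and secreted carbon,
making the conservation audit sharp. Kinetic ranges ($v^{max}$ 3–15 mmol
gDW⁻¹ h⁻¹, $K_m$ 0.1–2 mM, secretion fractions 0.1–0.5) are ordinary
heterotroph scales; at the default inoculum (1.6×10⁷ cells × 2.8×10⁻¹³ gDW
split 13 ways) growth saturates well inside the 24 h horizon, so
growth-cessation statistics resemble batch-culture reality.

The resulting dataset reproduces the features that matter for benchmarking:
variable richness, skewed fitness distributions, organisms that dominate
(>50%) somewhere and fail to grow elsewhere, auxotrophic non-growers, and
dense, variable exchange networks. What it does *not* emulate: genome-scale
stoichiometry, FBA-style flux re-optimization each step, non-metabolic
interactions, spatial structure, pH or temperature. Passing benchmarks here
demonstrates that the search machinery works against a truthful evaluator of
this structure — not that the simulator predicts any real community.

Two deliberate subtleties of the fixture are worth knowing. First, with a
death rate but no growth, all organisms decay identically, so the *empty*
environment has exactly uniform abundances and the maximal entropy
$\log_2 13$. The GA by contract proposes only non-empty environments, so
benchmarking uses the 175-environment non-empty space as both search space
and reference; the packaged mapping still contains all 176 rows. Second,
richness at the default presence threshold of 0 counts every organism with
positive biomass — and with first-order death nothing ever reaches exactly
zero, so richness is maximal by construction; the threshold is exposed for
users who want an abundance cutoff.

For the focal-parameter families the benchmark uses the selection logic one
would use on a real dataset: the abundance organism is one that grows in
roughly a third of environments, the flux target is the community's largest
byproduct receiver, and the secretion target its most highly secreted
metabolite. The acceptance suite runs each family over 50 seeds at the
shipped operating point with $G = 50$; the two flux/secretion families are
the hardest because their fitness landscapes top out in a cluster of
near-tied environments, where selection gradient carries almost no
information about which near-optimum strictly exceeds the 99th percentile —
the same slow convergence reported for rarely secreted metabolites in
genome-scale datasets.

## Problem sizes used in tests

The test and acceptance suites use: the 176-environment fixture mapping
(computed once per session); 50-seed GA and baseline sweeps at $G = 50$;
100-run invariant sweeps at $G = 8$; 100 random 4-organism communities at 4 h
/ 0.02 h for conservation checks; and a reduced $2\times2$ grid search with 3
seeds as a smoke test of the full grid machinery. These sizes keep the whole
suite in a few minutes on one CPU while exercising every code path at the
defaults used for real runs.

## Worked example

```{r example, eval = FALSE}
fx <- communityFixture(seed = 1)
mapping <- fixtureMapping(fx)                      # 176 simulations
space <- EnvironmentSpace(fx$pool, 3, includeEmpty = FALSE)

history <- runGA(space, lookupEvaluator(mapping), Objective("entropy"),
                 GAConfig(P = 10, sigma = 2, pC = 0.9, pM = 0.35,
                          G = 50, seed = 1))
history
ref <- referenceDistribution(mapping, Objective("entropy"))
computeMetrics(history, ref[setdiff(names(ref), "empty")])
```

## Known limitations

* The simulator is a consumer–resource surrogate: quantitative phenotypes of
  real organisms require a genome-scale evaluator behind the same contract
  (an extension point, not a shipped feature).
* The literal growth-cessation rule cannot classify never-growers; they are
  reported separately.
* Exchange counting is directional; the unordered count is also reported and
  the two coincide whenever each pair-metabolite transfer has a single net
  direction over the run, which holds for this simulator's outputs.
* On small enumerable spaces the strict-exceedance 99th-percentile criterion
  reduces to finding one of a handful of specific environments, and
  objectives with near-tied optima converge slowly — a property of the
  criterion, not a tunable of the engine.
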