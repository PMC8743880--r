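---
title: "Detecting strategic targeting of dominance interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting strategic targeting of dominance interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(domstrat)
```

## The problem

In group-living animals, dominance interactions are costly, so individuals
should be strategic about whom they direct them at — for example
concentrating expensive acts (chases, grabs) on close competitors, whose
relative rank is least settled, while spreading cheap acts (pecks,
displacements) or submissive signals more broadly. Detecting such strategies
from observational winner–loser data is harder than it looks, for two
reasons:

1. **Circularity.** The same interaction records are usually used both to
   infer the hierarchy and to measure who interacts with whom, so apparent
   rank-dependent targeting can be an artefact of reusing the data.
2. **Opportunity.** Stable groups regularly split into temporary subgroups
   (fission–fusion), and subgroup membership can itself be rank-assorted.
   Individuals close in rank then meet more often, and raw interaction
   counts show a spurious excess at small rank differences even when
   partners are chosen completely at random.

`domstrat` implements an inferential pipeline that addresses both: repeated
random data splitting separates hierarchy inference from strategy
measurement, and a subgroup-composition-constrained permutation null turns
raw counts into a *tendency to interact* — observed minus expected counts
given who was actually present.

## The pipeline

Each of many (by default 500) outer iterations runs these steps:

1. **Split.** The events are partitioned uniformly at random: a fraction
   (default 30%) goes to hierarchy inference, the rest to strategy
   measurement (`split_dataset()`). The subsets are disjoint, so rank
   differences and interaction tendencies are estimated independently.
2. **Rank.** A randomized-Elo hierarchy is fitted to the hierarchy subset
   (`elo_hierarchy()`): sequential Elo updates are averaged over many random
   replay orders of the events, removing dependence on observation order.
   Winners are the actors of aggressive events; for submissive signals the
   performer is the loser, so the winner is the recipient.
3. **Count.** Directed interaction counts per ordered dyad are taken from
   the strategy subset (`directed_dyad_counts()`). Counts stay at dyad
   level: with $N$ individuals there are $N-k$ dyads at rank difference
   $k$, so pooling counts by rank difference would fabricate a gradient.
4. **Permute.** One permuted dataset is generated
   (`permute_recipients()`): repeatedly pick an event, remove its actor
   from the individuals present at that moment, and redraw the recipient
   uniformly from the remainder. Actors, categories and present sets are
   untouched. Recipients may be of any rank, so the null is "random
   partner given opportunity", not a downwards heuristic.
5. **Smooth.** The tendency (observed − permuted counts), one value per
   directed dyad, is plotted against the signed rank difference
   (rank of actor − rank of recipient; negative when the actor outranks)
   and smoothed with cubic smoothing splines fitted *separately* for
   negative and positive differences (`fit_strategy_spline()`), because a
   single spline forced through zero would flatten genuine close-competitor
   peaks at −1.

Across iterations, the pointwise median and empirical 2.5/97.5 percentiles
of the spline predictions form the strategy band (`fit_strategy()`); a grid
point whose 95% range excludes zero marks a tendency significantly above or
below the opportunity-only expectation.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `hier_fraction` | 0.3 | share of events used for hierarchy inference; the rest measure tendencies |
| `n_iterations` | 500 | outer split iterations; uncertainty comes from here |
| `n_permutations` | 100000 | steps of the recipient-permutation chain per iteration |
| `df`, `lambda` | 3, 0.04 | smoothing-spline flexibility per side; `lambda` (the `smooth.spline` roughness penalty) takes precedence when given |
| `K`, `init_score`, `n_orderings` | 200, 1000, 1000 | Elo update size, starting score, and number of replay orders |

The Elo constants matter little for steep hierarchies: rank order is
determined by who beats whom, not by the score scale, and all constants are
configurable. The permutation chain only needs to be long enough that every
event is touched with high probability; because each step redraws a
recipient independently of the current state, the chain state after the
final step depends only on the last touch of each event, which is how the
implementation computes it (equivalent in distribution, far cheaper).

## The simulator: what it emulates and what it does not

`simulate_dominance()` generates data with known ground truth: `N`
individuals with fixed latent ranks, `X` temporary subgroups of mean size
`G`, one dyadic contest per subgroup, and a dominant-win probability
$P_{win} = 1 - (1-P_w)^{r_d}$ at absolute rank difference $r_d$ — at the
default $P_w = 0.9$ the dominant wins 90% of contests one rank apart and
almost always at larger gaps, matching a very steep hierarchy. Subgroup
membership is either uniform (inclusion probability $G/N$) or rank-assorted:
each subgroup gets a uniform target rank $z$ and individual $j$ joins with
probability proportional to a Gaussian kernel around $z$ with standard
deviation 2, rescaled to sum to $G$ and capped at 1 (the cap only binds for
extreme target ranks). Subgroups are redrawn whole until they contain at
least two individuals, which leaves the realized mean size slightly above
`G`. The defaults (`N = 20`, `X = 100`, `G = 5`, `P_w = 0.9`) are the group
size, sampling density and steepness regime the method was designed for.

Partner choice within a subgroup is uniform by default — the strategy-free
ground truth that the pipeline must report as "no significant grid points".
An optional recipient-preference kernel over signed rank difference can be
injected to create known strategies for power checks; the contest-outcome
draw still decides who ends up the actor, so the injected preference is
attenuated exactly as a behavioural preference would be in winner–loser
data.

The simulator deliberately omits features of real data: ranks never change
within a run, there are no bouts or escalation within interactions, no
observer detection bias, and subgroup composition is independent across
subgroups rather than autocorrelated in time. Passing the simulated
contracts therefore shows the *inference* is sound under the stated
generating model, not that field data meet its assumptions.

## Numerical and design choices

- **Split rounding.** The hierarchy subset gets
  `floor(hier_fraction * n + 0.5)` events, clamped to leave both subsets
  non-empty; the split is uniform over events (unstratified), the most
  literal reading of a random split.
- **Rankable-set conditioning.** At a 30% split some individuals may appear
  in no hierarchy-subset interaction and cannot be ranked. Each iteration
  conditions on the rankable set: strategy-subset events among ranked
  individuals are kept and present sets are intersected with the ranked
  set, so the permutation redraws recipients within the analyzable pool.
  This keeps per-actor observed and permuted counts identical — tendency
  rows sum to exactly zero — rather than leaking counts to individuals that
  cannot appear on the x-axis.
- **Evaluation grid.** Integer differences $-(N-1)\dots-1, 1\dots N-1$ for
  rank-based runs; 49 evenly spaced points per side of $[-1, 1]$ for
  score-based runs. Grid points outside an iteration's observed range use
  spline extrapolation; the band table reports the share of iterations that
  extrapolated at each point, because tail dyads are few and tail estimates
  correspondingly unstable.
- **Score-based variant.** `score_difference()` uses min–max normalized
  mean Elo scores and keeps the rank-difference sign convention (negative
  when the actor outranks the recipient; the top individual acting on the
  bottom one sits at −1).
- **Band and intervals.** Percentile method (empirical 2.5/97.5) throughout,
  both for the strategy band and for the Bayes-rule bootstrap.
- **One permuted dataset per iteration.** The tendency compares observed
  counts to a single permuted dataset; uncertainty comes from the outer
  iterations, not from averaging permutations within one iteration.
- **Ties.** Ties in mean Elo score are broken by individual id, making
  ranks deterministic given scores; tied `order` values keep file sequence.
- **Degenerate iterations** (e.g. a split leaving no usable strategy
  events) are dropped and counted in `n_failed` rather than redrawn.
- **Seeds.** One master seed per fit; per-iteration child seeds are derived
  from it, so any single iteration can be reproduced.

## Cost allocation by Bayes' rule

Within-category bands do not say whether higher-cost acts are *relatively*
concentrated on close competitors compared to lower-cost acts. For that,
`prob_high_given_rankdiff()` applies Bayes' rule at each signed rank
difference $R$:

$$P(A_h \mid R) = \frac{P(R \mid A_h)\, P(A_h)}{P(R)}$$

where $A_h$ is "the interaction is higher-cost aggressive" and all three
terms are relative frequencies over the pooled aggressive events.
Algebraically this equals $n_{high}(R) / (n_{high}(R) + n_{low}(R))$, which
the test suite uses as an independent oracle. `bootstrap_allocation()`
resamples the pooled events with replacement (so the replicate-level
baseline $P(A_h)$ varies, as it should) and labels each difference against
the baseline. The hierarchy feeding this analysis is, by default, a
randomized-Elo fit to the pooled aggressive events — pooling maximizes rank
precision and favours neither category; any hierarchy can be supplied
instead. The bootstrap unit is the event (not the dyad) with 1000
replicates by default; differences absent from a replicate contribute
nothing to that replicate.

## Problem sizes used in the shipped checks

The package's own validation runs use deliberately scaled problem sizes
chosen to exercise the contracts well inside routine-use compute: null and
artefact checks use the simulator defaults (`N = 20`, `X = 100`, `G = 5`,
`P_w = 0.9`) with 100 outer iterations and 1000-step permutation chains;
hierarchy-recovery checks use `X = 1000` (50 interactions per individual);
power checks inject a close-competitor kernel at 1200 events, comparable to
the densest observed groups. Randomized-Elo fits in these runs average 200
replay orders — at this steepness, rank order is already stable well below
that (the full default remains 1000).

## Known limitations

- The tendency scale depends on the number of observed interactions, so
  bands are not comparable across datasets or categories in absolute value;
  only their sign structure is.
- Sparse extreme-rank-difference dyads make band tails unstable; consult
  the `extrapolation_share` column before interpreting them.
- The permutation null conditions on observed subgroup composition; if
  composition itself responds to the strategy under study, the null is
  conservative in ways the simulator does not probe.
- Winner–loser data identify the winner, not the initiator; the method
  inherits the assumption that winners initiate, which is reasonable only
  for steep hierarchies.
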