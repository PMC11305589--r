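---
title: "Measuring community phases from dynamic communication patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring community phases from dynamic communication patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixbiotic)
```

## The problem

Social isolation and social fragmentation are both, at bottom, communication
problems: the isolated communicate too sporadically to form bonds, while
fragmented in-groups communicate intensely but only with themselves. The
philosophical notion of a *mixbiotic* society names the desirable middle
ground — diverse individuals mixing in proximity, balancing freedom
(openness) and solidarity (fellowship). This package quantifies where a
community sits between those extremes using only the *dynamics* of who
communicates when, complementing the static structure that conventional
social-network analysis describes and the entropy-based methods that dynamic
analyses usually require.

The central idea is to represent communication at each discrete time $t$ as a
vector over the $n$ community members,

$$\mathbf{Q}(t) = (q_1(t), \dots, q_n(t)),$$

where $q_i(t)$ is the information amount vertex $i$ carries at time $t$.
Recorded contact and message datasets carry participation but not content, so
the default is the binary convention $q_i(t) \in \{0, 1\}$ (did $i$
communicate at time $t$); a weighted mode summing event weights is available
for data that do record amounts (e.g. durations).

## Transition series and measures

Four series summarise consecutive steps $\mathbf{Q}(t) \to \mathbf{Q}(t+1)$:

* **information change** $I = (\sum_i q_i(t+1) - \sum_i q_i(t)) / (n u)$,
  normalised by the state in which all $n$ vertices hold one reference unit
  $u$;
* **Euclidean distance** $L = \lVert \mathbf{Q}(t+1) - \mathbf{Q}(t)
  \rVert_2 / (u \sqrt n)$, the absolute amount of pattern change;
* **relative distance change** $L_R = \lVert \mathbf{Q}(t+1) - \mathbf{Q}(t)
  \rVert_2 / \lVert \mathbf{Q}(t+1) \rVert_2$, change relative to the
  current activity level;
* **cosine similarity** $S = \mathbf{Q}(t+1) \cdot \mathbf{Q}(t) /
  (\lVert \mathbf{Q}(t+1) \rVert \lVert \mathbf{Q}(t) \rVert)$, which lies
  in $[0, 1]$ because activations are nonnegative.

Each series is summarised by its arithmetic mean and unbiased
($N-1$ divisor) variance, and three phase measures are read off:

| Phase | Measure | Signature |
|---|---|---|
| mobism (fragmentation) | $M_{mob} = \mu_L$ | biased and crowded: large ordered swings |
| atomism (isolation) | $M_{atom} = \mu_{LR}$ | separate and sporadic: large relative change |
| mixism (well-going) | $M_{mix} = \mu_S \cdot \sigma_S^2$ | balanced and cyclic: similarity that also varies |
| nihilism | all three $\approx 0$ | static and silent |

$M_{mix}$ is the interesting composite: it is zero both for perfectly
repetitive communication ($\sigma_S^2 = 0$) and for perfectly uncorrelated
communication ($\mu_S = 0$), and peaks when runs of similar patterns
alternate with turnover — the "edge of chaos" analogy. The desk-scale
demonstration (also a test) is three toy patterns on $n = 4$: a constant
pattern ($M_{mix} = 0$), a strict alternation of disjoint half-supports
($\mu_S = 0$ so $M_{mix} = 0$), and a 3+3 block rotation whose similarity
series $(1, 1, 0, 1, 1)$ gives $\mu_S = 0.8$, $\sigma_S^2 = 0.2$,
$M_{mix} = 0.16$, strictly above both extremes.

```{r toys}
block <- rbind(matrix(rep(c(1, 1, 0, 0), each = 3), nrow = 3),
               matrix(rep(c(0, 0, 1, 1), each = 3), nrow = 3))
ev <- tidyr::crossing(t = 1:6, v = 1:4) |>
  dplyr::filter(block[cbind(t, v)] == 1) |>
  dplyr::transmute(time = t, i = paste0("v", v), j = NA_character_)
m <- mixbiotic_measures(build_pattern_sequence(event_stream(ev)))
m[, c("mu_S", "var_S", "M_mix")]
```

## Conventions that matter

**Timeline.** The default timeline is the *event timeline*: the distinct
recorded timestamps, in order, with no wall-clock re-binning. `t_max` (the
number of distinct times) is then the number of pattern rows, and every row
has at least one active vertex, so all four series are defined everywhere.
A fixed-width `grid` timeline is available for data where silence itself is
informative; silent rows make $L_R$ and $S$ undefined (0/0), and the
affected transitions are dropped from *all four* series jointly so they stay
aligned (a `strict` flag errors instead). Timestamps are treated as opaque
ordinals — the package never re-bins 20-second windows or similar; whatever
resolution the instrument recorded defines the timeline.

**Transition count.** $T$ distinct times give $T - 1$ transitions, and the
means divide by the number of transitions actually used (reported as
`n_transitions`). Summing the series without dividing at all would push
$\mu_S$ above 1 on any long recording, which is inconsistent with the
measure's meaning, so a divisor is required. An alternative convention
divides means by $T$ (treating the unobserved transition into the first
recorded step as part of the record); it is available as
`mean_divisor = "t_max"` and differs by a factor $(T-1)/T$ — negligible at
the $10^3$–$10^4$ steps of real recordings but reported explicitly so the
bookkeeping is auditable.

**Reference unit.** `u` defaults to 1, the natural reference for binary
activations; with weighted data it sets the "one unit per vertex" state that
normalises $I$ and $L$. $S$ and $L_R$ are scale invariant, so `u` does not
touch them (a property-based test asserts this).

**Phase classification.** The measure table above only hypothesises which
measure dominates each phase; it does not give a decision rule. The rule
implemented in `classify_phase()` is a deliberate, documented convention:
a community with all three measures below `epsilon` (default $10^{-3}$) is
nihilistic; otherwise the three measures are min-max rescaled across a
caller-supplied comparison set (they live on different scales — $\mu_{LR}$
is an order of magnitude larger than $\mu_S \sigma_S^2$ even in balanced
communities) and the largest rescaled measure names the phase, with exact
ties broken in the fixed order mixism > mobism > atomism. Without a
comparison set the raw values are compared, which is only meaningful for
clear-cut cases.

**Radar normalisation.** For radar charts every item is divided by its
maximum across the communities being compared, so each axis spans $[0, 1]$
and at least one community reaches 1 per axis. Items that are identically
zero stay zero, with a warning.

## The polar trajectory

Each row also maps to a polar point: radius
$r(t) = \lVert \mathbf{Q}(t) \rVert_2$ and declination
$\theta(t) = \arccos\!\big(\sum_i q_i(t) / (\lVert \mathbf{Q}(t) \rVert
\sqrt n)\big)$, the angle between the pattern and the all-ones direction.
Nonnegative activations confine $\theta$ to the first quadrant
$[0, \pi/2]$: $\theta = 0$ means everyone participates equally, large
$\theta$ means activity concentrated in few vertices. For a binary row with
$k$ of $n$ vertices active, $r = \sqrt k$ and
$\theta = \arccos\sqrt{k/n}$ in closed form — the property the tests verify
for all $k \le n \le 12$. Connecting consecutive points draws the
community's communication trajectory: mob-like communities sweep along the
diagonal, atom-like ones jitter near the origin at wide angles. Silent rows
(grid timelines) have $r = 0$ and an undefined angle, recorded as missing
rather than as an arbitrary 0, since the $\arccos$ argument is 0/0 there;
segments bridging across them are flagged.

## The static baseline

`graph_features()` computes the conventional social-network-analysis
features on the time-aggregated simple graph: vertex/edge counts, density,
diameter and mean distance (infinite when the graph is disconnected), and
the mean local clustering coefficient, with the common convention that
vertices of degree < 2 contribute 0. Two edge notions are reported
side by side — distinct contacted pairs (`edge_count`, the notion entering
the density) and raw event records (`event_edge_count`) — because published
feature tables for some message datasets are only consistent under one or
the other, and exposing both lets users reconcile rather than guess.
igraph does the graph work; an independent brute-force BFS and triangle
counter verifies it in the test suite on random graphs of up to 30 vertices.

## The synthetic regime generator

To make every measure and the classifier testable without downloading any
dataset, `generate_regime()` draws seeded event streams whose dynamics
realise each phase's defining signature:

* **mobism** (default $n = 40$, clique size 20, $T = 400$): one clique is
  active at every step and its membership drifts by swapping exactly one
  member for an outsider per step. Consecutive patterns then have cosine
  similarity $(g-1)/g = 0.95$ — high and nearly constant, so
  $M_{mix} \approx 0$ — while every step moves the fixed Euclidean stride
  $\sqrt 2 / \sqrt n \approx 0.224$, the largest $\mu_L$ of the four
  regimes. The swap-per-step drift was chosen over a rare-jitter variant
  because a clique that barely changes produces almost no Euclidean
  movement at all and would make the "crowded" regime look static.
* **atomism** (default $n = 200$, one fresh uniformly random pair per step):
  no temporal carry-over, so consecutive patterns are almost always
  disjoint and $\mu_{LR} \approx \sqrt 2$, the per-regime maximum, while
  the large sparse roster keeps $\mu_L = 2/\sqrt n$ small — mirroring the
  large, sparsely active online communities the phase describes.
* **mixism** (default 4 groups of 10 on $n = 40$, rotating every 10 steps):
  long runs of identical patterns punctuated by complete turnover, giving
  $\mu_S \approx 0.9$ *and* $\sigma_S^2 \approx 0.09$, hence the largest
  $M_{mix}$.
* **nihilism** (default $n = 50$, per-step event probability 0.02): one
  static pair exchanges rare contacts; on the event timeline every pattern
  row is identical, so all three measures are exactly 0. The generator
  floors the number of recorded events at 3 so the variances are always
  defined; this floor cannot change any measure's value for this regime.

The generators are stylised on purpose. They reproduce the qualitative
dynamics signatures of the four phases, not the heavy-tailed contact
statistics, circadian rhythms, or community-size distributions of real
recordings — so passing the regime-separation tests shows the measures
*rank the intended dynamics correctly*, not that they are calibrated to any
real community. Real-data values should be computed with
`read_contact_list()` on the original releases. Each generation uses its
own RNG stream seeded from the spec and restores the global seed, so
identical specs are bit-for-bit reproducible and generation never perturbs
a surrounding analysis.

## Numerical choices

* All accumulation is in double precision on dense matrices; the datasets
  this targets ($n \lesssim 2000$, $T \lesssim 10^5$) fit comfortably.
* Cosine similarities are clamped to $[0, 1]$ after the fact: binary dot
  products are exact, but the product of norms can round a hair past the
  true value and spill $S$ outside the interval by $\sim 10^{-16}$.
* $\theta$ near 0 is intrinsically ill-conditioned ($\arccos$ amplifies a
  $10^{-16}$ argument error to $\sim 10^{-8}$); tests compare on the cosine
  scale where exactness matters.
* Ties in phase classification are broken mixism > mobism > atomism, so a
  community that maxes two rescaled measures at once is attributed to the
  phase closer to the well-going middle.
* Test problem sizes: property suites use 100 random patterns with
  $n \le 10$, $T \le 20$ and 50 random graphs with $V \le 30$; the regime
  suite runs the four default regimes over ten seeds. These sizes make the
  brute-force oracles exact and the whole suite fast while still exercising
  every code path.

## Limitations

* The measures see participation, not content; two communities exchanging
  pleasantries and arguments look identical.
* Directed messages are collapsed to undirected co-activation (sender and
  receiver both active at the send time); reply chains and threads are not
  modelled.
* The event timeline treats a message burst and a steady conversation with
  the same set of distinct timestamps identically; use the grid timeline
  when absolute pacing matters, and note the silent-row drop convention
  then applies.
* The phase *measures* come from the underlying model; the phase *decision
  rule* is this package's convention and should be read as a labelled
  heuristic, not part of the model.
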