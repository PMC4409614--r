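---
title: "Methods: directed weighted fight networks and their centrality measures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: directed weighted fight networks and their centrality measures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agonet)
```

## The analysis model

After unacquainted pigs are mixed into a pen they fight to establish a rank
order. `agonet` represents the first two days after mixing as one aggregated
directed weighted graph per pen:

* **nodes** — the full pen roster, so animals that never fought appear as
  isolated nodes with all centralities 0 rather than silently vanishing;
* **links** — each fight with a clear initiator adds weight 1 to the edge
  initiator → receiver; a *stand-off* (unclear initiator/receiver) adds two
  opposite edges of weight ½. Total edge weight therefore equals the number
  of fights, a conservation law the tests check exactly. Weights are
  multiples of ½ and thus exact in double precision — the checks use
  identity, not tolerances.

Events are filtered to the observation protocol first: start time inside an
observation window and duration ≥ 1 s. Windows are half-open
(`[start, end)`, start-inclusive) so adjacent windows never double-count;
the default protocol observes day 1 12:00–18:00 and day 2 07:00–18:00, 17 h
in total, with mixing anchored at the start of the first window. The
duration rule is "longer than one second"; with second-resolution logging
the implementable reading is `duration ≥ 1 s`, and the threshold is a
parameter (`min_duration`) for data logged at finer resolution.

Stand-off events carry no participant order; the readers keep `(a, b)` as
recorded, the network builder splits the weight symmetrically, and the
timeline export emits the pair in a canonical (sorted) order so downstream
consumers cannot mistake an arbitrary order for an initiator.

## Centrality measures and conventions

Seven measures, each binary and weighted: degree, in-degree, out-degree,
betweenness, and undirected/ingoing/outgoing closeness.

**Degree.** Binary degree counts distinct opponents (a reciprocal dyad is
one opponent); in/out variants count distinct attackers/victims. Weighted
degree sums fight weights (in = received, out = initiated, total = both).
Degree is reported unstandardized by default — pens within a level are
similar in size and the raw count is the interpretable quantity — with
`standardized = TRUE` dividing by `n − 1` for cross-size comparisons.

**Weighted distance.** The shortest-path length of an edge is `1/weight`:
animals that fight each other often are behaviorally "close". This is the
convention under which weighted closeness can exceed 1 (a dyad fighting
twice sits at distance ½) while normalized weighted betweenness remains in
[0, 1]. It is an assumption of this package, chosen because it is the only
standard convention consistent with both bounds at once; the alternative
(length = weight) would invert the meaning of frequent fighting.

**Betweenness.** For node `v`,
`C_B(v) = Σ_{s≠t≠v} σ_st(v)/σ_st / [(n−1)(n−2)]`, with `σ_st` the number of
shortest s→t paths (0 contribution when `t` is unreachable from `s`). All
tied shortest paths are counted via Brandes' dependency accumulation; there
is no tie-breaking. With `n < 3` there are no transit pairs and the measure
is defined as 0. Because weighted path lengths are sums of reciprocals,
equal-length paths are detected with an absolute tolerance of 1e-10 (for
example `1/3 + 1/3 + 1/3` vs `1/1` differ in the last bit); the brute-force
test oracle uses the same tolerance.

**Closeness.** Fight networks are routinely disconnected — a pen can contain
isolated animals, pure aggressors (unreachable by incoming paths), and
separate components — so plain closeness `(n−1)/Σd` is undefined. The
package uses component-scaled closeness: with `r` of the `n − 1` pen mates
reachable at total distance `d`,

C(u) = (r / (n−1)) · (r / d).

This yields 0 for isolates, keeps binary values in [0, 1], and penalizes
nodes that reach only a small component. The directed variants use forward
paths (outgoing: how fast an animal's aggression cascades through the pen)
and reversed paths (ingoing: how fast others' aggression reaches it). The
undirected variant runs on the undirected projection, where a dyad's weight
is the **sum** of its two directional weights — this preserves total contact
frequency (and the conservation law); `projection = "binary"` is available
for the union-of-links reading, since published range tables do not pin down
which collapse was used. `scaling = "off"` reports the unscaled inverse mean
distance to reachable animals for comparison with other software.

All shortest-path kernels (O(n²) Dijkstra per source, Brandes accumulation)
are compiled code; pens have at most a few dozen animals, so a priority
queue would be overhead. Correctness is established against an independent
brute-force oracle that enumerates every simple path on random graphs with
n ≤ 7 and agrees to 1e-9.

## Rank statistics

Centrality values in a pen are small-sample, skewed, and bounded, so all
comparisons are rank-based.

* **Kruskal-Wallis** (tie-corrected, χ² approximation with `k − 1` df)
  compares each measure across age levels. If all values are identical the
  statistic is defined as 0 with p = 1 (the tie-correction denominator
  vanishes there). The implementation wraps the standard `kruskal.test`;
  its statistic is verified against a from-first-principles tie-corrected H
  and against full enumeration of group assignments for N ≤ 8.
* **Significance letters.** The published convention "values with different
  letters differ (p < 0.05)" leaves the post-hoc procedure open. The package
  uses pairwise two-group Kruskal-Wallis tests (equivalent to rank-sum
  tests) at α = 0.05 without multiplicity correction — matching the
  footnote's stated test — with Bonferroni available behind `adjust`.
  Letters come from insert-and-absorb, so two levels share a letter exactly
  when their pairwise test is non-significant; intransitive patterns yield
  multi-letter labels such as `ab`. A non-significant global test short-
  circuits to all-`a`.
* **Spearman** is the Pearson correlation of mid-ranks with the t
  approximation on `n − 2` df. Fewer than 3 complete pairs or a zero-variance
  rank vector give an `NA` coefficient with a machine-readable note rather
  than an error, because pen-level inputs legitimately hit both cases.
* **Pooling.** Animals from all pens of a level are pooled as observations,
  matching how such tables are reported; this pseudo-replicates pens, so
  `pen_median = TRUE` offers a conservative pen-level alternative. With
  ~500 animals per level the pooled test is extremely powerful and flags
  distributional differences far below practical relevance — see
  "Limitations".

Cross-level correlations pair animals by identity through the trajectory
table and are emitted only for consecutive level pairs (weaned→growing,
growing→gilts), the comparisons that are interpretable as carry-over of
individual behavior.

## The synthetic study generator

No fight logs of this kind are publicly deposited, so the package ships a
generator that emulates the *structure* of a three-level study rather than
any particular data set:

| parameter | default | rationale |
|---|---|---|
| groups per level | 65 / 24 / 12 | standard design: many small weaned pens, fewer larger pens later |
| group sizes | 6–11 / 20–25 / 18–29 animals | housing dimensions per level |
| observation windows | day 1 12:00–18:00, day 2 07:00–18:00 | 17 h, night excluded |
| mean initiated fights per animal | 7 / 2.9 / 2.9 | anchors median total involvement at ≈ 12 / 5 / 5 fights (typical for this design) via `m(1 + e^{−σ²/2})`, giving the ~2.4× weaned intensity |
| trait SD σ (log scale) | 0.8 | reproduces the wide right tails (involvement ranges up to ~100 in small pens) |
| cross-level trait correlation | 0.3 | modest carry-over of individual aggressiveness, the order of published consecutive-level rank correlations |
| temporal decay (per h since mixing) | 0 / 0.15 / 0.15 | older levels concentrate fighting in the first ~6 h; weaned pens fight evenly |
| stand-off probability | 0.1 | a minority of fights lack a clear initiator |
| fight duration | log-normal(log 15, 0.9) s, ≥ 1 s | seconds-to-minutes fights, right-skewed |
| victim bias | 0 (uniform victims) | targeted-opponent choice available (`victim_bias > 0`) but off by default |

Each animal carries a latent log-aggressiveness trait `z ~ N(0, 1)`; its
fight-rate multiplier is `exp(σz − σ²/2)` (unit mean, so the level mean is
preserved). Initiated fight counts are Poisson; victims are uniform among
pen mates; fight times are drawn by inverse-CDF from an exponentially
thinned density over the observation windows; traits evolve between
consecutive levels as a stationary AR(1) with the configured correlation.
Animals not advancing to the next level are dropped uniformly at random
("resold"), and the survivors are re-partitioned into new pens. One random
stream is consumed in deterministic pen order, so a study is byte-identical
for a given seed.

What the generator does **not** emulate: winner–loser dynamics and rank-
order formation, non-stationary aggressiveness within a level, assortative
pen composition (real pens were sorted by weight and familiarity), observer
error, and any calibration to reproduce particular published medians or test
statistics beyond the intensity anchoring above. Tests passing on synthetic
studies therefore demonstrate that the *pipeline* is correct and that
configured structure is recovered — not that real pig data would show the
same effect sizes.

## Problem sizes used by the test suite

The acceptance-style tests use 200 random graphs (n ≤ 7) for the oracle
comparison, 100 replicate default studies for the cross-level ordering
pattern, 200 replicates per trait-correlation setting (at 20/6/3 groups, a
size chosen so the Monte-Carlo standard error of the mean estimate is well
below the ±0.05 acceptance band) for carry-over recovery, and 100 replicate
older-level pens for the temporal-decline property.

## Limitations

* The pooled Kruskal-Wallis over ~1350 animals detects even the structural
  differences between growing and gilt pens that follow from their different
  group-size ranges (20–25 vs 18–29 animals change normalized closeness and
  opponent-collision rates). On synthetic studies the growing and gilt
  levels therefore often earn *different* letters on degree/closeness, and
  the betweenness comparison is usually significant — whereas a boundary
  case (p ≈ 0.05) in real data can go either way. Qualitative letter
  patterns at this power are not a robust target for structural emulation;
  the weaned level separating from both older levels is.
* Closeness and weighted-distance conventions (component scaling, 1/weight)
  are assumptions reconstructed from the printed value ranges of this
  literature, not documented algorithms; both are options so other
  conventions can be compared.
* Temporal information inside the two-day window is only used for filtering
  and timelines; the networks are aggregates, so burst structure is
  deliberately lost.
* The letters procedure (unadjusted pairwise rank tests) inflates pairwise
  type-I error across 14 measures; it mirrors the reporting convention, not
  a recommendation.
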