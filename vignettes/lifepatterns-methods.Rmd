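---
title: "Methods: day patterns, life entropy and predictability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: day patterns, life entropy and predictability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The analysis in one paragraph

`lifepatterns` treats a person's day as a vector of time-slot locations: the
raw stream of timestamped location events is discretised so that each fixed
slot (default 1 h, so 24 slots per day) carries the location that dominated
it by dwell time. Days of one user are then grouped into recurring *day
patterns* (working day, home day, ...) by two independent clustering methods.
Regularity is quantified by the *life entropy* — the per-slot Shannon entropy
of the slot-location distribution, averaged over slots — computed before and
after conditioning on the patterns, and by a maximum-entropy null model.
Predictability is quantified by four estimators: guessing from the occupancy
distribution of the slot (with or without pattern conditioning), and guessing
from empirical transition matrices between slots (again with or without
patterns), including lags up to 12 h. Finally, working days are detected, and
the distribution of working-day lengths is fitted with a discrete-time
survival model whose leave-early and leave-late hazards both grow
exponentially towards/away from the typical length.

## Ingestion model

**Slotting.** Slots are half-open intervals `[t, t + slot)`. An event's dwell
runs from its timestamp to the next event of the same user or the end of its
own slot, whichever comes first; dwell never leaks into the next slot, so a
slot with no events is `MISSING`. The slot label is the location with maximal
total dwell; ties go to the location occupied earliest in the slot
(deterministic and data-independent). Slot lengths of 30, 60 and 120 minutes
are supported; all results default to 60 minutes.

**Padding.** Phones are often switched off overnight. A maximal run of at
most `max_gap_slots` (default 6) MISSING slots whose flanking observed slots
carry the *same* location is filled with that location; runs at the edges of
a user's record, longer runs, and runs with disagreeing flanks are left
untouched. Padding operates on the concatenated calendar sequence, so it
crosses midnight (the canonical case is a 01:00–05:00 phone-off gap flanked
by home).

**Filtering.** After padding, days with more than 30% MISSING slots are
excluded, and users with fewer than 30 accepted days are dropped. Both
thresholds are configuration fields.

**Timezone.** All timestamps are interpreted in a single configured timezone
(default UTC). DST transitions are resolved by local wall clock; the
generator emits UTC, so DST handling is untested beyond the parameter
pass-through.

## Location statistics

Location counts are *slot-dominance* counts (how many slots a location
dominates), not raw event counts — every downstream quantity lives on slot
data. A location is *significant* if its count is at least 1% of the user's
most common location; rarer locations are lumped into the ordinary symbol
`OTHER`. The pooled rank-frequency curve is the equal-weight average of
per-user normalised curves.

The power-law exponent of a rank-frequency sample is fitted by discrete
maximum likelihood on the truncated support `{xmin..rmax}` (the finite
normalising sum replaces zeta functions), with `xmin` chosen by minimising
the Kolmogorov–Smirnov distance of the fitted tail. Least-squares on log-log
axes is deliberately not offered; it is biased for heavy tails. Wald
confidence intervals come from the analytic Fisher information
(`Var[log r]` under the fitted law). Note that the *generator's* planted
visit-frequency law is a clean power law, but the realised slot-dominance
frequencies of a template-driven panel are not: templates concentrate mass on
a few locations and the noise law spreads the rest, so a KS-chosen cutoff fit
on a synthetic panel will legitimately report an exponent away from the
planted 1.7. The fitter-recovery tests therefore draw directly from the
planted law.

## Day patterns

**Distance and graph.** Two days are compared by the weighted Hamming
distance `D = sum_j u_j [d1_j != d2_j]` (unit weights by default; an optional
rarity weighting `u_j = 1/f(label)` is available since the source analysis's
exact weighting is not recoverable). MISSING slots are excluded and the sum
is renormalised to the full-day scale. Days become vertices of a complete
graph with weights `w = exp(-D / delta)`.

**The scale `delta`.** `delta` decides when two days still count as the same
routine. Days sharing a pattern with slot-noise rate `eps` differ in about
`2 eps n_slots` slots (2–3 at `eps = 0.05`, 24 slots), while distinct day
types differ by multi-hour blocks (6–12 slots). The default
`delta = n_slots / 12` (2 slots at 1-h resolution) sits between these scales.
A larger scale (e.g. `n_slots / 4`) makes the graph near-uniformly dense and
the *modularity resolution limit* then provably merges small minority
patterns: on a planted 3-pattern panel the true partition can have lower
modularity than a merged one, so no optimiser could recover it. This was
measured, not assumed — see the package tests.

**Extremal optimization (EO).** Communities are found by Duch–Arenas tau-EO:
recursive bisection in which vertices are ranked by fitness (within-community
strength fraction minus its expectation) and the vertex to move is drawn with
probability proportional to `rank^-tau` (`tau = 1.4`). A split is accepted
only if global weighted Newman–Girvan modularity increases, so the number of
clusters is emergent. A single-vertex-move polish pass follows; on all graphs
of up to 10 vertices that we can enumerate exhaustively, the result equals
the global modularity optimum. Known limitation: a pattern observed on only
1–2 days is mathematically unresolvable — for a singleton vertex the
modularity gain of merging it into any positively-weighted neighbour
community always wins. This is a property of modularity, not of EO.

**k-means.** Days are one-hot encoded (each slot expands to |alphabet| binary
columns; MISSING encodes as a zero block) and clustered by Euclidean k-means;
200 random initialisations are run and the lowest within-cluster
sum-of-squares solution kept. `k` defaults to the EO-emergent cluster count
so the two methods are compared on equal footing. When the number of distinct
day vectors is at most `k`, the exact zero-loss partition is returned
directly.

**Profiles.** A cluster's average day is the per-slot modal location;
deviation masks flag slots differing from the average day; rank enrichment
(mean location rank in deviating slots minus agreeing slots) verifies that
noise is made of rarer locations.

## Life entropy

All entropies are in bits (base 2); the worked values in the literature for
users with 7–22 significant locations (e.g. 2.70 bare) are only consistent
with bits. The bare entropy is
`S = (1/n_slots) sum_j H_j`, `H_j = -sum_i (n_ij/N_j) log2 (n_ij/N_j)` with
`n_ij` the number of days location `i` dominates slot `j` and `N_j` the
number of days with slot `j` observed (missing slots are excluded and the
slot renormalised rather than treated as a pseudo-location). The clustered
entropy is the size-weighted average `sum_c (n_c/N) S_c` of within-cluster
bare entropies, and the drop `dS = S - S_clustered` (relative drop
`100 dS / S`, defined as 0 when `S = 0`) measures how much apparent
randomness is really pattern multiplicity. On complete data `dS >= 0` for
*any* partition (conditioning cannot increase entropy); with missing data the
per-slot renormalisation can in principle break this, which the code flags
with a warning.

The null model is the maximum-entropy distribution with modal mass `p0` and
the residual spread uniformly over the remaining `n - 1` significant
locations: `S_null = -p0 log2 p0 - (1 - p0) log2((1 - p0)/(n - 1))`. Per
user, `p0` is the mean per-slot modal probability and `n` the
significant-location count.

**Plug-in bias.** The empirical (plug-in) entropy of a finitely sampled
distribution is biased downwards, most strongly where the distribution has a
wide thin tail and few observations — exactly the within-cluster case (tens
of days against a 50-location noise tail). The generator therefore reports,
next to the population entropies, the *exact finite-sample expectation* of
the plug-in estimator (a closed-form binomial sum, since the plug-in entropy
decomposes over per-location marginal counts). Recovery tests compare
like-with-like: measured plug-in values against expected plug-in values.
Comparing measured plug-in values against population entropies would show a
~15-point gap in the relative drop for *any* correct implementation at the
planted test's scale.

## Predictability

Per slot `j`, the occupancy model estimates `p_ij` (and `p_icj` within
cluster `c`). Two guess rules are reported because the printed rule of the
source analysis is not legible:

* **probability matching** (default): guess by sampling the estimated
  distribution; success probability `Q_j = sum_i p_ij^2` (the two-state
  special case `p^2 + (1-p)^2` is the tell-tale of this rule);
* **mode**: always guess the most probable location; `Q_j = max_i p_ij`.

With patterns, per-cluster qualities are averaged with weights `n_c/N`. Under
the matching rule the pattern-conditioned quality can never be smaller than
the unconditioned one (Jensen: `sum_c w_c sum_i p_icj^2 >=
sum_i (sum_c w_c p_icj)^2`), and the mode rule dominates the matching rule
per slot (`max p >= sum p^2`); both inequalities are asserted exactly in the
tests.

Transition (transfer) matrices count pairs `(location at slot j, location at
slot j + dt)` over the concatenated calendar sequence — pairs cross midnight,
MISSING members break pairs, and with patterns the counts split by the origin
day's cluster. Matrices are slot-dependent by default (`pooled = TRUE` pools
origins). Quality is evaluated in-sample on the observed pairs (the source
analysis gives no train/test split; a leave-one-day-out flag would be the
honest generalisation estimate and is noted as future work); under matching
the in-sample value equals `sum_a p_a sum_b T(a,b)^2`. The long-range curve
evaluates lags 1..12 h and fits `Q = a - b log(dt)`; on i.i.d. data both
methods collapse to `sum p^2` (flat curve), which the tests verify against
Monte-Carlo error.

## Working-day departure model

Home is the modal night-time (00–06) location; the work candidate is the
non-home location with maximal daytime (09–17) occupancy, and a user
qualifies as a regular worker with at least 20 days on which work occupies a
run of 4+ consecutive slots. A working day's length is last-to-first work
slot inclusive (a lunch break does not shorten it). Lengths are z-scored per
user and pooled.

The departure model is a discrete-time survival construction: the per-slot
hazard of leaving is `h(t) = min(1, h0 exp(a_early (t - T0)))` up to the
typical length `T0` and `h(t) = min(1, h0 exp(a_late (t - T0)))` beyond it —
"leaving gets easier by a constant factor per step" on both sides, with a
shared baseline `h0` so the hazard is continuous at `T0`. The pdf is
`h(t) prod_{s<t} (1 - h(s))`, normalised over the grid. `T0` is a *fitted*
parameter (near 0 in pooled z units) rather than fixed. The MLE runs on the
dimensionless grid-index scale (Nelder–Mead on `(logit h0, T0, log a_early,
log a_late)`, with a restart before the Hessian), which makes the fit exactly
invariant under affine rescaling of the lengths; standard errors come from
the observed information and goodness of fit from the KS distance. Because
the rate units of the published 0.045/0.046 values are ambiguous ("inverse
sigma-slot lengths"), the fitter reports rates both per caller unit and per
grid step.

The generator's `sample_departure_time` draws sequentially from the same
hazard (not from the normalised pdf), so the sampler/pdf KS consistency check
is a real test, not a tautology.

## The synthetic panel: what it emulates, and what a green test shows

Per user the generator plants: a power-law location alphabet
(`freq ~ rank^-1.7`); `K = 3` day templates — a working day (home nights,
contiguous work block from 08:00), a home day with a short errand, a leisure
day — assigned per day with working-day probability 5/7 (a five-day week);
per-slot noise at rate `eps = 0.05` drawn from the alphabet with weight
proportional to rank (rarer locations over-represented; uniform available) —
the rarity *direction* is stated by the source analysis, the linear law is a
package choice; working-day departure jitter from the hazard model
(defaults T0 = 9 slots, a_early = 0.7, a_late = 0.5, h0 = 0.15 per raw slot,
i.e. 9 ± 1.5-slot days); night phone-off gaps (01–05 removed with probability
0.5, home-flanked by construction) and 2% random slot gaps; events emitted at
5-minute resolution with small label carry-over at slot boundaries so
majority-rule ingestion is non-trivial. One master seed; user `u` gets stream
`seed + u`.

What the generator does **not** emulate: geographic structure (the analysis
is purely symbolic over location ids), weekly periodicity (template draws are
i.i.d. across days), long-range temporal correlation beyond the departure
model, device-specific missingness, and any heterogeneity of `eps` across
users. A green recovery test therefore establishes that the estimators invert
the generator's stated world — not that real panels satisfy that world.

## Numerical choices and degenerate inputs

* Ties in majority rule, modal labels and mode guesses are broken
  deterministically (earliest occupied / first occurrence / first index).
* Entropy of an empty support is 0; slots with no observations are skipped
  with a warning and the per-slot average renormalised.
* `entropy_drop` warns below `-1e-9` (possible only under missing-data
  renormalisation).
* EO uses modularity improvement threshold `1e-12`; fixed seeds give
  reproducible partitions.
* k-means retries are bounded by `n_runs`; duplicate-dominated inputs short-
  circuit to the exact partition.
* The departure likelihood floors the pdf at `1e-12` so the optimiser can
  escape regions whose fitted support misses observations; degenerate
  (constant) samples and samples below `min_n = 100` are rejected.
* All serialisations are plain text (CSV/JSON; YAML configs).

## Known limitations

* Modularity clustering cannot isolate patterns supported by 1–2 days
  (resolution limit); such days are absorbed by the nearest large pattern.
* Plug-in entropies are biased downwards at panel scale; compare against
  plug-in expectations, not population values.
* Prediction quality is evaluated in-sample by design parity with the source
  analysis.
* The pooled z-score departure fit mixes users with different length
  variances; `step` is set from the mean within-user standard deviation,
  which is a pragmatic, not principled, choice.
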