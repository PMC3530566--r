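# lifepatterns

Daily routines from location traces: pattern discovery, life entropy, and
next-location predictability.

## The problem

Smartphone-style location traces record, per user, a stream of
`(user, timestamp, location)` events. For anyone studying routine behaviour —
quantitative social science, movement ecology, epidemiological mobility
modelling — the interesting questions are: how regular is an individual's
day-to-day life, how much of the apparent randomness is really a *repertoire
of distinct routines*, and how predictable is the next location? This package
implements that analysis as a tested pipeline over symbolic day vectors:

1. **Ingest** — events are discretised into day vectors: each fixed time slot
   (default 1 h) gets the location with the largest dwell time (majority
   rule); short phone-off gaps flanked by the same location are padded; days
   with > 30% missing slots and users with < 30 accepted days are dropped.
2. **Location statistics** — slot-dominance counts per location, lumping of
   locations rarer than 1% of the top one into `OTHER`, and a discrete
   maximum-likelihood power-law fit (with KS-chosen cutoff) to rank-frequency
   samples.
3. **Day patterns** — per-user clustering of days, twice: extremal
   optimization (τ-EO) of weighted Newman–Girvan modularity on a day graph
   with weights `w = exp(-D/δ)` (`D` = weighted Hamming distance between day
   vectors), where the number of patterns is emergent; and best-of-200
   Euclidean k-means on one-hot day encodings.
4. **Life entropy** — per-slot Shannon entropy averaged over slots,

   `S = (1/n_slots) Σ_j H_j`, `H_j = −Σ_i (n_ij/N_j) log₂(n_ij/N_j)`,

   before clustering (bare), within clusters weighted by cluster size
   (`S_clust = Σ_c (n_c/N) S_c`), and for a max-entropy null model with
   concentrated modal mass `p₀`. The drop `ΔS = S − S_clust` measures how
   much "randomness" was really pattern multiplicity.
5. **Predictability** — success probability of guessing the slot's location
   from occupancy probabilities (`Q_j = Σ_i p_ij²` under probability
   matching, `max_i p_ij` under the mode rule) and from empirical transition
   matrices `P(location at j+Δt | location at j)`, each with and without
   pattern conditioning, plus lag curves to 12 h with a logarithmic fit.
6. **Working days** — detection of work location and regular workers,
   first-to-last day lengths, z-scored pooling, and an MLE fit of a
   two-sided exponential-hazard departure model
   (`h(t) = h₀ e^{a·(t−T0)}`, separate early/late rates `a`).

A synthetic-trace generator plants all of this structure (power-law location
alphabet, day templates, rank-biased slot noise, night phone-off gaps,
hazard-drawn work departures) and keeps the ground truth, so every estimator
is exercised by recovery tests.

## Worked example

```r
library(lifepatterns)

cfg <- run_config(generator = list(n_users = 4, n_days = 40),
                  n_runs = 20, min_workdays = 15, min_pooled_lengths = 50,
                  seed = 7)
report <- run_pipeline(cfg, quiet = TRUE)
print(report)
#> <pipeline_report> 4 users
#>   u001: 40 days, 4 locations, 4 patterns, S=0.85->0.28
#>   u002: 40 days, 4 locations, 4 patterns, S=0.81->0.24
#>   u003: 40 days, 4 locations, 4 patterns, S=0.79->0.28
#>   u004: 40 days, 4 locations, 4 patterns, S=0.67->0.26
```

Each line is one accepted user: accepted days, significant locations (after
the 1% rule), emergent pattern count, and bare → clustered entropy in bits.
Per-user detail:

```r
report$users$u001$entropy[, c("method", "S_bare", "S_clustered",
                              "relative_pct", "S_null", "n_patterns")]
#>   method S_bare S_clustered relative_pct S_null n_patterns
#> 1     eo  0.852       0.278         67.3   1.09          4
#> 2 kmeans  0.852       0.278         67.3   1.09          4
```

So for this user both clustering methods agree: conditioning on the four
discovered routines removes 67% of the apparent entropy, and the bare entropy
sits below the null-model bound (1.09 bits), as it must.

```r
str(report$users$u001$quality)
#> List of 4
#>  $ static_plain       : num 0.681
#>  $ static_patterns    : num 0.886
#>  $ transition_plain   : num 0.855
#>  $ transition_patterns: num 0.898
```

The four prediction qualities reproduce the expected ordering: knowing the
time of day alone gives 0.68; knowing the day's pattern lifts it to 0.89;
transition matrices reach 0.86 without patterns — most of the pattern
information is already encoded in the transitions — and 0.90 with them.
Quality decays only slowly with the prediction horizon
(`report$users$u001$q_dt$curve`: 0.898 at Δt = 1 h, 0.893 at 6 h).

Departure-model round trip at the published rate scale:

```r
set.seed(1)
x <- sample_departure_time(2e4, T0 = 9, a_early = 0.045, a_late = 0.046,
                           h0 = 0.05)
fit <- fit_departure_model(x)
#> a_early = 0.0468, a_late = 0.0454  (truth: 0.045 / 0.046)
```

## Command line

```sh
Rscript inst/cli/lifepatterns.R simulate --seed 1 --out traces_out
Rscript inst/cli/lifepatterns.R run-all --config config.yaml --out results
```

Configs are YAML or JSON with the fields of `run_config()`.

## Notes

See `vignettes/lifepatterns-methods.Rmd` for the model assumptions, parameter
defaults and their rationale, what the synthetic generator does and does not
emulate, numerical choices, and known limitations.
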