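---
title: "Knockout extinction models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knockout extinction models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(knockoutr)
```

## The model family

A plant–pollinator community is encoded as an `A × P` incidence matrix
`M`: `A` pollinator (animal) species in rows, `P` plant species in
columns, entries the observed interaction weight (visit counts) or, in
binary mode, presence/absence. A knockout extinction simulation removes
plants one at a time until nothing is left, tracking the surviving
interactions in the reduced matrix `C` and the pollinator survivor count
`a(p)` after each of the `p = 1..P` plant removals. Robustness is the
normalized area under that curve,

$$R = \frac{1}{AP}\sum_{p=0}^{P} a(p), \qquad a(0) = A,\; a(P) = 0 .$$

Because every pollinator must lose its last plant eventually, `a(P) = 0`
always holds and `1/P \le R < 1`. The value of `R` depends on the order of
plant removals, so repeated simulation yields a distribution `f(R)` whose
median we write `R_m`.

**Threshold rule.** All secondary (and further) extinctions are governed
by a single fractional threshold `T`: a node dies once it has lost a
fraction `≥ T` of its original edge count (binary) or of its original
total interaction weight (weighted). `T` is dimensionless with
`0 < T ≤ 1`; `T = 0` is rejected as uninformative (the first removal would
kill everything) and `T = 1` recovers the classical rule in which a
pollinator dies only with its last plant. Since whole edges are lost, a
binary node of degree `k` actually dies at the *effective threshold*
`⌈Tk⌉/k ≥ T`; `node_average_effective_threshold()` reports the network
average (over both guilds by default — the convention is configurable
because either choice is defensible and the average is reported, not
asserted).

**The three models.** All share the threshold rule and differ only in how
the next plant is chosen:

* **SO (Secondary Only).** The next plant is always drawn uniformly from
  the survivors; plants never die by the threshold rule. Consequently the
  extinction sequence is a uniformly random permutation of the `P` plants,
  and every plant's extinction-rank distribution `h(r)` is uniform — a
  property the test suite checks by chi-square.
* **DA (Deterministic Avalanche).** After a random trigger is removed and
  pollinator extinctions applied, any surviving plant that has itself
  lost a fraction `≥ T` of its edges/weight dies too, and its removal is
  processed the same way; the avalanche runs until no plant is marked,
  then a new random trigger is drawn. With `T = 1` no avalanche can ever
  fire (a plant can only lose its last pollinator if that pollinator had
  already lost this very plant), so DA reduces exactly to SO — an
  identity the tests verify run-for-run under shared seeds.
* **RW (Random Walk).** From the current plant `e`, the next victim is
  sampled among surviving plants `g` with probability proportional to
  `F_eg`, the number of surviving pollinators shared by `e` and `g`
  (the one-mode projection of `C`). Pollinators die by the threshold
  rule; plants die only by being visited by the walk. When `e` shares no
  pollinators with any survivor the walk restarts with a fresh uniform
  trigger. On a perfect matching `F ≡ 0`, every step is a restart, and RW
  degenerates to SO.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `threshold` (`T`) | 0.5 | fraction of original edges/weight | mid-range value; the conventional choice for threshold-rule studies. `R_m` rises monotonically with `T`, so conclusions should be checked across a sweep (`threshold_sweep()`). |
| `weighted` | `FALSE` | — | binary mode counts partners; weighted mode counts visits. Weighting amplifies the skew of effective dependence and broadens `f(R)`. |
| `n` (ensemble size) | 25,000 in reference analyses | runs | reference-scale Monte Carlo; tests use 2,000–5,000 with correspondingly widened statistical tolerances. |
| null-model `ensemble_size` | 10,000 | networks | reference scale for expected degree distributions and exemplar selection. |
| `master_seed` | user-supplied | — | every run/draw gets a seed derived from the master seed via a counter, so any single run is reproducible in isolation. |

## Design choices where the procedure was open

* **Within-avalanche order (DA).** When several plants are simultaneously
  at/over threshold, they are removed one at a time in uniformly random
  order, re-applying the pollinator rule and re-marking plants after each
  single removal, and recording `a(p)` after every individual plant
  removal. Rationale: the robustness sum needs `a(p)` at every integer
  `p`, and random serialization avoids index-order bias. Pollinator
  extinctions within one plant removal are simultaneous.
* **Walk bookkeeping (RW).** The next victim is chosen from the
  shared-pollinator row of the current plant *before* that plant is
  removed; the threshold rule is never applied to plants in RW, so a
  plant stranded with zero pollinators survives until visited. The
  restart condition is "the current plant shares no pollinator with any
  survivor", not "the graph is disconnected".
* **Ordered runs.** Degree ties are broken by original column index, so
  ordered sequences are exactly replayable.
* **Loss arithmetic.** Binary losses are integer edge counts compared
  against the precomputed per-node kill count `⌈Tk⌉` (guarded against
  floating-point error in `T·k`), so no tolerance is involved. Weighted
  losses compare against `T · total` with a relative guard of `1e-9` so
  that an exactly-threshold loss counts as extinction, per the `≥ T`
  rule.
* **Weighted denominators.** A node's loss fraction is measured against
  its *total original weight*, not per-edge dependencies.
* **Spearman p-values.** Exact permutation enumeration for `P ≤ 8`,
  two-sided t approximation otherwise. The coefficient itself uses
  average-rank ties. Positive ρ means high-degree plants die late.
* **Percentiles and medians.** Quantiles use linear interpolation between
  order statistics (the common box-plot convention); the median of an
  even-length sample is the midpoint of the two central order statistics;
  per-plant median ranks are computed the same way from the rank
  histograms.
* **Null-model objective.** The exemplar minimizes the L1 distance
  `Σ_k |g̃_A(k) − G_A(k)| + |g̃_P(k) − G_P(k)|` between a draw's degree
  distributions and the ensemble expectation — a signed sum would be
  identically zero by conservation of species counts, so L1 is the only
  usable reading. Draws containing zero-degree species contribute to the
  ensemble statistics but are ineligible as exemplars, because an
  extinction run requires every species to start alive.
* **Full randomization** places `E` interactions on distinct cells of the
  `A × P` grid (interactions are binary edges, so duplicates are
  meaningless).

## What the synthetic generator emulates — and what it does not

`generate_network()` produces networks with exact guild sizes and edge
count, no zero-degree species, an optional hub plant (degree
`≈ hub_fraction · A`) with preferential attachment supplying further
plant-degree skew, and i.i.d. geometric visit counts in weighted mode.
The bundled `ac_like` fixture (`P = 25`, `A = 79`, `E = 299`,
`hub_fraction = 0.6`, mean visit count 5) reproduces the *structural
regime* of a well-sampled, strongly skewed empirical plant–pollinator
community: connectance 0.151 to three decimals and a hub plant of degree
47 out of 79 pollinators. The geometric mean of 5 visits per edge was
chosen once as a realistic order of magnitude for visit-count data and is
not revisited.

It does **not** reproduce any particular empirical matrix: the precise
degree sequences, the correlation between weight and degree, nestedness
(the fixture's NODF is lower than typical highly nested communities), and
sampling artefacts are all unmodelled. A green qualitative test on
`ac_like` therefore establishes that the *mechanisms* behave as described
(avalanches spare hubs, walks seek them, plant-degree skew broadens
`f(R)`) — it does not certify numeric agreement with any published
analysis of empirical data, which would require the original matrices.

## Degenerate inputs and edge cases

* `P = 1` forces `R = 1` whatever the model or threshold — the robustness
  sum has a single nonzero term `a(0) = A`, giving `A/(A·1)`. The package
  computes it rather than forbidding it.
* Species with zero interactions are rejected at load time (they would
  make `a(0) ≠ A` and silently distort `R`), rather than dropped.
* Non-integer weights warn but are accepted: the mathematics needs only
  nonnegativity, while typical field data are counts.
* Disconnected networks are legal; the RW model simply never walks across
  components.

## Known limitations

* No stochastic per-node thresholds, no edge rewiring, no empirically
  estimated dependence weights, and no pollinator-side primary removals:
  plants are fixed as the primary guild.
* The Monte-Carlo engine is pure R; at reference scale (25,000 runs on a
  79 × 25 network) a model variant takes on the order of a minute of CPU.
* Null models operate on the binary pattern only; weighted degree-sequence
  manipulation is out of scope.
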