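---
title: "Methods: weighted additive scoring and swing-weight elicitation for tender MCDA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted additive scoring and swing-weight elicitation for tender MCDA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tendermcda)
```

## The decision problem

Two-phase pharmaceutical tenders separate technical assessment from price
negotiation. A technical committee scores each product bid on non-price
criteria; bids that clear a qualification threshold are handed to a
financial committee, which compares them by price per point. `tendermcda`
implements that workflow end to end: a configurable criteria model, a
group-vote elicitation pipeline for the criterion weights, the scoring
engine with hard exclusion rules, and the financial-phase ranking.

## The additive value model

With criterion weights $w_i$ (percentage points, $\sum_i w_i = 100$) and
score fractions $s_i \in [0,1]$, the total score of a bid is

$$S = \sum_i w_i \, s_i \in [0, 100].$$

For a categorical criterion, $s_i$ is the configured fraction of the option
the bid selects (e.g. full local manufacturing earns the whole
macroeconomic-benefit weight, local packaging a part of it, no activity
none). One criterion — pharmacovigilance services — is *external-score*:
the national drug authority reports a percentage fulfilment, and
$s_i = \text{percent}/100$ with no further transformation, since the
reported figure is already a fulfilment fraction.

Three option levels are **exclusion triggers**: a product not marketed in
its country of origin, lacking a GMP certificate, or with supply
reliability below 25% is disqualified regardless of every other score.
Triggers carry $s_i = 0$ by invariant, but the disqualification is a
separate veto, not a consequence of the zero: a bid scoring 100 elsewhere
still fails. Qualification is

$$\text{qualified} \iff \text{no trigger selected} \;\wedge\; S \ge T,$$

with threshold $T = 65$ points in the default configuration. The
comparison is inclusive (65.00 qualifies) and made at full precision —
display rounding to two decimals never promotes a 64.996 across the
threshold.

In the financial phase, qualified bids for the same active ingredient are
ordered by price per point $P/S$ at full precision (the familiar 2.14 for a
150-per-70-points bid is presentation rounding of $150/70 = 2.142857\ldots$).
The lowest $P/S$ is flagged preferred. Ties are broken by higher total
score, then lower price, then product id — a documented design choice
(favouring quality at equal value-for-money) where the procedure itself is
silent; the chain makes the comparator a strict total order, so output
never depends on input order. Unqualified bids are listed with their status
but never ranked, and an ingredient whose bids all failed is reported as
"no eligible supplier" rather than aborting the run. Split awards are out
of scope: exactly one preferred option is flagged, but the full ranking is
always emitted so a committee can deviate.

## Weight elicitation

Weights come from stakeholder vote panels, not from the analyst:

1. **Ranking.** Each participant ranks the K criteria; the consensus order
   is by ascending *mean* rank vote. Ties are broken by median rank vote,
   then lexicographic criterion id, so the output is deterministic and
   auditable.
2. **Adjacent importance ratios.** For each adjacent pair in the consensus
   order, participants state how much more important the higher-ranked
   criterion is (a multiplier $r_k \ge 1$; the higher-ranked item is the
   numerator). Per-pair votes are aggregated by *median*.
3. **SMART swing weights.** Raw weights multiply up from the last rank,
   $\mathrm{raw}_K = 1$, $\mathrm{raw}_k = r_k \cdot \mathrm{raw}_{k+1}$,
   and are normalized to sum to 100. Because every $r_k \ge 1$, weights are
   non-increasing in rank.

The mean-for-ranks / median-for-ratios-and-scores split mirrors the stated
workshop conventions: the median damps outlier votes on the open-scale
quantities. The even-$n$ median is the midpoint of the two central values.
Votes are processed at full precision; nothing is rounded before
aggregation. Whether ratio votes are elicited as multipliers, percentages
or point allocations was genuinely open; the multiplier convention with
median aggregation is the package's documented choice, and
`aggregate_ratio_votes()` is the single seam to swap if another aggregation
is preferred.

Modification proposals to the criteria list (exclude, merge, add, rename)
pass by *strict* majority — more than half of the votes, so 9 of 16 passes
and 8 of 16 does not. `apply_modification()` compacts ranks to $1..K'$ but
deliberately does **not** renormalize weights: in the intended workflow the
criteria list is fixed first and weights are elicited afterwards, so the
result is flagged `weights_stale` until re-elicited
(`set_elicited_weights()`) or manually re-validated.

```{r}
cfg <- primary_config()
for (m in workshop_modifications()) cfg <- apply_modification(cfg, m)
length(cfg$criteria)
```

## The default configuration

`default_config()` ships the adopted seven-criterion tool: weights
(23.49, 18.79, 15.53, 12.94, 10.78, 9.80, 8.67) in rank order, threshold
65, the three exclusion triggers, and the pharmacovigilance criterion as
external-score. Consecutive quotients of that weight vector are
approximately (1.25, 1.21, 1.20, 1.20, 1.10, 1.13), which is exactly what
the swing-weighting pipeline consumes — feeding those ratios back through
`swing_weights()` reproduces the vector to within 0.02 per entry.

Weights are carried at full precision and displayed at two decimals using
largest-remainder rounding (`display_weights()`), so the printed set sums
to exactly 100.00. The sum-to-100 validation tolerance defaults to 0.01
absolute points.

Option *labels and fractions are config data, not code*. The top level of
each criterion earns fraction 1 and exclusion triggers earn 0 by
invariant; the published tool defines the intermediate levels in its
scoring-function table, which is not fully reproduced in the accessible
text, so intermediate defaults here are evenly spaced placeholders flagged
`provisional: TRUE`. A deployment should replace them with its committee's
voted values (or elicit them via `aggregate_option_scores()`, which turns
0–100 option votes into median fractions); none of the package's invariants
depend on the placeholder values.

The configuration serializes to a versioned, canonical YAML schema
(`save_config()` / `load_config()`): stable key order and
17-significant-digit numerics make saves byte-reproducible and the
round-trip exact, and validation reports every violation with the offending
field path rather than stopping at the first.

## The synthetic-data generator

`fixture_spec()` + `generate_bids()` / `generate_vote_panel()` produce
inputs with known ground truth, in exactly the delimited formats the
pipeline reads, so every claim in the test suite is checked against
generated data rather than stored fixtures.

* **Panels.** The default panel has 35 participants, the size of the
  development workshops. With `vote_noise = 0`, every participant's rank
  vote equals the true ranking implied by `true_weights` (default: the
  published vector) and every ratio vote equals the adjacent quotient of
  the true weights, so the elicitation pipeline recovers the generating
  vector exactly — a parameter-recovery oracle. The noise model is single
  and documented: multiplicative log-normal noise (sd = `vote_noise` on the
  log scale) on ratio votes truncated to $\ge 1$; independent adjacent-pair
  swaps (probability `min(0.5, vote_noise)`) on rank votes; additive
  Gaussian jitter (sd = `100 * vote_noise`) on option-score votes, rounded
  to integers and clipped to [0, 100].
* **Bids.** A bid selects an exclusion-trigger option on one randomly
  chosen trigger-bearing criterion with probability `exclusion_rate`;
  otherwise selections are uniform over non-trigger options, prices uniform
  over `price_range`, external percentages uniform over [0, 100].
  Ingredients come from a small pool (about one per three products) so the
  per-ingredient ranking is exercised.

Generation is deterministic given the spec (including its seed) and leaves
the caller's RNG stream untouched.

What the generator does *not* emulate — and what passing tests therefore do
not show about real panels — includes strategic or correlated voting,
participant-specific biases, heaped/rounded ratio votes, missing votes, and
any dependence between a bid's price and its quality levels. The recovery
results characterize the pipeline's behaviour under an honest noise model,
not the measurement error of a real workshop.

## Numerical choices and degenerate inputs

* All comparisons (threshold, ranking) at full double precision; a single
  display rule (two decimals, largest-remainder for weight vectors) applied
  only at rendering.
* `swing_weights()` with an empty ratio vector is the single-criterion
  case (weight 100); an empty vector with more than one criterion id is an
  error. Ratios below 1 are rejected rather than reinterpreted as the
  inverse direction.
* Missing bid selections are a hard error, never imputed as zero — silent
  zero-scoring could disqualify a bid through a data-entry gap. Malformed
  rows in a bid table are isolated as per-row error records; only
  configuration errors abort a scoring run.
* Normalized weight vectors sum to 100 within 1e-9 before display
  rounding; validation of elicited configs uses a correspondingly tight
  tolerance.

## Problem sizes

The test suite and the acceptance script run at the study's own scale:
panels of 35 voters over 7 criteria, bid tables of 5–400 products,
200 seeded replicates for the noisy-recovery rate and 30-replicate grids
for the noise-monotonicity check — small enough that the whole suite
completes in seconds on one core.

## Known limitations

* Intermediate option fractions are provisional placeholders (above); the
  shipped totals are only as meaningful as the configured scoring
  functions.
* Supply reliability is modelled as an input option selection; computing
  the percentage from order histories is upstream of this package.
* No split-award logic, price negotiation, budget impact or currency
  conversion; currency is an opaque label.
* The elicitation pipeline assumes complete panels (every participant ranks
  every criterion and votes every adjacent pair); partial panels are
  rejected, not imputed.
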