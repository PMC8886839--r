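# tendermcda

Multi-criteria decision analysis (MCDA) for two-phase tenders of off-patent
(generic) medicines, built around the tool adopted by Egypt's unified
procurement authority for national oncology tenders.

National tenders for off-patent oncology medicines often attract many
interchangeable bids, and awarding on price alone ignores quality, supply
reliability and safety monitoring. In the two-phase process this package
supports, a technical committee first scores every bid on non-price
criteria; only bids that clear a qualification threshold move to the
financial phase, where they are compared by *price per point*. The package
is for procurement analysts and health-economics researchers who want that
workflow as reviewable, scriptable code rather than a spreadsheet.

## The model

Each product bid is scored on K weighted criteria. Criterion *i* has weight
*w<sub>i</sub>* (percentage points, Σ *w<sub>i</sub>* = 100) and yields a
score fraction *s<sub>i</sub>* ∈ [0, 1] — the fraction of the criterion
weight earned by the bid's selected option level (for the pharmacovigilance
criterion, the percentage reported by the drug authority divided by 100).
The total score on the 0–100 point scale is the additive value

> S = Σ<sub>i</sub> w<sub>i</sub> · s<sub>i</sub>

A bid **qualifies** iff it triggers no hard exclusion (not marketed in the
country of origin; no GMP certificate; supply reliability below 25%) and
S ≥ 65. Qualified bids for the same active ingredient are ranked by
P / S (price per point); the lowest is the preferred option.

Weights are elicited from stakeholder votes by SMART swing-weighting: with
criteria ranked 1..K by mean rank vote, participants state how much more
important each rank is than the next (ratios r<sub>k</sub> ≥ 1, aggregated
by median). Raw weights multiply up from the last rank
(raw<sub>K</sub> = 1, raw<sub>k</sub> = r<sub>k</sub> · raw<sub>k+1</sub>)
and are normalized to sum to 100. The shipped default configuration carries
the published weight vector (23.49, 18.79, 15.53, 12.94, 10.78, 9.80, 8.67).

## Worked example

```r
library(tendermcda)
cfg <- default_config()
cfg
#> <mcda_config> 7 criteria, threshold 65
#>   1. Use in reference countries              23.49%
#>   2. Equivalence with the reference product  18.79%
#>   3. Manufacturing quality                   15.53%
#>   4. Pharmacovigilance services              12.94%  [external score]
#>   5. Supply reliability                      10.78%
#>   6. Previous use in local settings           9.80%
#>   7. Macroeconomic benefit                    8.67%

sel <- list(
  reference_country_use = "marketed and used in two or more reference countries",
  reference_equivalence = "demonstrated equivalence with the reference product",
  manufacturing_quality = "GMP certificate from a stringent regulatory authority",
  supply_reliability    = "75% or more of orders on time and complete",
  local_use             = "previous local use with no reported problems",
  macroeconomic_benefit = "local packaging only in Egypt"
)
bidA <- product_bid("oncomed-A", "carboplatin", sel,
                    pharmacovigilance_percent = 90, price = 160)
selB <- sel
selB$reference_equivalence <- "no equivalence evidence"
selB$local_use <- "no previous use in local settings"
bidB <- product_bid("oncomed-B", "carboplatin", selB,
                    pharmacovigilance_percent = 75, price = 120)

evaluate(bidA, cfg)
#> <evaluation_result> oncomed-A (carboplatin): 94.37 points, qualified
evaluate(bidB, cfg)
#> <evaluation_result> oncomed-B (carboplatin): 63.84 points, below threshold

rank_tender(list(evaluate(bidA, cfg), evaluate(bidB, cfg)))
#>  active_ingredient product_id total_score price price_per_point          status
#>        carboplatin  oncomed-A       94.37   160            1.70       qualified
#>        carboplatin  oncomed-B       63.84   120                 below threshold
#>  rank_within_ingredient preferred
#>                       1      TRUE
#>                      NA     FALSE
```

Bid A earns most of its criterion weights and qualifies with 94.37 points;
despite its lower price, bid B misses the 65-point threshold and never
reaches the financial phase, so A is the preferred option at 1.70 currency
units per point.

The same workflow is available from a shell via `exec/mcda-tender`
(`validate-config`, `score`, `rank`, `elicit`, `simulate`), and weight
elicitation from vote tables via `cmd_elicit()` / `elicit_weights()`.

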