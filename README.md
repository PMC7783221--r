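# pharmnetrisk

Risk-based prioritisation of medicines for online-pharmacy surveillance
and test purchasing.

Surveillance teams and researchers who monitor the illicit internet
pharmacy market cannot test-purchase everything; `pharmnetrisk` implements
a two-axis method for choosing what to buy:

* **Severity** — a five-dimension patient-safety rubric scored from a
  product's SmPC/PIL attributes and registry status: general
  pharmaceutical risk (dosage form + application complexity, max 4),
  therapeutic risk (5 yes/no sub-dimensions, max 5), microbiological
  contamination risk (max 3), augmented online demand (shortage/misuse,
  max 2), and a counterfeiting check that overrides the total to 15 when
  a product is unregistered, investigational or withdrawn. The weighted
  score is `min(total / 10, 1)`, banded low ≤ 0.25 < medium < 0.75 ≤ high.
* **Probability of online purchase** — from a recorded search-result
  ledger: availability category (relevant links in the top 50 results:
  ≥ 15 → 1, 5–14 → 0.5, < 5 → 0.25) × affordability category (mean total
  price: < $25 → 1, $25–50 → 0.5, > $50 → 0.25), so the probability is
  always in {1, 0.5, 0.25, 0.125, 0.0625}, banded with the same
  boundaries.

Products land in a 3×3 severity × probability matrix; the occupants of the
maximal cell are the test-purchase candidates. The rubric is a config file
(`load_rubric()`), so other dosage forms and therapeutic classes can be
assessed without code changes.

## Worked example

The package ships a ten-product ophthalmic fixture set (glaucoma, allergy,
anti-infective and diagnostic eye drops) with per-product search ledgers:

```r
library(pharmnetrisk)

fx <- load_fixtures()
cards <- score_products(fx$profiles)        # safety severity
mk <- market_scores(fx$ledgers)             # availability x affordability
ranked <- rank_products(cards, mk)          # 3x3 matrix + ranking
ranked[, c("rank", "inn_name", "total", "weighted", "probability",
           "matrix_cell", "test_purchase_candidate")]
#> # A tibble: 10 × 7
#>     rank inn_name              total weighted probability matrix_cell   test_purchase_candidate
#>    <int> <chr>                 <int>    <dbl>       <dbl> <chr>         <lgl>
#>  1     1 Dorzolamide & timolol    10      1        1      high:high     TRUE
#>  2     2 Cyclopentolate            9      0.9      0.0625 high:low      FALSE
#>  3     3 Betaxolol                 7      0.7      0.25   medium:low    FALSE
#>  4     4 Latanoprost & timolol     7      0.7      0.25   medium:low    FALSE
#>  5     5 Brinzolamide              6      0.6      0.5    medium:medium FALSE
#>  6     6 Ciprofloxacin             6      0.6      0.25   medium:low    FALSE
#>  7     7 Sodium cromoglicate       5      0.5      0.5    medium:medium FALSE
#>  8     8 Travoprost                5      0.5      0.25   medium:low    FALSE
#>  9     9 Tetryzoline & antazoline  5      0.5      0.125  medium:low    FALSE
#> 10    10 Tetryzoline               5      0.5      0.125  medium:low    FALSE
```

Reading the top row: the dorzolamide & timolol combination scores 10 of 15
safety points (topical form with > 10 application instructions, systemic
mode of action with documented systemic ADRs and a pediatric indication,
multi-dose preserved bottle, in shortage), its ledger holds 20 relevant
vendor links at a mean price under $25, so both categories are *high* — it
is the only candidate the default max-both policy selects for test
purchase. `plot_risk_matrix(ranked)` draws the matrix;
`select_candidates(ranked, policy = "top_k", k = 2)` and
`cell_threshold` generalise the selection policy.

A thin command-line wrapper ships in `inst/cli/`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "pharmnetrisk", package = "pharmnetrisk"))')
Rscript "$CLI" assess \
  --profiles inst/extdata/eye_drop_profiles.csv \
  --ledger inst/extdata/eye_drop_ledgers.csv --out results/
#> candidates: Dorzolamide & timolol
#> wrote results/risk_assessment.json
```

Subcommands: `score`, `market`, `assess`, `fixtures` (export editable
copies of the packaged fixtures), `synth` (seeded synthetic profiles and
ledgers).

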