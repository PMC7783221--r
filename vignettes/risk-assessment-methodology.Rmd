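---
title: "A severity-by-probability risk assessment for medicines sold online"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A severity-by-probability risk assessment for medicines sold online}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharmnetrisk)
```

## The problem

Test purchasing — actually ordering a medicine from an online vendor and
analysing what arrives — is the strongest evidence available about the
illicit internet pharmacy market, but it is expensive: nobody can buy and
assay every product offered online. A surveillance programme therefore
needs a defensible way to decide *which* products to buy. `pharmnetrisk`
implements a two-axis prioritisation for that decision:

* **Severity** — a patient-safety risk score built from the product's own
  characteristics as recorded in its Summary of Product Characteristics
  (SmPC), Patient Information Leaflet (PIL) and registry status.
* **Probability** — how likely a consumer is to actually obtain the product
  online, derived from a recorded ledger of search-engine results:
  availability (how many vendors offer it) times affordability (what it
  costs, shipping included).

Products are placed on a 3×3 severity × probability matrix; the occupants
of the maximal cell are the test-purchase candidates.

## The safety rubric

The default rubric (`default_rubric()`) is tailored to ophthalmic
preparations and groups five dimensions:

| Dimension | Group | Max |
|---|---|---|
| 1. General pharmaceutical risk (dosage form, complexity of application) | intrinsic | 4 |
| 2. Therapeutic risk (mode of action, systemic absorption, damaged-eye indication, narrow therapeutic index, pediatric use) | intrinsic | 5 |
| 3. Microbiological contamination (multi-dose without filter, preservative, antibiotic API) | intrinsic | 3 |
| 4. Augmented demand (shortage, misuse potential) | extrinsic | 2 |
| 5. Counterfeiting (unregistered / investigational / withdrawn) | override | — |

All sub-dimensions are yes/no worth one point, except the complexity of
application, a three-point band on the SmPC instruction count (<5
instructions → 1, 5–10 → 2, >10 → 3). A non-counterfeit product scores at
most 14; a product failing the registry check is scored 15 outright
(only the unregistered/unlicensed branch of the WHO counterfeit taxonomy
is decidable before purchase — falsified and substandard status require the
physical product and are out of scope here).

Three scoring choices deserve explanation because the instrument leaves
them genuinely open:

* **Weighted divisor.** The weighted score divides the total by 10 even
  though the theoretical maximum is 15; the divisor is a config field, the
  theoretical max is stored separately, and the weighted score is clamped
  to 1.0 under the override so the banding stays on [0, 1].
* **Band boundaries.** Bands are *low* ≤ 0.25 < *medium* < 0.75 ≤ *high*.
  The closed/open assignment at the boundaries is chosen to agree with the
  instrument's own worked classifications (0.25 → low, 0.5 → medium,
  1.0 → high) and is shared by the severity and probability axes.
* **Systemic-absorption evidence (2.2).** The instrument describes a CIOMS
  frequency trigger — at least one very common, common, or severe local
  adverse reaction — without giving it a numbered slot, while the
  dimension maximum stays 5. We model the trigger as an alternative
  evidence path into sub-dimension 2.2 (`local_adr_trigger()`,
  switchable off via `use_adr_evidence = FALSE`) rather than a sixth
  sub-dimension.

Two more conventions: sub-dimension 3.1 is zeroed by *either* mitigation
(single-dose form or an antimicrobial filter), matching the instrument's
single combined rule; and the "limited access" sub-dimension 4.1 scores
drug shortage only — prescription status travels on the profile as
unscored metadata.

Missing answers are an error in strict mode (the default). Surveillance
practice sometimes has to score incomplete extractions, so
`impute = "low"` / `"high"` fills gaps uniformly with the low- or
high-risk answer and marks the scorecard as imputed. Note the direction of
risk is per-field: preservative content, antibiotic API and the filter are
*protective*, so high-risk imputation sets them absent.

## The market side

The probability of online purchase is computed from a **search ledger**: a
manually reviewed table of the first `top_n` (default 50) search-engine
results for a consumer-style query ("buy" + INN), each with a relevance
judgment (does the site sell the product directly to patients?) and the
total price where observed. The package never scrapes; relevance is an
input, as in manual review practice.

* **Availability**: the relevant-link count maps to category 1 (≥ 15
  links), 0.5 (5–14) or 0.25 (< 5). The availability *point* — the count
  divided by `reference_max` (default 20, the highest count observed in
  the reference data) — is reported for context but never enters the
  product; the arithmetic of the published tables forces the category,
  not the point, into the multiplication.
* **Affordability**: the representative price maps to point 1 (< $25),
  0.5 ($25–50) or 0 (> $50) and category 1 / 0.5 / 0.25 respectively;
  point and category differ only in the top band. Both $25 and $50 fall in
  the middle band ("between $25 and $50" read inclusively). The
  thresholds are configurable; the defaults were anchored at 5% and 10% of
  the 2018 Hungarian minimum wage.
* **Representative price**: the instrument does not state how one price is
  derived from several vendors; we use the mean total price over priced
  relevant entries within `top_n`, with an explicit `price_override` when
  no price was observed. Ledgers must be single-currency; mixing
  currencies is an error rather than a silent conversion.

The probability is the product of the two categories, hence always in
{1, 0.5, 0.25, 0.125, 0.0625}, and is banded with the same 0.25/0.75
boundaries as severity.

## Ranking and selection

`rank_products()` joins scorecards and market scores by product id and
sorts by (weighted severity, probability, relevant links, brand name).
The published method ranks informally; the explicit sort key and the
alphabetical tie-break are imposed here so the ranking is a deterministic
total order, stable under permutation of the input. `priority_score`
(weighted severity × probability) is a convenience scalar added by this
package, not part of the published method. `select_candidates()` offers
the instrument's implicit policy (`max_both`: severity and probability
categories both maximal in the set) plus `top_k` and `cell_threshold`
generalisations.

## The worked example

```{r fixtures}
fx <- load_fixtures()
cards <- score_products(fx$profiles)
mk <- market_scores(fx$ledgers)
ranked <- rank_products(cards, mk)
ranked[, c("rank", "inn_name", "total", "weighted", "probability",
           "matrix_cell", "test_purchase_candidate")]
```

The ten packaged eye drops (glaucoma, allergy, infection and diagnostic
products from the Hungarian market) reproduce the published result: the
dorzolamide & timolol combination scores 10/15 with purchase probability
1 and is the only max-both candidate; cyclopentolate follows at 9.

The fixture files are honest about their provenance. The published
narrative prints the two top totals, the general-dimension range (2–4),
the 2.2/2.3/shortage/antibiotic attributions and the full market table,
but not every flag of every product; the remaining flags are
*reconstructed* — chosen once to satisfy all printed constraints — and
tagged as such in `eye_drop_provenance.json`, including the one printed
conflict (the brand labelled single-dose while the scored narrative
states all products were multi-dose; we follow the scored statement). The
ledgers are synthetic by construction: link counts and price bands match
the published table, while URLs, ranks and individual vendor prices are
placeholders. Passing the fixture regression therefore shows the engine
reproduces the published arithmetic, not that we recovered the 2018
search results.

```{r plot, fig.width = 6, fig.height = 5}
plot_risk_matrix(ranked)
```

## The synthetic generator

`generate_profiles()` and `generate_ledgers()` emulate the study's input
shapes for property testing. Defaults are fixed once: topical multi-dose
eye-drop profiles with per-flag Bernoulli rates (0.5 for the common
therapeutic flags, lower for rarer attributes such as misuse potential at
0.1 and shortage at 0.2), instruction counts uniform on 1–15 (spanning
all three complexity bands), ledgers of 50 results with a 0.2 relevance
rate (mean 10 relevant links, matching the observed 3–20 range), and
log-uniform prices on $10–80 so every affordability band is exercised.
The seed fully determines the output. `exhaustive = TRUE` ignores the
rates and enumerates the full 3 × 2¹⁰ grid of complexity band ×
scored binary flags exactly once; the test suite checks that grid against
a brute-force summation oracle. What the generator does *not* emulate:
correlated answers (a real antibiotic eye drop is more likely to carry a
damaged-eye indication), multi-currency prices, and ledger noise such as
duplicate vendors — properties proven on synthetic data say nothing about
extraction quality from real SmPCs.

## Numerical and degenerate-input choices

Category values are small dyadic rationals (1, 0.5, 0.25, …), so all
category arithmetic is exact in floating point and equality tests need no
tolerance. Availability points are ordinary ratios reported as-is. An
empty ledger is valid (0 relevant links → low availability); affordability
on a ledger with no priced relevant entry is an error unless a price
override is supplied, rather than a silent NA. Empty assessment sets
select an empty candidate set without error. Problem sizes used by the
test suite — the 3,072-profile enumeration grid, 15–25 random profiles
for monotonicity sweeps, ledgers of 50 — were chosen as the smallest sets
that exercise every band and answer combination.

## Limitations

The instrument is illustrated on, and the default rubric tailored to,
ophthalmic preparations in one national market; other dosage forms need
their own sub-dimension configuration (`load_rubric()` exists for
exactly that). The severity and probability bands inherit the
instrument's hard thresholds, so products near a boundary can change cells
under small input changes. The toolkit scores what can be known before a
purchase; falsified or substandard quality, vendor legitimacy services
and laboratory analysis of purchased samples are explicitly downstream of
it.
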