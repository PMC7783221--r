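{
  "note": "Fixture profiles encode a published ten-product ophthalmic worked example. Flags not literally printed in the source narrative are reconstructed to satisfy every printed constraint and tagged below. Ledgers are synthetic: link counts and price bands match the published market table; URLs, ranks and individual prices are placeholders.",
  "reconstructed_fields": {
    "all_products": ["application_instruction_count (band constrained)", "mode_of_action_systemic", "narrow_therapeutic_index", "pediatric_indication_under6", "local_adrs"],
    "dorzolamide_timolol": "third therapeutic point assigned to the pediatric sub-dimension (2.5); the printed total of 10 does not identify which of 2.4/2.5 carries it",
    "cyclopentolate": "general/therapeutic split 3 + 3 chosen among the admissible assignments summing to 6 with complexity band < 3"
  },
  "conflicts": {
    "dorzolamide_timolol": "brand label says single-dose but the scored narrative states all products were multi-dose; the fixture follows the scored statement (multi_dose = true)"
  },
  "printed_constraints": ["general dimension spans 2..4; complexity band 3 only for dorzolamide & timolol", "systemic ADR (2.2) yes exactly for betaxolol, ciprofloxacin, latanoprost & timolol, dorzolamide & timolol", "damaged/inflamed indication (2.3) yes only for ciprofloxacin", "microbiological = 1 for ciprofloxacin (antibiotic API), 2 otherwise", "shortage yes exactly for cyclopentolate and dorzolamide & timolol; misuse no for all", "all products registered; totals 10 (dorzolamide & timolol), 9 (cyclopentolate), all >= 5"]
}
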