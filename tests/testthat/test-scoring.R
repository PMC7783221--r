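test_that("complexity band follows the three-point instruction scale", {
  expect_equal(complexity_band(12), 3L)
  expect_equal(complexity_band(7), 2L)
  expect_equal(complexity_band(0), 1L)
  # boundaries: 4|5 and 10|11
  counts <- 0:20
  expect_equal(complexity_band(counts), oracle_band(counts))
  expect_error(complexity_band(-1), "non-negative")
})

test_that("general dimension combines dosage form and complexity", {
  topical12 <- minimal_profile()
  topical12$application_instruction_count <- 12L
  expect_equal(score_general(topical12)$points, 4L)

  oral2 <- minimal_profile()
  oral2$dosage_form_class <- "conventional_oral"
  oral2$application_instruction_count <- 2L
  expect_equal(score_general(oral2)$points, 1L)

  topical7 <- minimal_profile()
  topical7$application_instruction_count <- 7L
  expect_equal(score_general(topical7)$points, 1L + oracle_band(7))
  expect_equal(score_general(topical7)$sub_scores$`1.2`, 2L)
})

test_that("CIOMS local-ADR trigger fires on common frequency or severe", {
  expect_false(local_adr_trigger(list()))
  expect_true(local_adr_trigger(list(
    adr_record("burning", "common", "minor"))))
  expect_true(local_adr_trigger(list(
    adr_record("keratitis", "rare", "severe"))))
  expect_false(local_adr_trigger(list(
    adr_record("irritation", "uncommon", "moderate"),
    adr_record("dry eye", "rare", "minor"))))
})

test_that("therapeutic dimension scores five yes/no answers with ADR evidence", {
  allno <- minimal_profile()
  expect_equal(score_therapeutic(allno)$points, 0L)

  allyes <- minimal_profile(
    mode_of_action_systemic = TRUE, systemic_adr_documented = TRUE,
    indication_damaged_or_inflamed = TRUE, narrow_therapeutic_index = TRUE,
    pediatric_indication_under6 = TRUE)
  expect_equal(score_therapeutic(allyes)$points, 5L)

  # 2.2 via local-ADR evidence only
  evid <- minimal_profile(
    local_adrs = list(adr_record("burning", "very_common", "minor")))
  d <- score_therapeutic(evid)
  expect_equal(d$sub_scores$`2.2`, 1L)
  expect_equal(score_therapeutic(evid, use_adr_evidence = FALSE)$points, 0L)
})

test_that("microbiological dimension scores mitigations as zeroes", {
  risky <- minimal_profile(contains_preservative = FALSE,
                           api_is_antibiotic = FALSE)
  expect_equal(score_microbiological(risky)$points, 3L)
  # multi-dose + preservative + antibiotic: only 3.1 left unmitigated... no:
  # antibiotic zeroes 3.3, preservative zeroes 3.2, multi-dose keeps 3.1
  anti <- minimal_profile(api_is_antibiotic = TRUE)
  expect_equal(score_microbiological(anti)$points, 1L)
  # multi-dose, preservative, non-antibiotic
  expect_equal(score_microbiological(minimal_profile())$points, 2L)
  # single-dose or filter zeroes 3.1 (either mitigation suffices)
  single <- minimal_profile(multi_dose = FALSE, api_is_antibiotic = TRUE)
  expect_equal(score_microbiological(single)$points, 0L)
  filtered <- minimal_profile(antimicrobial_filter = TRUE,
                              api_is_antibiotic = TRUE)
  expect_equal(score_microbiological(filtered)$points, 0L)
})

test_that("access dimension scores shortage and misuse independently", {
  expect_equal(score_access(minimal_profile(in_shortage = TRUE))$points, 1L)
  expect_equal(score_access(minimal_profile())$points, 0L)
  expect_equal(score_access(minimal_profile(in_shortage = TRUE,
                                            misuse_potential = TRUE))$points,
               2L)
})

test_that("counterfeit override triggers on unregistered statuses only", {
  expect_false(assess_counterfeit(minimal_profile())$override)
  for (status in c("unregistered", "investigational", "withdrawn")) {
    d <- assess_counterfeit(minimal_profile(registration_status = status))
    expect_true(d$override)
    expect_match(d$reason, status)
  }
  expect_error(assess_counterfeit(
    minimal_profile(registration_status = "bogus")), "registration_status")
})

test_that("score_product assembles totals, override, weighting and bands", {
  card <- score_product(minimal_profile(registration_status = "unregistered"))
  expect_equal(card$total, 15L)
  expect_true(card$override_applied)
  expect_equal(card$weighted, 1.0)  # clamped from 15/10 for banding
  expect_equal(card$severity_category, "high")

  # every answer at its low-risk value: single-dose, preserved, antibiotic
  oral_min <- minimal_profile(dosage_form_class = "conventional_oral",
                              application_instruction_count = 0L,
                              multi_dose = FALSE,
                              api_is_antibiotic = TRUE)
  card <- score_product(oral_min)
  expect_equal(card$total, 1L)
  expect_equal(card$weighted, 0.1)
  expect_equal(card$severity_category, "low")
})

test_that("strict mode aggregates missing answers; imputation fills them", {
  gappy <- minimal_profile()
  gappy$in_shortage <- NA
  gappy$contains_preservative <- NA
  expect_error(score_product(gappy), "4\\.1")
  expect_error(score_product(gappy), "3\\.2")

  lo <- score_product(gappy, impute = "low")
  expect_setequal(lo$imputed, c("in_shortage", "contains_preservative"))
  hi <- score_product(gappy, impute = "high")
  expect_gte(hi$total, lo$total)
  # low-risk imputation matches scoring the explicit low-risk answers
  expect_equal(lo$total, score_product(minimal_profile())$total)
})

test_that("flipping any answer to its risky value never lowers the score", {
  risky_flip <- list(
    mode_of_action_systemic = TRUE, systemic_adr_documented = TRUE,
    indication_damaged_or_inflamed = TRUE, narrow_therapeutic_index = TRUE,
    pediatric_indication_under6 = TRUE, multi_dose = TRUE,
    antimicrobial_filter = FALSE, contains_preservative = FALSE,
    api_is_antibiotic = FALSE, in_shortage = TRUE, misuse_potential = TRUE)
  sev_rank <- function(x) match(x, c("low", "medium", "high"))
  base_profiles <- generate_profiles(synthetic_spec(n = 25, seed = 42))
  for (i in seq_len(nrow(base_profiles))) {
    p <- base_profiles[i, ]
    base <- score_product(p)
    for (f in names(risky_flip)) {
      q <- p
      q[[f]] <- risky_flip[[f]]
      flipped <- score_product(q)
      expect_gte(flipped$total, base$total)
      expect_gte(flipped$weighted, base$weighted)
      expect_gte(sev_rank(flipped$severity_category),
                 sev_rank(base$severity_category))
    }
    # raising the instruction count cannot lower the band
    q <- p
    q$application_instruction_count <- 12L
    expect_gte(score_product(q)$total, base$total)
  }
})

test_that("override dominates every additive total", {
  profiles <- generate_profiles(synthetic_spec(n = 20, seed = 7))
  totals <- score_products(profiles)$total
  expect_true(all(totals <= default_rubric()$override_score))
})
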