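# Independent oracles the implementation is checked against. These stay
# deliberately naive: direct arithmetic and enumeration, no calls into the
# scoring engine.

# complexity band via cut() on the documented breakpoints
oracle_band <- function(count) {
  as.integer(cut(count, breaks = c(-1, 4.5, 10.5, Inf), labels = FALSE))
}

# total safety score by direct summation of flag points for a topical,
# filter-free, registered profile (the exhaustive enumeration grid)
oracle_total <- function(p) {
  1L +                                   # topical dosage form
    oracle_band(p$application_instruction_count) +
    p$mode_of_action_systemic + p$systemic_adr_documented +
    p$indication_damaged_or_inflamed + p$narrow_therapeutic_index +
    p$pediatric_indication_under6 +
    p$multi_dose +                       # no filter in the grid
    (!p$contains_preservative) + (!p$api_is_antibiotic) +
    p$in_shortage + p$misuse_potential
}

# affordability bands by lookup over a fine price grid
oracle_affordability_category <- function(price) {
  ifelse(price > 50, 0.25, ifelse(price >= 25, 0.5, 1))
}

# probability banding by exhaustive 3x3 category enumeration
oracle_probability_table <- function() {
  cats <- c(1, 0.5, 0.25)
  grid <- expand.grid(avail = cats, afford = cats)
  grid$prob <- grid$avail * grid$afford
  grid$band <- ifelse(grid$prob <= 0.25, "low",
                      ifelse(grid$prob >= 0.75, "high", "medium"))
  grid
}

minimal_profile <- function(...) {
  args <- list(
    product_id = "p", brand_name = "P", inn_name = "p",
    dosage_form_class = "parenteral_or_topical",
    application_instruction_count = 2,
    mode_of_action_systemic = FALSE, systemic_adr_documented = FALSE,
    indication_damaged_or_inflamed = FALSE,
    narrow_therapeutic_index = FALSE, pediatric_indication_under6 = FALSE,
    multi_dose = TRUE, antimicrobial_filter = FALSE,
    contains_preservative = TRUE, api_is_antibiotic = FALSE,
    in_shortage = FALSE, misuse_potential = FALSE,
    registration_status = "registered", rx_only = TRUE)
  do.call(product_profile, utils::modifyList(args, list(...)))
}

# build a single-product ledger in code
make_ledger <- function(product_id = "p", relevant_ranks = integer(),
                        prices = numeric(), n = 50) {
  price_col <- rep(NA_real_, n)
  if (length(relevant_ranks) > 0)
    price_col[relevant_ranks] <- rep_len(prices, length(relevant_ranks))
  structure(list(
    product_id = product_id, query = "buy p", engine = "test",
    capture_date = "2018-05-15",
    entries = tibble::tibble(
      rank = seq_len(n),
      url = sprintf("https://x%02d.example/p", seq_len(n)),
      is_relevant = seq_len(n) %in% relevant_ranks,
      total_price = price_col,
      currency = ifelse(seq_len(n) %in% relevant_ranks, "USD",
                        NA_character_))
  ), class = "search_ledger")
}
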