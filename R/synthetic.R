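#' Specification for synthetic profiles and ledgers
#'
#' Defines the study-like conditions the generator emulates: per-flag
#' Bernoulli rates for the yes/no rubric answers, an instruction-count
#' range, and ledger shape (review depth, relevance rate, log-uniform price
#' range). The seed fully determines the output. Defaults mirror the
#' reference study's setting: topical multi-dose products, ledgers of 50
#' reviewed results, a relevance rate giving the observed 3-20 relevant
#' links on average, and prices spanning all three affordability bands.
#'
#' @param n Number of products/ledgers to generate.
#' @param seed Integer seed; identical specs produce identical output.
#' @param answer_probabilities Named list of Bernoulli rates for the logical
#'   profile answers (missing names fall back to the defaults).
#' @param instruction_count_range Integer interval for the instruction
#'   count.
#' @param ledger_length Results per ledger (review depth).
#' @param relevance_rate Probability that a result is a relevant vendor.
#' @param price_distribution Length-2 interval; prices are log-uniform on
#'   it.
#' @param force_relevant Optional exact relevant-link count per ledger
#'   (overrides `relevance_rate`).
#' @param force_price Optional fixed price for every relevant entry.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n = 10, seed = 1,
                           answer_probabilities = list(),
                           instruction_count_range = c(1L, 15L),
                           ledger_length = 50L,
                           relevance_rate = 0.2,
                           price_distribution = c(10, 80),
                           force_relevant = NULL,
                           force_price = NULL) {
  defaults <- list(
    mode_of_action_systemic = 0.5, systemic_adr_documented = 0.5,
    indication_damaged_or_inflamed = 0.3, narrow_therapeutic_index = 0.2,
    pediatric_indication_under6 = 0.3, multi_dose = 0.8,
    antimicrobial_filter = 0.1, contains_preservative = 0.8,
    api_is_antibiotic = 0.2, in_shortage = 0.2, misuse_potential = 0.1
  )
  bad <- setdiff(names(answer_probabilities), names(defaults))
  if (length(bad) > 0)
    stop("unknown answer_probabilities: ", paste(bad, collapse = ", "),
         call. = FALSE)
  probs <- utils::modifyList(defaults, answer_probabilities)
  if (any(unlist(probs) < 0 | unlist(probs) > 1))
    stop("answer probabilities must lie in [0, 1]", call. = FALSE)
  if (n < 0 || n != trunc(n)) stop("n must be a non-negative integer",
                                   call. = FALSE)
  if (relevance_rate < 0 || relevance_rate > 1)
    stop("relevance_rate must lie in [0, 1]", call. = FALSE)
  if (price_distribution[1] <= 0 ||
      price_distribution[2] < price_distribution[1])
    stop("price_distribution must be a positive increasing interval",
         call. = FALSE)
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 answer_probabilities = probs,
                 instruction_count_range = as.integer(instruction_count_range),
                 ledger_length = as.integer(ledger_length),
                 relevance_rate = relevance_rate,
                 price_distribution = as.numeric(price_distribution),
                 force_relevant = force_relevant,
                 force_price = force_price),
            class = "synthetic_spec")
}

scored_flags <- c("mode_of_action_systemic", "systemic_adr_documented",
                  "indication_damaged_or_inflamed",
                  "narrow_therapeutic_index", "pediatric_indication_under6",
                  "multi_dose", "contains_preservative", "api_is_antibiotic",
                  "in_shortage", "misuse_potential")

#' Generate synthetic product profiles
#'
#' In random mode, draws `spec$n` topical eye-drop profiles with seeded
#' Bernoulli answers and a uniform instruction count, so every answer
#' combination has nonzero probability. In exhaustive mode, returns each of
#' the 3 x 2^10 combinations of complexity band and the ten scored binary
#' flags exactly once (the antimicrobial filter is held at no, so
#' sub-dimension 3.1 is driven by the multi-dose flag alone); exhaustive
#' output is the enumeration grid used by the brute-force scoring oracle.
#'
#' @param spec A [synthetic_spec()].
#' @param exhaustive Enumerate the full answer grid instead of sampling.
#' @return A profile tibble compatible with [score_products()].
#' @export
generate_profiles <- function(spec = synthetic_spec(), exhaustive = FALSE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (exhaustive) {
    grid <- expand.grid(c(list(band = 1:3),
                          stats::setNames(rep(list(c(FALSE, TRUE)),
                                              length(scored_flags)),
                                          scored_flags)),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    counts <- c(2L, 7L, 12L)  # representative counts for bands 1..3
    n <- nrow(grid)
    return(dplyr::bind_rows(lapply(seq_len(n), function(i) {
      args <- as.list(grid[i, scored_flags])
      do.call(product_profile, c(list(
        product_id = sprintf("grid_%04d", i),
        brand_name = sprintf("GRID %04d", i),
        inn_name = sprintf("gridine-%04d", i),
        dosage_form_class = "parenteral_or_topical",
        application_instruction_count = counts[grid$band[i]],
        antimicrobial_filter = FALSE,
        registration_status = "registered",
        rx_only = TRUE), args))
    })))
  }
  if (spec$n == 0) {
    return(product_profile("x", "x", "x",
                           dosage_form_class = "parenteral_or_topical",
                           application_instruction_count = 0)[0, ])
  }
  withr::with_seed(spec$seed, {
    rows <- lapply(seq_len(spec$n), function(i) {
      flags <- lapply(spec$answer_probabilities, function(p)
        stats::runif(1) < p)
      do.call(product_profile, c(list(
        product_id = sprintf("synth_%03d", i),
        brand_name = sprintf("SYNTH %03d", i),
        inn_name = sprintf("synthol-%03d", i),
        dosage_form_class = "parenteral_or_topical",
        application_instruction_count =
          sample(spec$instruction_count_range[1]:
                   spec$instruction_count_range[2], 1),
        registration_status = "registered",
        rx_only = stats::runif(1) < 0.5), flags))
    })
    dplyr::bind_rows(rows)
  })
}

#' Generate synthetic search ledgers
#'
#' Produces `spec$n` seeded ledgers of `spec$ledger_length` results.
#' Relevance is Bernoulli at `spec$relevance_rate` unless
#' `spec$force_relevant` pins the exact relevant-link count; prices on
#' relevant entries are log-uniform on `spec$price_distribution` unless
#' `spec$force_price` fixes them, so every availability and affordability
#' band is reachable.
#'
#' @param spec A [synthetic_spec()].
#' @return A named list of `search_ledger` objects.
#' @export
generate_ledgers <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, {
    out <- lapply(seq_len(spec$n), function(i) {
      m <- spec$ledger_length
      if (!is.null(spec$force_relevant)) {
        k <- min(spec$force_relevant, m)
        rel <- 1:m %in% sample(1:m, k)
      } else {
        rel <- stats::runif(m) < spec$relevance_rate
      }
      price <- rep(NA_real_, m)
      if (any(rel)) {
        price[rel] <- if (!is.null(spec$force_price)) {
          spec$force_price
        } else {
          round(exp(stats::runif(sum(rel),
                                 log(spec$price_distribution[1]),
                                 log(spec$price_distribution[2]))), 2)
        }
      }
      pid <- sprintf("synth_%03d", i)
      structure(list(
        product_id = pid,
        query = paste0("buy synthol-", sprintf("%03d", i)),
        engine = "synthetic",
        capture_date = NA_character_,
        entries = tibble::tibble(
          rank = 1:m,
          url = sprintf("https://%s%02d.example/%s",
                        ifelse(rel, "shop", "info"), 1:m, pid),
          is_relevant = rel,
          total_price = price,
          currency = ifelse(rel, "USD", NA_character_))
      ), class = "search_ledger")
    })
    stats::setNames(out, vapply(out, `[[`, character(1), "product_id"))
  })
}
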