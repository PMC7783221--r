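#' Complexity-of-application band
#'
#' Maps the number of application instructions in the SmPC/PIL onto the
#' three-point complexity scale: more than 10 instructions score 3, 5 to 10
#' score 2, fewer than 5 score 1.
#'
#' @param instruction_count Non-negative integer vector.
#' @return Integer vector of points in `{1, 2, 3}`.
#' @examples
#' complexity_band(c(0, 7, 12))
#' @export
complexity_band <- function(instruction_count) {
  if (any(is.na(instruction_count)) || any(instruction_count < 0) ||
      any(instruction_count != trunc(instruction_count)))
    stop("instruction count must be a non-negative integer", call. = FALSE)
  ifelse(instruction_count > 10, 3L,
         ifelse(instruction_count >= 5, 2L, 1L))
}

#' CIOMS local-ADR trigger
#'
#' A product's local adverse-reaction evidence satisfies the
#' systemic-absorption sub-dimension when at least one recorded reaction is
#' very common or common (CIOMS frequency bands), or severe at any frequency.
#'
#' @param adrs A list of [adr_record()] objects (possibly empty).
#' @return `TRUE` or `FALSE`.
#' @export
local_adr_trigger <- function(adrs) {
  if (length(adrs) == 0) return(FALSE)
  any(vapply(adrs, function(a) {
    a$frequency %in% c("very_common", "common") || a$severity == "severe"
  }, logical(1)))
}

dimension_score <- function(dimension_id, sub_scores, max_points) {
  structure(list(dimension_id = dimension_id,
                 sub_scores = sub_scores,
                 points = as.integer(sum(unlist(sub_scores))),
                 max_points = as.integer(max_points)),
            class = "dimension_score")
}

require_answers <- function(profile, fields, sub_id, strict) {
  missing <- fields[vapply(fields, function(f) {
    v <- profile[[f]]
    is.null(v) || length(v) != 1 || is.na(v)
  }, logical(1))]
  if (length(missing) > 0 && strict)
    stop("missing answer for sub-dimension ", sub_id, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  length(missing) == 0
}

#' Score the general pharmaceutical risk dimension
#'
#' Sub-dimension 1.1 awards 1 point to parenteral/topical or modified-release
#' dosage forms (0 for conventional oral); 1.2 adds the complexity band of
#' the instruction count. Maximum 4 points.
#'
#' @param profile A one-row profile tibble or named list.
#' @param strict Error on missing answers (default) instead of scoring 0.
#' @return A `dimension_score`.
#' @export
score_general <- function(profile, strict = TRUE) {
  p <- as_profile_row(profile)
  require_answers(p, "dosage_form_class", "1.1", strict)
  require_answers(p, "application_instruction_count", "1.2", strict)
  form_pt <- if (!is.null(p$dosage_form_class) && !is.na(p$dosage_form_class)) {
    if (p$dosage_form_class %in% c("parenteral_or_topical", "modified_release"))
      1L else 0L
  } else 0L
  cplx <- if (!is.null(p$application_instruction_count) &&
              !is.na(p$application_instruction_count))
    complexity_band(p$application_instruction_count) else 0L
  dimension_score("1", list(`1.1` = form_pt, `1.2` = cplx), 4L)
}

#' Score the therapeutic risk dimension
#'
#' Five yes/no sub-dimensions, 1 point each: systemic mode of action (2.1),
#' documented systemic ADR risk (2.2), indication for a damaged or inflamed
#' eye (2.3), narrow therapeutic index (2.4) and a pediatric indication below
#' 6 years (2.5). Sub-dimension 2.2 is also satisfied when the CIOMS
#' local-ADR trigger fires on the profile's `local_adrs` evidence (switch
#' off with `use_adr_evidence = FALSE`). Maximum 5 points.
#'
#' @inheritParams score_general
#' @param use_adr_evidence Allow [local_adr_trigger()] evidence to satisfy
#'   2.2 alongside the explicit flag.
#' @return A `dimension_score`.
#' @export
score_therapeutic <- function(profile, strict = TRUE, use_adr_evidence = TRUE) {
  p <- as_profile_row(profile)
  flag <- function(f, id) {
    require_answers(p, f, id, strict)
    isTRUE(p[[f]])
  }
  adrs <- p$local_adrs
  if (is.list(adrs) && length(adrs) == 1 && is.list(adrs[[1]]) &&
      !inherits(adrs[[1]], "adr_record"))
    adrs <- adrs[[1]]
  sys_adr <- flag("systemic_adr_documented", "2.2") ||
    (use_adr_evidence && local_adr_trigger(adrs %||% list()))
  dimension_score("2", list(
    `2.1` = as.integer(flag("mode_of_action_systemic", "2.1")),
    `2.2` = as.integer(sys_adr),
    `2.3` = as.integer(flag("indication_damaged_or_inflamed", "2.3")),
    `2.4` = as.integer(flag("narrow_therapeutic_index", "2.4")),
    `2.5` = as.integer(flag("pediatric_indication_under6", "2.5"))
  ), 5L)
}

#' Score the microbiological contamination risk dimension
#'
#' Sub-dimension 3.1 scores 1 unless the product is single-dose or has an
#' antimicrobial filter (either mitigation zeroes it); 3.2 scores 1 without
#' a preservative; 3.3 scores 1 unless the active ingredient is itself an
#' antibiotic. Maximum 3 points.
#'
#' @inheritParams score_general
#' @return A `dimension_score`.
#' @export
score_microbiological <- function(profile, strict = TRUE) {
  p <- as_profile_row(profile)
  require_answers(p, c("multi_dose", "antimicrobial_filter"), "3.1", strict)
  require_answers(p, "contains_preservative", "3.2", strict)
  require_answers(p, "api_is_antibiotic", "3.3", strict)
  s31 <- as.integer(isTRUE(p$multi_dose) && !isTRUE(p$antimicrobial_filter))
  s32 <- as.integer(!isTRUE(p$contains_preservative))
  s33 <- as.integer(!isTRUE(p$api_is_antibiotic))
  dimension_score("3", list(`3.1` = s31, `3.2` = s32, `3.3` = s33), 3L)
}

#' Score the augmented-demand (limited access) dimension
#'
#' 4.1 awards 1 point to products in documented shortage during the
#' evaluation period; 4.2 awards 1 point for documented misuse or abuse
#' potential. Prescription status is metadata and is not scored. Maximum 2
#' points.
#'
#' @inheritParams score_general
#' @return A `dimension_score`.
#' @export
score_access <- function(profile, strict = TRUE) {
  p <- as_profile_row(profile)
  require_answers(p, "in_shortage", "4.1", strict)
  require_answers(p, "misuse_potential", "4.2", strict)
  dimension_score("4", list(`4.1` = as.integer(isTRUE(p$in_shortage)),
                            `4.2` = as.integer(isTRUE(p$misuse_potential))), 2L)
}

#' Counterfeit-risk override decision
#'
#' A product is treated as potentially counterfeit — and its total safety
#' score overridden to the rubric's maximum — when the registry check finds
#' it unregistered, investigational, or withdrawn from the market. Only the
#' unregistered/unlicensed branch of the WHO counterfeit taxonomy can be
#' assessed before purchase; falsified and substandard status require the
#' physical product.
#'
#' @inheritParams score_general
#' @return A list with `override` (logical) and `reason` (character).
#' @export
assess_counterfeit <- function(profile, strict = TRUE) {
  p <- as_profile_row(profile)
  require_answers(p, "registration_status", "5.1", strict)
  status <- p$registration_status
  if (is.null(status) || is.na(status))
    return(list(override = FALSE, reason = "registration status unknown"))
  if (!status %in% c("registered", "unregistered", "investigational",
                     "withdrawn"))
    stop("unknown registration_status '", status, "'", call. = FALSE)
  if (status == "registered")
    list(override = FALSE, reason = "registered product")
  else
    list(override = TRUE, reason = paste0("registration status: ", status))
}

#' Score one product against the rubric
#'
#' Computes the four additive dimension scores, applies the counterfeit
#' override when triggered, divides the total by the rubric's weighted
#' divisor (clamping at 1 so banding stays on `[0, 1]`), and assigns the
#' severity category.
#'
#' @param profile A one-row profile tibble or named list.
#' @param rubric A `rubric_config`; defaults to the eye-drop rubric.
#' @param strict Error on missing answers. With `strict = FALSE` and an
#'   `impute` policy, gaps are filled uniformly with the low-risk
#'   (`"low"`) or high-risk (`"high"`) answer and the scorecard is marked
#'   imputed.
#' @param impute `"none"` (default), `"low"` or `"high"`.
#' @param use_adr_evidence Passed to [score_therapeutic()].
#' @return A `safety_scorecard`: product ref, per-dimension scores with
#'   sub-scores, `total`, `override_applied`, `weighted`,
#'   `severity_category`, `imputed`.
#' @examples
#' fx <- load_fixtures()
#' card <- score_product(fx$profiles[fx$profiles$product_id ==
#'                                     "dorzolamide_timolol", ])
#' card$total
#' @export
score_product <- function(profile, rubric = default_rubric(), strict = TRUE,
                          impute = c("none", "low", "high"),
                          use_adr_evidence = TRUE) {
  impute <- match.arg(impute)
  p <- as_profile_row(profile)
  imputed_fields <- character()
  if (impute != "none") {
    strict <- FALSE
    filled <- impute_profile(p, impute)
    imputed_fields <- filled$fields
    p <- filled$profile
  } else if (strict) {
    issues <- validate_profile(p, rubric)
    if (nrow(issues) > 0)
      stop("profile '", p$product_id %||% p$brand_name %||% "?",
           "' cannot be scored in strict mode:\n  ",
           paste(sprintf("[%s] %s: %s", issues$sub_dimension, issues$field,
                         issues$problem), collapse = "\n  "),
           call. = FALSE)
  }
  cf <- assess_counterfeit(p, strict = strict)
  dims <- list(
    score_general(p, strict = strict),
    score_therapeutic(p, strict = strict,
                      use_adr_evidence = use_adr_evidence),
    score_microbiological(p, strict = strict),
    score_access(p, strict = strict)
  )
  total <- if (cf$override) rubric$override_score
  else sum(vapply(dims, `[[`, integer(1), "points"))
  weighted <- min(total / rubric$weighted_divisor, 1.0)
  severity <- severity_band(weighted, rubric$severity_bands)
  structure(list(
    product_id = p$product_id %||% NA_character_,
    brand_name = p$brand_name %||% NA_character_,
    inn_name = p$inn_name %||% NA_character_,
    dimension_scores = dims,
    total = as.integer(total),
    override_applied = cf$override,
    override_reason = cf$reason,
    weighted = weighted,
    severity_category = severity,
    imputed = imputed_fields
  ), class = "safety_scorecard")
}

impute_profile <- function(p, direction) {
  low <- list(dosage_form_class = "conventional_oral",
              application_instruction_count = 0L,
              registration_status = "registered")
  high <- list(dosage_form_class = "parenteral_or_topical",
               application_instruction_count = 11L,
               registration_status = "registered")
  lgl_fields <- c("mode_of_action_systemic", "systemic_adr_documented",
                  "indication_damaged_or_inflamed", "narrow_therapeutic_index",
                  "pediatric_indication_under6", "multi_dose",
                  "contains_preservative", "api_is_antibiotic",
                  "in_shortage", "misuse_potential", "antimicrobial_filter")
  # in the rubric's direction of risk: preservative/antibiotic/filter
  # ABSENT is the risky state, so high-risk imputation sets them FALSE
  protective <- c("contains_preservative", "api_is_antibiotic",
                  "antimicrobial_filter")
  filled <- character()
  for (f in names(low)) {
    if (is.null(p[[f]]) || is.na(p[[f]])) {
      p[[f]] <- if (direction == "low") low[[f]] else high[[f]]
      filled <- c(filled, f)
    }
  }
  for (f in lgl_fields) {
    if (is.null(p[[f]]) || is.na(p[[f]])) {
      risky <- !(f %in% protective)
      p[[f]] <- if (direction == "high") risky else !risky
      filled <- c(filled, f)
    }
  }
  list(profile = p, fields = filled)
}

#' @export
print.safety_scorecard <- function(x, ...) {
  cat(sprintf("<safety_scorecard> %s (%s)\n", x$brand_name, x$inn_name))
  for (d in x$dimension_scores) {
    subs <- paste(sprintf("%s=%d", names(d$sub_scores),
                          unlist(d$sub_scores)), collapse = " ")
    cat(sprintf("  dim %s: %d/%d  [%s]\n", d$dimension_id, d$points,
                d$max_points, subs))
  }
  cat(sprintf("  total %d%s  weighted %.2f  severity %s\n", x$total,
              if (x$override_applied) " (counterfeit override)" else "",
              x$weighted, x$severity_category))
  if (length(x$imputed) > 0)
    cat("  imputed answers:", paste(x$imputed, collapse = ", "), "\n")
  invisible(x)
}

#' Score a table of product profiles
#'
#' Applies [score_product()] to each row and returns a tidy scorecard table.
#'
#' @param profiles A profile tibble (one row per product), e.g. from
#'   [read_profiles()] or [generate_profiles()].
#' @inheritParams score_product
#' @return A tibble with one row per product: identity columns, the four
#'   dimension points (`general`, `therapeutic`, `microbiological`,
#'   `access`), `total`, `override_applied`, `weighted`,
#'   `severity_category`, and a `scorecard` list-column holding the full
#'   `safety_scorecard` objects.
#' @export
score_products <- function(profiles, rubric = default_rubric(),
                           strict = TRUE, impute = c("none", "low", "high"),
                           use_adr_evidence = TRUE) {
  impute <- match.arg(impute)
  if (nrow(profiles) == 0)
    stop("no products to score", call. = FALSE)
  cards <- lapply(seq_len(nrow(profiles)), function(i)
    score_product(profiles[i, ], rubric = rubric, strict = strict,
                  impute = impute, use_adr_evidence = use_adr_evidence))
  dim_pts <- function(card, id) {
    for (d in card$dimension_scores) if (d$dimension_id == id)
      return(d$points)
    NA_integer_
  }
  tibble::tibble(
    product_id = vapply(cards, `[[`, character(1), "product_id"),
    brand_name = vapply(cards, `[[`, character(1), "brand_name"),
    inn_name = vapply(cards, `[[`, character(1), "inn_name"),
    general = vapply(cards, dim_pts, integer(1), id = "1"),
    therapeutic = vapply(cards, dim_pts, integer(1), id = "2"),
    microbiological = vapply(cards, dim_pts, integer(1), id = "3"),
    access = vapply(cards, dim_pts, integer(1), id = "4"),
    total = vapply(cards, `[[`, integer(1), "total"),
    override_applied = vapply(cards, `[[`, logical(1), "override_applied"),
    weighted = vapply(cards, `[[`, numeric(1), "weighted"),
    severity_category = vapply(cards, `[[`, character(1), "severity_category"),
    scorecard = cards
  )
}
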