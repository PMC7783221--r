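#' The default eye-drop patient-safety rubric
#'
#' Builds the scoring rubric for ophthalmic preparations: five dimensions
#' grouped into intrinsic risks (general pharmaceutical, therapeutic,
#' microbiological contamination), extrinsic risks (augmented demand for
#' online purchase) and the risk of counterfeiting, which does not score
#' additively but overrides the total when triggered.
#'
#' Scorable maxima are 4 (general), 5 (therapeutic), 3 (microbiological) and
#' 2 (augmented demand), so a non-counterfeit product scores at most 14; a
#' product flagged as potentially counterfeit (unregistered, investigational
#' or withdrawn) is assigned the override score of 15 outright. The weighted
#' score divides the total by 10 (the study's literal rule, kept separate
#' from the theoretical maximum of 15) and is clamped to 1 before banding.
#' Severity bands: low for weighted scores up to 0.25, high from 0.75
#' upward, medium in between.
#'
#' @return An object of class `rubric_config`.
#' @seealso [load_rubric()], [write_rubric()], [score_product()]
#' @examples
#' rb <- default_rubric()
#' vapply(rb$dimensions, function(d) d$max_points, integer(1))
#' @export
default_rubric <- function() {
  binary <- function(id, label, field) {
    list(id = id, label = label, answer_kind = "binary", fields = field,
         point_map = list(no = 0L, yes = 1L), max_points = 1L)
  }
  dims <- list(
    list(
      id = "1", label = "General pharmaceutical risk", group = "intrinsic",
      max_points = 4L,
      sub_rules = list(
        list(id = "1.1", label = "Dosage form", answer_kind = "enumerated",
             fields = "dosage_form_class",
             point_map = list(conventional_oral = 0L,
                              parenteral_or_topical = 1L,
                              modified_release = 1L),
             max_points = 1L),
        list(id = "1.2", label = "Complexity of application",
             answer_kind = "banded_count",
             fields = "application_instruction_count",
             bands = list(list(min = 0L, max = 4L, points = 1L),
                          list(min = 5L, max = 10L, points = 2L),
                          list(min = 11L, max = NULL, points = 3L)),
             max_points = 3L)
      )
    ),
    list(
      id = "2", label = "Therapeutic risk", group = "intrinsic",
      max_points = 5L,
      sub_rules = list(
        binary("2.1", "Mode of action", "mode_of_action_systemic"),
        binary("2.2", "Systemic absorption", "systemic_adr_documented"),
        binary("2.3", "Altered absorption (damaged or inflamed eye)",
               "indication_damaged_or_inflamed"),
        binary("2.4", "Narrow therapeutic index", "narrow_therapeutic_index"),
        binary("2.5", "Special patient group (pediatric < 6 y)",
               "pediatric_indication_under6")
      )
    ),
    list(
      id = "3", label = "Risk of microbiological contamination",
      group = "intrinsic", max_points = 3L,
      sub_rules = list(
        list(id = "3.1",
             label = "Single-dose vs. multi-dose or antimicrobial filter",
             answer_kind = "binary",
             fields = c("multi_dose", "antimicrobial_filter"),
             point_map = list(no = 0L, yes = 1L), max_points = 1L),
        binary("3.2", "Preservative content", "contains_preservative"),
        binary("3.3", "API is an antibiotic", "api_is_antibiotic")
      )
    ),
    list(
      id = "4", label = "Augmented demand for online purchase",
      group = "extrinsic", max_points = 2L,
      sub_rules = list(
        binary("4.1", "Limited access (drug shortage)", "in_shortage"),
        binary("4.2", "Misuse potential", "misuse_potential")
      )
    ),
    list(
      id = "5", label = "Risk of counterfeiting", group = "counterfeit",
      max_points = 0L,
      sub_rules = list(
        list(id = "5.1",
             label = "Unregistered, investigational or withdrawn product",
             answer_kind = "enumerated", fields = "registration_status",
             point_map = list(registered = 0L, unregistered = 1L,
                              investigational = 1L, withdrawn = 1L),
             max_points = 1L)
      )
    )
  )
  new_rubric_config(list(
    dimensions = dims,
    override_score = 15L,
    weighted_divisor = 10,
    severity_bands = list(low_max = 0.25, high_min = 0.75),
    theoretical_max = 15L
  ))
}

new_rubric_config <- function(x) {
  structure(x, class = "rubric_config")
}

#' @export
print.rubric_config <- function(x, ...) {
  cat("<rubric_config>\n")
  for (d in x$dimensions) {
    cat(sprintf("  %s. %s [%s, max %d]: %s\n", d$id, d$label, d$group,
                d$max_points,
                paste(vapply(d$sub_rules, `[[`, "", "id"), collapse = ", ")))
  }
  cat(sprintf("  override %d, divisor %s, bands low<=%s<medium<%s<=high\n",
              x$override_score, format(x$weighted_divisor),
              format(x$severity_bands$low_max),
              format(x$severity_bands$high_min)))
  invisible(x)
}

#' Serialize a rubric to JSON (canonical) or YAML
#'
#' @param rubric A `rubric_config`.
#' @param path Output file; its extension chooses the format (`.json`
#'   canonical, `.yml`/`.yaml` alternative). Omit to return the JSON string.
#' @return `path` invisibly, or the JSON string when `path` is `NULL`.
#' @export
write_rubric <- function(rubric, path = NULL) {
  stopifnot(inherits(rubric, "rubric_config"))
  x <- unclass(rubric)
  if (is.null(path)) {
    return(as.character(jsonlite::toJSON(x, auto_unbox = TRUE, null = "null",
                                         digits = NA, pretty = TRUE)))
  }
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path)
  } else {
    writeLines(as.character(jsonlite::toJSON(x, auto_unbox = TRUE,
                                             null = "null", digits = NA,
                                             pretty = TRUE)), path)
  }
  invisible(path)
}

#' Load and validate a rubric configuration
#'
#' Accepts a JSON (canonical) or YAML document describing the dimensions,
#' sub-dimension point rules, count bands, override score, weighted divisor
#' and severity bands. Every structural invariant is checked: point maps may
#' not exceed a rule's `max_points`, binary rules must map exactly
#' `no -> 0, yes -> 1`, count bands must be contiguous, non-overlapping and
#' cover all non-negative counts, a dimension's `max_points` must equal the
#' sum of its sub-rule maxima, and the override score must be at least the
#' sum of the non-counterfeit dimension maxima.
#'
#' @param path Path to a `.json`, `.yml` or `.yaml` document, or a literal
#'   JSON string.
#' @return A validated `rubric_config`.
#' @examples
#' p <- tempfile(fileext = ".json")
#' write_rubric(default_rubric(), p)
#' identical(load_rubric(p), default_rubric())
#' @export
load_rubric <- function(path) {
  if (length(path) == 1 && grepl("^\\s*\\{", path)) {
    x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    x <- yaml::read_yaml(path)
  } else {
    x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  validate_rubric(x)
}

validate_rubric <- function(x) {
  fail <- function(...) stop("rubric validation: ", sprintf(...), call. = FALSE)
  if (is.null(x$dimensions) || length(x$dimensions) == 0)
    fail("no dimensions defined")
  x$override_score <- as.integer(x$override_score %||% 15L)
  x$weighted_divisor <- as.numeric(x$weighted_divisor %||% 10)
  if (x$weighted_divisor <= 0) fail("weighted_divisor must be positive")
  x$theoretical_max <- as.integer(x$theoretical_max %||% x$override_score)
  bands <- x$severity_bands %||% list(low_max = 0.25, high_min = 0.75)
  if (is.null(bands$low_max) || is.null(bands$high_min) ||
      !(bands$low_max < bands$high_min))
    fail("severity_bands must give low_max < high_min")
  x$severity_bands <- list(low_max = as.numeric(bands$low_max),
                           high_min = as.numeric(bands$high_min))

  x$dimensions <- lapply(x$dimensions, function(d) {
    if (is.null(d$id) || is.null(d$group))
      fail("dimension missing id or group")
    if (!d$group %in% c("intrinsic", "extrinsic", "counterfeit"))
      fail("dimension %s: unknown group '%s'", d$id, d$group)
    d$max_points <- as.integer(d$max_points)
    d$sub_rules <- lapply(d$sub_rules, validate_sub_rule, fail = fail)
    sub_max <- sum(vapply(d$sub_rules, `[[`, integer(1), "max_points"))
    expected <- if (d$group == "counterfeit") d$max_points else sub_max
    if (d$group != "counterfeit" && d$max_points != sub_max)
      fail("dimension %s: max_points %d != sum of sub-rule maxima %d",
           d$id, d$max_points, sub_max)
    d
  })

  scorable <- sum(vapply(x$dimensions, function(d)
    if (d$group == "counterfeit") 0L else d$max_points, integer(1)))
  if (x$override_score < scorable)
    fail("override_score %d < sum of scorable dimension maxima %d",
         x$override_score, scorable)
  new_rubric_config(x[c("dimensions", "override_score", "weighted_divisor",
                        "severity_bands", "theoretical_max")])
}

validate_sub_rule <- function(r, fail) {
  if (is.null(r$id) || is.null(r$answer_kind))
    fail("sub-rule missing id or answer_kind")
  r$max_points <- as.integer(r$max_points)
  r$fields <- as.character(r$fields)
  if (r$answer_kind == "banded_count") {
    if (is.null(r$bands) || length(r$bands) == 0)
      fail("sub-rule %s: banded_count without bands", r$id)
    r$bands <- lapply(r$bands, function(b) {
      list(min = as.integer(b$min),
           max = if (is.null(b$max)) NULL else as.integer(b$max),
           points = as.integer(b$points))
    })
    mins <- vapply(r$bands, `[[`, integer(1), "min")
    r$bands <- r$bands[order(mins)]
    if (r$bands[[1]]$min != 0L)
      fail("sub-rule %s: bands do not start at 0", r$id)
    for (i in seq_along(r$bands)) {
      b <- r$bands[[i]]
      last <- i == length(r$bands)
      if (!last && is.null(b$max))
        fail("sub-rule %s: only the last band may be unbounded", r$id)
      if (last && !is.null(b$max))
        fail("sub-rule %s: bands do not cover all counts (gap above %d)",
             r$id, b$max)
      if (!last) {
        nxt <- r$bands[[i + 1]]
        if (nxt$min != b$max + 1L)
          fail("sub-rule %s: bands %d-%s and %d-%s are not contiguous",
               r$id, b$min, b$max, nxt$min, nxt$max %||% Inf)
      }
      if (b$points > r$max_points)
        fail("sub-rule %s: band points %d exceed max_points %d",
             r$id, b$points, r$max_points)
    }
  } else {
    pm <- lapply(r$point_map, as.integer)
    if (any(unlist(pm) < 0))
      fail("sub-rule %s: negative points in point_map", r$id)
    if (any(unlist(pm) > r$max_points))
      fail("sub-rule %s: point_map value exceeds max_points %d",
           r$id, r$max_points)
    if (r$answer_kind == "binary" &&
        !(setequal(names(pm), c("no", "yes")) &&
          pm$no == 0L && pm$yes == 1L))
      fail("sub-rule %s: binary rules must map exactly no->0, yes->1", r$id)
    r$point_map <- pm
  }
  r
}

#' Assign a severity or probability band to a weighted score
#'
#' Band semantics: `low` for scores at or below the lower boundary (0.25 by
#' default), `high` at or above the upper boundary (0.75), `medium` strictly
#' in between. These closed/open choices reproduce the study's own
#' classifications (0.25 is low, 0.5 medium, 1.0 high).
#'
#' @param score Numeric vector of weighted scores in `[0, 1]`.
#' @param bands A `severity_bands` list (`low_max`, `high_min`); defaults to
#'   the standard 0.25 / 0.75 boundaries.
#' @return Character vector in `{"low","medium","high"}`.
#' @export
severity_band <- function(score, bands = list(low_max = 0.25, high_min = 0.75)) {
  stopifnot(is.numeric(score), all(!is.na(score)))
  if (any(score < 0 | score > 1))
    stop("weighted score out of [0, 1]: ",
         paste(score[score < 0 | score > 1], collapse = ", "), call. = FALSE)
  dplyr::case_when(
    score <= bands$low_max ~ "low",
    score >= bands$high_min ~ "high",
    TRUE ~ "medium"
  )
}

#' Check a product profile against a rubric
#'
#' Returns one issue row per missing or malformed answer; an empty tibble
#' means the profile can be scored in strict mode. Counterfeit-group rules
#' are checked for presence of the registration status like any other field.
#'
#' @param profile A one-row profile tibble or a named list (see
#'   [product_profile()]).
#' @param rubric A `rubric_config`.
#' @return A tibble with columns `sub_dimension`, `field`, `problem`.
#' @export
validate_profile <- function(profile, rubric = default_rubric()) {
  profile <- as_profile_row(profile)
  issues <- list()
  push <- function(id, field, problem) {
    issues[[length(issues) + 1]] <<-
      tibble::tibble(sub_dimension = id, field = field, problem = problem)
  }
  for (d in rubric$dimensions) {
    for (r in d$sub_rules) {
      for (f in r$fields) {
        v <- profile[[f]]
        if (is.null(v) || length(v) != 1 || is.na(v)) {
          push(r$id, f, "missing answer")
          next
        }
        if (r$answer_kind == "binary" && !is.logical(v))
          push(r$id, f, "expected a yes/no (logical) answer")
        if (r$answer_kind == "banded_count") {
          if (!is.numeric(v) || v != trunc(v) || v < 0)
            push(r$id, f, "expected a non-negative integer count")
        }
        if (r$answer_kind == "enumerated" &&
            !as.character(v) %in% names(r$point_map))
          push(r$id, f, paste0("value '", v, "' not one of {",
                               paste(names(r$point_map), collapse = ", "), "}"))
      }
    }
  }
  if (length(issues) == 0) {
    tibble::tibble(sub_dimension = character(), field = character(),
                   problem = character())
  } else {
    dplyr::bind_rows(issues)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
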