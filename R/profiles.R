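#' Construct a product profile
#'
#' A product profile holds one medicinal product's identity plus every rubric
#' answer extracted from its Summary of Product Characteristics (SmPC),
#' Patient Information Leaflet (PIL) and registry checks. Yes/no answers are
#' logicals; `rx_only` is carried as metadata and never scored.
#'
#' @param product_id Stable identifier used to join profiles with search
#'   ledgers.
#' @param brand_name,inn_name Product brand name and active-ingredient (INN)
#'   name.
#' @param atc_code Optional ATC classification code.
#' @param dosage_form_class One of `"conventional_oral"`,
#'   `"parenteral_or_topical"`, `"modified_release"`.
#' @param application_instruction_count Number of application instructions in
#'   the SmPC/PIL (non-negative integer).
#' @param mode_of_action_systemic,systemic_adr_documented,
#'   indication_damaged_or_inflamed,narrow_therapeutic_index,
#'   pediatric_indication_under6 Therapeutic-risk answers (logical).
#' @param multi_dose,antimicrobial_filter,contains_preservative,
#'   api_is_antibiotic Microbiological-risk answers (logical).
#' @param in_shortage,misuse_potential Augmented-demand answers (logical).
#' @param registration_status One of `"registered"`, `"unregistered"`,
#'   `"investigational"`, `"withdrawn"`.
#' @param rx_only Prescription-only status (metadata, unscored).
#' @param local_adrs Optional list of local adverse-drug-reaction records,
#'   each built with [adr_record()]; evidence for the systemic-absorption
#'   sub-dimension via the CIOMS frequency trigger.
#' @return A one-row tibble with a `local_adrs` list-column.
#' @export
product_profile <- function(product_id, brand_name, inn_name,
                            atc_code = NA_character_,
                            dosage_form_class,
                            application_instruction_count,
                            mode_of_action_systemic = NA,
                            systemic_adr_documented = NA,
                            indication_damaged_or_inflamed = NA,
                            narrow_therapeutic_index = NA,
                            pediatric_indication_under6 = NA,
                            multi_dose = NA,
                            antimicrobial_filter = NA,
                            contains_preservative = NA,
                            api_is_antibiotic = NA,
                            in_shortage = NA,
                            misuse_potential = NA,
                            registration_status = "registered",
                            rx_only = NA,
                            local_adrs = list()) {
  if (!is.na(application_instruction_count) &&
      (application_instruction_count < 0 ||
       application_instruction_count != trunc(application_instruction_count)))
    stop("application_instruction_count must be a non-negative integer",
         call. = FALSE)
  tibble::tibble(
    product_id = as.character(product_id),
    brand_name = as.character(brand_name),
    inn_name = as.character(inn_name),
    atc_code = as.character(atc_code),
    dosage_form_class = as.character(dosage_form_class),
    application_instruction_count = as.integer(application_instruction_count),
    mode_of_action_systemic = as.logical(mode_of_action_systemic),
    systemic_adr_documented = as.logical(systemic_adr_documented),
    indication_damaged_or_inflamed = as.logical(indication_damaged_or_inflamed),
    narrow_therapeutic_index = as.logical(narrow_therapeutic_index),
    pediatric_indication_under6 = as.logical(pediatric_indication_under6),
    multi_dose = as.logical(multi_dose),
    antimicrobial_filter = as.logical(antimicrobial_filter),
    contains_preservative = as.logical(contains_preservative),
    api_is_antibiotic = as.logical(api_is_antibiotic),
    in_shortage = as.logical(in_shortage),
    misuse_potential = as.logical(misuse_potential),
    registration_status = as.character(registration_status),
    rx_only = as.logical(rx_only),
    local_adrs = list(local_adrs)
  )
}

#' Record a local adverse drug reaction
#'
#' Frequencies follow the CIOMS bands (very common >= 1/10 down to very rare
#' < 1/10,000, plus unknown); severity is a three-level judgment.
#'
#' @param term ADR term, e.g. `"ocular burning"`.
#' @param frequency One of `"very_common"`, `"common"`, `"uncommon"`,
#'   `"rare"`, `"very_rare"`, `"unknown"`.
#' @param severity One of `"minor"`, `"moderate"`, `"severe"`.
#' @return A named list of class `adr_record`.
#' @export
adr_record <- function(term, frequency, severity) {
  frequency <- match.arg(frequency, c("very_common", "common", "uncommon",
                                      "rare", "very_rare", "unknown"))
  severity <- match.arg(severity, c("minor", "moderate", "severe"))
  structure(list(term = as.character(term), frequency = frequency,
                 severity = severity), class = "adr_record")
}

#' Read product profiles from CSV or JSON
#'
#' CSV columns are named exactly as the profile fields with yes/no answers
#' encoded as `true`/`false`; the optional `local_adrs` column packs records
#' as `term|frequency|severity` separated by `;`. A JSON document is an array
#' of profile objects whose `local_adrs` are arrays of record objects.
#'
#' @param path A `.csv` or `.json` file.
#' @return A profile tibble, one row per product.
#' @export
read_profiles <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    return(dplyr::bind_rows(lapply(raw, function(p) {
      adrs <- lapply(p$local_adrs %||% list(), function(a)
        adr_record(a$term, a$frequency, a$severity))
      p$local_adrs <- NULL
      do.call(product_profile, c(p, list(local_adrs = adrs)))
    })))
  }
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  required <- c("product_id", "brand_name", "inn_name", "dosage_form_class",
                "application_instruction_count")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("profile CSV is missing required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  dplyr::bind_rows(lapply(seq_len(nrow(df)), function(i) {
    row <- as.list(df[i, ])
    adrs <- parse_adr_field(row$local_adrs %||% NA_character_)
    row$local_adrs <- NULL
    lgl <- c("mode_of_action_systemic", "systemic_adr_documented",
             "indication_damaged_or_inflamed", "narrow_therapeutic_index",
             "pediatric_indication_under6", "multi_dose",
             "antimicrobial_filter", "contains_preservative",
             "api_is_antibiotic", "in_shortage", "misuse_potential", "rx_only")
    for (f in intersect(lgl, names(row))) row[[f]] <- parse_yesno(row[[f]])
    row$application_instruction_count <-
      as.integer(row$application_instruction_count)
    do.call(product_profile, c(row, list(local_adrs = adrs)))
  }))
}

parse_yesno <- function(x) {
  if (is.na(x)) return(NA)
  v <- tolower(trimws(x))
  if (v %in% c("true", "yes", "1")) return(TRUE)
  if (v %in% c("false", "no", "0")) return(FALSE)
  stop("cannot parse yes/no value '", x, "'", call. = FALSE)
}

parse_adr_field <- function(x) {
  if (is.null(x) || is.na(x) || !nzchar(trimws(x))) return(list())
  lapply(strsplit(trimws(x), ";", fixed = TRUE)[[1]], function(rec) {
    parts <- strsplit(trimws(rec), "|", fixed = TRUE)[[1]]
    if (length(parts) != 3)
      stop("cannot parse local ADR record '", rec,
           "' (expected term|frequency|severity)", call. = FALSE)
    adr_record(parts[1], parts[2], parts[3])
  })
}

format_adr_field <- function(adrs) {
  if (length(adrs) == 0) return("")
  paste(vapply(adrs, function(a)
    paste(a$term, a$frequency, a$severity, sep = "|"), character(1)),
    collapse = ";")
}

as_profile_row <- function(profile) {
  if (is.data.frame(profile)) {
    if (nrow(profile) != 1)
      stop("expected a single profile row, got ", nrow(profile),
           call. = FALSE)
    return(as.list(profile))
  }
  as.list(profile)
}
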