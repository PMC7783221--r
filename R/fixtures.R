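#' Load the packaged ten-product ophthalmic fixture set
#'
#' The package ships a worked example of ten eye drops sold in Hungarian
#' community pharmacies (glaucoma, allergy, infection and diagnostic
#' products): one profile per product with every rubric answer, one
#' synthetic search ledger per product whose relevant-link counts and price
#' bands match the published market table, and the expected scores the
#' pipeline must reproduce. Profile flags that the source narrative does not
#' print literally are reconstructed to satisfy every printed constraint;
#' the provenance notes tag them.
#'
#' @return A `fixture_set` list: `profiles` (10-row tibble), `ledgers`
#'   (named list of 10 `search_ledger`s), `expected` (tibble of expected
#'   market columns and safety totals with a provenance tag per total), and
#'   `provenance` (notes on reconstructed fields and known conflicts).
#' @examples
#' fx <- load_fixtures()
#' nrow(fx$profiles)
#' @export
load_fixtures <- function() {
  path <- function(f) {
    p <- system.file("extdata", f, package = "pharmnetrisk")
    if (!nzchar(p) || !file.exists(p))
      stop("fixture file missing or corrupted: ", f, call. = FALSE)
    p
  }
  profiles <- read_profiles(path("eye_drop_profiles.csv"))
  ledgers <- parse_search_ledger(path("eye_drop_ledgers.csv"))
  expected <- readr::read_csv(path("eye_drop_expected.csv"),
                              show_col_types = FALSE)
  provenance <- jsonlite::fromJSON(path("eye_drop_provenance.json"),
                                   simplifyVector = TRUE)
  if (nrow(profiles) != 10 || length(ledgers) != 10 || nrow(expected) != 10)
    stop("fixture integrity error: expected 10 products in every file",
         call. = FALSE)
  if (!setequal(profiles$product_id, names(ledgers)) ||
      !setequal(profiles$product_id, expected$product_id))
    stop("fixture integrity error: product ids disagree across files",
         call. = FALSE)
  need <- c("relevant_links", "availability_point", "availability_category",
            "affordability_point", "affordability_category", "probability",
            "probability_category", "total", "total_provenance")
  if (!all(need %in% names(expected)))
    stop("fixture integrity error: expected-value table is missing columns: ",
         paste(setdiff(need, names(expected)), collapse = ", "),
         call. = FALSE)
  structure(list(profiles = profiles,
                 ledgers = ledgers[profiles$product_id],
                 expected = expected,
                 provenance = provenance),
            class = "fixture_set")
}

#' @export
print.fixture_set <- function(x, ...) {
  cat(sprintf("<fixture_set> %d products: %s\n", nrow(x$profiles),
              paste(x$profiles$inn_name, collapse = ", ")))
  invisible(x)
}

#' Export the packaged fixtures for user modification
#'
#' Copies the fixture CSV/JSON files into a directory so they can serve as
#' editable templates for new product sets.
#'
#' @param dir Target directory (created if needed).
#' @return The paths of the copied files, invisibly.
#' @export
export_fixtures <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c("eye_drop_profiles.csv", "eye_drop_ledgers.csv",
             "eye_drop_expected.csv", "eye_drop_provenance.json")
  out <- vapply(files, function(f) {
    src <- system.file("extdata", f, package = "pharmnetrisk")
    dst <- file.path(dir, f)
    file.copy(src, dst, overwrite = TRUE)
    dst
  }, character(1))
  invisible(out)
}
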