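#' Parse a search-result ledger from CSV
#'
#' A ledger records the manually reviewed results of one consumer-style
#' search (query "buy" + INN) for one product: rank, URL, a relevance
#' judgment (does the site offer the product directly to patients), and the
#' total price including shipping where observed. Relevance is an input
#' judgment, not computed; the package never queries a live search engine.
#'
#' @param path CSV file with columns `product_id`, `query`, `engine`,
#'   `capture_date`, `rank`, `url`, `is_relevant`, `total_price`,
#'   `currency` (the first four may be constant per product).
#' @return A list of `search_ledger` objects, one per `product_id`, each
#'   with `product_id`, `query`, `engine`, `capture_date` and an `entries`
#'   tibble sorted by rank. A single-product file yields a list of one.
#' @export
parse_search_ledger <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  required <- c("rank", "url", "is_relevant")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("ledger CSV is missing required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!"product_id" %in% names(df)) df$product_id <- "product"
  if (!"total_price" %in% names(df)) df$total_price <- NA_character_
  if (!"currency" %in% names(df)) df$currency <- NA_character_

  df$rank <- suppressWarnings(as.integer(df$rank))
  if (any(is.na(df$rank)) && nrow(df) > 0)
    stop("ledger has unparseable rank values", call. = FALSE)
  price_num <- suppressWarnings(as.numeric(df$total_price))
  bad <- which(!is.na(df$total_price) & nzchar(df$total_price) &
                 is.na(price_num))
  if (length(bad) > 0)
    stop("unparseable price at ledger row(s) ",
         paste(bad, collapse = ", "), ": ",
         paste(unique(df$total_price[bad]), collapse = ", "), call. = FALSE)
  df$total_price <- price_num
  if (any(!is.na(price_num) & price_num < 0))
    stop("negative price in ledger", call. = FALSE)
  df$is_relevant <- vapply(df$is_relevant, parse_yesno, logical(1),
                           USE.NAMES = FALSE)

  cur <- unique(stats::na.omit(df$currency[df$is_relevant &
                                             !is.na(df$total_price)]))
  if (length(cur) > 1)
    stop("mixed currencies in ledger: ", paste(cur, collapse = ", "),
         "; convert to a single currency first", call. = FALSE)

  lapply(split(df, df$product_id), function(sub) {
    if (anyDuplicated(sub$rank))
      stop("duplicate rank(s) in ledger for product '", sub$product_id[1],
           "': ", paste(unique(sub$rank[duplicated(sub$rank)]),
                        collapse = ", "), call. = FALSE)
    sub <- sub[order(sub$rank), ]
    structure(list(
      product_id = sub$product_id[1],
      query = if ("query" %in% names(sub)) sub$query[1] else NA_character_,
      engine = if ("engine" %in% names(sub)) sub$engine[1] else NA_character_,
      capture_date = if ("capture_date" %in% names(sub))
        sub$capture_date[1] else NA_character_,
      entries = tibble::as_tibble(sub[, c("rank", "url", "is_relevant",
                                          "total_price", "currency")])
    ), class = "search_ledger")
  })
}

#' @export
print.search_ledger <- function(x, ...) {
  cat(sprintf("<search_ledger> %s: %d entries, %d relevant (query '%s')\n",
              x$product_id, nrow(x$entries), sum(x$entries$is_relevant),
              x$query))
  invisible(x)
}

#' Count relevant links within the top search results
#'
#' @param ledger A `search_ledger`.
#' @param top_n How many leading results to consider (default 50, the
#'   documented review depth).
#' @return Integer count of relevant entries with rank at most `top_n`.
#' @export
count_relevant_links <- function(ledger, top_n = 50) {
  stopifnot(inherits(ledger, "search_ledger"), top_n >= 1)
  sum(ledger$entries$is_relevant & ledger$entries$rank <= top_n)
}

#' Availability point
#'
#' The availability point expresses the relevant-link count as a proportion
#' of the highest count observed for any product in the study (20 in the
#' reference data set). It is informational: the probability product uses
#' the availability *category*, not this proportion, and the value is not
#' clamped at 1.
#'
#' @param relevant_links Non-negative integer vector.
#' @param reference_max Positive reference count (default 20).
#' @return Numeric vector `relevant_links / reference_max`.
#' @export
availability_point <- function(relevant_links, reference_max = 20) {
  if (reference_max <= 0)
    stop("reference_max must be positive", call. = FALSE)
  if (any(relevant_links < 0))
    stop("relevant_links must be non-negative", call. = FALSE)
  relevant_links / reference_max
}

#' Availability category
#'
#' High accessibility (1) from 15 relevant links upward, medium (0.5) for 5
#' to 14 links, low (0.25) below 5.
#'
#' @param relevant_links Non-negative integer vector.
#' @return Numeric vector in `{1, 0.5, 0.25}`.
#' @export
availability_category <- function(relevant_links) {
  if (any(relevant_links < 0))
    stop("relevant_links must be non-negative", call. = FALSE)
  ifelse(relevant_links >= 15, 1,
         ifelse(relevant_links >= 5, 0.5, 0.25))
}

#' Affordability point and category
#'
#' Prices below $25 earn point 1 (category 1, low price range), prices from
#' $25 to $50 inclusive earn 0.5 (category 0.5, medium range), prices above
#' $50 earn 0 points but category 0.25 (high range). The point and category
#' diverge only in the top price band; the probability product uses the
#' category. Thresholds default to the study's, which anchored them at 5%
#' and 10% of the 2018 Hungarian minimum wage; both boundaries fall in the
#' middle band.
#'
#' @param price Non-negative price vector (single currency, shipping
#'   included).
#' @param thresholds Length-2 numeric, lower and upper band boundary.
#' @return A tibble with columns `price`, `affordability_point`,
#'   `affordability_category`.
#' @export
affordability <- function(price, thresholds = c(25, 50)) {
  stopifnot(length(thresholds) == 2, thresholds[1] < thresholds[2])
  if (any(is.na(price)) || any(price < 0))
    stop("price must be non-negative and known", call. = FALSE)
  point <- ifelse(price < thresholds[1], 1,
                  ifelse(price <= thresholds[2], 0.5, 0))
  category <- ifelse(price < thresholds[1], 1,
                     ifelse(price <= thresholds[2], 0.5, 0.25))
  tibble::tibble(price = price, affordability_point = point,
                 affordability_category = category)
}

#' Probability of online purchase
#'
#' The product of the availability and affordability categories. With both
#' factors in `{1, 0.5, 0.25}` the probability is always one of
#' `{1, 0.5, 0.25, 0.125, 0.0625}`.
#'
#' @param availability_category,affordability_category Values in
#'   `{1, 0.5, 0.25}`.
#' @return Their product.
#' @export
probability_score <- function(availability_category, affordability_category) {
  ok <- function(x) all(x %in% c(1, 0.5, 0.25))
  if (!ok(availability_category) || !ok(affordability_category))
    stop("categories must be in {1, 0.5, 0.25}", call. = FALSE)
  availability_category * affordability_category
}

#' Probability category
#'
#' Same banding as the severity side: low up to 0.25, high from 0.75,
#' medium in between.
#'
#' @param score Numeric vector in `[0, 1]`.
#' @return Character vector in `{"low","medium","high"}`.
#' @export
probability_category <- function(score) {
  severity_band(score)
}

#' Full market score for one ledger
#'
#' Counts relevant links in the top `top_n` results, derives the
#' availability point and category, takes the mean total price over priced
#' relevant entries within `top_n` as the representative price (or an
#' explicit `price_override`), bands affordability, and multiplies the two
#' categories into the probability of online purchase.
#'
#' @param ledger A `search_ledger`.
#' @param top_n Review depth (default 50).
#' @param reference_max Reference link count for the availability point
#'   (default 20).
#' @param price_thresholds Affordability band boundaries (default $25/$50).
#' @param price_override Optional explicit representative price, required
#'   when no relevant entry carries a price.
#' @return A one-row tibble: `product_id`, `relevant_links`,
#'   `availability_point`, `availability_category`, `representative_price`,
#'   `affordability_point`, `affordability_category`, `probability`,
#'   `probability_category`.
#' @examples
#' fx <- load_fixtures()
#' market_score(fx$ledgers[["dorzolamide_timolol"]])
#' @export
market_score <- function(ledger, top_n = 50, reference_max = 20,
                         price_thresholds = c(25, 50),
                         price_override = NULL) {
  stopifnot(inherits(ledger, "search_ledger"))
  n_rel <- count_relevant_links(ledger, top_n = top_n)
  avail_pt <- availability_point(n_rel, reference_max)
  avail_cat <- availability_category(n_rel)
  if (!is.null(price_override)) {
    price <- as.numeric(price_override)
  } else {
    e <- ledger$entries
    priced <- e$is_relevant & e$rank <= top_n & !is.na(e$total_price)
    if (!any(priced))
      stop("affordability unavailable for product '", ledger$product_id,
           "': no priced relevant entry within the top ", top_n,
           " results and no price override given", call. = FALSE)
    price <- mean(e$total_price[priced])
  }
  aff <- affordability(price, price_thresholds)
  prob <- probability_score(avail_cat, aff$affordability_category)
  tibble::tibble(
    product_id = ledger$product_id,
    relevant_links = n_rel,
    availability_point = avail_pt,
    availability_category = avail_cat,
    representative_price = price,
    affordability_point = aff$affordability_point,
    affordability_category = aff$affordability_category,
    probability = prob,
    probability_category = probability_category(prob)
  )
}

#' Market scores for a set of ledgers
#'
#' @param ledgers A list of `search_ledger` objects (e.g. from
#'   [parse_search_ledger()] or [load_fixtures()]).
#' @inheritParams market_score
#' @param price_overrides Optional named numeric vector of representative
#'   prices keyed by `product_id`.
#' @return A tibble with one [market_score()] row per ledger.
#' @export
market_scores <- function(ledgers, top_n = 50, reference_max = 20,
                          price_thresholds = c(25, 50),
                          price_overrides = NULL) {
  dplyr::bind_rows(lapply(ledgers, function(l) {
    ov <- if (!is.null(price_overrides) &&
              l$product_id %in% names(price_overrides))
      price_overrides[[l$product_id]] else NULL
    market_score(l, top_n = top_n, reference_max = reference_max,
                 price_thresholds = price_thresholds, price_override = ov)
  }))
}
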