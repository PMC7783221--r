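category_levels <- c("low", "medium", "high")

#' Risk-matrix cell for a severity/probability pair
#'
#' The matrix is the 3x3 grid of severity band x probability band; the
#' (high, high) cell is the maximal cell. Cells are ordered pairs:
#' (medium, low) and (low, medium) are distinct.
#'
#' @param severity_category,probability_category Values in
#'   `{"low","medium","high"}`.
#' @return Character vector `"severity:probability"`.
#' @export
matrix_cell <- function(severity_category, probability_category) {
  stopifnot(all(severity_category %in% category_levels),
            all(probability_category %in% category_levels))
  paste(severity_category, probability_category, sep = ":")
}

#' Rank products by combined patient-safety and market risk
#'
#' Joins a scorecard table with a market-score table by `product_id` and
#' sorts by (weighted severity score desc, probability desc, relevant links
#' desc, brand name asc). The alphabetical tie-break makes the ranking a
#' deterministic total order; `priority_score` (weighted severity x
#' probability) is attached as a convenience scalar beyond the published
#' method.
#'
#' @param scorecards A tibble from [score_products()].
#' @param market A tibble from [market_scores()].
#' @return A tibble of risk assessments, one row per product, ranked 1..n,
#'   with `matrix_cell`, `priority_score` and a `test_purchase_candidate`
#'   flag under the default "max-both" policy.
#' @examples
#' fx <- load_fixtures()
#' ranked <- rank_products(score_products(fx$profiles),
#'                         market_scores(fx$ledgers))
#' ranked$product_id[1]
#' @export
rank_products <- function(scorecards, market) {
  missing_market <- setdiff(scorecards$product_id, market$product_id)
  missing_cards <- setdiff(market$product_id, scorecards$product_id)
  if (length(missing_market) > 0 || length(missing_cards) > 0)
    stop("cannot join scorecards and market scores; unmatched product ids: ",
         paste(c(missing_market, missing_cards), collapse = ", "),
         call. = FALSE)
  joined <- dplyr::inner_join(
    dplyr::select(scorecards, "product_id", "brand_name", "inn_name",
                  "total", "override_applied", "weighted",
                  "severity_category"),
    dplyr::select(market, "product_id", "relevant_links",
                  "availability_category", "affordability_category",
                  "probability", "probability_category"),
    by = "product_id")
  joined <- dplyr::arrange(joined,
                           dplyr::desc(.data$weighted),
                           dplyr::desc(.data$probability),
                           dplyr::desc(.data$relevant_links),
                           .data$brand_name)
  joined$matrix_cell <- matrix_cell(joined$severity_category,
                                    joined$probability_category)
  joined$priority_score <- joined$weighted * joined$probability
  joined$rank <- seq_len(nrow(joined))
  candidates <- select_candidates(joined, policy = "max_both")
  joined$test_purchase_candidate <-
    joined$product_id %in% candidates$product_id
  joined
}

#' Select test-purchase candidates from ranked assessments
#'
#' Policies: `"max_both"` (default) keeps the products whose severity and
#' probability categories both equal the maximum category present in the
#' set; `"top_k"` keeps the `k` best-ranked products; `"cell_threshold"`
#' keeps products at or above a minimum severity and probability category.
#'
#' @param assessments A ranked tibble from [rank_products()].
#' @param policy `"max_both"`, `"top_k"` or `"cell_threshold"`.
#' @param k Number of products for `"top_k"`.
#' @param min_severity,min_probability Minimum categories for
#'   `"cell_threshold"`.
#' @return The selected subset of `assessments` (possibly empty).
#' @export
select_candidates <- function(assessments,
                              policy = c("max_both", "top_k",
                                         "cell_threshold"),
                              k = 1,
                              min_severity = "high",
                              min_probability = "high") {
  policy <- match.arg(policy)
  if (nrow(assessments) == 0) return(assessments)
  lev <- function(x) match(x, category_levels)
  switch(policy,
    max_both = {
      max_sev <- max(lev(assessments$severity_category))
      max_prob <- max(lev(assessments$probability_category))
      assessments[lev(assessments$severity_category) == max_sev &
                    lev(assessments$probability_category) == max_prob, ]
    },
    top_k = {
      stopifnot(k >= 1)
      ord <- if ("rank" %in% names(assessments))
        order(assessments$rank) else seq_len(nrow(assessments))
      assessments[ord[seq_len(min(k, nrow(assessments)))], ]
    },
    cell_threshold = {
      assessments[lev(assessments$severity_category) >= lev(min_severity) &
                    lev(assessments$probability_category) >=
                      lev(min_probability), ]
    }
  )
}

#' Render assessments as a Markdown table
#'
#' @param assessments A tibble from [rank_products()].
#' @return A character vector of Markdown lines.
#' @export
render_assessment_table <- function(assessments) {
  cols <- c("rank", "brand_name", "inn_name", "total", "weighted",
            "severity_category", "probability", "probability_category",
            "matrix_cell", "test_purchase_candidate")
  cols <- intersect(cols, names(assessments))
  df <- assessments[, cols]
  fmt <- vapply(seq_len(nrow(df)), function(i)
    paste0("| ", paste(vapply(df[i, ], function(v)
      format(v, trim = TRUE), character(1)), collapse = " | "), " |"),
    character(1))
  c(paste0("| ", paste(cols, collapse = " | "), " |"),
    paste0("|", paste(rep("---", length(cols)), collapse = "|"), "|"),
    fmt)
}

#' Plot the 3x3 risk matrix
#'
#' Places each product in its severity x probability cell; cells are shaded
#' by the combined level of the two bands.
#'
#' @param assessments A tibble from [rank_products()].
#' @return A ggplot object.
#' @export
plot_risk_matrix <- function(assessments) {
  grid <- tidyr::expand_grid(severity = factor(category_levels,
                                               levels = category_levels),
                             probability = factor(category_levels,
                                                  levels = category_levels))
  grid$level <- as.integer(grid$severity) + as.integer(grid$probability)
  pts <- assessments
  pts$severity <- factor(pts$severity_category, levels = category_levels)
  pts$probability <- factor(pts$probability_category,
                            levels = category_levels)
  lab <- dplyr::summarise(
    dplyr::group_by(pts, .data$severity, .data$probability),
    label = paste(.data$inn_name, collapse = "\n"), .groups = "drop")
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$probability,
                                     y = .data$severity)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$level), color = "grey30",
                       show.legend = FALSE) +
    ggplot2::scale_fill_gradient(low = "#cfe8cf", high = "#e06666") +
    ggplot2::geom_text(data = lab, ggplot2::aes(label = .data$label),
                       size = 3) +
    ggplot2::labs(x = "Probability of online purchase",
                  y = "Patient-safety severity",
                  title = "Severity x probability risk matrix") +
    ggplot2::theme_minimal()
}
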