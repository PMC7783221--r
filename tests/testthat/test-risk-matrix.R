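fixture_assessments <- function() {
  fx <- load_fixtures()
  rank_products(score_products(fx$profiles), market_scores(fx$ledgers))
}

test_that("matrix cells are ordered pairs on the 3x3 grid", {
  expect_equal(matrix_cell("high", "high"), "high:high")
  expect_equal(matrix_cell("low", "low"), "low:low")
  expect_false(matrix_cell("medium", "low") == matrix_cell("low", "medium"))
  expect_error(matrix_cell("extreme", "low"))
})

test_that("ranking joins, sorts deterministically and attaches priority", {
  ranked <- fixture_assessments()
  expect_equal(ranked$rank, 1:10)
  expect_equal(ranked$product_id[1], "dorzolamide_timolol")
  expect_equal(ranked$product_id[2], "cyclopentolate")
  expect_equal(ranked$priority_score,
               ranked$weighted * ranked$probability)
  # stable under permutation of input order
  fx <- load_fixtures()
  perm <- withr::with_seed(99, sample(1:10))
  ranked2 <- rank_products(score_products(fx$profiles[perm, ]),
                           market_scores(fx$ledgers))
  expect_equal(ranked2$product_id, ranked$product_id)

  # tie-breaks: probability, then links, then brand name
  expect_lt(which(ranked$product_id == "betaxolol"),
            which(ranked$product_id == "latanoprost_timolol"))
  expect_lt(which(ranked$product_id == "antazoline_tetryzoline"),
            which(ranked$product_id == "tetryzoline"))
})

test_that("unmatched product ids produce a join error naming them", {
  fx <- load_fixtures()
  cards <- score_products(fx$profiles)
  market <- market_scores(fx$ledgers[-1])
  expect_error(rank_products(cards, market), "betaxolol")
})

test_that("single product ranks first and alphabetical tie-break holds", {
  cards <- score_products(minimal_profile())
  market <- tibble::tibble(product_id = "p", relevant_links = 4L,
                           availability_category = 0.25,
                           affordability_category = 1, probability = 0.25,
                           probability_category = "low")
  ranked <- rank_products(cards, market)
  expect_equal(ranked$rank, 1L)

  two <- dplyr::bind_rows(
    minimal_profile(product_id = "b", brand_name = "ZETA"),
    minimal_profile(product_id = "a", brand_name = "ALPHA"))
  market2 <- tibble::tibble(product_id = c("b", "a"), relevant_links = 4L,
                            availability_category = 0.25,
                            affordability_category = 1, probability = 0.25,
                            probability_category = "low")
  ranked2 <- rank_products(score_products(two), market2)
  expect_equal(ranked2$brand_name, c("ALPHA", "ZETA"))
})

test_that("candidate selection policies behave as documented", {
  ranked <- fixture_assessments()
  maxboth <- select_candidates(ranked, policy = "max_both")
  expect_equal(maxboth$product_id, "dorzolamide_timolol")

  top2 <- select_candidates(ranked, policy = "top_k", k = 2)
  expect_equal(top2$product_id, c("dorzolamide_timolol", "cyclopentolate"))

  cell <- select_candidates(ranked, policy = "cell_threshold",
                            min_severity = "high", min_probability = "low")
  expect_setequal(cell$product_id, c("dorzolamide_timolol",
                                     "cyclopentolate"))

  empty <- ranked[0, ]
  expect_equal(nrow(select_candidates(empty)), 0)

  # max-both is never empty on non-empty input
  sub <- ranked[ranked$probability_category == "low", ]
  expect_gt(nrow(select_candidates(sub, policy = "max_both")), 0)
})

test_that("markdown table and matrix plot render", {
  ranked <- fixture_assessments()
  md <- render_assessment_table(ranked)
  expect_equal(length(md), nrow(ranked) + 2)
  expect_match(md[1], "rank \\| brand_name")
  p <- plot_risk_matrix(ranked)
  expect_s3_class(p, "ggplot")
})
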