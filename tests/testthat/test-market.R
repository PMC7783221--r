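test_that("ledger CSVs parse, sort, and reject malformed input", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("product_id,rank,url,is_relevant,total_price,currency",
               "a,3,https://x.example/1,true,12.5,USD",
               "a,1,https://x.example/2,false,,",
               "a,2,https://x.example/3,true,20,USD"), p)
  led <- parse_search_ledger(p)[["a"]]
  expect_s3_class(led, "search_ledger")
  expect_equal(led$entries$rank, 1:3)
  expect_equal(count_relevant_links(led), 2L)

  writeLines(c("product_id,rank,url,is_relevant",
               "a,3,u1,true", "a,3,u2,false"), p)
  expect_error(parse_search_ledger(p), "duplicate rank")

  writeLines(c("product_id,rank,url,is_relevant,total_price",
               "a,1,u1,true,cheap"), p)
  expect_error(parse_search_ledger(p), "row\\(s\\) 1")

  writeLines(c("product_id,rank,url,is_relevant,total_price,currency",
               "a,1,u1,true,10,USD", "a,2,u2,true,10,EUR"), p)
  expect_error(parse_search_ledger(p), "mixed currencies")

  writeLines("product_id,rank,url,is_relevant", p)
  expect_equal(length(parse_search_ledger(p)), 0L)
})

test_that("relevant links are counted within the review depth", {
  led <- make_ledger(relevant_ranks = c(2, 10, 30, 49), prices = 20)
  expect_equal(count_relevant_links(led), 4L)
  expect_equal(count_relevant_links(led, top_n = 20), 2L)
  deep <- make_ledger(relevant_ranks = c(45, 50), prices = 20)
  expect_equal(count_relevant_links(deep, top_n = 40), 0L)
  expect_equal(count_relevant_links(make_ledger()), 0L)
})

test_that("availability point is the proportion of the reference maximum", {
  expect_equal(availability_point(11), 0.55)
  expect_equal(availability_point(0), 0)
  expect_equal(availability_point(20), 1)
  expect_equal(availability_point(25), 1.25)  # informational, unclamped
  expect_error(availability_point(3, reference_max = 0), "positive")
})

test_that("availability categories band at 5 and 15 links", {
  expect_equal(availability_category(15), 1)
  expect_equal(availability_category(11), 0.5)
  expect_equal(availability_category(4), 0.25)
  expect_equal(availability_category(c(0, 4, 5, 14, 15, 40)),
               c(0.25, 0.25, 0.5, 0.5, 1, 1))
})

test_that("affordability bands prices at $25 and $50, boundaries inclusive", {
  a <- affordability(c(20, 60, 25, 50, 24.99, 50.01))
  expect_equal(a$affordability_point, c(1, 0, 0.5, 0.5, 1, 0))
  expect_equal(a$affordability_category, c(1, 0.25, 0.5, 0.5, 1, 0.25))
  # band oracle over a fine price grid
  grid <- seq(0, 100, by = 0.25)
  expect_equal(affordability(grid)$affordability_category,
               oracle_affordability_category(grid))
  expect_error(affordability(-1), "non-negative")
})

test_that("probability is the product of categories with closed range", {
  expect_equal(probability_score(0.25, 0.25), 0.0625)
  expect_equal(probability_score(1, 1), 1)
  expect_equal(probability_score(0.25, 0.5), 0.125)
  expect_error(probability_score(0.75, 1), "categories")

  tab <- oracle_probability_table()
  got <- probability_score(tab$avail, tab$afford)
  expect_equal(got, tab$prob)
  expect_true(all(got %in% c(1, 0.5, 0.25, 0.125, 0.0625)))
  expect_equal(probability_category(got), tab$band)
})

test_that("market_score assembles the full row and mean price policy", {
  led <- make_ledger(relevant_ranks = c(1, 5, 9), prices = c(10, 20, 30))
  ms <- market_score(led)
  expect_equal(ms$relevant_links, 3L)
  expect_equal(ms$representative_price, 20)
  expect_equal(ms$availability_category, 0.25)
  expect_equal(ms$affordability_category, 1)
  expect_equal(ms$probability, 0.25)
  expect_equal(ms$probability_category, "low")

  # price outside top_n is excluded from the mean
  ms2 <- market_score(led, top_n = 6)
  expect_equal(ms2$representative_price, 15)

  bare <- make_ledger(relevant_ranks = 3, prices = NA_real_)
  expect_error(market_score(bare), "affordability unavailable")
  ms3 <- market_score(bare, price_override = 10)
  expect_equal(ms3$probability, 0.25)
  expect_equal(ms3$probability_category, "low")

  none <- make_ledger()
  ms4 <- market_score(none, price_override = 10)
  expect_equal(ms4$availability_category, 0.25)
  expect_equal(ms4$probability, 0.25)
})

test_that("market monotonicity: links help, price hurts", {
  for (k in c(0, 3, 7, 14, 19)) {
    expect_gte(availability_point(k + 1), availability_point(k))
    expect_gte(availability_category(k + 1), availability_category(k))
  }
  prices <- seq(1, 99, by = 1)
  cats <- affordability(prices)$affordability_category
  expect_true(all(diff(cats) <= 0))
})
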