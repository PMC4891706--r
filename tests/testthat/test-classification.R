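test_that("line summaries take replicate medians", {
  m <- tibble::tibble(line_id = c("a", "a", "a", "b", "b", "b", "b"),
                      max_mean_distance = c(0.2, 0.4, 0.9, 0.1, 0.2, 0.3, 0.4),
                      pct_dead = c(10, 0, 20, 0, 20, 40, 100))
  s <- summarize_lines(m)
  expect_equal(s$median_max_mean_distance[s$line_id == "a"], 0.4)
  expect_equal(s$median_pct_dead[s$line_id == "b"], 30) # even-n: mean of pair
  expect_warning(summarize_lines(tibble::tibble(
    line_id = "x", max_mean_distance = 0.5, pct_dead = 0)),
    "fewer than 3")
  expect_error(summarize_lines(m[0, ]), class = "ringgap_error_validation")
})

test_that("boundaries are interpolated population percentiles", {
  s <- tibble::tibble(line_id = sprintf("l%03d", 1:100),
                      median_max_mean_distance = seq(0.01, 1, by = 0.01),
                      median_pct_dead = seq(0.5, 50, by = 0.5))
  b <- compute_boundaries(s)
  expect_equal(b$x_low, 0.109)
  expect_equal(b$x_high, 0.901)
  expect_equal(b$y_high, 45.05)
  # identical lines collapse the band
  same <- dplyr::mutate(s, median_max_mean_distance = 0.5)
  b2 <- compute_boundaries(same)
  expect_equal(b2$x_low, b2$x_high)
  expect_error(compute_boundaries(s[1:9, ]),
               class = "ringgap_error_validation")
})

test_that("the decision ladder assigns every region its category", {
  b <- structure(list(x_low = 0.3, x_high = 0.7, y_high = 40, n_lines = 10),
                 class = "screen_boundaries")
  cases <- tibble::tibble(
    line_id = as.character(1:7),
    median_max_mean_distance = c(0.2, 0.2, 0.8, 0.8, 0.5, 0.5, 0.3),
    median_pct_dead = c(10, 50, 50, 10, 50, 10, 10))
  got <- classify_lines(cases, b)$category
  expect_equal(as.character(got),
               c("overcautious", "very_clumsy", "overeager", "super_climber",
                 "clumsy", "normal", "overcautious")) # x == x_low inclusive
  # exactly one category each, partition property
  expect_false(any(is.na(got)))
})

test_that("census percentages are a partition summing to 100", {
  withr::with_seed(99, {
    s <- tibble::tibble(line_id = sprintf("l%03d", 1:200),
                        median_max_mean_distance = stats::runif(200),
                        median_pct_dead = stats::runif(200, 0, 100))
  })
  b <- compute_boundaries(s)
  cls <- classify_lines(s, b)
  cen <- category_census(cls)
  expect_equal(sum(cen$n), 200)
  expect_equal(sum(cen$pct), 100)
  # continuous tie-free x with n divisible by 10: exactly 10% under/over
  under <- sum(cen$pct[cen$category %in% c("overcautious", "very_clumsy")])
  over <- sum(cen$pct[cen$category %in% c("overeager", "super_climber")])
  expect_equal(under, 10)
  expect_equal(over, 10)
  # independent x, y: very_clumsy is the product of the 10% tails (~1%)
  vc <- cen$pct[cen$category == "very_clumsy"]
  expect_lte(vc, 5)
})

test_that("classification is invariant to joint monotone rescaling of x", {
  withr::with_seed(41, {
    s <- tibble::tibble(line_id = sprintf("l%03d", 1:50),
                        median_max_mean_distance = stats::runif(50),
                        median_pct_dead = stats::runif(50, 0, 100))
  })
  b <- compute_boundaries(s)
  ref <- classify_lines(s, b)$category
  # sqrt is monotone on [0, 1]; rescale summaries and recompute boundaries
  s2 <- dplyr::mutate(s, median_max_mean_distance =
                        sqrt(median_max_mean_distance))
  b2 <- compute_boundaries(s2)
  expect_equal(classify_lines(s2, b2)$category, ref)
})

test_that("control summaries use the same quantile convention", {
  m <- tibble::tibble(max_mean_distance = (1:100) / 100, pct_dead = 1:100)
  cs <- control_summary(m)
  row <- cs[cs$axis == "pct_dead", ]
  expect_equal(row$q25, 25.75)
  expect_equal(row$q75, 75.25)
  expect_equal(row$median, 50.5)
  expect_true(all(cs$q10 <= cs$q25 & cs$q25 <= cs$median &
                    cs$median <= cs$q75 & cs$q75 <= cs$q90))
  one <- tibble::tibble(max_mean_distance = rep(0.4, 5),
                        pct_dead = rep(20, 5))
  cs1 <- control_summary(one)
  expect_equal(cs1$q10, cs1$q90)
})
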