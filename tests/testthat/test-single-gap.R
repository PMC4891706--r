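test_that("per-fly fractions are counts over ten approaches", {
  log <- manual_log(n_attempt = 10, n_cross = 7)
  fr <- per_fly_fractions(log)
  expect_equal(fr$frac_attempt, 1.0)
  expect_equal(fr$frac_cross, 0.7)
  fr2 <- per_fly_fractions(manual_log(n_attempt = 4, n_fall = 2))
  expect_equal(fr2$frac_fall, 0.2)
  expect_equal(fr2$frac_fall_given_attempt, 0.5)
  fr0 <- per_fly_fractions(manual_log(n_attempt = 0))
  expect_equal(fr0$frac_attempt, 0)
  expect_equal(fr0$frac_cross, 0)
  expect_equal(fr0$frac_fall_given_attempt, 0)
})

test_that("malformed approach logs abort with validation errors", {
  log <- manual_log(n_attempt = 5, n_cross = 2)
  expect_error(per_fly_fractions(log[-1, ]),
               class = "ringgap_error_validation")
  bad <- dplyr::mutate(log, crossed = TRUE) # crossings without attempts
  expect_error(per_fly_fractions(bad), class = "ringgap_error_validation")
  both <- dplyr::mutate(log, fell = crossed) # fall and cross together
  expect_error(per_fly_fractions(both), class = "ringgap_error_validation")
})

test_that("box statistics are interpolated quantiles in order", {
  b <- box_stats(1:10)
  expect_equal(b$q25, 3.25)
  expect_equal(b$q75, 7.75)
  expect_equal(box_stats(seq(0, 1, by = 0.1))$median, 0.5)
  const <- box_stats(rep(0.3, 7))
  expect_equal(const$q10, const$q90)
  expect_error(box_stats(numeric()), class = "ringgap_error_validation")
})

test_that("exact rank-sum p-values match enumeration on the worked cases", {
  expect_equal(rank_sum_test(c(1, 2), c(3, 4))$p_value, 1 / 3)
  expect_equal(rank_sum_test(1:3, 4:6)$p_value, 0.1) # 2 of 20 splits
  expect_equal(rank_sum_test(c(2, 2, 2), c(2, 2))$p_value, 1) # degenerate
  sep <- rank_sum_test(seq(0.1, 1, 0.1), seq(2, 3, length.out = 10))
  expect_equal(sep$p_value, 2 / choose(20, 10))
  expect_error(rank_sum_test(numeric(), 1:3),
               class = "ringgap_error_validation")
})

test_that("exact path agrees with the independent oracle, including ties", {
  withr::with_seed(7, {
    for (i in 1:30) {
      a <- sample(1:6, sample(3:8, 1), replace = TRUE) # heavy ties
      b <- sample(1:6, sample(3:8, 1), replace = TRUE)
      mine <- rank_sum_test(a, b)
      orc <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                                 correct = TRUE))
      # with ties wilcox.test falls back to the corrected approximation;
      # compare my approximation path to it exactly
      expect_equal(mine$p_approx, orc$p.value, tolerance = 1e-10)
    }
    # tie-free: my exact path against the oracle's exact path
    for (i in 1:20) {
      a <- stats::runif(sample(2:8, 1))
      b <- stats::runif(sample(2:8, 1))
      mine <- rank_sum_test(a, b)
      orc <- stats::wilcox.test(a, b, exact = TRUE)
      expect_equal(mine$p_exact, orc$p.value, tolerance = 1e-10)
    }
  })
})

test_that("exact and approximate paths agree closely at 10 + 10", {
  withr::with_seed(42, {
    worst <- 0
    for (i in 1:100) {
      a <- stats::runif(10)
      b <- stats::runif(10, 0.2, 1.2)
      ts <- rank_sum_test(a, b)
      worst <- max(worst, abs(ts$p_exact - ts$p_approx))
    }
  })
  expect_lte(worst, 0.01)
})

test_that("star coding uses strict printed thresholds", {
  # thresholds are strict: p exactly at a cutoff takes the weaker code
  expect_equal(star_code(c(0.04, 0.0009, 0.05, 0.009, 0.2, 0.001)),
               c("*", "***", "ns", "**", "ns", "**"))
  expect_error(star_code(1.2), class = "ringgap_error_validation")
})

test_that("line-vs-control comparisons cover matched widths and metrics", {
  p <- ringgap_profile("control")
  logs <- dplyr::bind_rows(
    simulate_catwalk_session(p, catwalk_setup(2.5), 10, seed = 1,
                             line_id = "lineA"),
    simulate_catwalk_session(p, catwalk_setup(4.0), 10, seed = 2,
                             line_id = "lineA"))
  ctrl <- dplyr::bind_rows(
    simulate_catwalk_session(p, catwalk_setup(2.5), 10, seed = 1),
    simulate_catwalk_session(p, catwalk_setup(4.0), 10, seed = 2))
  cmp <- compare_to_control(per_fly_fractions(logs), per_fly_fractions(ctrl))
  expect_equal(nrow(cmp), 4) # 2 widths x 2 metrics
  # identical data: p = 1 everywhere, no stars
  expect_true(all(cmp$p_value == 1))
  expect_true(all(cmp$stars == "ns"))
  # unmatched widths warn and are skipped
  solo <- per_fly_fractions(
    simulate_catwalk_session(p, catwalk_setup(5.0), 10, seed = 3,
                             line_id = "lineA"))
  expect_warning(compare_to_control(
    dplyr::bind_rows(per_fly_fractions(logs), solo),
    per_fly_fractions(ctrl)), "skipped")
})

test_that("enhanced-gain flies attempt significantly more at wide gaps", {
  # C2-block-like gain 1.6 vs control at 5 mm, 15 flies per arm, 20 seeds:
  # attempt-rate comparisons go in the more-attempts direction and are
  # mostly significant.
  sig <- 0
  direction_ok <- 0
  for (s in 1:20) {
    line <- per_fly_fractions(simulate_catwalk_session(
      ringgap_profile("overeager"), catwalk_setup(5.0), 15, seed = 500 + s))
    ctrl <- per_fly_fractions(simulate_catwalk_session(
      ringgap_profile("control"), catwalk_setup(5.0), 15, seed = 900 + s))
    cmp <- compare_to_control(line, ctrl, metrics = "frac_attempt")
    direction_ok <- direction_ok + (cmp$direction >= 0)
    sig <- sig + (cmp$p_value < 0.05)
  }
  expect_gte(direction_ok, 19)
  expect_gte(sig, 15)
})

test_that("tidy methods return one-row summaries", {
  ts <- rank_sum_test(1:4, 3:8)
  td <- generics::tidy(ts)
  expect_equal(nrow(td), 1)
  expect_named(td, c("statistic", "p_value", "p_exact", "p_approx",
                     "method", "n_a", "n_b"))
})
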