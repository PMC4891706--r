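test_that("radial distances are relative to the disk radius", {
  geom <- arena_geometry()
  tr <- tibble::tibble(t_s = 0:2, x_mm = c(0, 69, 30), y_mm = c(0, 0, 40))
  r <- radial_distance_series(tr, geom)$r_rel
  expect_equal(r, c(0, 1, 50 / 69))
  out <- tibble::tibble(t_s = 0, x_mm = 100, y_mm = 0)
  expect_error(radial_distance_series(out, geom),
               class = "ringgap_error_validation")
})

test_that("mean distance averages all flies, dead ones frozen in place", {
  tr <- fixed_radius_tracks(c(0, 0.8))
  s <- mean_distance_series(tr)
  expect_equal(unique(s$mean_r), 0.4)
  expect_equal(nrow(s), 10)
  # fly order is irrelevant
  shuffled <- dplyr::arrange(tr, dplyr::desc(fly_id), t_s)
  attributes(shuffled) <- c(attributes(shuffled),
                            attributes(tr)[c("geometry")])
  expect_equal(mean_distance_series(shuffled, arena_geometry())$mean_r,
               s$mean_r)
  # missing samples are an error, not imputed
  broken <- tr[-3, ]
  expect_error(mean_distance_series(broken, arena_geometry()),
               class = "ringgap_error_validation")
})

test_that("series maximum is found with first-attainment tie-breaking", {
  s <- tibble::tibble(t_s = 0:3, mean_r = c(0.1, 0.5, 0.3, 0.5))
  m <- max_mean_distance_and_time(s)
  expect_equal(m$max_mean_distance, 0.5)
  expect_equal(m$time_to_max, 1)
  const <- tibble::tibble(t_s = 0:5, mean_r = rep(0.2, 6))
  expect_equal(max_mean_distance_and_time(const)$time_to_max, 0)
  inc <- tibble::tibble(t_s = 0:4, mean_r = seq(0.1, 0.5, by = 0.1))
  expect_equal(max_mean_distance_and_time(inc)$time_to_max, 4)
  expect_error(max_mean_distance_and_time(tibble::tibble(t_s = numeric(),
                                                         mean_r = numeric())),
               class = "ringgap_error_validation")
})

test_that("death detection flags only immobile flies inside a groove", {
  geom <- arena_geometry()
  mid1 <- (geom$groove_inner_radii[1] + geom$groove_outer_radii[1]) / 2
  # immobile in groove 1 from t = 4
  tr <- tibble::tibble(t_s = 0:9,
                       x_mm = c(1, 3, 6, 9, rep(mid1, 6)),
                       y_mm = 0)
  d <- detect_deaths_from_track(tr, geom)
  expect_true(d$is_dead)
  expect_equal(d$death_groove, 1L)
  expect_equal(d$death_time, 4)
  # immobile on land: alive
  land <- tibble::tibble(t_s = 0:9, x_mm = rep(5, 10), y_mm = 0)
  expect_false(detect_deaths_from_track(land, geom)$is_dead)
})

test_that("track-based death calls reproduce the simulator ground truth", {
  geom <- arena_geometry()
  for (s in 1:20) {
    tr <- simulate_ring_experiment(ringgap_profile("clumsy"), geom,
                                   duration = 150, seed = s)
    truth <- attr(tr, "death_groove")
    m <- ring_metrics(tr)
    expect_equal(m$n_dead, sum(!is.na(truth)))
    expect_equal(m$dead_per_groove[[1]],
                 tabulate(truth[!is.na(truth)], nbins = 5))
    expect_equal(m$n_dead, round(m$pct_dead * m$n_flies / 100))
  }
})

test_that("walking activity averages displacement over alive fly-seconds", {
  geom <- arena_geometry()
  # 15 flies, one advancing 2 mm per second, the others parked
  mover <- tibble::tibble(t_s = 0:9, fly_id = 1L,
                          x_mm = seq(0, 18, by = 2), y_mm = 0,
                          status = "alive")
  parked <- tidyr::expand_grid(fly_id = 2:15, t_s = 0:9)
  parked$x_mm <- 5
  parked$y_mm <- 0
  parked$status <- "alive"
  tr <- dplyr::bind_rows(mover, parked[, names(mover)])
  expect_equal(walking_activity(tr), 2 / 15)
  # a dead fly contributes no post-death displacement
  mover2 <- dplyr::mutate(mover, status = c("alive", rep("dead", 9)),
                          x_mm = c(0, rep(18, 9)))
  tr2 <- dplyr::bind_rows(mover2, parked[, names(mover)])
  expect_equal(walking_activity(tr2), 0)
  expect_equal(walking_activity(dplyr::mutate(parked[, names(mover)],
                                              x_mm = 5)), 0)
})

test_that("a fly frozen at the rim raises later means versus dropping it", {
  geom <- arena_geometry()
  # two flies: one roams at r_rel 0.3, one dies at the rim-side groove
  base <- fixed_radius_tracks(c(0.3, 0.9), duration = 8)
  with_dead <- dplyr::mutate(
    base, status = ifelse(fly_id == 2 & t_s >= 3, "dead", "alive"))
  attributes(with_dead) <- c(attributes(with_dead),
                             attributes(base)["geometry"])
  m_both <- mean_distance_series(with_dead, geom)$mean_r
  solo <- dplyr::filter(base, fly_id == 1)
  m_solo <- mean_distance_series(solo, geom)$mean_r
  expect_true(all(m_both >= m_solo))
})
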