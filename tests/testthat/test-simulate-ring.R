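test_that("ring simulation is deterministic under a fixed seed", {
  p <- ringgap_profile("control")
  a <- simulate_ring_experiment(p, duration = 120, seed = 11)
  b <- simulate_ring_experiment(p, duration = 120, seed = 11)
  expect_identical(a, b)
  c <- simulate_ring_experiment(p, duration = 120, seed = 12)
  expect_false(identical(a$x_mm, c$x_mm))
})

test_that("earlier flies are unchanged when the cohort grows", {
  p <- ringgap_profile("control")
  a <- simulate_ring_experiment(p, n_flies = 5, duration = 60, seed = 4)
  b <- simulate_ring_experiment(p, n_flies = 9, duration = 60, seed = 4)
  expect_identical(dplyr::filter(a, fly_id <= 5)$x_mm,
                   dplyr::filter(b, fly_id <= 5)$x_mm)
})

test_that("track invariants hold: grid, frozen dead flies, groove placement", {
  geom <- arena_geometry()
  tr <- simulate_ring_experiment(ringgap_profile("clumsy"), geom,
                                 duration = 300, seed = 2)
  expect_equal(sort(unique(tr$t_s)), 0:299)
  expect_equal(nrow(tr), 15 * 300)
  for (f in split(tr, tr$fly_id)) {
    dead_rows <- f[f$status == "dead", ]
    if (nrow(dead_rows) > 0) {
      # frozen position
      expect_equal(length(unique(dead_rows$x_mm)), 1)
      expect_equal(length(unique(dead_rows$y_mm)), 1)
      # inside a groove annulus
      r <- sqrt(dead_rows$x_mm[1]^2 + dead_rows$y_mm[1]^2)
      in_groove <- any(r >= geom$groove_inner_radii &
                         r <= geom$groove_outer_radii)
      expect_true(in_groove)
      # no dead -> alive flip
      expect_true(all(diff(f$status == "dead") >= 0))
    }
    # alive flies never inside a groove annulus
    alive <- f[f$status == "alive", ]
    r <- sqrt(alive$x_mm^2 + alive$y_mm^2)
    inside <- outer(r, geom$groove_inner_radii, ">=") &
      outer(r, geom$groove_outer_radii, "<=")
    expect_false(any(inside))
    # never outside the disk
    expect_true(all(r <= geom$disk_radius))
  }
})

test_that("alive plus drowned flies always account for the whole cohort", {
  for (s in 1:10) {
    tr <- simulate_ring_experiment(ringgap_profile("overeager"),
                                   duration = 200, seed = s)
    final <- dplyr::filter(tr, t_s == max(t_s))
    dg <- attr(tr, "death_groove")
    expect_equal(sum(final$status == "alive") + sum(!is.na(dg)), 15)
    expect_equal(sum(final$status == "dead"), sum(!is.na(dg)))
  }
})

test_that("degenerate decision parameters give the forced outcomes", {
  geom <- arena_geometry()
  # never attempt: everyone survives inside the innermost groove
  p0 <- bernoulli_profile(p_attempt = 0)
  tr <- simulate_ring_experiment(p0, geom, duration = 200, seed = 5)
  expect_true(all(tr$status == "alive"))
  r <- sqrt(tr$x_mm^2 + tr$y_mm^2)
  expect_true(all(r < geom$groove_inner_radii[1]))
  # always attempt, always cross, never fall: nobody dies, the rim is reached
  p1 <- bernoulli_profile(p_attempt = 1, p_success = 1, fall = 0)
  tr1 <- simulate_ring_experiment(p1, geom, duration = 600, seed = 5)
  expect_true(all(tr1$status == "alive"))
  r1 <- sqrt(tr1$x_mm^2 + tr1$y_mm^2)
  expect_true(max(r1) > geom$groove_outer_radii[5])
})

test_that("straight-line limit of the walk moves at the mean speed", {
  p <- behavior_profile("straight",
                        data.frame(width = c(2, 6), prob = c(0, 0)),
                        data.frame(width = c(2, 6), prob = c(0, 0)),
                        speed_mean = 3, speed_sd = 0, turn_p0 = 0)
  tr <- simulate_ring_experiment(p, n_flies = 1, duration = 5, seed = 9)
  step <- sqrt(diff(tr$x_mm)^2 + diff(tr$y_mm)^2)
  # every step before any wall contact is exactly speed_mean
  expect_true(all(abs(step - 3) < 1e-9 | step < 3))
})

test_that("drowning counts stay inside the binomial envelope of the fall rate", {
  # Distributional oracle: conditional on the number of attempts A recorded
  # by the simulator, drownings are Binomial(A, p_fall). Pool replicate
  # cohorts and check the pooled count against a 99.9% binomial envelope.
  p <- ringgap_profile("tarsi_clumsy") # fall 0.13
  deaths <- 0L
  attempts <- 0L
  for (s in 1:40) {
    tr <- simulate_ring_experiment(p, duration = 200, seed = 100 + s)
    deaths <- deaths + sum(!is.na(attr(tr, "death_groove")))
    attempts <- attempts + attr(tr, "n_attempts")
  }
  expect_gt(attempts, 500) # enough events for the envelope to mean something
  expect_gte(deaths, stats::qbinom(0.0005, attempts, 0.13))
  expect_lte(deaths, stats::qbinom(0.9995, attempts, 0.13))
})
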