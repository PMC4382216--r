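test_that("bearing separation handles wraparound and stays in [0, 180]", {
  expect_equal(bearing_separation(45, 315), 90)
  expect_equal(bearing_separation(10, 350), 20)
  expect_equal(bearing_separation(200, 20), 180)
  expect_error(bearing_separation(NA_real_, 10), "invalid")
  set.seed(1)
  a <- runif(500, 0, 360); b <- runif(500, 0, 360)
  s1 <- bearing_separation(a, b)
  expect_identical(s1, bearing_separation(b, a))
  expect_true(all(s1 >= 0 & s1 <= 180))
})

test_that("biangulation intersects rays and applies the filter rules in order", {
  ok <- triangulate_pair(c(0, 0), c(100, 0), 45, 315)
  expect_true(ok$accepted)
  expect_equal(c(ok$x, ok$y), c(50, 50), tolerance = 1e-9)
  # parallel bearings: separation 0 is outside 15-165
  expect_equal(triangulate_pair(c(0, 0), c(100, 0), 0, 0)$reason, "separation")
  # rays opening away from each other meet behind the observers
  expect_equal(triangulate_pair(c(0, 0), c(100, 0), 315, 45)$reason,
               "behind-observer")
  # narrow but admissible separation puts the fix beyond a reduced range:
  # azimuths 10/350 from a 100 m baseline intersect ~288 m from each observer
  far <- triangulate_pair(c(0, 0), c(100, 0), 10, 350, max_range = 200)
  expect_equal(far$reason, "out-of-range")
  expect_true(triangulate_pair(c(0, 0), c(100, 0), 10, 350)$accepted)
  expect_error(triangulate_pair(c(1, 1), c(1, 1), 10, 100), "coincident")
})

test_that("narrowing the filters never accepts more bearing pairs", {
  set.seed(2)
  n <- 300
  bearings <- data.frame(
    timestamp = seq_len(n), bat_id = "b",
    obs1_x = runif(n, -50, 50), obs1_y = runif(n, -50, 50),
    azimuth1_deg = runif(n, 0, 360),
    obs2_x = runif(n, 50, 150), obs2_y = runif(n, -50, 50),
    azimuth2_deg = runif(n, 0, 360))
  base <- nrow(triangulate_bearings(bearings)$fixes)
  tighter_range <- nrow(triangulate_bearings(bearings, max_range = 150)$fixes)
  tighter_sep <- nrow(triangulate_bearings(bearings,
                                           sep_bounds = c(40, 140))$fixes)
  expect_lte(tighter_range, base)
  expect_lte(tighter_sep, base)
})

test_that("stationary deduplication collapses runs and is idempotent", {
  same <- data.frame(x = rep(10, 5), y = rep(20, 5))
  expect_equal(nrow(deduplicate_stationary(same, 50)), 1)
  # alternating distant positions: no consecutive run to collapse
  alt <- data.frame(x = rep(c(0, 500), 10), y = 0)
  expect_equal(nrow(deduplicate_stationary(alt, 50)), 20)
  set.seed(3)
  rnd <- data.frame(x = cumsum(rnorm(30, 0, 80)), y = cumsum(rnorm(30, 0, 80)))
  expect_equal(nrow(deduplicate_stationary(rnd, 0)), 30)
  once <- deduplicate_stationary(rnd, 60)
  expect_identical(deduplicate_stationary(once, 60), once)
  expect_error(deduplicate_stationary(rnd, -1), "invalid")
})

test_that("session selection ranks by contact fraction with an 0.85 floor", {
  sched <- stats::setNames(rep(100, 6), 1:6)
  fr <- c(0.9, 0.95, 0.99, 0.5, 0.86, 0.7)
  fixes <- data.frame(session_id = rep(1:6, times = fr * 100))
  sel <- select_sessions(fixes, sched)
  expect_equal(sel$session_ids, c(3, 2, 1))
  expect_false(sel$flagged)
  low <- data.frame(session_id = rep(1:6, times = rep(50, 6)))
  sel2 <- select_sessions(low, sched)
  expect_length(sel2$session_ids, 0)
  expect_true(sel2$flagged)
  # full contact everywhere: ties broken by earliest session
  full <- data.frame(session_id = rep(1:6, each = 100))
  expect_equal(select_sessions(full, sched)$session_ids, c(1, 2, 3))
  expect_error(select_sessions(full[0, , drop = FALSE], numeric(0)), "invalid")
})

test_that("session assignment splits at gaps and respects explicit windows", {
  f <- data.frame(timestamp = c(0, 120, 240, 30000, 30120))
  a <- assign_sessions(f)
  expect_equal(a$session_id, c(1, 1, 1, 2, 2))
  w <- data.frame(start = c(0, 30000), end = c(1000, 31000))
  b <- assign_sessions(f, sessions = w)
  expect_equal(b$session_id, c(1, 1, 1, 2, 2))
  expect_warning(
    assign_sessions(data.frame(timestamp = c(0, 5000)), sessions = w),
    "outside")
})
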