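test_that("landscape generation is deterministic and respects its config", {
  cfg <- landscape_config(seed = 5)
  l1 <- generate_landscape(cfg)
  l2 <- generate_landscape(cfg)
  expect_identical(l1$map$codes, l2$map$codes)
  # no natural patches: only matrix classes (incl. degraded blobs) remain
  bare <- generate_landscape(landscape_config(n_natural_patches = 0,
                                              n_corridors = 0, seed = 2))
  expect_true(all(bare$map$codes %in% c(1L, 2L, 3L, 4L)))
  expect_false(any(bare$map$codes == 0L))
  # farmland is painted toward its target fraction (later classes may
  # overprint part of it)
  frac <- mean(bare$map$codes == 2L)
  expect_lt(abs(frac - 0.10), 0.05)
  # urban strip width matches the config
  urb <- colSums(l1$map$codes == 4L)
  expect_equal(sum(urb > 0) * l1$map$cellsize, 60)
})

test_that("tracks start each session at the roost and stay on the map", {
  l <- generate_landscape(landscape_config(seed = 3))
  roost <- l$truth$patch_centers[1, ]
  beh <- bat_behavior("resident", roost = roost, sessions = 2)
  tr <- simulate_track(l$map, beh, seed = 9)
  expect_equal(unique(tr$fixes$session_id), 1:2)
  expect_equal(nrow(tr$fixes), 2 * 180)
  # all positions classifiable (inside the map)
  expect_silent(classify_point(l$map, tr$fixes$x, tr$fixes$y))
  # first fix of each session is near the roost (one step at most)
  firsts <- tr$fixes[!duplicated(tr$fixes$session_id), ]
  expect_true(all(sqrt((firsts$x - roost[1])^2 +
                       (firsts$y - roost[2])^2) < 400))
  expect_error(
    simulate_track(l$map, bat_behavior("resident", roost = c(10, 10))),
    "natural")
})

test_that("noiseless bearings round-trip through triangulation exactly", {
  l <- generate_landscape(landscape_config(seed = 4))
  beh <- bat_behavior("resident", roost = l$truth$patch_centers[2, ],
                      sessions = 1)
  tr <- simulate_track(l$map, beh, seed = 10)
  br <- simulate_bearings(tr$fixes, bearing_sd = 0, seed = 10)
  tri <- triangulate_bearings(br, max_range = 400)
  got <- merge(tri$fixes, tr$fixes, by = "timestamp",
               suffixes = c("_est", "_true"))
  expect_gt(nrow(got), 100)
  expect_lt(max(abs(got$x_est - got$x_true)), 1e-6)
  expect_lt(max(abs(got$y_est - got$y_true)), 1e-6)
})

test_that("realistic bearing noise keeps the median position error small", {
  set.seed(15)
  true <- data.frame(timestamp = 1:1000, bat_id = "b",
                     x = runif(1000, 0, 500), y = runif(1000, 0, 500))
  br <- simulate_bearings(true, bearing_sd = 2, observer_offset = 200,
                          seed = 16)
  tri <- triangulate_bearings(br, max_range = 400)
  got <- merge(tri$fixes, true, by = "timestamp",
               suffixes = c("_est", "_true"))
  err <- sqrt((got$x_est - got$x_true)^2 + (got$y_est - got$y_true)^2)
  expect_lt(stats::median(err), 15)
})

test_that("pairs below the separation bound are all rejected", {
  true <- data.frame(timestamp = 1:50, bat_id = "b",
                     x = runif(50, 100, 400), y = runif(50, 100, 400))
  # observers placed 10 degrees apart as seen from the bat
  phi1 <- runif(50, 0, 2 * pi); phi2 <- phi1 + 10 * pi / 180
  br <- data.frame(
    timestamp = true$timestamp, bat_id = "b",
    obs1_x = true$x + 150 * sin(phi1), obs1_y = true$y + 150 * cos(phi1),
    obs2_x = true$x + 150 * sin(phi2), obs2_y = true$y + 150 * cos(phi2))
  br$azimuth1_deg <- (atan2(true$x - br$obs1_x, true$y - br$obs1_y) *
                        180 / pi) %% 360
  br$azimuth2_deg <- (atan2(true$x - br$obs2_x, true$y - br$obs2_y) *
                        180 / pi) %% 360
  tri <- triangulate_bearings(br)
  expect_equal(nrow(tri$fixes), 0)
  expect_true(all(tri$rejections$reason == "separation"))
})

test_that("a full study is reproducible and paper-like in structure", {
  st <- small_study()
  expect_equal(length(unique(st$bearings$bat_id)), 4)
  expect_equal(sum(st$truth$modes == "commuter"), 1)
  # commuter far sites sit 300-1100 m from the roost
  for (j in which(st$truth$modes == "commuter")) {
    b <- st$truth$tracks[[j]]$truth$behavior
    expect_true(sqrt(sum((b$far_site - b$roost)^2)) >= 300)
    expect_true(sqrt(sum((b$far_site - b$roost)^2)) <= 1100)
  }
  # regeneration is byte-identical on disk
  d1 <- file.path(tempdir(), "study_a"); d2 <- file.path(tempdir(), "study_b")
  write_study(st, d1)
  write_study(generate_study(n_bats = 4, commuter_fraction = 0.25,
                             sessions = 3, seed = 11), d2)
  for (f in c("bearings.csv", "roosts.csv", "landcover.asc", "truth.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("the paper-like preset produces 16 tracks with 5 commuters", {
  # structural check only (cheap): behaviour assignment and roost placement
  cfg <- landscape_config(seed = 20)
  l <- generate_landscape(cfg)
  set.seed(20)
  n_comm <- round(5 / 16 * 16)
  expect_equal(n_comm, 5)
  st <- small_study()
  for (r in seq_len(nrow(st$roosts)))
    expect_equal(classify_point(st$map, st$roosts$x[r], st$roosts$y[r]),
                 "natural")
})

test_that("full synthetic studies recover the qualitative selection and
           disturbance patterns", {
  # ten complete 16-bat studies through the whole pipeline; the qualitative
  # pattern of the habitat-selection table (natural ranked first with its
  # simultaneous CI above 1, urban last) and a positive disturbance effect
  # on daily-range size must emerge in at least 9 of 10
  rank_ok <- ci_ok <- beta_ok <- 0
  for (s in 1:10) {
    st <- generate_study(seed = s)
    res <- suppressWarnings(run_pipeline(st$bearings, st$map, st$roosts))
    sel <- res$selection
    rank_ok <- rank_ok + (sel$category[which.max(sel$wi)] == "natural" &&
                          sel$wi[sel$category == "urban"] <= min(sel$wi))
    ci_ok <- ci_ok + (sel$ci_low[sel$category == "natural"] > 1)
    d <- res$daily
    d$day <- d$session_id
    f <- fit_lmm(center_covariates(d, terms = "disturbance")$data,
                 "disturbance")
    beta_ok <- beta_ok + (unname(f$beta["disturbance"]) > 0)
  }
  expect_gte(rank_ok / 10, 0.9)
  expect_gte(ci_ok / 10, 0.9)
  expect_gte(beta_ok / 10, 0.9)
})
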