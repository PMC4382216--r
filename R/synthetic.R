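#' Configuration for a synthetic fragmented landscape
#'
#' Describes a categorical landscape of the kind the analysis assumes: a
#' pasture matrix holding a few natural-forest fragments with degraded
#' fringes and corridors, rectangular farmland blocks and one urban strip.
#' All generators are pure functions of (config, seed).
#'
#' @param extent side length of the square landscape (m, default 3000).
#' @param cell_size raster cell size (m, default 10).
#' @param n_natural_patches number of forest fragments (default 4).
#' @param patch_radius_range min/max fragment radius (m, default 150-350).
#' @param degraded_buffer_width width of the degraded fringe around each
#'   fragment (m, default 30).
#' @param n_degraded_patches degraded-forest blobs in the matrix (early
#'   succession / remnant trees; default 10), the typical destinations of
#'   commuting bouts.
#' @param degraded_patch_radius min/max radius of those blobs (m).
#' @param n_degraded_scatter small remnant-vegetation patches scattered
#'   through the matrix (clear-cut leftovers, live fences; default 60).
#' @param n_corridors degraded corridors between fragments (default 2).
#' @param farmland_fraction target fraction of the landscape under
#'   farmland blocks (default 0.10).
#' @param urban_strip_width width of the urban strip (m, default 60).
#' @param seed RNG seed.
#' @return a `landscape_config` list.
#' @export
landscape_config <- function(extent = 3000, cell_size = 10,
                             n_natural_patches = 4,
                             patch_radius_range = c(280, 420),
                             degraded_buffer_width = 30,
                             n_degraded_patches = 10,
                             degraded_patch_radius = c(100, 180),
                             n_degraded_scatter = 60,
                             n_corridors = 2,
                             farmland_fraction = 0.10,
                             urban_strip_width = 60,
                             seed = 1) {
  stopifnot(extent > 0, cell_size > 0, farmland_fraction >= 0,
            farmland_fraction <= 1, n_natural_patches >= 0)
  structure(as.list(environment()), class = "landscape_config")
}

#' Generate a synthetic categorical landscape
#'
#' @param config a [landscape_config()].
#' @return list with `map` (a `landcover_grid`) and `truth` (patch
#'   centers/radii and the full config) — regeneration from the same
#'   config is bit-identical.
#' @export
generate_landscape <- function(config) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  nc <- as.integer(config$extent / config$cell_size)
  codes <- matrix(3L, nc, nc) # pasture background
  cx <- (seq_len(nc) - 0.5) * config$cell_size
  cy <- (seq_len(nc) - 0.5) * config$cell_size
  X <- matrix(cx, nc, nc, byrow = TRUE)
  Y <- matrix(cy, nc, nc)

  # urban strip: vertical band away from the landscape centre
  ux <- stats::runif(1, 0.05, 0.2) * config$extent
  codes[X >= ux & X < ux + config$urban_strip_width] <- 4L

  # farmland: rectangular blocks on pasture until the target fraction
  target <- config$farmland_fraction * nc * nc
  placed <- 0
  tries <- 0
  while (placed < target && tries < 500) {
    tries <- tries + 1
    w <- stats::runif(1, 80, 250); h <- stats::runif(1, 80, 250)
    x0 <- stats::runif(1, 0, config$extent - w)
    y0 <- stats::runif(1, 0, config$extent - h)
    block <- X >= x0 & X < x0 + w & Y >= y0 & Y < y0 + h & codes == 3L
    codes[block] <- 2L
    placed <- placed + sum(block)
  }

  # natural fragments: non-overlapping noisy blobs with a degraded fringe
  centers <- matrix(numeric(0), 0, 2)
  radii <- numeric(0)
  margin <- config$degraded_buffer_width + max(config$patch_radius_range)
  for (p in seq_len(config$n_natural_patches)) {
    for (try in 1:200) {
      r <- stats::runif(1, config$patch_radius_range[1],
                        config$patch_radius_range[2])
      c_ <- stats::runif(2, margin, config$extent - margin)
      if (nrow(centers) == 0 ||
          all(sqrt(colSums((t(centers) - c_)^2)) >
              radii + r + 2 * config$degraded_buffer_width + 50)) {
        centers <- rbind(centers, c_)
        radii <- c(radii, r)
        break
      }
      if (try == 200) stop("placement error: could not place natural patch ", p)
    }
  }
  ph <- stats::runif(max(config$n_natural_patches, 1) * 2, 0, 2 * pi)
  for (p in seq_len(config$n_natural_patches)) {
    dx <- X - centers[p, 1]; dy <- Y - centers[p, 2]
    ang <- atan2(dy, dx)
    # smooth radial wobble makes the fragment blob-shaped
    rb <- radii[p] * (1 + 0.18 * sin(2 * ang + ph[2 * p - 1]) +
                        0.10 * sin(3 * ang + ph[2 * p]))
    d <- sqrt(dx^2 + dy^2)
    codes[d <= rb + config$degraded_buffer_width & codes != 0L] <- 1L
    codes[d <= rb] <- 0L
  }

  # degraded blobs in the matrix: early-succession stands bats commute to
  for (q in seq_len(config$n_degraded_patches)) {
    for (try in 1:200) {
      r <- stats::runif(1, config$degraded_patch_radius[1],
                        config$degraded_patch_radius[2])
      c_ <- stats::runif(2, r, config$extent - r)
      if (config$n_natural_patches == 0 ||
          all(sqrt(colSums((t(centers) - c_)^2)) >
              radii + config$degraded_buffer_width + r + 150)) break
    }
    d <- sqrt((X - c_[1])^2 + (Y - c_[2])^2)
    codes[d <= r & codes != 0L] <- 1L
  }

  # small remnant-vegetation patches scattered through the matrix,
  # kept off the fragments so they read as matrix vegetation
  for (q in seq_len(config$n_degraded_scatter)) {
    for (try in 1:50) {
      r <- stats::runif(1, 40, 100)
      c_ <- stats::runif(2, 0, config$extent)
      if (config$n_natural_patches == 0 ||
          all(sqrt(colSums((t(centers) - c_)^2)) >
              radii + config$degraded_buffer_width + r + 100)) break
    }
    d <- sqrt((X - c_[1])^2 + (Y - c_[2])^2)
    codes[d <= r & codes != 0L] <- 1L
  }

  # degraded corridors between fragment pairs
  if (config$n_natural_patches >= 2 && config$n_corridors > 0) {
    pairs <- utils::combn(config$n_natural_patches, 2)
    pick <- sample(ncol(pairs), min(config$n_corridors, ncol(pairs)))
    for (q in pick) {
      a <- centers[pairs[1, q], ]; b <- centers[pairs[2, q], ]
      ab <- b - a; len <- sqrt(sum(ab^2)); u <- ab / len
      t_ <- ((X - a[1]) * u[1] + (Y - a[2]) * u[2])
      perp <- abs((X - a[1]) * -u[2] + (Y - a[2]) * u[1])
      corridor <- t_ >= 0 & t_ <= len & perp <= 15 & codes != 0L
      codes[corridor] <- 1L
    }
  }

  map <- landcover_grid(codes, xll = 0, yll = 0, cellsize = config$cell_size)
  list(map = map,
       truth = list(config = unclass(config), patch_centers = centers,
                    patch_radii = radii))
}

#' Behaviour parameters for one synthetic bat
#'
#' A central-place forager hovering around its day roost, optionally
#' commuting to a second foraging site several hundred meters away (the
#' generating model behind two-focus-area home ranges).
#'
#' @param mode `"resident"` or `"commuter"`.
#' @param roost roost position (x, y), must lie in natural forest.
#' @param far_site second foraging site (commuters; 300-1100 m from the
#'   roost).
#' @param attraction_weights positive per-category weights steering
#'   habitat-dependent step acceptance (defaults: natural 2, degraded 1,
#'   farmland 0.6, pasture 0.3, urban 0.05).
#' @param step_scale mean step length per 2-min fix (m, default 60).
#' @param turning_concentration weight of the previous heading in the
#'   heading mixture, in \[0, 1) (default 0.4).
#' @param perch_prob probability per moving step of starting a perching
#'   bout (default 0.3); perch durations are geometric with mean
#'   `perch_mean` steps (default 4).
#' @param perch_mean mean perch duration in steps.
#' @param bout_rate expected commuting bouts per session (Poisson, capped
#'   at 2, so nights range from no bout to two bouts; default 1.5 for
#'   commuters, 0 for residents).
#' @param sessions number of 6-h nightly sessions (default 6).
#' @param fix_interval seconds between fixes (default 120).
#' @param session_length session length in seconds (default 21600).
#' @return a `bat_behavior` list.
#' @export
bat_behavior <- function(mode = c("resident", "commuter"), roost,
                         far_site = NULL,
                         attraction_weights = c(natural = 2, degraded = 1,
                                                farmland = 0.6, pasture = 0.3,
                                                urban = 0.05),
                         step_scale = 60, turning_concentration = 0.4,
                         perch_prob = 0.3, perch_mean = 4,
                         bout_rate = if (mode[1] == "commuter") 1.5 else 0,
                         sessions = 6, fix_interval = 120,
                         session_length = 21600) {
  mode <- match.arg(mode)
  if (mode == "commuter" && is.null(far_site))
    stop("invalid config: a commuter needs a far_site")
  stopifnot(all(attraction_weights > 0), bout_rate >= 0)
  structure(list(mode = mode, roost = roost, far_site = far_site,
                 attraction_weights = attraction_weights,
                 step_scale = step_scale,
                 turning_concentration = turning_concentration,
                 perch_prob = perch_prob, perch_mean = perch_mean,
                 bout_rate = bout_rate, sessions = sessions,
                 fix_interval = fix_interval,
                 session_length = session_length),
            class = "bat_behavior")
}

#' Simulate one bat's true movement track
#'
#' Goal-biased correlated random walk on the categorical landscape: each
#' step's heading mixes the previous heading with the bearing to the
#' current goal (roost area or far site) plus wrapped-normal noise, step
#' lengths are gamma(shape 2) with mean `step_scale`, and proposed steps
#' are accepted with probability proportional to the attraction weight of
#' the destination category (rejection sampling, at most 20 proposals,
#' then forced). Commuting bouts leave for the far site at Poisson times
#' (capped at 2 per session) and all sessions start and end at the roost.
#' Perching bouts hold the bat in place, producing the stationary runs the
#' deduplication stage removes.
#'
#' @param map a land-cover map.
#' @param behavior a [bat_behavior()].
#' @param bat_id label for the output track.
#' @param seed RNG seed.
#' @return list with `fixes` (data frame `timestamp`, `bat_id`,
#'   `session_id`, `x`, `y` — the exact simulated-truth positions) and
#'   `truth` (behaviour parameters and the realized per-category step
#'   tally).
#' @export
simulate_track <- function(map, behavior, bat_id = "bat1", seed = 1) {
  if (classify_point(map, behavior$roost[1], behavior$roost[2]) != "natural")
    stop("invalid config: roost must lie in natural forest")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  b <- behavior
  steps <- as.integer(b$session_length / b$fix_interval)
  wmax <- max(b$attraction_weights)
  use_tally <- stats::setNames(numeric(5), landcover_categories())
  out <- vector("list", b$sessions)

  extent_ok <- function(p) {
    ok <- tryCatch({ classify_point(map, p[1], p[2]); TRUE },
                   error = function(e) FALSE)
    ok
  }

  for (s in seq_len(b$sessions)) {
    pos <- b$roost
    heading <- stats::runif(1, 0, 2 * pi)
    xs <- ys <- numeric(steps)
    state <- "near"
    dwell <- 0L
    n_bouts <- if (b$mode == "commuter") min(stats::rpois(1, b$bout_rate), 2L) else 0L
    bout_starts <- sort(sample(20:(steps - 60), n_bouts))
    perch_left <- 0L
    for (i in seq_len(steps)) {
      if (state == "near" && i %in% bout_starts) state <- "to_far"
      # forced return so the session ends at the roost
      dist_roost <- sqrt(sum((pos - b$roost)^2))
      if (state != "near" &&
          (steps - i) * b$step_scale * 0.7 < dist_roost + 100)
        state <- "to_near"
      goal <- switch(state,
        near = b$roost, to_far = b$far_site, at_far = b$far_site,
        to_near = b$roost)
      if (perch_left > 0L) {
        perch_left <- perch_left - 1L
      } else if (state %in% c("near", "at_far") &&
                 stats::runif(1) < b$perch_prob) {
        perch_left <- 1L + stats::rgeom(1, 1 / b$perch_mean)
      } else {
        to_goal <- goal - pos
        dg <- sqrt(sum(to_goal^2))
        gb <- if (state %in% c("to_far", "to_near")) 0.85 else
          if (state == "at_far") min(0.8, dg / 120) else
          min(0.7, dg / 500) # loose tether while foraging near a goal
        mix <- b$turning_concentration
        dir <- (1 - gb) * (mix * c(sin(heading), cos(heading))) +
          (gb + (1 - gb) * (1 - mix)) * (if (dg > 1) to_goal / dg else c(0, 0))
        base_ang <- atan2(dir[1], dir[2])
        for (prop in 1:20) {
          ang <- base_ang + stats::rnorm(1, 0, 30 * pi / 180)
          len <- stats::rgamma(1, shape = 2, scale = b$step_scale / 2)
          cand <- pos + len * c(sin(ang), cos(ang))
          if (!extent_ok(cand)) next
          cat_ <- classify_point(map, cand[1], cand[2])
          if (stats::runif(1) < b$attraction_weights[cat_] / wmax) break
        }
        if (extent_ok(cand)) { pos <- cand; heading <- ang }
        if (state == "to_far" && sqrt(sum((pos - b$far_site)^2)) < 60) {
          state <- "at_far"; dwell <- 16L + stats::rpois(1, 10)
        } else if (state == "at_far") {
          dwell <- dwell - 1L
          if (dwell <= 0L) state <- "to_near"
        } else if (state == "to_near" &&
                   sqrt(sum((pos - b$roost)^2)) < 60) state <- "near"
      }
      xs[i] <- pos[1]; ys[i] <- pos[2]
      cat_ <- classify_point(map, pos[1], pos[2])
      use_tally[cat_] <- use_tally[cat_] + 1
    }
    out[[s]] <- data.frame(
      timestamp = (s - 1) * 86400 + seq_len(steps) * b$fix_interval,
      bat_id = bat_id, session_id = s, x = xs, y = ys)
  }
  list(fixes = do.call(rbind, out),
       truth = list(behavior = unclass(b), use_tally = use_tally,
                    seed = seed))
}

#' Simulate two-observer bearings for a true track
#'
#' For every true fix, two observers are placed around the bat at
#' distances up to `observer_offset` (capped at 350 m) with an
#' inter-observer angular separation drawn uniformly in \[40, 140\] degrees
#' as seen from the bat — so the separation filter is typically
#' satisfiable — and report the true azimuths to the bat perturbed by
#' wrapped-normal noise with standard deviation `bearing_sd` degrees.
#'
#' @param fixes true fixes (`timestamp`, `bat_id`, `x`, `y`).
#' @param bearing_sd bearing noise sd in degrees (default 2).
#' @param observer_offset nominal observer distance in meters (default 200).
#' @param contact per-session probability that a scheduled fix is actually
#'   observed (1 = full contact); either a single number or a vector
#'   recycled over sessions.
#' @param seed RNG seed.
#' @return data frame in the bearing-table schema (`timestamp`, `bat_id`,
#'   `obs1_x`, `obs1_y`, `azimuth1_deg`, `obs2_x`, `obs2_y`,
#'   `azimuth2_deg`, `activity`).
#' @export
simulate_bearings <- function(fixes, bearing_sd = 2, observer_offset = 200,
                              contact = 1, seed = 1) {
  stopifnot(bearing_sd >= 0)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (!is.null(fixes$session_id)) {
    sess <- fixes$session_id
  } else sess <- rep(1L, nrow(fixes))
  contact <- rep_len(contact, max(sess))
  keep <- stats::runif(nrow(fixes)) < contact[sess]
  f <- fixes[keep, , drop = FALSE]
  n <- nrow(f)
  base <- stats::runif(n, 0, 360)
  sep <- stats::runif(n, 40, 140)
  phi1 <- (base - sep / 2) * pi / 180
  phi2 <- (base + sep / 2) * pi / 180
  d1 <- pmin(stats::runif(n, 0.4, 1) * observer_offset, 350)
  d2 <- pmin(stats::runif(n, 0.4, 1) * observer_offset, 350)
  o1x <- f$x + d1 * sin(phi1); o1y <- f$y + d1 * cos(phi1)
  o2x <- f$x + d2 * sin(phi2); o2y <- f$y + d2 * cos(phi2)
  az <- function(ox, oy) (atan2(f$x - ox, f$y - oy) * 180 / pi) %% 360
  noise <- function(n) if (bearing_sd > 0) stats::rnorm(n, 0, bearing_sd) else 0
  data.frame(timestamp = f$timestamp, bat_id = f$bat_id,
             obs1_x = o1x, obs1_y = o1y,
             azimuth1_deg = (az(o1x, o1y) + noise(n)) %% 360,
             obs2_x = o2x, obs2_y = o2y,
             azimuth2_deg = (az(o2x, o2y) + noise(n)) %% 360,
             activity = "flying")
}

#' Generate a complete synthetic telemetry study
#'
#' End-to-end reproducible fixture: a landscape, `n_bats` tracks (a
#' fraction of them commuters with a far foraging site 300-1100 m from the
#' roost, placed in degraded habitat where possible), noisy two-observer
#' bearings with imperfect per-session contact, and the full ground truth.
#' The defaults emulate the study conditions the analysis was designed
#' for: 16 bats, 5/16 commuters, six 6-h sessions at 2-min fix intervals,
#' and accepted-fix counts per bat on the order of 100-400 after
#' filtering and deduplication.
#'
#' @param n_bats number of bats (default 16).
#' @param commuter_fraction fraction of commuters (default 5/16).
#' @param config a [landscape_config()] (default `landscape_config(seed =
#'   seed)`).
#' @param bearing_sd bearing noise sd (degrees, default 2).
#' @param sessions sessions per bat (default 6).
#' @param seed study seed; all per-bat seeds derive from it.
#' @return list with `map`, `bearings`, `roosts` (data frame `bat_id`,
#'   `x`, `y`), `truth` (per-bat behaviour, true tracks, landscape truth).
#' @export
generate_study <- function(n_bats = 16, commuter_fraction = 5 / 16,
                           config = NULL, bearing_sd = 2, sessions = 6,
                           seed = 1) {
  stopifnot(n_bats >= 2)
  if (is.null(config)) config <- landscape_config(seed = seed)
  land <- generate_landscape(config)
  map <- land$map
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  centers <- land$truth$patch_centers
  radii <- land$truth$patch_radii
  n_comm <- round(commuter_fraction * n_bats)
  modes <- sample(c(rep("commuter", n_comm),
                    rep("resident", n_bats - n_comm)))
  cell <- map$cellsize
  deg_cells <- which(map$codes == 1L, arr.ind = TRUE)
  deg_xy <- cbind(map$xll + (deg_cells[, 2] - 0.5) * cell,
                  map$yll + (deg_cells[, 1] - 0.5) * cell)
  nat_cells <- which(map$codes == 0L, arr.ind = TRUE)
  nat_xy <- cbind(map$xll + (nat_cells[, 2] - 0.5) * cell,
                  map$yll + (nat_cells[, 1] - 0.5) * cell)
  comm_seen <- 0L

  tracks <- vector("list", n_bats)
  bearings <- vector("list", n_bats)
  roosts <- data.frame(bat_id = character(0), x = numeric(0), y = numeric(0))
  for (j in seq_len(n_bats)) {
    p <- ((j - 1) %% nrow(centers)) + 1
    # roost near the fragment centre, guaranteed natural
    repeat {
      ang <- stats::runif(1, 0, 2 * pi)
      roost <- centers[p, ] + stats::runif(1, 0.72, 0.92) * radii[p] *
        c(cos(ang), sin(ang))
      if (classify_point(map, roost[1], roost[2]) == "natural") break
    }
    far <- NULL
    if (modes[j] == "commuter") {
      comm_seen <- comm_seen + 1L
      # most far foraging sites are degraded stands; occasionally (first
      # commuter, ~1 in 5) the far site lies in natural forest instead
      target_xy <- if (comm_seen == 1L) nat_xy else deg_xy
      d <- sqrt((target_xy[, 1] - roost[1])^2 +
                (target_xy[, 2] - roost[2])^2)
      cand <- which(d >= 300 & d <= 1100)
      far <- if (length(cand)) {
        # aim near the middle of the commuting-distance band
        target_xy[cand[which.min(abs(d[cand] - 660))], ]
      } else roost + c(660, 0)
    }
    beh <- bat_behavior(mode = modes[j], roost = roost, far_site = far,
                        sessions = sessions)
    tr <- simulate_track(map, beh, bat_id = paste0("bat", j),
                         seed = seed * 1000L + j)
    contact <- stats::rbeta(sessions, 24, 2.5) # most sessions above 0.85
    br <- simulate_bearings(tr$fixes, bearing_sd = bearing_sd,
                            contact = contact,
                            seed = seed * 1000L + 500L + j)
    tracks[[j]] <- tr
    bearings[[j]] <- br
    roosts <- rbind(roosts, data.frame(bat_id = paste0("bat", j),
                                       x = roost[1], y = roost[2]))
  }
  list(map = map,
       bearings = do.call(rbind, bearings),
       roosts = roosts,
       truth = list(landscape = land$truth, modes = modes,
                    tracks = tracks, seed = seed))
}
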