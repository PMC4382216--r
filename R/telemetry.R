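#' Angular separation between two compass bearings
#'
#' Smallest angle between two azimuths measured in degrees clockwise from
#' grid north; symmetric in its arguments and bounded in \[0, 180\].
#'
#' @param azimuth_1,azimuth_2 azimuths in degrees, in \[0, 360).
#' @return separation in degrees.
#' @examples
#' bearing_separation(45, 315) # 90
#' bearing_separation(10, 350) # 20
#' @export
bearing_separation <- function(azimuth_1, azimuth_2) {
  if (!all(is.finite(azimuth_1)) || !all(is.finite(azimuth_2)))
    stop("invalid input: non-finite azimuth")
  abs(((azimuth_1 - azimuth_2 + 180) %% 360) - 180)
}

#' Biangulate one pair of simultaneous bearings
#'
#' Estimates a transmitter location as the intersection of two bearing rays
#' taken by coordinated observers. A pair is accepted only if (in this
#' order) the angular separation lies within `sep_bounds`, the intersection
#' lies forward of both observers, and the fix is within `max_range` of
#' each observer. Azimuths are degrees clockwise from grid north, so a ray
#' from observer `o` with azimuth `a` is `o + t * (sin a, cos a)`, `t >= 0`.
#'
#' @param obs1,obs2 numeric length-2 observer positions (x, y) in meters.
#' @param azimuth_1,azimuth_2 azimuths in degrees.
#' @param max_range maximum transmitter range in meters (default 400).
#' @param sep_bounds acceptable separation interval in degrees
#'   (default `c(15, 165)`).
#' @param declination additive magnetic-declination correction in degrees
#'   applied to both azimuths (default 0).
#' @return list with `accepted` (logical); when accepted, `x`, `y` and the
#'   observer distances `range_1`, `range_2`; when rejected, `reason`, one
#'   of `"separation"`, `"behind-observer"`, `"out-of-range"`.
#' @examples
#' triangulate_pair(c(0, 0), c(100, 0), 45, 315) # fix at (50, 50)
#' @export
triangulate_pair <- function(obs1, obs2, azimuth_1, azimuth_2,
                             max_range = 400, sep_bounds = c(15, 165),
                             declination = 0) {
  stopifnot(length(obs1) == 2, length(obs2) == 2)
  if (!all(is.finite(c(obs1, obs2, azimuth_1, azimuth_2))))
    stop("invalid input: non-finite bearing record")
  if (all(obs1 == obs2)) stop("invalid input: coincident observer positions")
  a1 <- (azimuth_1 + declination) %% 360
  a2 <- (azimuth_2 + declination) %% 360
  sep <- bearing_separation(a1, a2)
  if (sep < sep_bounds[1] || sep > sep_bounds[2])
    return(list(accepted = FALSE, reason = "separation", separation = sep))
  d1 <- c(sin(a1 * pi / 180), cos(a1 * pi / 180))
  d2 <- c(sin(a2 * pi / 180), cos(a2 * pi / 180))
  # o1 + t1 d1 = o2 + t2 d2 ; separation filter excludes parallel rays
  A <- cbind(d1, -d2)
  t <- solve(A, obs2 - obs1)
  if (t[1] < 0 || t[2] < 0)
    return(list(accepted = FALSE, reason = "behind-observer", separation = sep))
  if (t[1] > max_range || t[2] > max_range)
    return(list(accepted = FALSE, reason = "out-of-range", separation = sep))
  p <- obs1 + t[1] * d1
  list(accepted = TRUE, x = unname(p[1]), y = unname(p[2]),
       range_1 = unname(t[1]), range_2 = unname(t[2]), separation = sep)
}

#' Triangulate a table of bearing records
#'
#' Applies [triangulate_pair()] to every row of a bearing table and splits
#' the result into accepted fixes and a rejection log.
#'
#' @param bearings data frame with columns `timestamp`, `bat_id`, `obs1_x`,
#'   `obs1_y`, `azimuth1_deg`, `obs2_x`, `obs2_y`, `azimuth2_deg` and
#'   optionally `activity`.
#' @inheritParams triangulate_pair
#' @return list with `fixes` (data frame `timestamp`, `bat_id`, `x`, `y`)
#'   and `rejections` (data frame `timestamp`, `bat_id`, `reason`).
#' @export
triangulate_bearings <- function(bearings, max_range = 400,
                                 sep_bounds = c(15, 165), declination = 0) {
  need <- c("timestamp", "bat_id", "obs1_x", "obs1_y", "azimuth1_deg",
            "obs2_x", "obs2_y", "azimuth2_deg")
  miss <- setdiff(need, names(bearings))
  if (length(miss)) stop("bearing table is missing columns: ",
                         paste(miss, collapse = ", "))
  n <- nrow(bearings)
  x <- y <- rep(NA_real_, n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    r <- triangulate_pair(
      c(bearings$obs1_x[i], bearings$obs1_y[i]),
      c(bearings$obs2_x[i], bearings$obs2_y[i]),
      bearings$azimuth1_deg[i], bearings$azimuth2_deg[i],
      max_range = max_range, sep_bounds = sep_bounds,
      declination = declination
    )
    if (r$accepted) { x[i] <- r$x; y[i] <- r$y } else reason[i] <- r$reason
  }
  ok <- is.na(reason)
  list(
    fixes = data.frame(timestamp = bearings$timestamp[ok],
                       bat_id = bearings$bat_id[ok],
                       x = x[ok], y = y[ok]),
    rejections = data.frame(timestamp = bearings$timestamp[!ok],
                            bat_id = bearings$bat_id[!ok],
                            reason = reason[!ok])
  )
}

#' Collapse stationary runs of fixes
#'
#' A transmitter that stays in place produces runs of fixes at (almost) the
#' same position; to reduce spatial autocorrelation each maximal run of
#' consecutive fixes within `stationary_radius` of the run's first fix is
#' collapsed to that first fix. The output is a subsequence of the input
#' and the operation is idempotent.
#'
#' @param fixes data frame with columns `x`, `y`, time-ordered, one animal.
#' @param stationary_radius radius in meters defining "same place"
#'   (default 50, on the order of typical biangulation error).
#' @return the retained rows of `fixes`.
#' @export
deduplicate_stationary <- function(fixes, stationary_radius = 50) {
  if (!is.finite(stationary_radius) || stationary_radius < 0)
    stop("invalid input: stationary_radius must be >= 0")
  n <- nrow(fixes)
  if (n <= 1) return(fixes)
  keep <- logical(n)
  anchor <- 1L
  keep[1] <- TRUE
  for (i in seq.int(2L, n)) {
    d <- sqrt((fixes$x[i] - fixes$x[anchor])^2 +
              (fixes$y[i] - fixes$y[anchor])^2)
    if (d > stationary_radius) {
      keep[i] <- TRUE
      anchor <- i
    }
  }
  fixes[keep, , drop = FALSE]
}

#' Assign fixes to observation sessions
#'
#' Sessions are nightly observation windows (nominally 6 h). They are
#' either supplied as a data frame of `start`/`end` times (seconds) or
#' inferred by splitting the fix sequence at gaps longer than `gap`.
#'
#' @param fixes time-ordered data frame with a `timestamp` column (seconds).
#' @param sessions optional data frame with columns `start`, `end`.
#' @param gap gap length in seconds that separates inferred sessions
#'   (default 7200, i.e. 2 h).
#' @return `fixes` with an integer `session_id` column (1-based); fixes
#'   outside every supplied window get `NA` and are dropped with a warning.
#' @export
assign_sessions <- function(fixes, sessions = NULL, gap = 7200) {
  if (nrow(fixes) == 0) return(cbind(fixes, session_id = integer(0)))
  ts <- fixes$timestamp
  if (is.unsorted(ts)) stop("fixes must be time-ordered")
  if (is.null(sessions)) {
    id <- cumsum(c(1L, as.integer(diff(ts) > gap)))
  } else {
    id <- rep(NA_integer_, length(ts))
    for (s in seq_len(nrow(sessions)))
      id[ts >= sessions$start[s] & ts <= sessions$end[s]] <- s
    if (anyNA(id)) {
      warning(sum(is.na(id)), " fixes fall outside every session window; dropped")
      fixes <- fixes[!is.na(id), , drop = FALSE]
      id <- id[!is.na(id)]
    }
  }
  fixes$session_id <- id
  fixes
}

#' Select the best-contact sessions of a track
#'
#' Ranks sessions by achieved contact (fixes obtained / fixes scheduled)
#' and keeps the `n_sessions` best among those at or above
#' `min_contact_fraction`. If fewer sessions qualify, all qualifying
#' sessions are returned and the result is flagged. Ties are broken in
#' favour of the earlier session.
#'
#' @param fixes data frame with `session_id` (deduplication not yet applied;
#'   contact is judged on raw triangulated fixes).
#' @param scheduled named vector or data frame giving the scheduled number
#'   of fixes per session (session length / fix interval).
#' @param min_contact_fraction minimum achieved-fix fraction (default 0.85).
#' @param n_sessions number of sessions to keep (default 3).
#' @return list with `session_ids` (kept, in rank order), `fractions`
#'   (achieved fraction for every session) and `flagged` (TRUE when fewer
#'   than `n_sessions` sessions qualified).
#' @export
select_sessions <- function(fixes, scheduled, min_contact_fraction = 0.85,
                            n_sessions = 3) {
  if (is.data.frame(scheduled))
    scheduled <- stats::setNames(scheduled$scheduled, scheduled$session_id)
  if (nrow(fixes) == 0 || length(scheduled) == 0)
    stop("invalid input: track has no sessions")
  counts <- table(factor(fixes$session_id, levels = names(scheduled)))
  frac <- as.numeric(counts) / as.numeric(scheduled)
  names(frac) <- names(scheduled)
  ok <- which(frac >= min_contact_fraction)
  ord <- ok[order(-frac[ok], ok)] # ties: earliest session first
  keep <- utils::head(ord, n_sessions)
  list(session_ids = as.integer(names(frac)[keep]),
       fractions = frac,
       flagged = length(keep) < n_sessions)
}
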