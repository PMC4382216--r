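#' Percent minimum convex polygon
#'
#' Computes the MCP home-range estimator at a given percent level: the
#' `ceiling(level/100 * n)` points closest to the arithmetic centroid of
#' all points are retained (single-pass peeling) and their convex hull is
#' returned. `level = 100` is the hull of all points.
#'
#' @param x,y fix coordinates in meters.
#' @param level percent of points retained, in (0, 100\] (default 95).
#' @return a `simple_polygon` (the hull), with attribute `kept` giving the
#'   indices of the retained points.
#' @export
mcp <- function(x, y, level = 95) {
  stopifnot(length(x) == length(y), level > 0, level <= 100)
  n <- length(x)
  if (n < 3) stop("degenerate geometry: need >= 3 points")
  cx <- mean(x); cy <- mean(y)
  d <- sqrt((x - cx)^2 + (y - cy)^2)
  keep <- order(d)[seq_len(ceiling(level / 100 * n))]
  hull <- convex_hull_polygon(x[keep], y[keep])
  attr(hull, "kept") <- sort(keep)
  hull
}

#' Number of nearest neighbours for fixed k-LoCoH
#'
#' The hull parameter is tied to sample size as `k = round(sqrt(n))`
#' (round-half-up), clamped to `[3, n]`. `rounding = "floor"` truncates
#' instead.
#'
#' @param n number of fixes (>= 9).
#' @param rounding `"round"` (half-up, default) or `"floor"`.
#' @return integer k.
#' @examples
#' locoh_k_from_n(416) # 20
#' @export
locoh_k_from_n <- function(n, rounding = c("round", "floor")) {
  rounding <- match.arg(rounding)
  if (!is.finite(n) || n < 9) stop("insufficient data: need >= 9 fixes")
  k <- switch(rounding,
    round = floor(sqrt(n) + 0.5),
    floor = floor(sqrt(n))
  )
  as.integer(min(max(k, 3), n))
}

#' Fixed k-LoCoH isopleth
#'
#' Builds one local convex hull per fix from the fix and its `k - 1`
#' nearest neighbours (Euclidean distance; ties broken by input index),
#' sorts the hulls by ascending area (ties by root index) and unions them
#' in order until the union contains at least `fraction * n` of the fixes.
#' The union is reported as its disjoint connected components; hulls that
#' touch or overlap belong to the same component.
#'
#' Hulls that collapse below three distinct vertices (duplicate or
#' collinear points) contribute zero area but still cover their own member
#' points.
#'
#' @param x,y fix coordinates in meters.
#' @param k number of points per hull (root + k - 1 neighbours), >= 3. The
#'   alternative convention (k neighbours plus the root, k + 1 points per
#'   hull) is selected with `neighbour_rule = "k-plus-root"`.
#' @param fraction target fraction of fixes covered (default 0.5).
#' @param neighbour_rule `"k-total"` (default) or `"k-plus-root"`.
#' @return object of class `locoh_isopleth`: list with `components` (each a
#'   list of `simple_polygon` hulls), `covered` (indices of fixes inside
#'   the union), `hull_order` (root indices of the hulls used, in union
#'   order), `n`, `k`, `fraction`.
#' @export
locoh_isopleth <- function(x, y, k, fraction = 0.5,
                           neighbour_rule = c("k-total", "k-plus-root")) {
  neighbour_rule <- match.arg(neighbour_rule)
  stopifnot(length(x) == length(y))
  n <- length(x)
  m <- if (neighbour_rule == "k-total") k else k + 1L
  if (k < 3) stop("k must be >= 3")
  if (n < m) stop("insufficient data: need >= ", m, " fixes")

  d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
  hulls <- vector("list", n)
  areas <- numeric(n)
  for (i in seq_len(n)) {
    nb <- order(d2[i, ], seq_len(n))[seq_len(m)] # root is its own nearest
    hulls[[i]] <- local_hull(x[nb], y[nb], members = nb)
    areas[i] <- hulls[[i]]$area
  }

  ord <- order(areas, seq_len(n))
  covered <- logical(n)
  used <- integer(0)
  target <- fraction * n
  for (i in ord) {
    used <- c(used, i)
    covered <- covered | hull_covers(hulls[[i]], x, y)
    if (sum(covered) >= target) break
  }

  comp <- hull_components(hulls[used])
  components <- lapply(comp, function(idx) hulls[used][idx])
  structure(
    list(components = components, covered = which(covered),
         hull_order = used, n = n, k = as.integer(k), fraction = fraction),
    class = "locoh_isopleth"
  )
}

# hull of a local point set; degenerate sets (collinear/duplicate) fall back
# to a zero-area record that still covers its member points
local_hull <- function(x, y, members) {
  h <- tryCatch(convex_hull_polygon(x, y), error = function(e) NULL)
  if (is.null(h)) {
    h <- structure(list(x = x, y = y, area = 0,
                        perimeter = 2 * ring_perimeter(x, y)),
                   class = c("degenerate_hull", "simple_polygon"))
  }
  h$members <- members
  h
}

hull_covers <- function(h, x, y) {
  if (inherits(h, "degenerate_hull")) {
    out <- logical(length(x))
    out[h$members] <- TRUE
    return(out)
  }
  point_in_convex(h, x, y)
}

# connected components of the hull-overlap graph (touching merges)
hull_components <- function(hulls) {
  m <- length(hulls)
  if (m == 0) return(list())
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (m > 1) {
    for (i in seq_len(m - 1)) for (j in seq.int(i + 1, m)) {
      if (find(i) != find(j) && hulls_touch(hulls[[i]], hulls[[j]]))
        parent[find(j)] <- find(i)
    }
  }
  roots <- vapply(seq_len(m), find, integer(1))
  unname(split(seq_len(m), roots))
}

hulls_touch <- function(a, b) {
  if (inherits(a, "degenerate_hull") || inherits(b, "degenerate_hull")) {
    # degenerate hulls attach through shared or contained points
    if (inherits(b, "degenerate_hull") && !inherits(a, "degenerate_hull"))
      return(any(point_in_convex(a, b$x, b$y)))
    if (inherits(a, "degenerate_hull") && !inherits(b, "degenerate_hull"))
      return(any(point_in_convex(b, a$x, a$y)))
    return(any(outer(a$x, b$x, "==") & outer(a$y, b$y, "==")))
  }
  convex_overlap(a, b)
}

#' Count focus areas of an isopleth
#'
#' Focus (focal foraging) areas are the disjoint connected components of a
#' LoCoH isopleth; hulls that touch are merged before counting.
#'
#' @param isopleth a `locoh_isopleth`.
#' @return integer count (0 for an empty isopleth).
#' @export
count_focus_areas <- function(isopleth) {
  stopifnot(inherits(isopleth, "locoh_isopleth"))
  length(isopleth$components)
}

#' Assign points to isopleth components
#'
#' For each disjoint component of a LoCoH isopleth, flags which of the
#' supplied points fall inside any of the component's hulls.
#'
#' @param isopleth a `locoh_isopleth`.
#' @param x,y point coordinates.
#' @return list of logical vectors, one per component.
#' @export
focus_membership <- function(isopleth, x, y) {
  lapply(isopleth$components, function(hulls) {
    inside <- rep(FALSE, length(x))
    for (h in hulls) inside <- inside | hull_covers(h, x, y)
    inside
  })
}

#' Area of an isopleth union by lattice sampling
#'
#' The union of local hulls is measured on a deterministic regular lattice
#' of spacing `cell` meters: the union area is the number of lattice points
#' inside any hull times `cell^2`. Exactness improves as `cell` shrinks.
#'
#' @param isopleth a `locoh_isopleth`.
#' @param cell lattice spacing in meters (default 5).
#' @return list with `total` area (m^2) and `per_component` areas.
#' @export
isopleth_area <- function(isopleth, cell = 5) {
  comps <- isopleth$components
  if (length(comps) == 0) return(list(total = 0, per_component = numeric(0)))
  per <- vapply(comps, function(hulls) {
    xs <- unlist(lapply(hulls, `[[`, "x"))
    ys <- unlist(lapply(hulls, `[[`, "y"))
    gx <- seq(min(xs) - cell, max(xs) + cell, by = cell)
    gy <- seq(min(ys) - cell, max(ys) + cell, by = cell)
    g <- expand.grid(x = gx, y = gy)
    inside <- logical(nrow(g))
    for (h in hulls) if (!inherits(h, "degenerate_hull"))
      inside <- inside | point_in_convex(h, g$x, g$y)
    sum(inside) * cell^2
  }, numeric(1))
  list(total = sum(per), per_component = per)
}

#' Per-session daily ranges
#'
#' The daily range is the 95% MCP of the fixes of one observation session
#' (nominally 6 h). Sessions with fewer than 3 usable fixes, or whose fixes
#' are collinear, are skipped with a warning.
#'
#' @param fixes data frame with `x`, `y`, `session_id` for one animal,
#'   deduplicated.
#' @param level MCP percent level (default 95).
#' @return data frame `session_id`, `n_fixes`, `area` (m^2), `log_area`
#'   (natural log of m^2), plus a list column `polygon`.
#' @export
daily_ranges <- function(fixes, level = 95) {
  out <- lapply(split(fixes, fixes$session_id), function(s) {
    poly <- tryCatch(mcp(s$x, s$y, level = level), error = function(e) NULL)
    if (is.null(poly)) {
      warning("session ", s$session_id[1],
              " skipped: fewer than 3 usable fixes or degenerate geometry")
      return(NULL)
    }
    data.frame(session_id = s$session_id[1], n_fixes = nrow(s),
               area = poly$area, log_area = log(poly$area),
               polygon = I(list(poly)))
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Per-animal home-range summary
#'
#' Runs the full home-range stage for one track: 95% and 100% MCPs, fixed
#' k-LoCoH 50% isopleth with `k = round(sqrt(n))`, focus-area count and
#' compactness of the 95% MCP.
#'
#' @param fixes deduplicated data frame with `x`, `y` for one animal.
#' @param mcp_level MCP percent level (default 95).
#' @param locoh_fraction isopleth fraction (default 0.5).
#' @param k_rounding passed to [locoh_k_from_n()].
#' @return list with `hr_tot_ha`, `n_fixes`, `compactness`,
#'   `n_focus_areas`, `mcp95`, `mcp100`, `isopleth`, `k`.
#' @export
home_range <- function(fixes, mcp_level = 95, locoh_fraction = 0.5,
                       k_rounding = "round") {
  n <- nrow(fixes)
  m95 <- mcp(fixes$x, fixes$y, level = mcp_level)
  m100 <- mcp(fixes$x, fixes$y, level = 100)
  k <- locoh_k_from_n(n, rounding = k_rounding)
  iso <- locoh_isopleth(fixes$x, fixes$y, k = k, fraction = locoh_fraction)
  list(hr_tot_ha = m95$area / 1e4, n_fixes = n,
       compactness = compactness_ratio(m95),
       n_focus_areas = count_focus_areas(iso),
       mcp95 = m95, mcp100 = m100, isopleth = iso, k = k)
}
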