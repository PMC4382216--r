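#' Land-cover categories
#'
#' The five structural land-cover classes used throughout the package, in
#' their canonical order (grid code = position - 1).
#' @export
landcover_categories <- function() {
  c("natural", "degraded", "farmland", "pasture", "urban")
}

#' Categorical land-cover map on a regular grid
#'
#' The grid dialect of the land-cover map: integer category codes 0-4 on a
#' regular planar lattice. Cell ownership is half-open in both axes: the
#' cell at column `i`, row `j` owns `[x0 + (i-1) cell, x0 + i cell) x
#' [y0 + (j-1) cell, y0 + j cell)`.
#'
#' @param codes integer matrix (rows = y from the bottom, cols = x) with
#'   values in 0..4.
#' @param xll,yll lower-left corner coordinates (meters).
#' @param cellsize cell edge length (meters).
#' @return object of class `landcover_grid`.
#' @export
landcover_grid <- function(codes, xll = 0, yll = 0, cellsize = 10) {
  stopifnot(is.matrix(codes), all(codes %in% 0:4), cellsize > 0)
  structure(list(codes = codes, xll = xll, yll = yll, cellsize = cellsize,
                 categories = landcover_categories()),
            class = "landcover_grid")
}

#' @export
print.landcover_grid <- function(x, ...) {
  cat(sprintf("<landcover_grid> %d x %d cells of %g m, origin (%g, %g)\n",
              ncol(x$codes), nrow(x$codes), x$cellsize, x$xll, x$yll))
  invisible(x)
}

#' Categorical land-cover map from labelled polygons
#'
#' The polygon dialect: a list of category-labelled `simple_polygon`
#' features over a declared background category. Points on a shared
#' boundary resolve to the polygon listed first.
#'
#' @param polygons list of `simple_polygon` (convex not required for
#'   containment tests here; vertices define a simple ring).
#' @param categories character vector, one category per polygon.
#' @param background category for points in no polygon (default "pasture").
#' @return object of class `landcover_polygons`.
#' @export
landcover_polygons <- function(polygons, categories, background = "pasture") {
  stopifnot(length(polygons) == length(categories),
            all(categories %in% landcover_categories()),
            background %in% landcover_categories())
  structure(list(polygons = polygons, poly_categories = categories,
                 background = background,
                 categories = landcover_categories()),
            class = "landcover_polygons")
}

# even-odd ray-casting containment for a simple (not necessarily convex) ring
point_in_ring <- function(poly, px, py) {
  n <- length(poly$x)
  j <- c(n, seq_len(n - 1L))
  inside <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    xi <- poly$x[i]; yi <- poly$y[i]
    xj <- poly$x[j[i]]; yj <- poly$y[j[i]]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
  }
  inside
}

#' Classify points by land cover
#'
#' @param map a `landcover_grid` or `landcover_polygons`.
#' @param px,py point coordinates (vectors).
#' @return character vector of categories.
#' @export
classify_point <- function(map, px, py) UseMethod("classify_point", map)

#' @export
classify_point.landcover_grid <- function(map, px, py) {
  ci <- floor((px - map$xll) / map$cellsize) + 1L
  ri <- floor((py - map$yll) / map$cellsize) + 1L
  bad <- ci < 1 | ci > ncol(map$codes) | ri < 1 | ri > nrow(map$codes)
  if (any(bad)) stop("out of extent: ", sum(bad), " point(s) outside the map")
  map$categories[map$codes[cbind(ri, ci)] + 1L]
}

#' @export
classify_point.landcover_polygons <- function(map, px, py) {
  out <- rep(map$background, length(px))
  undecided <- rep(TRUE, length(px))
  for (i in seq_along(map$polygons)) { # first-listed polygon wins ties
    if (!any(undecided)) break
    hit <- undecided & point_in_ring(map$polygons[[i]], px, py)
    out[hit] <- map$poly_categories[i]
    undecided <- undecided & !hit
  }
  out
}

#' Per-animal availability circle
#'
#' Available habitat for one animal is the disc centred on its day roost
#' (the mean of the roost coordinates when several roosts were used) whose
#' radius is the maximum distance from that centre to the boundary of the
#' animal's 95% MCP — attained at an MCP vertex.
#'
#' @param roosts data frame or matrix with roost `x`, `y` (>= 1 row).
#' @param mcp95 the animal's 95% MCP (`simple_polygon`).
#' @return list with `center` (x, y) and `radius` (m).
#' @export
availability_circle <- function(roosts, mcp95) {
  roosts <- as.data.frame(roosts)
  if (nrow(roosts) == 0) stop("invalid input: empty roost list")
  cx <- mean(roosts$x); cy <- mean(roosts$y)
  r <- max(sqrt((mcp95$x - cx)^2 + (mcp95$y - cy)^2))
  list(center = c(x = cx, y = cy), radius = r)
}

#' Habitat composition of a region
#'
#' Area fractions of the land-cover categories within a disc or polygon,
#' measured on a deterministic regular lattice of spacing `cell` meters
#' (lattice points inside the region are classified and tallied).
#' Fractions sum to 1.
#'
#' @param map a land-cover map.
#' @param region either `list(center =, radius =)` (a disc, e.g. from
#'   [availability_circle()]) or a `simple_polygon`.
#' @param cell sampling lattice spacing in meters (default: the grid's own
#'   cell size for grid maps, 10 m for polygon maps).
#' @return named numeric vector of fractions over all five categories,
#'   with attribute `n_cells` (lattice points used).
#' @export
composition <- function(map, region, cell = NULL) {
  if (is.null(cell))
    cell <- if (inherits(map, "landcover_grid")) map$cellsize else 10
  if (inherits(region, "simple_polygon")) {
    xr <- range(region$x); yr <- range(region$y)
    inside_region <- function(px, py) point_in_ring(region, px, py)
  } else {
    stopifnot(!is.null(region$center), !is.null(region$radius))
    xr <- region$center[1] + c(-1, 1) * region$radius
    yr <- region$center[2] + c(-1, 1) * region$radius
    inside_region <- function(px, py)
      (px - region$center[1])^2 + (py - region$center[2])^2 <= region$radius^2
  }
  gx <- seq(xr[1] + cell / 2, xr[2], by = cell)
  gy <- seq(yr[1] + cell / 2, yr[2], by = cell)
  g <- expand.grid(x = gx, y = gy)
  g <- g[inside_region(g$x, g$y), , drop = FALSE]
  if (nrow(g) == 0) stop("out of extent: region contains no sampling points")
  # silently drop lattice points beyond a grid map's extent (region clipping)
  cats <- tryCatch(classify_point(map, g$x, g$y), error = function(e) {
    if (inherits(map, "landcover_grid")) {
      ok <- g$x >= map$xll & g$x < map$xll + ncol(map$codes) * map$cellsize &
            g$y >= map$yll & g$y < map$yll + nrow(map$codes) * map$cellsize
      if (!any(ok)) stop("out of extent: region fully outside the map")
      g <<- g[ok, , drop = FALSE]
      classify_point(map, g$x, g$y)
    } else stop(e)
  })
  tab <- table(factor(cats, levels = landcover_categories()))
  out <- as.numeric(tab) / sum(tab)
  names(out) <- landcover_categories()
  attr(out, "n_cells") <- nrow(g)
  out
}

#' Manly design-III habitat-selection ratios
#'
#' Pooled selection ratios with use and availability measured per animal
#' (design III): `w_i = sum_j u_ij / sum_j u_+j pi_ij`, where `u_ij` is the
#' number of fixes of animal `j` in category `i` and `pi_ij` the fraction
#' of category `i` available to animal `j`. Standard errors come from the
#' ratio-estimator variance over animals, simultaneous Bonferroni
#' confidence bounds use the `alpha / (2 I)` normal quantile (`I` =
#' categories with nonzero availability) with negative lower bounds
#' truncated to 0, and the global log-likelihood chi-square tests identical
#' use and availability with `df = sum_j (I_j - 1)`.
#'
#' @param used integer matrix of fix counts, animals in rows, categories in
#'   columns (named by category).
#' @param available numeric matrix of availability fractions, same shape,
#'   rows summing to 1.
#' @param alpha simultaneous error rate (default 0.05).
#' @return data frame `category`, `wi`, `se`, `ci_low`, `ci_high`, with
#'   attributes `chi2`, `df`, `p`.
#' @export
selection_ratios <- function(used, available, alpha = 0.05) {
  used <- as.matrix(used); available <- as.matrix(available)
  stopifnot(dim(used) == dim(available), nrow(used) >= 2,
            all(used >= 0), all(available >= 0))
  if (any(abs(rowSums(available) - 1) > 1e-6))
    stop("invalid input: availability rows must sum to 1")
  if (any(rowSums(used) == 0))
    stop("invalid input: every animal needs a nonzero total used count")
  if (any(used > 0 & available == 0))
    warning("category used but unavailable for some animal; ",
            "treated as available at the observed minimum")
  J <- nrow(used)
  u_tot <- rowSums(used)                  # u_+j
  E <- available * u_tot                  # expected use u_+j * pi_ij
  EA <- colSums(E)
  # a category available to no animal (and hence unusable) gets w = 0 and
  # no interval, mirroring the convention of printed selection tables
  wi <- ifelse(EA > 0, colSums(used) / EA, 0)
  # ratio-estimator variance over animals
  se <- sqrt(vapply(seq_len(ncol(used)), function(i) {
    if (EA[i] == 0) return(0)
    resid <- used[, i] - wi[i] * E[, i]
    sum(resid^2) * J / (J - 1) / EA[i]^2
  }, numeric(1)))
  I <- sum(colSums(available) > 0)
  z <- stats::qnorm(1 - alpha / (2 * I))
  ci_low <- pmax(wi - z * se, 0)
  ci_high <- wi + z * se
  ci_low[EA == 0] <- NA_real_
  ci_high[EA == 0] <- NA_real_
  # log-likelihood chi-square, 0 * log(0) = 0
  ll <- used * log(ifelse(used > 0, used / pmax(E, .Machine$double.xmin), 1))
  chi2 <- 2 * sum(ll[used > 0])
  df <- sum(apply(available > 0, 1, sum) - 1)
  out <- data.frame(category = colnames(used), wi = wi, se = se,
                    ci_low = ci_low, ci_high = ci_high, row.names = NULL)
  attr(out, "chi2") <- chi2
  attr(out, "df") <- df
  attr(out, "p") <- stats::pchisq(chi2, df, lower.tail = FALSE)
  attr(out, "alpha") <- alpha
  out
}

#' Exact Fisher test for an r x c contingency table
#'
#' Exact conditional p-value (probability mass of all tables with the
#' observed margins whose hypergeometric probability does not exceed the
#' observed one), delegated to the exact network algorithm in
#' [stats::fisher.test()]; tables whose margins exceed `max_cells` expected
#' workspace fall back to a seeded Monte-Carlo estimate with its standard
#' error attached.
#'
#' @param table non-negative integer matrix (2 x K here).
#' @param mc_budget approximate enumeration budget before the Monte-Carlo
#'   fallback engages (default 1e7).
#' @param B Monte-Carlo replicates for the fallback (default 1e5).
#' @param seed seed for the fallback (default 1).
#' @return p-value; when simulated, attributes `simulated = TRUE` and
#'   `mc_se`.
#' @export
fisher_exact_rxc <- function(table, mc_budget = 1e7, B = 1e5, seed = 1) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop("invalid input: counts must be non-negative integers")
  keep_c <- colSums(table) > 0
  keep_r <- rowSums(table) > 0
  table <- table[keep_r, keep_c, drop = FALSE]
  if (any(dim(table) < 2)) return(1) # nothing left to compare
  # crude size proxy: product of (margin + 1) over the free cells
  size <- prod(pmin(colSums(table), rowSums(table)[1]) + 1)
  if (size <= mc_budget) {
    stats::fisher.test(table, workspace = 2e7)$p.value
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    p <- stats::fisher.test(table, simulate.p.value = TRUE, B = B)$p.value
    attr(p, "simulated") <- TRUE
    attr(p, "mc_se") <- sqrt(p * (1 - p) / B)
    p
  }
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Holm (sequential Bonferroni) step-down correction
#'
#' Orders the p-values ascending and compares the i-th smallest to
#' `alpha / (m - i + 1)`; rejections form a prefix of the sorted list.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @param alpha family-wise error rate (default 0.05).
#' @return data frame `p`, `threshold`, `reject` in the input order.
#' @export
holm_bonferroni <- function(pvalues, alpha = 0.05) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  m <- length(pvalues)
  ord <- order(pvalues)
  thr <- alpha / (m - seq_len(m) + 1)
  pass <- pvalues[ord] <= thr
  # step-down: stop at the first failure
  if (any(!pass)) pass[seq.int(which.min(pass), m)] <- FALSE
  out <- data.frame(p = pvalues,
                    threshold = thr[order(ord)],
                    reject = pass[order(ord)])
  out
}
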