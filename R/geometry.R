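#' Planar polygon primitives
#'
#' Home ranges are planar polygons in a projected coordinate system (meters).
#' A `simple_polygon` stores an ordered, counterclockwise vertex ring
#' (implicitly closed) together with its shoelace area and perimeter. All
#' geometry in the package is planar; no reprojection is ever performed.
#'
#' @param x,y numeric vertex coordinates (meters), at least 3 vertices.
#' @return An object of class `simple_polygon` with elements `x`, `y`,
#'   `area` (m^2) and `perimeter` (m).
#' @examples
#' sq <- simple_polygon(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' sq$area      # 1
#' sq$perimeter # 4
#' @export
simple_polygon <- function(x, y) {
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  if (length(x) < 3) stop("degenerate geometry: a polygon needs >= 3 vertices")
  a <- signed_area(x, y)
  if (a < 0) { # enforce counterclockwise orientation
    x <- rev(x); y <- rev(y); a <- -a
  }
  if (a <= 0) stop("degenerate geometry: polygon has zero area")
  structure(
    list(x = x, y = y, area = a, perimeter = ring_perimeter(x, y)),
    class = "simple_polygon"
  )
}

#' @export
print.simple_polygon <- function(x, ...) {
  cat(sprintf("<simple_polygon> %d vertices, area %.6g m^2, perimeter %.6g m\n",
              length(x$x), x$area, x$perimeter))
  invisible(x)
}

# shoelace signed area; positive for counterclockwise rings
signed_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

ring_perimeter <- function(x, y) {
  n <- length(x)
  j <- c(seq.int(2L, n), 1L)
  sum(sqrt((x[j] - x)^2 + (y[j] - y)^2))
}

#' Convex hull of a point set as a `simple_polygon`
#'
#' @param x,y point coordinates (>= 3 non-collinear points).
#' @return A `simple_polygon`; vertex order is counterclockwise.
#' @export
convex_hull_polygon <- function(x, y) {
  stopifnot(length(x) == length(y))
  pts <- unique(data.frame(x = x, y = y))
  if (nrow(pts) < 3) stop("degenerate geometry: fewer than 3 distinct points")
  h <- grDevices::chull(pts$x, pts$y) # clockwise order
  if (length(h) < 3 || abs(signed_area(pts$x[h], pts$y[h])) < 1e-12)
    stop("degenerate geometry: points are collinear")
  simple_polygon(pts$x[h], pts$y[h])
}

#' Test whether points fall inside a convex polygon
#'
#' Boundary points count as inside (half-plane tests with tolerance `eps`,
#' scaled to the polygon's extent).
#'
#' @param poly a `simple_polygon` assumed convex (counterclockwise).
#' @param px,py point coordinates (vectors).
#' @return logical vector.
#' @export
point_in_convex <- function(poly, px, py, eps = 1e-9) {
  n <- length(poly$x)
  j <- c(seq.int(2L, n), 1L)
  scale <- max(abs(c(poly$x, poly$y)), 1)
  inside <- rep(TRUE, length(px))
  for (i in seq_len(n)) {
    ex <- poly$x[j[i]] - poly$x[i]
    ey <- poly$y[j[i]] - poly$y[i]
    cr <- ex * (py - poly$y[i]) - ey * (px - poly$x[i])
    inside <- inside & (cr >= -eps * scale)
    if (!any(inside)) break
  }
  inside
}

# Separating-axis test for two convex polygons; touching counts as overlap.
convex_overlap <- function(a, b, eps = 1e-9) {
  scale <- max(abs(c(a$x, a$y, b$x, b$y)), 1)
  axes_of <- function(p) {
    n <- length(p$x)
    j <- c(seq.int(2L, n), 1L)
    cbind(-(p$y[j] - p$y), p$x[j] - p$x) # outward-ish normals; sign irrelevant
  }
  sep <- function(axes) {
    for (i in seq_len(nrow(axes))) {
      ax <- axes[i, 1]; ay <- axes[i, 2]
      nrm <- sqrt(ax^2 + ay^2)
      if (nrm < 1e-300) next
      pa <- (a$x * ax + a$y * ay) / nrm
      pb <- (b$x * ax + b$y * ay) / nrm
      if (max(pa) < min(pb) - eps * scale || max(pb) < min(pa) - eps * scale)
        return(TRUE)
    }
    FALSE
  }
  !(sep(axes_of(a)) || sep(axes_of(b)))
}

#' Compactness ratio of a polygon (isoperimetric quotient)
#'
#' The ratio of the polygon's area to the area of a circle with the same
#' perimeter: `4 * pi * area / perimeter^2`. Equals 1 only for a circle;
#' values near 0 indicate elongated, linear shapes. Scale-invariant.
#'
#' @param polygon a `simple_polygon`.
#' @return numeric in (0, 1].
#' @examples
#' compactness_ratio(simple_polygon(c(0, 1, 1, 0), c(0, 0, 1, 1))) # pi/4
#' @export
compactness_ratio <- function(polygon) {
  stopifnot(inherits(polygon, "simple_polygon"))
  if (!is.finite(polygon$perimeter) || polygon$perimeter <= 0)
    stop("degenerate geometry: zero perimeter")
  4 * pi * polygon$area / polygon$perimeter^2
}
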