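#' Polygon area
#'
#' Enclosed area of a closed outline by the shoelace formula.
#'
#' @param outline A [outline()] object.
#' @return Area in mm^2 (strictly positive).
#' @export
polygon_area <- function(outline) {
  o <- as_outline(outline)
  abs(shoelace_area(o$x, o$y))
}

#' Polygon perimeter
#'
#' @param outline A [outline()] object.
#' @return Perimeter in mm, including the implicit closing edge.
#' @export
polygon_perimeter <- function(outline) {
  o <- as_outline(outline)
  dx <- c(diff(o$x), o$x[1] - o$x[length(o$x)])
  dy <- c(diff(o$y), o$y[1] - o$y[length(o$y)])
  sum(sqrt(dx^2 + dy^2))
}

#' Area-weighted polygon centroid
#'
#' Centroid of the enclosed region (not the vertex mean), which anchors the
#' reflection-axis search and all normalisation steps.
#'
#' @param outline A [outline()] object.
#' @return Numeric vector `c(x, y)` in mm.
#' @export
polygon_centroid <- function(outline) {
  o <- as_outline(outline)
  x <- o$x; y <- o$y
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) stop("degenerate polygon: zero area", call. = FALSE)
  c(x = sum((x + x2) * cr) / (6 * a), y = sum((y + y2) * cr) / (6 * a))
}

#' Resample an outline by uniform arc length
#'
#' Re-parameterises the boundary with `n` vertices equally spaced along the
#' perimeter, starting at the current first vertex. Uniform spacing is what
#' makes sinusoidal boundary perturbations and reflection-overlap scores
#' independent of the original digitisation density.
#'
#' @param outline A [outline()] object.
#' @param n Number of output vertices (>= 16; default 512, the resolution
#'   used for all metric computations).
#' @return A resampled [outline()].
#' @export
resample_outline <- function(outline, n = 512) {
  o <- as_outline(outline)
  if (!is.numeric(n) || length(n) != 1 || n < 16)
    stop("n must be a single integer >= 16", call. = FALSE)
  n <- as.integer(n)
  xc <- c(o$x, o$x[1]); yc <- c(o$y, o$y[1])
  s <- c(0, cumsum(sqrt(diff(xc)^2 + diff(yc)^2)))
  targets <- seq(0, s[length(s)], length.out = n + 1)[-(n + 1)]
  nx <- stats::approx(s, xc, xout = targets, ties = "ordered")$y
  ny <- stats::approx(s, yc, xout = targets, ties = "ordered")$y
  outline(nx, ny, label = o$label, provenance = o$provenance, check = FALSE)
}

#' Scale an outline to a target blade area
#'
#' Uniform scaling about the area centroid. The study design holds blade
#' area constant at 100 mm^2 so that shape, not size, is the only variable.
#'
#' @param outline A [outline()] object.
#' @param target_area Target area in mm^2 (default 100).
#' @return A scaled [outline()] whose area equals `target_area` to within
#'   relative 1e-9.
#' @export
normalize_area <- function(outline, target_area = 100) {
  o <- as_outline(outline)
  if (!is.numeric(target_area) || length(target_area) != 1 ||
      !is.finite(target_area) || target_area <= 0)
    stop("target_area must be a single positive number", call. = FALSE)
  a <- polygon_area(o)
  k <- sqrt(target_area / a)
  ctr <- polygon_centroid(o)
  outline(ctr[1] + k * (o$x - ctr[1]), ctr[2] + k * (o$y - ctr[2]),
          label = o$label, provenance = o$provenance, check = FALSE)
}

#' Reflect an outline about an axis through its centroid
#'
#' The mirror operator underlying the symmetry number: the outline is
#' reflected about the line through its area centroid at `axis_angle` from
#' the x-axis. Applying the reflection twice returns the input.
#'
#' @param outline A [outline()] object.
#' @param axis_angle Axis angle in radians.
#' @return The mirrored [outline()] (re-oriented counterclockwise).
#' @export
reflect_outline <- function(outline, axis_angle) {
  o <- as_outline(outline)
  ctr <- polygon_centroid(o)
  c2 <- cos(2 * axis_angle); s2 <- sin(2 * axis_angle)
  dx <- o$x - ctr[1]; dy <- o$y - ctr[2]
  nx <- ctr[1] + c2 * dx + s2 * dy
  ny <- ctr[2] + s2 * dx - c2 * dy
  # reflection reverses vertex order; restore counterclockwise storage
  outline(rev(nx), rev(ny), label = o$label, provenance = o$provenance,
          check = FALSE)
}

#' Intersection and union areas of two outlines
#'
#' Boolean overlap of two simple polygons (polygon clipping via the Clipper
#' library). The union area is derived by inclusion–exclusion.
#'
#' @param a,b [outline()] objects.
#' @return Named numeric vector `c(intersection = , union = )` in mm^2.
#' @export
overlap_areas <- function(a, b) {
  a <- as_outline(a); b <- as_outline(b)
  i <- intersection_area(a, b)
  c(intersection = i, union = polygon_area(a) + polygon_area(b) - i)
}

# total intersection area of two simple polygons
intersection_area <- function(a, b) {
  rings <- tryCatch(
    polyclip::polyclip(list(x = a$x, y = a$y), list(x = b$x, y = b$y),
                       op = "intersection",
                       fillA = "nonzero", fillB = "nonzero"),
    error = function(e) stop("geometry error in boolean overlap: ",
                             conditionMessage(e), call. = FALSE))
  if (length(rings) == 0) return(0)
  sum(vapply(rings, function(r) abs(shoelace_area(r$x, r$y)), 0))
}

#' Symmetric-difference area of two outlines
#'
#' Area of the region covered by exactly one of the two shapes, computed by
#' inclusion–exclusion from the boolean intersection. This is the area
#' bookkeeping behind the digital-mutation magnitude.
#'
#' @param a,b [outline()] objects.
#' @return Area in mm^2.
#' @export
symmetric_difference_area <- function(a, b) {
  a <- as_outline(a); b <- as_outline(b)
  polygon_area(a) + polygon_area(b) - 2 * intersection_area(a, b)
}

#' Convex hull area of an outline
#'
#' @param outline A [outline()] object.
#' @return Hull area in mm^2 (always >= the polygon area).
#' @export
convex_hull_area <- function(outline) {
  o <- as_outline(outline)
  h <- grDevices::chull(o$x, o$y)
  abs(shoelace_area(o$x[h], o$y[h]))
}
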