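#' Closed blade outlines
#'
#' An outline is the package's universal shape representation: a closed,
#' simple (non self-intersecting) polygon in millimetres, stored
#' counterclockwise with no repeated consecutive vertices. The closing edge
#' from the last vertex back to the first is implicit.
#'
#' @param x Numeric vector of x coordinates (mm), or a two-column matrix /
#'   data frame of vertices (in which case `y` is ignored).
#' @param y Numeric vector of y coordinates (mm).
#' @param label Free-text identifier for the shape.
#' @param provenance One of `"species"`, `"mutated"`, `"random_walk"`,
#'   `"ideal"`, `"parametric"`.
#' @param repair If `TRUE`, a self-intersecting input is repaired by a
#'   zero-distance boolean clean-up (largest resulting ring is kept). The
#'   default `FALSE` rejects such inputs, because silent repair changes the
#'   enclosed area and corrupts downstream area bookkeeping.
#' @param check If `FALSE`, skip the simplicity check (used internally by
#'   operations that provably preserve simplicity).
#'
#' @return An object of class `leaf_outline`: a list with numeric fields
#'   `x`, `y` and character fields `label`, `provenance`.
#' @details Clockwise inputs are silently reversed to counterclockwise;
#'   mask-tracing tools emit either orientation. Consecutive vertices closer
#'   than 1e-9 mm are merged.
#' @examples
#' sq <- outline(c(0, 1, 1, 0), c(0, 0, 1, 1), label = "unit square")
#' polygon_area(sq)
#' @export
outline <- function(x, y = NULL, label = "", provenance = "parametric",
                    repair = FALSE, check = TRUE) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) >= 2)
    y <- as.numeric(x[, 2]); x <- as.numeric(x[, 1])
  } else if (is.data.frame(x)) {
    stopifnot(ncol(x) >= 2)
    y <- as.numeric(x[[2]]); x <- as.numeric(x[[1]])
  }
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y))
    stop("outline coordinates must be numeric vectors of equal length",
         call. = FALSE)
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y)))
    stop("outline coordinates must be finite", call. = FALSE)
  provenance <- match.arg(provenance,
                          c("species", "mutated", "random_walk", "ideal",
                            "parametric"))

  # drop an explicit closing vertex, then merge consecutive duplicates
  n <- length(x)
  if (n >= 2 && abs(x[n] - x[1]) < 1e-9 && abs(y[n] - y[1]) < 1e-9) {
    x <- x[-n]; y <- y[-n]
  }
  keep <- c(TRUE, abs(diff(x)) > 1e-9 | abs(diff(y)) > 1e-9)
  x <- x[keep]; y <- y[keep]

  if (length(x) < 3)
    stop("invalid outline: fewer than 3 distinct vertices", call. = FALSE)

  a <- shoelace_area(x, y)
  if (abs(a) < 1e-12)
    stop("invalid outline: degenerate (zero area) polygon", call. = FALSE)
  if (a < 0) { # orientation repair: accept clockwise input, store CCW
    x <- rev(x); y <- rev(y)
  }

  if (check && !is_simple_polygon(x, y)) {
    if (!repair)
      stop("invalid outline: polygon is self-intersecting ",
           "(pass repair = TRUE to apply a boolean clean-up)", call. = FALSE)
    rings <- polyclip::polysimplify(list(x = x, y = y), filltype = "nonzero")
    if (length(rings) == 0)
      stop("outline repair failed: no valid ring produced", call. = FALSE)
    areas <- vapply(rings, function(r) abs(shoelace_area(r$x, r$y)), 0)
    r <- rings[[which.max(areas)]]
    return(outline(r$x, r$y, label = label, provenance = provenance,
                   repair = FALSE, check = FALSE))
  }

  structure(list(x = x, y = y, label = label, provenance = provenance),
            class = "leaf_outline")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Test whether an object is a leaf outline
#' @param x Object to test.
#' @return `TRUE` for `leaf_outline` objects.
#' @export
is_outline <- function(x) inherits(x, "leaf_outline")

as_outline <- function(x) {
  if (is_outline(x)) return(x)
  stop("expected a 'leaf_outline' object; see outline()", call. = FALSE)
}

#' @export
print.leaf_outline <- function(x, ...) {
  cat(sprintf("<leaf_outline> %s [%s]: %d vertices, area %.4g mm^2\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              x$provenance, length(x$x), polygon_area(x)))
  invisible(x)
}

#' @export
as.data.frame.leaf_outline <- function(x, ...) {
  data.frame(x_mm = x$x, y_mm = x$y)
}

#' @export
plot.leaf_outline <- function(x, ..., asp = 1) {
  graphics::plot(c(x$x, x$x[1]), c(x$y, x$y[1]), type = "l", asp = asp,
                 xlab = "x (mm)", ylab = "y (mm)",
                 main = if (nzchar(x$label)) x$label else NULL, ...)
  invisible(x)
}

# Simplicity test: no two non-adjacent edges may properly intersect, and
# adjacent edges may touch only at their shared vertex. O(n^2), vectorised.
is_simple_polygon <- function(x, y) {
  length(find_self_intersection(x, y)) == 0
}

# Returns integer(0) if simple, else c(i, j): indices of two crossing edges.
find_self_intersection <- function(x, y) {
  n <- length(x)
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  i <- rep.int(seq_len(n - 1), times = (n - 1):1)
  j <- sequence((n - 1):1) + i
  # skip adjacent edge pairs (share an endpoint), incl. the wrap pair (1, n)
  adj <- (j - i == 1) | (i == 1 & j == n)
  i <- i[adj == FALSE]; j <- j[adj == FALSE]
  if (length(i) == 0) return(integer(0))

  d <- function(ax, ay, bx, by, px, py) (bx - ax) * (py - ay) - (by - ay) * (px - ax)
  d1 <- d(x[i], y[i], x2[i], y2[i], x[j],  y[j])
  d2 <- d(x[i], y[i], x2[i], y2[i], x2[j], y2[j])
  d3 <- d(x[j], y[j], x2[j], y2[j], x[i],  y[i])
  d4 <- d(x[j], y[j], x2[j], y2[j], x2[i], y2[i])
  # strict crossing; collinear touching is tolerated at tolerance 1e-12
  cross <- (d1 * d2 < -1e-12) & (d3 * d4 < -1e-12)
  if (!any(cross)) return(integer(0))
  k <- which(cross)[1]
  c(i[k], j[k])
}

# signed shoelace area; positive for counterclockwise vertex order
shoelace_area <- function(x, y) {
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}
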