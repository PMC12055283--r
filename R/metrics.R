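# Registries for the two shape statistics. Both are pluggable by name so an
# alternative definition (e.g. one matching a different published formula)
# can be swapped in without any API change downstream.
.leafsettle_metrics <- new.env(parent = emptyenv())
.leafsettle_metrics$symmetry <- list()
.leafsettle_metrics$lobedness <- list()

#' Register a named symmetry metric
#'
#' A symmetry metric is a function `(outline, axis_angle) -> score in [0, 1]`
#' scoring how well the outline matches its own mirror image about the axis
#' through the centroid at `axis_angle`. [symmetry_number()] maximises the
#' registered score over axis angles.
#'
#' @param name Metric name.
#' @param fn Function of `(outline, axis_angle)` returning a scalar score.
#' @return `name`, invisibly.
#' @export
register_symmetry_metric <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1, is.function(fn))
  .leafsettle_metrics$symmetry[[name]] <- fn
  invisible(name)
}

#' Register a named lobedness metric
#'
#' A lobedness metric is a function `(outline) -> score in [0, 1)` measuring
#' how strongly the blade's mass is distributed into lobes (0 for convex
#' blades).
#'
#' @param name Metric name.
#' @param fn Function of `(outline)` returning a scalar score.
#' @return `name`, invisibly.
#' @export
register_lobedness_metric <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1, is.function(fn))
  .leafsettle_metrics$lobedness[[name]] <- fn
  invisible(name)
}

get_metric <- function(kind, name) {
  fn <- .leafsettle_metrics[[kind]][[name]]
  if (is.null(fn))
    stop(sprintf("unknown %s metric '%s'; registered: %s", kind, name,
                 paste(names(.leafsettle_metrics[[kind]]), collapse = ", ")),
         call. = FALSE)
  fn
}

# default symmetry score: intersection-over-union of the outline with its
# reflection about the axis
reflection_iou <- function(outline, axis_angle) {
  ov <- overlap_areas(outline, reflect_outline(outline, axis_angle))
  unname(ov["intersection"] / ov["union"])
}

# default lobedness: 1 - solidity (hull-deficit fraction)
hull_deficit <- function(outline) {
  1 - polygon_area(outline) / convex_hull_area(outline)
}

#' Reflection-symmetry number S
#'
#' Scores the blade's best reflection symmetry: the maximum, over mirror
#' axes through the area centroid, of the overlap between the outline and
#' its reflection. With the default `reflection_iou` metric the score is the
#' intersection-over-union of the two polygons, so S = 1 when the shape has
#' at least one mirror axis and S falls well below 1 for asymmetric blades.
#'
#' The search scans `coarse_angles` axis directions uniformly over
#' `[0, pi)` and then (optionally) refines around the best direction by
#' golden-section search to 1e-4 rad. The overlap score is piecewise-smooth
#' in the axis angle, so this two-stage search matches a dense brute-force
#' scan to well within the discretisation error of the outline itself.
#'
#' @param outline A [outline()] object. For reproducible values across input
#'   resolutions, compute metrics on outlines resampled to 512 vertices (as
#'   [morphometrics()] does).
#' @param coarse_angles Number of coarse axis directions (default 180).
#' @param refine If `TRUE` (default), golden-section refinement around the
#'   best coarse direction.
#' @param metric Name of a registered symmetry metric
#'   (default `"reflection_iou"`).
#' @return List with elements `S` (the score) and `axis_angle` (the
#'   maximising mirror-axis angle in `[0, pi)`, radians).
#' @seealso [lobedness_number()], [morphometrics()],
#'   [register_symmetry_metric()]
#' @export
symmetry_number <- function(outline, coarse_angles = 180, refine = TRUE,
                            metric = "reflection_iou") {
  o <- as_outline(outline)
  score <- get_metric("symmetry", metric)
  stopifnot(coarse_angles >= 4)

  angles <- seq(0, pi, length.out = coarse_angles + 1)[-(coarse_angles + 1)]
  vals <- vapply(angles, function(th) score(o, th), 0)
  k <- which.max(vals)
  best_angle <- angles[k]; best <- vals[k]

  if (refine) {
    h <- pi / coarse_angles
    gs <- golden_max(function(th) score(o, th),
                     best_angle - h, best_angle + h, tol = 1e-4)
    if (gs$value > best) {
      best <- gs$value
      best_angle <- gs$arg %% pi
    }
  }
  list(S = best, axis_angle = best_angle)
}

# golden-section maximisation on [lo, hi]
golden_max <- function(f, lo, hi, tol = 1e-4) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  while (b - a > tol) {
    if (f1 < f2) {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- f(c2)
    } else {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- f(c1)
    }
  }
  arg <- (a + b) / 2
  list(arg = arg, value = f(arg))
}

#' Lobedness number L
#'
#' Scores how strongly the blade's mass is distributed into lobes. The
#' default `hull_deficit` metric is one minus the solidity (the ratio of
#' blade area to convex-hull area): 0 for unlobed convex blades, growing
#' towards 1 as lobes deepen.
#'
#' @param outline A [outline()] object.
#' @param metric Name of a registered lobedness metric
#'   (default `"hull_deficit"`).
#' @return The lobedness score in `[0, 1)`.
#' @seealso [symmetry_number()], [register_lobedness_metric()]
#' @export
lobedness_number <- function(outline, metric = "hull_deficit") {
  o <- as_outline(outline)
  get_metric("lobedness", metric)(o)
}

#' Full morphometric summary of an outline
#'
#' Standardises the outline (resampling to `resample_n` vertices by arc
#' length, then scaling to the configured blade area) and computes the two
#' shape statistics S and L together with area, perimeter and centroid.
#' S and L are invariant under translation, rotation and uniform scaling of
#' the input, so the standardisation only fixes the discretisation.
#'
#' @param outline A [outline()] object.
#' @param resample_n Vertex count for metric computation (default 512).
#' @param blade_area Blade area all shapes are scaled to, mm^2 (default 100).
#' @param coarse_angles Coarse axis count for the symmetry search.
#' @param symmetry_metric,lobedness_metric Registered metric names.
#' @return A one-row [tibble::tibble()] with columns `label`, `provenance`,
#'   `S`, `L`, `best_axis_angle`, `area_mm2`, `perimeter_mm`, `centroid_x`,
#'   `centroid_y`. Values are kept at full precision; round only for
#'   presentation.
#' @examples
#' hexagon <- ideal_forms()[["hexagon"]]
#' morphometrics(hexagon)
#' @export
morphometrics <- function(outline, resample_n = 512, blade_area = 100,
                          coarse_angles = 180,
                          symmetry_metric = "reflection_iou",
                          lobedness_metric = "hull_deficit") {
  o <- normalize_area(resample_outline(as_outline(outline), resample_n),
                      blade_area)
  sym <- symmetry_number(o, coarse_angles = coarse_angles,
                         metric = symmetry_metric)
  ctr <- polygon_centroid(o)
  tibble::tibble(
    label = o$label,
    provenance = o$provenance,
    S = sym$S,
    L = lobedness_number(o, metric = lobedness_metric),
    best_axis_angle = sym$axis_angle,
    area_mm2 = polygon_area(o),
    perimeter_mm = polygon_perimeter(o),
    centroid_x = unname(ctr[1]),
    centroid_y = unname(ctr[2])
  )
}
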