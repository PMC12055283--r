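#' The ten ideal comparison forms
#'
#' A fixed set of ten mirror-symmetric reference shapes, all normalised to
#' the study blade area: a disc, the regular polygons with 3, 4, 5, 6 and 8
#' sides, ellipses of aspect ratio 1.5, 2 and 3, and a stadium (a square
#' with semicircular caps). Every form has at least one reflection axis
#' (S = 1); the disc and regular polygons are convex (L = 0).
#'
#' @param blade_area Target area in mm^2 (default 100).
#' @param n_vertices Vertices per outline (default 512).
#' @param forms Character vector selecting / reordering the forms by name;
#'   the default keeps the full set of ten.
#' @return Named list of [outline()] objects.
#' @export
ideal_forms <- function(blade_area = 100, n_vertices = 512,
                        forms = c("disc", "triangle", "square", "pentagon",
                                  "hexagon", "octagon", "ellipse_1.5",
                                  "ellipse_2", "ellipse_3", "stadium")) {
  makers <- list(
    disc = function() circle_outline(n_vertices),
    triangle = function() regular_polygon(3, n_vertices),
    square = function() regular_polygon(4, n_vertices),
    pentagon = function() regular_polygon(5, n_vertices),
    hexagon = function() regular_polygon(6, n_vertices),
    octagon = function() regular_polygon(8, n_vertices),
    `ellipse_1.5` = function() ellipse_outline(1.5, n_vertices),
    ellipse_2 = function() ellipse_outline(2, n_vertices),
    ellipse_3 = function() ellipse_outline(3, n_vertices),
    stadium = function() stadium_outline(n_vertices)
  )
  forms <- match.arg(forms, names(makers), several.ok = TRUE)
  out <- lapply(forms, function(nm) {
    o <- makers[[nm]]()
    o$label <- nm
    o$provenance <- "ideal"
    normalize_area(o, blade_area)
  })
  names(out) <- forms
  out
}

circle_outline <- function(n = 512, r = 1) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  outline(r * cos(th), r * sin(th), check = FALSE)
}

regular_polygon <- function(sides, n = 512) {
  th <- seq(pi / 2, pi / 2 + 2 * pi, length.out = sides + 1)[-(sides + 1)]
  resample_outline(outline(cos(th), sin(th), check = FALSE), n)
}

ellipse_outline <- function(aspect, n = 512) {
  th <- seq(0, 2 * pi, length.out = 4 * n + 1)[-(4 * n + 1)]
  resample_outline(outline(aspect * cos(th), sin(th), check = FALSE), n)
}

stadium_outline <- function(n = 512) {
  # unit-radius caps on a 2 x 2r rectangle
  th1 <- seq(-pi / 2, pi / 2, length.out = 2 * n)
  th2 <- seq(pi / 2, 3 * pi / 2, length.out = 2 * n)
  x <- c(1 + cos(th1), -1 + cos(th2))
  y <- c(sin(th1), sin(th2))
  resample_outline(outline(x, y, check = FALSE), n)
}

#' Parametric leaf-like outline with tunable symmetry and lobedness
#'
#' A radial shape family used as a controllable test fixture spanning the
#' S-L plane: a base ellipse modulated by an even lobe harmonic of depth
#' `lobe_depth`, plus a mixed odd-harmonic term scaled by `asymmetry` that
#' breaks every mirror axis. With `asymmetry = 0` the outline has an exact
#' mirror axis (so S = 1); increasing `asymmetry` at fixed lobes lowers S,
#' and increasing `lobe_depth` at fixed lobe count raises L.
#'
#' @param lobe_count Number of lobes (integer >= 2).
#' @param lobe_depth Lobe modulation depth in `[0, 1)`.
#' @param asymmetry Asymmetry strength in `[0, 1)`.
#' @param aspect_ratio Base ellipse aspect ratio (> 0).
#' @param n_vertices Vertices in the generated outline (default 512).
#' @param blade_area Target area in mm^2 (default 100).
#' @param label Shape label.
#' @return An [outline()] with provenance `"parametric"`.
#' @examples
#' leaf <- parametric_leaf(lobe_count = 5, lobe_depth = 0.4)
#' lobedness_number(leaf)
#' @export
parametric_leaf <- function(lobe_count = 5, lobe_depth = 0, asymmetry = 0,
                            aspect_ratio = 1, n_vertices = 512,
                            blade_area = 100, label = "parametric_leaf") {
  stopifnot(lobe_count >= 2, lobe_depth >= 0, lobe_depth < 1,
            asymmetry >= 0, asymmetry < 1, aspect_ratio > 0)
  th <- seq(0, 2 * pi, length.out = 4 * n_vertices + 1)[-(4 * n_vertices + 1)]
  a <- aspect_ratio
  r_ell <- a / sqrt((cos(th))^2 + (a * sin(th))^2)
  mod <- 1 + 0.45 * lobe_depth * cos(lobe_count * th) +
    asymmetry * (0.25 * sin(2 * th) + 0.18 * sin(3 * th + 1))
  r <- r_ell * mod
  if (min(r) <= 0.02 * max(r))
    stop("parametric leaf generation failed: radius collapses to zero ",
         "(reduce lobe_depth or asymmetry)", call. = FALSE)
  o <- tryCatch(
    outline(r * cos(th), r * sin(th), label = label,
            provenance = "parametric"),
    error = function(e)
      stop("parametric leaf generation failed: ", conditionMessage(e),
           call. = FALSE))
  normalize_area(resample_outline(o, n_vertices), blade_area)
}

#' Random blob outline from a diffusing-particle path
#'
#' Generates an irregular closed shape as the outer boundary of the region
#' swept by a thickened two-dimensional Gaussian random walk: the walk is
#' rasterised, dilated to `path_width`, and the largest closed iso-contour
#' of the (lightly blurred) occupancy field is extracted at sub-pixel
#' precision, smoothed, resampled and normalised to the blade area. These
#' shapes populate the asymmetric, moderately lobed part of the S-L plane
#' that neither leaves nor ideal forms reach.
#'
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments (same seed, same outline).
#' @param n_steps Number of walk steps (>= 100; default 2000).
#' @param step_sigma Standard deviation of each step, mm (default 0.5).
#' @param path_width Width to which the path is dilated, mm (default 1).
#' @param smoothing_window Circular moving-average window (vertices) applied
#'   to the extracted contour (default 9); keeps curvature bounded so the
#'   outline remains cuttable.
#' @param n_vertices Vertices in the result (default 512).
#' @param blade_area Target area, mm^2 (default 100).
#' @param max_retries Reseeded attempts before giving up (default 10).
#' @return An [outline()] with provenance `"random_walk"`.
#' @export
random_walk_shape <- function(seed, n_steps = 2000, step_sigma = 0.5,
                              path_width = 1.0, smoothing_window = 9,
                              n_vertices = 512, blade_area = 100,
                              max_retries = 10) {
  stopifnot(n_steps >= 100, path_width > 0, step_sigma > 0)
  for (attempt in 0:(max_retries - 1)) {
    sub_seed <- (as.integer(seed) + 99991L * attempt) %% 2147483647L
    o <- try_random_walk_shape(sub_seed, n_steps, step_sigma, path_width,
                               smoothing_window, n_vertices, blade_area)
    if (!is.null(o)) return(o)
  }
  stop("random walk shape generation failed after ", max_retries,
       " reseeded attempts", call. = FALSE)
}

try_random_walk_shape <- function(seed, n_steps, step_sigma, path_width,
                                  smoothing_window, n_vertices, blade_area) {
  px <- path_width / 4 # raster resolution
  walk <- with_preserved_seed(seed, {
    list(x = cumsum(stats::rnorm(n_steps, sd = step_sigma)),
         y = cumsum(stats::rnorm(n_steps, sd = step_sigma)))
  })

  # densify so consecutive samples are < px/2 apart, then rasterise
  seg <- sqrt(diff(walk$x)^2 + diff(walk$y)^2)
  ns <- pmax(1L, ceiling(seg / (px / 2)))
  t_dense <- unlist(lapply(seq_along(ns), function(i)
    seq(i, i + 1, length.out = ns[i] + 1)[-(ns[i] + 1)]))
  xd <- stats::approx(seq_len(n_steps), walk$x, xout = t_dense)$y
  yd <- stats::approx(seq_len(n_steps), walk$y, xout = t_dense)$y

  pad <- path_width + 4 * px
  gx <- seq(min(xd) - pad, max(xd) + pad, by = px)
  gy <- seq(min(yd) - pad, max(yd) + pad, by = px)
  occ <- matrix(0, nrow = length(gy), ncol = length(gx))
  ci <- pmin(pmax(round((xd - gx[1]) / px) + 1, 1), length(gx))
  ri <- pmin(pmax(round((yd - gy[1]) / px) + 1, 1), length(gy))
  occ[cbind(ri, ci)] <- 1

  occ <- dilate_disk(occ, radius = ceiling(path_width / 2 / px))
  occ <- box_blur(box_blur(occ))

  lines <- isoband::isolines(gx, gy, occ, levels = 0.5)[[1]]
  if (length(lines$x) == 0) return(NULL)
  ids <- unique(lines$id)
  best <- NULL; best_area <- -Inf
  for (id in ids) {
    sel <- lines$id == id
    cx <- lines$x[sel]; cy <- lines$y[sel]
    if (length(cx) < 16) next
    a <- abs(shoelace_area(cx, cy))
    if (a > best_area) { best_area <- a; best <- list(x = cx, y = cy) }
  }
  if (is.null(best)) return(NULL)

  sx <- circular_moving_average(best$x, smoothing_window)
  sy <- circular_moving_average(best$y, smoothing_window)
  o <- tryCatch(
    outline(sx, sy, label = sprintf("rw_seed_%d", seed),
            provenance = "random_walk", repair = TRUE),
    error = function(e) NULL)
  if (is.null(o)) return(NULL)
  o <- resample_outline(o, n_vertices)
  if (!is_simple_polygon(o$x, o$y)) return(NULL)
  normalize_area(o, blade_area)
}

# binary dilation with a disk structuring element, via shift-OR
dilate_disk <- function(m, radius) {
  out <- m
  nr <- nrow(m); nc <- ncol(m)
  for (dr in -radius:radius) for (dc in -radius:radius) {
    if (dr == 0 && dc == 0) next
    if (dr^2 + dc^2 > radius^2) next
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    rt <- max(1, 1 - dr):min(nr, nr - dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    ct <- max(1, 1 - dc):min(nc, nc - dc)
    out[rt, ct] <- pmax(out[rt, ct], m[rs, cs])
  }
  out
}

# 3x3 box blur with edge replication
box_blur <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- m[c(1, 1:nr, nr), c(1, 1:nc, nc)]
  acc <- matrix(0, nr, nc)
  for (dr in 0:2) for (dc in 0:2)
    acc <- acc + p[dr + 1:nr, dc + 1:nc]
  acc / 9
}

circular_moving_average <- function(v, w) {
  if (w <= 1) return(v)
  w <- as.integer(w)
  if (w %% 2 == 0) w <- w + 1L
  h <- (w - 1L) %/% 2L
  n <- length(v)
  ext <- c(v[(n - h + 1):n], v, v[1:h])
  stats::filter(ext, rep(1 / w, w), sides = 2)[(h + 1):(h + n)]
}
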