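# Shared fixtures and independent oracles, all built in code.

# Smooth random blob: positive radial Fourier series around the origin.
# Simple by construction (star-shaped), irregular enough to have S < 1.
random_blob <- function(seed, n = 256, harmonics = 6, roughness = 0.25) {
  set.seed(seed)
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r <- rep(1, n)
  for (k in 2:harmonics) {
    amp <- roughness / k
    r <- r + amp * (runif(1, -1, 1) * cos(k * th) +
                    runif(1, -1, 1) * sin(k * th))
  }
  r <- pmax(r, 0.1)
  outline(r * cos(th), r * sin(th), label = sprintf("blob_%d", seed))
}

# plus-sign: union of a 1 x 3 and a 3 x 1 rectangle crossed at the centre;
# polygon area 5, convex hull area 7
plus_sign <- function() {
  x <- c(-0.5, 0.5, 0.5, 1.5, 1.5, 0.5, 0.5, -0.5, -0.5, -1.5, -1.5, -0.5)
  y <- c(-1.5, -1.5, -0.5, -0.5, 0.5, 0.5, 1.5, 1.5, 0.5, 0.5, -0.5, -0.5)
  outline(x, y, label = "plus")
}

scalene_triangle <- function() outline(c(0, 4, 0), c(0, 0, 2))

unit_square <- function() outline(c(0, 1, 1, 0), c(0, 0, 1, 1))

# Independent brute-force symmetry oracle: dense scan over axis angles,
# no golden-section refinement, direct reflection IoU at every angle.
brute_force_symmetry <- function(o, n_angles = 3600) {
  angles <- seq(0, pi, length.out = n_angles + 1)[-(n_angles + 1)]
  best <- -Inf; best_angle <- NA
  for (th in angles) {
    ov <- overlap_areas(o, reflect_outline(o, th))
    iou <- ov[["intersection"]] / ov[["union"]]
    if (iou > best) { best <- iou; best_angle <- th }
  }
  list(S = best, axis_angle = best_angle)
}

# Monte-Carlo point-in-polygon area oracle (even-odd ray crossing)
mc_polygon_area <- function(o, n_samples = 1e5, seed = 1) {
  set.seed(seed)
  bx <- range(o$x); by <- range(o$y)
  px <- runif(n_samples, bx[1], bx[2])
  py <- runif(n_samples, by[1], by[2])
  inside <- point_in_polygon(px, py, o$x, o$y)
  mean(inside) * diff(bx) * diff(by)
}

point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}
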