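test_that("polygon area matches closed forms and repairs orientation", {
  expect_equal(polygon_area(unit_square()), 1)
  # regular 256-gon of circumradius 1: (n/2) R^2 sin(2 pi / n)
  g <- leafsettle:::circle_outline(256)
  expect_equal(polygon_area(g), 128 * sin(2 * pi / 256), tolerance = 1e-12)
  cw <- outline(rev(c(0, 1, 1, 0)), rev(c(0, 0, 1, 1)))
  expect_equal(polygon_area(cw), 1)
  expect_gt(leafsettle:::shoelace_area(cw$x, cw$y), 0) # stored CCW
})

test_that("invalid outlines are rejected", {
  expect_error(outline(c(0, 1), c(0, 1)), "fewer than 3")
  expect_error(outline(c(0, 1, 2), c(0, 0, 0)), "zero area")
  # self-crossing boundary (one edge cuts through another)
  xi <- c(0, 4, 4, 1, 0); yi <- c(0, 0, 2, -1, 2)
  expect_error(outline(xi, yi), "self-intersecting")
  expect_silent(o <- outline(xi, yi, repair = TRUE))
  expect_true(is_outline(o))
})

test_that("centroid is area-weighted and equivariant under translation", {
  expect_equal(unname(polygon_centroid(unit_square())), c(0.5, 0.5))
  sq2 <- outline(c(0, 1, 1, 0) + 10, c(0, 0, 1, 1) + 10)
  expect_equal(unname(polygon_centroid(sq2)), c(10.5, 10.5))
  # two unit squares side by side form a 2 x 1 rectangle: centroid (1, 0.5)
  ell <- outline(c(0, 2, 2, 0), c(0, 0, 1, 1))
  expect_equal(unname(polygon_centroid(ell)), c(1, 0.5))
})

test_that("area/centroid behave under random similarity transforms", {
  for (seed in 1:5) {
    o <- random_blob(seed)
    set.seed(seed + 100)
    th <- runif(1, 0, 2 * pi); k <- runif(1, 0.5, 3)
    dx <- runif(1, -20, 20); dy <- runif(1, -20, 20)
    o2 <- outline(k * (o$x * cos(th) - o$y * sin(th)) + dx,
                  k * (o$x * sin(th) + o$y * cos(th)) + dy)
    expect_equal(polygon_area(o2), k^2 * polygon_area(o), tolerance = 1e-9)
    c1 <- polygon_centroid(o); c2 <- polygon_centroid(o2)
    expect_equal(unname(c2[1]),
                 unname(k * (c1[1] * cos(th) - c1[2] * sin(th)) + dx),
                 tolerance = 1e-9)
  }
})

test_that("Monte-Carlo point-in-polygon oracle agrees with shoelace area", {
  for (seed in c(2, 11, 23)) {
    o <- random_blob(seed)
    expect_equal(mc_polygon_area(o, 1e5, seed = seed), polygon_area(o),
                 tolerance = 0.01)
  }
})

test_that("resampling preserves area and spacing and is idempotent", {
  circ <- leafsettle:::circle_outline(256)
  r512 <- resample_outline(circ, 512)
  expect_length(r512$x, 512)
  expect_equal(polygon_area(r512), polygon_area(circ), tolerance = 1e-3)

  sq <- resample_outline(unit_square(), 400)
  expect_length(sq$x, 400)
  # about 100 vertices per side (corner vertices fall on two sides)
  expect_equal(sum(abs(sq$y) < 1e-9), 100, tolerance = 1)

  again <- resample_outline(circ, 256) # already uniformly spaced
  expect_lt(max(abs(again$x - circ$x), abs(again$y - circ$y)), 1e-6)

  expect_error(resample_outline(circ, 8), ">= 16")
})

test_that("normalize_area hits the target exactly and is a projection", {
  sq <- normalize_area(unit_square(), 100)
  expect_equal(polygon_area(sq), 100, tolerance = 1e-9)
  expect_equal(diff(range(sq$x)), 10, tolerance = 1e-9)

  circ <- normalize_area(leafsettle:::circle_outline(512), 100)
  # radius of the 100 mm^2 circle: sqrt(100/pi) (slightly larger for the
  # inscribed polygon)
  expect_equal(max(sqrt((circ$x - 0)^2 + (circ$y - 0)^2)),
               sqrt(100 / pi), tolerance = 1e-3)

  twice <- normalize_area(circ, 100)
  expect_lt(max(abs(twice$x - circ$x)), 1e-9)

  expect_error(normalize_area(sq, -5), "positive")

  for (seed in 1:5) {
    o <- normalize_area(random_blob(seed), 100)
    expect_equal(polygon_area(o), 100, tolerance = 1e-9)
  }
})

test_that("reflection is an involution and preserves area", {
  tri <- scalene_triangle()
  ctr <- polygon_centroid(tri)
  ref <- reflect_outline(tri, pi / 2) # vertical axis through centroid
  expect_equal(polygon_area(ref), polygon_area(tri))
  expect_equal(sort(2 * ctr[1] - ref$x), sort(tri$x), tolerance = 1e-12)

  for (th in c(0, 0.3, 1.1, 2.9)) {
    back <- reflect_outline(reflect_outline(tri, th), th)
    expect_lt(max(abs(back$x - tri$x), abs(back$y - tri$y)), 1e-9)
  }

  # a square reflected about the vertical axis maps onto itself
  sq <- unit_square()
  rs <- reflect_outline(sq, pi / 2)
  expect_equal(sort(round(rs$x, 9)), sort(sq$x))
})

test_that("overlap areas match analytic cases and are symmetric", {
  sq <- unit_square()
  expect_equal(unname(overlap_areas(sq, sq)), c(1, 1))
  far <- outline(c(5, 6, 6, 5), c(0, 0, 1, 1))
  expect_equal(unname(overlap_areas(sq, far)), c(0, 2))
  off <- outline(c(0.5, 1.5, 1.5, 0.5), c(0, 0, 1, 1))
  expect_equal(unname(overlap_areas(sq, off)), c(0.5, 1.5))
  expect_equal(overlap_areas(off, sq), overlap_areas(sq, off))
  for (seed in 1:3) {
    o <- random_blob(seed)
    a <- polygon_area(o)
    # the clipping backend snaps to a fine integer grid (~1e-8 relative)
    expect_equal(unname(overlap_areas(o, o)), c(a, a), tolerance = 1e-6)
  }
})

test_that("convex hull area bounds polygon area", {
  expect_equal(convex_hull_area(unit_square()), 1)
  # plus sign: hull is the 3x3 square minus four half-unit corner triangles
  expect_equal(convex_hull_area(plus_sign()), 7)
  expect_equal(polygon_area(plus_sign()), 5)
  circ <- leafsettle:::circle_outline(256)
  expect_equal(convex_hull_area(circ), polygon_area(circ),
               tolerance = 1e-6)
  for (seed in 1:5)
    expect_gte(convex_hull_area(random_blob(seed)),
               polygon_area(random_blob(seed)) - 1e-12)
})
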