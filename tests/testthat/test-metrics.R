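test_that("mirror-symmetric shapes score S = 1", {
  hexa <- ideal_forms()[["hexagon"]]
  expect_equal(symmetry_number(hexa)$S, 1, tolerance = 5e-3)
  for (o in ideal_forms(forms = c("triangle", "ellipse_2", "stadium")))
    expect_equal(symmetry_number(o)$S, 1, tolerance = 5e-3)
  # mirror-symmetric parametric leaf
  expect_equal(symmetry_number(parametric_leaf(5, 0.4, asymmetry = 0))$S, 1,
               tolerance = 5e-3)
})

test_that("optimized axis search matches the dense brute-force scan", {
  tri <- resample_outline(scalene_triangle(), 256)
  bf <- brute_force_symmetry(tri, 3600)
  opt <- symmetry_number(tri)
  expect_equal(opt$S, bf$S, tolerance = 1e-3)

  for (seed in 1:6) {
    o <- random_blob(seed)
    expect_equal(symmetry_number(o)$S, brute_force_symmetry(o, 720)$S,
                 tolerance = 1e-3)
  }
})

test_that("the maximising axis is a genuine reflection axis", {
  ell <- ideal_forms()[["ellipse_2"]]
  ax <- symmetry_number(ell)$axis_angle
  # the ellipse's axes are horizontal/vertical
  expect_lt(min(abs(ax - c(0, pi / 2, pi))), 0.02)
})

test_that("lobedness is zero for convex shapes and 2/7 for the plus sign", {
  expect_equal(lobedness_number(unit_square()), 0)
  expect_equal(lobedness_number(ideal_forms()[["disc"]]), 0,
               tolerance = 1e-9)
  expect_equal(lobedness_number(plus_sign()), 2 / 7)
})

test_that("L grows with lobe depth at fixed lobe count", {
  L <- vapply(seq(0, 0.8, by = 0.2),
              function(d) lobedness_number(parametric_leaf(5, d)), 0)
  expect_true(all(diff(L) >= 0))
  expect_gt(L[3], 0.05)
})

test_that("S and L are invariant under similarity transforms", {
  b <- random_blob(3)
  th <- 37 * pi / 180
  b2 <- outline(3 * (b$x * cos(th) - b$y * sin(th)) + 5,
                3 * (b$x * sin(th) + b$y * cos(th)) - 2)
  m1 <- morphometrics(b); m2 <- morphometrics(b2)
  expect_equal(m1$S, m2$S, tolerance = 1e-3)
  expect_equal(m1$L, m2$L, tolerance = 1e-3)
})

test_that("a one-segment sinusoidal mutation of the disc lowers S", {
  disc <- ideal_forms()[["disc"]]
  mut <- digital_mutate(disc,
                        mutation_spec(0.5, segments = list(c(0, 0.25))))
  expect_lt(symmetry_number(mut$mutated)$S, symmetry_number(disc)$S)
})

test_that("morphometrics bundles standardised metrics", {
  m <- morphometrics(ideal_forms()[["disc"]])
  expect_equal(m$S, 1, tolerance = 5e-3)
  expect_equal(m$L, 0, tolerance = 1e-9)
  expect_equal(m$area_mm2, 100, tolerance = 1e-9)
  expect_equal(m$perimeter_mm, 2 * sqrt(100 * pi), tolerance = 1e-3)
})

test_that("both metrics are pluggable by name without API change", {
  # radial mismatch symmetry score and rectangularity-style lobedness
  register_symmetry_metric("neg_overlap_deficit", function(o, th) {
    ov <- overlap_areas(o, reflect_outline(o, th))
    1 - (ov[["union"]] - ov[["intersection"]]) / ov[["union"]]
  })
  register_lobedness_metric("perimeter_excess", function(o) {
    p <- polygon_perimeter(o)
    1 - 2 * sqrt(pi * polygon_area(o)) / p
  })
  b <- random_blob(5)
  s_alt <- symmetry_number(b, metric = "neg_overlap_deficit")$S
  expect_equal(s_alt, symmetry_number(b)$S, tolerance = 1e-6) # same score here
  l_alt <- lobedness_number(b, metric = "perimeter_excess")
  expect_false(isTRUE(all.equal(l_alt, lobedness_number(b))))
  m <- morphometrics(b, symmetry_metric = "neg_overlap_deficit",
                     lobedness_metric = "perimeter_excess")
  expect_equal(m$L, lobedness_number(
    normalize_area(resample_outline(b, 512), 100),
    metric = "perimeter_excess"))
  expect_error(symmetry_number(b, metric = "no_such"), "unknown")
})
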