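disc100 <- ideal_forms()[["disc"]]
R100 <- sqrt(100 / pi)

test_that("zero amplitude is the identity mutation", {
  res <- digital_mutate(disc100, mutation_spec(0))
  expect_equal(res$epsilon, 0)
  expect_equal(res$delta_area, 0)
  expect_lt(max(abs(res$mutated$x - normalize_area(disc100, 100)$x)), 1e-9)
})

test_that("full-boundary disc mutation matches the first-order estimate", {
  # integer wavenumber 12 -> wavelength P/12; first order: eps ~ 4 a R / A0
  P <- polygon_perimeter(disc100)
  res <- digital_mutate(disc100, mutation_spec(0.5, wavelength = P / 12))
  expect_equal(res$epsilon, 4 * 0.5 * R100 / 100, tolerance = 0.05)

  # small-amplitude limit: eps -> (2/pi) a P / A0 within 10%
  a <- 0.05 * sqrt(100) * 0.1
  res2 <- digital_mutate(disc100, mutation_spec(a))
  expect_equal(res2$epsilon, (2 / pi) * a * P / 100, tolerance = 0.10)
})

test_that("delta area agrees with an independent boolean xor oracle", {
  res <- digital_mutate(disc100, mutation_spec(0.4))
  orig <- normalize_area(resample_outline(disc100, 512), 100)
  m <- res$mutated_raw
  rings <- polyclip::polyclip(list(x = orig$x, y = orig$y),
                              list(x = m$x, y = m$y),
                              op = "xor", fillA = "nonzero",
                              fillB = "nonzero")
  xor_area <- sum(vapply(rings, function(r)
    abs(leafsettle:::shoelace_area(r$x, r$y)), 0))
  expect_equal(res$delta_area, xor_area, tolerance = 0.02)
})

test_that("mutation magnitude is invariant under similarity transforms", {
  b <- random_blob(4)
  b2 <- outline(2.5 * b$x + 7, 2.5 * b$y - 3)
  sp <- mutation_spec(0.3, segments = list(c(0.1, 0.5)))
  expect_equal(digital_mutate(b, sp)$epsilon, digital_mutate(b2, sp)$epsilon,
               tolerance = 1e-6)
})

test_that("mutated outlines keep the constant blade area", {
  for (a in c(0.2, 0.5, 0.9)) {
    res <- digital_mutate(disc100, mutation_spec(a))
    expect_equal(polygon_area(res$mutated), 100, tolerance = 1e-9)
  }
})

test_that("mutation series is monotone, deterministic and aborts cleanly", {
  ser <- mutation_series(disc100, c(0, 0.2, 0.4, 0.8))
  eps <- vapply(ser, `[[`, 0, "epsilon")
  expect_equal(eps[1], 0)
  expect_true(all(diff(eps) > 0))

  one <- mutation_series(disc100, 0)
  expect_length(one, 1)
  expect_equal(one[[1]]$epsilon, 0)

  sp <- mutation_spec(0, seed = 42, n_random_segments = 2,
                      segment_length = 0.2)
  e1 <- vapply(mutation_series(disc100, c(0, 0.3, 0.6), sp), `[[`, 0,
               "epsilon")
  e2 <- vapply(mutation_series(disc100, c(0, 0.3, 0.6), sp), `[[`, 0,
               "epsilon")
  expect_identical(e1, e2)

  expect_error(mutation_series(disc100, c(0.1, 0.2)), "start at 0")
  expect_error(mutation_series(disc100, c(0, 3, 2)), "sorted")
  # an absurd amplitude must fail with the series index reported
  expect_error(mutation_series(disc100, c(0, 50)), "index 2")
})

test_that("self-intersecting mutations report the offending segment", {
  expect_error(digital_mutate(disc100, mutation_spec(8)),
               "self-intersection in segment")
})

test_that("mutation specs are validated", {
  expect_error(mutation_spec(-1), "amplitude")
  expect_error(mutation_spec(1, segments = list(c(0.5, 0.2))), "start < end")
  expect_error(mutation_spec(1, segments = list(c(0, 0.6), c(0.5, 0.9))),
               "overlap")
  expect_error(mutation_spec(1, n_random_segments = 2), "seed")
  tbl <- mutation_table(mutation_series(disc100, c(0, 0.3)))
  expect_named(tbl, c("amplitude", "epsilon", "delta_area"))
  expect_equal(nrow(tbl), 2)
})
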