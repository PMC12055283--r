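#' Specify a digital mutation
#'
#' A digital mutation perturbs segments of a blade's boundary with a
#' short-wavelength sinusoid directed along the local outward normal,
#' mimicking the large-amplitude/short-wavelength margin irregularity of
#' naturally asymmetric mutant leaves.
#'
#' @param amplitude Peak displacement in mm (>= 0).
#' @param wavelength Sinusoid wavelength along the boundary arc length, mm.
#'   `NULL` (default) uses perimeter/24. For a mutation covering the full
#'   boundary the wavelength is snapped to the nearest integer number of
#'   waves so the perturbation closes smoothly.
#' @param segments List of `c(start, end)` fractions of the total perimeter
#'   in `[0, 1]`, non-overlapping. The default single segment `c(0, 1)`
#'   perturbs the whole boundary. Ignored when `n_random_segments` is given.
#' @param phase Phase offset in radians.
#' @param seed Integer seed used only when segments are drawn at random.
#' @param n_random_segments If not `NULL`, draw this many non-overlapping
#'   random segments of length `segment_length` (perimeter fraction) using
#'   `seed`.
#' @param segment_length Length of each random segment as a perimeter
#'   fraction.
#' @param taper_fraction Fraction of each partial segment's length over
#'   which the displacement is cosine-tapered to zero at both ends
#'   (default 0.05); prevents kinks and self-intersections at segment
#'   boundaries. Full-boundary mutations are periodic and are not tapered.
#' @return A `mutation_spec` object.
#' @seealso [digital_mutate()]
#' @export
mutation_spec <- function(amplitude, wavelength = NULL,
                          segments = list(c(0, 1)), phase = 0, seed = NULL,
                          n_random_segments = NULL, segment_length = 0.25,
                          taper_fraction = 0.05) {
  stopifnot(is.numeric(amplitude), length(amplitude) == 1, amplitude >= 0)
  if (!is.null(wavelength))
    stopifnot(is.numeric(wavelength), length(wavelength) == 1, wavelength > 0)
  if (!is.null(n_random_segments)) {
    stopifnot(n_random_segments >= 1, segment_length > 0,
              n_random_segments * segment_length <= 1)
    if (is.null(seed))
      stop("seed is required when segments are drawn at random", call. = FALSE)
  } else {
    segments <- lapply(segments, function(s) {
      s <- as.numeric(s)
      if (length(s) != 2 || s[1] < 0 || s[2] > 1 || s[1] >= s[2])
        stop("each segment must be c(start, end) with 0 <= start < end <= 1",
             call. = FALSE)
      s
    })
    segments <- segments[order(vapply(segments, `[`, 0, 1))]
    if (length(segments) > 1) {
      starts <- vapply(segments, `[`, 0, 1)
      ends <- vapply(segments, `[`, 0, 2)
      if (any(starts[-1] < ends[-length(ends)]))
        stop("segments must not overlap", call. = FALSE)
    }
  }
  structure(list(amplitude = amplitude, wavelength = wavelength,
                 segments = segments, phase = phase, seed = seed,
                 n_random_segments = n_random_segments,
                 segment_length = segment_length,
                 taper_fraction = taper_fraction),
            class = "mutation_spec")
}

#' Apply a digital mutation to an outline
#'
#' The outline is standardised (resampled by arc length and scaled to the
#' blade area), then vertices inside the chosen boundary segments are
#' displaced along the local outward normal by
#' `amplitude * sin(2*pi*s/wavelength + phase)`, where `s` is the arc length
#' from the segment start. The mutation magnitude is the modified-area
#' fraction `epsilon = delta_area / original_area`, with `delta_area` the
#' symmetric-difference area between the original and mutated polygons.
#' A net signed area change would be compensated away by the constant-area
#' protocol and could not grow with amplitude; the symmetric difference
#' measures the modification itself. `epsilon` is therefore computed
#' *before* the mutated blade is rescaled back to the target area.
#'
#' @param outline A [outline()] object.
#' @param spec A [mutation_spec()].
#' @param resample_n Vertex count for the standardised outline (default 512).
#' @param blade_area Constant blade area in mm^2 (default 100); the mutated
#'   outline is re-normalised to this area.
#' @return A `mutation_result` list: `mutated` (the re-normalised outline),
#'   `mutated_raw` (the perturbed outline before re-normalisation),
#'   `epsilon`, `delta_area` (mm^2), `original_area` (mm^2), `amplitude`,
#'   `wavelength` (the wavelength actually used, mm), `segments`.
#' @examples
#' disc <- ideal_forms()[["disc"]]
#' res <- digital_mutate(disc, mutation_spec(amplitude = 0.5))
#' res$epsilon
#' @export
digital_mutate <- function(outline, spec, resample_n = 512,
                           blade_area = 100) {
  o <- normalize_area(resample_outline(as_outline(outline), resample_n),
                      blade_area)
  if (!inherits(spec, "mutation_spec"))
    stop("spec must be a mutation_spec object", call. = FALSE)
  P <- polygon_perimeter(o)
  n <- length(o$x)

  segments <- resolve_segments(spec)
  lambda <- spec$wavelength %||% (P / 24)
  if (lambda >= P)
    stop("wavelength must be smaller than the perimeter", call. = FALSE)

  # vertex arc lengths (uniform after resampling, but computed exactly)
  xc <- c(o$x, o$x[1]); yc <- c(o$y, o$y[1])
  seg_len <- sqrt(diff(xc)^2 + diff(yc)^2)
  s <- c(0, cumsum(seg_len))[seq_len(n)]

  disp <- numeric(n)
  which_segment <- integer(n) # 0 = unperturbed
  for (k in seq_along(segments)) {
    f <- segments[[k]]
    full <- isTRUE(all.equal(f, c(0, 1)))
    s0 <- f[1] * P; s1 <- f[2] * P
    idx <- which(s >= s0 & s < s1)
    if (length(idx) == 0) next
    sl <- s[idx] - s0
    lam <- lambda
    if (full) {
      # periodic closure: integer number of waves around the boundary
      lam <- P / max(1, round(P / lambda))
      taper <- 1
    } else {
      tl <- spec$taper_fraction * (s1 - s0)
      if (tl > 0) {
        taper <- pmin(1, pmin(sl, (s1 - s0) - sl) / tl)
        taper <- (1 - cos(taper * pi)) / 2
      } else taper <- 1
    }
    disp[idx] <- spec$amplitude * sin(2 * pi * sl / lam + spec$phase) * taper
    which_segment[idx] <- k
  }

  nrm <- vertex_normals(o$x, o$y)
  mx <- o$x + disp * nrm$x
  my <- o$y + disp * nrm$y

  bad <- find_self_intersection(mx, my)
  if (length(bad) > 0) {
    seg_hit <- which_segment[bad]
    seg_hit <- seg_hit[seg_hit > 0][1]
    stop(sprintf(paste0("mutation failure: amplitude %.3g mm causes ",
                        "self-intersection in segment %d"),
                 spec$amplitude, if (is.na(seg_hit)) 1L else seg_hit),
         call. = FALSE)
  }

  mutated_raw <- outline(mx, my, label = o$label, provenance = "mutated",
                         check = FALSE)
  a0 <- polygon_area(o)
  delta <- if (spec$amplitude == 0) 0 else
    symmetric_difference_area(o, mutated_raw)
  structure(list(mutated = normalize_area(mutated_raw, blade_area),
                 mutated_raw = mutated_raw,
                 epsilon = delta / a0,
                 delta_area = delta,
                 original_area = a0,
                 amplitude = spec$amplitude,
                 wavelength = lambda,
                 segments = segments),
            class = "mutation_result")
}

#' @export
print.mutation_result <- function(x, ...) {
  cat(sprintf(paste0("<mutation_result> amplitude %.3g mm, epsilon %.4g ",
                     "(delta area %.4g / %.4g mm^2)\n"),
              x$amplitude, x$epsilon, x$delta_area, x$original_area))
  invisible(x)
}

# draw / validate the segment list of a spec
resolve_segments <- function(spec) {
  if (is.null(spec$n_random_segments)) return(spec$segments)
  m <- spec$n_random_segments
  len <- spec$segment_length
  with_preserved_seed(spec$seed, {
    placed <- NULL
    for (try in 1:100) {
      starts <- sort(stats::runif(m, 0, 1 - len))
      if (m == 1 || all(diff(starts) >= len)) {
        placed <- lapply(starts, function(st) c(st, st + len))
        break
      }
    }
    if (is.null(placed))
      stop("could not place non-overlapping random segments", call. = FALSE)
    placed
  })
}

# outward unit normals at vertices of a CCW polygon
vertex_normals <- function(x, y) {
  n <- length(x)
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  ex <- xn - x; ey <- yn - y                  # edge i: vertex i -> i+1
  el <- sqrt(ex^2 + ey^2)
  enx <- ey / el; eny <- -ex / el             # outward for CCW order
  pnx <- c(enx[n], enx[-n]); pny <- c(eny[n], eny[-n]) # edge into vertex i
  vx <- enx + pnx; vy <- eny + pny
  vl <- sqrt(vx^2 + vy^2)
  vl[vl < 1e-12] <- 1
  list(x = vx / vl, y = vy / vl)
}

#' Apply a series of digital mutations of growing amplitude
#'
#' Applies the same mutation geometry at each amplitude of an ascending
#' series starting at 0, as in a progressive-mutation experiment. The
#' modified-area fraction `epsilon` is non-decreasing along the series.
#'
#' @param outline A [outline()] object.
#' @param amplitudes Numeric vector of amplitudes in mm, sorted ascending,
#'   starting at 0.
#' @param spec A [mutation_spec()] whose amplitude field is overridden by
#'   each series value.
#' @param ... Passed to [digital_mutate()].
#' @return List of `mutation_result` objects, one per amplitude.
#' @export
mutation_series <- function(outline, amplitudes, spec = mutation_spec(0),
                            ...) {
  stopifnot(is.numeric(amplitudes), length(amplitudes) >= 1)
  if (amplitudes[1] != 0 || is.unsorted(amplitudes))
    stop("amplitudes must be sorted ascending and start at 0", call. = FALSE)
  lapply(seq_along(amplitudes), function(i) {
    sp <- spec
    sp$amplitude <- amplitudes[i]
    tryCatch(digital_mutate(outline, sp, ...),
             error = function(e)
               stop(sprintf("mutation series failed at index %d: %s",
                            i, conditionMessage(e)), call. = FALSE))
  })
}

#' Tabulate a mutation series
#'
#' @param results List of `mutation_result` objects from [mutation_series()].
#' @return Tibble with columns `amplitude`, `epsilon`, `delta_area`.
#' @export
mutation_table <- function(results) {
  tibble::tibble(
    amplitude = vapply(results, `[[`, 0, "amplitude"),
    epsilon = vapply(results, `[[`, 0, "epsilon"),
    delta_area = vapply(results, `[[`, 0, "delta_area")
  )
}

# Evaluate `code` under a given RNG seed without disturbing the caller's
# RNG state.
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  if (!is.null(seed)) set.seed(seed)
  force(code)
}
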