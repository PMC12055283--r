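# All file formats are plain text: millimetre coordinates, '.' decimal
# separator, UTF-8, LF line endings, numbers at 6 significant digits.
# Fixed formatting keeps outputs byte-stable for a given seed.

fmt_num <- function(v) {
  out <- vapply(v, function(x) {
    if (is.na(x)) "NA" else sprintf("%.6g", x)
  }, "")
  out
}

write_lines_lf <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
}

#' Extract a blade outline from a binary mask image
#'
#' Traces the largest closed contour of the foreground at the 0.5 iso-level
#' by marching squares, giving sub-pixel vertex placement (linear
#' interpolation between pixel centres), which reduces pixelation bias in
#' the symmetry score of near-symmetric blades. The contour is converted to
#' millimetres, oriented counterclockwise and resampled.
#'
#' @param mask A numeric/logical matrix (values in `[0, 1]`; rows are image
#'   rows, top first), or a path to a PNG/TIFF file (read with the png or
#'   tiff package; grayscale or first channel).
#' @param mm_per_pixel Physical pixel size, mm (default 0.1).
#' @param n_vertices Vertices in the resulting outline (default 512).
#' @param label,provenance Passed to [outline()].
#' @return An [outline()] in mm, origin at the image's bottom-left corner.
#' @export
read_mask_outline <- function(mask, mm_per_pixel = 0.1, n_vertices = 512,
                              label = "mask", provenance = "species") {
  stopifnot(mm_per_pixel > 0)
  if (is.character(mask)) mask <- load_image_matrix(mask)
  if (is.logical(mask)) mask <- mask * 1
  stopifnot(is.matrix(mask), is.numeric(mask))
  if (max(mask) <= 0) stop("empty mask: no foreground pixels", call. = FALSE)

  # pad with background so foreground touching the border still closes
  nr <- nrow(mask); nc <- ncol(mask)
  p <- matrix(0, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- mask
  # x along columns; y in mm with row 1 (image top) at the largest y
  gx <- (0:(nc + 1)) * mm_per_pixel
  gy <- ((nr + 1):0) * mm_per_pixel

  lines <- isoband::isolines(gx, gy, p, levels = 0.5)[[1]]
  if (length(lines$x) == 0)
    stop("empty mask: no contour at the 0.5 level", call. = FALSE)
  ids <- unique(lines$id)
  if (length(ids) > 1)
    warning("mask has ", length(ids),
            " foreground contours; keeping the largest", call. = FALSE)
  best <- NULL; best_area <- -Inf
  for (id in ids) {
    sel <- lines$id == id
    a <- abs(shoelace_area(lines$x[sel], lines$y[sel]))
    if (a > best_area) {
      best_area <- a
      best <- list(x = lines$x[sel], y = lines$y[sel])
    }
  }
  o <- outline(best$x, best$y, label = label, provenance = provenance,
               repair = TRUE)
  resample_outline(o, n_vertices)
}

load_image_matrix <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop("reading PNG masks requires the 'png' package", call. = FALSE)
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF masks requires the 'tiff' package", call. = FALSE)
    tiff::readTIFF(path)
  } else stop("unsupported mask image format: .", ext, call. = FALSE)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

#' Write an outline to CSV
#'
#' Format: optional metadata lines `# label: ...` and `# provenance: ...`,
#' then a `x_mm,y_mm` header and one vertex per line.
#'
#' @param outline A [outline()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_outline_csv <- function(outline, path) {
  o <- as_outline(outline)
  lines <- c(sprintf("# label: %s", o$label),
             sprintf("# provenance: %s", o$provenance),
             "x_mm,y_mm",
             sprintf("%.9f,%.9f", o$x, o$y))
  write_lines_lf(lines, path)
  invisible(path)
}

#' Read an outline from CSV
#'
#' @param path File written by [write_outline_csv()] (or any CSV with
#'   columns `x_mm,y_mm`; decimal separator must be `.`).
#' @param ... Passed to [outline()] (e.g. `repair = TRUE`).
#' @return An [outline()] object.
#' @export
read_outline_csv <- function(path, ...) {
  raw <- readLines(path, warn = FALSE)
  label <- ""; provenance <- "species"
  meta <- grepl("^#", raw)
  for (ln in raw[meta]) {
    if (grepl("^#\\s*label:", ln))
      label <- trimws(sub("^#\\s*label:", "", ln))
    if (grepl("^#\\s*provenance:", ln))
      provenance <- trimws(sub("^#\\s*provenance:", "", ln))
  }
  body_idx <- which(!meta & nzchar(trimws(raw)))
  if (length(body_idx) < 1) stop("outline CSV is empty", call. = FALSE)
  header <- raw[body_idx[1]]
  if (!identical(trimws(strsplit(header, ",")[[1]])[1:2],
                 c("x_mm", "y_mm")))
    stop("outline CSV must have header 'x_mm,y_mm'", call. = FALSE)
  rows <- body_idx[-1]
  if (length(rows) < 3)
    stop("format error: outline CSV has fewer than 3 vertex rows",
         call. = FALSE)
  xs <- numeric(length(rows)); ys <- numeric(length(rows))
  for (i in seq_along(rows)) {
    parts <- strsplit(raw[rows[i]], ",")[[1]]
    vals <- suppressWarnings(as.numeric(parts))
    if (length(vals) != 2 || anyNA(vals))
      stop(sprintf(paste0("format error at line %d: expected two numeric ",
                          "fields 'x,y' (decimal separator must be '.')"),
                   rows[i]), call. = FALSE)
    xs[i] <- vals[1]; ys[i] <- vals[2]
  }
  outline(xs, ys, label = label, provenance = provenance, ...)
}

#' Export outlines as a laser-scale SVG
#'
#' Writes one closed, stroke-only path per outline in millimetre user
#' units (the document width/height carry `mm` units and the viewBox
#' matches), the layout a laser cutter consumes directly. Outlines are
#' translated into the positive quadrant with a margin; the SVG y-axis
#' points down, so shapes appear vertically mirrored relative to plot
#' coordinates (area and metrics are unaffected).
#'
#' @param outlines A single [outline()] or a list of outlines.
#' @param path Output file path.
#' @param stroke_width Cut-line width, mm (default 0.1).
#' @param margin Margin around the drawing, mm (default 2).
#' @return `path`, invisibly.
#' @export
export_svg <- function(outlines, path, stroke_width = 0.1, margin = 2) {
  if (is_outline(outlines)) outlines <- list(outlines)
  stopifnot(all(vapply(outlines, is_outline, TRUE)))
  if (length(outlines) == 0) {
    w <- 2 * margin; h <- 2 * margin
    write_lines_lf(c(svg_header(w, h), "</svg>"), path)
    return(invisible(path))
  }
  all_x <- unlist(lapply(outlines, `[[`, "x"))
  all_y <- unlist(lapply(outlines, `[[`, "y"))
  x0 <- min(all_x); y1 <- max(all_y)
  w <- diff(range(all_x)) + 2 * margin
  h <- diff(range(all_y)) + 2 * margin
  paths <- vapply(outlines, function(o) {
    px <- o$x - x0 + margin
    py <- y1 - o$y + margin # flip: SVG y points down
    d <- paste0("M ", sprintf("%.5f %.5f", px[1], py[1]), " L ",
                paste(sprintf("%.5f %.5f", px[-1], py[-1]),
                      collapse = " "), " Z")
    sprintf(paste0('<path id="%s" d="%s" fill="none" stroke="black" ',
                   'stroke-width="%.3f"/>'),
            xml_escape(o$label), d, stroke_width)
  }, "")
  write_lines_lf(c(svg_header(w, h), paths, "</svg>"), path)
  invisible(path)
}

svg_header <- function(w, h) {
  c('<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
                   'width="%.5fmm" height="%.5fmm" ',
                   'viewBox="0 0 %.5f %.5f">'), w, h, w, h))
}

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  s <- gsub(">", "&gt;", s, fixed = TRUE)
  gsub('"', "&quot;", s, fixed = TRUE)
}

#' Read outlines back from an exported SVG
#'
#' Parses the absolute `M`/`L`/`Z` path commands written by [export_svg()]
#' and undoes the y-axis flip using the document height. Translation is not
#' undone (the SVG does not record the original origin), so round-tripped
#' outlines match the source up to translation.
#'
#' @param path SVG file path.
#' @return List of [outline()] objects.
#' @export
read_svg_outlines <- function(path) {
  doc <- xml2::read_xml(path)
  h <- as.numeric(strsplit(xml2::xml_attr(doc, "viewBox"), " ")[[1]][4])
  nodes <- xml2::xml_find_all(doc, ".//*[local-name()='path']")
  lapply(nodes, function(nd) {
    d <- xml2::xml_attr(nd, "d")
    toks <- strsplit(trimws(gsub("[MLZz]", " ", d)), "\\s+")[[1]]
    vals <- as.numeric(toks)
    if (anyNA(vals) || length(vals) %% 2 != 0)
      stop("unsupported SVG path data: ", substr(d, 1, 40), call. = FALSE)
    xs <- vals[seq(1, length(vals), 2)]
    ys <- h - vals[seq(2, length(vals), 2)] # undo the y flip
    lab <- xml2::xml_attr(nd, "id")
    outline(xs, ys, label = if (is.na(lab)) "" else lab,
            provenance = "species")
  })
}

results_schema <- c("shape_id", "provenance", "S", "L", "area_mm2",
                    "VS_mm_s", "sem", "relative_speed", "reynolds", "regime")

#' Write a study results table to CSV
#'
#' One row per shape with the settling-study schema: identifiers, shape
#' metrics, mean terminal speed and its SEM, speed relative to the disc
#' control, Reynolds number and symmetry regime. Column order is fixed and
#' numbers are written at 6 significant digits, so output is byte-stable.
#'
#' @param results Data frame containing at least the schema columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(results, path) {
  miss <- setdiff(results_schema, names(results))
  if (length(miss) > 0)
    stop("results table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  num_cols <- c("S", "L", "area_mm2", "VS_mm_s", "sem", "relative_speed",
                "reynolds")
  rows <- vapply(seq_len(nrow(results)), function(i) {
    vals <- vapply(results_schema, function(cn) {
      v <- results[[cn]][i]
      if (cn %in% num_cols) fmt_num(as.numeric(v)) else as.character(v)
    }, "")
    paste(vals, collapse = ",")
  }, "")
  write_lines_lf(c(paste(results_schema, collapse = ","), rows), path)
  invisible(path)
}

#' Read a study results table from CSV
#'
#' @param path File written by [write_results_csv()].
#' @return A [tibble::tibble()] with the results schema.
#' @export
read_results_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(results_schema, names(df))
  if (length(miss) > 0)
    stop("schema error: results CSV is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  tibble::as_tibble(df[results_schema])
}

#' Write trajectories to CSV
#'
#' Schema: `shape_id,trial_id,t_s,x_mm,z_mm`, header required.
#'
#' @param trajectories A trajectory tibble (rows from one or many trials).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectories, path) {
  need <- c("shape_id", "trial_id", "t_s", "x_mm", "z_mm")
  miss <- setdiff(need, names(trajectories))
  if (length(miss) > 0)
    stop("trajectory table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  rows <- sprintf("%s,%d,%s,%s,%s",
                  trajectories$shape_id, as.integer(trajectories$trial_id),
                  fmt_num(trajectories$t_s), fmt_num(trajectories$x_mm),
                  fmt_num(trajectories$z_mm))
  write_lines_lf(c(paste(need, collapse = ","), rows), path)
  invisible(path)
}

#' Read trajectories from CSV
#'
#' @param path File with schema `shape_id,trial_id,t_s,x_mm,z_mm`.
#' @return A [tibble::tibble()] of trajectory samples.
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("shape_id", "trial_id", "t_s", "x_mm", "z_mm")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("trajectory CSV is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (cn in c("t_s", "x_mm", "z_mm"))
    if (!is.numeric(df[[cn]]))
      stop("trajectory CSV column ", cn,
           " is not numeric (decimal separator must be '.')", call. = FALSE)
  tibble::as_tibble(df[need])
}
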