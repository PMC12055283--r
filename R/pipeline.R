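#' Classify a shape's symmetry regime
#'
#' The settling experiments show two regimes separated at a symmetry value
#' of 0.75: above the threshold shapes settle on par with the disc control,
#' at or below it they settle substantially slower. The boundary value is
#' assigned to the low-symmetry regime (a strict `S > threshold` is
#' required for `"high_symmetry"`).
#'
#' @param S Symmetry number(s) in `(0, 1]`.
#' @param threshold Regime threshold (default 0.75).
#' @return Character vector, `"high_symmetry"` or `"low_symmetry"`.
#' @examples
#' classify_regime(c(0.9, 0.75, 0.6))
#' @export
classify_regime <- function(S, threshold = 0.75) {
  if (any(!is.finite(S)) || any(S <= 0) || any(S > 1))
    stop("S must lie in (0, 1]", call. = FALSE)
  stopifnot(threshold > 0, threshold < 1)
  ifelse(S > threshold, "high_symmetry", "low_symmetry")
}

#' Run the full shape-versus-settling study
#'
#' Orchestrates the whole analysis: for every shape, re-standardises the
#' outline (resampling, blade-area normalisation), computes the symmetry
#' and lobedness numbers, estimates a terminal speed from every trial
#' trajectory, aggregates trials into a mean speed with SEM, scales speeds
#' by the disc control, attaches Reynolds numbers and classifies the
#' symmetry regime. Shapes whose metrics or speed estimation fail are
#' excluded and counted in the report.
#'
#' @param study Either a `synthetic_study` from [make_synthetic_study()],
#'   or a list with elements `shapes` (named list of [outline()]s) and
#'   `trajectories` (a trajectory tibble covering those shapes). `NULL`
#'   builds a synthetic study from the `...` arguments.
#' @param control_shape_id Shape id of the disc control (default taken
#'   from the study, else `"disc_control"`).
#' @param symmetry_threshold Regime threshold (default 0.75).
#' @param blade_area Blade area all shapes are scaled to, mm^2.
#' @param resample_n Vertex count for metric computation.
#' @param coarse_angles Coarse axis count for the symmetry search.
#' @param ctx A [fluid_context()] for Reynolds numbers.
#' @param ... Passed to [make_synthetic_study()] when `study` is `NULL`
#'   (e.g. `n_random`, `trials_per_shape`, `seed`).
#' @return A `settling_study_result` list: `results` (tibble, one row per
#'   shape, results-CSV schema), `summary` (S/L ranges and per-regime
#'   relative-speed envelopes), `excluded` (tibble of failed shapes),
#'   `report` (character vector of markdown lines), `control_shape_id`.
#' @examples
#' \donttest{
#' res <- run_study(n_random = 2, trials_per_shape = 3, seed = 1)
#' res$results[, c("shape_id", "S", "L", "relative_speed", "regime")]
#' }
#' @export
run_study <- function(study = NULL, control_shape_id = NULL,
                      symmetry_threshold = 0.75, blade_area = 100,
                      resample_n = 512, coarse_angles = 180,
                      ctx = fluid_context(), ...) {
  if (is.null(study)) study <- make_synthetic_study(...)
  if (is.null(control_shape_id))
    control_shape_id <- study$control_shape_id %||% "disc_control"
  shapes <- study$shapes
  traj <- study$trajectories
  if (is.null(shapes) || is.null(traj))
    stop("study must provide 'shapes' and 'trajectories'", call. = FALSE)
  if (!control_shape_id %in% names(shapes))
    stop("configuration error: control shape '", control_shape_id,
         "' not present in the study", call. = FALSE)

  per_shape_speeds <- function(id) {
    rows <- traj[traj$shape_id == id, , drop = FALSE]
    trials <- split(rows, rows$trial_id)
    vapply(trials, function(tr)
      estimate_terminal_speed(tr)$speed, 0)
  }

  control_mean <- mean(per_shape_speeds(control_shape_id))

  rows <- list(); excluded <- list()
  for (id in names(shapes)) {
    res <- tryCatch({
      mo <- morphometrics(shapes[[id]], resample_n = resample_n,
                          blade_area = blade_area,
                          coarse_angles = coarse_angles)
      agg <- aggregate_trials(per_shape_speeds(id),
                              control_mean = control_mean, ctx = ctx)
      tibble::tibble(
        shape_id = id,
        provenance = mo$provenance,
        S = mo$S, L = mo$L,
        area_mm2 = mo$area_mm2,
        VS_mm_s = agg$mean_speed,
        sem = agg$sem,
        n_trials = agg$n_trials,
        relative_speed = agg$relative_speed,
        reynolds = agg$reynolds,
        regime = classify_regime(mo$S, symmetry_threshold)
      )
    }, error = function(e) e)
    if (inherits(res, "error")) {
      excluded[[id]] <- tibble::tibble(shape_id = id,
                                       reason = conditionMessage(res))
    } else rows[[id]] <- res
  }
  results <- do.call(rbind, unname(rows))
  excluded <- if (length(excluded) > 0) do.call(rbind, unname(excluded))
  else tibble::tibble(shape_id = character(), reason = character())

  env <- function(v) {
    if (length(v) == 0) return(NULL)
    q <- stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    list(min = q[1], q25 = q[2], median = q[3], q75 = q[4], max = q[5],
         n = length(v))
  }
  summary <- list(
    n_shapes_in = length(shapes),
    n_rows_out = nrow(results),
    n_excluded = nrow(excluded),
    S_range = range(results$S),
    L_range = range(results$L),
    control_mean_speed = control_mean,
    relative_speed_high = env(results$relative_speed[
      results$regime == "high_symmetry"]),
    relative_speed_low = env(results$relative_speed[
      results$regime == "low_symmetry"])
  )

  structure(list(results = results, summary = summary, excluded = excluded,
                 report = render_report(results, summary,
                                        symmetry_threshold),
                 control_shape_id = control_shape_id),
            class = "settling_study_result")
}

render_report <- function(results, summary, threshold) {
  envline <- function(nm, e) {
    if (is.null(e)) return(sprintf("- %s: no shapes", nm))
    sprintf(paste0("- %s (n = %d): relative speed min %.3f, ",
                   "q25 %.3f, median %.3f, q75 %.3f, max %.3f"),
            nm, e$n, e$min, e$q25, e$median, e$q75, e$max)
  }
  c("# Settling study report", "",
    sprintf("Shapes analysed: %d of %d (%d excluded)",
            summary$n_rows_out, summary$n_shapes_in, summary$n_excluded),
    sprintf("Control mean settling speed: %.4g mm/s",
            summary$control_mean_speed),
    sprintf("Symmetry range: %.3f - %.3f; lobedness range: %.3f - %.3f",
            summary$S_range[1], summary$S_range[2],
            summary$L_range[1], summary$L_range[2]), "",
    sprintf("## Regimes (threshold S = %.2f)", threshold),
    envline("high symmetry", summary$relative_speed_high),
    envline("low symmetry", summary$relative_speed_low))
}

#' @export
print.settling_study_result <- function(x, ...) {
  cat(paste(x$report, collapse = "\n"), "\n")
  invisible(x)
}

#' Scatter plot of the study's shape-speed relationship
#'
#' Plots lobedness against symmetry, coloured by relative settling speed,
#' with the regime threshold marked - the study's summary figure. Requires
#' ggplot2.
#'
#' @param result A `settling_study_result` from [run_study()].
#' @param threshold Symmetry threshold drawn as a reference line.
#' @return A ggplot object.
#' @export
plot_study_scatter <- function(result, threshold = 0.75) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_study_scatter requires ggplot2", call. = FALSE)
  df <- result$results
  ggplot2::ggplot(df, ggplot2::aes(x = .data$L, y = .data$S,
                                   colour = .data$relative_speed)) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_viridis_c(name = "V / V_disc") +
    ggplot2::labs(x = "lobedness L", y = "symmetry S") +
    ggplot2::theme_minimal()
}
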