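#' Parameters of the phenomenological settling model
#'
#' Calibration constants, not fitted values: they encode the reported
#' envelopes of the settling experiments so that the full pipeline can be
#' exercised and validated on synthetic data. Shapes with symmetry above
#' the threshold settle on par with the disc control (within +/-10 percent,
#' decreasing with lobedness); asymmetric shapes settle 15-30 percent
#' slower, insensitive to lobedness (midpoint 0.775 relative speed).
#'
#' @param symmetry_threshold Symmetry value separating the two regimes
#'   (default 0.75).
#' @param high_symmetry_lobedness_slope Linear decrease of relative speed
#'   with L above the threshold (default 0.5).
#' @param low_symmetry_relative_speed Relative speed below the threshold
#'   (default 0.775).
#' @param trial_cv Per-trial coefficient of variation of settling speed
#'   (default 0.15, chosen so 25 trials pin the mean within ~3 percent).
#' @param control_speed Absolute settling speed of the disc control, mm/s
#'   (default 10, i.e. 1 cm/s).
#' @return A `settling_model_params` list.
#' @export
settling_model_params <- function(symmetry_threshold = 0.75,
                                  high_symmetry_lobedness_slope = 0.5,
                                  low_symmetry_relative_speed = 0.775,
                                  trial_cv = 0.15, control_speed = 10) {
  stopifnot(symmetry_threshold > 0, symmetry_threshold < 1,
            low_symmetry_relative_speed > 0, control_speed > 0,
            trial_cv >= 0)
  structure(list(symmetry_threshold = symmetry_threshold,
                 high_symmetry_lobedness_slope = high_symmetry_lobedness_slope,
                 low_symmetry_relative_speed = low_symmetry_relative_speed,
                 trial_cv = trial_cv, control_speed = control_speed),
            class = "settling_model_params")
}

#' Expected relative settling speed of a shape
#'
#' Piecewise shape-to-speed model: above the symmetry threshold the
#' relative speed is `1 - slope * L`, clipped to `[0.9, 1.1]`; at or below
#' the threshold it is a constant, independent of lobedness. The hard
#' threshold reflects the two observed regimes; an optional logistic blend
#' is available for sensitivity checks but is off by default.
#'
#' @param S Symmetry number(s) in `(0, 1]`.
#' @param L Lobedness number(s) in `[0, 1)`.
#' @param params A [settling_model_params()].
#' @param blend If `TRUE`, blend the two branches logistically across the
#'   threshold instead of switching discontinuously.
#' @param blend_width Logistic width in S units (used when `blend = TRUE`).
#' @return Expected speed relative to the disc control (vectorised).
#' @examples
#' settling_speed_model(S = 1, L = 0)      # disc control: 1
#' settling_speed_model(S = 0.6, L = 0.3)  # low-symmetry regime
#' @export
settling_speed_model <- function(S, L, params = settling_model_params(),
                                 blend = FALSE, blend_width = 0.02) {
  if (any(!is.finite(S)) || any(S <= 0) || any(S > 1))
    stop("S must lie in (0, 1]", call. = FALSE)
  if (any(!is.finite(L)) || any(L < 0) || any(L >= 1))
    stop("L must lie in [0, 1)", call. = FALSE)
  hi <- pmin(pmax(1 - params$high_symmetry_lobedness_slope * L, 0.9), 1.1)
  lo <- rep(params$low_symmetry_relative_speed, length.out = length(hi))
  if (blend) {
    p <- stats::plogis((S - params$symmetry_threshold) / blend_width)
    p * hi + (1 - p) * lo
  } else {
    ifelse(S > params$symmetry_threshold, hi, lo)
  }
}

#' Configuration of the trajectory simulator
#'
#' @param duration Record length in seconds (default 10; must exceed five
#'   transient time constants).
#' @param dt Sampling interval in seconds (default 0.02, i.e. 50 fps).
#' @param transient_tau Time constant of the initial acceleration
#'   transient, s (default 0.5).
#' @param flutter_amplitude Lateral flutter amplitude, mm (default 2).
#' @param flutter_freq Flutter frequency, Hz (default 1.5).
#' @param position_noise_sd Tracking noise standard deviation, mm
#'   (default 0.1).
#' @return A `trajectory_sim_config` list.
#' @export
trajectory_sim_config <- function(duration = 10, dt = 0.02,
                                  transient_tau = 0.5,
                                  flutter_amplitude = 2, flutter_freq = 1.5,
                                  position_noise_sd = 0.1) {
  stopifnot(dt > 0, duration > 5 * transient_tau, position_noise_sd >= 0)
  structure(list(duration = duration, dt = dt,
                 transient_tau = transient_tau,
                 flutter_amplitude = flutter_amplitude,
                 flutter_freq = flutter_freq,
                 position_noise_sd = position_noise_sd),
            class = "trajectory_sim_config")
}

#' Simulate one settling trajectory
#'
#' Depth follows `z(t) = v * (t - tau * (1 - exp(-t / tau)))`, the exact
#' trajectory of a body relaxing exponentially to terminal speed `v`, plus
#' Gaussian tracking noise; the lateral coordinate carries sinusoidal
#' flutter plus noise.
#'
#' @param true_speed Terminal speed `v` in mm/s (> 0).
#' @param cfg A [trajectory_sim_config()].
#' @param seed Integer seed (`NULL` uses the current RNG state).
#' @param shape_id,trial_id Identifiers stored in the result.
#' @return A [trajectory()] tibble.
#' @export
simulate_trajectory <- function(true_speed, cfg = trajectory_sim_config(),
                                seed = NULL, shape_id = "shape",
                                trial_id = 1L) {
  stopifnot(is.numeric(true_speed), length(true_speed) == 1, true_speed > 0)
  t <- seq(0, cfg$duration, by = cfg$dt)
  with_preserved_seed(seed, {
    z <- true_speed * (t - cfg$transient_tau *
                         (1 - exp(-t / cfg$transient_tau))) +
      stats::rnorm(length(t), sd = cfg$position_noise_sd)
    x <- cfg$flutter_amplitude * sin(2 * pi * cfg$flutter_freq * t) +
      stats::rnorm(length(t), sd = cfg$position_noise_sd)
    trajectory(t, x, z, shape_id = shape_id, trial_id = trial_id)
  })
}

#' Build a complete synthetic settling study
#'
#' Generates a full stand-in for the settling experiment: the ten ideal
#' forms, a spread of parametric leaves, `n_random` random-walk shapes and
#' a disc control; computes (S, L) for each shape; draws per-trial settling
#' speeds from the phenomenological model with multiplicative trial noise;
#' and simulates a tracked trajectory for every trial. The returned truth
#' table allows end-to-end parameter-recovery tests of the pipeline.
#'
#' All randomness derives from `seed` by a fixed splitting scheme
#' (per-shape base seeds `(seed * 100003 + 1009 * shape_index) mod 2^31-1`,
#' incremented per trial), so the study is reproducible.
#'
#' @param n_random Number of random-walk shapes (default 120).
#' @param trials_per_shape Trials per shape (default 25).
#' @param seed Master seed (default 0).
#' @param params A [settling_model_params()].
#' @param sim A [trajectory_sim_config()].
#' @param parametric List of argument lists for [parametric_leaf()];
#'   `NULL` uses a default spread of six leaves covering both regimes.
#' @param n_vertices,blade_area Shape standardisation settings.
#' @param morpho_coarse_angles Coarse axis count for the symmetry search.
#' @return A `synthetic_study` list: `shapes` (named list of outlines),
#'   `morphometrics` (tibble), `truth` (tibble with true relative and
#'   absolute speeds), `trajectories` (one tibble for all trials),
#'   `params`, `sim`, `seed`, `control_shape_id`.
#' @export
make_synthetic_study <- function(n_random = 120, trials_per_shape = 25,
                                 seed = 0, params = settling_model_params(),
                                 sim = trajectory_sim_config(),
                                 parametric = NULL, n_vertices = 512,
                                 blade_area = 100,
                                 morpho_coarse_angles = 180) {
  stopifnot(n_random >= 1, trials_per_shape >= 1)
  if (is.null(parametric))
    parametric <- list(
      list(lobe_count = 5, lobe_depth = 0.2, asymmetry = 0),
      list(lobe_count = 5, lobe_depth = 0.5, asymmetry = 0),
      list(lobe_count = 3, lobe_depth = 0.35, asymmetry = 0.15,
           aspect_ratio = 1.5),
      list(lobe_count = 5, lobe_depth = 0.3, asymmetry = 0.35),
      list(lobe_count = 4, lobe_depth = 0.2, asymmetry = 0.6),
      list(lobe_count = 6, lobe_depth = 0.4, asymmetry = 0.8))

  shapes <- list()
  disc <- ideal_forms(blade_area, n_vertices, forms = "disc")[[1]]
  disc$label <- "disc_control"
  shapes[["disc_control"]] <- disc
  ideals <- ideal_forms(blade_area, n_vertices)
  names(ideals) <- paste0("ideal_", names(ideals))
  for (nm in names(ideals)) {
    ideals[[nm]]$label <- nm
    shapes[[nm]] <- ideals[[nm]]
  }
  for (i in seq_along(parametric)) {
    args <- c(parametric[[i]], list(n_vertices = n_vertices,
                                    blade_area = blade_area,
                                    label = sprintf("leaf_%02d", i)))
    shapes[[args$label]] <- do.call(parametric_leaf, args)
  }
  for (i in seq_len(n_random)) {
    id <- sprintf("rw_%03d", i)
    o <- random_walk_shape(seed = shape_seed(seed, 10000L + i),
                           n_vertices = n_vertices, blade_area = blade_area)
    o$label <- id
    shapes[[id]] <- o
  }

  morpho <- do.call(rbind, lapply(shapes, morphometrics,
                                  resample_n = n_vertices,
                                  blade_area = blade_area,
                                  coarse_angles = morpho_coarse_angles))
  morpho <- tibble::add_column(morpho, shape_id = names(shapes),
                               .before = 1)

  truth <- tibble::tibble(
    shape_id = morpho$shape_id,
    provenance = morpho$provenance,
    S = morpho$S,
    L = morpho$L,
    true_relative_speed = settling_speed_model(morpho$S, morpho$L, params),
    true_speed = NA_real_
  )
  # the disc control defines relative speed 1 exactly
  truth$true_relative_speed[truth$shape_id == "disc_control"] <- 1
  truth$true_speed <- params$control_speed * truth$true_relative_speed

  trajectories <- vector("list", nrow(truth) * trials_per_shape)
  k <- 0
  for (i in seq_len(nrow(truth))) {
    base <- shape_seed(seed, i)
    trial_speeds <- with_preserved_seed(base, {
      mu <- truth$true_speed[i]
      pmax(0.2 * mu,
           stats::rnorm(trials_per_shape, mean = mu,
                        sd = params$trial_cv * mu))
    })
    for (j in seq_len(trials_per_shape)) {
      k <- k + 1
      trajectories[[k]] <- simulate_trajectory(
        trial_speeds[j], cfg = sim, seed = (base + j) %% 2147483647L,
        shape_id = truth$shape_id[i], trial_id = j)
    }
  }

  structure(list(shapes = shapes, morphometrics = morpho, truth = truth,
                 trajectories = do.call(rbind, trajectories),
                 params = params, sim = sim, seed = seed,
                 control_shape_id = "disc_control"),
            class = "synthetic_study")
}

# deterministic sub-seed derivation, kept inside 32-bit integer range
shape_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 100003 + 1009 * as.numeric(index)) %%
               2147483647)
}

#' @export
print.synthetic_study <- function(x, ...) {
  n_traj <- nrow(unique(x$trajectories[c("shape_id", "trial_id")]))
  cat(sprintf("<synthetic_study> %d shapes, %d trajectories (seed %s)\n",
              length(x$shapes), n_traj, format(x$seed)))
  invisible(x)
}
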