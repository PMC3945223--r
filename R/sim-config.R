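#' Configuration for the synthetic tracked-cell generator
#'
#' Bundles every tunable of the synthetic clone simulator. Defaults emulate the
#' screen's study conditions: 4 fields of view (FOVs) per clone, 10--20 tracked
#' cells per FOV, movies of at least 24 h sampled every 20 minutes, and cell
#' individuality (the persistence of a cell's deviation from the clone mean)
#' lasting roughly one cell generation.
#'
#' Protein level and motility are each modelled as a slow, per-cell
#' individuality component (a stationary Ornstein--Uhlenbeck process on the
#' frame grid, mixing coefficient `exp(-dt / tau)`) plus frame-level white
#' noise. `individuality_var_frac_*` sets the share of total variance carried
#' by the slow component; `coupling_rho` is the correlation between the
#' protein- and motility-individuality processes (0 for null clones).
#'
#' @param n_fovs Number of fields of view per clone.
#' @param cells_per_fov Cells tracked in each FOV (must be at least 2 so the
#'   within-FOV permutation null is defined).
#' @param n_frames Frames per movie (at least 3; angle change needs 3 frames).
#' @param dt Frame interval in minutes.
#' @param individuality_var_frac_protein,individuality_var_frac_motility
#'   Fraction of the unit total variance contributed by the slow individuality
#'   component, in `[0, 1)`.
#' @param tau_individuality Correlation time of the individuality process in
#'   hours (default 20 h, about one cell generation).
#' @param coupling_rho Correlation in `[-1, 1]` planted between protein and
#'   motility individuality.
#' @param fov_effect_sd Standard deviation of per-FOV batch effects: additive
#'   `N(0, sd)` offsets on protein features and multiplicative
#'   `exp(N(0, sd))` factors on speed.
#' @param turn_kappa Directional-persistence parameter (>= 0). 0 gives
#'   uniform (isotropic) turning; larger values concentrate turns around 0,
#'   increasingly so at higher instantaneous speed, which produces the
#'   negative velocity/angle-change coupling seen in migrating cells.
#' @param speed_mean,speed_sd Mean and standard deviation of step length in
#'   micrometres per frame interval.
#' @param truncate_frac Fraction of cells whose track is randomly truncated
#'   (exercises the fully-tracked-cells filter; synthetic tracks otherwise
#'   have no gaps).
#' @param seed Optional integer seed; generators are pure functions of
#'   (config, seed).
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_fovs = 2, cells_per_fov = 4, n_frames = 12)
#' cfg$dt
#' @export
sim_config <- function(n_fovs = 4,
                       cells_per_fov = 15,
                       n_frames = 72,
                       dt = 20,
                       individuality_var_frac_protein = 0.4,
                       individuality_var_frac_motility = 0.4,
                       tau_individuality = 20,
                       coupling_rho = 0,
                       fov_effect_sd = 0.1,
                       turn_kappa = 2,
                       speed_mean = 10,
                       speed_sd = 3,
                       truncate_frac = 0,
                       seed = NULL) {
  cfg <- list(
    n_fovs = n_fovs, cells_per_fov = cells_per_fov, n_frames = n_frames,
    dt = dt,
    individuality_var_frac_protein = individuality_var_frac_protein,
    individuality_var_frac_motility = individuality_var_frac_motility,
    tau_individuality = tau_individuality,
    coupling_rho = coupling_rho,
    fov_effect_sd = fov_effect_sd,
    turn_kappa = turn_kappa,
    speed_mean = speed_mean,
    speed_sd = speed_sd,
    truncate_frac = truncate_frac,
    seed = seed
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  num <- cfg[setdiff(names(cfg), "seed")]
  if (!all(vapply(num, function(v) is.numeric(v) && length(v) == 1 && is.finite(v),
                  logical(1)))) {
    stop("all sim_config parameters must be single finite numbers", call. = FALSE)
  }
  if (cfg$n_fovs < 1) stop("n_fovs must be >= 1", call. = FALSE)
  if (cfg$cells_per_fov < 2) {
    stop("cells_per_fov must be >= 2 (within-FOV permutation needs i != j)",
         call. = FALSE)
  }
  if (cfg$n_frames < 3) stop("n_frames must be >= 3 (angle change needs 3 frames)",
                             call. = FALSE)
  if (cfg$dt <= 0) stop("dt must be positive", call. = FALSE)
  for (f in c("individuality_var_frac_protein", "individuality_var_frac_motility")) {
    if (cfg[[f]] < 0 || cfg[[f]] >= 1) {
      stop(f, " must lie in [0, 1)", call. = FALSE)
    }
  }
  if (cfg$tau_individuality <= 0) stop("tau_individuality must be positive",
                                       call. = FALSE)
  if (abs(cfg$coupling_rho) > 1) stop("coupling_rho must lie in [-1, 1]",
                                      call. = FALSE)
  if (cfg$fov_effect_sd < 0) stop("fov_effect_sd must be >= 0", call. = FALSE)
  if (cfg$turn_kappa < 0) stop("turn_kappa must be >= 0", call. = FALSE)
  if (cfg$speed_mean < 0) stop("speed_mean must be >= 0", call. = FALSE)
  if (cfg$speed_sd < 0) stop("speed_sd must be >= 0", call. = FALSE)
  if (cfg$truncate_frac < 0 || cfg$truncate_frac >= 1) {
    stop("truncate_frac must lie in [0, 1)", call. = FALSE)
  }
  if (!is.null(cfg$seed)) cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d FOVs x %d cells x %d frames, dt = %g min\n",
              x$n_fovs, x$cells_per_fov, x$n_frames, x$dt))
  cat(sprintf("  individuality var frac: protein %.2f, motility %.2f (tau = %g h)\n",
              x$individuality_var_frac_protein, x$individuality_var_frac_motility,
              x$tau_individuality))
  cat(sprintf("  coupling_rho = %g, fov_effect_sd = %g, turn_kappa = %g\n",
              x$coupling_rho, x$fov_effect_sd, x$turn_kappa))
  cat(sprintf("  speed: %g +/- %g um/frame\n", x$speed_mean, x$speed_sd))
  invisible(x)
}

# AR(1) mixing coefficient per frame for an OU correlation time tau (hours)
ar1_phi <- function(cfg) exp(-cfg$dt / (cfg$tau_individuality * 60))
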