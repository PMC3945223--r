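# Stationary AR(1) (discretised Ornstein-Uhlenbeck) path with unit marginal
# variance, started from the supplied standard-normal initial value so that
# the marginal distribution is stationary from frame 1.
ar1_path <- function(n, phi, z0) {
  if (!is.finite(z0)) stop("individuality value must be finite", call. = FALSE)
  if (phi >= 1) return(rep(z0, n))
  if (n == 1) return(z0)
  innov <- stats::rnorm(n - 1, sd = sqrt(1 - phi^2))
  as.numeric(stats::filter(c(z0, innov), phi, method = "recursive", init = 0))
}

# Wrap an angle (radians) into (-pi, pi]
wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

#' Simulate one cell's protein-level trace
#'
#' The trace is the sum of a slow cell-individuality component -- a stationary
#' Ornstein--Uhlenbeck process with correlation time `tau_individuality`
#' contributing `individuality_var_frac_protein` of the variance -- and
#' frame-level white noise. The stationary marginal variance is 1 (unit
#' scaled); FOV offsets are added downstream by [simulate_clone()]. The
#' trace autocorrelation at lag `k` frames is
#' `frac * exp(-k * dt / (60 * tau))`.
#'
#' Uses the current RNG stream; call `set.seed()` (or pass a seeded config to
#' [simulate_clone()]) for reproducibility.
#'
#' @param config A [sim_config()].
#' @param cell_individuality Standard-normal individuality score of the cell
#'   (the initial state of the slow component).
#' @return Numeric vector of length `config$n_frames`.
#' @examples
#' set.seed(1)
#' tr <- simulate_protein_trace(sim_config(n_frames = 24), cell_individuality = 0.5)
#' length(tr)
#' @export
simulate_protein_trace <- function(config, cell_individuality = stats::rnorm(1)) {
  config <- validate_sim_config(config)
  frac <- config$individuality_var_frac_protein
  u <- ar1_path(config$n_frames, ar1_phi(config), cell_individuality)
  sqrt(frac) * u + sqrt(1 - frac) * stats::rnorm(config$n_frames)
}

#' Simulate one cell's trajectory as a persistent random walk
#'
#' Step lengths (speeds) are drawn around `speed_mean` with a slow motility-
#' individuality component (fraction `individuality_var_frac_motility` of the
#' `speed_sd^2` variance) plus white noise; negative draws are clipped to 0.
#' The heading turns between steps by an angle whose dispersion shrinks as
#' `turn_kappa` times the instantaneous relative speed grows: fast cells turn
#' less, reproducing the negative correlation between velocity and angle
#' change of migrating cells. `turn_kappa = 0` gives isotropic (uniform)
#' turning.
#'
#' @inheritParams simulate_protein_trace
#' @param motility_individuality Either a single standard-normal individuality
#'   score (the slow component's initial state) or a precomputed
#'   individuality path of length `n_frames` (used by [simulate_clone()] to
#'   plant protein--motility coupling).
#' @param fov_speed_factor Multiplicative FOV batch effect on speed
#'   (default 1).
#' @return A tibble with columns `frame` (0-based), `x`, `y` (micrometres).
#' @examples
#' set.seed(1)
#' simulate_trajectory(sim_config(n_frames = 6))
#' @export
simulate_trajectory <- function(config,
                                motility_individuality = stats::rnorm(1),
                                fov_speed_factor = 1) {
  config <- validate_sim_config(config)
  n <- config$n_frames
  phi <- ar1_phi(config)
  u <- if (length(motility_individuality) == 1) {
    ar1_path(n, phi, motility_individuality)
  } else {
    if (length(motility_individuality) != n) {
      stop("motility_individuality path must have length n_frames", call. = FALSE)
    }
    motility_individuality
  }
  fm <- config$individuality_var_frac_motility
  n_steps <- n - 1
  speeds <- config$speed_mean * fov_speed_factor +
    config$speed_sd * (sqrt(fm) * u[-1] + sqrt(1 - fm) * stats::rnorm(n_steps))
  speeds <- pmax(speeds, 0)

  ref_speed <- config$speed_mean * fov_speed_factor
  kappa_eff <- if (ref_speed > 0) config$turn_kappa * speeds / ref_speed
               else rep(config$turn_kappa, n_steps)

  headings <- numeric(n_steps)
  headings[1] <- stats::runif(1, -pi, pi)
  if (n_steps > 1) {
    # turn between step j and j+1 is damped by the speed of step j, so the
    # observed angle change at frame j pairs with the velocity at frame j
    k <- kappa_eff[-n_steps]
    turn <- numeric(n_steps - 1)
    gauss <- k > 0
    turn[gauss] <- wrap_angle(stats::rnorm(sum(gauss), 0, 1 / sqrt(k[gauss])))
    turn[!gauss] <- stats::runif(sum(!gauss), -pi, pi)
    headings <- cumsum(c(headings[1], turn))
  }

  tibble::tibble(
    frame = 0:(n - 1),
    x = c(0, cumsum(speeds * cos(headings))),
    y = c(0, cumsum(speeds * sin(headings)))
  )
}
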