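#' Simulate one clone of tracked cells with known ground truth
#'
#' Generates `n_fovs * cells_per_fov` cells, each with a protein-level trace,
#' contrast and texture traces, and a persistent-random-walk trajectory.
#' Coupling between protein and motility is planted at the individuality
#' level: each coupled protein feature's slow component is
#' `rho * u_m + sqrt(1 - rho^2) * w`, where `u_m` is the cell's motility
#' individuality path and `w` an independent path, so the two processes hold
#' cross-correlation `rho` at every frame. FOV batch effects are additive on
#' protein features and multiplicative on speed.
#'
#' With `patches = TRUE` the contrast and texture columns are measured from
#' synthetic image patches (Gaussian spots whose amplitude follows the
#' latent contrast trace) through the package's own GLCM feature chain,
#' instead of being emitted directly as latent traces.
#'
#' @inheritParams simulate_protein_trace
#' @param clone_id Identifier written into the `protein_id` column.
#' @param seed Optional integer seed (overrides `config$seed`).
#' @param coupled_features Which protein features carry the planted coupling
#'   (subset of `"level"`, `"contrast"`, `"texture"`; default `"level"`).
#' @param patches If `TRUE`, derive contrast/texture from simulated image
#'   patches (slower; exercises the imaging chain).
#' @param patch_size,patch_spots Patch geometry used when `patches = TRUE`.
#' @param patch_dir Optional directory; when given (and `patches = TRUE`)
#'   each patch and its mask are written as TIFF files named
#'   `<clone>/<fov>/<cell>_<frame>.tif` (requires the tiff package).
#' @return A tibble of track rows (`protein_id`, `fov_id`, `cell_id`,
#'   `frame`, `time`, `x`, `y`, `level`, `contrast`, `texture`) with
#'   attributes `truth_coupling` (the `coupling_rho` used) and `truth_label`
#'   (`"true_positive"` if `coupling_rho != 0`, else `"null"`).
#' @examples
#' cl <- simulate_clone(sim_config(n_fovs = 2, cells_per_fov = 3, n_frames = 8),
#'                      clone_id = "demo", seed = 1)
#' attr(cl, "truth_label")
#' @export
simulate_clone <- function(config, clone_id = "protein_001", seed = NULL,
                           coupled_features = "level",
                           patches = FALSE, patch_size = 32, patch_spots = 8,
                           patch_dir = NULL) {
  config <- validate_sim_config(config)
  if (!all(coupled_features %in% c("level", "contrast", "texture"))) {
    stop("coupled_features must be a subset of level/contrast/texture", call. = FALSE)
  }
  seed <- seed %||% config$seed
  if (!is.null(seed)) set.seed(as.integer(seed))

  n <- config$n_frames
  phi <- ar1_phi(config)
  fp <- config$individuality_var_frac_protein
  feats <- c("level", "contrast", "texture")

  rows <- vector("list", config$n_fovs * config$cells_per_fov)
  k <- 0
  for (f in seq_len(config$n_fovs)) {
    fov_id <- sprintf("fov%02d", f)
    fov_offset <- stats::rnorm(1, 0, config$fov_effect_sd)
    fov_speed_factor <- exp(stats::rnorm(1, 0, config$fov_effect_sd))
    for (c in seq_len(config$cells_per_fov)) {
      cell_id <- sprintf("%s_c%02d", fov_id, c)
      u_m <- ar1_path(n, phi, stats::rnorm(1))
      traj <- simulate_trajectory(config, motility_individuality = u_m,
                                  fov_speed_factor = fov_speed_factor)
      tr <- list()
      latent <- list()
      for (feat in feats) {
        rho <- if (feat %in% coupled_features) config$coupling_rho else 0
        u_f <- rho * u_m + sqrt(1 - rho^2) * ar1_path(n, phi, stats::rnorm(1))
        latent[[feat]] <- sqrt(fp) * u_f + sqrt(1 - fp) * stats::rnorm(n)
        tr[[feat]] <- latent[[feat]] + fov_offset
      }
      if (patches) {
        pf <- measure_patch_traces(latent$contrast, clone_id, fov_id, cell_id,
                                   patch_size, patch_spots, patch_dir)
        tr$contrast <- pf$contrast
        tr$texture <- pf$texture
      }
      keep <- n
      if (config$truncate_frac > 0 && stats::runif(1) < config$truncate_frac) {
        keep <- sample(2:(n - 1), 1)
      }
      k <- k + 1
      rows[[k]] <- tibble::tibble(
        protein_id = clone_id, fov_id = fov_id, cell_id = cell_id,
        frame = 0:(keep - 1), time = (0:(keep - 1)) * config$dt,
        x = traj$x[seq_len(keep)], y = traj$y[seq_len(keep)],
        level = tr$level[seq_len(keep)],
        contrast = tr$contrast[seq_len(keep)],
        texture = tr$texture[seq_len(keep)]
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "truth_coupling") <- config$coupling_rho
  attr(out, "truth_label") <- if (config$coupling_rho != 0) "true_positive" else "null"
  out
}

# Render per-frame patches whose spot amplitude follows the latent contrast
# trace, and measure contrast/texture through the GLCM chain.
measure_patch_traces <- function(latent_contrast, clone_id, fov_id, cell_id,
                                 patch_size, patch_spots, patch_dir) {
  n <- length(latent_contrast)
  contrast <- numeric(n)
  texture <- numeric(n)
  for (t in seq_len(n)) {
    p <- simulate_patch(size = patch_size, n_spots = patch_spots,
                        spot_amplitude = exp(0.5 * latent_contrast[t]),
                        background = 1, noise_sd = 0.02)
    if (!is.null(patch_dir)) {
      dir <- file.path(patch_dir, clone_id, fov_id)
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      write_patch_tiff(p, file.path(dir, sprintf("%s_%03d.tif", cell_id, t - 1)))
    }
    pf <- patch_features(p)
    contrast[t] <- pf$contrast
    texture[t] <- pf$texture_correlation
  }
  list(contrast = contrast, texture = texture)
}

#' Simulate a whole screen dataset with planted positives
#'
#' Draws `n_true` clones with `coupling_rho = coupling_rho_true` and `n_null`
#' independent (coupling 0) clones, each from a deterministically derived
#' sub-seed, and returns the pooled track table together with a ground-truth
#' table for recovery analyses.
#'
#' @inheritParams simulate_clone
#' @param n_true,n_null Number of planted-positive and null clones.
#' @param coupling_rho_true Coupling planted in the positive clones.
#' @return A list with elements `tracks` (tibble of all clones' rows) and
#'   `truth` (tibble: `protein_id`, `truth_label`, `truth_coupling`, `seed`).
#' @examples
#' ds <- simulate_screen_dataset(sim_config(cells_per_fov = 3, n_frames = 8),
#'                               n_true = 1, n_null = 2, seed = 1)
#' ds$truth
#' @export
simulate_screen_dataset <- function(config, n_true = 10, n_null = 90,
                                    coupling_rho_true = 0.6, seed = NULL,
                                    coupled_features = "level") {
  config <- validate_sim_config(config)
  if (n_true + n_null < 1) stop("n_true + n_null must be >= 1", call. = FALSE)
  seed <- seed %||% config$seed
  if (!is.null(seed)) set.seed(as.integer(seed))
  n_clones <- n_true + n_null
  clone_seeds <- sample.int(.Machine$integer.max - 1L, n_clones)
  labels <- c(rep("true_positive", n_true), rep("null", n_null))
  rhos <- ifelse(labels == "true_positive", coupling_rho_true, 0)
  ids <- sprintf("protein_%03d", seq_len(n_clones))

  tracks <- purrr::pmap(
    list(ids, rhos, clone_seeds),
    function(id, rho, s) {
      cfg <- config
      cfg$coupling_rho <- rho
      simulate_clone(cfg, clone_id = id, seed = s,
                     coupled_features = coupled_features)
    }
  )
  list(
    tracks = dplyr::bind_rows(tracks),
    truth = tibble::tibble(protein_id = ids, truth_label = labels,
                           truth_coupling = rhos, seed = clone_seeds)
  )
}
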