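#' Simulate a synthetic fluorescence image patch
#'
#' Renders a "cell" as a smooth radial intensity dome inside a disk-shaped
#' mask (mimicking the gradual intensity fall-off of a real cell body), with
#' `n_spots` sharp Gaussian puncta added on top and optional Gaussian pixel
#' noise (clipped at zero). Because downstream quantization is per-image
#' min--max, the smooth dome sets the dynamic range, so a spotless cell is
#' low-contrast while bright puncta create large adjacent-pixel level jumps:
#' increasing `n_spots * spot_amplitude` raises GLCM contrast on average.
#' With `n_spots = 0`, `cell_profile = 0` and `noise_sd = 0` the patch is
#' constant and all texture features take their degenerate values (contrast
#' 0, texture correlation undefined, energy 1).
#'
#' @param size Patch side length in pixels (>= 8).
#' @param n_spots Number of Gaussian spots.
#' @param spot_amplitude Peak amplitude of each spot.
#' @param background Flat background level inside and outside the cell.
#' @param noise_sd Standard deviation of additive pixel noise.
#' @param cell_profile Amplitude of the smooth radial dome of the cell body,
#'   in `background` units.
#' @param seed Optional seed for reproducibility.
#' @return An [image_patch()] (intensities plus disk mask).
#' @examples
#' p <- simulate_patch(size = 16, n_spots = 3, seed = 1)
#' patch_features(p)$contrast > 0
#' @export
simulate_patch <- function(size = 64, n_spots = 12, spot_amplitude = 3,
                           background = 1, noise_sd = 0.02, cell_profile = 1,
                           seed = NULL) {
  if (size < 8) stop("size must be >= 8", call. = FALSE)
  if (n_spots < 0 || spot_amplitude < 0 || background < 0 || noise_sd < 0 ||
      cell_profile < 0) {
    stop("n_spots, spot_amplitude, background, noise_sd and cell_profile must be >= 0",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  ctr <- (size + 1) / 2
  radius <- size / 2 - 1
  xs <- matrix(rep(seq_len(size), each = size), size, size)   # column index
  ys <- matrix(rep(seq_len(size), times = size), size, size)  # row index
  r2 <- (xs - ctr)^2 + (ys - ctr)^2
  mask <- r2 <= radius^2
  img <- matrix(background, size, size)
  img <- img + background * cell_profile * pmax(1 - r2 / radius^2, 0)
  if (n_spots > 0) {
    inside <- which(mask)
    centers <- sample(inside, n_spots, replace = TRUE)
    sigma <- max(1, size / 24)  # sharp puncta
    for (cidx in centers) {
      cy <- (cidx - 1) %% size + 1
      cx <- (cidx - 1) %/% size + 1
      img <- img + spot_amplitude *
        exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * sigma^2))
    }
  }
  if (noise_sd > 0) img <- img + matrix(stats::rnorm(size^2, 0, noise_sd), size, size)
  image_patch(pmax(img, 0), mask)
}
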