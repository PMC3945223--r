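#' Velocity series from tracked centroids
#'
#' Velocity at frame `i` is the Euclidean distance between the centroids at
#' frames `i - 1` and `i`, in micrometres per frame interval (the frame
#' spacing `dt` is carried in table metadata, not folded into the units).
#'
#' @param centroids Two-column matrix or data frame of `x`, `y` positions in
#'   micrometres, one row per consecutive frame.
#' @return Numeric vector of length `nrow(centroids) - 1`, indexed by the
#'   later frame; `NA` where either endpoint is non-finite.
#' @examples
#' velocity_series(rbind(c(0, 0), c(3, 4)))  # 5
#' @export
velocity_series <- function(centroids) {
  xy <- as.matrix(centroids)[, 1:2, drop = FALSE]
  if (nrow(xy) < 2) stop("need at least 2 frames", call. = FALSE)
  v <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
  v[!is.finite(v)] <- NA_real_
  v
}

#' Turning-angle-change series from tracked centroids
#'
#' The angle change at frame `i` is the unsigned angle (degrees, in
#' `[0, 180]`) between the displacement from frame `i - 1` to `i` and the
#' displacement from `i` to `i + 1`. Persistent motion gives low values.
#' Undefined (`NA`) when either displacement has zero length: a stationary
#' cell has no direction, and reporting 0 would fabricate persistence.
#'
#' @inheritParams velocity_series
#' @return Numeric vector of length `nrow(centroids) - 2`, indexed by the
#'   middle frame.
#' @examples
#' angle_change_series(rbind(c(0, 0), c(1, 0), c(1, 1)))  # 90
#' @export
angle_change_series <- function(centroids) {
  xy <- as.matrix(centroids)[, 1:2, drop = FALSE]
  if (nrow(xy) < 3) stop("need at least 3 frames", call. = FALSE)
  dx <- diff(xy[, 1]); dy <- diff(xy[, 2])
  n <- length(dx)
  a <- cbind(dx[-n], dy[-n])
  b <- cbind(dx[-1], dy[-1])
  na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
  cosang <- rowSums(a * b) / (na * nb)
  ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  ang[na == 0 | nb == 0 | !is.finite(cosang)] <- NA_real_
  ang
}

#' Aspect ratio of a cell mask
#'
#' Ratio of the major to the minor axis of the best-fit second-moment ellipse
#' of the mask pixels (>= 1 by construction). Undefined (`NA`) for masks with
#' fewer than 3 pixels or with all pixels collinear.
#'
#' @param mask Logical matrix marking the cell pixels.
#' @return Scalar >= 1, or `NA` for degenerate masks.
#' @examples
#' aspect_ratio(matrix(TRUE, 10, 40))  # about 4
#' @export
aspect_ratio <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 3) return(NA_real_)
  ev <- eigen(stats::cov(idx), symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] <= 1e-12) return(NA_real_)
  sqrt(ev[1] / ev[2])
}

#' Per-lag Pearson autocorrelation of a single-cell trace
#'
#' Lag `k`'s value is the Pearson correlation of the series with its copy
#' shifted by `k` frames (lag 0 is 1 by definition). Used to quantify cell
#' individuality: traces with a persistent individual component decay with
#' the component's correlation time.
#'
#' @param series Numeric vector (one value per frame).
#' @param max_lag Largest lag, in frames.
#' @return Numeric vector of length `max_lag + 1` (lags `0 .. max_lag`);
#'   `NA` at positive lags for a constant series.
#' @examples
#' trace_autocorrelation(sin(1:100), max_lag = 2)
#' @export
trace_autocorrelation <- function(series, max_lag) {
  n <- length(series)
  if (n <= max_lag + 2) stop("series length must exceed max_lag + 2", call. = FALSE)
  out <- numeric(max_lag + 1)
  out[1] <- 1
  constant <- stats::sd(series) == 0
  for (k in seq_len(max_lag)) {
    out[k + 1] <- if (constant) NA_real_ else
      suppressWarnings(stats::cor(series[1:(n - k)], series[(k + 1):n]))
  }
  out
}

# Angle-change series padded with NA to align with the frame grid
pad_angles <- function(x, y) {
  n <- length(x)
  if (n < 3) return(rep(NA_real_, n))
  c(NA_real_, angle_change_series(cbind(x, y)), NA_real_)
}

#' Append motility features to a track table
#'
#' Computes `velocity` (assigned to the later frame of each displacement) and
#' `angle_change` (assigned to the middle frame of each triple) per cell.
#' Series are computed within maximal runs of consecutive frames only; a gap
#' splits the series and the features at run boundaries are `NA`.
#'
#' @param tracks Track tibble with columns `protein_id`, `fov_id`, `cell_id`,
#'   `frame`, `x`, `y` (see [read_tracks()]).
#' @return The input tibble, arranged by cell and frame, with `velocity` and
#'   `angle_change` columns appended.
#' @examples
#' tr <- simulate_clone(sim_config(cells_per_fov = 2, n_frames = 6), seed = 1)
#' add_motility_features(tr)
#' @export
add_motility_features <- function(tracks) {
  tracks |>
    dplyr::group_by(.data$protein_id, .data$fov_id, .data$cell_id) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::mutate(.run = cumsum(c(TRUE, diff(.data$frame) != 1))) |>
    dplyr::group_by(.data$.run, .add = TRUE) |>
    dplyr::mutate(
      velocity = if (dplyr::n() >= 2) {
        c(NA_real_, velocity_series(cbind(.data$x, .data$y)))
      } else NA_real_,
      angle_change = pad_angles(.data$x, .data$y)
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-".run")
}
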