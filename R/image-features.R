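#' Construct a masked image patch
#'
#' Container for a background-subtracted single-channel fluorescence patch and
#' the boolean mask marking the pixels inside the cell. Negative intensities
#' (possible after background subtraction) are clipped to zero and counted.
#'
#' @param intensities Non-negative numeric matrix (after background
#'   subtraction; negatives are clipped).
#' @param mask Logical matrix of the same shape, `TRUE` inside the cell.
#'   Defaults to all `TRUE`.
#' @param background_level Already-subtracted background offset, recorded for
#'   provenance.
#' @return An object of class `image_patch`: a list with `intensities`,
#'   `mask`, `background_level` and `n_clipped`.
#' @examples
#' p <- image_patch(matrix(1:4, 2, 2))
#' total_intensity(p)
#' @export
image_patch <- function(intensities, mask = NULL, background_level = 0) {
  if (!is.matrix(intensities) || !is.numeric(intensities)) {
    stop("intensities must be a numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(intensities))) {
    stop("intensities must be finite", call. = FALSE)
  }
  if (is.null(mask)) mask <- matrix(TRUE, nrow(intensities), ncol(intensities))
  if (!is.matrix(mask) || !identical(dim(mask), dim(intensities))) {
    stop("mask must be a logical matrix with the same shape as intensities",
         call. = FALSE)
  }
  mask <- mask & TRUE  # coerce numeric 0/1 masks
  n_clipped <- sum(intensities < 0 & mask)
  intensities[intensities < 0] <- 0
  structure(
    list(intensities = intensities, mask = mask,
         background_level = background_level, n_clipped = n_clipped),
    class = "image_patch"
  )
}

as_image_patch <- function(x) {
  if (inherits(x, "image_patch")) x else image_patch(x)
}

#' Quantize a patch to a fixed number of gray levels
#'
#' Linear min--max rescaling of the in-mask intensities to integer levels
#' `0 .. levels - 1` (64 levels by default). A constant in-mask patch maps to
#' level 0 everywhere. Quantization is per image, preserving the ordering of
#' pixel intensities.
#'
#' @param patch An [image_patch()] (or bare matrix).
#' @param levels Number of gray levels (>= 2).
#' @return A list of class `quantized_patch` with integer matrix `gray`,
#'   the `mask`, and `levels`.
#' @examples
#' q <- rescale_gray_levels(image_patch(matrix(0:3, 2, 2)), levels = 2)
#' q$gray
#' @export
rescale_gray_levels <- function(patch, levels = 64) {
  patch <- as_image_patch(patch)
  if (levels < 2) stop("levels must be >= 2", call. = FALSE)
  v <- patch$intensities[patch$mask]
  if (length(v) == 0) stop("mask excludes every pixel", call. = FALSE)
  lo <- min(v); hi <- max(v)
  gray <- matrix(0L, nrow(patch$intensities), ncol(patch$intensities))
  if (hi > lo) {
    g <- floor((patch$intensities - lo) / (hi - lo) * levels)
    g[g >= levels] <- levels - 1
    g[g < 0] <- 0L  # out-of-mask pixels below the in-mask min
    gray <- matrix(as.integer(g), nrow(g), ncol(g))
  }
  structure(list(gray = gray, mask = patch$mask, levels = as.integer(levels)),
            class = "quantized_patch")
}

#' Gray-level co-occurrence matrix of horizontally adjacent pixels
#'
#' Counts how often gray level `i` occurs horizontally adjacent to gray level
#' `j`, using only pixel pairs with **both** pixels inside the mask, and
#' normalises the counts to probabilities `p(i, j)` summing to 1. In the
#' default symmetric (Haralick) mode each pair contributes to both `(i, j)`
#' and `(j, i)`, so the matrix and its marginals are symmetric.
#'
#' @param quantized A `quantized_patch` from [rescale_gray_levels()], or an
#'   integer matrix of gray levels in `0 .. levels - 1`.
#' @param mask Logical matrix (required when `quantized` is a bare matrix).
#' @param levels Number of gray levels (required for a bare matrix).
#' @param symmetric Count each ordered pair in both directions (default
#'   `TRUE`); set `FALSE` for ordered left-to-right accumulation.
#' @return An object of class `glcm`: list with probability matrix `p`
#'   (`levels x levels`), `levels`, `n_pairs` (number of contributing
#'   horizontal pairs, each counted once) and `symmetric`.
#' @examples
#' q <- rescale_gray_levels(image_patch(matrix(c(0, 0, 1, 1), 2, 2)), levels = 2)
#' compute_glcm(q)$p
#' @export
compute_glcm <- function(quantized, mask = NULL, levels = NULL, symmetric = TRUE) {
  if (inherits(quantized, "quantized_patch")) {
    gray <- quantized$gray; mask <- quantized$mask; levels <- quantized$levels
  } else {
    gray <- quantized
    if (is.null(mask)) mask <- matrix(TRUE, nrow(gray), ncol(gray))
    if (is.null(levels)) levels <- max(gray) + 1L
  }
  L <- as.integer(levels)
  if (ncol(gray) < 2) stop("patch needs at least 2 columns for horizontal pairs",
                           call. = FALSE)
  nc <- ncol(gray)
  a <- gray[, -nc, drop = FALSE]
  b <- gray[, -1, drop = FALSE]
  ok <- mask[, -nc, drop = FALSE] & mask[, -1, drop = FALSE]
  n_pairs <- sum(ok)
  if (n_pairs == 0) stop("no horizontally adjacent in-mask pixel pair", call. = FALSE)
  idx <- a[ok] + b[ok] * L + 1L       # column-major: entry (i+1, j+1)
  counts <- matrix(tabulate(idx, nbins = L * L), L, L)
  if (symmetric) counts <- counts + t(counts)
  structure(list(p = counts / sum(counts), levels = L,
                 n_pairs = n_pairs, symmetric = symmetric),
            class = "glcm")
}

#' GLCM contrast
#'
#' `sum over (i, j) of (i - j)^2 p(i, j)`: 0 for a constant-intensity image,
#' large when adjacent pixels have very different intensities. Bounded by
#' `(levels - 1)^2`.
#'
#' @param glcm A [compute_glcm()] result.
#' @return Non-negative scalar.
#' @examples
#' g <- list(p = matrix(c(0, .5, .5, 0), 2, 2), levels = 2L)
#' class(g) <- "glcm"
#' glcm_contrast(g)  # 1
#' @export
glcm_contrast <- function(glcm) {
  i <- seq_len(glcm$levels) - 1
  sum(outer(i, i, "-")^2 * glcm$p)
}

glcm_marginals <- function(glcm) {
  i <- seq_len(glcm$levels) - 1
  pi_ <- rowSums(glcm$p)
  pj_ <- colSums(glcm$p)
  mu_i <- sum(i * pi_); mu_j <- sum(i * pj_)
  list(mu_i = mu_i, mu_j = mu_j,
       sigma_i = sqrt(max(sum(i^2 * pi_) - mu_i^2, 0)),
       sigma_j = sqrt(max(sum(i^2 * pj_) - mu_j^2, 0)))
}

#' GLCM texture correlation
#'
#' Measures the linear dependency of gray levels on those of neighbouring
#' pixels: `sum (i - mu_i)(j - mu_j) p(i, j) / (sigma_i sigma_j)` with the
#' marginal means and standard deviations of the co-occurrence matrix. Lies
#' in `[-1, 1]`; undefined (`NA`) when `sigma_i * sigma_j = 0` (constant
#' image).
#'
#' @inheritParams glcm_contrast
#' @return Scalar in `[-1, 1]`, or `NA` when undefined.
#' @export
glcm_texture_correlation <- function(glcm) {
  m <- glcm_marginals(glcm)
  if (m$sigma_i * m$sigma_j <= 1e-12) return(NA_real_)
  i <- seq_len(glcm$levels) - 1
  cov <- sum(outer(i - m$mu_i, i - m$mu_j) * glcm$p)
  max(min(cov / (m$sigma_i * m$sigma_j), 1), -1)
}

#' Additional Haralick features: homogeneity and energy
#'
#' Homogeneity is `sum p(i, j) / (1 + |i - j|)`; energy is `sum p(i, j)^2`.
#' Both lie in `(0, 1]`, equal to 1 for a constant image.
#'
#' @inheritParams glcm_contrast
#' @return Named list with `homogeneity` and `energy`.
#' @export
glcm_extra_features <- function(glcm) {
  i <- seq_len(glcm$levels) - 1
  list(homogeneity = sum(glcm$p / (1 + abs(outer(i, i, "-")))),
       energy = sum(glcm$p^2))
}

#' Total fluorescence intensity inside the mask
#'
#' The summed intensity of all in-mask pixels (the protein-level feature).
#' Additive over disjoint mask partitions and linear in intensity.
#'
#' @param patch An [image_patch()] (or bare matrix).
#' @return Non-negative scalar.
#' @export
total_intensity <- function(patch) {
  patch <- as_image_patch(patch)
  if (!any(patch$mask)) stop("mask excludes every pixel", call. = FALSE)
  sum(patch$intensities[patch$mask])
}

# 90-degree rotation (counter-clockwise); 4 applications restore the input
rotate90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]

#' All protein features of a patch, optionally rotation-averaged
#'
#' Quantizes the patch, builds the horizontal-offset GLCM and returns total
#' intensity, contrast, texture correlation, homogeneity, energy and the GLCM
#' marginal moments as a one-row tibble. With `rotations = 4` the texture
#' features are arithmetic means over the patch rotated by 0/90/180/270
#' degrees, which makes them insensitive to patch orientation; texture
#' correlation averages over the rotations where it is defined (`NA` if all
#' are undefined).
#'
#' @inheritParams rescale_gray_levels
#' @param rotations 1 (horizontal offset only) or 4 (rotation-averaged).
#' @param symmetric Passed to [compute_glcm()].
#' @return One-row tibble with columns `total_intensity`, `contrast`,
#'   `texture_correlation`, `homogeneity`, `energy`, `mu_i`, `mu_j`,
#'   `sigma_i`, `sigma_j`, `n_pairs`, `levels`, `rotations`.
#' @examples
#' patch_features(simulate_patch(size = 16, seed = 1), rotations = 4)
#' @export
patch_features <- function(patch, levels = 64, rotations = 1, symmetric = TRUE) {
  patch <- as_image_patch(patch)
  if (!rotations %in% c(1, 4)) stop("rotations must be 1 or 4", call. = FALSE)
  q <- rescale_gray_levels(patch, levels)
  per_rot <- list()
  gray <- q$gray; mask <- q$mask
  for (r in seq_len(rotations)) {
    g <- compute_glcm(gray, mask, levels = q$levels, symmetric = symmetric)
    m <- glcm_marginals(g)
    ex <- glcm_extra_features(g)
    per_rot[[r]] <- c(contrast = glcm_contrast(g),
                      texture_correlation = glcm_texture_correlation(g),
                      homogeneity = ex$homogeneity, energy = ex$energy,
                      mu_i = m$mu_i, mu_j = m$mu_j,
                      sigma_i = m$sigma_i, sigma_j = m$sigma_j,
                      n_pairs = g$n_pairs)
    if (r < rotations) {
      gray <- rotate90(gray)
      mask <- rotate90(mask)
    }
  }
  vals <- do.call(rbind, per_rot)
  avg <- colMeans(vals)
  tc <- vals[, "texture_correlation"]
  avg["texture_correlation"] <- if (all(is.na(tc))) NA_real_ else mean(tc, na.rm = TRUE)
  tibble::tibble(
    total_intensity = total_intensity(patch),
    contrast = avg[["contrast"]],
    texture_correlation = avg[["texture_correlation"]],
    homogeneity = avg[["homogeneity"]],
    energy = avg[["energy"]],
    mu_i = avg[["mu_i"]], mu_j = avg[["mu_j"]],
    sigma_i = avg[["sigma_i"]], sigma_j = avg[["sigma_j"]],
    n_pairs = vals[1, "n_pairs"],
    levels = levels, rotations = rotations
  )
}
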