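test_that("gray-level rescaling follows the linear min-max bin rule", {
  # constant patch: degenerate range maps to level 0
  q <- rescale_gray_levels(image_patch(matrix(5, 3, 3)), levels = 64)
  expect_true(all(q$gray == 0))
  # two values, two levels
  q <- rescale_gray_levels(image_patch(matrix(c(0, 10, 0, 10), 2, 2)), levels = 2)
  expect_equal(sort(unique(as.vector(q$gray))), c(0, 1))
  # 0..127 into 64 levels: every level holds exactly two consecutive values
  q <- rescale_gray_levels(image_patch(matrix(0:127, 8, 16)), levels = 64)
  runs <- table(q$gray[order(q$gray)])
  expect_equal(as.vector(runs), rep(2, 64))
  expect_equal(sort(unique(as.vector(q$gray))), 0:63)
})

test_that("rescaling preserves intensity ordering", {
  set.seed(1)
  for (i in 1:10) {
    img <- matrix(runif(48, 0, 100), 6, 8)
    q <- rescale_gray_levels(image_patch(img), levels = 16)
    o <- order(img)
    expect_true(all(diff(q$gray[o]) >= 0))
  }
})

test_that("GLCM matches brute-force pair enumeration on random small patches", {
  set.seed(2)
  for (i in 1:40) {
    nr <- sample(2:8, 1); nc <- sample(2:8, 1)
    L <- sample(2:4, 1)
    gray <- matrix(sample(0:(L - 1), nr * nc, replace = TRUE), nr, nc)
    mask <- matrix(runif(nr * nc) > 0.25, nr, nc)
    ok <- mask[, -nc, drop = FALSE] & mask[, -1, drop = FALSE]
    if (!any(ok)) mask[] <- TRUE
    for (sym in c(TRUE, FALSE)) {
      g <- compute_glcm(gray, mask, levels = L, symmetric = sym)
      o <- glcm_oracle(gray, mask, L, symmetric = sym)
      expect_identical(g$p, o$p)
      expect_equal(g$n_pairs, o$n_pairs)
      expect_equal(sum(g$p), 1, tolerance = 1e-12)
    }
  }
})

test_that("GLCM worked examples evaluate exactly", {
  # [[0,1],[0,1]]: both rows are (0,1)
  g <- compute_glcm(matrix(c(0, 1, 0, 1), 2, 2, byrow = TRUE), levels = 2)
  expect_equal(g$p, matrix(c(0, 0.5, 0.5, 0), 2, 2))
  # constant 1x3 row
  g0 <- compute_glcm(matrix(0L, 1, 3), levels = 2)
  expect_equal(g0$p[1, 1], 1)
  # masking a column removes the pairs that span it
  gray <- matrix(0L, 2, 4)
  mask <- matrix(TRUE, 2, 4); mask[, 2] <- FALSE
  g <- compute_glcm(gray, mask, levels = 2)
  expect_equal(g$n_pairs, 2)  # only columns 3-4 remain paired, per row
  # no eligible pair is an error
  expect_error(compute_glcm(matrix(0L, 1, 3),
                            matrix(c(TRUE, FALSE, TRUE), 1, 3), levels = 2),
               "no horizontally adjacent")
})

glcm_from_p <- function(p) {
  structure(list(p = p, levels = nrow(p), n_pairs = 1L, symmetric = TRUE),
            class = "glcm")
}

test_that("contrast, texture correlation, homogeneity and energy evaluate exactly", {
  p01 <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  pconst <- matrix(c(1, 0, 0, 0), 2, 2)
  pdiag <- diag(c(0.5, 0.5))
  expect_equal(glcm_contrast(glcm_from_p(pconst)), 0)
  expect_equal(glcm_contrast(glcm_from_p(p01)), 1)
  L <- 64
  pmax_sep <- matrix(0, L, L); pmax_sep[1, L] <- 1
  expect_equal(glcm_contrast(glcm_from_p(pmax_sep)), (L - 1)^2)
  expect_equal(glcm_texture_correlation(glcm_from_p(pdiag)), 1)
  expect_equal(glcm_texture_correlation(glcm_from_p(p01)), -1)
  expect_true(is.na(glcm_texture_correlation(glcm_from_p(pconst))))
  ex <- glcm_extra_features(glcm_from_p(pconst))
  expect_equal(ex$homogeneity, 1); expect_equal(ex$energy, 1)
  ex <- glcm_extra_features(glcm_from_p(p01))
  expect_equal(ex$homogeneity, 0.5); expect_equal(ex$energy, 0.5)
  punif <- matrix(1 / L^2, L, L)
  expect_equal(glcm_extra_features(glcm_from_p(punif))$energy, 1 / L^2)
})

test_that("feature bounds hold on random patches", {
  set.seed(3)
  for (i in 1:15) {
    img <- matrix(runif(20 * 20, 0, 50), 20, 20)
    f <- patch_features(image_patch(img), levels = 16)
    expect_gte(f$contrast, 0); expect_lte(f$contrast, 15^2)
    expect_true(is.na(f$texture_correlation) || abs(f$texture_correlation) <= 1)
    expect_gt(f$energy, 0); expect_lte(f$energy, 1)
    expect_gt(f$homogeneity, 0); expect_lte(f$homogeneity, 1)
  }
})

test_that("rotation-averaged features track single-orientation features", {
  set.seed(4)
  unrot <- numeric(40); rot <- numeric(40)
  for (i in 1:40) {
    p <- simulate_patch(size = 24, n_spots = sample(2:12, 1),
                        spot_amplitude = runif(1, 1, 4))
    unrot[i] <- patch_features(p, rotations = 1)$contrast
    rot[i] <- patch_features(p, rotations = 4)$contrast
  }
  expect_gte(cor(unrot, rot, method = "spearman"), 0.9)

  # vertical stripes: the 90-degree rotation converts vertical to horizontal
  # adjacency, and the average lies between the two single orientations
  stripes <- image_patch(matrix(rep(c(0, 10), each = 16, times = 8), 16, 16))
  h <- patch_features(stripes, levels = 2, rotations = 1)$contrast
  q <- rescale_gray_levels(stripes, 2)
  v <- glcm_contrast(compute_glcm(t(q$gray), t(q$mask), levels = 2))
  avg <- patch_features(stripes, levels = 2, rotations = 4)$contrast
  expect_gte(avg, min(h, v)); expect_lte(avg, max(h, v))

  # constant patch stays 0 under rotation averaging
  expect_equal(patch_features(image_patch(matrix(1, 8, 8)), rotations = 4)$contrast, 0)
})

test_that("total intensity is an in-mask sum: linear and additive", {
  img <- matrix(2, 10, 10)
  expect_equal(total_intensity(image_patch(img)), 200)
  expect_equal(total_intensity(image_patch(2 * img)), 400)
  maskA <- matrix(FALSE, 10, 10); maskA[1:5, ] <- TRUE
  expect_equal(total_intensity(image_patch(img, maskA)) +
                 total_intensity(image_patch(img, !maskA)),
               total_intensity(image_patch(img)))
  expect_error(total_intensity(image_patch(img, matrix(FALSE, 10, 10))),
               "mask excludes")
})

test_that("negative intensities are clipped and counted", {
  p <- image_patch(matrix(c(-1, 2, 3, -4), 2, 2))
  expect_equal(p$n_clipped, 2)
  expect_true(all(p$intensities >= 0))
})
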