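test_that("clone structure: FOV partition, cell counts, consecutive frames", {
  cfg <- tiny_config()
  cl <- simulate_clone(cfg, clone_id = "p1", seed = 1)
  expect_equal(dplyr::n_distinct(cl$fov_id), cfg$n_fovs)
  counts <- dplyr::count(dplyr::distinct(cl, fov_id, cell_id), fov_id)
  expect_true(all(counts$n == cfg$cells_per_fov))
  by_cell <- split(cl$frame, cl$cell_id)
  expect_true(all(vapply(by_cell, function(f) identical(f, 0:(cfg$n_frames - 1)),
                         logical(1))))
  expect_identical(attr(cl, "truth_label"), "null")
  expect_identical(attr(simulate_clone(tiny_config(coupling_rho = 0.5), seed = 1),
                        "truth_label"), "true_positive")
})

test_that("null clones have independent protein and motility features", {
  cfg <- sim_config()
  rs <- vapply(1:60, function(i) {
    ft <- build_feature_table(simulate_clone(cfg, seed = 300 + i))
    cor(ft$level, ft$velocity, use = "pairwise")
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.02)
})

test_that("planted coupling reproduces the variance-decomposition prediction", {
  # with individuality fractions f_p, f_m and coupling rho, the pooled
  # level~velocity correlation tends to rho * sqrt(f_p * f_m)
  cfg <- sim_config(coupling_rho = 0.5, fov_effect_sd = 0)
  rs <- vapply(1:60, function(i) {
    ft <- build_feature_table(simulate_clone(cfg, seed = 400 + i))
    cor(ft$level, ft$velocity, use = "pairwise")
  }, numeric(1))
  expect_equal(mean(rs), 0.5 * sqrt(0.4 * 0.4), tolerance = 0.08)
})

test_that("between-cell variance share of protein level matches the individuality fraction", {
  # with an effectively infinite correlation time the slow component is a
  # per-cell constant, so the between-cell share of variance equals the
  # configured fraction
  cfg <- sim_config(n_fovs = 10, cells_per_fov = 50, tau_individuality = 1e8,
                    fov_effect_sd = 0)
  cl <- simulate_clone(cfg, seed = 11)
  between <- var(tapply(cl$level, cl$cell_id, mean))
  total <- var(cl$level)
  expect_equal(between / total, 0.4, tolerance = 0.15)
})

test_that("track truncation exercises the fully-tracked filter", {
  cfg <- tiny_config(truncate_frac = 0.6)
  cl <- simulate_clone(cfg, seed = 21)
  lens <- tapply(cl$frame, cl$cell_id, length)
  expect_true(any(lens < cfg$n_frames))
  ft <- build_feature_table(cl, fully_tracked_only = TRUE)
  expect_true(all(tapply(ft$frame, ft$cell_id, length) == cfg$n_frames))
})

test_that("patch-derived features are attached when patches are requested", {
  cfg <- sim_config(n_fovs = 1, cells_per_fov = 2, n_frames = 4)
  cl <- simulate_clone(cfg, seed = 31, patches = TRUE, patch_size = 16,
                       patch_spots = 4)
  expect_true(all(is.finite(cl$contrast)))
  expect_true(all(cl$contrast >= 0))
  expect_true(all(is.na(cl$texture) | abs(cl$texture) <= 1))
})

test_that("screen datasets carry a truth table and derive distinct clone seeds", {
  cfg <- tiny_config()
  ds <- simulate_screen_dataset(cfg, n_true = 2, n_null = 3,
                                coupling_rho_true = 0.6, seed = 9)
  expect_equal(nrow(ds$truth), 5)
  expect_equal(sum(ds$truth$truth_label == "true_positive"), 2)
  expect_equal(anyDuplicated(ds$truth$seed), 0)
  expect_setequal(unique(ds$tracks$protein_id), ds$truth$protein_id)
  # determinism
  ds2 <- simulate_screen_dataset(cfg, n_true = 2, n_null = 3,
                                 coupling_rho_true = 0.6, seed = 9)
  expect_identical(ds$tracks, ds2$tracks)
  expect_identical(ds$truth, ds2$truth)
  # all-null dataset
  ds0 <- simulate_screen_dataset(cfg, n_true = 0, n_null = 2, seed = 9)
  expect_true(all(ds0$truth$truth_label == "null"))
})
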