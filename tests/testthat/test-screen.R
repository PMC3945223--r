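test_that("feature table pooling counts rows and applies the fully-tracked filter", {
  cfg <- tiny_config()
  cl <- simulate_clone(cfg, seed = 1)
  ft <- build_feature_table(cl)
  expect_equal(nrow(ft), cfg$n_fovs * cfg$cells_per_fov * cfg$n_frames)
  # no truncated tracks: flag makes no difference
  expect_equal(nrow(build_feature_table(cl, fully_tracked_only = TRUE)), nrow(ft))
  # truncate one cell by hand: flag on drops exactly that cell
  cl2 <- cl[!(cl$cell_id == cl$cell_id[1] & cl$frame >= 5), ]
  ft2 <- build_feature_table(cl2, fully_tracked_only = TRUE)
  expect_false(cl$cell_id[1] %in% ft2$cell_id)
  expect_equal(nrow(ft2), (cfg$n_fovs * cfg$cells_per_fov - 1) * cfg$n_frames)
  expect_error(build_feature_table(cl[0, ]), "empty")
  expect_error(build_feature_table(dplyr::select(cl, -level)), "missing required")
})

test_that("pooled correlations behave as Pearson/Spearman on pooled rows", {
  tab <- make_sloped_table(c(1, 1), n_cells = 4, n_frames = 30, noise_sd = 0)
  tab$level <- tab$velocity  # identical columns
  rec <- correlate_protein(tab, "p1")
  lv <- rec[rec$comparison == "level~velocity", ]
  expect_equal(lv$pearson_r, 1)
  expect_equal(lv$spearman_r, 1)
  expect_equal(lv$n_points, nrow(tab))
  # monotone non-linear transform: ranks unchanged, linearity broken
  tab$level <- exp(tab$velocity)
  lv <- correlate_protein(tab, "p1")[1, ]
  expect_equal(lv$spearman_r, 1)
  expect_lt(lv$pearson_r, 1)
  # constant feature gives an undefined flag
  tab$level <- 1
  lv <- correlate_protein(tab, "p1")[1, ]
  expect_true(is.na(lv$pearson_r) && is.na(lv$spearman_r))
})

test_that("within-FOV permutation is a frame-aligned derangement", {
  cfg <- tiny_config()
  ft <- build_feature_table(simulate_clone(cfg, seed = 2))
  set.seed(7)
  pm <- permute_within_fov(ft)
  # derangement: no cell keeps its own protein trace
  expect_true(all(pm$donor_cell_id != pm$cell_id))
  # donors come from the same FOV
  donor_fov <- ft$fov_id[match(paste(pm$donor_cell_id, pm$frame),
                               paste(ft$cell_id, ft$frame))]
  expect_true(all(donor_fov == pm$fov_id))
  # marginals of every feature and per-FOV cell counts unchanged
  expect_equal(sort(pm$level), sort(ft$level))
  expect_equal(sort(pm$contrast), sort(ft$contrast))
  expect_equal(sort(pm$velocity), sort(ft$velocity))
  expect_equal(table(pm$fov_id), table(ft$fov_id))
  # time alignment: donor value at the same frame
  i <- 50
  j <- which(ft$cell_id == pm$donor_cell_id[i] & ft$frame == pm$frame[i])
  expect_equal(pm$level[i], ft$level[j])

  # a 2-cell FOV has a unique derangement: the swap
  fov1_cells <- unique(ft$cell_id[ft$fov_id == "fov01"])[1:2]
  small <- ft[ft$cell_id %in% fov1_cells, ]
  sw <- permute_within_fov(small)
  expect_true(all(sw$donor_cell_id[sw$cell_id == fov1_cells[1]] == fov1_cells[2]))
  expect_true(all(sw$donor_cell_id[sw$cell_id == fov1_cells[2]] == fov1_cells[1]))

  # single-cell FOVs cannot satisfy i != j and are dropped with a warning
  one <- ft[ft$cell_id == ft$cell_id[1], ]
  expect_warning(out <- permute_within_fov(one), "single cell")
  expect_equal(nrow(out), 0)
})

test_that("permutation collapses a planted coupling below threshold", {
  cfg <- sim_config(coupling_rho = 0.8)
  ft <- build_feature_table(simulate_clone(cfg, seed = 3))
  expect_gt(cor(ft$level, ft$velocity, use = "pairwise"), 0.15)
  set.seed(8)
  perm_r <- vapply(1:10, function(k) {
    pm <- permute_within_fov(ft)
    cor(pm$level, pm$velocity, use = "pairwise")
  }, numeric(1))
  expect_gte(sum(abs(perm_r) < 0.15), 9)
})

test_that("candidate calling follows the dual-threshold, sign-consistent rule", {
  rec <- tibble::tibble(
    protein_id = c("a", "b", "c", "d"),
    protein_feature = "level", motility_feature = "velocity",
    comparison = "level~velocity",
    pearson_r = c(0.30, 0.20, 0.20, -0.16),
    spearman_r = c(0.22, 0.10, -0.20, -0.19),
    n_points = 1000
  )
  calls <- call_candidates(rec, threshold = 0.15)
  expect_equal(calls$candidate[calls$protein_id == "a"], TRUE)   # both above
  expect_equal(calls$candidate[calls$protein_id == "b"], FALSE)  # Spearman below
  expect_equal(calls$candidate[calls$protein_id == "c"], FALSE)  # sign conflict
  expect_equal(calls$candidate[calls$protein_id == "d"], TRUE)   # both negative
  expect_true(calls$by_level[calls$protein_id == "a"])
  expect_false(calls$multi_measure[calls$protein_id == "a"])
  # multi-measure: passing on two distinct protein features
  rec2 <- dplyr::bind_rows(rec[1, ],
                           dplyr::mutate(rec[1, ], protein_feature = "contrast",
                                         comparison = "contrast~velocity"))
  calls2 <- call_candidates(rec2, threshold = 0.15)
  expect_true(calls2$multi_measure)
  # the minimum-points rule removes under-sampled comparisons
  expect_false(call_candidates(rec[1, ], threshold = 0.15,
                               min_points = 5000)$candidate)
})

test_that("raising the threshold never increases hits or the FDR numerator", {
  cfg <- tiny_config()
  ds <- simulate_screen_dataset(cfg, n_true = 2, n_null = 4,
                                coupling_rho_true = 0.9, seed = 5)
  ft <- build_feature_table(ds$tracks)
  rec <- correlate_features(ft)
  null <- build_null_distribution(ft, n_perm = 3, seed = 5)
  prev_hits <- Inf; prev_null <- Inf
  for (thr in c(0.05, 0.15, 0.3, 0.6)) {
    f <- estimate_fdr(rec, null, threshold = thr, min_points = 10)
    hits <- sum(f$n_real_hits); nh <- sum(f$mean_null_hits)
    expect_lte(hits, prev_hits); expect_lte(nh, prev_null)
    prev_hits <- hits; prev_null <- nh
  }
})

test_that("FDR is about 1 on null data and undefined with no real hits", {
  cfg <- sim_config(cells_per_fov = 8, n_frames = 24)
  ds <- simulate_screen_dataset(cfg, n_true = 0, n_null = 12, seed = 6)
  ft <- build_feature_table(ds$tracks)
  rec <- correlate_features(ft)
  null <- build_null_distribution(ft, n_perm = 4, seed = 6)
  # low threshold: essentially everything passes in both real and permuted data
  f <- estimate_fdr(rec, null, threshold = 1e-6, min_points = 10)
  expect_true(all(f$fdr_estimate[f$n_real_hits > 0] > 0.8))
  # threshold beyond any |R|: no real hit, estimate undefined
  f2 <- estimate_fdr(rec, null, threshold = 0.999, min_points = 10)
  expect_true(all(is.na(f2$fdr_estimate)))
})

test_that("the FOV robustness filter requires a strict majority of supporting FOVs", {
  # consistent coupling in all four FOVs: robust
  tab <- make_sloped_table(c(0.5, 0.5, 0.5, 0.5), seed = 21)
  rec <- correlate_features(tab)
  calls <- call_candidates(rec)
  out <- fov_robustness_filter(tab, rec, calls)
  expect_true(out$fov_robust[out$protein_id == "p1"])
  expect_true(out$final_candidate[1])
  # coupling driven by a single FOV: called on pooled data but not robust
  tab2 <- make_sloped_table(c(1.5, 0, 0, 0), seed = 22)
  rec2 <- correlate_features(tab2)
  calls2 <- call_candidates(rec2)
  expect_true(calls2$candidate[1])
  out2 <- fov_robustness_filter(tab2, rec2, calls2)
  expect_false(out2$fov_robust[1])
  expect_false(out2$final_candidate[1])
})

test_that("a planted clone with FOV batch effects passes the robustness filter", {
  cfg <- sim_config(coupling_rho = 0.8)
  robust <- vapply(1:20, function(i) {
    ft <- build_feature_table(simulate_clone(cfg, seed = 600 + i))
    rec <- correlate_features(ft)
    calls <- call_candidates(rec)
    if (!calls$candidate[1]) return(NA)
    fov_robustness_filter(ft, rec, calls)$fov_robust[1]
  }, logical(1))
  expect_gte(mean(robust, na.rm = TRUE), 0.9)
})

test_that("the screen is deterministic given a seed", {
  cfg <- tiny_config()
  ds <- simulate_screen_dataset(cfg, n_true = 1, n_null = 3,
                                coupling_rho_true = 0.8, seed = 30)
  ft <- build_feature_table(ds$tracks)
  s1 <- screen_motility(ft, min_points = 10, seed = 99)
  s2 <- screen_motility(ft, min_points = 10, seed = 99)
  expect_identical(s1$null$values, s2$null$values)
  expect_identical(s1$calls, s2$calls)
  expect_identical(s1$fdr, s2$fdr)
})

test_that("tidy and glance summarise a screen", {
  cfg <- tiny_config()
  ds <- simulate_screen_dataset(cfg, n_true = 1, n_null = 2,
                                coupling_rho_true = 0.9, seed = 31)
  scr <- screen_motility(build_feature_table(ds$tracks), min_points = 10,
                         seed = 31)
  td <- tidy(scr)
  expect_equal(nrow(td), 3 * 6)
  expect_true(all(c("pass", "candidate", "final_candidate") %in% names(td)))
  gl <- glance(scr)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_proteins, 3)
})
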