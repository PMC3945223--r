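protein_feature_names <- function(table) {
  intersect(c("level", "contrast", "texture"), names(table))
}
motility_feature_names <- c("velocity", "angle_change")

# Dual-threshold pass rule: both statistics beyond the threshold, same sign
passes_dual <- function(pearson_r, spearman_r, threshold) {
  !is.na(pearson_r) & !is.na(spearman_r) &
    abs(pearson_r) >= threshold & abs(spearman_r) >= threshold &
    sign(pearson_r) == sign(spearman_r)
}

#' Pool tracked cells into the per-protein feature table
#'
#' Validates the track table, (re)computes motility features, and optionally
#' restricts to fully tracked cells: cells observed in every frame of their
#' protein's movie, from frame 0 to the last frame present for that protein.
#' Rows with undefined features are retained as `NA` markers and excluded
#' later, pairwise per comparison.
#'
#' @param tracks Track tibble (see [read_tracks()]); motility columns are
#'   computed if absent.
#' @param fully_tracked_only Drop cells that were not tracked from the start
#'   to the end of the movie.
#' @return Feature-table tibble (one row per cell and frame) with attribute
#'   `fully_tracked_only`.
#' @examples
#' tr <- simulate_clone(sim_config(cells_per_fov = 2, n_frames = 6), seed = 1)
#' nrow(build_feature_table(tr))
#' @export
build_feature_table <- function(tracks, fully_tracked_only = FALSE) {
  if (nrow(tracks) == 0) stop("tracks is empty", call. = FALSE)
  req <- c("protein_id", "fov_id", "cell_id", "frame", "x", "y", "level")
  miss <- setdiff(req, names(tracks))
  if (length(miss) > 0) {
    stop("tracks is missing required columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tab <- if (all(motility_feature_names %in% names(tracks))) tracks
         else add_motility_features(tracks)
  if (fully_tracked_only) {
    tab <- tab |>
      dplyr::group_by(.data$protein_id) |>
      dplyr::mutate(.movie_end = max(.data$frame)) |>
      dplyr::group_by(.data$fov_id, .data$cell_id, .add = TRUE) |>
      dplyr::filter(min(.data$frame) == 0,
                    dplyr::n_distinct(.data$frame) == .data$.movie_end[1] + 1) |>
      dplyr::ungroup() |>
      dplyr::select(-".movie_end")
    if (nrow(tab) == 0) {
      stop("fully_tracked_only filter removed every cell", call. = FALSE)
    }
  }
  attr(tab, "fully_tracked_only") <- fully_tracked_only
  tab
}

cor_pair <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    return(list(pearson_r = NA_real_, spearman_r = NA_real_, n_points = n))
  }
  list(pearson_r = stats::cor(x[ok], y[ok]),
       spearman_r = stats::cor(x[ok], y[ok], method = "spearman"),
       n_points = n)
}

#' Correlate protein features with motility features, pooled over cells
#'
#' For each protein, pools all cells in all FOVs at all frames and computes
#' the six feature-pair comparisons -- (level, contrast, texture) x
#' (velocity, angle change) -- with both Pearson and Spearman correlation.
#' No binning is applied; rows with a missing value in either feature are
#' deleted pairwise, per comparison. A constant feature yields `NA`
#' correlations for its comparisons.
#'
#' @param table Feature table from [build_feature_table()].
#' @return Tibble with one row per protein and comparison: `protein_id`,
#'   `protein_feature`, `motility_feature`, `comparison` (e.g.
#'   `"level~velocity"`), `pearson_r`, `spearman_r`, `n_points`.
#' @export
correlate_features <- function(table) {
  pf <- protein_feature_names(table)
  if (length(pf) == 0) stop("no protein feature columns in table", call. = FALSE)
  table |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::group_modify(function(d, key) {
      tidyr::expand_grid(protein_feature = pf,
                         motility_feature = motility_feature_names) |>
        dplyr::rowwise() |>
        dplyr::mutate(tibble::as_tibble(
          cor_pair(d[[.data$protein_feature]], d[[.data$motility_feature]])
        )) |>
        dplyr::ungroup()
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(comparison = paste(.data$protein_feature,
                                     .data$motility_feature, sep = "~"),
                  .after = "motility_feature")
}

#' @rdname correlate_features
#' @param protein_id Restrict to one protein.
#' @export
correlate_protein <- function(table, protein_id) {
  correlate_features(table[table$protein_id %in% protein_id, , drop = FALSE])
}

# Random derangement (permutation with no fixed point) of 1..n, n >= 2
derangement <- function(n) {
  if (n < 2) stop("derangement needs n >= 2", call. = FALSE)
  if (n == 2) return(c(2L, 1L))
  repeat {
    p <- sample.int(n)
    if (all(p != seq_len(n))) return(p)
  }
}

#' Permute protein traces across cells within each field of view
#'
#' Builds one randomised dataset: within every FOV, each cell's protein
#' features (level, contrast, texture) at all frames are replaced by the
#' protein features of a *different* cell of the same FOV (a random
#' derangement of the FOV's cells), keeping time alignment -- frame `t` maps
#' to frame `t`. Motility features stay with their own cell, so any
#' protein--motility association is broken while per-feature marginals,
#' within-FOV structure and temporal autocorrelation are preserved. Traces of
#' unequal length are paired on their common frames; frames absent from the
#' donor become `NA`. FOVs with a single cell cannot satisfy `i != j` and are
#' dropped with a warning.
#'
#' @param table Feature table (one or more proteins; the permutation is drawn
#'   independently per protein and FOV).
#' @return The table with protein-feature columns replaced by donor values
#'   and a `donor_cell_id` column appended.
#' @export
permute_within_fov <- function(table) {
  pf <- protein_feature_names(table)
  table |>
    dplyr::group_by(.data$protein_id, .data$fov_id) |>
    dplyr::group_modify(function(d, key) {
      cells <- unique(d$cell_id)
      if (length(cells) < 2) {
        warning("FOV ", key$fov_id, " has a single cell; excluded from permutation",
                call. = FALSE)
        return(d[0, , drop = FALSE])
      }
      donor_of <- stats::setNames(cells[derangement(length(cells))], cells)
      key_self <- paste(d$cell_id, d$frame)
      key_donor <- paste(donor_of[d$cell_id], d$frame)
      idx <- match(key_donor, key_self)
      out <- d
      for (f in pf) out[[f]] <- d[[f]][idx]
      out$donor_cell_id <- unname(donor_of[d$cell_id])
      out
    }) |>
    dplyr::ungroup()
}

#' Build the within-FOV permutation null distribution
#'
#' Repeats the within-FOV trace permutation `n_perm` times (default 10) and
#' recomputes all six comparisons with both statistics for every protein,
#' yielding `n_perm x n_proteins` null correlation values per comparison.
#'
#' @inheritParams correlate_features
#' @param n_perm Number of independent permuted datasets.
#' @param threshold Candidate threshold carried along for FDR estimation.
#' @param seed Optional seed.
#' @return Object of class `null_distribution`: list with `values` (tibble of
#'   per-permutation correlation records, column `perm`), `n_perm`,
#'   `threshold`.
#' @export
build_null_distribution <- function(table, n_perm = 10, threshold = 0.15,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  values <- purrr::map_dfr(seq_len(n_perm), function(k) {
    correlate_features(permute_within_fov(table)) |>
      dplyr::mutate(perm = k)
  })
  structure(list(values = values, n_perm = n_perm, threshold = threshold),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> %d permutations, threshold %.2f, %d values\n",
              x$n_perm, x$threshold, nrow(x$values)))
  invisible(x)
}

#' Estimate the false discovery rate at a correlation threshold
#'
#' For each comparison, the FDR is the mean per-permutation count of proteins
#' whose permuted data passes the dual rule (|R| >= threshold in both Pearson
#' and Spearman, signs agreeing) divided by the count of real proteins
#' passing the same rule. Undefined (`NA`) when no real protein passes;
#' estimates above 1 (possible on null data) are capped at 1.
#'
#' @param real_records Correlation records from [correlate_features()].
#' @param null A [build_null_distribution()] result.
#' @param threshold Dual-correlation threshold (defaults to the null's).
#' @param min_points Comparisons with fewer complete pairs are ignored.
#' @return Tibble: `comparison`, `n_real_hits`, `mean_null_hits`,
#'   `fdr_estimate`.
#' @export
estimate_fdr <- function(real_records, null, threshold = NULL, min_points = 50) {
  threshold <- threshold %||% null$threshold
  real <- real_records |>
    dplyr::group_by(.data$comparison) |>
    dplyr::summarise(n_real_hits = sum(
      passes_dual(.data$pearson_r, .data$spearman_r, threshold) &
        .data$n_points >= min_points
    ), .groups = "drop")
  nulls <- null$values |>
    dplyr::group_by(.data$comparison, .data$perm) |>
    dplyr::summarise(hits = sum(
      passes_dual(.data$pearson_r, .data$spearman_r, threshold) &
        .data$n_points >= min_points
    ), .groups = "drop_last") |>
    dplyr::summarise(mean_null_hits = mean(.data$hits), .groups = "drop")
  dplyr::left_join(real, nulls, by = "comparison") |>
    dplyr::mutate(fdr_estimate = ifelse(.data$n_real_hits > 0,
                                        pmin(.data$mean_null_hits / .data$n_real_hits, 1),
                                        NA_real_))
}

#' Call candidate proteins with the dual-correlation threshold
#'
#' A comparison passes when |R| >= `threshold` in **both** the Pearson and
#' Spearman statistic with agreeing signs and at least `min_points` complete
#' pairs; a protein is a candidate when at least one of its six comparisons
#' passes. Per-feature flags and the multi-measure flag (passing comparisons
#' on >= 2 distinct protein features) are filled for downstream breakdowns.
#'
#' @inheritParams estimate_fdr
#' @param records Correlation records from [correlate_features()].
#' @param threshold Dual-correlation threshold (default 0.15).
#' @return Tibble with one row per protein: `protein_id`, `candidate`,
#'   `passing_comparisons` (comma-separated), `n_passing`, `by_level`,
#'   `by_contrast`, `by_texture`, `multi_measure`.
#' @export
call_candidates <- function(records, threshold = 0.15, min_points = 50) {
  records |>
    dplyr::mutate(pass = passes_dual(.data$pearson_r, .data$spearman_r, threshold) &
                    .data$n_points >= min_points) |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(
      candidate = any(.data$pass),
      passing_comparisons = paste(.data$comparison[.data$pass], collapse = ","),
      n_passing = sum(.data$pass),
      by_level = any(.data$pass & .data$protein_feature == "level"),
      by_contrast = any(.data$pass & .data$protein_feature == "contrast"),
      by_texture = any(.data$pass & .data$protein_feature == "texture"),
      multi_measure = dplyr::n_distinct(.data$protein_feature[.data$pass]) >= 2,
      .groups = "drop"
    )
}

#' Per-field-of-view robustness filter
#'
#' A candidate passes when, for at least one of its passing comparisons,
#' strictly more than `majority_fraction` of the evaluable FOVs individually
#' show a Pearson correlation of the same sign as the pooled value with
#' |R| >= `threshold`. FOVs with fewer than `min_points` complete pairs are
#' not evaluable; candidates with fewer than 2 evaluable FOVs get `NA`
#' robustness and are retained or dropped according to
#' `retain_undefined`.
#'
#' @inheritParams call_candidates
#' @param table Feature table the records were computed from.
#' @param calls Candidate calls from [call_candidates()].
#' @param majority_fraction Fraction of evaluable FOVs that must individually
#'   support the pooled correlation (strict majority by default).
#' @param retain_undefined Keep candidates whose robustness cannot be
#'   evaluated (default `TRUE`, with `fov_robust = NA`).
#' @return `calls` with `fov_robust` and `final_candidate` columns appended.
#' @export
fov_robustness_filter <- function(table, records, calls, threshold = 0.15,
                                  majority_fraction = 0.5, min_points = 50,
                                  retain_undefined = TRUE) {
  rec <- records |>
    dplyr::mutate(pass = passes_dual(.data$pearson_r, .data$spearman_r, threshold) &
                    .data$n_points >= min_points)
  robust_one <- function(pid) {
    pr <- rec[rec$protein_id == pid & rec$pass, , drop = FALSE]
    if (nrow(pr) == 0) return(FALSE)
    d <- table[table$protein_id == pid, , drop = FALSE]
    any_eval <- FALSE
    for (i in seq_len(nrow(pr))) {
      pooled_sign <- sign(pr$pearson_r[i])
      xcol <- pr$protein_feature[i]; ycol <- pr$motility_feature[i]
      per_fov <- d |>
        dplyr::group_by(.data$fov_id) |>
        dplyr::summarise(tibble::as_tibble(cor_pair(.data[[xcol]], .data[[ycol]])),
                         .groups = "drop") |>
        dplyr::filter(.data$n_points >= min_points, !is.na(.data$pearson_r))
      n_eval <- nrow(per_fov)
      if (n_eval < 2) next
      any_eval <- TRUE
      n_support <- sum(sign(per_fov$pearson_r) == pooled_sign &
                         abs(per_fov$pearson_r) >= threshold)
      if (n_support > majority_fraction * n_eval) return(TRUE)
    }
    if (any_eval) FALSE else NA
  }
  calls$fov_robust <- NA
  cand <- which(calls$candidate)
  calls$fov_robust[cand] <- vapply(calls$protein_id[cand], robust_one, logical(1))
  calls$final_candidate <- calls$candidate &
    (calls$fov_robust %in% TRUE | (is.na(calls$fov_robust) & retain_undefined & calls$candidate))
  calls
}

#' Run the full correlation screen on a feature table
#'
#' Orchestrates the screen: pooled Pearson + Spearman correlations for all
#' six comparisons per protein, the within-FOV trace-permutation null
#' (`n_perm` derangement permutations), per-comparison FDR estimates at the
#' dual threshold, candidate calls, and the per-FOV robustness filter.
#'
#' @inheritParams build_null_distribution
#' @inheritParams fov_robustness_filter
#' @param seed Seed for the permutation null (required for reproducible
#'   output).
#' @return Object of class `motility_screen`: list with `correlations`,
#'   `null` (a `null_distribution`), `fdr`, `calls`, `params`. Supports
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' ds <- simulate_screen_dataset(sim_config(cells_per_fov = 4, n_frames = 12),
#'                               n_true = 1, n_null = 3, seed = 1)
#' scr <- screen_motility(build_feature_table(ds$tracks), min_points = 10, seed = 1)
#' scr$calls
#' @export
screen_motility <- function(table, threshold = 0.15, n_perm = 10,
                            min_points = 50, majority_fraction = 0.5,
                            retain_undefined = TRUE, seed = NULL) {
  correlations <- correlate_features(table)
  null <- build_null_distribution(table, n_perm = n_perm, threshold = threshold,
                                  seed = seed)
  fdr <- estimate_fdr(correlations, null, threshold = threshold,
                      min_points = min_points)
  calls <- call_candidates(correlations, threshold = threshold,
                           min_points = min_points)
  calls <- fov_robustness_filter(table, correlations, calls,
                                 threshold = threshold,
                                 majority_fraction = majority_fraction,
                                 min_points = min_points,
                                 retain_undefined = retain_undefined)
  structure(
    list(correlations = correlations, null = null, fdr = fdr, calls = calls,
         params = list(threshold = threshold, n_perm = n_perm,
                       min_points = min_points,
                       majority_fraction = majority_fraction,
                       retain_undefined = retain_undefined, seed = seed)),
    class = "motility_screen"
  )
}

#' @export
print.motility_screen <- function(x, ...) {
  cat("<motility_screen>\n")
  cat(sprintf("  %d proteins, threshold |R| >= %.2f (Pearson & Spearman), %d permutations\n",
              dplyr::n_distinct(x$correlations$protein_id),
              x$params$threshold, x$params$n_perm))
  cat(sprintf("  candidates: %d (final, after FOV robustness: %d)\n",
              sum(x$calls$candidate), sum(x$calls$final_candidate)))
  fdr <- x$fdr[!is.na(x$fdr$fdr_estimate), ]
  if (nrow(fdr) > 0) {
    cat("  FDR estimates:\n")
    for (i in seq_len(nrow(fdr))) {
      cat(sprintf("    %-22s %.2f (%d real hits)\n", fdr$comparison[i],
                  fdr$fdr_estimate[i], fdr$n_real_hits[i]))
    }
  }
  invisible(x)
}
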