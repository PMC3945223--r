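#' Tidy a motility screen
#'
#' Returns the per-protein, per-comparison correlation records with the
#' dual-threshold pass flag and the protein-level candidate verdicts joined
#' on.
#'
#' @param x A [screen_motility()] result.
#' @param ... Unused.
#' @return A tibble with one row per protein and comparison.
#' @export
tidy.motility_screen <- function(x, ...) {
  x$correlations |>
    dplyr::mutate(pass = passes_dual(.data$pearson_r, .data$spearman_r,
                                     x$params$threshold) &
                    .data$n_points >= x$params$min_points) |>
    dplyr::left_join(
      dplyr::select(x$calls, "protein_id", "candidate", "fov_robust",
                    "final_candidate"),
      by = "protein_id"
    )
}

#' Glance at a motility screen
#'
#' @inheritParams tidy.motility_screen
#' @return A one-row tibble summarising the screen: protein and candidate
#'   counts, thresholds, permutation count, and the FDR estimate for the
#'   level-versus-velocity comparison (`NA` when undefined).
#' @export
glance.motility_screen <- function(x, ...) {
  lv <- x$fdr$fdr_estimate[x$fdr$comparison == "level~velocity"]
  tibble::tibble(
    n_proteins = dplyr::n_distinct(x$correlations$protein_id),
    n_candidates = sum(x$calls$candidate),
    n_final_candidates = sum(x$calls$final_candidate),
    threshold = x$params$threshold,
    n_perm = x$params$n_perm,
    fdr_level_velocity = if (length(lv) == 1) lv else NA_real_
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
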