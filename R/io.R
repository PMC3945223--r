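track_col_types <- function() {
  readr::cols(
    protein_id = readr::col_character(),
    fov_id = readr::col_character(),
    cell_id = readr::col_character(),
    frame = readr::col_integer(),
    .default = readr::col_double()
  )
}

#' Read a canonical track table
#'
#' Reads the pipeline's tab-separated track format: one row per cell and
#' frame with columns `protein_id`, `fov_id`, `cell_id`, `frame` (0-based),
#' `time` (minutes), `x`, `y` (micrometres), `level`, and optionally
#' `contrast`, `texture`, `velocity`, `angle_change`. Undefined values are
#' the literal token `NA`. The key `(protein_id, fov_id, cell_id, frame)`
#' must be unique.
#'
#' @param path Path to a TSV file with header.
#' @return Validated track tibble, arranged by protein, FOV, cell, frame.
#' @export
read_tracks <- function(path) {
  tab <- readr::read_tsv(path, col_types = track_col_types(),
                         progress = FALSE)
  req <- c("protein_id", "fov_id", "cell_id", "frame", "x", "y", "level")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0) {
    stop("track file is missing required columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(tab$protein_id, tab$fov_id, tab$cell_id, tab$frame)
  dup <- anyDuplicated(key)
  if (dup > 0) {
    stop("duplicate (protein, fov, cell, frame) row: ", key[dup], call. = FALSE)
  }
  bad <- which(!is.finite(tab$x) | !is.finite(tab$y))
  if (length(bad) > 0) {
    stop("non-finite centroid coordinates at data row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  dplyr::arrange(tab, .data$protein_id, .data$fov_id, .data$cell_id, .data$frame)
}

#' Write a track table in the canonical TSV format
#'
#' @param tracks Track tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  readr::write_tsv(tracks, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Patch TIFF round-trip helpers
#'
#' Writes a patch as a single-channel 32-bit float TIFF with intensities scaled by
#' `max_value` (the quantization used downstream is per-image min--max, so
#' contrast and texture are unaffected by the scaling; total intensity is in
#' `max_value` units). The mask is written alongside with suffix `_mask`.
#' Requires the tiff package.
#'
#' @param patch An [image_patch()].
#' @param path Output TIFF path.
#' @param max_value Intensity mapped to the top of the unit range.
#' @return `path`, invisibly.
#' @export
write_patch_tiff <- function(patch, path, max_value = 2^16 - 1) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the tiff package is required for TIFF I/O", call. = FALSE)
  }
  tiff::writeTIFF(pmin(patch$intensities / max_value, 1), path,
                  bits.per.sample = 32)
  tiff::writeTIFF(patch$mask * 1, mask_path_for(path), bits.per.sample = 8)
  invisible(path)
}

mask_path_for <- function(path, mask_suffix = "_mask") {
  sub("(\\.[^.]+)$", paste0(mask_suffix, "\\1"), path)
}

#' @rdname write_patch_tiff
#' @param mask_suffix Suffix of the companion mask file.
#' @return For `read_patch_tiff`, an [image_patch()].
#' @export
read_patch_tiff <- function(path, mask_suffix = "_mask", max_value = 2^16 - 1) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the tiff package is required for TIFF I/O", call. = FALSE)
  }
  img <- tiff::readTIFF(path) * max_value
  mp <- mask_path_for(path, mask_suffix)
  mask <- if (file.exists(mp)) tiff::readTIFF(mp) > 0.5 else NULL
  image_patch(img, mask)
}

#' Compute protein features for a directory of patch TIFFs
#'
#' Applies [patch_features()] to every non-mask TIFF in a directory (masks
#' are matched by `mask_suffix`), mirroring the per-(cell, frame) feature
#' extraction stage.
#'
#' @param dir Directory containing patch TIFFs.
#' @inheritParams read_patch_tiff
#' @inheritParams patch_features
#' @return Tibble with one row per patch, column `file` first.
#' @export
features_from_patch_dir <- function(dir, mask_suffix = "_mask", levels = 64,
                                    rotations = 1, max_value = 2^16 - 1) {
  files <- list.files(dir, pattern = "\\.tiff?$", recursive = TRUE,
                      full.names = TRUE)
  files <- files[!grepl(paste0(mask_suffix, "\\.tiff?$"), files)]
  if (length(files) == 0) stop("no patch TIFFs found in ", dir, call. = FALSE)
  purrr::map_dfr(files, function(f) {
    p <- read_patch_tiff(f, mask_suffix = mask_suffix, max_value = max_value)
    dplyr::bind_cols(tibble::tibble(file = f),
                     patch_features(p, levels = levels, rotations = rotations))
  })
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end screen. Either `tracks_file` or
#' `simulate` must be given. All parameters are validated before any stage
#' runs, and the configuration (with the seed) is echoed into the output
#' directory as `config.json`.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Master seed; every random stage derives from it.
#' @param tracks_file Canonical track TSV to screen.
#' @param simulate Alternatively, a list of arguments to
#'   [simulate_screen_dataset()] (any [sim_config()] field plus `n_true`,
#'   `n_null`, `coupling_rho_true`).
#' @param threshold,n_perm,min_points,majority_fraction,fully_tracked_only
#'   Screen parameters, see [screen_motility()] and [build_feature_table()].
#' @param annotations_file Optional annotation TSV (`gene_id`, `category`)
#'   for the enrichment stage.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed, tracks_file = NULL, simulate = NULL,
                            threshold = 0.15, n_perm = 10, min_points = 50,
                            majority_fraction = 0.5, fully_tracked_only = FALSE,
                            annotations_file = NULL) {
  if (is.null(tracks_file) && is.null(simulate)) {
    stop("provide either tracks_file or simulate", call. = FALSE)
  }
  if (!is.null(tracks_file) && !file.exists(tracks_file)) {
    stop("tracks_file does not exist: ", tracks_file, call. = FALSE)
  }
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)",
                                             call. = FALSE)
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 tracks_file = tracks_file, simulate = simulate,
                 threshold = threshold, n_perm = n_perm,
                 min_points = min_points,
                 majority_fraction = majority_fraction,
                 fully_tracked_only = fully_tracked_only,
                 annotations_file = annotations_file),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with the fields of `pipeline_config()`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the end-to-end screen pipeline
#'
#' Loads (or simulates) tracks, builds the feature table, runs
#' [screen_motility()], optionally tests annotation enrichment of the final
#' candidates, and writes every stage output to `config$out_dir`:
#' `correlations.tsv` (wide, one row per protein with the six Pearson and
#' six Spearman values), `correlations_long.tsv`, `permuted_correlations.tsv`
#' (the permutation null values), `fdr.tsv`, `candidates.tsv`,
#' `feature_breakdown.tsv`, `enrichment.tsv` (when annotations are given),
#' `truth_recovery.tsv` (when simulating), `config.json` and `log.txt` with
#' per-stage row counts and drop reasons. Reruns with the same configuration
#' and seed are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the `motility_screen` object, the feature
#'   `table`, stage outputs and file `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  set.seed(config$seed)
  truth <- NULL
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    cfg_fields <- intersect(names(sim_args), names(formals(sim_config)))
    scfg <- do.call(sim_config, sim_args[cfg_fields])
    ds_args <- sim_args[intersect(names(sim_args),
                                  c("n_true", "n_null", "coupling_rho_true",
                                    "coupled_features"))]
    ds <- do.call(simulate_screen_dataset,
                  c(list(config = scfg, seed = config$seed), ds_args))
    tracks <- ds$tracks
    truth <- ds$truth
    note("simulate: %d clones, %d rows", nrow(truth), nrow(tracks))
  } else {
    tracks <- read_tracks(config$tracks_file)
    note("read_tracks: %d rows from %s", nrow(tracks), config$tracks_file)
  }

  table <- build_feature_table(tracks,
                               fully_tracked_only = config$fully_tracked_only)
  note("feature_table: %d rows (%d dropped by fully_tracked_only=%s)",
       nrow(table), nrow(tracks) - nrow(table), config$fully_tracked_only)

  scr <- screen_motility(table, threshold = config$threshold,
                         n_perm = config$n_perm,
                         min_points = config$min_points,
                         majority_fraction = config$majority_fraction,
                         seed = config$seed + 1L)
  note("screen: %d proteins, %d candidates, %d final",
       dplyr::n_distinct(scr$correlations$protein_id),
       sum(scr$calls$candidate), sum(scr$calls$final_candidate))

  p <- function(f) file.path(config$out_dir, f)
  wide <- scr$correlations |>
    dplyr::select("protein_id", "comparison", "pearson_r", "spearman_r",
                  "n_points") |>
    tidyr::pivot_wider(names_from = "comparison",
                       values_from = c("pearson_r", "spearman_r", "n_points"))
  readr::write_tsv(wide, p("correlations.tsv"), na = "NA", progress = FALSE)
  readr::write_tsv(scr$correlations, p("correlations_long.tsv"), na = "NA",
                   progress = FALSE)
  readr::write_tsv(scr$null$values, p("permuted_correlations.tsv"), na = "NA",
                   progress = FALSE)
  readr::write_tsv(scr$fdr, p("fdr.tsv"), na = "NA", progress = FALSE)
  readr::write_tsv(scr$calls, p("candidates.tsv"), na = "NA", progress = FALSE)
  breakdown <- feature_breakdown(scr$calls)
  readr::write_tsv(breakdown, p("feature_breakdown.tsv"), na = "NA",
                   progress = FALSE)

  enrichment <- NULL
  if (!is.null(config$annotations_file)) {
    ann <- readr::read_tsv(config$annotations_file, col_types = readr::cols(),
                           progress = FALSE)
    enrichment <- enrich_categories(
      candidates = scr$calls$protein_id[scr$calls$final_candidate],
      background = scr$calls$protein_id,
      annotations = ann
    )
    readr::write_tsv(enrichment, p("enrichment.tsv"), na = "NA",
                     progress = FALSE)
    note("enrichment: %d categories tested", nrow(enrichment))
  }

  if (!is.null(truth)) {
    recovery <- dplyr::left_join(truth, scr$calls, by = "protein_id")
    readr::write_tsv(recovery, p("truth_recovery.tsv"), na = "NA",
                     progress = FALSE)
    tp <- sum(recovery$final_candidate & recovery$truth_label == "true_positive")
    fp <- sum(recovery$final_candidate & recovery$truth_label == "null")
    note("truth recovery: %d/%d planted positives called, %d false positives",
         tp, sum(truth$truth_label == "true_positive"), fp)
  }

  jsonlite::write_json(unclass(config), p("config.json"), auto_unbox = TRUE,
                       null = "null", pretty = TRUE)
  writeLines(log_lines, p("log.txt"))

  invisible(list(screen = scr, table = table, truth = truth,
                 enrichment = enrichment, log = log_lines,
                 paths = list(out_dir = config$out_dir)))
}
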