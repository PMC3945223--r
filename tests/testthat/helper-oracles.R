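# Independent brute-force oracles used to cross-check the implementation.

# Co-occurrence probabilities by explicit enumeration of every horizontal
# pixel pair with both pixels in the mask.
glcm_oracle <- function(gray, mask, levels, symmetric = TRUE) {
  counts <- matrix(0, levels, levels)
  n_pairs <- 0
  for (r in seq_len(nrow(gray))) {
    for (cc in seq_len(ncol(gray) - 1)) {
      if (mask[r, cc] && mask[r, cc + 1]) {
        n_pairs <- n_pairs + 1
        i <- gray[r, cc] + 1
        j <- gray[r, cc + 1] + 1
        counts[i, j] <- counts[i, j] + 1
        if (symmetric) counts[j, i] <- counts[j, i] + 1
      }
    }
  }
  list(p = counts / sum(counts), n_pairs = n_pairs)
}

# Upper-tail hypergeometric probability by exhaustive enumeration of all
# C(N, n) candidate draws (feasible for N <= 12).
hyper_oracle <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  in_cat <- colSums(draws <= K)  # genes 1..K are the category members
  mean(in_cat >= k)
}

# A small, fast simulation configuration for unit tests.
tiny_config <- function(...) {
  sim_config(n_fovs = 2, cells_per_fov = 4, n_frames = 12, ...)
}

# Feature table with per-FOV linear protein~velocity coupling of known slope,
# for exercising the candidate-calling and robustness rules directly.
make_sloped_table <- function(slopes, n_cells = 6, n_frames = 40, seed = 1,
                              noise_sd = 0.5) {
  set.seed(seed)
  rows <- list()
  for (f in seq_along(slopes)) {
    for (c in seq_len(n_cells)) {
      v <- rnorm(n_frames)
      rows[[length(rows) + 1]] <- tibble::tibble(
        protein_id = "p1", fov_id = sprintf("fov%d", f),
        cell_id = sprintf("f%d_c%d", f, c),
        frame = 0:(n_frames - 1), time = 0:(n_frames - 1),
        x = 0, y = 0,
        level = slopes[f] * v + rnorm(n_frames, sd = noise_sd),
        contrast = rnorm(n_frames), texture = rnorm(n_frames),
        velocity = v, angle_change = rnorm(n_frames)
      )
    }
  }
  dplyr::bind_rows(rows)
}
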