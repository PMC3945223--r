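#' Upper-tail hypergeometric p-value
#'
#' Exact probability of drawing at least `k` category members when sampling
#' `n` genes without replacement from a background of `N` genes of which `K`
#' are in the category: `P(X >= k)`. Tests over-representation only; `k = 0`
#' gives 1.
#'
#' @param N Background size.
#' @param K Background genes in the category.
#' @param n Candidate-list size.
#' @param k Candidates in the category.
#' @return Scalar p-value in `(0, 1]`.
#' @examples
#' hypergeometric_pvalue(10, 5, 4, 4)  # 5/210
#' @export
hypergeometric_pvalue <- function(N, K, n, k) {
  args <- c(N = N, K = K, n = n, k = k)
  if (any(!is.finite(args)) || any(args < 0) || any(args != round(args))) {
    stop("N, K, n, k must be non-negative integers", call. = FALSE)
  }
  if (K > N || n > N || k > min(K, n)) {
    stop("inconsistent counts: need K <= N, n <= N, k <= min(K, n)", call. = FALSE)
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Annotation-category enrichment of a candidate list
#'
#' For every annotation category, counts the background genes (`K`) and
#' candidate genes (`k`) it contains and computes the upper-tail
#' hypergeometric p-value of the candidates' over-representation against the
#' background. Categories absent from the background (`K = 0`) are skipped
#' with a message. P-values are reported raw (the permutation-based FDR of
#' the screen, not a multiple-category correction, controls false
#' discoveries upstream).
#'
#' @param candidates Character vector of candidate gene ids (must be a subset
#'   of `background`).
#' @param background Character vector of all screened gene ids.
#' @param annotations Tibble with columns `gene_id` and `category` (a gene
#'   appears at most once per category; when sources list several
#'   localizations, the first/primary one is assigned upstream).
#' @return Tibble sorted by p-value: `category`, `N`, `K`, `n`, `k`,
#'   `p_value`.
#' @examples
#' ann <- tibble::tibble(gene_id = c("a", "b", "c"), category = "motility_known")
#' enrich_categories(c("a", "b"), letters[1:10], ann)
#' @export
enrich_categories <- function(candidates, background, annotations) {
  background <- unique(background)
  candidates <- unique(candidates)
  outside <- setdiff(candidates, background)
  if (length(outside) > 0) {
    stop("candidate gene(s) not in background: ", paste(outside, collapse = ", "),
         call. = FALSE)
  }
  if (!all(c("gene_id", "category") %in% names(annotations))) {
    stop("annotations needs columns gene_id and category", call. = FALSE)
  }
  ann <- dplyr::distinct(annotations, .data$gene_id, .data$category)
  N <- length(background); n <- length(candidates)
  res <- ann |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(
      K = sum(.data$gene_id %in% background),
      k = sum(.data$gene_id %in% candidates),
      .groups = "drop"
    )
  skipped <- res$category[res$K == 0]
  if (length(skipped) > 0) {
    message("skipping categories absent from background: ",
            paste(skipped, collapse = ", "))
  }
  res |>
    dplyr::filter(.data$K > 0) |>
    dplyr::mutate(N = N, n = n,
                  p_value = purrr::pmap_dbl(list(N, .data$K, n, .data$k),
                                            hypergeometric_pvalue)) |>
    dplyr::select("category", "N", "K", "n", "k", "p_value") |>
    dplyr::arrange(.data$p_value)
}

#' Breakdown of candidates by correlating protein feature
#'
#' Tallies how candidates correlate with motility: by protein level, by
#' contrast, by texture, and by more than one measure. Because a protein can
#' pass comparisons on several features, both an inclusive tally (a protein
#' counts under every feature it passes on) and an exclusive one (proteins
#' passing on >= 2 features count only under `multi_measure`) are emitted.
#'
#' @param calls Candidate calls from [call_candidates()] (or a
#'   `motility_screen`'s `calls`).
#' @return Tibble: `tally` (`"inclusive"` or `"exclusive"`), `class`,
#'   `count`, `fraction` (of candidates).
#' @export
feature_breakdown <- function(calls) {
  cand <- calls[calls$candidate, , drop = FALSE]
  n <- nrow(cand)
  frac <- function(x) if (n > 0) x / n else NA_real_
  multi <- cand$multi_measure
  inclusive <- tibble::tibble(
    tally = "inclusive",
    class = c("level", "contrast", "texture", "multi_measure"),
    count = c(sum(cand$by_level), sum(cand$by_contrast), sum(cand$by_texture),
              sum(multi))
  )
  exclusive <- tibble::tibble(
    tally = "exclusive",
    class = c("level", "contrast", "texture", "multi_measure"),
    count = c(sum(cand$by_level & !multi), sum(cand$by_contrast & !multi),
              sum(cand$by_texture & !multi), sum(multi))
  )
  dplyr::bind_rows(inclusive, exclusive) |>
    dplyr::mutate(n_candidates = n, fraction = frac(.data$count))
}
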