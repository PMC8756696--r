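# Term enrichment of a foreground protein set against a background with
# Fisher's exact test (one-sided, over-representation direction) via the
# hypergeometric distribution, plus Benjamini-Hochberg adjustment.

#' Read an annotation table
#'
#' A TSV with columns `protein_id`, `term_id` and optionally `term_label`.
#'
#' @param path Path to the TSV (with header).
#' @return A tibble with one row per (protein, term).
#' @export
read_annotations <- function(path) {
  ann <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE, show_col_types = FALSE)
  req <- c("protein_id", "term_id")
  if (!all(req %in% names(ann))) {
    stop("annotation table needs columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  ann
}

#' Fisher term enrichment of a foreground set against a background
#'
#' For each term with at least `min_term_size` background members, the
#' one-sided (over-representation) Fisher exact p-value is the upper
#' hypergeometric tail `P(X >= k)` for `k` foreground hits out of `n`
#' foreground proteins, `K` background hits and `N` background proteins.
#' Benjamini-Hochberg q-values are computed across tested terms.
#'
#' @param foreground Character vector of foreground protein ids (must be a
#'   subset of `background`).
#' @param background Character vector of background protein ids.
#' @param annotations Annotation tibble (`protein_id`, `term_id`, optional
#'   `term_label`); annotations outside the background are ignored.
#' @param min_term_size Smallest background term size tested.
#' @param adjust Add Benjamini-Hochberg `q_value` (default TRUE).
#' @return A tibble of class `enrichment_tbl`, sorted by p-value, with
#'   `term_id`, `term_label`, `k`, `K`, `n`, `N`, `odds_ratio`,
#'   `p_value` and (optionally) `q_value`.
#' @export
fisher_enrich <- function(foreground, background, annotations,
                          min_term_size = 2, adjust = TRUE) {
  foreground <- unique(foreground)
  background <- unique(background)
  outside <- setdiff(foreground, background)
  if (length(outside) > 0) {
    stop("foreground ids not in background: ",
         paste(outside, collapse = ", "), call. = FALSE)
  }
  ann <- annotations |>
    dplyr::filter(.data$protein_id %in% background) |>
    dplyr::distinct(.data$protein_id, .data$term_id, .keep_all = TRUE)
  if (!"term_label" %in% names(ann)) ann$term_label <- NA_character_
  n <- length(foreground)
  N <- length(background)
  rows <- ann |>
    dplyr::group_by(.data$term_id) |>
    dplyr::summarise(
      term_label = .data$term_label[1],
      K = dplyr::n(),
      k = sum(.data$protein_id %in% foreground),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$K >= min_term_size) |>
    dplyr::mutate(
      n = n, N = N,
      odds_ratio = (.data$k * (N - n - .data$K + .data$k)) /
        pmax(1e-300, (n - .data$k) * (.data$K - .data$k)),
      p_value = stats::phyper(.data$k - 1, .data$K, N - .data$K, n,
                              lower.tail = FALSE)
    )
  if (adjust) rows$q_value <- stats::p.adjust(rows$p_value, "BH")
  out <- dplyr::arrange(rows, .data$p_value, .data$term_id)
  out <- out[, c("term_id", "term_label", "k", "K", "n", "N",
                 "odds_ratio", "p_value",
                 if (adjust) "q_value")]
  as_result_tbl(out, "enrichment_tbl")
}
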