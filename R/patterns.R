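# Per-tissue abundance patterns of homolog pairs: paralog abundance
# divergence (|log2 copy1/copy2| > 2, p <= 0.05), homeolog abundance bias
# (signed log2 A/B with the same thresholds), cross-tissue overlaps,
# bias-count comparisons and copy-level differential-abundance categories.

# Replicate values (one tissue) for each member of each pair, as list cols.
pair_replicates <- function(pairs, qm, tissue) {
  vals <- qm |>
    dplyr::filter(.data$tissue == !!tissue, !is.na(.data$abundance),
                  .data$abundance > 0) |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(v = list(.data$abundance), .groups = "drop")
  lookup <- stats::setNames(vals$v, vals$protein_id)
  fetch <- function(ids) {
    out <- purrr::map(lookup[ids],
                      function(v) if (is.null(v)) numeric(0) else v)
    names(out) <- NULL
    out
  }
  list(a = fetch(pairs$id_a), b = fetch(pairs$id_b))
}

pair_ratio_test <- function(va, vb, var_equal = FALSE) {
  if (length(va) < 2 || length(vb) < 2) {
    return(c(ratio = NA_real_, p = NA_real_))
  }
  c(ratio = log2(mean(va) / mean(vb)),
    p = log_t_test(log2(va), log2(vb), var_equal = var_equal))
}

#' Classify paralog abundance divergence in one tissue
#'
#' A paralogous pair is abundantly divergent when the absolute value of
#' log2(copy1 mean / copy2 mean) exceeds `threshold` (strictly) and a
#' two-sided t-test between the two copies' log2 replicate values gives
#' `p <= alpha`. Copy order is canonical (lexicographic id) and irrelevant
#' to the call, which uses the absolute ratio. Pairs with fewer than two
#' measured replicates for either copy are untestable.
#'
#' @param pairs Pair tibble (rows with `relation == "paralog"` are used).
#' @param qm A `quant_tbl`.
#' @param tissue Tissue label.
#' @param threshold Log2 ratio threshold (strict).
#' @param alpha Significance level.
#' @param var_equal Pooled-variance t-test instead of Welch.
#' @return A tibble of class `divergence_tbl`: `id_a`, `id_b`, `tissue`,
#'   `abs_log2_ratio`, `p_value`, `divergent` (logical, NA when
#'   untestable), `status`.
#' @export
paralog_divergence <- function(pairs, qm, tissue, threshold = 2,
                               alpha = 0.05, var_equal = FALSE) {
  pp <- dplyr::filter(pairs, .data$relation == "paralog")
  reps <- pair_replicates(pp, qm, tissue)
  res <- purrr::map2(reps$a, reps$b, pair_ratio_test, var_equal = var_equal)
  ratio <- abs(purrr::map_dbl(res, "ratio"))
  p <- purrr::map_dbl(res, "p")
  divergent <- ifelse(is.na(ratio) | is.na(p), NA,
                      ratio > threshold & p <= alpha)
  out <- tibble::tibble(
    id_a = pp$id_a, id_b = pp$id_b, tissue = tissue,
    abs_log2_ratio = ratio, p_value = p, divergent = divergent,
    status = dplyr::case_when(
      is.na(divergent) ~ "untestable",
      divergent ~ "divergent",
      TRUE ~ "not_divergent"
    )
  )
  as_result_tbl(out, "divergence_tbl")
}

#' Classify homeolog abundance bias in one tissue
#'
#' The ratio is oriented sub-genome A over sub-genome B using the pairs'
#' `sub_genome_a` / `sub_genome_b` columns. A pair is `A_biased` when
#' log2(A/B) exceeds `threshold` (strictly) with `p <= alpha`, `B_biased`
#' when it is below `-threshold` with `p <= alpha`, otherwise `unbiased`;
#' pairs with insufficient replicates are `untestable`.
#'
#' @inheritParams paralog_divergence
#' @return A tibble of class `bias_tbl`: `id_a`, `id_b` (A copy first),
#'   `tissue`, `log2_ratio_AB`, `p_value`, `class`.
#' @export
homeolog_bias <- function(pairs, qm, tissue, threshold = 2, alpha = 0.05,
                          var_equal = FALSE) {
  hp <- dplyr::filter(pairs, .data$relation == "homeolog")
  if (!all(c("sub_genome_a", "sub_genome_b") %in% names(hp))) {
    stop("pairs need `sub_genome_a` and `sub_genome_b` columns",
         call. = FALSE)
  }
  bad <- !((hp$sub_genome_a == "A" & hp$sub_genome_b == "B") |
             (hp$sub_genome_a == "B" & hp$sub_genome_b == "A"))
  if (any(bad)) {
    stop("homeolog pair lacking one sub-genome A and one sub-genome B ",
         "member: ", hp$id_a[bad][1], " / ", hp$id_b[bad][1], call. = FALSE)
  }
  # orient so the first member is the A copy
  flip <- hp$sub_genome_a == "B"
  id_A <- ifelse(flip, hp$id_b, hp$id_a)
  id_B <- ifelse(flip, hp$id_a, hp$id_b)
  oriented <- tibble::tibble(id_a = id_A, id_b = id_B)
  reps <- pair_replicates(oriented, qm, tissue)
  res <- purrr::map2(reps$a, reps$b, pair_ratio_test, var_equal = var_equal)
  ratio <- purrr::map_dbl(res, "ratio")
  p <- purrr::map_dbl(res, "p")
  out <- tibble::tibble(
    id_a = id_A, id_b = id_B, tissue = tissue,
    log2_ratio_AB = ratio, p_value = p,
    class = dplyr::case_when(
      is.na(ratio) | is.na(p) ~ "untestable",
      ratio > threshold & p <= alpha ~ "A_biased",
      ratio < -threshold & p <= alpha ~ "B_biased",
      TRUE ~ "unbiased"
    )
  )
  as_result_tbl(out, "bias_tbl")
}

is_positive_call <- function(res) {
  if ("divergent" %in% names(res)) {
    return(!is.na(res$divergent) & res$divergent)
  }
  if ("class" %in% names(res)) {
    return(res$class %in% c("A_biased", "B_biased"))
  }
  stop("not a divergence or bias result table", call. = FALSE)
}

is_untestable_call <- function(res) {
  if ("divergent" %in% names(res)) return(is.na(res$divergent))
  res$class == "untestable"
}

#' Cross-tissue overlap of divergent or biased pairs
#'
#' Both result tables must cover the same pair universe. Pairs untestable
#' in either tissue are excluded from the denominators. When `qm` is
#' supplied, pairs positive in both tissues are additionally compared
#' between tissues by a paired two-sided Wilcoxon signed-rank test on the
#' pair-level mean abundance (mean of the two members' tissue means).
#'
#' @param results_t1,results_t2 `divergence_tbl` or `bias_tbl` objects for
#'   the two tissues.
#' @param qm Optional `quant_tbl` for the paired abundance comparison.
#' @return A list of class `overlap_summary`: `counts` (n_testable, both,
#'   only per tissue, neither), `tissues`, and optionally
#'   `paired_test` (V statistic and p).
#' @export
cross_tissue_overlap <- function(results_t1, results_t2, qm = NULL) {
  key1 <- paste(results_t1$id_a, results_t1$id_b)
  key2 <- paste(results_t2$id_a, results_t2$id_b)
  if (!setequal(key1, key2) || length(key1) != length(key2)) {
    stop("result tables cover different pair universes", call. = FALSE)
  }
  results_t2 <- results_t2[match(key1, key2), ]
  testable <- !is_untestable_call(results_t1) &
    !is_untestable_call(results_t2)
  p1 <- is_positive_call(results_t1) & testable
  p2 <- is_positive_call(results_t2) & testable
  tissues <- c(results_t1$tissue[1], results_t2$tissue[1])
  counts <- tibble::tibble(
    n_pairs = length(key1),
    n_testable = sum(testable),
    n_positive_t1 = sum(p1),
    n_positive_t2 = sum(p2),
    n_both = sum(p1 & p2),
    n_only_t1 = sum(p1 & !p2),
    n_only_t2 = sum(!p1 & p2),
    n_neither = sum(testable & !p1 & !p2)
  )
  out <- list(counts = counts, tissues = tissues)
  if (!is.null(qm) && counts$n_both >= 2) {
    common <- results_t1[p1 & p2, c("id_a", "id_b")]
    m1 <- mean_abundance(qm, tissues[1])
    m2 <- mean_abundance(qm, tissues[2])
    pm <- function(mm) {
      (mm$mean_abundance[match(common$id_a, mm$protein_id)] +
         mm$mean_abundance[match(common$id_b, mm$protein_id)]) / 2
    }
    x <- pm(m1)
    y <- pm(m2)
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) >= 2 && any(x[ok] != y[ok])) {
      wt <- stats::wilcox.test(x[ok], y[ok], paired = TRUE, exact = FALSE)
      out$paired_test <- list(statistic = unname(wt$statistic),
                              p_value = wt$p.value, n = sum(ok))
    }
  }
  structure(out, class = "overlap_summary")
}

#' Compare biased homeolog counts between sub-genomes and tissues
#'
#' Per tissue, counts of A-biased and B-biased pairs with an exact
#' two-sided binomial test of the A:B split against 0.5; with exactly two
#' tissues, a 2x2 Fisher exact test of sub-genome split across tissues.
#'
#' @param bias_results A `bias_tbl` covering one or more tissues (bind
#'   per-tissue results with their `tissue` column), or a list of
#'   `bias_tbl` objects.
#' @return A list of class `bias_count_test`: `counts` (tibble with
#'   `tissue`, `n_A_biased`, `n_B_biased`, `n_biased`, `binom_p`),
#'   `cross_tissue_p` (NA unless exactly two tissues).
#' @export
compare_bias_counts <- function(bias_results) {
  if (is.list(bias_results) && !is.data.frame(bias_results)) {
    bias_results <- dplyr::bind_rows(bias_results)
  }
  counts <- bias_results |>
    dplyr::group_by(.data$tissue) |>
    dplyr::summarise(
      n_A_biased = sum(.data$class == "A_biased"),
      n_B_biased = sum(.data$class == "B_biased"),
      .groups = "drop"
    ) |>
    dplyr::mutate(n_biased = .data$n_A_biased + .data$n_B_biased)
  counts$binom_p <- purrr::map2_dbl(
    counts$n_A_biased, counts$n_biased,
    function(k, n) if (n == 0) NA_real_
                   else stats::binom.test(k, n, p = 0.5)$p.value
  )
  cross_p <- NA_real_
  if (nrow(counts) == 2 && all(counts$n_biased > 0)) {
    m <- matrix(c(counts$n_A_biased, counts$n_B_biased), nrow = 2)
    cross_p <- stats::fisher.test(m)$p.value
  }
  structure(list(counts = counts, cross_tissue_p = cross_p),
            class = "bias_count_test")
}

#' Categorise pairs by how many copies are differentially abundant
#'
#' Using a tissue-contrast differential-abundance table, each pair is
#' `double_copy` when both members are differentially abundant (status up
#' or down), `single_copy` when exactly one is, and `neither` otherwise
#' (including pairs with an untestable or uncovered member). Among
#' informative pairs (at least one differentially abundant member) the
#' single-copy fraction is the "asymmetric abundance" fraction. Where both
#' categories are populated, the per-pair differential-abundance gap
#' |log2fc(copy1) - log2fc(copy2)| is compared between single- and
#' double-copy pairs by a two-sided Mann-Whitney test.
#'
#' @param pairs Pair tibble with `id_a`, `id_b`, `relation`.
#' @param dap_results A `dap_tbl` from [differential_abundance()].
#' @return A list of class `copy_categories`: `categories` (per-pair
#'   tibble with `category` and `delta_log2fc`), `summary` (per relation:
#'   counts, asymmetric count/total and percent), `gap_test` (per
#'   relation rank-test p comparing single vs double gaps, NA when a group
#'   is empty).
#' @export
copy_level_categories <- function(pairs, dap_results) {
  da_status <- stats::setNames(dap_results$status, dap_results$protein_id)
  da_lfc <- stats::setNames(dap_results$log2fc, dap_results$protein_id)
  is_da <- function(id) {
    s <- da_status[id]
    !is.na(s) & s %in% c("up", "down")
  }
  da_a <- is_da(pairs$id_a)
  da_b <- is_da(pairs$id_b)
  categories <- tibble::tibble(
    id_a = pairs$id_a, id_b = pairs$id_b, relation = pairs$relation,
    da_a = da_a, da_b = da_b,
    category = dplyr::case_when(
      da_a & da_b ~ "double_copy",
      da_a | da_b ~ "single_copy",
      TRUE ~ "neither"
    ),
    delta_log2fc = abs(unname(da_lfc[pairs$id_a]) -
                         unname(da_lfc[pairs$id_b]))
  )
  summary <- categories |>
    dplyr::group_by(.data$relation) |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      n_double = sum(.data$category == "double_copy"),
      n_single = sum(.data$category == "single_copy"),
      n_neither = sum(.data$category == "neither"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n_informative = .data$n_double + .data$n_single,
      asymmetric_fraction = ifelse(.data$n_informative > 0,
                                   .data$n_single / .data$n_informative,
                                   NA_real_),
      asymmetric_percent = 100 * .data$asymmetric_fraction
    )
  gap_test <- categories |>
    dplyr::filter(.data$category != "neither",
                  !is.na(.data$delta_log2fc)) |>
    dplyr::group_by(.data$relation) |>
    dplyr::summarise(
      p_value = {
        s <- .data$delta_log2fc[.data$category == "single_copy"]
        d <- .data$delta_log2fc[.data$category == "double_copy"]
        if (length(s) > 0 && length(d) > 0) mann_whitney(s, d)$p_value
        else NA_real_
      },
      .groups = "drop"
    )
  structure(list(categories = categories, summary = summary,
                 gap_test = gap_test),
            class = "copy_categories")
}
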