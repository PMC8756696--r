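# Quantification matrices and differential abundance between two tissues.
# The headline rule is deliberately simple: a protein is differentially
# abundant when |log2(mean first tissue / mean second tissue)| exceeds 2
# (strictly) and a two-sided t-test on log2 replicate values gives p <= 0.05.

#' Read a wide quantification table into long (tidy) form
#'
#' The file is a TSV whose first column is `protein_id` and whose remaining
#' columns are samples. Sample-to-(tissue, replicate) mapping comes from
#' `design`; when `design` is NULL, column names of the form
#' `<tissue>_<replicate>` are parsed directly. Empty cells and "NA" are
#' missing; negative values are rejected; zeros are treated as missing
#' (abundances are strictly positive when measured).
#'
#' @param path Path to the TSV.
#' @param design Optional tibble with columns `sample`, `tissue`,
#'   `replicate`.
#' @return A long tibble of class `quant_tbl` with columns `protein_id`,
#'   `sample`, `tissue`, `replicate`, `abundance`.
#' @export
read_quant <- function(path, design = NULL) {
  wide <- readr::read_tsv(path, col_types = readr::cols(
    protein_id = readr::col_character(), .default = readr::col_double()
  ), na = c("", "NA"), progress = FALSE, show_col_types = FALSE)
  if (anyDuplicated(wide$protein_id)) {
    dup <- wide$protein_id[duplicated(wide$protein_id)][1]
    stop("duplicate protein id '", dup, "' in ", path, call. = FALSE)
  }
  samples <- setdiff(names(wide), "protein_id")
  if (is.null(design)) {
    m <- stringr::str_match(samples, "^(.*)_([0-9]+)$")
    if (anyNA(m[, 1])) {
      stop("cannot parse sample name(s) ",
           paste(samples[is.na(m[, 1])], collapse = ", "),
           " as <tissue>_<replicate>; supply `design`", call. = FALSE)
    }
    design <- tibble::tibble(sample = samples, tissue = m[, 2],
                             replicate = as.integer(m[, 3]))
  } else {
    unknown <- setdiff(samples, design$sample)
    if (length(unknown) > 0) {
      stop("sample(s) absent from design: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  long <- tidyr::pivot_longer(wide, -"protein_id", names_to = "sample",
                              values_to = "abundance") |>
    dplyr::inner_join(design, by = "sample")
  neg <- which(!is.na(long$abundance) & long$abundance < 0)
  if (length(neg) > 0) {
    stop("negative abundance for protein '", long$protein_id[neg[1]],
         "' in sample '", long$sample[neg[1]], "'", call. = FALSE)
  }
  long$abundance[!is.na(long$abundance) & long$abundance == 0] <- NA_real_
  out <- long[, c("protein_id", "sample", "tissue", "replicate", "abundance")]
  as_result_tbl(out, "quant_tbl")
}

#' Write a long quantification table in wide TSV form
#'
#' @param qm A `quant_tbl`.
#' @param path Output path; missing values are written as empty cells.
#' @return `path`, invisibly.
#' @export
write_quant <- function(qm, path) {
  wide <- tidyr::pivot_wider(
    qm[, c("protein_id", "sample", "abundance")],
    names_from = "sample", values_from = "abundance"
  )
  readr::write_tsv(wide, path, na = "")
  invisible(path)
}

#' Summarise missingness per tissue replicate and compare tissues
#'
#' Computes the fraction of missing measurements in each replicate of each
#' tissue and compares the two tissues' per-replicate fractions with a
#' two-sided Mann-Whitney test (exact rank permutation at these group
#' sizes). With no variation in the fractions the test is degenerate and p
#' is reported as 1.
#'
#' @param qm A `quant_tbl` with exactly two tissues.
#' @return A list of class `missingness_summary`: `rates` (tibble with
#'   `tissue`, `replicate`, `n_proteins`, `n_missing`, `miss_rate`),
#'   `u_statistic`, `p_value`, `tissues`.
#' @export
summarize_missingness <- function(qm) {
  rates <- qm |>
    dplyr::group_by(.data$tissue, .data$replicate) |>
    dplyr::summarise(n_proteins = dplyr::n(),
                     n_missing = sum(is.na(.data$abundance)),
                     miss_rate = mean(is.na(.data$abundance)),
                     .groups = "drop")
  tissues <- unique(rates$tissue)
  if (length(tissues) != 2) {
    stop("missingness comparison needs exactly two tissues", call. = FALSE)
  }
  if (any(table(rates$tissue) < 2)) {
    stop("need >= 2 replicates per tissue", call. = FALSE)
  }
  x <- rates$miss_rate[rates$tissue == tissues[1]]
  y <- rates$miss_rate[rates$tissue == tissues[2]]
  mw <- mann_whitney(x, y)
  structure(
    list(rates = rates, u_statistic = mw$u, p_value = mw$p_value,
         tissues = tissues),
    class = "missingness_summary"
  )
}

#' Per-protein mean abundance in one tissue
#'
#' Arithmetic mean over non-missing replicate values; NA when nothing was
#' measured.
#'
#' @param qm A `quant_tbl`.
#' @param tissue Tissue label.
#' @return Tibble with `protein_id`, `mean_abundance`, `n_used`.
#' @export
mean_abundance <- function(qm, tissue) {
  if (!tissue %in% qm$tissue) {
    stop("unknown tissue '", tissue, "'", call. = FALSE)
  }
  qm |>
    dplyr::filter(.data$tissue == !!tissue) |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(
      mean_abundance = if (all(is.na(.data$abundance))) NA_real_
                       else mean(.data$abundance, na.rm = TRUE),
      n_used = sum(!is.na(.data$abundance)),
      .groups = "drop"
    )
}

#' Call differentially abundant proteins between two tissues
#'
#' Per protein, the fold change is `log2(mean(tissue_a) / mean(tissue_b))`
#' on raw replicate means, and significance comes from a two-sided
#' two-sample t-test on log2-transformed replicate values (Welch by
#' default). A protein is `up` when `log2fc > lfc_threshold` (strictly) and
#' `p <= alpha`, `down` when `log2fc < -lfc_threshold` and `p <= alpha`,
#' and `untestable` when either tissue has fewer than two measured
#' replicates or an undefined mean.
#'
#' @param qm A `quant_tbl`.
#' @param tissue_a,tissue_b Tissue labels; `log2fc` is a over b.
#' @param lfc_threshold Log2 fold-change threshold (strict inequality).
#' @param alpha Significance level (p <= alpha).
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @param adjust Add a Benjamini-Hochberg `q_value` column (the status call
#'   still uses the raw p-value rule).
#' @return A tibble of class `dap_tbl`: `protein_id`, `log2fc`, `p_value`,
#'   `n_a`, `n_b`, `status` (`up`, `down`, `not_significant`,
#'   `untestable`), optionally `q_value`. Tissue orientation is stored in
#'   attributes `tissue_a` / `tissue_b`.
#' @export
differential_abundance <- function(qm, tissue_a = "leaf", tissue_b = "root",
                                   lfc_threshold = 2, alpha = 0.05,
                                   var_equal = FALSE, adjust = FALSE) {
  for (t in c(tissue_a, tissue_b)) {
    if (!t %in% qm$tissue) stop("unknown tissue '", t, "'", call. = FALSE)
  }
  if (lfc_threshold <= 0) stop("`lfc_threshold` must be > 0", call. = FALSE)
  wide <- qm |>
    dplyr::filter(.data$tissue %in% c(tissue_a, tissue_b)) |>
    dplyr::group_by(.data$protein_id)
  res <- wide |>
    dplyr::summarise(
      r = list(dap_one(.data$abundance[.data$tissue == tissue_a],
                       .data$abundance[.data$tissue == tissue_b],
                       var_equal)),
      .groups = "drop"
    ) |>
    tidyr::unnest_wider("r")
  res$status <- dap_status(res$log2fc, res$p_value, lfc_threshold, alpha)
  if (adjust) {
    res$q_value <- NA_real_
    testable <- !is.na(res$p_value)
    res$q_value[testable] <- stats::p.adjust(res$p_value[testable], "BH")
  }
  out <- as_result_tbl(res, "dap_tbl")
  attr(out, "tissue_a") <- tissue_a
  attr(out, "tissue_b") <- tissue_b
  attr(out, "lfc_threshold") <- lfc_threshold
  attr(out, "alpha") <- alpha
  out
}

dap_one <- function(a, b, var_equal) {
  a <- a[!is.na(a) & is.finite(log2(a))]
  b <- b[!is.na(b) & is.finite(log2(b))]
  if (length(a) < 2 || length(b) < 2) {
    return(list(log2fc = NA_real_, p_value = NA_real_,
                n_a = length(a), n_b = length(b)))
  }
  list(
    log2fc = log2(mean(a) / mean(b)),
    p_value = log_t_test(log2(a), log2(b), var_equal = var_equal),
    n_a = length(a), n_b = length(b)
  )
}

dap_status <- function(log2fc, p, lfc_threshold, alpha) {
  dplyr::case_when(
    is.na(log2fc) | is.na(p) ~ "untestable",
    log2fc > lfc_threshold & p <= alpha ~ "up",
    log2fc < -lfc_threshold & p <= alpha ~ "down",
    TRUE ~ "not_significant"
  )
}
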