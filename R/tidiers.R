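# broom-style tidiers and glance summaries for the package's result
# objects, so they drop into tidyverse workflows.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a missingness summary
#'
#' @param x A `missingness_summary`.
#' @param ... Unused.
#' @return The per-replicate rate tibble.
#' @export
tidy.missingness_summary <- function(x, ...) x$rates

#' @rdname tidy.missingness_summary
#' @export
glance.missingness_summary <- function(x, ...) {
  tibble::tibble(u_statistic = x$u_statistic, p_value = x$p_value)
}

#' Tidy bias-count comparisons
#'
#' @param x A `bias_count_test`.
#' @param ... Unused.
#' @return Per-tissue counts with binomial p-values.
#' @export
tidy.bias_count_test <- function(x, ...) x$counts

#' @rdname tidy.bias_count_test
#' @export
glance.bias_count_test <- function(x, ...) {
  tibble::tibble(cross_tissue_p = x$cross_tissue_p)
}

#' Tidy copy-level categories
#'
#' @param x A `copy_categories`.
#' @param ... Unused.
#' @return The per-pair category tibble.
#' @export
tidy.copy_categories <- function(x, ...) x$categories

#' @rdname tidy.copy_categories
#' @export
glance.copy_categories <- function(x, ...) x$summary

#' Tidy a cross-tissue overlap summary
#'
#' @param x An `overlap_summary`.
#' @param ... Unused.
#' @return The overlap count tibble.
#' @export
tidy.overlap_summary <- function(x, ...) x$counts

#' Summarise a differential-abundance table
#'
#' @param x A `dap_tbl`.
#' @param ... Unused.
#' @return One-row tibble of status counts and thresholds.
#' @export
glance.dap_tbl <- function(x, ...) {
  tibble::tibble(
    n_proteins = nrow(x),
    n_up = sum(x$status == "up"),
    n_down = sum(x$status == "down"),
    n_untestable = sum(x$status == "untestable"),
    lfc_threshold = attr(x, "lfc_threshold"),
    alpha = attr(x, "alpha")
  )
}

#' Summarise a homeolog-bias table
#'
#' @param x A `bias_tbl`.
#' @param ... Unused.
#' @return One-row tibble of class counts.
#' @export
glance.bias_tbl <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x),
    n_A_biased = sum(x$class == "A_biased"),
    n_B_biased = sum(x$class == "B_biased"),
    n_unbiased = sum(x$class == "unbiased"),
    n_untestable = sum(x$class == "untestable")
  )
}

#' Summarise a Ka/Ks table
#'
#' @param x A `kaks_tbl`.
#' @param ... Unused.
#' @return Per-relation means and selection-class counts (kept pairs).
#' @export
glance.kaks_tbl <- function(x, ...) {
  grp <- if ("relation" %in% names(x)) "relation" else character(0)
  x |>
    dplyr::filter(!.data$excluded) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      n_kept = dplyr::n(),
      mean_ka = mean(.data$ka),
      mean_ks = mean(.data$ks),
      mean_ratio = mean(.data$ratio),
      n_purifying = sum(.data$selection == "purifying"),
      n_neutral = sum(.data$selection == "neutral"),
      n_positive = sum(.data$selection == "positive"),
      .groups = "drop"
    )
}

#' Summarise a pipeline run
#'
#' @param x A `homeoprot_run`.
#' @param ... Unused.
#' @return One-row tibble of headline counts.
#' @export
glance.homeoprot_run <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    n_proteins = s$n_proteins,
    n_quantified = s$n_proteins_quantified,
    n_da = s$n_da,
    n_paralog_pairs = s$n_paralog_pairs,
    n_homeolog_pairs = s$n_homeolog_pairs,
    kaks_mean_paralog = s$kaks_mean$paralog,
    kaks_mean_homeolog = s$kaks_mean$homeolog
  )
}
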