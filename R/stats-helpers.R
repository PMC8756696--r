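# Small statistical helpers used across modules.

#' Two-sample Welch t-test on log2 abundances with degenerate handling
#'
#' Wraps [stats::t.test()]; when both groups have zero variance the test is
#' undefined and the p-value is set to 1 if the group means are equal and to
#' 0 otherwise (an infinite separation of two constant groups).
#'
#' @param x,y Numeric vectors (log2 scale), length >= 2 each.
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return p-value in `[0, 1]`.
#' @keywords internal
log_t_test <- function(x, y, var_equal = FALSE) {
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  stats::t.test(x, y, var.equal = var_equal)$p.value
}

#' Exact two-sided Mann-Whitney test by rank permutation
#'
#' For tiny groups (such as per-replicate missingness fractions, 3 vs 3) an
#' exact permutation of midranks is both correct under ties and fully
#' enumerable. Beyond `max_enumerate` combinations the normal approximation
#' of [stats::wilcox.test()] is used instead.
#'
#' @param x,y Numeric vectors.
#' @param max_enumerate Largest number of group assignments to enumerate.
#' @return A list with `u` (Mann-Whitney U for the `x` group) and `p_value`
#'   (two-sided, by distance of U from its null mean).
#' @keywords internal
mann_whitney <- function(x, y, max_enumerate = 20000) {
  n1 <- length(x)
  n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  n_comb <- choose(n1 + n2, n1)
  if (n_comb <= max_enumerate) {
    idx <- utils::combn(n1 + n2, n1)
    u_all <- apply(idx, 2, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
  } else {
    p <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  }
  list(u = u_obs, p_value = p)
}

# Jukes-Cantor correction of a proportion of differing sites.
jukes_cantor <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) return(NA_real_)
  -3 / 4 * log(1 - 4 * p / 3)
}

# Tag a tibble with a result subclass so autoplot()/glance() can dispatch.
as_result_tbl <- function(x, subclass) {
  class(x) <- unique(c(subclass, class(x)))
  x
}
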