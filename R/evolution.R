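# Molecular-evolution analysis of homolog pairs: protein alignments are
# back-translated to codon alignments, Ka and Ks are estimated by
# Nei-Gojobori (1986) counting — mutational-opportunity site fractions,
# pathway-averaged difference counts, Jukes-Cantor correction — pairs with
# negligible divergence (Ka/Ks < 0.001 or Ka = 0) or saturated synonymous
# divergence are excluded, and kept pairs are classified as purifying
# (Ka/Ks < 1), neutral (= 1) or positive (> 1) selection.

#' Globally align two protein sequences (gapped strings)
#'
#' Convenience wrapper around the package's global aligner returning the
#' two gapped rows of the alignment, ready for [backtranslate()].
#'
#' @inheritParams align_pairwise
#' @return A list with gapped strings `a` and `b`.
#' @export
align_protein_pair <- function(query, subject, gap_open = 10,
                               gap_extend = 1, matrix = "BLOSUM62") {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(subject),
    type = "global", substitutionMatrix = matrix,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  list(a = as.character(Biostrings::alignedPattern(pa)),
       b = as.character(Biostrings::alignedSubject(pa)))
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Each aligned residue column is replaced by the corresponding codon of
#' the matching CDS and each residue gap by a codon-sized gap (`---`), so
#' the codon alignment mirrors the protein alignment's gap structure
#' exactly. Each CDS must translate residue-for-residue to its degapped
#' protein row under the standard code; a single trailing stop codon on a
#' CDS is tolerated and trimmed.
#'
#' @param aln_a,aln_b Gapped protein rows of equal length.
#' @param cds_a,cds_b The corresponding coding sequences.
#' @param ids Optional length-2 identifier vector used in error messages.
#' @return A list of class `codon_alignment` with gapped codon strings `a`
#'   and `b`.
#' @export
backtranslate <- function(aln_a, aln_b, cds_a, cds_b,
                          ids = c("seq_a", "seq_b")) {
  if (nchar(aln_a) != nchar(aln_b)) {
    stop("aligned rows differ in length", call. = FALSE)
  }
  row <- function(aln, cds, id) {
    codons <- split_codons(toupper(cds))
    if (length(codons) > 0 && is_stop_codon(codons[length(codons)])) {
      codons <- codons[-length(codons)]
    }
    residues <- strsplit(aln, "")[[1]]
    ungapped <- residues[residues != "-"]
    if (length(ungapped) != length(codons)) {
      stop("CDS of '", id, "' has ", length(codons),
           " codons but the protein row has ", length(ungapped),
           " residues", call. = FALSE)
    }
    expected <- translate_codon(codons)
    mismatch <- which(expected != ungapped)
    if (length(mismatch) > 0) {
      k <- mismatch[1]
      stop("translation mismatch for '", id, "' at residue ", k,
           ": expected '", ungapped[k], "', CDS encodes '", expected[k],
           "'", call. = FALSE)
    }
    out <- character(length(residues))
    out[residues == "-"] <- "---"
    out[residues != "-"] <- codons
    paste(out, collapse = "")
  }
  structure(
    list(a = row(aln_a, cds_a, ids[1]), b = row(aln_b, cds_b, ids[2])),
    class = "codon_alignment"
  )
}

#' Estimate Ka and Ks by Nei-Gojobori counting
#'
#' Synonymous site fractions come from each codon's single-base mutational
#' opportunity (changes to stop codons excluded, so every codon carries
#' exactly 3 sites) averaged over the two rows; observed differences are
#' averaged over all minimal substitution pathways between differing
#' codons, excluding pathways through stop codons; the difference
#' proportions are corrected with the Jukes-Cantor formula. Codon columns
#' containing gaps or ambiguous bases are skipped. A proportion >= 3/4 is
#' beyond the correction's range and the corresponding rate is marked
#' saturated. Pairs with `Ka/Ks < 0.001` or `Ka = 0` are flagged as
#' low-divergence exclusions; kept pairs are classified as purifying,
#' neutral or positive selection by Ka/Ks < 1, = 1 (to within 1e-9) or
#' > 1.
#'
#' @param ca A `codon_alignment` from [backtranslate()], or a list with
#'   gapped codon strings `a` and `b`.
#' @return A one-row tibble: `ka`, `ks`, `ratio`, `n_sites_n`,
#'   `n_sites_s`, `n_diff_n`, `n_diff_s`, `n_codons_compared`,
#'   `n_blocked_paths`, `excluded`, `excluded_reason`
#'   (`low_divergence`, `saturated` or `none`), `selection`.
#' @export
kaks_counting <- function(ca) {
  cod_a <- split_codons(toupper(ca$a))
  cod_b <- split_codons(toupper(ca$b))
  if (length(cod_a) != length(cod_b)) {
    stop("codon alignment rows differ in length", call. = FALSE)
  }
  clean <- grepl("^[ACGT]{3}$", cod_a) & grepl("^[ACGT]{3}$", cod_b) &
    !is_stop_codon_safe(cod_a) & !is_stop_codon_safe(cod_b)
  cod_a <- cod_a[clean]
  cod_b <- cod_b[clean]
  n_comp <- length(cod_a)
  if (n_comp == 0) {
    return(kaks_row(ka = NA_real_, ks = NA_real_, ratio = NA_real_,
                    n_sites = 0, s_sites = 0, nd = 0, sd = 0, n_comp = 0,
                    n_blocked = 0, excluded = TRUE,
                    reason = "no_comparable_codons",
                    selection = "not_classified"))
  }
  s_sites <- 0
  sd <- 0
  nd <- 0
  blocked <- 0
  for (i in seq_len(n_comp)) {
    s_sites <- s_sites + (ng86_codon_sites(cod_a[i])[["S"]] +
                            ng86_codon_sites(cod_b[i])[["S"]]) / 2
    d <- ng86_codon_diffs(cod_a[i], cod_b[i])
    sd <- sd + d[["Sd"]]
    nd <- nd + d[["Nd"]]
    blocked <- blocked + d[["blocked"]]
  }
  n_sites <- 3 * n_comp - s_sites
  ps <- if (s_sites > 0) sd / s_sites else NA_real_
  pn <- if (n_sites > 0) nd / n_sites else NA_real_
  ks <- jukes_cantor(ps)
  ka <- jukes_cantor(pn)
  saturated <- (!is.na(ps) && ps >= 0.75) || (!is.na(pn) && pn >= 0.75)
  ratio <- if (!is.na(ka) && !is.na(ks) && ks > 0) ka / ks else NA_real_
  low_div <- (!is.na(ratio) && ratio < 0.001) ||
    (!is.na(ka) && ka == 0)
  reason <- if (saturated) "saturated"
            else if (low_div) "low_divergence"
            else if (is.na(ratio)) "low_divergence"  # Ks = 0 with Ka > 0
            else "none"
  excluded <- reason != "none"
  selection <- if (excluded) "not_classified" else classify_selection(ratio)
  kaks_row(ka = ka, ks = ks, ratio = ratio, n_sites = n_sites,
           s_sites = s_sites, nd = nd, sd = sd, n_comp = n_comp,
           n_blocked = blocked, excluded = excluded, reason = reason,
           selection = selection)
}

is_stop_codon_safe <- function(codon) {
  out <- rep(FALSE, length(codon))
  ok <- grepl("^[ACGT]{3}$", codon)
  out[ok] <- is_stop_codon(codon[ok])
  out
}

classify_selection <- function(ratio, tol = 1e-9) {
  if (abs(ratio - 1) <= tol) "neutral"
  else if (ratio > 1) "positive"
  else "purifying"
}

kaks_row <- function(ka, ks, ratio, n_sites, s_sites, nd, sd, n_comp,
                     n_blocked, excluded, reason, selection) {
  tibble::tibble(
    ka = as.numeric(ka), ks = as.numeric(ks), ratio = as.numeric(ratio),
    n_sites_n = n_sites, n_sites_s = s_sites,
    n_diff_n = nd, n_diff_s = sd,
    n_codons_compared = n_comp, n_blocked_paths = n_blocked,
    excluded = excluded, excluded_reason = reason, selection = selection
  )
}

#' Estimate Ka/Ks for a table of homolog pairs
#'
#' For each pair the two proteins are globally aligned, back-translated
#' with their CDS and passed to [kaks_counting()].
#'
#' @param pairs Pair tibble with `id_a`, `id_b` (and optionally
#'   `relation`, carried through).
#' @param sequences Sequence tibble with columns `id`, `protein`, `cds`
#'   (as from [simulate_families()]), or a list with named character
#'   vectors `proteins` and `cds`.
#' @inheritParams align_pairwise
#' @return A tibble of class `kaks_tbl`: pair columns plus the
#'   [kaks_counting()] fields.
#' @export
kaks_pairs <- function(pairs, sequences, gap_open = 10, gap_extend = 1,
                       matrix = "BLOSUM62") {
  if (is.data.frame(sequences)) {
    prot <- stats::setNames(sequences$protein, sequences$id)
    cds <- stats::setNames(sequences$cds, sequences$id)
  } else {
    prot <- sequences$proteins
    cds <- sequences$cds
  }
  ids <- unique(c(pairs$id_a, pairs$id_b))
  missing <- ids[!(ids %in% names(prot) & ids %in% names(cds))]
  if (length(missing) > 0) {
    stop("no protein/CDS for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rows <- purrr::map2(pairs$id_a, pairs$id_b, function(a, b) {
    aln <- align_protein_pair(prot[[a]], prot[[b]], gap_open, gap_extend,
                              matrix)
    kaks_counting(backtranslate(aln$a, aln$b, cds[[a]], cds[[b]],
                                ids = c(a, b)))
  })
  out <- dplyr::bind_cols(
    pairs[, intersect(c("id_a", "id_b", "relation"), names(pairs))],
    dplyr::bind_rows(rows)
  )
  as_result_tbl(out, "kaks_tbl")
}

#' Partition Ka/Ks results into kept and excluded pairs
#'
#' @param results A `kaks_tbl`.
#' @return A list with `kept`, `excluded`, and `counts` (a tibble of
#'   exclusion reasons).
#' @export
apply_exclusions <- function(results) {
  kept <- dplyr::filter(results, !.data$excluded)
  excluded <- dplyr::filter(results, .data$excluded)
  counts <- results |>
    dplyr::count(.data$excluded_reason, name = "n")
  list(kept = kept, excluded = excluded, counts = counts)
}

#' Correlate Ka/Ks with an abundance measure
#'
#' Spearman rank correlation (by default) between pair-level Ka/Ks ratios
#' and a pair-level measure (abundance or differential abundance), per
#' group. Groups with fewer than three complete observations are flagged
#' rather than given a fabricated estimate.
#'
#' @param kaks A `kaks_tbl` (kept results; excluded rows are dropped).
#' @param values Tibble with `id_a`, `id_b`, a `value` column and optional
#'   grouping columns (e.g. `tissue`, `measure`).
#' @param method Correlation method passed to [stats::cor.test()].
#' @return A tibble with the grouping columns plus `n`, `rho`, `p_value`
#'   and `note` (`"ok"` or `"insufficient_data"`).
#' @export
correlate_rate_abundance <- function(kaks, values, method = "spearman") {
  kept <- kaks[!kaks$excluded & !is.na(kaks$ratio),
               intersect(c("id_a", "id_b", "relation", "ratio"),
                         names(kaks))]
  merged <- dplyr::inner_join(kept, values, by = c("id_a", "id_b"))
  group_cols <- setdiff(names(values), c("id_a", "id_b", "value"))
  if ("relation" %in% names(merged)) {
    group_cols <- union("relation", group_cols)
  }
  merged |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::summarise(
      res = list({
        ok <- !is.na(.data$ratio) & !is.na(.data$value)
        if (sum(ok) < 3) {
          list(n = sum(ok), rho = NA_real_, p_value = NA_real_,
               note = "insufficient_data")
        } else {
          ct <- suppressWarnings(stats::cor.test(
            .data$ratio[ok], .data$value[ok], method = method
          ))
          list(n = sum(ok), rho = unname(ct$estimate),
               p_value = ct$p.value, note = "ok")
        }
      }),
      .groups = "drop"
    ) |>
    tidyr::unnest_wider("res")
}
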