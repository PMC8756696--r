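# Homolog pairing from pairwise alignment statistics. Hits pass three
# filters — alignment length > 80% of each sequence, identity > 80%, and
# E-value <= 1e-10 — and pairs are then formed by reciprocal best hit
# within each relation class (within-sub-genome paralogs; cross-sub-genome
# A x B homeologs).

outfmt6_cols <- c("query_id", "subject_id", "percent_identity",
                  "alignment_length", "mismatches", "gap_opens",
                  "qstart", "qend", "sstart", "send", "e_value", "score")

#' Read a 12-column tabular alignment file
#'
#' The conventional BLAST `-outfmt 6` layout: query, subject, percent
#' identity, alignment length, mismatches, gap opens, query/subject
#' start/end, E-value, bit score. The tabular format omits sequence
#' lengths, so they are supplied separately. Self-hits are dropped.
#'
#' @param path Path to the tab-separated hit table (no header).
#' @param lengths Sequence lengths: a named integer vector, or a tibble
#'   with columns `id` and `length`.
#' @return A tibble of hits with `query_length` and `subject_length` added.
#' @export
read_alignment_table <- function(path, lengths) {
  lengths <- as_length_lookup(lengths)
  # parsing problems are re-raised as errors below, so readr's own
  # warning is redundant
  hits <- suppressWarnings(readr::read_tsv(
    path, col_names = outfmt6_cols,
    col_types = readr::cols(
      query_id = readr::col_character(),
      subject_id = readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE, show_col_types = FALSE
  ))
  probs <- readr::problems(hits)
  if (nrow(probs) > 0) {
    stop("malformed alignment table '", path, "': ",
         paste0("line ", probs$row, " (", probs$expected, ", got '",
                probs$actual, "')", collapse = "; "),
         call. = FALSE)
  }
  hits <- dplyr::filter(hits, .data$query_id != .data$subject_id)
  ids <- unique(c(hits$query_id, hits$subject_id))
  missing <- ids[!ids %in% names(lengths)]
  if (length(missing) > 0) {
    stop("no sequence length supplied for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  hits$query_length <- unname(lengths[hits$query_id])
  hits$subject_length <- unname(lengths[hits$subject_id])
  bad <- which(hits$percent_identity < 0 | hits$percent_identity > 100)
  if (length(bad) > 0) {
    stop("percent identity outside [0, 100] at row ", bad[1], call. = FALSE)
  }
  hits
}

as_length_lookup <- function(lengths) {
  if (is.data.frame(lengths)) {
    lengths <- stats::setNames(lengths$length, lengths$id)
  }
  if (is.null(names(lengths))) {
    stop("`lengths` must be named by sequence id", call. = FALSE)
  }
  lengths
}

#' Write hits in 12-column tabular format
#'
#' @param hits A hit tibble (as from [read_alignment_table()] or
#'   [align_pairwise()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_table <- function(hits, path) {
  for (col in outfmt6_cols) {
    if (!col %in% names(hits)) hits[[col]] <- NA
  }
  readr::write_tsv(hits[, outfmt6_cols], path, col_names = FALSE, na = "")
  invisible(path)
}

#' Global pairwise protein alignment as a hit record
#'
#' Needleman-Wunsch global alignment with a BLOSUM62 substitution matrix
#' and affine gaps (a gap of length L costs `gap_open + L * gap_extend`).
#' Percent identity is identical aligned residue pairs over aligned
#' columns; alignment length is the number of aligned columns. No E-value
#' is defined for a single global alignment.
#'
#' @param query,subject Protein sequences (character scalars).
#' @param query_id,subject_id Identifiers recorded in the hit.
#' @param gap_open,gap_extend Positive gap penalties.
#' @param matrix Substitution matrix name (a matrix shipped with
#'   Biostrings) or a numeric matrix.
#' @return A one-row hit tibble.
#' @export
align_pairwise <- function(query, subject, query_id = "query",
                           subject_id = "subject", gap_open = 10,
                           gap_extend = 1, matrix = "BLOSUM62") {
  if (nchar(query) == 0 || nchar(subject) == 0) {
    stop("cannot align an empty sequence", call. = FALSE)
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(subject),
    type = "global", substitutionMatrix = matrix,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  aln_q <- as.character(Biostrings::alignedPattern(pa))
  aln_s <- as.character(Biostrings::alignedSubject(pa))
  qc <- strsplit(aln_q, "")[[1]]
  sc <- strsplit(aln_s, "")[[1]]
  cols <- !(qc == "-" & sc == "-")
  n_cols <- sum(cols)
  n_ident <- sum(qc[cols] == sc[cols] & qc[cols] != "-")
  tibble::tibble(
    query_id = query_id, subject_id = subject_id,
    percent_identity = 100 * n_ident / n_cols,
    alignment_length = n_cols,
    mismatches = sum(qc[cols] != sc[cols] & qc[cols] != "-" & sc[cols] != "-"),
    gap_opens = count_gap_opens(qc) + count_gap_opens(sc),
    qstart = 1L, qend = nchar(query), sstart = 1L, send = nchar(subject),
    e_value = NA_real_, score = Biostrings::score(pa),
    query_length = nchar(query), subject_length = nchar(subject)
  )
}

count_gap_opens <- function(chars) {
  gap <- chars == "-"
  sum(gap & !c(FALSE, gap[-length(gap)]))
}

#' All-vs-all global alignment of a protein set
#'
#' Computes alignment scores for every unordered pair and, optionally, full
#' hit records only for each sequence's `top_n` scoring partners (a
#' practical shortcut at larger set sizes: reciprocal best hits and
#' 80%-identity survivors always rank near the top by score).
#'
#' @param sequences A tibble with columns `id` and `protein` (as from
#'   [simulate_families()]'s `sequences`), or a named character vector.
#' @param top_n Full alignments per query; `NULL` aligns all pairs.
#' @inheritParams align_pairwise
#' @return A hit tibble, one row per aligned ordered-canonical pair.
#' @export
align_all <- function(sequences, top_n = NULL, gap_open = 10,
                      gap_extend = 1, matrix = "BLOSUM62") {
  if (is.data.frame(sequences)) {
    seqs <- stats::setNames(sequences$protein, sequences$id)
  } else {
    seqs <- sequences
  }
  n <- length(seqs)
  if (n < 2) return(align_pairwise(seqs[1], seqs[1])[0, ])
  ids <- names(seqs)
  aaset <- Biostrings::AAStringSet(seqs)
  scores <- matrix(-Inf, n, n, dimnames = list(ids, ids))
  for (j in seq_len(n)) {
    idx <- seq_len(n) < j
    if (!any(idx)) next
    sc <- Biostrings::pairwiseAlignment(
      aaset[idx], aaset[[j]], type = "global", substitutionMatrix = matrix,
      gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE
    )
    scores[idx, j] <- sc
    scores[j, idx] <- sc
  }
  wanted <- matrix(FALSE, n, n)
  if (is.null(top_n) || top_n >= n - 1) {
    wanted[upper.tri(wanted)] <- TRUE
  } else {
    for (i in seq_len(n)) {
      part <- order(scores[i, ], decreasing = TRUE)
      part <- setdiff(part, i)[seq_len(top_n)]
      wanted[i, part] <- TRUE
    }
    wanted <- (wanted | t(wanted)) & upper.tri(wanted)
  }
  pairs <- which(wanted, arr.ind = TRUE)
  out <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]
    j <- pairs[k, 2]
    out[[k]] <- align_pairwise(seqs[[i]], seqs[[j]], ids[i], ids[j],
                               gap_open, gap_extend, matrix)
  }
  dplyr::bind_rows(out)
}

#' Filter alignment hits by coverage, identity and E-value
#'
#' A hit survives iff its alignment length exceeds 80% of the query length
#' AND 80% of the subject length, its percent identity exceeds 80, and its
#' E-value (when present) is at most 1e-10. Coverage and identity are
#' strict inequalities.
#'
#' @param hits Hit tibble carrying `query_length` and `subject_length`.
#' @param min_coverage Coverage fraction each sequence must exceed.
#' @param min_identity Percent identity the hit must exceed.
#' @param max_evalue Largest acceptable E-value; hits without an E-value
#'   (built-in global alignments) pass this criterion.
#' @return The surviving hits.
#' @export
filter_hits <- function(hits, min_coverage = 0.80, min_identity = 80,
                        max_evalue = 1e-10) {
  if (nrow(hits) == 0) return(hits)
  dplyr::filter(
    hits,
    .data$alignment_length / .data$query_length > min_coverage,
    .data$alignment_length / .data$subject_length > min_coverage,
    .data$percent_identity > min_identity,
    is.na(.data$e_value) | .data$e_value <= max_evalue
  )
}

#' Sub-genome assignment rules
#'
#' An ordered table of (regular expression, label); the first matching
#' pattern wins and unmatched chromosomes are `"unassigned"`.
#' `default_subgenome_rules()` maps `chrA*`/`chrB*`;
#' `arachis_subgenome_rules()` maps the *Arachis hypogaea* convention
#' `Arahy.01`–`Arahy.10` to sub-genome A and `Arahy.11`–`Arahy.20` to B.
#'
#' @return A tibble with columns `pattern` and `label`.
#' @export
default_subgenome_rules <- function() {
  tibble::tibble(pattern = c("^chrA", "^chrB"), label = c("A", "B"))
}

#' @rdname default_subgenome_rules
#' @export
arachis_subgenome_rules <- function() {
  tibble::tibble(
    pattern = c("^Arahy\\.(0[1-9]|10)$", "^Arahy\\.(1[1-9]|20)$"),
    label = c("A", "B")
  )
}

#' Assign chromosomes to sub-genomes
#'
#' @param chromosome Character vector of chromosome names.
#' @param rules A rules tibble (see [default_subgenome_rules()]).
#' @return Character vector of labels (`"unassigned"` when no rule matches).
#' @export
assign_subgenome <- function(chromosome, rules = default_subgenome_rules()) {
  out <- rep("unassigned", length(chromosome))
  for (i in rev(seq_len(nrow(rules)))) {
    hit <- stringr::str_detect(chromosome, rules$pattern[i])
    out[hit] <- rules$label[i]  # earlier rules overwrite later ones
  }
  out
}

#' Pair homologs by reciprocal best hit within relation classes
#'
#' Hits are symmetrised (both directions considered), each protein's best
#' partner is taken by score within the paralog class (same assigned
#' sub-genome) and the homeolog class (sub-genome A vs B), and a pair is
#' emitted only when each member is the other's best hit in that class.
#' Ties in score break lexicographically by partner id. Proteins with an
#' unassigned sub-genome take part in neither class. With
#' `mode = "all"` every passing hit becomes a pair instead.
#'
#' @param hits Filtered hit tibble.
#' @param sub_genomes Sub-genome assignments: a named character vector or a
#'   tibble with columns `id` and `sub_genome`.
#' @param mode `"rbh"` (default) or `"all"`.
#' @return A tibble of pairs: `id_a`, `id_b` (lexicographic order),
#'   `relation`, `sub_genome_a`, `sub_genome_b`, plus the supporting hit's
#'   identity, coverages, E-value and score.
#' @export
pair_homologs <- function(hits, sub_genomes, mode = c("rbh", "all")) {
  mode <- match.arg(mode)
  if (is.data.frame(sub_genomes)) {
    sub_genomes <- stats::setNames(sub_genomes$sub_genome, sub_genomes$id)
  }
  empty <- tibble::tibble(
    id_a = character(), id_b = character(), relation = character(),
    sub_genome_a = character(), sub_genome_b = character(),
    percent_identity = numeric(), coverage_a = numeric(),
    coverage_b = numeric(), e_value = numeric(), score = numeric()
  )
  if (nrow(hits) == 0) return(empty)

  flipped <- hits
  flipped[, c("query_id", "subject_id", "query_length", "subject_length",
              "qstart", "qend", "sstart", "send")] <-
    hits[, c("subject_id", "query_id", "subject_length", "query_length",
             "sstart", "send", "qstart", "qend")]
  sym <- dplyr::bind_rows(hits, flipped) |>
    dplyr::group_by(.data$query_id, .data$subject_id) |>
    dplyr::slice_max(.data$score, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()

  ids <- unique(c(sym$query_id, sym$subject_id))
  missing <- ids[!ids %in% names(sub_genomes)]
  if (length(missing) > 0) {
    stop("no sub-genome assignment for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sym$sg_q <- unname(sub_genomes[sym$query_id])
  sym$sg_s <- unname(sub_genomes[sym$subject_id])
  sym <- dplyr::filter(sym, .data$sg_q != "unassigned",
                       .data$sg_s != "unassigned")
  sym$relation <- ifelse(sym$sg_q == sym$sg_s, "paralog", "homeolog")

  if (mode == "all") {
    keep <- dplyr::filter(sym, .data$query_id < .data$subject_id)
  } else {
    best <- sym |>
      dplyr::arrange(.data$query_id, .data$relation,
                     dplyr::desc(.data$score), .data$subject_id) |>
      dplyr::distinct(.data$query_id, .data$relation, .keep_all = TRUE)
    fwd <- dplyr::filter(best, .data$query_id < .data$subject_id)
    rev_key <- paste(best$subject_id, best$query_id, best$relation)
    keep <- fwd[paste(fwd$query_id, fwd$subject_id, fwd$relation) %in%
                  rev_key, ]
  }
  if (nrow(keep) == 0) return(empty)
  tibble::tibble(
    id_a = keep$query_id, id_b = keep$subject_id, relation = keep$relation,
    sub_genome_a = keep$sg_q, sub_genome_b = keep$sg_s,
    percent_identity = keep$percent_identity,
    coverage_a = keep$alignment_length / keep$query_length,
    coverage_b = keep$alignment_length / keep$subject_length,
    e_value = keep$e_value, score = keep$score
  ) |>
    dplyr::arrange(.data$id_a, .data$id_b)
}
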