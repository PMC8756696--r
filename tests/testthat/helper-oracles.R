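# Independent oracles used across the suite. These deliberately re-derive
# results by brute force (exhaustive DP, recursive enumeration, tail sums)
# rather than calling the implementation paths they check.

# ---- affine-gap global alignment score by Gotoh three-state DP ----------
# Convention matches the package aligner: a gap of length L costs
# gap_open + L * gap_extend.
oracle_align_score <- function(a, b, submat, gap_open = 10,
                               gap_extend = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  neg <- -1e9
  M <- matrix(neg, n + 1, m + 1)
  Ix <- matrix(neg, n + 1, m + 1)  # gap in b (consuming a)
  Iy <- matrix(neg, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) {
    Ix[i + 1, 1] <- -(gap_open + i * gap_extend)
  }
  for (j in seq_len(m)) {
    Iy[1, j + 1] <- -(gap_open + j * gap_extend)
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- submat[av[i], bv[j]]
      M[i + 1, j + 1] <- max(M[i, j], Ix[i, j], Iy[i, j]) + s
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_extend,
                              Ix[i, j + 1] - gap_extend)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_extend,
                              Iy[i + 1, j] - gap_extend)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# ---- genetic-code helpers for the NG86 oracle ---------------------------
oracle_code <- {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}
oracle_translate <- function(codon) unname(oracle_code[codon])
oracle_is_stop <- function(codon) oracle_code[codon] == "*"

# Synonymous site count of one codon: per position, synonymous fraction of
# the non-stop single-base changes.
oracle_syn_sites <- function(codon) {
  bases <- c("A", "C", "G", "T")
  aa <- oracle_translate(codon)
  total <- 0
  for (pos in 1:3) {
    alts <- character(0)
    for (bb in setdiff(bases, substr(codon, pos, pos))) {
      alt <- codon
      substr(alt, pos, pos) <- bb
      alts <- c(alts, alt)
    }
    ok <- !oracle_is_stop(alts)
    if (any(ok)) {
      total <- total + sum(oracle_translate(alts[ok]) == aa) / sum(ok)
    }
  }
  total
}

# Pathway-averaged difference counts by depth-first enumeration of every
# substitution order, skipping pathways through stop codons.
oracle_path_counts <- function(c1, c2) {
  if (c1 == c2) return(c(0, 0))
  paths <- list()
  walk <- function(cur, remaining, sd, nd, blocked) {
    if (length(remaining) == 0) {
      paths[[length(paths) + 1]] <<- list(sd = sd, nd = nd,
                                          blocked = blocked)
      return(invisible())
    }
    for (p in remaining) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (oracle_is_stop(nxt) && nxt != c2) {
        walk(nxt, setdiff(remaining, p), sd, nd + 1, TRUE)
      } else if (oracle_translate(nxt) == oracle_translate(cur)) {
        walk(nxt, setdiff(remaining, p), sd + 1, nd, blocked)
      } else {
        walk(nxt, setdiff(remaining, p), sd, nd + 1, blocked)
      }
    }
  }
  diffpos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  walk(c1, diffpos, 0, 0, FALSE)
  open <- Filter(function(p) !p$blocked, paths)
  use <- if (length(open) > 0) open else paths
  c(mean(vapply(use, `[[`, numeric(1), "sd")),
    mean(vapply(use, `[[`, numeric(1), "nd")))
}

# ---- tiny-sample exact Mann-Whitney by direct enumeration ---------------
oracle_mann_whitney_p <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  mu <- n1 * length(y) / 2
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(length(r), n1)
  u_all <- apply(idx, 2, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
}

# ---- fixture builders ---------------------------------------------------
# A long quant tibble from a named list of per-protein replicate values,
# e.g. list(P1 = list(leaf = c(..), root = c(..))).
make_quant <- function(values) {
  rows <- list()
  for (pid in names(values)) {
    for (tt in names(values[[pid]])) {
      v <- values[[pid]][[tt]]
      rows[[length(rows) + 1]] <- tibble::tibble(
        protein_id = pid, tissue = tt, replicate = seq_along(v),
        sample = paste0(tt, "_", seq_along(v)), abundance = v
      )
    }
  }
  out <- dplyr::bind_rows(rows)[, c("protein_id", "sample", "tissue",
                                    "replicate", "abundance")]
  structure(out, class = c("quant_tbl", class(tibble::tibble())))
}

# A minimal hit row with every field the filters and pairing need.
make_hit <- function(q, s, pident = 95, len = 100, qlen = 100, slen = 100,
                     evalue = 1e-50, score = 200) {
  tibble::tibble(
    query_id = q, subject_id = s, percent_identity = pident,
    alignment_length = len, mismatches = 0, gap_opens = 0,
    qstart = 1, qend = len, sstart = 1, send = len,
    e_value = evalue, score = score, query_length = qlen,
    subject_length = slen
  )
}
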