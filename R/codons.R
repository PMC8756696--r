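# Codon-level machinery shared by the sequence simulator and the Ka/Ks
# estimator. The genetic code is taken from Biostrings::GENETIC_CODE
# (standard code, table 1).

.codon_cache <- new.env(parent = emptyenv())

genetic_code_map <- function() {
  if (is.null(.codon_cache$code)) {
    gc <- Biostrings::GENETIC_CODE
    .codon_cache$code <- stats::setNames(as.character(gc), names(gc))
  }
  .codon_cache$code
}

sense_codons <- function() {
  code <- genetic_code_map()
  names(code)[code != "*"]
}

is_stop_codon <- function(codon) {
  unname(genetic_code_map()[codon] == "*")
}

translate_codon <- function(codon) {
  unname(genetic_code_map()[codon])
}

#' Split a CDS string into codon triplets
#'
#' @param cds A character scalar whose length is divisible by 3.
#' @return Character vector of codons.
#' @keywords internal
split_codons <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) {
    stop("CDS length (", n, ") is not divisible by 3", call. = FALSE)
  }
  if (n == 0L) return(character(0))
  substring(cds, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

#' Translate a CDS string under the standard genetic code
#'
#' Internal stops are an error; a single trailing stop codon is dropped.
#'
#' @param cds Character scalar, length divisible by 3, ACGT alphabet.
#' @return Character scalar of amino-acid residues.
#' @keywords internal
translate_cds <- function(cds) {
  codons <- split_codons(toupper(cds))
  if (length(codons) == 0L) return("")
  aa <- genetic_code_map()[codons]
  if (anyNA(aa)) {
    bad <- which(is.na(aa))[1L]
    stop("unrecognised codon '", codons[bad], "' at codon position ", bad,
         call. = FALSE)
  }
  aa <- unname(aa)
  n <- length(aa)
  if (aa[n] == "*") aa <- aa[-n]
  if (any(aa == "*")) {
    stop("internal stop codon at codon position ", which(aa == "*")[1L],
         call. = FALSE)
  }
  paste(aa, collapse = "")
}

# The three single-base neighbours of a codon at one position.
codon_neighbours <- function(codon, pos) {
  bases <- c("A", "C", "G", "T")
  ref <- substr(codon, pos, pos)
  out <- character(0)
  for (b in setdiff(bases, ref)) {
    alt <- codon
    substr(alt, pos, pos) <- b
    out <- c(out, alt)
  }
  out
}

# Nei-Gojobori mutational-opportunity site fractions for one codon.
# At each position the synonymous fraction is (synonymous changes) /
# (changes not creating a stop); changes to stop codons are excluded from
# both numerator and denominator so that S + N = 3 per codon.
ng86_codon_sites <- function(codon) {
  key <- paste0("sites_", codon)
  hit <- .codon_cache[[key]]
  if (!is.null(hit)) return(hit)
  aa <- translate_codon(codon)
  s <- 0
  for (pos in 1:3) {
    nb <- codon_neighbours(codon, pos)
    keep <- !is_stop_codon(nb)
    if (!any(keep)) next  # cannot happen with the standard code; guard anyway
    s <- s + sum(translate_codon(nb[keep]) == aa) / sum(keep)
  }
  out <- c(S = s, N = 3 - s)
  assign(key, out, envir = .codon_cache)
  out
}

# Pathway-averaged synonymous / nonsynonymous difference counts between two
# sense codons. All orderings of the differing positions are enumerated;
# pathways passing through a stop codon are excluded from the average. If
# every pathway is blocked (possible only for 2- and 3-fold differences),
# the pair is scored over all pathways with stop-involving steps counted as
# nonsynonymous, and flagged.
ng86_codon_diffs <- function(codon1, codon2) {
  if (codon1 == codon2) return(c(Sd = 0, Nd = 0, blocked = 0))
  key <- paste0("diff_", codon1, "_", codon2)
  hit <- .codon_cache[[key]]
  if (!is.null(hit)) return(hit)

  pos <- which(strsplit(codon1, "")[[1]] != strsplit(codon2, "")[[1]])
  orderings <- permute_all(pos)
  path_sd <- numeric(0)
  path_nd <- numeric(0)
  all_sd <- numeric(0)
  all_nd <- numeric(0)
  for (ord in orderings) {
    cur <- codon1
    sd <- 0
    nd <- 0
    blocked <- FALSE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(codon2, p, p)
      if (is_stop_codon(nxt) && nxt != codon2) {
        blocked <- TRUE
        nd <- nd + 1  # only used in the all-pathway fallback
      } else if (translate_codon(nxt) == translate_codon(cur)) {
        sd <- sd + 1
      } else {
        nd <- nd + 1
      }
      cur <- nxt
    }
    all_sd <- c(all_sd, sd)
    all_nd <- c(all_nd, nd)
    if (!blocked) {
      path_sd <- c(path_sd, sd)
      path_nd <- c(path_nd, nd)
    }
  }
  out <- if (length(path_sd) > 0) {
    c(Sd = mean(path_sd), Nd = mean(path_nd), blocked = 0)
  } else {
    c(Sd = mean(all_sd), Nd = mean(all_nd), blocked = 1)
  }
  assign(key, out, envir = .codon_cache)
  out
}

# All permutations of a small vector (<= 3 elements here).
permute_all <- function(x) {
  n <- length(x)
  if (n <= 1L) return(list(x))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in permute_all(x[-i])) {
      out[[length(out) + 1L]] <- c(x[i], rest)
    }
  }
  out
}
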