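# Synthetic allotetraploid proteome generator. Gene families carry one copy
# per sub-genome (a homeolog pair, A x B) and a configurable fraction carry
# an extra within-sub-genome duplicate (a paralog pair). CDS pairs are
# diverged by a single-nucleotide proposal process whose nonsynonymous
# acceptance probability is governed by a true dN/dS (omega), so the Ka/Ks
# estimator can be validated against known rates. Quantification emulates a
# two-tissue, replicated TMT-style experiment on the log2 scale.

#' Simulation configuration for a synthetic allotetraploid proteome
#'
#' @param n_families Number of gene families. Each contributes one sub-genome
#'   A copy and one sub-genome B copy (a homeolog pair).
#' @param paralog_fraction Fraction of families carrying an additional
#'   within-sub-genome duplicate (a paralog pair), in `[0, 1]`.
#' @param n_codons Codons per CDS.
#' @param omega_range Length-2 numeric, the range (min, max) from which each
#'   family's true dN/dS is drawn uniformly. Values must be > 0.
#' @param ks_target Expected synonymous substitutions per synonymous site
#'   between the two members of each generated pair.
#' @param tissues Character vector of tissue labels; the first tissue is the
#'   numerator of every tissue fold change.
#' @param n_replicates Biological replicates per tissue (>= 2).
#' @param bias_effect_log2 True log2 abundance offset given to the favoured
#'   copy of a biased pair.
#' @param biased_fraction Fraction of pairs (homeolog and paralog alike)
#'   receiving a true bias, in `[0, 1]`.
#' @param de_fraction Fraction of proteins given a true tissue effect.
#' @param de_effect_log2 Magnitude of the true tissue log2 fold change
#'   (sign drawn at random per protein).
#' @param base_log2_mean,base_log2_sd Mean and s.d. of the per-family
#'   baseline abundance on the log2 scale (shared by a family's members,
#'   so homolog copies are equally abundant unless biased).
#' @param noise_sigma Standard deviation of replicate noise on the log2
#'   scale (>= 0).
#' @param missing_rate Probability that any one measurement is missing
#'   (missing completely at random), in `[0, 1]`.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_families = 150,
                              paralog_fraction = 0.3,
                              n_codons = 300,
                              omega_range = c(0.05, 0.6),
                              ks_target = 0.3,
                              tissues = c("leaf", "root"),
                              n_replicates = 3,
                              bias_effect_log2 = 3,
                              biased_fraction = 0.3,
                              de_fraction = 0.075,
                              de_effect_log2 = 3,
                              base_log2_mean = 15,
                              base_log2_sd = 2,
                              noise_sigma = 0.2,
                              missing_rate = 0.025,
                              seed = 1L) {
  cfg <- list(
    n_families = n_families, paralog_fraction = paralog_fraction,
    n_codons = n_codons, omega_range = omega_range, ks_target = ks_target,
    tissues = tissues, n_replicates = n_replicates,
    bias_effect_log2 = bias_effect_log2, biased_fraction = biased_fraction,
    de_fraction = de_fraction, de_effect_log2 = de_effect_log2,
    base_log2_mean = base_log2_mean, base_log2_sd = base_log2_sd,
    noise_sigma = noise_sigma, missing_rate = missing_rate,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  fail <- function(field, why) {
    stop("invalid simulation config: `", field, "` ", why, call. = FALSE)
  }
  if (!is.numeric(cfg$n_families) || cfg$n_families < 1) {
    fail("n_families", "must be a positive integer")
  }
  for (f in c("paralog_fraction", "biased_fraction", "de_fraction",
              "missing_rate")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v > 1) fail(f, "must lie in [0, 1]")
  }
  if (!is.numeric(cfg$n_codons) || cfg$n_codons < 1) {
    fail("n_codons", "must be a positive integer")
  }
  if (length(cfg$omega_range) != 2 || any(cfg$omega_range <= 0)) {
    fail("omega_range", "must be two values > 0 (omega must be > 0)")
  }
  if (diff(cfg$omega_range) < 0) fail("omega_range", "must be (min, max)")
  if (!is.numeric(cfg$ks_target) || cfg$ks_target < 0) {
    fail("ks_target", "must be >= 0")
  }
  if (length(cfg$tissues) < 2) fail("tissues", "needs at least two labels")
  if (cfg$n_replicates < 2) fail("n_replicates", "must be >= 2")
  if (cfg$noise_sigma < 0) fail("noise_sigma", "must be >= 0")
  invisible(cfg)
}

#' Draw a random stop-free CDS
#'
#' Codons are drawn uniformly from the 61 sense codons of the standard code.
#'
#' @param n_codons Number of codons.
#' @return Character scalar CDS.
#' @export
random_cds <- function(n_codons) {
  paste(sample(sense_codons(), n_codons, replace = TRUE), collapse = "")
}

# Apply `n_syn_events` accepted synonymous substitutions to one lineage,
# with nonsynonymous substitutions arising alongside at a rate set by omega.
# Proposals are single-nucleotide, uniform over sites and target bases;
# proposals creating a stop codon are rejected. A synonymous proposal is
# accepted with probability min(1, 1/omega) and a nonsynonymous one with
# probability min(1, omega), so the accepted nonsynonymous:synonymous ratio
# is omega times the mutational-opportunity ratio.
mutate_lineage <- function(codons, n_syn_events, omega) {
  n_sites <- 3L * length(codons)
  acc_syn <- 0L
  acc_non <- 0L
  p_syn <- min(1, 1 / omega)
  p_non <- min(1, omega)
  guard <- 0L
  max_prop <- 2000L * (n_syn_events + 10L)
  while (acc_syn < n_syn_events) {
    guard <- guard + 1L
    if (guard > max_prop) {
      stop("substitution proposal limit exceeded; omega or ks_target ",
           "may be extreme", call. = FALSE)
    }
    site <- sample.int(n_sites, 1L)
    ci <- (site - 1L) %/% 3L + 1L
    pos <- (site - 1L) %% 3L + 1L
    old <- codons[ci]
    alt <- codon_neighbours(old, pos)
    new <- alt[sample.int(length(alt), 1L)]
    if (is_stop_codon(new)) next
    if (translate_codon(new) == translate_codon(old)) {
      if (stats::runif(1) <= p_syn) {
        codons[ci] <- new
        acc_syn <- acc_syn + 1L
      }
    } else {
      if (stats::runif(1) <= p_non) {
        codons[ci] <- new
        acc_non <- acc_non + 1L
      }
    }
  }
  list(codons = codons, n_syn = acc_syn, n_nonsyn = acc_non)
}

#' Evolve a codon-sequence pair from a common ancestor at a known dN/dS
#'
#' Substitutions are introduced independently on each lineage; the number of
#' synonymous events per lineage is Poisson with mean `ks_target / 2` times
#' the ancestor's synonymous site count, so the expected pairwise synonymous
#' divergence is `ks_target`. Realised event counts are returned so that
#' estimator recovery can be checked against the generator's own bookkeeping.
#'
#' @param ancestral_cds Stop-free CDS whose length is divisible by 3.
#' @param omega True dN/dS (> 0) governing nonsynonymous acceptance.
#' @param ks_target Expected pairwise synonymous divergence (>= 0).
#' @param seed Optional integer; when supplied the result is a pure function
#'   of the arguments.
#' @return A list with `cds_1`, `cds_2`, and `counts`, a tibble of realised
#'   synonymous / nonsynonymous event counts per lineage.
#' @export
evolve_pair <- function(ancestral_cds, omega, ks_target, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (omega <= 0) stop("`omega` must be > 0", call. = FALSE)
  if (ks_target < 0) stop("`ks_target` must be >= 0", call. = FALSE)
  codons <- split_codons(toupper(ancestral_cds))
  if (any(is_stop_codon(codons))) {
    stop("ancestral CDS contains a stop codon", call. = FALSE)
  }
  s_sites <- sum(vapply(codons, function(cd) ng86_codon_sites(cd)[["S"]],
                        numeric(1)))
  n_events <- stats::rpois(2, lambda = ks_target / 2 * s_sites)
  l1 <- mutate_lineage(codons, n_events[1], omega)
  l2 <- mutate_lineage(codons, n_events[2], omega)
  list(
    cds_1 = paste(l1$codons, collapse = ""),
    cds_2 = paste(l2$codons, collapse = ""),
    counts = tibble::tibble(
      lineage = c(1L, 2L),
      n_syn = c(l1$n_syn, l2$n_syn),
      n_nonsyn = c(l1$n_nonsyn, l2$n_nonsyn)
    )
  )
}

# One-sided divergence used for within-sub-genome duplicates: the parent
# copy is left untouched and the duplicate accumulates the full ks_target,
# which keeps the parent strictly closer to its homeolog partner than the
# duplicate is.
mutate_duplicate <- function(cds, omega, ks_target) {
  codons <- split_codons(cds)
  s_sites <- sum(vapply(codons, function(cd) ng86_codon_sites(cd)[["S"]],
                        numeric(1)))
  n <- stats::rpois(1, lambda = ks_target * s_sites)
  paste(mutate_lineage(codons, n, omega)$codons, collapse = "")
}

#' Simulate gene families of an allotetraploid proteome
#'
#' Every family yields one sub-genome A copy and one sub-genome B copy
#' (its homeolog pair); a `paralog_fraction` subset additionally yields a
#' duplicate of the A copy (its paralog pair). Abundance ground truth —
#' per-protein baselines, tissue effects and per-pair bias offsets — is
#' drawn here so that [simulate_quant()] is a deterministic function of the
#' truth plus noise.
#'
#' Bias offsets are placed on the B copy of a homeolog pair and on the
#' duplicate copy of a paralog pair (with the sign set by the favoured
#' side), so a protein shared between the two pair types never carries a
#' confounding offset.
#'
#' @param config A [simulation_config()].
#' @return A list of class `sim_proteome` with `sequences` (tibble: id,
#'   family, chromosome, sub_genome, cds, protein) and `truth` (list with
#'   `pairs` and `proteins` tibbles).
#' @export
simulate_families <- function(config = simulation_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  n_par <- round(config$n_families * config$paralog_fraction)
  has_paralog <- rep(FALSE, config$n_families)
  if (n_par > 0) has_paralog[sample.int(config$n_families, n_par)] <- TRUE

  seqs <- vector("list", config$n_families)
  pair_rows <- vector("list", config$n_families)
  fam_omega <- stats::runif(config$n_families, config$omega_range[1],
                            config$omega_range[2])
  for (i in seq_len(config$n_families)) {
    fam <- sprintf("Fam%04d", i)
    chr_i <- sprintf("%02d", (i - 1L) %% 10L + 1L)
    anc <- random_cds(config$n_codons)
    hp <- evolve_pair(anc, fam_omega[i], config$ks_target)
    ids <- c(paste0(fam, ".A1"), paste0(fam, ".B1"))
    cds <- c(hp$cds_1, hp$cds_2)
    chrom <- c(paste0("chrA", chr_i), paste0("chrB", chr_i))
    sg <- c("A", "B")
    rows <- list(tibble::tibble(
      id_a = ids[1], id_b = ids[2], relation = "homeolog",
      family = fam, true_omega = fam_omega[i]
    ))
    if (has_paralog[i]) {
      dup <- mutate_duplicate(hp$cds_1, fam_omega[i], config$ks_target)
      ids <- c(ids, paste0(fam, ".A2"))
      cds <- c(cds, dup)
      chrom <- c(chrom, paste0("chrA", chr_i))
      sg <- c(sg, "A")
      rows[[2]] <- tibble::tibble(
        id_a = paste0(fam, ".A1"), id_b = paste0(fam, ".A2"),
        relation = "paralog", family = fam, true_omega = fam_omega[i]
      )
    }
    seqs[[i]] <- tibble::tibble(
      id = ids, family = fam, chromosome = chrom, sub_genome = sg, cds = cds,
      protein = vapply(cds, translate_cds, character(1), USE.NAMES = FALSE)
    )
    pair_rows[[i]] <- dplyr::bind_rows(rows)
  }
  sequences <- dplyr::bind_rows(seqs)
  pairs <- dplyr::bind_rows(pair_rows)

  # Abundance ground truth. The offset carrier is id_b in both pair types
  # (the B homeolog; the A2 duplicate).
  n_pairs <- nrow(pairs)
  biased <- stats::runif(n_pairs) < config$biased_fraction
  favour_first <- stats::runif(n_pairs) < 0.5
  pairs$bias_log2 <- ifelse(biased, config$bias_effect_log2, 0)
  pairs$bias_direction <- dplyr::case_when(
    !biased ~ "none",
    pairs$relation == "homeolog" & favour_first ~ "A",
    pairs$relation == "homeolog" ~ "B",
    favour_first ~ "copy1",
    TRUE ~ "copy2"
  )

  # Baselines are drawn per family and shared by its members: homeolog and
  # paralog copies of one family have equal abundance unless an explicit
  # bias offset or tissue effect separates them.
  fam_base <- stats::setNames(
    stats::rnorm(config$n_families, config$base_log2_mean,
                 config$base_log2_sd),
    unique(sequences$family)
  )
  prot <- tibble::tibble(
    protein_id = sequences$id,
    base_log2 = unname(fam_base[sequences$family]),
    true_log2fc = 0,
    bias_offset_log2 = 0
  )
  de <- stats::runif(nrow(prot)) < config$de_fraction
  sign <- ifelse(stats::runif(nrow(prot)) < 0.5, 1, -1)
  prot$true_log2fc[de] <- (config$de_effect_log2 * sign)[de]

  # Materialise pair biases as an offset on the id_b member: favouring the
  # id_a side means pushing id_b down, and vice versa.
  for (j in which(pairs$bias_log2 > 0)) {
    up_first <- pairs$bias_direction[j] %in% c("A", "copy1")
    k <- match(pairs$id_b[j], prot$protein_id)
    prot$bias_offset_log2[k] <- prot$bias_offset_log2[k] +
      if (up_first) -pairs$bias_log2[j] else pairs$bias_log2[j]
  }

  structure(
    list(sequences = sequences,
         truth = list(pairs = pairs, proteins = prot),
         config = config),
    class = "sim_proteome"
  )
}

#' Simulate a replicated two-tissue quantification matrix
#'
#' Each measurement is `2 ^ (base + tissue effect + bias offset +
#' Normal(0, noise_sigma))`; the tissue effect applies to the first tissue
#' label so `true_log2fc` is oriented first-tissue over second. Cells are
#' then set missing independently with probability `missing_rate`.
#'
#' @param sim A `sim_proteome` from [simulate_families()], or its `truth`
#'   element.
#' @param config A [simulation_config()]; defaults to the one stored in
#'   `sim`.
#' @param seed Integer seed for the noise and missingness draws; defaults
#'   to `config$seed + 1` so a full simulation is a pure function of its
#'   configuration while still using different draws than the sequence
#'   stage. Pass different seeds to draw replicate datasets from one
#'   simulated proteome.
#' @return A long tibble (class `quant_tbl`) with columns `protein_id`,
#'   `sample`, `tissue`, `replicate`, `abundance` (NA = missing). Missing
#'   cells are kept as explicit NA rows.
#' @export
simulate_quant <- function(sim, config = NULL, seed = NULL) {
  truth <- if (inherits(sim, "sim_proteome")) sim$truth else sim
  if (is.null(config)) config <- sim$config
  validate_sim_config(config)
  if (is.null(seed)) seed <- config$seed + 1L
  set.seed(as.integer(seed))
  prot <- truth$proteins
  design <- tidyr::expand_grid(
    tissue = config$tissues,
    replicate = seq_len(config$n_replicates)
  )
  design$sample <- paste0(design$tissue, "_", design$replicate)

  qm <- tidyr::expand_grid(protein_id = prot$protein_id,
                           sample = design$sample) |>
    dplyr::left_join(design, by = "sample") |>
    dplyr::left_join(prot, by = "protein_id")
  log2_mean <- qm$base_log2 + qm$bias_offset_log2 +
    ifelse(qm$tissue == config$tissues[1], qm$true_log2fc, 0)
  qm$abundance <- 2^(log2_mean + stats::rnorm(nrow(qm), 0, config$noise_sigma))
  qm$abundance[stats::runif(nrow(qm)) < config$missing_rate] <- NA_real_
  out <- qm[, c("protein_id", "sample", "tissue", "replicate", "abundance")]
  as_result_tbl(out, "quant_tbl")
}

#' Write a simulated proteome to disk
#'
#' Writes `proteins.faa`, `cds.fna`, `quant.tsv` (wide, one column per
#' sample named `<tissue>_<replicate>`), `truth_pairs.tsv`,
#' `truth_proteins.tsv` and `config.json`.
#'
#' @param sim A `sim_proteome`.
#' @param qm A `quant_tbl` from [simulate_quant()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, qm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  aa <- Biostrings::AAStringSet(stats::setNames(sim$sequences$protein,
                                                sim$sequences$id))
  nt <- Biostrings::DNAStringSet(stats::setNames(sim$sequences$cds,
                                                 sim$sequences$id))
  Biostrings::writeXStringSet(aa, file.path(dir, "proteins.faa"))
  Biostrings::writeXStringSet(nt, file.path(dir, "cds.fna"))
  write_quant(qm, file.path(dir, "quant.tsv"))
  readr::write_tsv(sim$truth$pairs, file.path(dir, "truth_pairs.tsv"))
  readr::write_tsv(sim$truth$proteins, file.path(dir, "truth_proteins.tsv"))
  jsonlite::write_json(unclass(sim$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
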