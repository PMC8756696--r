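test_that("back-translation maps residues to codons and gaps to codon gaps", {
  # ungapped identical alignment: codon rows are the CDS verbatim
  ca <- backtranslate("MEK", "MEK", "ATGGAAAAA", "ATGGAGAAG")
  expect_equal(ca$a, "ATGGAAAAA")
  expect_equal(ca$b, "ATGGAGAAG")
  # a residue gap expands to a codon-sized gap at the right position
  ca2 <- backtranslate("ME-K", "MEAK", "ATGGAAAAA", "ATGGAAGCTAAA")
  expect_equal(ca2$a, "ATGGAA---AAA")
  expect_equal(ca2$b, "ATGGAAGCTAAA")
  # trailing stop codons are tolerated and trimmed
  ca3 <- backtranslate("MEK", "MEK", "ATGGAAAAATAA", "ATGGAGAAG")
  expect_equal(ca3$a, "ATGGAAAAA")
})

test_that("translation mismatches name the sequence, position and residues", {
  expect_error(backtranslate("MEK", "MEK", "ATGGAAAAA", "ATGCATAAG",
                             ids = c("s1", "s2")),
               "s2.*residue 2.*'E'.*'H'")
  expect_error(backtranslate("MEKL", "MEKL", "ATGGAAAAA", "ATGGAGAAG"),
               "3 codons.*4 residues")
})

test_that("degap and translate of a codon alignment returns the proteins", {
  set.seed(41)
  for (i in 1:20) {
    anc <- random_cds(40)
    ep <- evolve_pair(anc, omega = 0.4, ks_target = 0.5)
    p1 <- translate_cds(ep$cds_1)
    p2 <- translate_cds(ep$cds_2)
    aln <- align_protein_pair(p1, p2)
    ca <- backtranslate(aln$a, aln$b, ep$cds_1, ep$cds_2)
    expect_identical(translate_cds(gsub("-", "", ca$a)), p1)
    expect_identical(translate_cds(gsub("-", "", ca$b)), p2)
  }
})

test_that("NG86 site fractions and difference counts match enumeration", {
  # TTT: only the third position can change synonymously (1 of 3 changes)
  expect_equal(homeoprot:::ng86_codon_sites("TTT")[["S"]], 1 / 3)
  # TTT vs TTC: one synonymous difference, no nonsynonymous
  d <- homeoprot:::ng86_codon_diffs("TTT", "TTC")
  expect_equal(d[["Sd"]], 1)
  expect_equal(d[["Nd"]], 0)
  # every sense codon carries exactly 3 sites
  for (cd in homeoprot:::sense_codons()) {
    s <- homeoprot:::ng86_codon_sites(cd)
    expect_equal(s[["S"]] + s[["N"]], 3)
    expect_equal(s[["S"]], oracle_syn_sites(cd))
  }
})

test_that("pathway averaging over sense-codon pairs matches the DFS oracle", {
  # spot-check a seeded sample of the 61x61 grid here; the full grid runs
  # in the acceptance suite
  set.seed(43)
  sc <- homeoprot:::sense_codons()
  for (i in 1:200) {
    c1 <- sample(sc, 1)
    c2 <- sample(sc, 1)
    got <- homeoprot:::ng86_codon_diffs(c1, c2)
    want <- oracle_path_counts(c1, c2)
    expect_equal(unname(got[c("Sd", "Nd")]), want, info = paste(c1, c2))
  }
})

test_that("identical sequences give Ka = Ks = 0 and a low-divergence flag", {
  cds <- "ATGGCTAAATTTGGG"
  r <- kaks_counting(list(a = cds, b = cds))
  expect_equal(r$ka, 0)
  expect_equal(r$ks, 0)
  expect_true(r$excluded)
  expect_equal(r$excluded_reason, "low_divergence")
  expect_equal(r$selection, "not_classified")
})

test_that("kaks counting is symmetric and conserves sites", {
  set.seed(47)
  ep <- evolve_pair(random_cds(100), omega = 0.3, ks_target = 0.4)
  r1 <- kaks_counting(list(a = ep$cds_1, b = ep$cds_2))
  r2 <- kaks_counting(list(a = ep$cds_2, b = ep$cds_1))
  expect_equal(r1$ka, r2$ka)
  expect_equal(r1$ks, r2$ks)
  expect_equal(r1$n_sites_n + r1$n_sites_s, 3 * r1$n_codons_compared)
})

test_that("synonymous-only differences move Ks and leave Ka at zero", {
  a <- c("TTT", "GGA", "CCA", "AAA", "CGT")
  b1 <- c("TTC", "GGA", "CCA", "AAA", "CGT")  # one synonymous change
  b2 <- c("TTC", "GGG", "CCA", "AAA", "CGT")  # two synonymous changes
  r0 <- kaks_counting(list(a = paste(a, collapse = ""),
                           b = paste(a, collapse = "")))
  r1 <- kaks_counting(list(a = paste(a, collapse = ""),
                           b = paste(b1, collapse = "")))
  r2 <- kaks_counting(list(a = paste(a, collapse = ""),
                           b = paste(b2, collapse = "")))
  expect_equal(r1$ka, 0)
  expect_equal(r2$ka, 0)
  expect_true(r0$ks < r1$ks && r1$ks < r2$ks)
})

test_that("gapped and ambiguous codon columns are skipped", {
  r <- kaks_counting(list(a = "ATG---TTT", b = "ATGGCTTTC"))
  expect_equal(r$n_codons_compared, 2)
  r2 <- kaks_counting(list(a = "ATGNNNTTT", b = "ATGGCTTTC"))
  expect_equal(r2$n_codons_compared, 2)
  r3 <- kaks_counting(list(a = "---", b = "ATG"))
  expect_true(r3$excluded)
  expect_equal(r3$excluded_reason, "no_comparable_codons")
})

test_that("exclusion rules partition results as specified", {
  res <- tibble::tibble(
    id_a = c("a", "b", "c", "d"), id_b = c("x", "y", "z", "w"),
    relation = "paralog",
    ka = c(0.001, 0.1, 0, 0.2), ks = c(2, 0.4, 0.3, NA),
    ratio = c(0.0005, 0.25, 0, NA),
    excluded = c(TRUE, FALSE, TRUE, TRUE),
    excluded_reason = c("low_divergence", "none", "low_divergence",
                        "saturated"),
    selection = c("not_classified", "purifying", "not_classified",
                  "not_classified")
  )
  parts <- apply_exclusions(res)
  expect_equal(parts$kept$id_a, "b")
  expect_equal(nrow(parts$excluded), 3)
  expect_equal(sum(parts$counts$n), 4)
})

test_that("selection classes follow the Ka/Ks trichotomy", {
  expect_equal(homeoprot:::classify_selection(0.24), "purifying")
  expect_equal(homeoprot:::classify_selection(1), "neutral")
  expect_equal(homeoprot:::classify_selection(1 + 1e-12), "neutral")
  expect_equal(homeoprot:::classify_selection(1.3), "positive")
})

test_that("estimated Ka/Ks recovers the generator's omega", {
  set.seed(53)
  ratios <- replicate(30, {
    ep <- evolve_pair(random_cds(300), omega = 0.2, ks_target = 0.3)
    kaks_counting(list(a = ep$cds_1, b = ep$cds_2))$ratio
  })
  expect_lt(abs(mean(ratios) - 0.2), 0.1)
})

test_that("rank correlations match a brute-force rank oracle", {
  kk <- tibble::tibble(
    id_a = paste0("a", 1:10), id_b = paste0("b", 1:10),
    relation = "paralog",
    ratio = c(0.9, 0.8, 0.7, 0.6, 0.5, 0.45, 0.3, 0.2, 0.15, 0.1),
    excluded = FALSE
  )
  # perfectly anticorrelated measure
  vals <- tibble::tibble(id_a = kk$id_a, id_b = kk$id_b,
                         value = seq(1, 10))
  cr <- correlate_rate_abundance(kk, vals)
  expect_equal(cr$rho, -1)
  # brute-force Spearman: Pearson on ranks
  set.seed(59)
  vals2 <- tibble::tibble(id_a = kk$id_a, id_b = kk$id_b,
                          value = rnorm(10))
  cr2 <- correlate_rate_abundance(kk, vals2)
  rho_oracle <- stats::cor(rank(kk$ratio), rank(vals2$value))
  expect_equal(cr2$rho, rho_oracle)
  # insufficient data is flagged, not fabricated
  cr3 <- correlate_rate_abundance(kk[1:2, ], vals2[1:2, ])
  expect_equal(cr3$note, "insufficient_data")
  expect_true(is.na(cr3$rho))
})

test_that("abundance-dependent omega is recovered as a negative correlation", {
  # construct pairs whose true omega decreases with a synthetic abundance
  set.seed(61)
  n <- 60
  abundance <- sort(runif(n, 5, 25))
  omega <- 0.6 - 0.02 * abundance + rnorm(n, 0, 0.02)
  omega <- pmax(omega, 0.02)
  rows <- lapply(seq_len(n), function(i) {
    ep <- evolve_pair(random_cds(120), omega = omega[i], ks_target = 0.4)
    kaks_counting(list(a = ep$cds_1, b = ep$cds_2))
  })
  kk <- dplyr::bind_cols(
    tibble::tibble(id_a = paste0("a", 1:n), id_b = paste0("b", 1:n),
                   relation = "paralog"),
    dplyr::bind_rows(rows)
  )
  vals <- tibble::tibble(id_a = kk$id_a, id_b = kk$id_b, value = abundance)
  cr <- correlate_rate_abundance(kk, vals)
  expect_lt(cr$rho, 0)
  expect_lte(cr$p_value, 0.05)
})

test_that("kaks_pairs drives the full alignment chain per pair", {
  cfg <- simulation_config(n_families = 5, n_codons = 60, seed = 67)
  sim <- simulate_families(cfg)
  kk <- kaks_pairs(sim$truth$pairs, sim$sequences)
  expect_equal(nrow(kk), nrow(sim$truth$pairs))
  expect_true(all(kk$n_codons_compared > 0))
  expect_error(
    kaks_pairs(tibble::tibble(id_a = "nope", id_b = "nix"),
               sim$sequences),
    "nope"
  )
})
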