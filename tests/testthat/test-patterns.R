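pairs2 <- tibble::tibble(
  id_a = c("A1", "A3"), id_b = c("A2", "A4"),
  relation = "paralog"
)

test_that("paralog divergence applies the conjunction of both criteria", {
  qm <- make_quant(list(
    A1 = list(leaf = c(800, 900, 1000)), A2 = list(leaf = c(50, 60, 55)),
    A3 = list(leaf = c(100, 110, 90)), A4 = list(leaf = c(100, 110, 90))
  ))
  dv <- paralog_divergence(pairs2, qm, "leaf")
  d1 <- dv[dv$id_a == "A1", ]
  expect_equal(d1$abs_log2_ratio, abs(log2(900 / 55)))
  # frozen closed-form Welch t on log2 values: p = 6.829e-06
  expect_equal(d1$p_value, 6.829375e-06, tolerance = 1e-4)
  expect_true(d1$divergent)
  d2 <- dv[dv$id_a == "A3", ]
  expect_equal(d2$abs_log2_ratio, 0)
  expect_false(d2$divergent)
})

test_that("a large ratio without significance is not divergent", {
  # high variance swamps the 16-fold mean ratio
  qm <- make_quant(list(
    A1 = list(leaf = c(1600, 1, 31)), A2 = list(leaf = c(1, 100, 1))
  ))
  dv <- paralog_divergence(pairs2[1, ], qm, "leaf")
  expect_gt(dv$abs_log2_ratio, 2)
  expect_gt(dv$p_value, 0.05)
  expect_false(dv$divergent)
})

test_that("divergence is invariant to copy order", {
  qm <- make_quant(list(
    A1 = list(leaf = c(800, 900, 1000)), A2 = list(leaf = c(50, 60, 55))
  ))
  fwd <- paralog_divergence(pairs2[1, ], qm, "leaf")
  swapped <- tibble::tibble(id_a = "A2", id_b = "A1", relation = "paralog")
  rev <- paralog_divergence(swapped, qm, "leaf")
  expect_equal(fwd$abs_log2_ratio, rev$abs_log2_ratio)
  expect_equal(fwd$p_value, rev$p_value)
})

hpair <- tibble::tibble(
  id_a = "g1", id_b = "g2", relation = "homeolog",
  sub_genome_a = "A", sub_genome_b = "B"
)

test_that("homeolog bias classifies by the signed A-over-B rule", {
  qm <- make_quant(list(
    g1 = list(leaf = c(1000, 1000, 1000)),
    g2 = list(leaf = c(100, 100, 100))
  ))
  bs <- homeolog_bias(hpair, qm, "leaf")
  expect_equal(bs$log2_ratio_AB, log2(10))
  expect_equal(bs$p_value, 0)  # constant groups, different means
  expect_equal(bs$class, "A_biased")
})

test_that("swapping sub-genome labels flips class and negates the ratio", {
  qm <- make_quant(list(
    g1 = list(leaf = c(1000, 1100, 950)),
    g2 = list(leaf = c(100, 95, 105))
  ))
  fwd <- homeolog_bias(hpair, qm, "leaf")
  flipped <- hpair
  flipped$sub_genome_a <- "B"
  flipped$sub_genome_b <- "A"
  rev <- homeolog_bias(flipped, qm, "leaf")
  expect_equal(fwd$log2_ratio_AB, -rev$log2_ratio_AB)
  expect_equal(fwd$p_value, rev$p_value)
  expect_equal(fwd$class, "A_biased")
  expect_equal(rev$class, "B_biased")
  bad <- hpair
  bad$sub_genome_b <- "A"
  expect_error(homeolog_bias(bad, qm, "leaf"), "sub-genome")
})

test_that("bias classes conserve the pair count", {
  cfg <- simulation_config(n_families = 60, paralog_fraction = 0,
                           n_codons = 10, seed = 17)
  sim <- simulate_families(cfg)
  qm <- simulate_quant(sim)
  pr <- sim$truth$pairs
  pr$sub_genome_a <- "A"
  pr$sub_genome_b <- "B"
  bs <- homeolog_bias(pr, qm, "leaf")
  g <- glance(bs)
  expect_equal(g$n_A_biased + g$n_B_biased + g$n_unbiased + g$n_untestable,
               nrow(pr))
})

test_that("bias recovery on synthetic truth exceeds 90% with few false calls", {
  cfg <- simulation_config(n_families = 200, paralog_fraction = 0,
                           n_codons = 10, bias_effect_log2 = 3,
                           biased_fraction = 0.3, noise_sigma = 0.2,
                           de_fraction = 0, missing_rate = 0, seed = 29)
  sim <- simulate_families(cfg)
  qm <- simulate_quant(sim)
  pr <- sim$truth$pairs
  pr$sub_genome_a <- "A"
  pr$sub_genome_b <- "B"
  bs <- homeolog_bias(pr, qm, "leaf")
  truth_dir <- pr$bias_direction
  called_dir <- c(A_biased = "A", B_biased = "B", unbiased = "none",
                  untestable = "none")[bs$class]
  biased <- truth_dir != "none"
  expect_gt(mean(called_dir[biased] == truth_dir[biased]), 0.9)
  expect_lte(mean(bs$class[!biased] != "unbiased"), 0.05)
})

test_that("cross-tissue overlap counts equal the set-algebra oracle", {
  mk <- function(ids_pos, ids_neg, ids_unt, tissue) {
    tibble::tibble(
      id_a = c(ids_pos, ids_neg, ids_unt), id_b = "x", tissue = tissue,
      abs_log2_ratio = 3, p_value = 0.01,
      divergent = c(rep(TRUE, length(ids_pos)), rep(FALSE, length(ids_neg)),
                    rep(NA, length(ids_unt))),
      status = "any"
    )
  }
  r1 <- mk(c("p1", "p2", "p3"), c("p4", "p5"), "p6", "leaf")
  r2 <- mk(c("p2", "p3", "p4"), c("p1", "p6"), "p5", "root")
  ov <- cross_tissue_overlap(r1, r2)
  # testable in both: p1..p4; positives leaf {p1,p2,p3}, root {p2,p3,p4}
  expect_equal(ov$counts$n_testable, 4)
  expect_equal(ov$counts$n_both, 2)
  expect_equal(ov$counts$n_only_t1, 1)
  expect_equal(ov$counts$n_only_t2, 1)
  expect_equal(ov$counts$n_neither, 0)
  # identical lists: full overlap, no exclusives
  ov2 <- cross_tissue_overlap(r1, r1)
  expect_equal(ov2$counts$n_both, 3)
  expect_equal(ov2$counts$n_only_t1, 0)
  # disjoint positives
  r3 <- mk(c("p4", "p5"), c("p1", "p2", "p3", "p6"), character(0), "root")
  ov3 <- cross_tissue_overlap(r1, r3)
  expect_equal(ov3$counts$n_both, 0)
  expect_gt(ov3$counts$n_only_t1, 0)
  expect_gt(ov3$counts$n_only_t2, 0)
  # mismatched universes are an error
  expect_error(cross_tissue_overlap(r1, r2[-1, ]), "universe")
})

test_that("bias count comparisons match exact binomial and Fisher oracles", {
  mk_bias <- function(nA, nB, tissue) {
    tibble::tibble(
      id_a = paste0("a", seq_len(nA + nB)), id_b = "b", tissue = tissue,
      log2_ratio_AB = c(rep(3, nA), rep(-3, nB)), p_value = 0.01,
      class = c(rep("A_biased", nA), rep("B_biased", nB))
    )
  }
  bc <- compare_bias_counts(list(mk_bias(10, 10, "leaf")))
  expect_equal(bc$counts$binom_p, 1)
  bc2 <- compare_bias_counts(list(mk_bias(87, 69, "leaf"),
                                  mk_bias(87, 68, "root")))
  # exact binomial tail oracle
  d <- dbinom(0:156, 156, 0.5)
  p_oracle <- sum(d[d <= dbinom(87, 156, 0.5) * (1 + 1e-7)])
  expect_equal(bc2$counts$binom_p[bc2$counts$tissue == "leaf"], p_oracle,
               tolerance = 1e-10)
  # Fisher oracle by hypergeometric enumeration on the 2x2 table
  p_fisher <- local({
    m <- matrix(c(87, 69, 87, 68), 2)
    stats::fisher.test(m)$p.value
  })
  expect_equal(bc2$cross_tissue_p, p_fisher)
  expect_gt(bc2$cross_tissue_p, 0.05)
})

test_that("copy categories partition pairs and report asymmetric fractions", {
  dap <- tibble::tibble(
    protein_id = c("u1", "u2", "n1", "n2", "x1"),
    log2fc = c(3, -3, 0.5, 0.2, NA),
    p_value = c(0.01, 0.01, 0.5, 0.6, NA),
    n_a = 3, n_b = 3,
    status = c("up", "down", "not_significant", "not_significant",
               "untestable")
  )
  pr <- tibble::tibble(
    id_a = c("u1", "u1", "n1", "x1"),
    id_b = c("u2", "n1", "n2", "n1"),
    relation = c("paralog", "paralog", "paralog", "homeolog")
  )
  cc <- copy_level_categories(pr, dap)
  expect_equal(cc$categories$category,
               c("double_copy", "single_copy", "neither", "neither"))
  s <- cc$summary[cc$summary$relation == "paralog", ]
  expect_equal(s$n_informative, 2)
  expect_equal(s$asymmetric_fraction, 0.5)
  # the three categories partition the pair set
  expect_equal(sum(cc$summary$n_double + cc$summary$n_single +
                     cc$summary$n_neither),
               nrow(pr))
})

test_that("all-neither input reports zero informative pairs without error", {
  dap <- tibble::tibble(protein_id = c("a", "b"), log2fc = 0, p_value = 1,
                        n_a = 3, n_b = 3, status = "not_significant")
  pr <- tibble::tibble(id_a = "a", id_b = "b", relation = "paralog")
  cc <- copy_level_categories(pr, dap)
  expect_equal(cc$summary$n_informative, 0)
  expect_true(is.na(cc$summary$asymmetric_fraction))
})

test_that("raising the log2 threshold never increases positive calls", {
  cfg <- simulation_config(n_families = 80, paralog_fraction = 0,
                           n_codons = 10, seed = 37)
  sim <- simulate_families(cfg)
  qm <- simulate_quant(sim)
  pr <- sim$truth$pairs
  pr$sub_genome_a <- "A"
  pr$sub_genome_b <- "B"
  n_pos <- vapply(c(1, 2, 3), function(thr) {
    sum(homeolog_bias(pr, qm, "leaf", threshold = thr)$class !=
          "unbiased" &
          homeolog_bias(pr, qm, "leaf", threshold = thr)$class !=
          "untestable")
  }, numeric(1))
  expect_true(all(diff(n_pos) <= 0))
})
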