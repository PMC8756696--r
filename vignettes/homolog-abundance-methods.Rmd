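---
title: "Methods: homolog abundance patterns in an allotetraploid proteome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homolog abundance patterns in an allotetraploid proteome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homeoprot)
```

## The problem

Allotetraploid species such as cultivated peanut (*Arachis hypogaea*,
AABB) carry two diverged sub-genomes, A and B. Most genes therefore exist
as a **homeolog pair** — one copy per sub-genome — and a subset carry
additional **paralogs**, duplicates that arose within one sub-genome.
Quantitative proteomics of such a species asks, per pair: are the two
copies equally abundant, or has one copy taken over (homeolog abundance
bias, paralog abundance divergence)? How do such patterns compare between
tissues? And is protein-level evolutionary rate (Ka/Ks) related to
abundance, as the expression rate–evolutionary rate (E–R) anticorrelation
predicts?

`homeoprot` implements this analysis end to end on tabular data: a
protein × sample quantification matrix with a two-tissue, replicated
design; protein and CDS sequences; and pairwise alignment statistics. A
synthetic-data generator produces all of these with known ground truth,
so every stage is testable without external data.

## The classification rules

All rules operate on the log2 scale with a strict ratio threshold of 2
and a t-test at `p <= 0.05`:

* **Differential abundance** (between tissues): per protein,
  `log2fc = log2(mean leaf / mean root)` on raw replicate means; a
  two-sided two-sample t-test on the log2 replicate values; called up
  when `log2fc > 2` and `p <= 0.05`, down when `log2fc < -2` at the same
  significance.
* **Paralog divergence** (within a tissue): `|log2(copy1/copy2)| > 2`
  with `p <= 0.05`. The rule is symmetric, so copy order is canonical
  (lexicographic) and irrelevant.
* **Homeolog bias** (within a tissue): signed `log2(A/B) > 2` gives an
  A-biased pair, `< -2` a B-biased pair, again with `p <= 0.05`.
* **Copy-level categories** (for a tissue contrast): a pair is
  double-copy when both members are differentially abundant, single-copy
  when exactly one is. Among informative pairs (at least one DA member),
  the single-copy fraction is the *asymmetric abundance* fraction.

Thresholds are strict inequalities: a ratio of exactly 2 (or identity of
exactly 80 in the homology filters) does not pass. Proteins or pairs with
fewer than two measured replicates on either side are reported
`untestable`, never silently dropped, and untestable pairs are excluded
from cross-tissue overlap denominators.

### t-test variant

The default is Welch (unequal variance), a robust choice at n = 3; a
pooled-variance variant is available via `var_equal = TRUE`. When both
groups are constant the statistic is undefined and the p-value is set to
1 when the means agree and 0 otherwise. A relevant numerical fact,
exercised by the calibration tests: with equal group variances — which
the synthetic generator guarantees by construction — the pooled test is
exactly calibrated, while Welch rejects at about 0.034 rather than 0.05
at n = 3 per group. The calibration checks therefore use the pooled
variant; the headline default remains Welch. No multiple-testing
correction is applied in the headline path (an optional
Benjamini–Hochberg column is available via `adjust = TRUE`), mirroring
the raw-p convention the classification rules assume.

### Missingness comparison

Per-replicate missing fractions are compared between tissues with a
two-sided Mann–Whitney test. At 3 vs 3 replicates the null support is 20
rank assignments, so the test is computed by exact permutation of
midranks (correct under ties); beyond 20,000 combinations it falls back
to the normal approximation of `wilcox.test()`. A side effect worth
knowing: with 3 vs 3 the smallest attainable two-sided p is 0.1, so this
comparison can never be "significant" at 0.05 — which is the appropriate
behaviour for a 3-replicate design.

## Homolog pairing

Candidate hits (from an external 12-column tabular alignment file, or
from the built-in all-vs-all global aligner) pass three filters, each
required:

1. alignment length > 80% of the query length **and** > 80% of the
   subject length,
2. percent identity > 80,
3. E-value ≤ 1e-10 (hits without an E-value — global alignments — pass
   this criterion).

"Similarity" is read as the tabular format's percent-identity column.
Surviving hits are symmetrised and pairs are formed by **reciprocal best
hit** by score within each relation class: within-sub-genome (paralog)
and cross-sub-genome A × B (homeolog). Ties break lexicographically by
partner id; pair members are stored in lexicographic order. Proteins with
an unassigned sub-genome take part in neither class. A keep-all-passing
mode (`mode = "all"`) is available since the RBH requirement is a design
choice, not forced by the filters.

The built-in aligner is Needleman–Wunsch with BLOSUM62 and affine gaps
(gap of length L costs `10 + L`); its scores are verified against an
independent dynamic-programming oracle in the test suite. At larger set
sizes `align_all()` computes scores for all pairs but full hit records
only for each sequence's `top_n` best-scoring partners; reciprocal best
hits and 80%-identity survivors always rank at the top by score, so this
is a compute shortcut, not a change of rule. Exactness-sensitive tests
use `top_n = NULL`.

## Ka/Ks estimation

Protein pairs are globally aligned and back-translated codon-by-codon
(each residue column becomes its codon, each residue gap a `---`), after
verifying that each CDS translates residue-for-residue to its protein; a
trailing stop codon is trimmed. The estimator is Nei–Gojobori (1986)
counting:

* **Sites**: at each codon position, the synonymous fraction of the
  non-stop single-base changes; mutations to stop codons are excluded
  from numerator and denominator, so each codon carries exactly 3 sites
  (S + N = 3). Site totals are averaged over the two sequences.
* **Differences**: for each differing codon pair, all orderings of the
  differing positions are enumerated and the synonymous/nonsynonymous
  step counts averaged over pathways that avoid stop codons. If every
  pathway is blocked (rare 2–3-fold differences), the pair is scored over
  all pathways with stop-involving steps counted as nonsynonymous and the
  pair is flagged (`n_blocked_paths`).
* **Correction**: proportions are Jukes–Cantor corrected; a proportion
  ≥ 3/4 is outside the correction's range and marks the pair `saturated`.

Pairs with `Ka/Ks < 0.001` or `Ka = 0` are excluded as low-divergence
(such ratios are numerically meaningless); a pair with `Ks = 0` but
`Ka > 0` has an undefined ratio and is recorded under the same
low-divergence reason. Kept pairs are classified as purifying
(`Ka/Ks < 1`), neutral (`= 1`, within 1e-9) or positive (`> 1`).
Codon columns containing gaps or ambiguous bases are skipped.

Rate–abundance correlations are Spearman's rho per group (relation ×
tissue × measure). The pair-level abundance is the mean of the two
members' log2 tissue means; the pair-level differential abundance is the
mean of the members' log2 fold changes. Groups with fewer than three
complete pairs are flagged `insufficient_data` rather than given a
number.

## Enrichment

`fisher_enrich()` is the one-sided (over-representation) Fisher exact
test via the hypergeometric upper tail, per term with at least
`min_term_size` background members, with Benjamini–Hochberg q-values
across tested terms (disable with `adjust = FALSE` to mirror raw-p
reporting). Annotation retrieval is out of scope: annotations are a
user-supplied `protein_id`/`term_id` table.

## The synthetic generator

`simulate_families()` emulates an allotetraploid proteome at desk scale:

* Each family draws a stop-free ancestral CDS (codons uniform over the
  61 sense codons) and evolves an A and a B copy from it; a
  `paralog_fraction` subset duplicates the A copy. Substitution proposals
  are single-nucleotide, uniform over sites and target bases; proposals
  creating stops are rejected; a nonsynonymous proposal is accepted with
  probability `min(1, omega)` (and synonymous with `min(1, 1/omega)`), so
  the accepted nonsynonymous:synonymous ratio is omega times the
  mutational opportunity — exactly the assumption set under which the
  NG86 estimator is interpretable, making recovery tests meaningful.
  Synonymous events per lineage are Poisson with mean `ks_target/2`
  times the ancestor's synonymous site count.
* The paralog duplicate evolves **one-sidedly** (the parent copy is left
  untouched and the duplicate takes a full `ks_target` of divergence).
  With symmetric post-duplication divergence the two A copies would be
  equidistant from the B copy in expectation and the "true" homeolog
  partner would be undefined; one-sided divergence keeps the parent
  strictly closer, so truth-recovery comparisons are well-posed.
* Abundance: `2^(base + tissue effect + bias offset + N(0, noise_sigma))`.
  The baseline is drawn **per family** and shared by its members, so
  homolog copies are equally abundant unless an effect separates them.
  Bias offsets are placed on the B copy of a homeolog pair and on the
  duplicate copy of a paralog pair, so a protein belonging to both pair
  types never carries a confounding offset. Tissue effects
  (`de_fraction`, sign random per protein) apply to the first tissue.
  Cells go missing completely at random at `missing_rate`.

Defaults are chosen as the study conditions the analysis assumes: two
tissues (leaf, root) × 3 replicates; `missing_rate = 0.025` (the ~2.5%
per-replicate miss rate a TMT experiment of this kind reports);
`bias_effect_log2 = 3` with `biased_fraction = 0.3` and
`noise_sigma = 0.2` (a clearly-detectable effect against realistic
replicate noise); `ks_target = 0.3` with omega in (0.05, 0.6), which
yields Ka/Ks values in the purifying regime (~0.2–0.3) comparable to
what proteome-wide homolog scans report, while keeping protein identity
near the 80% filter boundary so the filters are actually exercised;
`n_families = 150` (≈ 345 proteins), a deliberate desk-scale proteome.
The generator does **not** emulate peptide-level effects (digestion,
reporter-ion compression), intensity-dependent missingness, correlated
replicate structure, or indels (so alignments are gap-free unless real
data supplies them); passing tests therefore demonstrate correctness of
the statistical machinery under the stated model, not robustness to
those real-data features.

`simulate_quant()` takes its own seed (default `config$seed + 1`), so a
full simulation is a pure function of its configuration and replicate
null datasets can be drawn from one simulated proteome.

## Numerical choices and degenerate inputs

* Zero-variance t-tests: p = 1 (equal means) or 0 (unequal), avoiding
  0/0.
* Zero abundances are treated as missing on reading (measured abundances
  are strictly positive); negative values are a hard error naming the
  protein and sample.
* `copy_level_categories()` with no informative pairs reports zero
  informative pairs and an `NA` fraction — no division by zero.
* Codon-pair difference counts and site fractions are cached
  (memoised) per codon pair, which makes the 61 × 61 exhaustive check
  and the per-pair estimates cheap.
* All randomness flows from explicit integer seeds; two runs of
  `run_pipeline()` with the same configuration write byte-identical
  outputs.

## Problem sizes used in the checks

The shipped checks run at deliberate desk scale: the default pipeline at
150 families (≈ 345 proteins, ≈ 96 recovered pairs); bias recovery at
200 homeolog pairs; estimator recovery at 50 pairs × 300 codons; null
calibration of the DA caller at 2000 proteins and of the missingness
comparison over 200 replicate null datasets; the aligner oracle on 50
random ≤ 10-residue pairs; and the NG86 oracle over all 61 × 61 sense
codon pairs.

## Known limitations

* The pairing rule (RBH) and coverage definition (single-hit span) are
  conventional choices; studies differ on whether all passing pairs are
  kept and on HSP stitching, neither of which is implemented.
* NG86 with Jukes–Cantor is the most transparent counting estimator but
  ignores transition/transversion bias and codon-frequency effects;
  estimates on strongly biased real sequences will differ from
  maximum-likelihood codon models.
* The headline significance rule uses raw p-values per the analysis
  convention it implements; use `adjust = TRUE` for BH-corrected calls.
* With 3 replicates the missingness comparison cannot reach p < 0.1 (see
  above); it is a sanity check, not a powerful test.

## A worked run

```{r, eval = FALSE}
cfg <- simulation_config(n_families = 60, seed = 7)
run <- run_pipeline(cfg, quiet = TRUE)
glance(run)
tidy(run$bias_counts)
glance(run$kaks)
autoplot(run$dap)
```
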