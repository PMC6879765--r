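---
title: "Methods: RMAF, matching weights and sex-disparity inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RMAF, matching weights and sex-disparity inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xdisparity)
```

# The problem

Most non-reproductive cancers are more frequent and more lethal in males.
One mechanistic route runs through p53 and the X chromosome: males carry a
single X copy, so any somatic mutation in an X-linked p53-network gene is
necessarily expressed; females carry two copies, of which X-inactivation
(Xi) silences one, so roughly half of randomly placed X mutations can land
on the inactive copy and never reach the transcriptome. `xdisparity`
packages the computations needed to quantify this asymmetry from cohort
data: a transcription-level mutation metric (RMAF), registry-scale
incidence integration, covariate balancing, per-gene weighted association
tests, burden models and survival stratification.

# RMAF and the NEM/EM classification

For a somatic DNA mutation, RMAF is the fraction of mRNA reads overlapping
the mutated position that carry the mutant allele — the mRNA analogue of
the DNA variant allele frequency. The classification rules, in the order
the pipeline (`rmaf_table()`) applies them:

1. **Class filter** (`filter_mutations()`): only the eight variant classes
   with plausible transcript impact (3'/5' UTR, frameshift ins/del,
   missense, nonsense, splice region/site) are analysed; patients with
   15,000 or more somatic mutations (hypermutators) are removed entirely
   (strictly fewer than 15,000 are kept). The cap is assessed on the total
   somatic count before the class filter, which also makes the filter
   idempotent.
2. **Direct quotient**: with at least 10 pileup reads,
   `RMAF = alt / (alt + ref)`. Exactly 10 reads uses the quotient; fewer
   goes to the fallback.
3. **Low-coverage fallback**, within the sex-and-cancer-matched cohort:
   (a) if the gene fails the 5-CPM majority rule there, the mutation is
   discarded (`not_expressed_gene`); (b) otherwise, a z-score of the
   sample's expression against the cohort decides: z ≤ −4 is interpreted
   as the mutation knocking its own gene down and assigns RMAF 1
   (`knockdown_assigned`); larger z discards (`insufficient_info`).
   A cohort smaller than 3 samples also discards — a standard deviation
   from fewer samples is too unstable to support a ±4-sigma call.
4. **Gene-level resolution** (`resolve_gene_level()`): one mutation per
   patient and gene, the one with the highest RMAF; ties break to the
   smallest genomic position so results are order-independent.
5. **Thresholds** (`classify_rmaf()`): RMAF ≤ 0.20 is a non-expressed
   mutation (NEM), RMAF ≥ 0.75 an expressed mutation (EM); both boundaries
   inclusive. Intermediate records are reported but enter neither class in
   any downstream statistic.

Numerical choices worth knowing:

* **z-score scale.** The z-score is computed on `log2(CPM + 1)`, not raw
  CPM: expression is roughly log-normal across samples, and the log scale
  stabilises the variance so that "4 standard deviations below the mean"
  means the same thing for high- and low-expressed genes. This is a
  deliberate choice where either scale is defensible; on fixtures with a
  controlled cohort both scales classify the package's test cases
  identically.
* **Majority rule.** "Expressed in the majority of samples" is read
  strictly: more than 50% of the cohort's samples at CPM ≥ 5 (the 5 is
  inclusive). The same rule backs `filter_low_expression()`, so the
  package has a single low-expression semantics.
* **Degenerate cohorts.** A zero cohort standard deviation makes the
  z-score undefined; such mutations are discarded as `insufficient_info`
  (they can never witness a 4-sigma excursion).
* A mutation with no pileup row at all is treated as zero reads and routed
  through the fallback, not silently dropped.

# Incidence integration

`build_incidence_table()` combines a population registry rate per 100,000
with the cohort mutation frequency: `per100k_mut = rate x n_mut / n_total`,
and per cancer the male/female ratio of those rates. Two rendering rules
matter: all ratios are computed from **unrounded** intermediates (rounding
first demonstrably changes several 1-decimal cells), and rounding at the
rendering step (`render_incidence_table()`) is half-away-from-zero, which
matches how such tables are conventionally printed. Eligibility for the
four-cell analysis (`eligible_cancers()`) requires at least five patients
in each of female/male x mutant/wild-type; patients with unknown TP53
status count nowhere. Registry rates are consumed as given (they are
age-adjusted upstream); no additional standardisation is applied. Mapping
registry categories onto cohort cancer codes (e.g. head-and-neck vs oral
cavity and pharynx) is the caller's responsibility via the incidence table.

# Propensity scores and matching weights

Sex is not randomised: age, race, smoking and stage distributions differ
between male and female patients, and any of them can fake or mask a sex
effect. `fit_propensity()` models `P(male | covariates)` by logistic
regression **within each cancer type** (cohort composition is
disease-specific). Missing categorical values form an explicit
`"(missing)"` level; missing ages are median-imputed. The matching weight

```
w = min(e, 1 - e) / Pr(observed sex)     (e = fitted probability of male)
```

emulates 1:1 matching while keeping every subject: weights are bounded by
1, the minority-predicted group at a given `e` gets weight 1, and both
sexes attain 1 together only at `e = 0.5`. Relabelling the sexes maps
`e -> 1 - e` and leaves every weight unchanged.

`balance_loop()` checks weighted standardized mean differences (SMD:
weighted male mean minus weighted female mean over the pooled unweighted
SD) for every covariate **and for the square of every numeric covariate** —
first moments alone cannot see variance-only confounding, and the square
is exactly what the revision step can fix. The loop: iteration 1 fits main
effects; if any |SMD| ≥ 0.1 (the conventional balance criterion),
iteration 2 adds squared terms for the unbalanced numeric covariates,
iteration 3 adds pairwise interactions involving unbalanced covariates,
iteration 4 adds all squares; it stops when balanced or after `max_iter`
(default 5) rounds, and failure is flagged in the report and as a warning,
never silently. Model enrichment was chosen over trimming because it
preserves the sample and is reproducible. A revised model that overfits to
separation falls back to the last stable fit; complete separation of the
main-effects model (the fitted score perfectly classifies the sexes) is an
error pointing at the offending design, because no reweighting is
meaningful there. Individual fitted probabilities pinned near 0 or 1 are
tolerated — their matching weight goes to zero, which is the scheme
working as intended.

# Per-gene weighted tests, chi-scores and companions

For each gene with NEM/EM-classified mutations in both sexes,
`gene_nem_tests()` forms the 2x2 table sex x {NEM, EM} whose cells are
**sums of matching weights**, and computes the Pearson chi-squared
statistic on it (1 df). No continuity correction is applied — half-unit
corrections are meaningless for non-integer cells — and with unit weights
the statistic reduces exactly to the textbook chi-squared (tested to
1e-10). Genes with mutations in one sex only, or with a zero weighted
margin, are untestable and are excluded before Benjamini–Hochberg
adjustment, so the BH family is exactly the testable genes of the
analysis. The chi-score is the signed square root of the statistic,
positive when the weighted female NEM proportion exceeds the male one;
under per-gene nulls these scores are asymptotically standard normal,
which the acceptance checks verify empirically (mean within ±0.1, SD
within [0.9, 1.1] over 2000 null genes). `set_vs_rest()` compares the
chi-scores of a designated gene set against the remaining genes with a
two-sided Wilcoxon rank-sum test.

The burden model (`burden_model()`) is a weighted Poisson log-linear
regression of per-patient mutation counts on sex (male reference), with a
Wald 95% CI on the female/male rate ratio; patients with zero qualifying
mutations are kept as explicit zeros. The logit-scale RMAF comparison
(`rmaf_sex_compare()`) regresses `logit(RMAF)` on sex with cancer-type
adjustment, clipping RMAF to `[0.01, 0.99]` so fully silenced (0) and
fully expressed (1) mutations stay finite; the clip bound is a tuning
constant, and with mass at the boundaries the coefficient should be read
as a direction-and-significance summary rather than a calibrated effect
size. `size_nem_correlation()` is the Pearson correlation of per-gene NEM
counts with gene length — the check that NEM accumulation is not simply a
gene-size artefact of random Xi.

Whether per-gene tests should pool cancer types or stratify is a genuinely
open design point; the package pools by default (weights already absorb
cohort composition) and the per-cancer route is available by subsetting
the records before testing.

# Survival

`survival_by_tp53()` and `survival_by_expression()` wrap Kaplan–Meier
estimation and the two-group log-rank test (via the survival package) with
the package's stratification rules: follow-up truncated at a configurable
horizon (14 years for TP53-status contrasts, 10 for expression splits, the
two windows such analyses conventionally use), expression splits at the
median with ties assigned to the bottom stratum (deterministic and
order-independent), run within each cancer type by default because
expression scales are cancer-specific. No propensity weighting is applied
inside survival analyses. Cox models and competing risks are out of scope.

# The synthetic cohort generator

`simulate_cohort()` produces every input the pipeline consumes, plus a
truth table, under a configurable design (`sim_config()`). What it
emulates, with defaults:

* **Cancer panel**: 13 non-reproductive cancer types with sex-specific
  TP53 mutation probabilities and per-100,000 incidence taken from the
  bundled registry/cohort input table.
* **Mutation burden**: per-patient Poisson counts; X chromosome mean 4
  (female) vs 2 (male) — the twofold copy-number expectation at a
  realistic per-patient scale — and autosomes 60.9 vs 60 (rate ratio
  1.015, the near-parity whole-exome regime). Mutations land on genes
  proportional to length.
* **Xi**: each non-escape female X mutation is silenced with probability
  0.5 (random inactivation); 15% of X genes escape and express both
  copies, the mutated one contributing half the mRNA. Xi is simulated
  per-mutation, not as a cellular mosaic: bulk sequencing of a clonal
  tumour effectively fixes one active copy per locus.
* **Reads**: negative-binomial depth (mean 50, size 5 — overdispersed like
  real RNA coverage), binomial mutant reads at the state's expression
  fraction (1 for male/active-copy, 0.5 for escape heterozygotes, 0 for
  silenced). A 2% per-mutation knockdown probability abolishes the gene's
  expression in that sample (zero reads, zeroed count column), exercising
  the z-score fallback. 5% of genes are not expressed at all, exercising
  the discard rule; 10% of simulated mutations carry non-functional
  variant classes, exercising the class filter.
* **Confounding**: male age shifted +2 years, male smoking log-odds +0.8;
  race and stage balanced. **Survival**: exponential, wild-type median 5
  years, TP53-mutant hazard ratio 1.6, 5%/year dropout, 14-year horizon.
* A fixed `seed` makes the bundle byte-identical across runs.

What it deliberately does **not** emulate: mutational signatures, copy
number, tumour purity gradients, skewed Xi distributions (the silencing
probability is a knob, not a biological claim), or per-cell mosaicism.
Passing tests on this generator therefore demonstrate that the pipeline's
rules and statistics recover known structure under the stated model — not
that real tumour data satisfy that model.

# Problem sizes and recovery conditions

The test-suite and acceptance-script simulations use: a 2002-patient
cohort (77 per cancer per sex) for parameter recovery, with read depth
raised to mean 100 and the escape channel switched off so that the
female NEM fraction isolates the Xi silencing probability (with escape
genes on, escape-gene mutations are intermediate at deep coverage and the
silenced fraction among classified mutations is (1 − escape) x 0.5 by
construction); 2000 null genes for type-I and chi-score calibration with
weights drawn from a balance-looped null cohort of 400; 100 replicates of
561 null genes for the BH false-discovery check; and a 200-mutation
constructed fixture, scored rule-by-rule against a literal independent
re-derivation, for RMAF rule fidelity. These sizes give Monte-Carlo
standard errors comfortably inside the asserted bands.

# Interface notes and limitations

The package is function-first: tibble-in/tibble-out functions that chain
with the pipe, `tidy()`/`glance()` accessors on fitted objects and
`autoplot()`/`plot_*()` for figures are the interface; file I/O is
TSV-based (`read_clinical()`, `read_mutations()`, `read_pileups()`,
`read_counts()`, `read_incidence()`, `write_cohort()`). BAM pileup
extraction is intentionally outside the core — the pileup table is the
contract. Known limitations: RMAF is not corrected for tumour purity or
copy number (the asymmetric 0.2/0.75 thresholds absorb some of both);
pseudoautosomal genes are not treated specially (callers can exclude them
from the mutation table if desired); the weighted chi-squared relies on
asymptotic calibration, which degrades for genes with very few mutations
or highly variable weights; and the balance loop's revision vocabulary
(squares and pairwise interactions) cannot fix every conceivable
imbalance — it flags what it cannot balance.
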