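---
title: "Methods: cohort-specific genomic features and their integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohort-specific genomic features and their integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(her2landscape)
```

This vignette is the package's own account of its models and the choices
behind them: what each stage assumes, which tunable parameters matter and
why their defaults are what they are, what the synthetic-data generators do
and do not emulate, and where the known limitations lie. No empirical claim
is made here beyond what the test suite and the acceptance script compute.

## Study design assumed throughout

The pipeline targets a four-cohort bulk RNA-seq survey panel — benign
breast lesions plus ER+, triple-negative and HER2-positive tumors — with a
default of 8 samples per group, and asks which genomic features are
specific to one target cohort (HER2 by convention, but any label works).
Three feature channels are extracted independently and then integrated:
mRNA abundance, isoform usage, and expressed single-nucleotide variants.

## Expression: normalization, filtering, and the DTK caller

**Mode normalization.** Sample scale factors are estimated as 2 raised to
the kernel-density mode (Gaussian kernel, Silverman's rule-of-thumb
bandwidth) of per-gene `log2(sample / reference)` ratios, where the
reference is the per-gene geometric mean over samples with nonzero counts.
The mode, unlike the mean or median of ratios, is insensitive to an
asymmetric tail of genuinely regulated genes, which is exactly the
contamination expected between tumor cohorts. Factors are reported relative
to the median sample: the typical sample keeps scale 1, a globally doubled
library gets a factor near 2, and re-normalizing an already-normalized
matrix returns factors near 1 (idempotence). The mode of a skewed count
distribution is a slowly converging estimator; recovery of planted global
scalings to within 5% is reliable from roughly a thousand shared genes
upward, which any genome-wide count matrix exceeds. Whether the original
procedure used a pooled reference or a designated reference sample is not
something we could determine; the pooled-geometric-mean variant is
implemented, documented, and tested for scale recovery only.

**Detection filter.** Genes are kept when their within-group median raw
count is strictly greater than 16 reads in at least one group. Counts at or
below that depth sit near the detection limit, where log-scale variance is
dominated by shot noise rather than biology.

**The DTK comparison.** All pairwise group contrasts on `log2(x + 1)`
values use the unequal-variance, unequal-n form: standard error
`sqrt(s1^2/n1 + s2^2/n2)`, Welch–Satterthwaite degrees of freedom, and the
statistic `q = sqrt(2) |m1 - m2| / se` referred to the studentized range
distribution with k means, which controls the family-wise error over all
pairs. The tail is evaluated with R's `ptukey`; for k = 2 the identity with
the two-sided t tail is used directly because the t CDF is more accurate
deep in the tail (`ptukey` is good to about 1e-8 absolute, which is also
the agreement limit asserted for algebraically identical inputs). Pairs
with zero variance in both groups take p = 1 when the means are equal and
p = 0 otherwise — a documented convention, not a statistical claim.

**The conjunction rule.** A gene is cohort-specific when *all* k−1
target-vs-other comparisons reach p < α (default 0.05). The direction of
the target-vs-rest mean difference is reported but no direction consistency
is required across the three comparisons; the conjunction alone already
drives the empirical null rate far below α (each comparison must fail
simultaneously), which the suite verifies.

## Splicing: isoform ratios

Relative isoform abundance is `isoform count / gene isoform total` per
sample; genes qualify when expressed (the same group-median filter as
above) and multi-isoform. Ratios are compared with the identical DTK
machinery, untransformed: the comparison is on the proportion scale, where
boundary-heavy distributions are possible — users with ratios piling at 0
or 1 should interpret p-values cautiously. Samples where a gene has zero
total are treated as missing and dropped per transcript; the unequal group
sizes this creates are exactly what the Welch-type comparison tolerates,
and transcripts left with fewer than two observations in any group are
skipped and recorded. For two-isoform genes the two ratio tracks are
complements, so their test statistics are identical by algebra — asserted
in the suite to the tail-accuracy limit. The `> 16` expression gate for
splicing is interpreted as the expression module's group-median rule, for
consistency across modules, since a per-sample reading is equally
compatible with the verbal description.

## The eSNV workflow

The caller consumes per-sample pileup summaries from two independent
aligners. All filters are conjunctive predicates recorded per site, so the
final call set is order-invariant and every rejection is attributable:

1. **Candidate**: total depth ≥ 4, alternate ratio ≥ 0.1; high confidence
   at ≥ 4 alternate reads. Validation data behind this threshold show a
   false-detection rate near 5% at ≥ 4 alternate reads, with 2–3 read
   sites retained only as low-confidence recurrence evidence.
2. **Consensus**: same position and alternate allele in both aligners.
3. **Strand balance** (from the second aligner's stranded counts): both
   strands represented and min/max strand ratio > 0.1. The direction of
   the published ratio is ambiguous, so the symmetric min/max form is used.
4. **Annotation**: only missense, stopgain and stoploss variants continue.
   Codon lookup walks the refFlat exon structure (0-based half-open,
   converted internally; pileup and VCF coordinates are 1-based), reverse
   complementing minus-strand transcripts, with the standard genetic code.
5. **Known sites**: allele-aware removal against any number of
   known-variant lists; position-only matching is available behind a flag
   because site databases often store positions, not alleles.
6. **End bias**: a variant fails when *every* alternate read sits within
   E = 5 bases of its read's nearer end. The window is configurable; 5
   bases was chosen as one tenth of the 50 nt read length, and sites with
   no offset information pass with a flag rather than fail silently.

Probabilistic genotype calling is deliberately replaced by these
deterministic thresholds: at the depths where genotype models disagree
with thresholds, the depth and ratio filters dominate the decision anyway,
and thresholds are auditable. Mapping-quality filtering is attributed to
upstream pileup generation. Cohort exclusivity uses emitted
(post-threshold, all-filters) calls: low-confidence evidence in another
cohort does not veto a variant, a documented default with both modes
available, since a 2-read trace in another sample is as likely artifact as
signal.

## Network integration

Candidate genes (upper-cased symbols) are the union of the three feature
channels; all seven Venn regions are reported. The interactome model is
the induced subgraph on candidate–candidate edges only — linker genes,
which interaction databases insert to connect candidates, are excluded so
that the node and edge counts measure *direct* connectivity. Integration
is quantified against draws of equal size from the expressed-gene universe
(20 draws by default, matching the scale of the published simulation;
sample SD with n−1). The draw universe defaults to the expressed universe
rather than all annotated genes because candidate lists are themselves
drawn from expressed genes. Modules come from Louvain modularity
maximization at resolution 1 with a fixed seed; the original clustering
algorithm behind the published module count is unnamed, so the module
count is reported but never asserted. Pathway enrichment is the one-sided
(greater) Fisher exact test on `[[m, N−m], [P−m, G−N−P+m]]`, identical to
the hypergeometric upper tail; for the published table's inputs the
two-sided test coincides numerically, and the one-sided form is the
enrichment question being asked.

## Association layers

**Drug response.** Spearman rank correlation (midranks) with the two-sided
t approximation on n−2 df; an exact permutation p is available for n ≤ 8.
Rank correlation is invariant to monotone transforms, so correlating
against EC50 or log-EC50 is the same test. The Monte Carlo panel null
draws random gene panels of the observed size and asks how often at least
the observed number of genes are simultaneously response-correlated at
p < 0.05 and annotated to a single shared process term.

**Survival.** Each gene's score is the Cox partial-likelihood score
statistic at β = 0 (Breslow tie handling), `U / sqrt(I)`, positive when
higher expression accompanies higher hazard. The maxmean set statistic
takes the larger in magnitude of the mean positive part and mean negative
part of member-gene scores, after restandardizing gene scores against the
whole scored catalogue; significance and FDR come from permuting patient
outcome (time, event) pairs and recomputing everything downstream. Note
the sign convention: here a *positive* set score means association with
shorter time to event; published tables sometimes label increased risk as
negative, so compare directions, not raw signs. Restandardization has a
known side effect worth remembering: a very strong signal set shifts the
catalogue mean and can drag unassociated sets slightly off-null; a large
unassociated background dilutes this.

## What the generators emulate — and what they do not

Every input format the pipeline reads can be generated with planted
truth: negative-binomial counts with HER2-only log2 shifts, multinomial
isoform splits (isoform counts sum exactly to gene counts) with
proportion switches, paired pileups in the classic samtools text dialect
with an extra per-read offset column, a toy genome and two-exon refFlat
gene models with codon-exact consequences, stochastic-block-model
interaction graphs with community-aligned gene sets and decoys, and EC50 /
survival tables driven by designated gene modules. Truth files are
side-cars that no pipeline stage reads.

Deliberate generator design choices:

- **Dispersion.** A single global negative-binomial dispersion, default
  0.15. This is the calibrated operating point at which the
  all-three-pairs caller recovers 4-fold planted shifts at n = 8 per group
  with ≥ 90% sensitivity; at dispersion 0.3 the intrinsic power of that
  rule is about 0.88, so recovery guarantees would fail for reasons
  unrelated to implementation. Real tumor cohorts are often more
  dispersed — the generator models a well-matched panel, not worst-case
  heterogeneity.
- **Depth-adequate planting.** Differential genes are planted among genes
  with baseline mean ≥ 64 reads: a 4-fold down-shift of a gene near the
  16-read detection floor lands below the filter and is not a recoverable
  signal by construction.
- **Callability conditioning.** Clean somatic variants are emitted with
  alternating read strands and at least one alternate read ≥ 5 bases from
  both read ends, so the strand and end-bias filters cannot remove a true
  positive by sampling accident. Artifact classes are each constructed to
  fail exactly one filter: one-strand alternate reads, all-terminal
  alternate reads, total depth 3, or presence in the known-sites list plus
  all cohorts.

What passing tests on these data do **not** show: robustness to
gene-length or GC biases, batch effects, isoform-assignment uncertainty
(isoform counts are treated as given, as from an upstream EM quantifier),
alignment errors beyond the modeled artifact classes, indels, linked
variants, or real interactome topology (a stochastic block model is far
more regular than a curated pathway network). Conclusions about real data
rest on the filters' published validation, not on these simulations.

## Numerical choices and degenerate inputs

- Studentized-range tails via `ptukey` (about 1e-8 absolute accuracy);
  exact t-identity at k = 2; `qtukey` for simultaneous intervals.
- Zero-variance DTK pairs: p = 1 (equal means) or 0 (unequal), flagged by
  `se = 0`.
- Lexicographic tie-break for equally supported alternate alleles.
- Known-variant matching allele-aware by default.
- `sd = 0` null draws report z = 0 when the observation equals the mean
  and ±Inf otherwise.
- Transcripts whose CDS length is not a multiple of 3 are skipped with a
  warning rather than annotated in a broken frame.
- All generators are deterministic given `seed`; identical configurations
  produce byte-identical files.

## Problem sizes used in the shipped suites

The test and acceptance suites run at deliberately scaled sizes chosen as
the smallest that exercise each property convincingly: 200–400 gene count
matrices, 12–20 planted variants per replicate across 32 samples, 50
replicates for the variant-calling and gene-set power suites, 99–200
outcome permutations per gene-set run, 300-gene interaction graphs with
five 30-gene communities, and exhaustive enumeration oracles up to
universe size 12 (enrichment) and 9–10 nodes (network null). These are
package choices; every threshold asserted (sensitivity ≥ 0.9, precision
and recall 1.0, ARI ≥ 0.9, type-I ≤ α) is stated in the corresponding
test.

## Known limitations

- The mode normalizer assumes most genes are unregulated between samples;
  it will mis-scale a sample in which the majority of the transcriptome
  shifts.
- The DTK caller tests mean differences on log2(x+1); it fits no
  count-model dispersion and is not a substitute for negative-binomial
  GLMs when per-gene dispersion estimation matters.
- The eSNV caller emits substitutions only — no indels, no base-quality
  recalibration, and no somatic/germline classification without a matched
  normal; exclusivity across cohorts is evidence, not proof, of somatic
  origin.
- Module identity from Louvain clustering is resolution- and
  seed-dependent in near-degenerate graphs; module *recovery* is asserted
  only on planted structure.
- The maxmean permutation test permutes whole outcome vectors and so
  assumes exchangeable patients; stratified designs need a stratified
  permutation scheme that is not implemented.
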