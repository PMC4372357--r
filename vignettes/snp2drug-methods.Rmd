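---
title: "snp2drug: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{snp2drug: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snp2drug)
```

## The problem and the model

A GWAS risk locus is a statistical signal, not a gene. `snp2drug`
implements a pragmatic evidence-integration model: every candidate gene
at a locus is scored against seven independent-ish binary criteria, the
criterion count (0–7) is the gene score, and genes with score ≥ 2 are
declared *biological risk genes*. The model makes three assumptions
worth stating plainly:

* **Criteria are unweighted.** A missense variant and a text-mining hit
  contribute equally. This is deliberate: the score is a transparent
  evidence count, not a calibrated probability, and the package offers
  no weighting precisely because any weights would be arbitrary.
  `criterionCorrelation()` exists so users can check on their own data
  that the criteria are weakly correlated, which is what makes an
  unweighted sum defensible.
* **Upstream tools are oracles.** Text-mining relatedness and
  PPI-seed connectivity scores (and the variant annotation, eQTL
  mapping, somatic and knockout-phenotype catalogues) are consumed as
  pre-computed tables, never re-derived. The interface is the table.
* **Gene identity is the upper-cased symbol.** No identifier mapping is
  attempted; inputs must already agree on symbols.

### Candidate mapping

The locus of a lead SNP is the span of the lead plus all LD proxies with
r² strictly above the threshold (default 0.80), optionally flanked.
Candidates are genes whose bodies intersect that span, always unioned
with the nearest gene, so a gene-poor locus still yields one candidate.
Distance is to the gene-body edge, not the TSS, and strand is ignored —
the simplest defensible proximity notion, and the one that needs no
annotation beyond gene coordinates. Ties (equidistant genes) break to
the smaller start coordinate, then the lexicographically smaller symbol,
so results are reproducible across input orderings.

### The seven criteria

All significance thresholds are strict (`<`); a p-value of exactly 0.05,
an FDR of exactly 0.50, an r² of exactly 0.80, a distance of exactly
250 kb all fail. Boundary behaviour is pinned by tests.

1. **Missense** — the lead or any qualifying proxy carries a missense
   consequence annotated to *this* gene.
2. **cis-eQTL** — a row links the lead to the gene with FDR < 0.50,
   p < 0.0016 and SNP–probe distance < 250 kb. When the lead is absent
   from the eQTL table entirely, the qualifying proxy with the highest
   r² that is present substitutes for it (r² ties break to the smaller
   distance). Absence after substitution scores 0, never an error.
3./4. **Text-mining / PPI-seed p-values** — gene present with p < 0.05.
5. **Somatic catalogue membership** — case-insensitive set membership.
6./7. **Knockout-phenotype / functional-term enrichment** — the gene
   belongs to at least one category whose overlap with the whole
   candidate set is significant (hypergeometric upper tail, p < 0.05).
   This "member of an enriched category" reading is the only
   operationalization consistent with reporting category-level
   enrichment but gene-level indicators; it also means criteria 6–7 are
   the one place where rows are not independent — the enrichment is
   computed once over the candidate set and shared by all rows.

An EASE-style conservative variant (the observed overlap reduced by one
before the tail) is available behind `easeAdjust`, default off: the
plain hypergeometric tail is the stated test, the EASE variant a
robustness option.

### The exact hypergeometric engine

`hypergeomUpperTail(N, K, n, k)` evaluates P(X ≥ k) exactly, in log
space (`lchoose` terms accumulated by log-sum-exp), never via normal or
binomial approximation: the drug-overlap tail of interest is of order
1e-5 at N ≈ 1.1e4, where approximations visibly drift. `k = 0` returns
exactly 1 by definition. The engine is pinned against brute-force pmf
enumeration for every valid (N ≤ 60, K, n, k) at 1e-12 tolerance, and
against `stats::phyper` implicitly through those sweeps (the tests use
plain `choose()` arithmetic as the oracle so the check is independent of
any library tail implementation).

The universe size N is an explicit argument everywhere. It is a property
of the interaction-network snapshot, not derivable from the other
tables, so the bundle stores it (`geneUniverseN`, defaulting to the PPI
node count — the most conservative derivable value). Consequently the
package does not claim to reproduce enrichment p-values whose universe
was never published; it reproduces the ones whose full (N, K, n, k) is
known.

### Drug-target overlap

Biological risk genes are expanded exactly one hop through the PPI
network into the set *x* (seeds missing from the network stay in *x*).
Overlaps with the approved-disease-drug target set *y* and the all-drug
target set *z* are scored by fold (k/(Kn/N)) and the exact tail; the
relative fold (k_y/K_y)/(k_z/K_z) compares the two hit rates, with a
one-sided Fisher test as the comparison p. Published folds are printed
truncated to two decimals, so tests accept a value in [printed,
printed + 0.01). The packaged overlap fixture uses |x| = 584 — the
31 + 553 decomposition — because that is the only cardinality consistent
with the published 12.09/1.55/7.78/1.78e-5 arithmetic at N = 11303; with
it, the exact tail also reproduces the published 1.2e-4 for the 70/871
overlap. Connection paths (SNP → risk gene → interacting gene → drug)
are de-duplicated on (risk gene, interactor, drug) and ordered
lexicographically for reproducible export.

### Chromatin permutation test

Per cell type, the statistic is the number of loci with at least one
member SNP (lead or qualifying proxy) inside a peak, each locus counted
once. The null samples positions uniformly without replacement from a
user-supplied SNP universe. The published analysis does not specify the
null's matching, so the default is the simplest defensible one — one
position per locus — with `matchLocusSize` sampling as many positions
per null locus as the observed locus has members. The size-matched null
is the right choice whenever loci carry several proxies: a multi-SNP
locus has a mechanically higher chance of touching a peak, and the
single-position null then overstates enrichment in *every* cell type.
The p estimator is add-one, p = (1 + #{null ≥ obs})/(1 + iterations), so
p ∈ (0, 1] and never exactly 0. Each cell type's seed derives from the
global seed and the cell-type name, so results are independent of scan
order and of which other cell types are present.

## The synthetic-data generator

`simulateBundle()` works top-down: it first draws the 7-column indicator
matrix it wants the pipeline to recover — planted genes succeed at
`elevatedRate`, all others at per-criterion background rates — and then
builds every resource table by inverse construction so evidence
evaluation reproduces the drawn matrix exactly. This inverse
construction is the evidence module's primary correctness harness: a
recovery mismatch is a pipeline bug, not simulation noise. For the
enrichment criteria the flagged candidates are placed in one category
(plus non-candidate filler trimmed until the category tests significant)
and background categories contain non-candidate genes only; when too few
genes are flagged for any category to reach significance, the flags are
retracted to 0 so truth and bundle stay consistent.

Defaults are the study conditions the pipeline was designed around: 50
risk loci over a 2000-gene universe with about 2.8 candidate genes per
locus (≈140 SNP–gene pairs), 35 planted genes at success rate 0.7,
background criterion rates (0.014, 0.09, 0.17, 0.014, 0.04, 0.18, 0.15)
chosen so realized per-criterion hit counts are of the order reported
for a 140-pair analysis, 34 chromatin cell types with the first one
enriched (80% of loci covered vs 5% background coverage), an
Erdős–Rényi PPI background (edge probability 0.002) plus planted links
(probability 0.5) between planted genes and the 8 disease-approved
targets among 150 drug targets. Loci are disjoint runs of consecutive
genes bracketed by r² = 0.95/0.90 proxies (plus an r² = 0.5 decoy), so
locus mapping recovers exactly the run. Chromosomes are abstract
(`chrS1`…); no genome build is referenced.

What the generator does **not** emulate — and therefore what passing
tests do not show about real data: realistic LD structure or allele
frequencies (proxies are placed, not sampled from haplotypes), gene
length and density variation, correlated criteria (real annotation
sources share ascertainment biases), overlapping loci that share genes,
and expression-level noise behind the eQTL table. Recovery being exact
on synthetic bundles demonstrates the arithmetic is implemented
correctly, not that the seven criteria identify causal genes.

`nullBundle()` switches every planted effect off (no planted genes, no
planted drug links, enriched coverage lowered to background) for
type-I-error and calibration checks. The drug-overlap null check asserts
type-I *control* (the rejection fraction does not exceed the nominal
level plus sampling slack) rather than two-sided calibration, because a
discrete hypergeometric test is conservative by construction.

## Numerical and testing choices

* **Coordinates.** Intervals live in `GRanges` (1-based, closed); BED
  input/output (0-based, half-open) and 1-based point positions are
  converted at the I/O boundary only, and interval arithmetic is
  delegated to IRanges. A fixed conversion battery pins the convention.
* **Determinism.** One global seed; every stochastic stage derives its
  own seed from it and a string label via a small rolling hash kept
  below 2^31. Same seed ⇒ bit-identical outputs, verified down to file
  digests.
* **Degenerate inputs.** Empty pair lists, empty peak sets, empty drug
  tables, absent score classes and zero-variance criterion columns all
  return typed empty/NA-flagged results rather than errors; undefined
  correlations are reported as missing, never as 0.
* **Calibration test sizes.** The permutation-uniformity check uses 200
  replicates of 600 single-SNP null loci at 2000 iterations: with ~5%
  peak coverage the null statistic then has fine-grained support, which
  a Kolmogorov–Smirnov comparison against the *continuous* uniform
  requires (with few loci the add-one p-value is too discrete for KS to
  be meaningful). Planted-recovery checks run 20 generator seeds at the
  default scale; the hypergeometric sweep covers every instance up to
  N = 60.
* **The score threshold is ≥ 2**, inclusive: the published table of
  biological genes contains score-2 rows, which settles the
  inclusive/exclusive ambiguity in the surrounding prose. The
  nearest-gene flag never contributes to the score; the published rows
  sum correctly without it.

## Known limitations

* The seven-criterion score is a heuristic evidence count; it has no
  calibrated error rate and the package deliberately does not attach
  one.
* Criteria 6–7 couple rows through the shared enrichment step, so
  adding candidates can flip other rows' indicators in either
  direction; the monotonicity guarantee ("more resource rows never
  lower an indicator") holds for criteria 1–5 only.
* The permutation null does not match allele frequency or distance to
  TSS; `matchLocusSize` is the only matching offered.
* One printed evidence row (SYNJ2) has a missing indicator cell in the
  source table; it is transcribed with the missing cell as 0 (any
  placement is consistent with its printed score) and flagged
  `ambiguous` in the fixture.
* The published risk-SNP table prints 64 rows containing 51 distinct
  rsids, while its surrounding text says 50; the package reports counts
  computed from the table and asserts no headline total.
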