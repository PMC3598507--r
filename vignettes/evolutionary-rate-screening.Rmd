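---
title: "Evolutionary-rate screening of drug targets: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary-rate screening of drug targets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evorate)
```

## The scientific question and the model

Antibacterial drug targets are hypothesized to sit under unusually strong
purifying selection: most mutations in them — including many that would
confer resistance — are deleterious and are removed from the population.
If true, the evolutionary rate of a gene is a usable drugability score,
and it should separate three mutually exclusive gene sets within a
genome: approved drug targets (ADT), experimentally essential non-targets
(ESS), and the background (ALL), in the order ADT < ESS < ALL.

`evorate` measures rate two ways, both *counting* statistics on codon
alignments:

* **pN/pS** on clusters of conspecific strain sequences: the ratio of
  nonsynonymous to synonymous polymorphism counts. It deliberately omits
  normalization by the number of possible mutation sites — it is a
  within-species diversity contrast, not an absolute rate — so its neutral
  expectation is the mutational-opportunity ratio (around 3 for a typical
  gene), not 1.
* **dN/dS (omega)** on sequence pairs, Nei–Gojobori (1986) counting with
  site normalization and the Jukes–Cantor multiple-hit correction. Its
  neutral expectation is 1, and on simulated data its per-class means land
  close to the configured acceptance rates.

pN/pS is the primary statistic: for closely related strains almost all
observed variants are segregating polymorphisms, and it is robust to the
recombination and saturation artefacts that bias dN/dS. dN/dS is the
supplementary cross-check — it only counts fixed differences, which makes
it robust to the opposite confounder, diversity loss under drug-driven
selective sweeps.

## Mutation classification

The unit operation is classifying a codon difference into (possibly
fractional) nonsynonymous and synonymous counts. For a single-position
difference the amino-acid comparison decides directly. For 2–3 differing
positions, all `k!` orderings of the single-base steps are enumerated;
orderings that pass through a stop codon at an intermediate step are
discarded and the N/S step counts are averaged over the remainder. If
*every* ordering transits a stop, all orderings are used, with steps into
or out of a stop counted as nonsynonymous — a documented fallback that
keeps the operation total on sense-codon pairs. The counts always sum to
the Hamming distance of the pair. The test suite compares this operation
against an independently coded brute-force enumerator on all 61 × 61
sense-codon pairs.

## Column filtering and multi-row clusters

Codon columns containing a gap, an `N`, or a stop codon in any row are
wholly excluded before counting (`n_codons_used` reports what survives).
This avoids frame ambiguity at the cost of discarding some signal; it is
applied identically to both statistics so their gene sets match.

Most strain clusters are pairs. For clusters with more rows, pN/pS uses
*allele counting*: identical row sequences are collapsed first, the
per-column base state is the majority codon among the distinct sequences
(ties resolved to the reference row's codon), and each distinct non-base
codon contributes one classified variant. Collapsing duplicates before
taking the majority is a deliberate choice: it makes the estimate exactly
invariant to duplicating any row (an allele's multiplicity carries no
information here), which a raw row-multiplicity majority would violate.

The divergence estimator is strictly pairwise; in pipelines over larger
clusters it uses the reference row against the first other row.

## Corrections and degenerate inputs

* **pS → 1**: genes of closely related strains frequently show only
  nonsynonymous variants. With `s_count == 0` the ratio is formed over a
  denominator of 1 and flagged `s_corrected`; no division by zero can
  occur anywhere in a run.
* **dS = 0** in dN/dS is handled in the same spirit: the reported ratio is
  the *uncorrected* nonsynonymous proportion `pN*` over 1, flagged.
* **Saturation**: a difference proportion at or beyond 3/4 has no
  Jukes–Cantor correction; the estimate is marked unusable.
* **No polymorphism / no retained columns**: zero counts, marked unusable;
  unusable genes are excluded from tests, ranking and enrichment, and the
  per-reason exclusion counts surface in the pipeline's provenance block
  so the filtering is auditable.
* **Recombination**: a four-gamete screen over all pairs of biallelic
  nucleotide sites flags genes (any violating pair) for exclusion from
  dN/dS summaries only. With fewer than four rows the screen is vacuous
  and reports no violation.

## Group testing

`partition_genes` gives drug-target status precedence (an essential target
is ADT), removes targets from ESS and both from ALL; the pairwise
Mann–Whitney U tests then compare disjoint sets, avoiding the bias of
testing overlapping groups. The U test delegates to `wilcox.test`: exact
null distribution when both samples have < 50 observations and no ties,
otherwise the normal approximation with tie and continuity correction.
The Benjamini–Yekutieli step-up (valid under arbitrary dependence) is
applied across the whole family of hypotheses — the three tests of a
single-species run, or all species' tests jointly in a multi-species
design. Set means carry 95% percentile bootstrap CIs (default 2000
resamples under the run seed); the CI method is this package's choice, as
box-plot-of-means displays rarely state theirs.

## Ranking, KO groups, study-set selection

Percentiles use `100 * midrank / n` — with ~10³ genes any standard
convention shifts a gene by under one percentile, so the simplest
tie-stable one is used. Integer ranks break ties by gene id to stay a
permutation. KO orthology groups are summarized by mean and *sample* SD of
per-genome ratios over contributing genomes only, with SD fixed at 0 for
single-contributor groups, and are reported slowest-first. The GO study
set is the `floor(fraction * n)` slowest genes (default fraction 0.10);
flooring is conservative, and boundary ties resolve by gene id for
reproducibility.

## GO enrichment

Annotations are closed upward through `is_a` and `part_of` edges only —
standard practice for molecular-function annotation of the era the
pipeline emulates. Enrichment is term-for-term: per term a one-sided
hypergeometric tail `P(X >= study_count)`, raw p reported as the headline
column (the convention of term-for-term tools), with a Benjamini–Hochberg
column alongside since GO terms are strongly dependent. Genes lacking any
annotation stay in the denominators by default (`annotated_only = FALSE`),
reflecting that only part of a genome carries GO terms; the flag exposes
the stricter convention.

## Orthology resolution

Where a cluster carries more than one candidate ortholog per genome, the
one-to-one resolution mimics reciprocal best BLAST hits with a
deterministic scorer: Needleman–Wunsch global protein alignment under
BLOSUM62 with affine gaps (opening 10, extension 0.5). A member is kept if
it is the reference member's best hit within its genome *and* the
reference member is its best hit among all members outside its genome;
score ties break lexicographically by gene id, and genomes failing
reciprocity are dropped rather than guessed — conservative one-to-one
orthology. Tests check the decision against brute-force all-pairs best-hit
enumeration on small clusters.

## The synthetic-data generator

The generator is first-class, tested code: it defines the conditions under
which the pipeline's inferential claims are verified.

* **Mechanism**: per gene a random ancestral CDS (ATG start, uniform sense
  codons); each strain sequence evolves independently from it (star
  topology — the closely-related-strains polymorphism setting, which also
  keeps four-gamete fixtures clean). Proposed substitutions number
  `Poisson(expected_subs_per_codon × n_codons)`, at uniform sites with
  uniform alternative bases, applied sequentially. Stop-creating proposals
  are rejected; synonymous proposals always accepted; nonsynonymous ones
  accepted with probability `min(1, omega)`. Acceptance thinning is the
  simplest mechanism that makes counted pN/pS approximately proportional
  to omega; the pipeline only needs ordinal recovery, not likelihood-exact
  codon dynamics.
* **Default conditions**: 35 drug targets, 300 essential, 1000 background
  genes (a bacterial genome scaled to desk size, preserving the order of
  magnitude of the set-size imbalance), omega 0.1/0.3/0.6, 300-codon
  genes, strain pairs, 0.2 proposed substitutions per codon per branch —
  enough polymorphism that almost every gene is usable.
* **GO layer**: a small molecular-function DAG (including a diamond for
  propagation tests) with `GO:0005198` designated the "slow" term; ~70% of
  genes get annotations, and constrained classes (ADT, ESS) receive the
  slow term with odds multiplied by `slow_term_enrichment` (default 8 — an
  odds ratio strong enough to be recoverable from a ~130-gene study set at
  a base rate of 0.08, comparable to the strong top terms of real
  term-for-term tables).
* **Ground truth**: exact accepted-mutation tallies per gene. In the
  single-hit regime (≤ 0.05 proposals per codon) these reconcile exactly
  with re-classified ancestor/derived differences, and the tests assert
  this.

What the generator does **not** emulate: indels and alignment error,
codon-usage and GC bias, recombination, demography and linkage,
shared phylogenetic structure among strains, and annotation noise. Passing
tests therefore certify the counting and inference machinery on clean
inputs, not robustness to real-data artefacts.

## Problem sizes and reproducibility

The test suite verifies exact oracles at full coverage where enumeration
is cheap (all sense-codon pairs; all Mann–Whitney layouts up to n = 10;
1000 random BY vectors; hypergeometric configurations to population 60)
and uses 20 seeded full-scale replicates (1335 genes each) for the
end-to-end ordering-recovery property. `scripts/acceptance.R` re-runs the
same computation from scratch; all randomness in the package flows from
explicit seeds, and identical configurations reproduce byte-identical
report tables (the provenance block records seed, configuration and
filter-step counts).

## Known limitations

* pN/pS is not comparable across genes with very different codon
  compositions (no opportunity normalization — by design).
* The dN/dS path trusts the four-gamete screen, which has no power against
  recombination leaving fewer than four sampled rows or non-biallelic
  traces.
* The multi-row majority-base rule summarizes a column by one base state;
  columns with three or more alleles contribute variants relative to that
  state only.
* The OBO parser covers the 1.2 subset the pipeline consumes (`is_a`,
  `relationship: part_of`, obsolescence); it is not a general ontology
  library.
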