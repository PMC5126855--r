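---
title: "Methods: boundary-aware trimming, panel QC, concordance and rule-based curation"
author: "panelcurate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: boundary-aware trimming, panel QC, concordance and rule-based curation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelcurate)
```

panelcurate implements the computational core of a targeted
disorders-of-sex-development (DSD) gene-panel diagnostic: trimming and QC
for amplicon (circularisation-chemistry) libraries, variant-callset
concordance, and a rule-based curation engine with cohort-level yield
aggregation. This vignette explains each method, its assumptions, the
tunable parameters, and the deliberate design decisions.

## Coordinate conventions

BED input and output are 0-based half-open; VCF positions are 1-based. All
in-memory intervals are `GRanges` (1-based, closed), the Bioconductor
convention, and conversion happens only at I/O boundaries. An amplicon
`[100, 220)` in BED becomes `101–220` in a `GRanges` and round-trips back
bit-exactly. Keeping a single in-memory convention (rather than carrying
0-based arithmetic through the code) avoids off-by-one drift and lets every
interval operation go through IRanges/GenomicRanges.

## Boundary-aware adapter trimming

Amplicon libraries produced by circularisation-based enrichment have a
property that general-purpose adapter trimmers cannot exploit: every read
begins exactly at one of the two termini of a known amplicon. If the read
is longer than its amplicon (length $L$), sequencing continues into ligated
adapter at offset exactly $L$. Generic adapter search must trade
over-trimming (cutting real bases that merely resemble adapter) against
under-trimming (retained adapter producing high-confidence false variant
calls); knowing the junction position removes the trade-off.

`buildBoundaryIndex()` stores, per amplicon, the first $k$ reference bases
(read-1 orientation) and the reverse complement of the last $k$ bases
(read-2 orientation), each mapped to the amplicon length. `trimRead()` then:

1. matches the read's first $k$ bases against the index (exact hash first,
   then a scan tolerating up to `maxMismatch` mismatches; `N` counts as a
   mismatch);
2. for each candidate amplicon length $L <$ read length, compares the read
   bases at offset $L$ against the adapter prefix over
   $\min(\text{adapterSpan}, \text{overhang})$ bases with the same mismatch
   tolerance;
3. trims to $L$ bases (sequence and qualities in lockstep) only if exactly
   one junction is adapter-consistent. Several consistent candidate
   junctions leave the read unassigned and untouched — false trimming
   destroys real bases, so the trimmer never cuts on ambiguous evidence. A
   boundary match without adapter evidence leaves the read untrimmed; no
   boundary match leaves it unassigned.

Defaults: $k = 12$, `maxMismatch = 1`, `adapterSpan = 10`. These are the
package's own calibration: $k = 12$ makes a chance terminus match on random
sequence rare ($4^{-12}$ per entry before mismatch tolerance) while staying
well below the shortest practical amplicon; one mismatch per comparison
window tolerates typical substitution error without materially raising the
chance-match probability, which for the adapter window is
$(1 + 3s)\,0.25^s \approx 3\times10^{-5}$ at $s = 10$. The test suite
checks this bound empirically on 10,000 adapter-free reads.

Mates are processed independently, each against the orientation it can
match; there is no mate rescue. Trimming is idempotent, outputs are always
prefixes of inputs, and on error-free simulated data with 50% planted
read-through the planted junction is recovered for ≥ 99% of reads (100% in
practice; with 1% substitution error and `maxMismatch = 2`, ≥ 95%).

What the simulator emulates — and does not. `simulatePanelReads()` plants
read-through by drawing reads from amplicons shorter than the read length
and appending adapter at the boundary; it models uniform substitution
error, uniform base composition, and collision-free terminal k-mers (a
guard that can be disabled by constructing collisions explicitly, as the
tests do). It does not model indels in reads, quality decay along the
read, chimeric amplicons, or the biased base composition of real panels;
passing tests demonstrate algorithmic correctness at the stated error
rates, not performance on any particular instrument's error profile.

## Panel QC metrics

`depthFromAlignments()` computes per-base depth over the target footprint
via `Rsamtools::pileup` (or from a per-base TSV). Every primary aligned
base counts once; there is deliberately **no deduplication**, because
amplicon reads legitimately share identical start/end positions ("towers")
and deduplication would collapse true coverage.

* `coverageCdf()` — fraction of targeted bases covered at ≥ each
  threshold; the median over an even base count is the lower central value
  (integer depths, deterministic).
* `uniformity()` — fraction of bases with depth ≥ `factor` × mean
  (default 0.5). Whole-genome-like low-dispersion tracks score higher than
  panel-like high-dispersion tracks; `factor = 0` is identically 1.
* `targetingEfficiency()` — read-level: reads overlapping any target by
  ≥ 1 bp over **all** reads (unmapped included in the denominator);
  base-level: aligned (M/=/X) bases inside targets over all aligned bases.
  Soft-clipped bases are not counted as aligned — they were not asserted
  against the reference. "Fragments" are interpreted as individual reads,
  not proper pairs.
* `ampliconFailureReport()` — reads are assigned to the amplicon whose
  interval contains the read start (ties to the leftmost amplicon), the
  natural assignment when reads start exactly at amplicon boundaries.
  Failure = zero assigned reads; consistency across samples is classified
  as `consistent` (all samples), `sporadic` (exactly one), `intermediate`,
  or `none`, and the four classes partition the design.
* `geneCoverageReport()` — per-gene fraction of targeted bases at ≥ 20×
  (the diagnostic-coverage convention). Genes without targeted bases are
  flagged rather than reported as 0, so a missing locus map entry cannot
  masquerade as a failed gene. Genes shadowed by high-homology pseudogenes
  (where multimapped reads are dropped upstream) show near-zero fractions
  and are flagged low.

All depth metrics are verified against a brute-force per-base oracle on
≤ 10 kb toy targets.

## Callset concordance

`normalizeVariants()` splits multi-allelic records, rejects `ref == alt`,
and canonicalises each allele pair: shared trailing bases are stripped
(extending left from the reference when an allele would empty, which
left-aligns indels through repeat tracts), then shared leading bases are
stripped. Two representations of the same indel therefore map to the same
`chrom:pos:ref:alt` key.

`matchCallsets()` compares normalized truth and query at allele level —
genotype agreement is **not** required, because the evaluated quantity is
variant-call sensitivity, not genotyping accuracy. INDELs with length
change ≥ 10 bp are excluded from both sides ("INDELs smaller than 10 bp",
read literally: the boundary value 10 is excluded), and the comparison can
be masked to confident regions. Reported quantities: sensitivity
$= TP/(TP+FN)$, false positive rate $= FP/(TP+FP) = 1 -$ precision, and a
ROC obtained by sweeping the observed query quality scores descending.
Haplotype-complex matching (the full vcfeval algorithm) is out of scope;
on synthetic and small real callsets left-align + trim suffices, and
representation mismatches on complex loci are a documented limitation.

The callset simulator plants `round(sens × n)` true positives and
`round(tp × fpr/(1−fpr))` false positives, with TP qualities ~ N(100, 10)
and FP qualities ~ N(30, 10) so true calls stochastically dominate. At
n = 1000, sensitivity 0.97 / FPR 0.02 is recovered exactly / within 0.005.
The published evaluation against reference-sample truth sets operates at
this same point, but reproducing those exact numbers requires
accession-scale external data; the synthetic recovery demonstrates the
comparison machinery, not the assay.

## Variant filtering and classification

Filters are conjunctive, order-independent, and every rule evaluated is
recorded in an audit trail:

| rule | fail condition | default |
|---|---|---|
| frequency (×3) | 1000 Genomes, ESP, or max ExAC subpopulation AF > `mafMax` | 0.01 |
| consequence | synonymous or other | — |
| recurrence | > `cohortRecurrenceMax` samples in one run or in the database | 15 |
| gene panel | gene not in the 64-gene registry | — |
| quality/depth | *flags* (does not fail) below `minQual`/`minDepth` | 30 / 10 |

Absent population frequencies pass (unobserved = novel). The quality gate
flags for manual review instead of auto-failing because low-quality calls
in the source workflow went to visual inspection and orthogonal validation
rather than being discarded; `filterVariant()` records the flag in the
trail so downstream consumers can enforce a stricter policy.

Inheritance: singletons are never discarded for inheritance — genotype
alone supports models (hom/hemi → recessive/X-linked, het → dominant) and
parental data are unavailable. With trio genotypes the supported models are
derived (de novo; inherited dominant; recessive homozygote with both
parents carriers; X-linked; compound heterozygote when two heterozygous
variants in the same gene arrive on opposite parental origins) and a
variant is dropped when no supported model intersects the gene's
inheritance modes — e.g. a single heterozygous variant in a recessive-only
gene inherited from one healthy parent. This asymmetry is why singleton
cohorts accumulate more VUS than trios.

Classification (first match wins):

1. androgen-receptor CAG/GGN repeat-tract change → **VUS-3** (repeat
   lengths are not reliably genotyped from short amplicon reads);
2. null variant (frameshift, stop gain, splice site) in a gene with a
   known loss-of-function mechanism, phenotype fits → **pathogenic**;
3. missense previously reported in a patient with a similar phenotype →
   **pathogenic**;
4. novel missense, phenotype fit, consistent inheritance, ≥ `t` of 4
   in-silico predictors (SIFT, PolyPhen2, LRT, MutationTaster) damaging →
   **likely pathogenic**;
5. phenotype fit, damaging support < `t` → **VUS-1**;
6. damaging support ≥ `t`, phenotype mismatch → **VUS-2**;
7. otherwise **VUS-1**.

The damaging-predictor threshold `t` is one configurable value, default
**≥ 3 of 4**. The source guidelines state the upgrade rule once as
"greater than three of four" and once as "at least three of four"; the
engine does not resolve that contradiction — it exposes
`minDamagingPredictors` (the stricter 4-of-4 reading is one argument away)
and defaults to ≥ 3, the reading consistent with the VUS-2 wording.
Missing predictions count as non-damaging (conservative: missing evidence
never upgrades). `phenotypeFit()` is a set intersection between the
patient's phenotype category and the gene's registry categories, with
`unknown` fitting everything; the mapping ships as editable packaged data
(`inst/extdata/dsd_gene_registry.tsv`) rather than hard-coded truth,
because "fits the phenotype" for poorly characterised patients is a
clinical judgement, not a fact the software can own. In the packaged
registry `lof_mechanism` is true except for duplication/gain-of-function
entries (SOX3, NR0B1).

Per patient, the best classification by precedence pathogenic > likely
pathogenic > VUS (tiers tie) determines the outcome; only pathogenic and
likely pathogenic constitute a genetic diagnosis. A patient with curated
variants in ≥ 2 distinct genes is reported as possibly oligogenic; two
variants in one gene are a possible compound heterozygote, not oligogenic.

## Cohort aggregation and the reference fixture

`summarizeCohort()` stratifies by karyotype class × phenotype category
(optionally × recruitment) and recomputes percentages from counts with
half-up rounding. Counts are authoritative: where a printed percentage
elsewhere disagrees with the recomputed one (22/37 is 59.46%, printed as
60%), the count stands and the percentage is recomputed. `table2Fixture()`
deterministically encodes the published cohort arithmetic (278 + 48
patients across 18 subtype rows) and reproduces every per-category
diagnosed count exactly; the published total singleton count is internally
inconsistent in its source (215 vs 216) and the fixture encodes the
per-row values (summing to 215) without attempting to reconcile the
discrepancy.

`geneTally()` deduplicates by normalized variant key before counting, so
recurrent variants contribute once to unique-variant counts, and computes
unique protein-changing variants per coding kilobase when coding sizes are
supplied (genes without a size get `NA` plus a warning, never a silent 0).

## Numerical and testing choices

* All simulators pin the PRNG (`Mersenne-Twister`, inversion,
  rejection sampling) and are byte-identical under a fixed seed.
* Problem sizes in tests and the acceptance script — 1,000 read pairs /
  truth variants, 10,000 reads for the over-trim bound, 120-patient planted
  cohorts — are the package's chosen verification scale: large enough for
  the binomial tolerances asserted, small enough to run comfortably on a
  laptop.
* The locus map (gene → genomic interval) is always user-supplied or
  synthetic: amplicon coordinates of the original design are not published,
  so per-gene coverage is exercised on constructed maps.
* The cohort-wide unique-variant check (151 unique variants across 28
  genes) runs on a synthetic observation table with the same aggregate
  structure (187 observations, 22 recurrent variants), since the original
  per-patient supplement is not redistributable; it verifies the
  deduplication machinery, not the historical dataset.

## Known limitations

* No haplotype-aware variant matching; complex representations can
  mismatch.
* No CNV detection, no live annotation (population frequencies, in-silico
  predictions and reported status are inputs), and no repeat-length
  genotyping — repeat-tract membership is an input flag.
* Genes shadowed by high-homology pseudogenes (e.g. CYP21A2) cannot be
  reliably called by any short-amplicon design; the QC layer flags them but
  the package does not attempt to resolve them.
* The trimmer assumes reads start at amplicon boundaries; it is not a
  general-purpose adapter trimmer.
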