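---
title: "Translation-signature scoring and ncORF catalog construction"
author: "riboCatalog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Translation-signature scoring and ncORF catalog construction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages(library(riboCatalog))
```

## The problem

Ribosome profiling (Ribo-seq) reveals translation outside annotated
coding sequences: upstream and downstream ORFs in the UTRs of mRNAs,
ORFs in alternative reading frames of known CDSs, and ORFs on long
non-coding RNAs. Candidate ncORFs are published by many independent
studies with different callers, samples and reference versions, so a
reference catalog needs three things: a way to merge heterogeneous
candidate sets against one transcript annotation, a standardized,
caller-independent measure of translation evidence, and transparent
bookkeeping of every record that enters or leaves the catalog.
riboCatalog implements that pipeline as reusable components over
Bioconductor containers (GRanges/GRangesList), with a seeded simulator
so every stage is testable without external data.

## Translation-signature scores

Each candidate ORF is scored against a pooled, strand-specific,
single-nucleotide P-site track. P-site offsets are inferred upstream
(by the read-processing pipeline that produced the track); this
package never sees raw reads. Three metrics are computed per ORF and
per dataset, all on the ORF's *body* (sense codons; the stop codon is
excluded by default — see *Numerical choices*):

* **PIF (P-sites in frame)** — the fraction of the body's P-sites that
  fall on frame 0, the first base of each codon. A perfectly periodic
  signal gives 1; frame-agnostic noise gives about 1/3.
* **Uniformity** — the fraction of body codons whose own P-sites are
  *strictly* more than 1/3 in frame 0. Codons with no P-sites fail,
  so sparse or gappy coverage is penalized even when the covered
  positions are periodic: the metric rewards translation throughout
  the ORF's length.
* **Drop-off** — terminating ribosomes should leave a sharp boundary
  at the stop codon. With B the in-frame P-sites in the 15-nt
  transcript window immediately 5' of the stop codon and A the
  in-frame P-sites in the 15-nt window immediately 3' of it, Drop-off
  is B / (B + A). The windows live on the *transcript*, not the ORF:
  for a very short ORF the before-window extends 5' of the start
  codon, and both windows truncate at transcript ends. The stop codon
  itself belongs to neither window, so terminating-ribosome pileups on
  the stop do not contaminate either side. The reading frame is
  extended beyond the ORF in both directions from the start codon so
  that "in frame" is well defined within the flanks.

A score is *missing* (`NA`) exactly when its defining denominator is
zero, and a missing score always fails the thresholds downstream:
absence of evidence never counts as evidence.

**PPM (P-sites per million)** supports an expression flag: per-ORF
P-site counts are divided by body length and the densities scaled so
they sum to one million over the evaluated universe. PPM therefore
depends on the universe's composition; the catalog pipeline uses the
kept ncORFs plus all annotated CDS bodies, and records that choice in
its output. PPM > 1 is reported as an expression flag but never gates
Primary membership.

## Threshold calibration

What counts as "translated like a canonical gene" is calibrated from
the same dataset being scored: the three metrics are computed for
annotated protein-coding CDSs, a normal distribution is moment-fitted
to each metric's reference distribution, and the pass thresholds are

* PIF, Uniformity: the fitted point exceeded by 95% of reference CDSs,
  `mu - z(0.95) * sd` (`z(0.95) = qnorm(0.95) = 1.645`); the tail is a
  parameter of `deriveThresholds()`.
* Drop-off: the fitted mean `mu`.

all clamped to [0, 1]. The published per-dataset thresholds for the
two large pooled resources ship as named defaults
(`defaultThresholds("bodymap_v45")`: 0.7589 / 0.713 / 0.92;
`"ribocrypt_v45"`: 0.5112 / 0.8779 / 0.88) so scoring can run without
calibration data. An ORF passes a dataset when **all three** scores
meet their thresholds (inclusive boundaries, since thresholds are
reported at limited precision), and enters the **Primary set** when it
passes in **any** evaluated dataset. The lower-tail reading of the
"95th percentile" is forced by the shipped values themselves: typical
CDSs score far above 0.76 PIF, so the threshold must be the point that
95% of CDSs *exceed*.

## Catalog construction

`buildCatalog()` runs the stages in a fixed order, and every input
record ends in exactly one bucket (a validity invariant of the
returned report):

1. **Collapse** — records identical in chromosome, strand and exact
   block list merge into one, pooling source studies and legacy names.
2. **Map** — an ORF maps to a transcript only when its blocks form a
   contiguous sub-path of the transcript's spliced structure
   (junction-exact). Exonic containment with a different junction is
   not enough: a junction mismatch means a different transcript. ORFs
   compatible only with genes of unknown biotype are reported
   unmapped rather than guessed.
3. **Exclude** — an ORF sharing any genomic position, same strand and
   same codon phase, with a CDS of a protein-coding or
   nonsense-mediated-decay transcript is excluded (`same_frame_cds`);
   partial overlap suffices. Any same-strand exonic overlap with a
   pseudogene gene excludes in any frame (`pseudogene`), because
   non-uniquely-mapping reads make pseudogene calls unreliable.
   Opposite-strand overlap is kept: annotation overlap is read
   strand-specifically here, the conservative reading.
4. **Assign a host isoform** — candidates are ordered by: readthrough
   transcripts demoted below everything; MANE Select first; then best
   APPRIS rank (principal_1 = 1 ... alternative_2 = 7, untagged worst);
   then best transcript support level (untagged worst); then
   protein-coding biotype over non-coding; ties broken by transcript
   id so the choice is order-independent.
5. **Classify** into exactly one of seven types: `lncRNA-ORF` (lncRNA
   host gene), `PT-ORF` (non-coding transcript of a coding gene), and
   — relative to the host CDS in spliced coordinates — `uORF`,
   `uoORF`, `intORF`, `dORF`, `doORF`. An ORF spanning 5' UTR, CDS and
   3' UTR simultaneously is not representable in this schema and is
   reported as an error.
6. **Score** each ORF in each dataset, compute PPM over the ORF+CDS
   universe, apply the thresholds and the any-dataset Primary rule.
7. **Cluster isoforms** — two ORFs are isoforms when they share at
   least one genomic codon (same three positions, strand and order);
   clusters are connected components. Shared start / shared stop and
   a >= 90% overlap flag (measured against the shorter ORF's codon
   count, the stricter symmetric choice; configurable) are recorded
   per related pair. Genomic codon sharing is used rather than
   amino-acid string matching, which would relate unrelated loci.
8. **Name** — ORFs holding a legacy `c<chrom>riboseqorf<k>` name keep
   it; the rest are numbered upward from the per-chromosome legacy
   maximum in genomic-start order. Non-catalog legacy aliases are
   carried in a `legacy_names_v35` column, not reused.

The report also bins the Comprehensive and Primary sets by body length
(20-nt bins to 500 nt, then open-ended) and by type, the summaries
used to examine length- and type-dependent pass rates.

## The simulator

`simulateAnnotation()` + `simulatePsites()` generate the study
conditions every test runs under: a toy genome (well under 1 Mb) with
three-exon coding genes on both strands, a retained-intron non-coding
isoform, extra isoforms covering the MANE/APPRIS/TSL/readthrough
assignment branches, a two-exon lncRNA gene and an overlapping
same-strand pseudogene. Planted ORFs cover all seven types (including
a junction-spanning uORF and a 2-codon minimal ORF) plus decoys:
frame-shifted signal, zero coverage, a same-frame CDS clone, an
intronic ORF, a pseudogene-overlapping ORF, and duplicate records from
a second synthetic study.

P-sites follow a gamma–Poisson–multinomial model: per sense codon an
intensity is drawn from a gamma with configurable mean and shape, the
codon count from a Poisson of that intensity, and counts are placed on
the codon's three bases with probability `f` on frame 0 and
`(1 - f)/2` on each other frame. In-frame reads are added after each
stop at Poisson rate `lambda` times the realized in-frame count of the
15-nt before-window, so expected Drop-off is `1/(1 + lambda)`. The
defaults are chosen once as realistic deep-pooled-data conditions:
`f = 0.85` (the overall 3-nt periodicity of a billion-read pooled
resource), 20 P-sites per codon, gamma shape 1 (exponential per-codon
variability, a deliberately heavy overdispersion), `lambda = 0.05`.
The model is a test harness, not a claim about Ribo-seq biology: it
has no sequence bias, no read-length structure, no rRNA contamination,
and its codon intensities are independent. Passing tests therefore
demonstrate correctness of the scoring and catalog logic under
controlled truth, not performance on real libraries.

With CDS signal enabled, ORFs overlapping an annotated CDS in another
frame (uoORF, intORF, doORF) inherit mixed periodic signal and
routinely miss the thresholds — the same behaviour reported for the
real catalogs — so the simulation truth table only promises those
types membership in the Comprehensive set.

## Numerical choices

* Internal coordinates are 1-based closed throughout (the GRanges
  convention); rtracklayer converts BED/bedGraph at the boundary, and
  GTF is parsed by a small internal reader because repeated Ensembl
  `tag` attributes (which carry MANE/APPRIS/readthrough) must all be
  retained.
* The stop codon is excluded from PIF/Uniformity bodies by default
  (`includeStop = FALSE` to flip): Drop-off owns the stop region, and
  terminating-ribosome pileups would otherwise inflate in-frame
  totals.
* The per-codon Uniformity test is strict (`> 1/3`), so a perfectly
  uniform codon with equal thirds fails rather than passing by tie.
* Pass boundaries are inclusive (`>=`): thresholds are printed at 4
  decimals and exclusion at exact equality would be noise-sensitive.
* bedGraph values must be integers to 1e-6 and non-negative;
  overlapping spans within one strand are rejected as ambiguous
  rather than summed.
* Zero-count codons fail Uniformity; zero-denominator scores are `NA`
  and `NA` fails thresholds.
* Whether the original score implementations include the stop codon in
  the PIF/Uniformity denominator is not derivable from the published
  descriptions; the exclusion here is a documented default with a
  switch, and the same applies to the Drop-off before-window being a
  transcript window that may reach 5' of a short ORF's start.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline on
simulations of 2 coding genes + 1 lncRNA gene (25 candidate records,
~18,000 P-sites per track), 50-seed batches for the decoy-exclusion
property, and 10,000-draw Monte Carlo checks for calibration — sizes
chosen so the whole suite completes in a few minutes while keeping
every binomial check at 3 standard errors or better.

## Limitations

* Scoring assumes one translated frame per region; overlapping ORFs
  mix signals and are systematically under-scored (reported, not
  corrected).
* Host assignment and classification depend on annotation quality;
  ORFs compatible with zero transcripts of the allowed biotypes are
  reported unmapped rather than rescued.
* PPM values are only comparable within one universe composition.
* The simulator's independence assumptions make its recovery tests
  necessary, not sufficient, evidence for real-data behaviour.
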