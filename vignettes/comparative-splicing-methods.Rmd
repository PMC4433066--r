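---
title: "Methods: comparative alternative-splicing analysis in splicediverge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative alternative-splicing analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicediverge)
```

This vignette is the package's own account of its methods: the event model
and its assumptions, the comparative statistic, the synthetic-data
generator that stands in for sequencing data, and the numerical and design
choices made where the problem left the design open.

## Coordinates and inputs

All genomic coordinates inside the package are 0-based, half-open, on a
named chromosome with an explicit strand. GTF input (1-based, inclusive) is
converted at the boundary by `read_gtf()`/`write_gtf()`; BED is taken as-is
(it already matches). Chromosome names are matched as exact text — no
"chr"-prefix normalization. Transcripts must be stranded: splice-site
classification is meaningless without a strand, so `.` strands are rejected
for exon features (they remain legal in BED annotations).

## The event model

A transcript is an ordered, disjoint exon list; its **splice chain** is the
ordered list of its introns. Only **multiexonic** genes (≥ 1 transcript
with ≥ 2 exons) can splice and enter the analysis.

Events are enumerated per pair of distinct isoform splice structures. For a
pair, the **variable regions** are the maximal segments between consecutive
splice sites shared by the two transcripts, with the intersection of the
two transcript spans bounding the outermost segments. A segment where the
two chains differ is one event; its `signature` (chromosome, strand,
flanks, sorted chains) identifies it across isoform pairs and libraries, so
a gene's event set is the signature union over all pairs, and
`merge_catalogs()` extends the same union across libraries.

Two deliberate consequences:

* **Termini are not events.** Differences confined to transcript 5'/3'
  ends — alternative first/last exons, and any intron that straddles the
  span intersection — produce no event. The accounting covers internal
  splicing differences only.
* **Joint emission was rejected.** An alternative design emits one event
  per variable region over *all* transcripts jointly (regions bounded by
  sites common to every covering transcript). We found this provably
  disagrees with the pairwise union whenever planted events interact — for
  example, an IR isoform and an ES isoform sharing a flank merge into one
  region whose joint chain set classifies as OTHER, while the pairwise
  union correctly reports the IR, the ES, and their AD-like contrast. The
  pairwise union is the semantics the rest of the package (and its
  brute-force test oracle) pins down.

### Classification

For two chains, shared introns are stripped and the remainders matched
against a rule table: empty vs one intron = IR; empty vs two = IR1 + IR2;
two single introns sharing an acceptor = AD, sharing a donor = AA, disjoint
= "IR1 or IR2"; one intron vs two (three) spanning the same bounds =
ES (ES1 + ES2); anything else OTHER. Donor means the intron boundary nearer
the transcript 5' end: on the minus strand chains are mirrored
(`x -> -x`) before the rules apply, which makes the AD/AA calls
strand-correct without a second rule table. With ≥ 3 chains a simple type
is assigned only when every pairwise comparison agrees on it (IR, ES, AD or
AA); otherwise OTHER. Mutually exclusive exons have no named type and fall
into OTHER by design. The classifier accepts any boundary shift ≥ 1 bp; the
generator never plants shifts under 2 bp, matching the smallest
donor/acceptor shifts observed in real data.

## Junctions, orthologs, expression matching

A splice junction is a distinct intron interval per (chromosome, strand) —
gene identity is ignored, so junctions shared by overlapping genes collapse,
matching "unique junction" accounting. Boundary dinucleotides are read from
the genome (reverse-complemented on the minus strand) and classified
GT-AG / GC-AG / AT-AC / other; "other" is reported, never dropped. The
read-support screen keeps junctions with support **strictly greater than**
`min_reads` (default 10), i.e. ≥ 11 reads.

Orthologs are reciprocal best hits over 12-column tabular alignment output:
best = minimal e-value, ties broken by maximal bitscore then lexicographic
subject id (a fixed, documented tie-break — the original scripts being
unavailable, this is a potential source of count drift); both directions
must agree and both e-values must be ≤ `evalue_max` (default 1e-10).
Coverage for the 95%-identity/95%-coverage transcript-matching filter is
alignment length over query length for the single best HSP; no HSP
chaining.

AS-level comparisons are restricted to expression-matched genes so that
event-count differences do not merely track expression. When a
differential-expression flag list is available it is used directly (matched
= universe minus flagged); otherwise a pseudo-count rule
|log2((FPKM~A~+1)/(FPKM~B~+1))| ≤ 1 stands in. DE model fitting itself is
out of scope here.

## The AS level and altered-gene calls

The **AS level** of a group is unique merged events per alternatively
spliced gene, reported to 2 decimals. Per expression-matched ortholog the
two unique counts are compared: events in one group only give
*gained*/*lost*; a ≥ `fold` (default 4) ratio of nonzero counts gives
*up/down four-fold*; everything else is *unchanged*. The fold rule uses
unique merged counts rather than per-library totals because the comparison
targets species-level AS complexity; whether to use unique or summed counts
was an open choice and the unique-count convention is what the headline
events-per-gene ratios are based on. A gene overlaps a selection region
when its exon-hull span shares ≥ 1 bp with the region (the minimal
defensible rule absent a stated one).

## Genomic features and TEs

Feature vectors use the union of exons across isoforms for exon statistics,
the longest transcript for intron statistics (a representative-isoform
convention; a "union introns" alternative is a one-line change), the
exon-hull span for gene length, and the span sequence for GC content
(exonic-only GC is a defensible alternative; span was chosen and is
documented here). Associations with per-gene unique event counts use
Spearman rank correlation: the features are heavy-tailed and only monotone
association is claimed; Pearson is available behind `method = "pearson"`.
Constant features yield `NA` coefficients, not errors.

A TE is counted inside a retained intron only under **full containment**
("contained" is read literally); `rule = "overlap50"` offers a ≥ 50%-length
overlap alternative. One intron may contain several TEs, so introns-with-TE
≤ TE count.

## Variants and saturation

Variant tables (plain TSV, or minimal VCF: CHROM/POS/REF/ALT/QUAL + DP,
multi-allelic records split) are screened at quality > 20 and depth > 15,
both strict as conventionally printed. Transitions are A↔G and C↔T; the
remaining eight ordered pairs are transversions. Region assignment has
precedence exon > intron > intergenic over the annotation, so labels
partition the variants.

Depth saturation is modelled as **binomial thinning** of the full-depth
support table: each read survives independently with probability equal to
the depth fraction, an event is detected at ≥ 11 thinned reads (the same
junction screen), and genes are detected via their events. The original
design resampled raw reads and re-ran assembly per sub-library; that is not
reproducible at desk scale, and thinning preserves exactly the quantity the
curve is about — the probability that an event's support crosses the
detection threshold at reduced depth. The default grid of nine fractions
plays the role of 0.5–4.5 Gb sub-libraries of a 4.5 Gb run, with 50
replicates.

## The synthetic-data generator

`generate_bundle()` emulates a two-group comparative study on one genome:
group-B gene models sit at the orthologous loci under their own ids (the
real study anchored both species to one reference, which is what makes
junction sets comparable). Defaults are the study conditions: the AS-type
mixture is the published maize composition (IR 31.48%, AA 30.75%,
AD 14.34%, ES 11.49%, composites 4.53%, other 7.41%); 45.5% / 32.52% of
multiexonic genes splice in groups A/B with mean unique events per AS gene
4.12 / 2.26; 20% of multiexonic orthologs are A-only ("gained") and 5%
carry a ≥ 4-fold excess; junction classes are planted at
96.17 / 2.79 / 0.51 / 0.53%; 1.05% of retained introns receive an embedded
TE (≥ 5 bp inside both boundaries, types weighted as published); SNPs are
planted at Ts/Tv 1.77 with 30% indels (±1–20 bp); junction support is
negative binomial (mean 50, size 0.5 — the long tail that produces a
detection plateau); expression is log-normal with 10% DE genes. How often
the same isoform recurs across libraries is not published; it is an exposed
parameter (`recurrence_prob`, default 0.8), with every isoform guaranteed
in at least one library.

Generator-specific design points:

* **Events are isolated by spacer introns.** Consecutive planted events on
  one gene are separated by an untouched intron, so no planted pair shares
  or removes a boundary site. Without this, pairwise comparisons of two
  alternative isoforms create genuine extra events (e.g. two adjacent IR
  isoforms form an "IR1 or IR2" pattern), which is correct behaviour of the
  classifier but makes planted-vs-recovered accounting ambiguous. With
  spacers, recovery of planted events is exact, which is what the test
  suite asserts.
* **"IR1 or IR2" is special.** It exists only as two isoforms each
  retaining a different intron *without* the fully spliced form; the
  generator therefore plants it only as a gene's sole event and omits that
  gene's base isoform. As a consequence the realized share of this subtype
  runs below its configured share in multi-event genes; the recovered
  mixture still sits within the ±3-point envelope the tests check.
* **Dinucleotides are written, not sampled post hoc**, with exact
  (rounded) class counts; minority classes are only assigned to junctions
  that share no boundary site with another junction, so planted bases never
  conflict. Orthology bitscores are alignment length × 2 — a filler;
  nothing downstream depends on bitscore magnitudes beyond ordering.
* Decoys are planted for the RBH caller: secondary weaker hits,
  one-directional bests from group-specific genes, and one mutually-best
  pair above the e-value ceiling.

What the generator does **not** emulate: read-level noise (no FASTQ),
sequence evolution between the groups (group-B exons reuse group-A
coordinates), indel realism inside exons, incomplete transcript models, or
overlapping genes. Passing tests therefore demonstrate correctness of the
event algebra, the comparative statistics and the accounting — not
robustness to assembly artifacts in real transcript models.

## Numerical conventions and degenerate inputs

Percentages are reported to 2 decimals (1 decimal for junction sharing),
event-per-gene ratios to 2 decimals. Zero denominators flag `NA` rather
than erroring (empty catalogs, zero transversions, zero AS genes). All
randomness flows from a single integer seed; a fixed seed reproduces a
bundle byte for byte. Test and acceptance problem sizes — 150–300 genes for
unit properties, 1000 genes for divergence recovery, 2000 genes for mixture
recovery, 200 random genes against the brute-force oracle, 50 saturation
replicates — were chosen as the smallest sizes at which the binomial
sampling error of the planted rates is comfortably inside the asserted
tolerances.

## Known limitations

* Events are typed from annotation structure alone; no read evidence
  weights or PSI quantification.
* The four-fold rule on small unique counts is coarse (3 vs 1 is
  "unchanged", 4 vs 1 is altered); it reproduces the published convention
  rather than a statistical test.
* RBH is one-to-one; paralogous families and many-to-many orthology are out
  of scope, as are synteny-aware calls.
* The saturation surrogate cannot reproduce assembly-level effects of depth
  (novel junction discovery), only detection-threshold effects.
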