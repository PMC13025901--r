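---
title: "Transcript diversity analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcript diversity analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txdiversity)
```

# Overview

`txdiversity` analyses transcript-isoform diversity in a long-read isoform
catalog observed against a reference annotation, combined with short-read
two-condition expression data. The pipeline has five analytical stages —
structural classification, alternative-splicing (AS) event typing,
differential expression, major-transcript (MT) switching, and alternative
polyadenylation (APA) — plus a reference terminus-extension utility and a
synthetic-data generator that plants ground truth for every stage. This
vignette explains the models and the decisions behind them; it states no
empirical result that the test suite and `scripts/acceptance.R` do not
themselves compute.

# Coordinate model

All internal coordinates are 0-based half-open `[start, end)`; the GTF
convention (1-based inclusive) is converted only inside `read_annotation()`
and `write_annotation()`. This keeps midpoint and UTRR arithmetic free of
off-by-one ambiguity. A transcript is a strand-aware exon chain; its intron
chain — the ordered list of (donor, acceptor) pairs — is the unit of
structural comparison throughout.

# Structural classification

`classify_transcripts()` places each observed model into exactly one of
eight categories by a fixed cascade over same-strand overlapping reference
genes:

1. **fusion** — exonic overlap with two or more distinct genes;
2. **FSM** — intron chain identical to a reference transcript;
3. **ISM** — intron chain a contiguous sub-chain of a reference transcript;
4. **NIC** — all splice sites known in the assigned gene, but the chain is
   new (a new combination of known junctions or a new pairing of a known
   donor and acceptor);
5. **NNC** — at least one splice site absent from the assigned gene;
6. **genic** — mono-exonic within a gene span (with an FSM exception when a
   mono-exon model reciprocally overlaps a mono-exon reference transcript by
   at least 80%);
7. **antisense** — overlaps a gene only on the opposite strand;
8. **intergenic** — no gene overlap.

Junction matching is exact by default (`junction_tolerance = 0`): terminus
jitter in long-read models does not move splice sites, so no fuzz window is
needed for the FSM/ISM decision; a tolerance is available for noisy inputs.
The assigned gene is the candidate contributing the most matched junctions,
with exonic overlap breaking ties. Antisense and intergenic models are
merged into novel gene loci by same-strand single-linkage overlap, which is
the natural way to turn individual novel models into a count of novel genes.
Mono-exon handling (category 6 and its 80% exception) is a convention of
this package: mono-exon calls carry no junction evidence, so they are kept
out of the junction-defined categories.

For the catalog summary, "known transcript" means FSM only. ISM models match
annotated structures but have distinct termini; they are tallied separately
(`n_annotated_category` = FSM + ISM) rather than folded into the known/novel
split, because the two groupings answer different questions and folding them
together silently would make the reported novel share ambiguous.

# AS event typing

`detect_as_events()` decomposes every unordered transcript pair of a gene
into maximal *variant regions*: runs of positions where the two models
disagree on exonic status, bounded on both sides by shared exonic sequence
inside the pair's common span. Regions touching the common-span edge are
alternative termini, not AS events, and are discarded. Each region is typed
by its splice-site signature:

- **ES** — one form intronic across the region, the other carrying one or
  more complete exons, with both forms splicing at the shared flanks;
- **IR** — one form's single intron exactly spanning a region that is
  uninterrupted exon in the other;
- **A5SS / A3SS** — a single differing segment adjacent to one flank with
  the partner splice site shared; the label is assigned relative to the
  biological strand (the donor side is 5');
- **MEE** — one internal exon from each form, mutually non-overlapping,
  between shared outer flanks;
- **complex** — anything else; reported but excluded from the five-way
  proportions, which mirrors how event-typing tools report untypable codes.

Events are deduplicated per gene on (type, anchors, region), so an event
shared by many transcript pairs counts once and the event multiset does not
depend on input order. Mono-exon transcripts participate only as the
retaining form of IR — the other types are junction-defined. The test suite
checks the decomposition against an independent per-base brute-force oracle
over randomly generated toy genes, and checks strand correctness two ways:
relabelling the strand swaps A5SS and A3SS, while a true mirror (reflected
coordinates plus flipped strand) preserves every label.

# Expression, DE, and major transcripts

Counts are filtered by the CPM rule (CPM ≥ 1 in at least three libraries of
one condition), quantified as FPKM on annotated exonic length, and tested
for differential expression with a self-contained negative-binomial Wald
test: median-of-ratios size factors, method-of-moments dispersion pooled
over the two groups, shrunk toward the across-gene median with a prior
weight of four degrees of freedom, and a Wald statistic on the log2
fold-change referred to a t distribution with residual-plus-prior degrees of
freedom. The t reference is a small-sample (moderated-t) correction: with
three replicates per group a normal reference is visibly anti-conservative,
and the prior degrees of freedom are exactly those implied by the dispersion
shrinkage weight. DE calls use |log2FC| ≥ 1 and raw p < 0.05; an FDR column
is available but off by default because the stated criterion uses raw p.
Transcript-level FPKM uses annotated exonic length (effective length is not
modelled).

The MT of a gene in a condition is the isoform with the highest mean FPKM,
required to exceed the runner-up by a margin. The phrase "expressing at
least > 10 higher" reads most literally as an additive difference, so the
default is `margin_mode = "absolute"` with margin 10 FPKM; a fold mode is
provided because a 10-fold reading is also plausible, and reports name the
mode used. Genes whose margin fails in either condition are *indeterminate*
and excluded from the AMT/MT-constant dichotomy rather than silently lumped
into either side. AMT calls require a confident MT in both conditions
(`--require-margin-both` semantics; the one-flag-away alternative of
comparing top-ranked isoforms regardless of margin is available by setting
the margin to 0). Expression-change ratios |E2 − E1|/E1 are binned into
0–50%, 50–100%, 100–200% and >200% (half-open bins, absolute value, since a
gene's expression can fall), and the AMT versus MT-constant distributions
are compared with a chi-square homogeneity test.

# APA analysis

Strand-aware transcript 3' ends of a gene are clustered by single linkage
with a 24-nt window; the window is configurable because the upstream tools
in this field do not publish one — 24 nt sits above typical cleavage
heterogeneity and below the spacing of distinct sites. Only transcripts
whose 3' ends represent full-length termini of an annotated gene
(FSM/ISM/NIC/NNC) contribute; genic fragments and fusion models do not.
This, together with the read-support threshold (`min_support = 2`), stands
in for the original two-method concordance and positional filtering, which
cannot be re-run here. A gene with two or more surviving clusters is an APA
gene.

The UTRR is the genomic distance between the first and last PAS in
transcription order. Isoforms ending strictly downstream of the UTRR
midpoint are distal (M), strictly upstream proximal (m); a PAS exactly at
the midpoint joins neither sum (the definitions are strict). A gene is an M
gene when the M/m expression ratio exceeds 1 and a P gene below 1, with a
guarded infinite ratio when the m sum is zero. The major PAS (mPAS) is the
cluster with the highest usage, ties resolved downstream-most; usage is
measured by per-condition expression of member isoforms, because read
support in a pooled long-read catalog carries no per-condition information.
The poly(A)-signal scan counts all overlapping hexamers in the 50 nt
upstream of each PAS (mRNA sense) and reports the rank of AATAAA; degenerate
motif discovery is out of scope.

# Reference terminus extension

`extend_termini()` implements the annotation-repair rule for incomplete
references: assembled short-read models that overlap a reference
transcript's terminal exon and protrude beyond it can move that terminus
when at least `min_support = 2` models agree ("multiple" is not a number, so
it is a parameter). The 3' terminus moves to the most-protruding candidate;
the 5' terminus to the least-protruding one, the conservative reading of
"shortest 5' ends" (a flag disables 5' extension entirely, the other
reading of that sentence). A 5' boundary that coincides with a candidate
model end is treated as already evidence-defined and is not moved — this
makes the operation idempotent while keeping the conservative choice.
Internal junctions never move. All transcripts with qualifying support are
eligible; restricting to a candidate list is a caller-side subset.

# The synthetic-data generator

The generator defines the study conditions: two conditions (d30/d90) with
three replicates, gene loci laid out without overlap on two chromosomes and
both strands, 1–4 isoforms per gene derived from a multi-exon backbone by
planting AS variants in configurable proportions (default
ES/IR/A3SS/A5SS/MEE = 40/30/15/10/5), and 1–4 tandem PASs in a long terminal
exon with 120–400 nt spacing — far above the 24-nt cluster window, so
planted sites stay separable under the default ±10 nt 3'-end jitter (kept
below half the window so jitter can never split or merge a planted site;
5'-end jitter is ±30 nt, which junction-based classification ignores). An
ORF ending 250 nt upstream of the proximal PAS is planted in each terminal
exon, giving proximal isoforms a ~250-nt 3'-UTR; AATAAA is planted 20 nt
upstream of each PAS with probability 0.8. The observed catalog draws
categories from proportions close to a real spleen Iso-seq catalog (FSM
14%, ISM 25%, NIC 24%, NNC 32%, the remainder split among fusion, genic,
antisense, intergenic). Long-read support is shifted-geometric — a free
choice, since no noise model for consensus-isoform support is published —
with PAS-bearing models starting at 2 so that every planted site clears the
default cluster support threshold.

Expression is built in expected-FPKM space per condition: lognormal gene
levels; per-condition PAS usage with one dominant site (the distal-most with
probability 0.7, emulating distal preference; dominant-site switching for a
configurable fraction of APA genes); the designated MT chosen inside the
dominant PAS group and forced to dominate by a factor of 2, with group sums
re-normalised to the planted usage weights afterwards so the M/m balance
keeps a clear margin; a 2^±2 gene-level scaling for planted DE genes applied
after MT enforcement so fold changes stay intact. The FPKM scale is pinned
(Σ FPKM×length = 10^9) so FPKM recomputed from sampled counts matches the
planted values. Counts are negative binomial with configurable dispersion
(default 0.05); at dispersion 0 counts equal rounded means, the noiseless
limit in which every planted label is recoverable exactly. Ground truth is
derived from the final expected values — the same quantities the analysis
estimates — so planted labels and recoverable labels cannot drift apart.
Because a mock library holds only hundreds of transcripts, absolute FPKM
values are larger than in a real transcriptome (the per-library FPKM mass is
fixed); all margin-based logic therefore operates comfortably above the
10-FPKM MT margin. AMT planting is restricted to genes without a planted
mPAS shift; shift genes may still realise an MT switch (the dominant-site
change moves the MT), and the truth tables record what was realised.

What the generator does *not* emulate: sequencing error and alignment
artifacts, internal priming, incomplete 5' degradation profiles,
between-replicate library composition effects, and correlated dispersion.
Passing recovery tests therefore demonstrate the correctness of the
implementations under clean planted structure, not performance on real
long-read data.

# Numerical choices and degenerate inputs

- Report percentages are always re-derived from counts with 2-decimal
  half-up rounding (`round_half_up()`), never stored, so parts sum to
  wholes in every report.
- Zero library sizes, duplicate feature ids, negative values, mixed-strand
  genes and zero-length exons are hard errors; an all-C upstream window, a
  window clipped at a contig edge, an empty observed catalog and a
  zero-usage condition (mPAS undefined, shift NA) degrade gracefully.
- The dispersion floor inside the Wald test is 1e-8, as is the epsilon
  added inside logs.
- Problem sizes in the tests and acceptance script (hundreds of genes, a
  few thousand transcripts) were chosen as the smallest scales at which all
  planted structure is represented with comfortable counting statistics.

# Known limitations

- Absolute event counts are not comparable across tools: pair
  deduplication conventions differ, so only proportions are meaningful.
- The NB Wald test is a deliberately simple stand-in for a full GLM
  framework: no covariates, no shrinkage of fold changes, no outlier
  refitting.
- APA "two-method concordance" is operationalised as dual thresholds on one
  clustering; a second independent PAS caller is out of scope.
- The genic/antisense/intergenic split of a real catalog depends on
  assembler behaviour the generator does not model; only the planted
  recipes are guaranteed recoverable.
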