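# txdiversity

Transcript-isoform diversity analysis for long-read isoform catalogs with
two-condition short-read expression data.

Developing tissues regulate genes not only by changing overall expression
but by switching which isoform dominates and which polyadenylation site is
used. Characterising this requires several coordinated analyses over a
long-read (Iso-seq-style) transcript catalog: deciding which observed
models are annotated and which are novel, typing the splicing differences
between isoforms of a gene, finding genes whose *major transcript* changes
between conditions, and measuring 3'-UTR length preference through
alternative polyadenylation. `txdiversity` implements that pipeline for
bioinformaticians working with transcript models (GTF/BED12) and count
tables, together with a synthetic-data generator that plants ground truth
so every stage is testable end to end.

## What it computes

- **Structural classification** of each observed transcript against a
  reference annotation into FSM / ISM / NIC / NNC / fusion / genic /
  antisense / intergenic, by intron-chain comparison (FSM: chain identical
  to a reference isoform; ISM: a contiguous sub-chain; NIC: known splice
  sites in a new combination; NNC: ≥ 1 novel site), with novel-gene locus
  building and Table-style catalog summaries.
- **AS event detection**: for each transcript pair of a gene, maximal
  variant regions bounded by shared exonic sequence are typed as
  ES / IR / A3SS / A5SS / MEE (strand-aware) or `complex`, deduplicated per
  gene.
- **Differential expression**: CPM filtering (CPM ≥ 1 in ≥ 3 libraries of
  one condition) and a self-contained negative-binomial Wald test
  (median-of-ratios normalisation, moment dispersion with moderated-t
  small-sample correction), calling genes at |log2FC| ≥ 1, p < 0.05.
- **Major-transcript (MT) switching**: the MT of a gene per condition is
  the isoform whose mean FPKM exceeds the runner-up by a margin (default:
  absolute difference > 10); AMT genes are those whose MT identity differs
  between conditions, intersected with DE calls and binned by
  expression-change category.
- **APA**: single-linkage clustering of transcript 3' ends into PASs
  (24-nt window, support ≥ 2), APA gene calls, UTRR geometry, distal (M)
  vs proximal (m) isoform expression with M/P gene status per condition,
  major-PAS shift detection, poly(A)-signal hexamer scanning (AATAAA rank),
  and 3'-UTR length distributions from predicted ORFs.
- **Reference terminus extension** from assembled short-read models
  (shortest protruding 5' end, longest protruding 3' end, support ≥ 2).
- **Synthetic data**: `simulate_dataset()` generates a reference + genome,
  an observed catalog covering all eight categories, and NB counts for
  2 conditions × 3 replicates with planted MT switches, DE genes, PAS
  usage shifts and AATAAA signals, plus truth tables for recovery testing.

## Worked example

```r
library(txdiversity)

cfg <- sim_config(n_genes = 60, n_observed = 240)
sim <- simulate_dataset(cfg, seed = 11)
res <- run_pipeline(sim$observed$annotation, sim$reference$annotation,
                    sim$expression$counts, genome = sim$reference$genome)
print(res)
```

```
# Transcript diversity report

- Transcripts: 240 (11.67% known / 88.33% novel)
- Genes: 64 (59 annotated, 5 novel)
- Genes with >1 isoform: 56 (87.5%); with >=10: 0 (0%)
- Structural categories: FSM 28, ISM 63, NIC 64, NNC 77, fusion 1, genic 2, antisense 5, intergenic 0
- AS events: 151 in 50 genes (ES 40.4%, IR 4.64%, A3SS 24.5%, A5SS 22.52%, MEE 7.95%)
- DEGs: 11 (3 up, 8 down)
- AMT genes: 19 (MT-constant: 45); DE-AMT: 4 (2 up, 2 down)
- APA genes: 31; mPAS shifts: 12
- M:P ratio d30: 2.88; d90: 2.1
- AATAAA rank: 1
```

Reading this: of 240 simulated long-read models, 28 match a reference
isoform exactly (known, 11.67%) and the rest are novel at transcript level;
151 unique AS events were typed with exon skipping the most common; 19
genes switch their dominant isoform between the two conditions, of which 4
are also differentially expressed; 31 genes use more than one
polyadenylation site and 12 of them switch their major site; M genes
(distal-dominated) outnumber P genes in both conditions; and the canonical
AATAAA signal is the top-ranked hexamer upstream of the called PASs. The
per-stage tables (`structural_calls.tsv`, `as_events.tsv`, `de_calls.tsv`,
`mt_calls.tsv`, `pas_clusters.tsv`, ...) are written when `outdir` is
given.

The `analysis/` directory holds the same workflow as numbered driver
scripts (`01_simulate.R` … `06_report.R`) writing their tables under
`results/`; run them in order from the repository root.

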