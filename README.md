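# raceltr

Analysis of genome-wide targeted 5′ RACE-Seq screens for transcriptionally
active LTR retrotransposons (MaLR families THE1A–D, MSTA, MSTB), and of
their consequences for nearby gene expression.

Solitary LTRs carry cryptic promoters. A RACE-Seq screen primed from a
conserved transcribed LTR region turns each sequencing peak into evidence
that a particular LTR copy is active in a particular sample. This package
implements the full downstream analysis:

* **Primer compatibility** — ungapped scan of every annotated repeat copy
  for the consensus primer; a copy is amplifiable when its best match has
  at most 8 mismatches (Hamming distance, `N` counts as mismatch).
* **Peak calling** — deterministic threshold/merge/width caller on read
  coverage, followed by a per-base 2-of-3 replicate consensus (low
  replicate sharing, 7–30% on real data, makes the consensus filter
  necessary).
* **Annotation** — peaks are assigned to the repeat instance with maximal
  overlap (strand inherited from the repeat) and to genomic regions using
  a strand-aware promoter window of 1 kb upstream to +100 bp of the TSS;
  family composition is compared with the genomic repeat complement to
  quantify detection bias (THE1B excess).
* **Comparative statistics** — binary activation matrix over loci ×
  samples; group-specific/shared counts; Dice similarity
  *D* = 2|A∩B|/(|A|+|B|) with average-linkage clustering; upper-tail
  hypergeometric tests computed in log space.
* **Expression integration** — nearest same-strand downstream gene links,
  strand-oriented metagene profiles around active LTRs, per-cell-line-pair
  log2 fold changes, hypergeometric enrichment of LTR-driven genes among
  upregulated genes, a four-way transcript typology (upstream promoter /
  intragenic isoform / antisense / intergenic lncRNA), and correlation
  clustering of samples over LTR-linked genes.
* **Synthetic data** — a generator that plants every structure above
  (diverged LTR copies, group-structured activation, capture dropout,
  LTR-driven expression boosts) so the whole analysis runs and is tested
  without any external data.

## Worked example

The six numbered scripts under `analysis/` run the chain stage by stage on
one simulated study (seed via `RACELTR_SEED`, default 1), writing tables
under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_scan_primer.R
Rscript analysis/03_call_peaks.R
Rscript analysis/04_annotate.R
Rscript analysis/05_compare.R
Rscript analysis/06_integrate.R
```

Selected output from those runs:

```
300 instances scanned with 25 nt primer; 252 amplifiable (84%).
Amplifiable fraction by family: MSTA=0.69, MSTB=0.42, THE1A=0.98, THE1B=1, THE1C=0.96, THE1D=0.89
...
L428: 85 replicate peaks -> 30 consensus regions; 20% of merged peaks in all 3 replicates
Replicate sharing mean 0.215 - inside the 7-30% band observed on real RACE-Seq data.
...
THE1B: 30% of detected loci vs 25% of the genomic complement (ratio 1.20) - detection biased towards THE1B, as on real data
...
Active-locus universe: 80 loci. Tumour-specific 65, control-specific 15, shared within tumour 6 (unique to tumour 6).
Pairwise tumour overlap hypergeometric p: 2.85e-05, 0.000235, 1.2e-06 - all significant (p < 0.01)
Dice clustering: tumour-like samples form their own clade: TRUE
...
Transcript typology: antisense=23, intergenic_lncRNA=15, intragenic_isoform=23, upstream_promoter=19; agreement with planted truth 100%
LTR-driven genes vs upregulated genes (hypergeometric): max p = 6.42e-12 - significant for every pair
```

Reading: the primer's family-specific mismatches make THE1 copies amplify
almost completely while MST copies drop out, which inflates THE1B among
detected loci exactly as on real data; capture dropout keeps all-replicate
sharing near 20%, so only 2-of-3 consensus regions are analysed; tumour
samples share an activation core (overlap far above the amplifiable-pool
expectation) and cluster away from controls; and the genes driven by active
LTRs are strongly enriched among the genes upregulated in each tumour line
against each control.

The same chain runs in one call:

```r
library(raceltr)
res <- run_pipeline(sim_config(seed = 1), outdir = "run")
res$group_sets$counts
res$enrichment$max_p
```

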