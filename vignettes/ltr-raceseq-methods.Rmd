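---
title: "Methods: genome-wide RACE-Seq analysis of LTR promoter activation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-wide RACE-Seq analysis of LTR promoter activation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis problem

Solitary long terminal repeats (LTRs) of the MaLR class — THE1A–D, MSTA,
MSTB — can act as cryptic promoters. A targeted 5′ RACE-Seq screen primes
reverse transcription from a conserved, transcribed LTR region and sequences
the products, so every peak of aligned RACE fragments marks an LTR that is
transcriptionally active in that sample. Comparing active-LTR repertoires
between tumour-like and control cell lines, and integrating them with
RNA-Seq expression, asks three questions: which LTR families are activated,
is activation cell-type specific, and does an active LTR drive transcription
of a downstream gene?

`raceltr` implements that analysis chain as a set of testable functions
(`R/`), driven either end-to-end (`run_pipeline()`) or stage by stage
(`analysis/01_simulate.R` … `06_integrate.R`). Because the original screen's
raw sequencing data cannot be redistributed or processed at desk scale, the
package ships a synthetic-data generator that plants every structure the
analysis is supposed to detect; the tests then verify detection against the
planted truth.

## Coordinate and container conventions

All intervals are 0-based half-open (BED convention) in plain data frames;
RepeatMasker's 1-based inclusive records are converted at the I/O boundary
(`read_repeatmasker_out()`). Interval algebra (overlap, coverage, merging)
is delegated to `IRanges`/`GenomicRanges`; coverage tracks are `RleList`
objects, one run-length-encoded vector per chromosome per strand.

## The synthetic study conditions

`sim_config()` fixes the reference conditions:

* **Genome** — 2 Mb over 2 chromosomes; 300 LTR instances (THE1B 25%, the
  other five families 15% each, echoing the roughly balanced MaLR
  complement of a mammalian genome); 240 gene models with two exons each.
* **Primer model** — each family consensus is a random 350 bp sequence
  sharing an embedded 82 bp conserved 5′ region; the 25 nt primer is the
  core of that region. Family-specific fixed substitutions are planted in
  the primer window (THE1B 0, THE1A 1, THE1C 2, THE1D 3, MSTA 5, MSTB 6),
  then every copy diverges at 15% per base — a realistic divergence for
  repeats of MaLR age. Under the 8-mismatch amplification budget this
  leaves essentially all THE1 copies amplifiable but only ~65%/~45% of
  MSTA/MSTB, which is the mechanism behind the THE1B detection bias the
  screen shows on real data.
* **Activation** — tumour-like samples (L428, L1236, KMH2) each activate
  20% of loci, 60% of which form a core shared by the group; control-like
  samples (Reh, Namalwa) activate ~6.7% from a disjoint pool, also with a
  0.6 shared fraction. Disjoint pools are an idealisation: real tumour and
  control repertoires overlap partially.
* **RACE capture** — an active, amplifiable locus yields 200 identical
  150 bp fragments starting at its best primer match, per replicate, but
  each (locus, replicate) capture fails independently with probability
  0.45. With 3 replicates this puts the expected fraction of per-sample
  peaks seen in all three replicates at 0.55³/(1−0.45³) ≈ 0.18, inside the
  7–30% range such screens show in practice — the reason all downstream
  analysis uses a 2-of-3 replicate consensus. 2000 background reads per
  replicate are placed uniformly.
* **Expression** — baseline FPKM is log-normal (meanlog log 10, sdlog 1),
  with multiplicative log-normal noise (sdlog 0.2) per gene and sample. A
  gene driven by an LTR active in a sample has its FPKM multiplied by 4 in
  that sample. Coverage tracks carry exonic baseline signal plus, for each
  active locus, a constant-height transcript on the LTR strand.

### Planted transcript types

Repeat instances are laid out in "cassettes" cycling through the four LTR
transcript types the analysis must distinguish: (1) intergenic locus 1.2 kb
upstream of a same-strand gene (an upstream promoter; 1.2 kb mirrors the
known LTR-driven cases), (2) locus inside the intron of a same-strand gene
(shorter-isoform promoter), (3) intergenic locus whose transcript runs into
a downstream opposite-strand gene (antisense), and (4) an isolated locus
with a 2 kb transcript and no reachable gene (intergenic lncRNA). Cassettes
are mirrored wholesale for minus-strand draws so "downstream" is always
correct in transcription orientation, and every gene's promoter window
(1 kb upstream to +100 bp of the TSS, strand-aware) is contained within its
own cassette so windows never swallow a neighbouring repeat. Antisense loci
leave their gene's expression unchanged; only types 1–2 boost a gene.

The generator does **not** model indels, sequencing errors, quality scores,
PCR duplicates, nested repeats, partially overlapping tumour/control pools,
or fragment-length variation. Passing tests therefore demonstrate that the
analysis chain is correct for the structures it claims to detect — not that
it is robust to every artefact of real libraries.

## Stage parameters

| Parameter | Default | Why |
|---|---|---|
| `max_mismatches` | 8 | amplification budget of the assay |
| `min_height` | 5 reads | well below a captured locus (200 reads), far above uniform background (~0.15×) |
| `merge_gap` | 100 bp | joins ragged sub-peaks of one locus; smaller than inter-locus spacing |
| `min_width` | 50 bp | a third of the fragment length; removes slivers |
| `min_replicates` | 2 of 3 | the conservative filter applied to real RACE-Seq data |
| promoter window | −1000…+100 bp of TSS | the screen's definition; strand-aware (the text leaves genomic-left vs strand-aware open; strand-aware is the biologically meaningful reading) |
| `min_overlap_bases` | 1 | RACE peaks are narrow and primer-anchored |
| `max_link_distance` | 50 kb | covers the known 1.2 kb and 20 kb upstream exemplars with headroom |
| contiguous-signal rule | ≥1× over ≥80% of bases | declares a transcript to "reach" the linked gene |
| meta-profile | ±5 kb, 50 bp bins | locus-centred, oriented by LTR strand |
| fold change | log2 with pseudocount 1 | zero-safe and symmetric |
| upregulation threshold | log2 FC ≥ 1 | 2-fold, conventional |
| correlation transform | log2(FPKM+1), Pearson | standard for FPKM matrices |

## Numerical and procedural choices

* **Peak calling** is a transparent threshold/merge/width procedure
  (maximal runs of coverage ≥ `min_height`; runs separated by fewer than
  `merge_gap` uncovered bases merged; short runs dropped). It is
  deliberately simple so an exhaustive run-enumeration oracle can verify it
  on random inputs.
* **Replicate consensus** is defined per base (bases covered in ≥
  `min_replicates` replicates, extracted as maximal runs, support = maximal
  per-base replicate depth), which is order-invariant and oracle-checkable,
  rather than by pairwise peak overlap.
* **Peak strand** is `"."` until a repeat is assigned; the repeat
  annotation supplies the strand, as in the original screen.
* **Hypergeometric tails** are accumulated in log space via `lchoose` and
  cross-checked against `stats::phyper` and, for small populations, against
  exhaustive enumeration of all draws.
* **Dice clustering** uses average linkage on 1 − Dice over active-locus
  sets (locus identity, not base-pair overlap); ties resolve by input
  order, so a fixed sample order yields a fixed tree.
* **Overlap significance between two samples' repertoires** takes the
  population to be all amplifiable instances — the pool an active set is
  drawn from. Conditioning on the detected union instead would make shared
  cores look unsurprising by construction.
* **Enrichment of upregulated genes near active LTRs** is computed per
  (tumour, control) sample pair — fold change of one line over another, as
  the screen plots it — with draws = genes driven by that tumour sample's
  active LTRs through the `upstream_promoter`/`intragenic_isoform`
  relations. Averaging lines first would shrink a 4-fold single-line effect
  to the significance boundary; per-pair testing keeps the design of the
  original comparison. The headline value is the maximum (most
  conservative) p over pairs.
* **Recovery accounting** compares pipeline detections against the
  generator's *capture* ground truth: a locus is detectable in a sample
  only if it emitted reads in ≥ 2 replicates. Activation alone is not
  detectability — with 45% capture dropout, a per-sample activation
  recovery above ~57% is impossible for any consensus caller, so measuring
  against emitted data is the only reading under which "recovery" evaluates
  the analysis rather than the assay. The dropout model itself is checked
  separately through the replicate-sharing band.
* **Degenerate inputs** — empty peak sets, all-zero coverage, loci whose
  profile window leaves the chromosome (skipped and counted), both-empty
  Dice sets (error), zero-variance expression columns (error naming the
  sample) — are handled explicitly and tested.

## Problem sizes

The default conditions (2 Mb, 300 loci, 5 samples × 3 replicates, ~24k
reads per replicate) run in ~10 s; the test suite repeats them over 10
seeds for the stability checks and uses a 0.3 Mb / 40-locus configuration
for module tests. These sizes were chosen so the planted effects sit well
above sampling noise while a full run stays interactive.

## Known limitations

* The peak caller has no local background model or per-peak FDR; it is
  matched to the high signal-to-noise regime of targeted RACE, not to
  ChIP-Seq-like data.
* The four-way transcript classifier trusts the contiguous-signal rule; on
  real data, fragmented coverage would demote upstream-promoter calls to
  lncRNA calls.
* Replicate capture dropout is modelled as a flat per-locus Bernoulli; on
  real data dropout correlates with primer mismatch count, so family-level
  sharing fractions would differ.
* The expression model has no dispersion structure or library-size
  variation; fold changes are descriptive, not a differential-expression
  model.
* Nested or fragmented repeats and overlapping genes are not modelled;
  assignment ties (broken by repeat start) are untested against such
  configurations.
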