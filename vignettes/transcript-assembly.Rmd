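---
title: "Block-based transcript assembly for intron-poor genomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Block-based transcript assembly for intron-poor genomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txblocks)
```

## The problem

General-purpose transcriptome assemblers are built for spliced, isoform-rich
transcriptomes. Applied to yeasts or prokaryotes — genomes where introns are
rare and polycistronic transcription is possible — they fragment transcripts
at every sequencing dropout and stitch neighbouring genes together whenever
their transcripts happen to abut. txblocks implements a reference-guided
assembler designed for exactly this regime: strand-specific single-end
RNA-seq alignments plus a gene annotation go in, and transcript spans with
signed 5'/3'-UTR lengths, intron calls, polycistronic validations and
non-coding transcript classes come out.

## The procedure

**Blocks.** Unspliced read segments on one strand that overlap, or that are
separated by a zero-coverage gap strictly shorter than `min_gap_forced_join`,
are joined into maximal *blocks*. Blocks with fewer than `min_reads` reads
are discarded: isolated read clumps in intergenic space are background, not
transcription. Spliced-read segments are kept on a separate depth track; they
carry junction evidence, not block structure.

**Learned joining statistics.** Blocks overlapping a same-strand annotated
gene are *reference-based*. Within one gene, consecutive reference-based
blocks are fragments of a single transcript broken by coverage dropouts, so
the gaps between them — and the ratio of their mean coverages — sample the
library's own dropout behaviour. The assembler records the mean and sample
standard deviation of both quantities at every run.

**Adaptive joining.** An unassigned (intergenic) block adjacent to a
reference-based block is absorbed into it when its gap is at most the learned
gap mean plus `sd_multiplier` standard deviations *and* its coverage ratio is
at least the learned ratio mean minus `sd_multiplier` standard deviations.
After each pass, merged spans, coverages and the statistics themselves are
recomputed, and the procedure repeats to a fixed point. Unabsorbed blocks
survive as candidate novel transcripts. Two details the procedure leaves
open are fixed as follows: statistics are recomputed once per pass (all
merges within a pass use the pass's frozen thresholds), which makes the
result independent of within-pass evaluation order; and when a block
qualifies on both sides it merges toward the smaller gap, ties going to the
higher coverage ratio and then upstream — an arbitrary but deterministic
rule.

**Introns.** Spliced reads sharing an exact junction are grouped; a junction
is accepted when its spliced support is at least `intron_ratio` times the
mean unspliced depth at the two flanking exonic bases (donor−1, acceptor+1).
The flanking-base definition is the minimal symmetric reading of "depth at
the intron-exon boundary"; no junction clustering is attempted, because
mis-aligned junction reads are exactly what the ratio filter is for. A
junction with support but zero unspliced competition is accepted with an
infinite ratio. The default threshold is 0.1; genomes with pervasive
spurious junctions warrant 0.65 (the stricter calibration used for
*Naumovozyma castellii*).

**Final transcripts.** Blocks assigned to the same gene are merged across
their gaps — a gap containing an accepted junction is recorded as an intron,
and intronic bases are excluded from the transcript's mean coverage. For
transcripts with mean coverage above `high_coverage_threshold` (default 20),
each end is trimmed inward while the per-base depth is at or below
`trim_depth` (default 3): deep libraries grow long low-coverage UTR "tails"
that inflate end estimates, while shallow transcripts are left untouched
because trimming them would eat real signal. Trimming inspects raw per-base
depth with no smoothing — the rule is a per-base condition — and stops at the
first base above the threshold.

**Polycistronic validation.** A draft spanning two or more same-strand genes
is genuinely polycistronic only if transcription is continuous and balanced
across it. For each adjacent gene pair: the inter-gene interval must contain
no zero-depth base; its mean depth must be at least `t_intergenic` (0.5) of
the weaker gene's mean depth; and the two genes' depths must agree within
`t_genes` (min/max at least 0.5). A failing draft is split at the deepest
intergenic minimum and the pieces re-validated. The two 0.5 thresholds are
this package's own defaults for a published validation approach whose exact
constants are not public; both are exposed as parameters and should be
treated as tunables, not gospel.

**UTRs.** UTR lengths are measured between the assembled transcript ends and
the annotated gene boundaries (for yeast annotations, the ORF), in transcript
orientation: on the minus strand the 5'-UTR sits at the right end of the
span. Negative values are kept, not clamped — they flag transcripts truncated
relative to the annotation, which is diagnostic (see the poly-A discussion
below).

**Classification.** Each transcript receives exactly one of six labels by a
cascade: covered same-strand genes dominate (protein_coding / tRNA /
other_ncRNA by the gene's class); otherwise a strict majority
(`antisense_frac`, default 0.5, strict inequality) of the transcript's length
antisense to protein-coding genes makes it a SAUT; otherwise full containment
in an accepted intron of a same-strand transcript makes it an intronic ncRNA;
everything else is a SUT, reported with its closest annotated gene (ties
toward the downstream gene on the transcript's strand). The majority rule
avoids labelling transcripts with incidental terminal overlap as antisense;
a transcript both intergenic and partially antisense gets a single label,
never two.

**Comparative layer.** Across samples, genes covered above
`high_coverage_threshold` in *every* sample are compared pairwise on 5'-UTR
length; a pair differing by `utr_diff_threshold` (default 50) bases or more
is *variable*. Genes variable in no comparison are conserved, in one to
`highly_variable_min − 1` comparisons variable, and in `highly_variable_min`
(default 6) or more highly variable. The 50-base rule is applied as ≥ 50
throughout, so boundary values count as variable; the upper end of the
"highly variable" range is an empirical observation, not a rule, so no upper
cap is applied. A SAUT is *conserved* when every sample has at least one
SAUT antisense to the same (orthologous) gene; ortholog mapping is an input
table, never inferred. Polycistronic pairs validated in only some growth
conditions are demoted to separate transcripts — they are adjacent genes
whose transcripts happen to abut in that condition.

## Parameters

| parameter | default | unit | role |
|---|---|---|---|
| `min_gap_forced_join` | 25 | bases | zero-coverage gaps shorter than this never split a block |
| `min_reads` | 5 | reads | block noise filter |
| `intron_ratio` | 0.1 | — | junction acceptance threshold (0.65 strict mode) |
| `max_spliced_distance` | 1000 | bases | maximum intron a spliced read may span |
| `small_deletion_max` | 10 | bases | reference skips at or below this are deletions, not introns |
| `trim_depth` | 3 | reads | per-base depth at or below this is trimmed from tails |
| `high_coverage_threshold` | 20 | mean depth | gate for trimming and for UTR comparisons |
| `sd_multiplier` | 2 | SDs | width of the adaptive joining band |
| `t_intergenic`, `t_genes` | 0.5, 0.5 | — | polycistronic continuity/balance thresholds |
| `antisense_frac` | 0.5 | fraction | strict majority for the SAUT call |
| `utr_diff_threshold` | 50 | bases | UTR variability threshold |
| `highly_variable_min` | 6 | comparisons | highly-variable class threshold |

`min_reads` and `min_gap_forced_join` are the two knobs a user should adapt
to library depth; the defaults suit *Saccharomyces*-scale genomes at typical
RNA-seq depths. When fewer than two within-gene block pairs exist to learn
from (toy inputs), the joining thresholds fall back to
`min_gap_forced_join × 5` and a coverage ratio of 0.5 — conservative values
that keep behaviour defined rather than guessing a spread from one point.
The coverage ratio itself is defined as min/max of the two blocks' mean
coverages: symmetric and bounded in (0, 1]. Block mean coverage is computed
over the full span *including* internal zero-depth positions, which penalises
spurious long merges.

## What the simulator emulates — and what it does not

`sim_genome()` lays out non-overlapping transcription units (coding genes
with drawn UTRs, optional tRNA/ncRNA genes, antisense and intergenic ncRNAs,
bicistronic units) and returns the annotation *without* UTRs, so UTR recovery
is a genuine reconstruction task. Truth UTR ranges (20–200 bases 5',
50–250 bases 3') and gene lengths (500–2000 bases) are round figures of the
yeast scale; per-transcript depths may be constant or log-normal.

`sim_reads()` reproduces the pathologies that motivate the assembler's rules:

- 50-base strand-specific single-end reads;
- preferred start windows (hotspots) separated by low-coverage regions;
- zero-coverage windows inside transcripts, with two deliberate
  regularisations: windows are kept at least three read lengths apart so two
  drawn windows never fuse into one longer gap, and each window's edges are
  pinned by a flanking read so the zero-coverage run has exactly the drawn
  length — without pinning, the effective gap is the window plus a random
  sampling dropout, and a "short" window can silently exceed the forced-join
  threshold;
- uniform background noise reads on random strands, labelled `noise_*` in
  read names so tests can verify the noise filter removes exactly
  background-only blocks;
- poly-A loss: removal of every read overlapping a transcript's 3'-terminal
  read-length bases, the footprint of SOLiD-era poly-A read filtering. Under
  it the assembler's 3'-UTRs are systematically short by about one read
  length while 5'-UTRs stay centred on truth — the package reproduces this
  as a direction, not a magnitude, since the magnitude depends on the real
  library's end chemistry;
- the first and last feasible read start in each transcript are always
  sampled ("anchoring"), so truth termini are covered as they are at study
  depth; at toy depths pure uniform sampling leaves a transcript's first
  base uncovered about half the time, which would turn every boundary test
  into a coin flip about the sampler rather than the assembler.

The simulator does **not** model sequencing error, base quality, colour-space
encoding, mappability, or biological replicate variance. Passing its tests
therefore shows that the assembly logic is correct under the stated coverage
model — not that boundary accuracy on a real library will match the clean
recovery rates seen here.

## Numerical and degenerate-input choices

- Coordinates are 1-based inclusive everywhere; alignment input is converted
  at the boundary, once.
- Read strand comes from the alignment flag only (the protocol is
  strand-specific); secondary/supplementary/unmapped records are dropped, and
  primary alignments stand proxy for unique mapping.
- Transcript mean coverage is rounded to three decimals at finalisation so
  the GFF output dialect round-trips bit-identically.
- Recorded introns must nest strictly inside the transcript and be pairwise
  disjoint; overlapping accepted junctions are resolved greedily by support,
  then position.
- An empty read set, an empty block set and an empty transcript set all flow
  through every stage and produce valid empty outputs.
- Boundary-error experiments (exact recovery, poly-A bias) are run with
  trimming disabled: trimming is a deliberate end-shortening step, and
  leaving it on would mix its few-base effect into measurements of the
  assembler's intrinsic boundary behaviour. Trimming has its own contract
  tests.
- Tests and the acceptance script use deliberately small problem sizes —
  20–25 genes for boundary and comparison fixtures, 200 transcripts for the
  poly-A direction experiment, 100 random sets of 100–400 reads for the
  block oracle — chosen as the smallest sizes at which each property is
  non-trivial.

## Known limitations

- Paired-end information is ignored by design; alternative splicing and
  isoform resolution are out of scope (rare in the target genomes).
- Very low-coverage non-coding transcripts fragment, inflating apparent
  SUT counts; no amount of parameter tuning fully fixes this without deeper
  sequencing.
- The polycistronic test is a coverage-continuity stand-in; orthogonal
  evidence (paired-end reads, polyadenylation sites) is needed for a
  definitive call.
- UTRs are measured against annotated gene spans; annotation errors (wrong
  start codons) surface as apparent UTR anomalies rather than being
  corrected.
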