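---
title: "strseq: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{strseq: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strseq)
```

## The problem

Short tandem repeats (STRs, microsatellites) are 1-6 bp motifs repeated in
tandem; alleles differ by motif copy number. Standard short-read pipelines
genotype them poorly: alignment across a length-polymorphic repeat is
ambiguous, PCR amplification introduces stutter (slippage reads whose
repeat count brackets the true allele, biased toward deletions), and
random fragmentation truncates many reads inside the repeat so they carry
no usable count.

`strseq` implements the informatics for a targeted-capture design that
sidesteps these problems. Each targeted locus is served by 40-mer primer
probes on both strands. In a captured read pair, Read 2 begins with the
probe sequence, so its alignment start position identifies the targeted
locus: every pair whose Read 2 aligns within 2 bases of an expected probe
position receives that probe's integer index (the `ZP` tag), and Read 1
inherits it from its mate without ever needing to align. Read 1 spans the
repeat itself and is genotyped by string matching, not alignment: a read
counts only if it contains the exact 15-base 5' flank, a variable region
with at least the locus minimum of exact tandem motif copies, and the
exact 15-base 3' flank. The repeat count is the variable-region length
divided by the motif length (a 28-base region over a GATA motif is 7
repeats).

## Genotype model

Spanning-read counts per repeat count form the locus allele histogram.
The major allele is the best-supported count. Every other count is a
candidate secondary allele, classed by its allelic distance `d` from the
major: `-1`, `+1`, `<-1`, `>+1`. A candidate makes the call heterozygous
when its reads reach a class-specific fraction of the major-allele reads:

| class | `-1` | `+1` | `<-1` | `>+1` |
|-------|------|------|-------|-------|
| threshold | 0.35 | 0.15 | 0.45 | 0.02 |

The asymmetry encodes two empirical facts: stutter is deletion-biased
(so a `-1` neighbour needs strong support before it is believed), and
long alleles are disproportionately lost to read-length truncation (so a
distant longer allele is believed on very little support). The `<-1`
threshold exceeding the `-1` threshold is kept exactly as published even
though it is counter-intuitive. `calibrate_thresholds()` reproduces the
calibration procedure: per class, sweep every observed
secondary-to-major fraction and keep the smallest threshold whose
false-call rate on known homozygotes stays at or below 0.01, maximizing
sensitivity on known heterozygotes. The published text phrases the 0.01
bound as a "type II" constraint while describing a false-positive
control; we expose it as the false-positive bound `max_false_positive`,
since maximizing sensitivity bounds type II by construction.

Tie-breaks the source leaves open, fixed here: a major-allele tie goes to
the shorter repeat (deletion-biased stutter makes the shorter
interpretation likelier) and is flagged; when several secondaries pass,
the one with most reads wins, then smaller |distance|, then shorter
allele (a diploid call admits at most two alleles). Non-integral variable
regions use floor division with a remainder flag. Calls below
`min_total_reads = 5` spanning reads are no-calls, echoing the 5x
coverage floor used for the orthogonal-method comparison.

**Dosage.** Genotypes from sequencing and from capillary electrophoresis
(CE) are compared on a platform-neutral scale: the dosage of a genotype
is the sum over both allele copies of (allele length - reference tract
length) in bp. A reference tract of 18 bp with heterozygous 16 bp and
24 bp alleles has dosage -2 + 6 = 4. The published example is
heterozygous; we take the summation form literally, so a homozygote
contributes its allele twice (`2 x (20 - 18) = 4`).

**Stutter fraction.** Non-allelic reads over total spanning reads,
per locus — the QC statistic that separates PCR-amplified from PCR-free
libraries.

## SNP calling and haplotyping

SNPs near the repeat are read from Read 2 only (single-strand by
design). Because the synthetic probe DNA matches the reference, the 40
probe bases are masked before any pileup: the first 40 aligned bases of
forward Read 2s, the last 40 of reverse ones. The caller is a deliberate
simplification of a Bayesian caller — a frequency-plus-quality pileup
honoring the published filter cascade (alternate fraction >= 0.05,
coverage >= 3, base quality >= 15, mapping quality >= 25, supporting
mapping-quality sum >= 90, supporting allele-quality sum >= 60; indels
and multi-nucleotide variants are out of scope). Post-filters: calls
inside repeat tracts (+/-5 b) are excluded, any two calls closer than
6 bp are both removed (the boundary at exactly 6 bp is kept; the
published "within 6 bp" is ambiguous against thinning-tool semantics,
so the boundary is configurable), non-PASS calls go, and the average
alternate base quality must exceed 8 (the published `QUAL/AO > 8`).

Haplotyping is read-backed, not statistical: for each pair with an
intact repeat whose masked Read 2 covers a called SNP, the (SNP base,
repeat count) pair is accumulated. Reads showing a third base, or an
allele whose called frequency is zero, are dropped. At a heterozygous
SNP each base takes its majority repeat count; at a homozygous SNP the
repeat margin is re-evaluated with the genotype threshold logic, giving
one or two haplotypes sharing the SNP base.

## Cohort layer

*CE comparison*: annotation boundaries differ between platforms by
whole repeat units, so a per-locus offset — the median over samples of
(sequencing allele − CE allele), pairing sorted alleles positionally —
is subtracted before the equality test. Concordance is then invariant
under any constant per-locus annotation shift (an acceptance property).

*Trios*: a child genotype is Mendelian-concordant when its two alleles
partition one-per-parent; a child haplotype set likewise, with a
homozygous child haplotype required in both parents. Parents are
re-evaluated at the child's variant sites; a parent carries a haplotype
when it holds at least 15% of the parent's phased reads there (longer
alleles lose reads to truncation and stutter spreads counts, so 50% is
not a usable bar). Only sites with >= 10 reads in all three members
qualify.

*Mixtures*: a haplotype present in the minor contributor and absent
from every major contributor is informative. Its expected read fraction
under minor ratio r is r/2 if the minor is heterozygous for it, r if
homozygous; its observed fraction is supporting reads over all phased
reads at the site. Detection requires >= 2 supporting reads — the
source reports detections without a floor; 2 guards against singleton
sequencing error. Regression diagnostics are computed on log10 scales
with zero observations excluded.

## The simulator: what it emulates, and what it does not

The simulator generates the same file formats the pipeline consumes
(panel bundle, FASTA genome, SAM/FASTQ reads) plus per-read truth, so
every pipeline claim can be tested against a known answer. Per locus it
lays out, on one synthetic chromosome: a primitive random motif (lengths
1-6, weighted toward tetramers), a repeat tract, unique 15-base flanks,
one plus and one minus 40-mer probe, one proximal SNP covered by the
plus-probe Read 2, and one guide-RNA cut boundary per probe orientation
(upstream and downstream), each placing the whole tract within 100 bases
of the cut. Loci are spaced 1 kb apart — targeted capture, not a
whole-genome model.

Stutter: a read's repeat count shifts with probability `p_stutter`;
the shift is a deletion with probability `p_deletion = 0.8` and has
magnitude `1 + Geometric(1 - step_decay)`. Defaults `p_stutter = 0.032`
(PCR) and `0.009` (PCR-free) echo the published cohort medians of 3.2%
and 0.9%. No quantitative step distribution is published; `step_decay =
0.05` (multi-unit steps ~5% of events) matches the order reported for
slippage models in the STR literature and was fixed before any
acceptance measurement. Base calls carry a flat Q35 quality with 0.1%
substitution errors — enough to exercise the quality filters, with no
instrument-profile modeling.

Fragmentation: the non-probe fragment end is either uniform over the
read-length window beside the tract (`random`) or, with probability
`on_target_prob = 0.56` (the published on-target read fraction under
CRISPR-Cas9 targeted fragmentation), normal around the cut boundary
with `jitter_sd = 1` b. Because spanning probability under random
fragmentation falls with tract length, the simulator reproduces the two
published effects of targeted fragmentation: a higher spanning-read
fraction and tighter heterozygous allele-fraction balance.

A green test on this world establishes the pipeline's logic — indexing,
extraction, thresholds, phasing arithmetic — under its stated noise
model. It does not establish robustness to real-data pathologies the
generator deliberately omits: off-target priming, alignment error,
flanking indels, repeat-adjacent homology, instrument-specific quality
decay.

## Numerical and convention choices

- **Coordinates** are 1-based inclusive internally (the R/Bioconductor
  convention); BED I/O converts at the boundary via rtracklayer, SAM is
  natively 1-based. The upstream design brief assumed 0-based half-open
  throughout; in R that convention would fight every container it
  touches, and the on-disk formats are unchanged either way.
- **Cut sites** are stored one per probe orientation (two per locus):
  a single-sided cut cannot serve both probe orientations, and the
  published design likewise placed guides on both sides of the repeat.
  A cut position is the coordinate of the first base downstream of the
  blunt cut, so an on-target fragment boundary equals it exactly.
- **Probe matching** uses alignment position only, never sequence;
  nearest probe wins within the 2-base tolerance and an exact tie is
  discarded with a warning rather than silently mis-indexed.
- **Flank matching** is exact string matching over an enumerated
  variant set (reference flank plus single-substitution alternates from
  called flank SNPs); no fuzzy matching. Mismatch tolerance belongs to
  the variant caller, not the matcher.
- **PAM geometry** for guide design is NGG with the blunt cut 3 bp 5'
  of the PAM (standard SpCas9), both configurable; the source does not
  state its PAM rule. "Additive genotype frequency > 1.0" for SNP
  validation is read as the cross-population sum of non-reference
  genotype frequencies — the definition is not given and this is a
  documented interpretation. The Willems unit-size text says 2-5 but
  lists a unit-6 score minimum; the filter supports 2-6 and callers may
  restrict.
- **Determinism**: every stochastic entry point takes a seed; equal
  seeds give byte-identical outputs, and the pipeline manifest carries a
  content signature to verify it.

## Known limitations

No gapped or partial-repeat genotyping (truncating reads are counted
only as filter statistics); biallelic substitutions only — no indel,
MNP, or multi-SNP haplotype extension; uniqueness screening is an
exhaustive scan suitable for desk-scale synthetic references, not a
genome-scale index; published cohort-level numbers that depend on the
deposited sequencing data (overall CE concordance, trio percentages,
stutter medians, dispersion s.d.) are represented by worked examples and
direction/property tests, not reproduced.
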