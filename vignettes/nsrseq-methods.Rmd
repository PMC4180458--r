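---
title: "NSR-seq primer design and ncRNA profiling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{NSR-seq primer design and ncRNA profiling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nsrseq)
```

## The problem

Ribosomal RNA dominates total RNA, so an RNA-seq library built with fully
random hexamer priming spends most of its reads on rRNA. The
"not-so-random" (NSR) priming strategy removes that waste at the priming
step: from the 4096 possible hexamers, discard every hexamer that has a
perfect match to the organism's rRNA transcripts, and prime cDNA synthesis
with the surviving set only. Libraries made this way are strand-specific
and strongly rRNA-depleted without a separate physical depletion step. For
the *C. elegans* rRNA complement (cytoplasmic 18S/28S/5.8S/5S plus the
mitochondrial rRNAs), this filter removes 3157 hexamers and leaves an NSR
set of 939.

This package implements the full computational side of that strategy:

1. **Primer design** — k-mer enumeration, rRNA filtering, adapter-bearing
   oligo sheets, and coverage statistics of the surviving set over target
   transcript collections (`enumerate_kmers()`, `filter_hexamers()`,
   `design_oligos()`, `hexamer_coverage()`).
2. **Quantification** — classification of aligned reads into genomic
   categories, per-transcript counting, RPKM, and spike-in ladder
   correlations that estimate priming/amplification bias
   (`classify_alignments()`, `count_reads()`, `compute_rpkm()`,
   `spikein_correlation()`).
3. **Differential ncRNA analysis** — two-fold threshold calling between a
   wild type and a regulator deletion mutant, chromosomal enrichment,
   genomic clustering of differential loci, condition-dependent status
   shifts, and a 2^-ddCt qPCR calculator (`call_differential()`,
   `chromosome_enrichment()`, `find_clusters()`, `status_shift()`,
   `ddct_fold_change()`).
4. **Promoter motif scanning** — strand-aware promoter windows around the
   TSS scanned for degenerate IUPAC motifs, by default the p53-family
   response element RRRCWWGYYY (`extract_promoters()`, `scan_motif()`,
   `motif_fraction()`).
5. **Synthetic data** — a deterministic generator that emulates the whole
   study design with a ground-truth ledger (`fixture_spec()`,
   `simulate_fixture()`, `simulate_spikein_ladder()`,
   `make_rrna_filter_case()`).

## Primer design conventions

**Strand mode.** "Perfect match to rRNA" is orientation-ambiguous: a
primer can match the rRNA sequence itself (sense), its reverse complement
(antisense), or either. `filter_hexamers()` exposes all three as
`mode = c("sense", "antisense", "both")` with `"sense"` as default, which
mirrors the operational description of aligning hexamer sequences to rRNA
transcripts. The three retained sets are nested (`both` ⊆ `sense`,
`both` ⊆ `antisense`), which the test suite asserts as an invariant.

**Alphabet.** References are uppercased and U→T-normalized on ingest, so
RNA-alphabet rRNA files work directly. IUPAC ambiguity codes are tolerated
in references, but any window containing one matches no k-mer: a primer
cannot perfectly match an ambiguous base. Characters outside the IUPAC DNA
alphabet are a hard error naming the offending record.

**Occurrence counting.** Coverage statistics count overlapping
occurrences, because each occurrence is a distinct priming start site; the
density statistic (transcript length / total occurrences) is the mean
spacing between available priming sites and is reported as `NA` when a
transcript has none.

**Oligo templates.** The emitted synthesis templates are
`adapter1 + N + reverse-complement(hexamer)` for first-strand priming and
`adapter2 + N + hexamer` for second-strand priming, with the
Illumina-compatible annealing sites `TCCGATCTCT`/`TCCGATCTGA` as defaults
and any IUPAC string accepted. Output order is the (lexicographic) set
order so oligo sheets are reproducible.

## Read classification and RPKM

Each primary alignment gets exactly one category by fixed priority:
rRNA > spike-in > sense-exonic mRNA > sense-exonic known ncRNA >
antisense-of-coding-exon > intronic > intergenic. "Sense" compares read
strand to transcript strand; antisense is defined only against coding
(mRNA) exons; rRNA and spike-in loci capture either strand, since reads on
those loci are rRNA/spike-in material regardless of orientation. The
minimum overlap is 1 base and configurable. Reads on chromosomes missing
from the annotation are counted as intergenic with a warning rather than
dropped, so category fractions always sum to 1 over classified reads.
Spike-in reads are reported as their own category (they are external
controls, not a genomic compartment); the Table-style renderer prints the
six canonical genomic columns and notes the spike-in percentage
separately.

Counting is by exon overlap, sense-only when `strandedness = "stranded"`
(the NSR libraries are strand-specific). A read overlapping several
transcripts increments each of them — the simplest reproducible convention
— and the per-sample library size is the number of primary alignments
including rRNA and spike-ins, consistent with reporting rRNA as a
percentage of mapped reads. RPKM is the exact textbook quantity
`count / (exonic_length/1000) / (library_size/1e6)`, asserted cell-by-cell
invertible in the tests.

**Correlation scale.** A spike-in ladder spanning six orders of magnitude
makes linear Pearson correlation degenerate (the top species dominate), so
`spikein_correlation()` defaults to log10 with a pseudocount of 0.01 RPKM.
The pseudocount keeps undetected species finite; set it to 0 for exact
affine-invariance checks on all-positive data (zeros are then dropped as
non-finite, with the used species count reported). Linear scale is
available.

## Differential calling

Calling is by pure thresholds, not a statistical test: a locus passes when
the larger of the two RPKM values exceeds `rpkm_min` (default 1) and the
pseudocounted ratio `(b + 0.01)/(a + 0.01)` is at least `fc_min` (default
2) in either direction. The gate is applied to the larger sample so on/off
loci — which the repressed/activated language explicitly includes — are
not silently discarded. The pseudocount of 0.01 RPKM keeps on/off ratios
finite and is configurable. Direction is named from the regulator's
perspective: higher in the mutant means the locus is repressed by the
factor in the wild type.

**Clusters.** No community-standard clustering criterion exists for differential
ncRNA loci, so `find_clusters()` uses transparent single-linkage chaining:
loci whose successive start coordinates lie within `max_gap` (default
10 kb) chain together, chains need `min_size` members (default 3), and by
default members must share a direction. The defaults are recorded in the
output and the result is provably order-invariant. Because the criterion
is a package choice, no externally reported cluster count is treated as a
recoverable quantity; instead the generator plants clusters with known
geometry and the suite requires exact recovery.

**Enrichment.** Chromosomal enrichment compares the passing loci against
the universe the calling ran over (all annotated ncRNA loci, not all
genes) with a one-sided exact binomial test per chromosome; no
multiplicity correction by default, Bonferroni available.

**qPCR.** `ddct_fold_change()` implements 2^-ddCt with replicate Ct rows;
the mean ddCt maps to a fold change and the replicate SEM is reported on
the ddCt (cycle) scale, where the error distribution is symmetric.

## Promoter windows and motif scanning

Promoter windows span 2 kb upstream through 500 bp downstream of the TSS
(TSS included in the downstream part), oriented in transcription
direction; minus-strand windows are reverse-complemented so position 0 is
always the most-upstream base. Windows are clipped at chromosome ends with
a warning, and the TSS position inside the clipped window is tracked so
hit offsets stay TSS-anchored. Hit offsets are signed (negative =
upstream) and anchor the match's most-upstream base; for unclipped
windows they range over [-2000, 500 - motif length].

Scanning honors IUPAC degeneracy in the pattern only — an N in the genome
matches nothing — and scans both strands by default, since p53-family
response elements are functional in either orientation. The implementation
delegates the match to `Biostrings::matchPattern(fixed = "subject")`; the
test suite independently verifies it against the exhaustive expansion of
the pattern (256 concrete 10-mers for RRRCWWGYYY) at every offset.
Multi-isoform genes should be reduced to their most-upstream isoform
before window extraction; the functions operate per supplied transcript
row, so per-isoform scanning is available by simply not reducing.

## The synthetic-data generator

`simulate_fixture()` builds, deterministically under one seed, everything
the downstream modules consume: a six-chromosome genome at GC 0.36
(worm-like base composition), annotated mRNA loci (two 300-nt exons with
a 200-nt intron), 200 single-exon ncRNA loci, rRNA loci, a 92-species
spike-in ladder spanning a 10^6-fold concentration range with lengths
250–2000 nt, and per-sample 80-nt single-end reads whose genomic category
mix defaults to 10% rRNA / 60% mRNA / 5% ncRNA / 5% antisense /
10% intronic / 10% intergenic with ~0.5% spike-in reads.

**Count model.** Expected counts are per-locus weights times the planted
fold in the comparison sample, times a per-locus lognormal bias
multiplier `10^N(0, sigma)` (default sigma 0.1) that is drawn once and
shared across samples, with independent per-sample Poisson sampling on
top. The shared multiplier models species-specific priming and
amplification bias, which is the reproducible component of NSR libraries:
it distorts sample-vs-reference ladder correlations but cancels in
sample-vs-sample comparisons and in two-condition fold changes, exactly
the structure seen in real spike-in tables. A negative binomial layer is
deliberately absent: without replicate-dispersion information there is
nothing to calibrate it against, and the Poisson-plus-shared-bias model
already reproduces the qualitative behavior the tests need. Planted
differential loci (default: 20 ncRNA loci at 2.5-fold, 6 of them in two
3-member clusters with 4-kb internal gaps, the rest isolated singletons)
receive a higher base weight so they sit well above the RPKM gate, as
called loci must.

**Layout.** The genome layout is deterministic: planted clusters go at the
head of their chromosome with a 25-kb isolation margin, then regular loci
are dealt round-robin across chromosomes with 5-kb gaps. The margins
guarantee that planted clusters can be recovered exactly at the default
10-kb chaining gap and that isolated differential singletons never chain
by accident. Infeasible geometry (loci exceeding a chromosome) fails
before any file is written.

**Ladder geometry.** The spike-in ladder mimics the commercial mixes: 23
concentration levels of 4 species each. Lengths are drawn uniformly over
250–2000 nt and dealt to levels snake-wise by size, so each level's
aggregate length — and therefore its aggregate expected read mass — is
balanced and the expected-count span tracks the configured 10^6 dynamic
range within a factor of two. Expected read mass is proportional to
concentration × length, so RPKM is proportional to concentration and a
noise-free ladder gives a reference correlation of exactly 1 (the
generator returns continuous expected mass instead of integers when
`sigma = 0, poisson = FALSE`, precisely so this contract is checkable
without rounding distortion).

**What the generator does not emulate.** Sequencing errors, quality
variation, adapter contamination, mappability, multi-mapping, positional
or GC priming bias (an optional hexamer-start bias is out of scope), and
real annotation complexity (overlapping genes, isoforms). Passing the
planted-recovery suites therefore demonstrates that the analysis code is
correct, not that the thresholds would achieve the same sensitivity on
real libraries.

## Problem sizes and numerical choices

The default fixture uses 200,000 reads per sample across 244 loci — small
enough that the whole two-condition pipeline (simulation, classification,
counting, RPKM, calling, clustering) runs in seconds, large enough that
planted 2.5-fold signals at the default noise are recovered with
sensitivity ≥ 0.95 and false-positive rate ≤ 0.05 with comfortable
margin. The noisy-ladder correlation test asserts a band ([0.93, 0.97] at
sigma = 0.2) frozen from a 100-replicate simulation. Exactness contracts
(RPKM inversion, zero-noise correlation, oracle equivalence of the k-mer
filter and the motif scanner) are asserted to 1e-12 or exactly.
Percentages in rendered report tables use half-up rounding to two
decimals, implemented with an epsilon guard against binary representation
error. Coordinates are 0-based half-open internally and 1-based closed in
GFF3/SAM, converted at the I/O boundary.

## Known limitations

- Organism-specific results (the 939-hexamer set from the real rRNA
  complement, spike-in correlations of real libraries, differential ncRNA
  counts) require the organism's rRNA reference, the commercial ladder
  FASTA, and accessioned sequencing data, none of which are bundled; the
  package certifies its operations against brute-force oracles and
  planted-truth fixtures instead, and `make_rrna_filter_case()` can
  reconstruct a reference with any prescribed removal count for scale
  testing.
- Threshold calling has no replicate-aware error model by design; treat
  the calls as candidate lists, as the qPCR validation workflow assumes.
- The cluster definition is a package convention; vary `max_gap` and
  `min_size` to probe robustness before interpreting cluster counts.
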