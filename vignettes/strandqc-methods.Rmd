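---
title: "strandqc: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{strandqc: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strandqc)
```

# Scope

`strandqc` computes the alignment-level quality metrics used to evaluate
strand-specific (dUTP/UNG) paired-end RNA-seq libraries: junction-based
strand-specificity, read-category percentages, rRNA and mitochondrial
fractions, gene-level expression and detection, the 5′/3′ transcript
coverage-bias ratio, base error rates by mismatch counting, spike-in
dose-response and error rates, insert-size estimation from mitochondrial
alignments, seeded down-sampling and duplicate marking. It consumes
coordinate-sorted paired-end alignments (plain-text SAM dialect), a GTF
gene annotation, a genome FASTA and a spike-in panel; it does not perform
genome alignment, differential expression, isoform quantification or
clustering.

Every metric is validated by *parameter recovery*: the package ships a
synthetic-data generator that emits toy references, annotation, spike-in
panels and already-aligned spliced read pairs with full ground-truth
bookkeeping, and the test suite checks that each metric recovers the
generative parameter at a stated tolerance.

# The statistics

## Strand-specificity

The dUTP protocol destroys the second cDNA strand, so in a perfect library
the second-in-pair read maps on the transcript's strand. The statistic used
here is junction-based: for every annotated exon-exon junction, spanning
reads are tallied as *sense* or *antisense* according to the fragment
strand inferred from the flags under the configured library orientation,
and strand-specificity is the fraction of junctions with **zero** antisense
spanning reads. Restricting to junction-spanning reads excludes signal from
genomic-DNA background, which cannot produce spliced alignments.

Two deliberate choices:

* **A read spans a junction only when its N-skip matches the annotated
  intron exactly (both coordinates) and both flanking M blocks cover at
  least `min_overhang` (default 3) reference bases.** The exact-match rule
  is the strictest reading of "reads spanning exon-exon junctions" and
  refuses credit to misaligned skips; the overhang suppresses 1–2-base
  spurious spans.
* **The default denominator is junctions observed by at least one spanning
  read.** Over *all* annotated junctions the statistic would reward shallow
  libraries (unobserved junctions trivially have zero antisense reads);
  over observed junctions it is depth-robust. The literal all-junctions
  variant is available via `literal_denominator = TRUE`.

Because strand is inferred from flags, not sequence, substitution errors
cannot flip it; the suite checks that the statistic is exactly 1.0 whenever
the generator's antisense rate is 0, at any error rate, and strictly
decreasing in the antisense rate. Note the statistic saturates quickly with
depth: at typical per-junction coverage even a 1% antisense rate leaves
few junctions clean, which is why strand-agnostic libraries score near
zero.

## Read classification and expression

Reads are classified by **majority of aligned reference bases with
precedence exonic > intronic > intergenic**: exonic if at least half the
M-operation bases fall in annotated exons, else intronic if at least half
fall within a gene span, else intergenic. The annotation never defines a
tie-break, so the ≥50% rule with fixed precedence keeps the decision
deterministic and testable.

A read is assigned to a gene when it is exonic and all of its
exon-overlapping bases fall within that single gene; reads touching exons
of two genes are tallied as ambiguous and excluded from expression (but
still classified, so category percentages lose no evidence). Expression is
reported as RPKM over the union of exon bases per gene — the era-appropriate
unit that makes the correlation and coverage computations unit-free —
and cross-library correlation is the Pearson correlation of
`log2(RPKM + 0.1)` over genes detected in at least one library. The 0.1
pseudocount is calibrated to real library depths (millions of assigned
reads); on toy-depth simulations a single read can produce a large RPKM, so
the replicate-concordance test uses a deep, mildly-dispersed world where
every expressed gene is well-sampled.

Duplicate-flagged reads are excluded from every metric except the
duplicate rate itself, mirroring standard post-markup practice.

## 5′/3′ coverage bias

For one transcript per gene (the longest), coverage is counted over exonic
bases only and concatenated 5′→3′ (reversed for minus-strand transcripts).
Transcripts with exonic length ≥ 500 and mean coverage ≥ 5 are
mean-normalised — so highly expressed transcripts cannot dominate —
rebinned to 100 bins, and averaged. The ratio is the mean of bins 1–20 over
the mean of bins 81–100. The printed 0.87–1.1 range of comparable
pipelines has no recoverable formula, so those values are treated as
qualitative anchors only: ≈1 means unbiased, <1 means 3′ bias. A 20% window
is wide enough to be stable at moderate depth while still contrasting the
transcript ends.

## Error rates

The base error rate counts substitutions in M-operation bases against the
reference (soft-clips, insertions, deletions and N-skips excluded from both
numerator and denominator), optionally above a base-quality floor and
outside a BED-style variant mask. Real variants inflate the absolute value,
which is why the statistic is meant for *relative* comparisons between
libraries; the mask is provided instead of a variant caller.

The spike-in error rate compares assigned pool reads against the known
panel sequences over gapless aligned spans, reported per 1000 nt.
Indels are not modelled by the generator and not counted — the
generator/estimator pair is kept self-consistent and substitutions-only,
and this is stated rather than silent.

## Spike-in analysis

The pool is every pair in which at least one mate is unmapped. A small
internal realigner assigns pool reads to panel members: exact
`seed_length`-mer seeding (default 20, both orientations), gapless
extension over the full read, identity over the aligned span, with
acceptance at identity ≥ 0.95 and span ≥ 0.9 of the read, ties broken by
identity, span, then lexicographic id — deterministic and order-independent.
This is a contract-level stand-in for an external aligner run in
high-specificity mode, not a reimplementation of one.

One caveat matters when the realigner feeds the error-rate estimate: an
identity *floor* censors exactly the high-error reads being measured. At a
1% substitution rate, rejecting reads below 0.95 identity (≥4 mismatches in
75 nt) biases the estimate downward by roughly a third of the binomial 99%
interval. The error-recovery acceptance run therefore uses
`min_identity = 0.9`, at which the rejection probability (≥8 substitutions)
is ~1e-7 and censoring is negligible for every tested rate.

Dose-response is the Pearson correlation of `log2(observed abundance)`
(assigned reads per kilobase of spike-in) versus `log2(expected
concentration)` over members with at least one read. Because undetected
members are excluded, abundances are strictly positive and **no pseudocount
is needed**; the default of 0 keeps the statistic exactly 1.0 for perfectly
proportional counts (a pseudocount argument exists for users who want one).
In the recovery test, Poisson counts are drawn with
concentration-proportional means scaled so the least-concentrated member
has mean 100: every member is then informative and the log-log relation is
sampled over the full four-order dose range, which is the regime the
statistic is designed to summarise. At pipeline scale with only a few
hundred spike reads the correlation is legitimately much lower — detection
at the low-concentration end is Poisson-limited — and the package reports
whatever the data support.

## Insert size, down-sampling, duplicates

Insert size uses pairs where both mates map to the mitochondrial contig
with the proper-pair flag and no N operation: chrM is deep and unspliced,
so the outer distance (the positive template length, once per pair) is an
unconfounded fragment-length estimate. Inserts of 0 or above `max_insert`
(default 2000) are excluded.

Down-sampling selects an exact number of distinct fragment names uniformly
without replacement under a caller-supplied seed and keeps mates together.
Exact counts (rather than per-read Bernoulli thinning) remove one source of
noise when libraries are compared at matched depth. With
`downsample_repeats > 1`, `run_qc()` repeats the downstream pipeline with
consecutive seeds and attaches a per-metric mean/min/max stability table —
the standard way to check that depth-normalised results are stable under
random read sampling.

Duplicate marking groups fragments by (read1 contig, unclipped 5′ position,
strand; read2 likewise), where unclipped positions back out soft clips so
differently-clipped copies still collide. The highest summed base quality
wins; ties break by query name, so marking is independent of record order.
Optical-duplicate detection is omitted — synthetic names carry no tile
coordinates. Fragments with an unmapped mate are never flagged.

On a toy genome the coordinate space is small, so *distinct* fragments can
legitimately share both endpoints; any coordinate-keyed marker must flag
them, and the measured rate sits slightly above the PCR-copy bookkeeping
truth (by ~1–3% at 20k fragments over 120 genes — on a real genome this
false-positive rate is negligible). The duplicate-recovery acceptance run
therefore uses a collision-negligible world (300 genes, dispersion 0.5,
3000 fragments; expected chance collisions ≪ 1 fragment) so the check
isolates the marker; the suite also asserts the measured rate never falls
below truth, which the key construction guarantees.

# The synthetic world

Defaults describe a healthy dUTP library of the kind the metrics were
built to monitor: PE75 reads; fragment lengths Normal(300, 30) truncated to
`[read length, source length]`; 120 spliced genes (2–6 exons of 120–400 nt,
introns 100–600 nt) on two autosome-like contigs plus two single-exon rRNA
genes and one long unspliced mitochondrial gene on a 16 kb chrM; per-gene
expression weights log-normal with σ = 1; substitution rate 0.003 (middle
of the 0.002–0.004 range typical of such libraries); geometric PCR copies
with mean 0.1 extra (≈9% duplicates); category fractions 1% rRNA
(an efficient mRNA isolation), 5% mitochondrial, 15% intronic, 3%
intergenic, 2% spike-in, remainder exonic; a 92-member spike-in panel with
log-uniform concentrations spanning four orders of magnitude and lengths
250–2000 nt; antisense rate 0 and no 3′ bias unless the experiment turns
those knobs.

Mechanics worth knowing:

* Reads are emitted as **already-aligned records** with exact spliced
  cigars (N operations precisely at annotated introns), because every stage
  under study starts downstream of alignment. There is no alignment-error
  model.
* The 3′-bias knob draws fragment starts with density ∝ `exp(b·x)` in
  relative transcript position `x`, so `b = 0` is uniform and larger `b`
  pushes starts toward the 3′ end; the bias acceptance run uses `b = 3`,
  a strong but realistic degradation profile.
* Geometric PCR-copy counts give a one-parameter duplication knob with
  expected duplicate fraction `m/(1+m)`.
* Spike-in fragments are emitted as unmapped pairs carrying sequence; a
  configurable fraction instead pairs an unmapped spike mate with a mapped
  genomic "decoy" read (which carries substitution errors like any other
  read), so pool extraction exercises the "unaligned itself, or has an
  unaligned mate" rule in both shapes.
* Everything is reproducible: the reference generator and the library
  simulator consume separate streams derived from the config seed, and
  identical configs give byte-identical files.

What a green test does **not** establish: the generator has no indels, no
quality-score structure, no GC or positional sequence bias, no optical
duplicates, no alignment errors, and toy-scale gene models. Recovery tests
validate the estimators' contracts, not their behaviour on pathological
real data.

# Numerical and degenerate-input choices

* All internal coordinates are 0-based half-open; SAM (1-based) and GTF
  (1-based inclusive) are converted only at the file boundary.
* Only cigar operations M, I, D, N, S are accepted; hard clips and padding
  fail loudly rather than miscounting silently.
* Metrics with empty denominators (no junction-spanning reads, no exonic
  reads, no qualifying mitochondrial pairs, <3 detected spike-ins) return
  `NA` with a warning, and reports serialise them as JSON `null` — present,
  never absent.
* Report JSON is written with 17 significant digits so a round-trip
  reproduces every double exactly; the panel table writes concentrations
  with `%.17g` for the same reason.
* Ties in duplicate marking and spike-in assignment are broken
  deterministically (quality/identity, then span, then lexicographic), so
  every pipeline output is invariant under record shuffling.

# Known limitations

* The category rule, strand-specificity denominator, 5′/3′ window and
  expression unit are reasoned reconstructions of common practice, stated
  above; published values computed with in-house tools can differ in
  detail, so cross-pipeline comparisons should be qualitative.
* The spike-in realigner is gapless; reads with indels against the panel
  are unassigned rather than gap-aligned.
* `% rRNA` is alignment-based (reads assigned to rRNA-biotype genes), not
  a k-mer screen; libraries whose rRNA fails to align are under-counted.
* Down-sampling before duplicate marking is the default stage order (the
  order depth-matched comparisons are usually run in); the reverse order is
  available via `downsample_after_dedup`.
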