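---
title: "Detecting recombination-suppression blocks on a Y chromosome from male-specific k-mers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting recombination-suppression blocks on a Y chromosome from male-specific k-mers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ystrata)
```

## The problem

In an XY system the male-specific region of the Y does not recombine with the
X, so it accumulates substitutions that exist in no female genome. If
recombination stopped in discrete events rather than gradually, the Y should
carry *evolutionary strata*: contiguous spans with distinct levels of X–Y
divergence, visible as steps in the density of male-specific sequence. With
short-read data from several males and females and a *phased* assembly of one
male, those strata can be located without ever assembling the Y end-to-end:

1. count fixed-length words (k-mers, default k = 16) in each individual's
   reads;
2. keep k-mers present at coverage in **all** males and at/below error
   tolerance in **all** females — the putative hemizygous-Y vocabulary;
3. match that vocabulary against both haplotypes of every phased contig: a
   well-phased Y-linked contig shows a strongly asymmetric match count, and
   the denser haplotype is its Y copy;
4. sort Y-linked contigs by male-specific k-mer density and scan for step
   changes; maximal runs between steps are **k-mer density blocks (KDBs)**,
   the candidate strata;
5. place contigs on an annotated relative's genome via best alignment hits to
   check whether blocks retain ancestral gene order (collinearity).

The package implements this chain end to end, plus a seeded generator of
ground-truthed synthetic studies used by the test suite.

## Counting and matching (module conventions)

K-mers are encoded 2 bits per base and collapsed to the *canonical* form, the
numerically smaller of a window and its reverse complement. Unstranded short
reads sample both strands uniformly, so stranded counting would halve and
split counts arbitrarily; canonical counting makes the read strand
irrelevant. A non-canonical mode is exposed (`canonical = FALSE`) for
strand-resolved inputs. Windows containing any non-ACGT character contribute
nothing (they are skipped whole, the standard k-mer-counter rule), and
soft-masked lowercase bases count as their uppercase equivalents — masking
affects only effective length, below. Positions are 0-based, intervals
half-open. The counting and matching kernels are written in C++ (collect,
sort, run-length encode) because a 16-mer code does not fit an R integer and
tens of millions of windows per sample are routine.

## Per-sample thresholds and the coverage spectrum

A k-mer count spectrum has an error peak at counts 1–2, a trough, and a
coverage mode; truly Y-linked k-mers sit near *half* the diploid depth
(hemizygous). The male-specific filter keeps a k-mer iff its count is
`>= male_min` in every male and `<= female_max` in every female (absent = 0).
All bounds are inclusive, which normalises the published exclusive phrasings
(`> 24` becomes `male_min = 25`, and females are excluded above their
tolerance: `female_max` 21/9/8). The shipped `paper_thresholds()` profile
records those six cutoffs; every threshold is an explicit parameter because
it must track each sample's actual depth.

`find_error_trough()` locates the error/genomic boundary as the end of the
initial descent of the spectrum (the first upward turn, ties to the smaller
count, optional 3-bin smoothing). A formalisation that takes the global
argmax over counts ≥ 2 as "the mode" fails on realistic spectra: at 1 %
per-base error the count-2 bin (recurrent errors) can exceed every coverage
bin, leaving no interior mode; the first-upturn rule is the convention
k-mer-spectrum tools use and reduces to the same answer on clean spectra.
A monotone spectrum raises an error rather than guessing.

For the synthetic study at 20× per haplotype, `synthetic_thresholds()` uses
`male_min` 5 (reference) / 3 (additional) and `female_max` 2: Y k-mers are
expected near 17× (20× scaled by the fraction of read windows that contain a
full k-mer, (100−16+1)/100), error k-mers at 1–2×, and a female read set
shows a true Y k-mer only through a specific error at a specific site
(expected count ≈ 0.1 per variant window), so a tolerance of 2 discards
almost nothing real.

## Haplotype assignment and the selection cascade

For each contig both haplotypes are matched against the male-specific set.
`ratio` is larger/smaller count (`Inf` when the smaller is 0 — the cleanest
phasing signal); an exact tie carries no signal and the contig is never
selectable. Density uses *effective length*: sequence length minus N/n
(always) and minus soft-masked bases for long-read contigs whose repeats are
actually resolved (`is_bac`), so unresolved gaps do not dilute density.
Selection keeps contigs with `ratio >= 2.5`, at least 30 male-specific
k-mers on the Y haplotype, and at most 2000 effective bp per k-mer — all
inclusive ("at least" phrasing) — and orders them densest first with
contig-id tie-breaks, so every downstream step is deterministic.

## Segmentation: the leading/trailing ratio scan

With contigs sorted densest first, position *i* (a 0-based boundary after
*i* contigs) gets the ratio of the mean density of the five contigs already
passed (trailing, denser) to the five about to be entered (leading). Means
are taken over density in k-mers per bp; the reciprocal scale
(`convention = "bp_per_kmer"`) is exposed because means of reciprocals
differ and plots are conventionally drawn on bp-per-kmer. Within a
homogeneous block the ratio hovers near 1; a step between blocks appears as
a peak near the fold change.

Breakpoints are scan positions reaching `peak_min_ratio` (default 1.5) that
are strict local maxima within `min_separation` positions (default = window,
leftmost of a plateau). Two numerical conventions deserve note:

* **Edge positions are never peaks** (unless the scan is shorter than three
  positions, where no interior exists). Because the contigs are *sorted*,
  the last leading window holds the smallest order statistics of the final
  block, so the ratio drifts upward into the scan edge even for a perfectly
  homogeneous block — with per-contig count CV ≈ 0.3 the expected tail
  ratio is ≈ 1.7, above any usable threshold. A monotone rise into the edge
  is a tail artifact, not a peak.
* **The threshold has no principled universal value** — the published
  analysis read peaks by eye. 1.5 separates ≥ 1.5-fold shifts from
  within-block sorting noise at the simulated conditions, but the same
  sorting attenuates true 3× steps (the trailing window holds the *low*
  order statistics of the denser block): across 50 generator seeds the
  default preset's two 3× boundaries are both recovered within ±1 contig in
  92 % of runs, with the misses being true peaks attenuated just below 1.5
  or spurious interior peaks in the sparsest stratum. That failure rate is
  a property of the windowed-ratio heuristic at ~11 variants per contig,
  not of the implementation.

`assign_blocks()` turns *k* breakpoints into *k*+1 contiguous blocks; means
over blocks use k-mers-per-bp (block `mean_bp_per_kmer` is the reciprocal of
the mean density), and block means are automatically ordered because the
contig list is.

## Synteny anchors

Alignment itself is out of scope; the package consumes the 12-column tabular
hit format, reduces to one best hit per contig (max bitscore, ties by file
order then subject name — "first hit" formalised), anchors each contig at
the midpoint of its best hit's subject interval, and reports per block: the
dominant chromosome (mode), the fraction and span of anchors on it,
secondary chromosomes, and a Kendall-type concordance in [−1, 1] between
density rank and anchor position (tau-a: concordant minus discordant pairs
over all pairs; undefined below two same-chromosome anchors).

## The synthetic study

The generator is the package's stand-in for the original sequencing data and
defines the conditions every end-to-end test uses:

* ancestral X: uniform random DNA; Y = X plus per-stratum substitutions at
  the stratum's variant density (defaults 0.01 / 0.0033 / 0.0011 per bp over
  three 200 kb strata — 3× steps, the smallest the scan is designed for);
* substitutions are Poisson in number and placed uniformly with pairwise
  spacing > k (a shifted uniform construction, so the count is exactly
  Poisson with no thinning bias); each substitution then creates ≈ k
  Y-specific k-mers and no window covers two variants, which makes planted
  k-mer counts analytically predictable and recorded exactly in the truth
  tables;
* the male's assembly is a 10 kb tiling: sex contigs carry (X window, Y
  window) with the Y haplotype index randomised per contig; autosomal
  contigs differ only by heterozygous SNVs at 0.001/bp; 5 % of contigs get a
  central N-run over 10 % of their length to exercise effective-length
  rules;
* males are sequenced as {X, Y} plus a diploid autosome, females as {X, X′}
  (X′ = X with individual heterozygous SNVs at 0.001/bp), at 20× per
  haplotype, 100 bp reads, uniform starts, random strand; the default is
  noiseless and robustness runs use 1 % uniform substitution error;
* one master seed derives labelled sub-seeds per stream, so adding a sample
  leaves every other file byte-identical.

Desk-scale sizes (600 kb sex region, 200 kb autosome, six samples) keep a
full simulate-count-filter-score-segment run around one to two minutes while
leaving ≈ 100–1600 planted k-mers per contig, enough to expose the
order-statistics effects discussed above. What the generator does **not**
emulate: indels and structural divergence (substitution-only), repeats and
paralogy (uniform random background), linked-read barcoding, quality-score
structure, GC bias, and real assembly phasing errors. Passing tests
therefore demonstrate the inference chain's correctness and its noise
behaviour under the stated model — not performance on real genomes, where
repeat-induced k-mer collisions and imperfect phasing are the dominant
error sources.

## Degenerate inputs and numerical choices

An empty male-specific set (or no selected contigs) ends the pipeline
cleanly with zero blocks; fewer selected contigs than `2 * window` yields a
single block without a scan. Ties in haplotype counts give no Y call. A
zero match count on the minor haplotype gives `ratio = Inf`, which passes
any ratio threshold. Breakpoints must be strictly inside (0, n). All
randomness is R's Mersenne-Twister under explicit sub-seeds; gzip output
carries no timestamps, so identical config + seed reproduces byte-identical
files (asserted in the tests).

## Problem sizes used by the tests

Unit tests run oracle comparisons at ≤ 5 kb sequences and ≤ 10,000-k-mer
tables; the end-to-end tests run the full default preset (noiseless and at
1 % error), a zero-divergence null, and a reduced two-stratum determinism
re-run. The whole suite completes in a few minutes on one core.
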