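---
title: "Segment-based joint Poisson quantification of transcript abundance"
author: "segquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segment-based joint Poisson quantification of transcript abundance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages(library(segquant))
```

## The problem

A short RNA-seq read rarely identifies its source transcript uniquely:
alternative isoforms of one gene overlap, and paralogous genes and
pseudogenes share long stretches of sequence. Quantification methods
that discard multi-mapping reads, or that distribute them by ad hoc
rules, systematically misestimate exactly the genes for which
quantification is hardest. The mainstream answer is a multinomial
model over individual reads with a hidden origin variable, fit by EM.
segquant implements the alternative: make mappability explicit in a
precomputed partition of the transcriptome, and the hidden variable
disappears.

## Segments, virtual reads, and sequence-sharing sets

A *virtual read* is a read-length substring of a transcript (for
paired-end data, a pair of such substrings whose end-to-end span is a
fragment size). The multiset of (transcript, number of positions) to
which a virtual read's sequence maps is its *alignment class* --
`[t1, t2, t3, t3]` is the class of a sequence occurring once on t1 and
t2 and twice on t3 (an internal repeat). All distinct virtual reads
with the same class form a *segment* $C$; the number of distinct
virtual reads in it is the segment length $L_C$ at that fragment size.
When a fragment-size distribution is available, the overall
$L_C = \sum_F P(F)\, L_C(F)$. Segment lengths adjust for mappability
and read length automatically: summed with multiplicity over the
segments containing a transcript, they tile the transcript exactly
($\sum_C m_{t}(C) L_C = \ell_t - r + 1$ for read length $r$, a
conservation law the test suite checks on random transcriptomes).

Transcripts connected, directly or transitively, by shared segments
form a *sequence-sharing set*: the smallest closed unit on which
estimation must be joint. The sets are the connected components of the
transcript--segment incidence graph and partition the transcriptome.

## The model

The observed read count $X_C$ of each segment is modeled as Poisson
with mean proportional to the summed rates of its class members times
its length:

$$X_C \sim \mathrm{Poisson}\!\left(\lambda_C\right), \qquad
  \lambda_C = \Big(\sum_{i \in Z_C} e_i\Big)\, L_C\, M ,$$

with $e_i$ the abundance of transcript $i$ (expected reads per
virtual-length unit), multiplicities counted ($e_{t_3}$ enters twice
for `[t1,t2,t3,t3]`), and $M$ a depth scale factor. Within each
sequence-sharing set the joint likelihood $\prod_C LH(e; X_C)$ is
maximized over all its segments simultaneously. Because every read
falls in exactly one segment, there is no hidden assignment variable
and no EM; the model is nevertheless statistically equivalent to the
conditional multinomial likelihood over segment counts, which the test
suite verifies by brute force on small instances. We fix $M = 1$
during optimization: $M$ rescales $e$ linearly and cancels in TPM, so
all depth normalization happens afterwards.

From the fitted rates, with $N$ counted reads:
$\mathrm{FPKM}_i = e_i \cdot 10^9 / N$,
$\mathrm{TPM}_i = \mathrm{FPKM}_i / \sum_j \mathrm{FPKM}_j \times 10^6$,
and the inferred read count
$\widehat{\mathrm{Readcount}}_i = N \cdot \mathrm{FPKM}_i
 \big(\sum_{i \in C} L_C\big) / 10^9$, where
$\sum_{i \in C} L_C$ is the *effective length* of transcript $i$ --
the sum of the lengths of all segments containing it. We sum segment
lengths here *without* multiplicity weighting: the effective length is
the amount of distinct mappable sequence available to the transcript,
and an internal repeat does not add new distinct virtual-read
sequences. Gene-level counts are sums over the gene's isoforms.

A two-gene instance makes the mechanics concrete: genes of virtual
lengths 10 and 20 sharing a region of length 3 produce three segments
(lengths 7, 17, 3) with counts 70, 340, 90. The joint MLE is
$\hat e = (10, 20)$, and the 90 shared reads split 30:60 -- the read
densities observed in the uniquely mappable regions:

```{r worked-example}
ex <- twoGeneExample()
fit <- hillClimb(ex$A, ex$lengths, ex$counts)
round(as.numeric(fit), 3)
allocateMultireads(as.numeric(fit), ex$A, ex$counts)[3, ]
```

## Counting reads

The counting stage takes "n mismatches, all" alignments (SAM/BAM, all
alignments per read reported, `NM` tags or `MD` fallback) and filters
each read to its minimum-mismatch set ("n mismatches, best") before
resolving its alignment class against the index. This filtering
matters: near the error rates of real data, keeping *all*
mismatch-tolerant alignments makes reads from near-identical paralogs
ambiguous that perfect matching would have placed, biasing unique-read
counts toward dissimilar genes; keeping only each read's best
alignments restores the balance. `mismatchStrategyExperiment()`
reproduces this on three 56-bp genes, two identical except at two
positions, with 1000 full-length reads per gene, aligned by exhaustive
Hamming comparison so no external aligner is involved.

Reads whose class is not in the index (pruned segments, or classes
that only mismatches can create) are discarded with a reason, as are
reads with soft-clips or indels (the model assumes fixed-length
ungapped virtual reads), reads with more than 100 alignments after
best filtering (little information, per-read cap configurable),
paired reads whose retained alignments imply more than one fragment
size, and -- for stranded libraries -- antisense alignments. The
per-reason tally is exact: counted plus discarded equals reads seen.
The empirical fragment-size distribution of the counted pairs, raw and
unsmoothed, truncated and renormalized to the indexed range, provides
the weights for $L_C$; single-end fixed-length data use a point mass
at the read length (the read length acts as the minimum fragment
size).

## Optimization

Each set's log-likelihood is concave in $e$ on the non-negative
orthant. We maximize it by projected gradient ascent with an adaptive
step: a step is accepted only if the likelihood increases (the climb
is monotone), doubled after acceptance and halved on rejection, with
coordinates clamped at zero. Convergence is declared when the relative
change of every coordinate stays below the user precision (default
$10^{-3}$) for three consecutive accepted steps; `maxIterations`
(default $10^5$) caps the climb with a warning. Single-transcript sets
use the closed form $\hat e = \sum X_C / \sum m\,L_C$; sets with no
observed reads are reported at zero without optimization.

The climb is restarted 4 times (configurable) from random initial
points -- a log-uniform scalar spanning $[10^{-3}, 10^3]$ times the
set's mean-rate scale, applied to all coordinates -- and the
coordinate-wise mean of the converged points is reported. Placing the
initial points on the diagonal is a deliberate design choice: gradient
dynamics then treat transcripts the data cannot distinguish exactly
symmetrically, so two sequence-identical transcripts are estimated at
the same level (only their sum being identifiable), rather than at an
arbitrary point of the likelihood ridge that a per-coordinate random
start would select. We considered cyclic coordinate ascent with
independent per-coordinate starts and rejected it for precisely this
degeneracy: its restart average over a flat ridge is an
initial-point lottery. Transcripts involved in such ridges (identical
alignment-class profiles, or restarts disagreeing beyond
$10\times$ precision) are flagged `solvable = FALSE` in the output.

## Indexing choices

Substring clustering is specified by its postcondition -- two
positions cluster together iff their read-length substrings are
identical (up to reverse complement in unstranded mode, canonicalized
to the lexicographically smaller representative) -- and implemented as
a sorted k-mer table; a length-bounded suffix array would be an
equivalent efficiency device, not a different model. Substrings
containing `N` have undefined mappability and produce no virtual
reads. Coordinates are 0-based half-open internally; SAM positions are
converted on input. Virtual pairs are generated in FR orientation;
unstranded mode also accepts the swapped orientation.

Oversized sequence-sharing sets (above 5000 transcripts by default)
are broken up by iteratively dropping multi-transcript segments with
weighted length below a threshold and rebuilding the sets. The
threshold schedule is geometric (start 2, double each round) -- a
choice, since only "increasing" is prescribed by the method; dropped
classes are recorded so their reads are discarded at counting time.
Pruning runs at build time, before any dataset is seen, so it uses a
provisional weighted length: the uniform average over the indexed
fragment sizes, identical to the final value for single-end data and
replaced by the empirical weighting at quantification time.

The index serializes to a versioned JSON container (`format_version`
1); loading refuses versions it does not know. JSON keeps the format
portable and diffable; for transcriptomes of hundreds of thousands of
isoforms a binary container would be preferable, and the version field
leaves room for one. Single-end variable-read-length data are indexed
over a user-supplied size range rather than all observed lengths.

## What the simulator does and does not emulate

`makeTranscriptome()` / `simulateReads()` generate the study
conditions used throughout the tests: 200 transcripts of 400-2000 bp,
20 paralog pairs (18 differing at 5 positions, 2 identical
duplicates in the recovery experiment), log-normal expression
(sdlog 1.5), and 100,000 error-free 50-bp single-end reads, drawn
proportional to abundance times virtual length with uniform positions
and i.i.d. substitution errors at a configurable rate. Under these
conditions the full pipeline recovers true abundances with Pearson
$r \ge 0.95$ between $\log(\widehat{TPM}+1)$ and $\log(TPM+1)$, and
identical duplicates agree to well under 10 %.

The simulator deliberately omits what the model itself does not
represent: GC and positional coverage bias, PCR duplication, size
selection, quality-score-dependent errors, indels, and intron
structure. Passing tests therefore demonstrate correctness of the
segmentation, counting and estimation machinery under the model's own
assumptions -- not robustness to library-preparation artifacts of real
data, for which no bias model is included by design.

## Problem sizes and determinism

The test suite and the acceptance script run in a few minutes on one
CPU: the recovery experiment uses the 200-transcript / 100k-read
conditions above; optimizer cross-checks run 100 random instances of
at most 3 transcripts and 5 segments against a dense grid search
refined by L-BFGS-B and a brute-force multinomial MLE; conservation is
checked on 50 random transcriptomes. Every stochastic component --
transcriptome, reads, restart initial points -- is seeded, and
rebuilding an index or rerunning a seeded quantification is
byte-identical. `--threads` never changes results: sets are
independent likelihoods, so parallelism is a wall-time concern only
(the current implementation is serial).

## Limitations

- Reads with indels or clipping are discarded rather than modeled;
  aligners must report all alignments up to the mismatch allowance
  for best-filtering to behave as intended.
- No bias correction of any kind; counts are exported for external
  differential-expression tools rather than tested here.
- Effective length can fall slightly below transcript length when
  segments are pruned or reads hit the alignment cap.
- The estimator reports point estimates only; no confidence intervals
  or posteriors.
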