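---
title: "Resolving multi-mapped reads by coverage variance minimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving multi-mapped reads by coverage variance minimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covres)
```

## The problem

Short-read aligners report a single placement for most reads, but a
substantial fraction (10--20%, depending on read length, aligner
sensitivity and genome repetitiveness) aligns equally well to several
locations. Common workarounds -- discarding ambiguous reads, keeping the
aligner's top hit, picking at random, or spreading fractional weight --
all distort coverage in repeat-rich regions and propagate into
quantification and variant calling.

`covres` post-processes a queryname-grouped SAM/BAM file and keeps
exactly one alignment per read (or read pair), chosen so that the read
coverage across the genome becomes as uniform as the candidate set
allows. The principle is that, within a local region, sequencing
coverage should be roughly flat; a candidate placement that fills a
coverage trough is more plausible than one that piles onto an existing
stack.

## The procedure

1. **Grouping.** The input must have all alignments of a read adjacent
   (`samtools sort -n` or `collate` order). Each read name forms one
   group of candidate placements; uniquely mapping reads are
   single-candidate groups. Supplementary (chimeric) records are dropped
   from candidacy; unmapped records pass through.
2. **Filtering (optional).** With an edit-distance filter `delta`, only
   candidates whose `NM` is at most `min(NM) + delta` within the group
   are kept; `delta = 0` keeps only the placements with as few edit
   operations as the best one.
3. **Pairing (optional).** For paired-end data, the candidate list of a
   group is the list of *feasible pairs*: same reference, forward--reverse
   orientation with the leftmost mate on the plus strand, and outermost
   footprint distance at most `max_pair_dist`. A pair with no feasible
   combination falls back to two independent single-end groups and loses
   its proper-pair flag in the output.
4. **Initialization.** One candidate per group is selected by best
   alignment score (`AS`, ties to input order), by input order, or
   uniformly at random under the configured seed. The selected
   footprints, including all unique reads, form the global coverage map.
5. **Sweeps.** In input order, each ambiguous group compares its current
   selection $a$ against each alternative $b$ and accepts a swap when

   $$\ell^-(a) + \ell^+(b) < \ell^+(a) + \ell^-(b),$$

   strictly, where $\ell^+(x)$ / $\ell^-(x)$ is the empirical variance
   of coverage in a window around $x$ with $x$ placed / removed. The map
   is updated immediately on every accepted swap, and the new selection
   becomes the baseline for the group's remaining candidates. Sweeps
   repeat up to `iterations` times (default 3) and stop early when a
   sweep changes nothing.

### Windows

The window of a placement is its reference footprint (the maximal runs
of `M`/`=`/`X` CIGAR operations; `N` and `D` split it) extended by
`window_flank` bp on each side, clipped at the reference ends. Intronic
gaps are never part of a window. The default flank of 20 bp keeps the
loss local and each evaluation O(footprint + flank); it is exposed on
the command line (`-w`).

### Joint versus independent loss evaluation

How the four loss terms are evaluated matters more than it may appear.
`covres` supports two modes behind one switch (`loss_mode`):

* **`joint` (default).** All terms are pooled variances over the
  *union* of the two candidates' windows, with the alternative's terms
  evaluated in the context of the current placement removed. The
  four-term rule then reduces to accepting the swap exactly when the
  pooled variance of the union region decreases. Because both windows
  enter one variance with one common mean, a systematic coverage excess
  at the current location relative to the alternative is visible to the
  decision, and every accepted swap strictly lowers the variance of the
  only region the swap touches -- the sweep is a descent method and
  cannot oscillate.
* **`independent`.** Each candidate is scored in its own window with its
  own window mean, which makes each term invariant under adding a
  constant to that window. This form reacts only to the local *texture*
  (dips and bumps) and is blind to a level difference between the two
  windows. On a perfectly duplicated segment tiled uniformly, where by
  conservation the two copies' coverages always sum to a constant, it
  provably stalls in states where one copy holds roughly two thirds of
  the reads in a smooth dome: a smooth gradient looks locally flat, so
  no single swap improves either window. We keep this form available
  because it is the more conservative choice when neighbouring regions
  have genuinely different expected coverage, but the joint form is the
  default because it is what actually drives the coverage to uniformity
  (see the tiling experiment below).

Ties -- in particular a swap between two placements with identical
coverage context -- keep the incumbent. Strictness guarantees
termination; the comparison uses a relative tolerance of $10^{-12}$ so
that exact ties are not decided by floating-point noise.

### Paired candidates

A pair's coverage footprint is the union of the two mates' footprints,
so overlapping mates are counted once. For the per-candidate losses the
two mates' window variances are summed; in joint mode the union region
covers all windows of both mates of both candidates.

### Annotation-aware windows (RNA-seq)

Exon boundaries implied by an annotation separate regions whose coverage
comes from different transcript contexts; pooling across them would make
the variance reflect biology rather than placement quality. Given a
GTF/GFF3 file, every exon start and end becomes a breakpoint (0-based,
half-open), and each window flank is trimmed at the nearest breakpoint
so no window interval crosses one. The footprint itself is never
trimmed; a read that crosses an annotated boundary unspliced leaves its
window untrimmed, since the annotation evidently does not describe that
alignment. With an empty annotation the windows are identical to the
unannotated case. A spliced window's intervals are pooled into one
variance by default; `per_interval = TRUE` sums per-interval variances
instead (the pooled form uses all positions jointly and is the default
because trimming already confines each interval to one exonic context).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `window_flank` | 20 bp | flank added to each footprint interval |
| `iterations` | 3 | maximum sweeps; early stop on a zero-change sweep |
| `edit_delta` | off | keep candidates with `NM <= min(NM) + delta` |
| `init` | `best` | `best` / `order` / `random` initial selection |
| `seed` | 42 | seeds all randomness (random init) |
| `max_pair_dist` | 400 kb | outermost mate distance of a feasible pair |
| `max_candidates` | 1000 | per-group candidate cap, best `NM` first |
| `loss_mode` | `joint` | see above |

`max_pair_dist` is generous enough to span long introns in RNA-seq while
bounding the quadratic pair enumeration; the candidate cap bounds the
worst case on degenerate repeats.

## What the synthetic fixtures emulate

The package validates itself on generated data with known truth:

* `fixture_genome()` draws a uniform-random sequence and copies chosen
  segments (optionally point-mutated) elsewhere -- the minimal structure
  that produces multi-mappers with a known answer.
* `tile_reads()` emits one k-mer per position, so interior positions
  have true coverage exactly `k` at step 1.
* `exhaustive_align()` reports *every* placement of every read up to a
  mismatch allowance, on both strands, with exact `NM` tags -- a
  download-free stand-in for an external aligner whose candidate sets
  are complete by construction.
* `micro_instance()` builds small single-reference instances in which
  unique reads shape, at each candidate locus, either a flat background
  or a one-deep trough exactly the shape of the read footprint, with the
  trough level never above any flat level of the same group. Filling the
  trough is then the unique global minimiser of the total coverage
  variance, which `enumerate_optimum()` finds by exhaustive enumeration,
  independently of the resolver.

The standard end-to-end instance is a 100 kb genome with one exact 2 kb
duplication, tiled with 50-mers at step 1 and exhaustively aligned with
zero mismatches. Under input-order initialization every ambiguous read
initially lands on the leftmost copy, roughly doubling its coverage and
starving the second copy -- the most adversarial start. The resolver
restores coverage 50 at every interior position, typically in a single
sweep (one member of each twin pair moves), with sweep 2 confirming the
fixpoint. This instance is deliberately *clean*: no sequencing errors,
no quality strings, constant read length, complete candidate sets, no
library biases or expression differences. Passing it shows the
assignment machinery is correct, not that real libraries are uniform;
on real data the uniformity assumption holds only locally, which is why
the windows are small and annotation trimming exists.

Validation problem sizes (chosen to keep the whole suite in the minutes
range): the 100 kb standard instance for the end-to-end checks; 3--8 kb
genomes for behavioural tests; 100 micro-instances of up to 8 ambiguous
groups with up to 3 candidates each (at most a few thousand enumerable
assignments) for the brute-force comparison; 1000 random windows for the
loss oracle.

## Numerical and degenerate-input choices

* Variance is the population form ($N$ divisor): consistent with an
  "empirical variance" and well-defined on one-position windows.
* Coverage is held in dense per-reference integer vectors, allocated
  lazily; increments are exact, and removal below zero is an error
  rather than a silent clamp, because it can only mean a bookkeeping
  bug.
* Coordinates are 0-based half-open everywhere internally; SAM's
  1-based `POS` is converted at the I/O boundary only.
* `NM` is taken from the tag; when absent, a CIGAR with `=`/`X`
  operations yields the count of `X`, `I` and `D` bases, otherwise the
  edit distance is treated as 0 with a single warning.
* Sweep order is input-file order, candidate order is input order within
  the group; together with the seeded random init this makes runs
  byte-reproducible.
* `MAPQ` of a promoted secondary record is preserved as-is; the tool
  selects among reported placements and has no basis to rescore them.

## Known limitations

* The sweep is a greedy local search: it attains the enumerable optimum
  on instances built to be reachable by single swaps, but on general
  inputs it converges to a local optimum of the windowed objective.
* Joint evaluation compares coverage *levels* between the two candidate
  neighbourhoods. Between loci of genuinely different expected coverage
  (e.g. two genes at different expression), this pressure toward
  equal levels is a modelling assumption that can be softened with
  annotation trimming or `loss_mode = "independent"`.
* Mate tuples beyond pairs, CRAM input, on-the-fly name sorting and
  mapping-quality recomputation are out of scope; multi-threading is
  deliberately absent so that results equal the order-deterministic
  single-threaded semantics.

## A small worked example

```{r example}
fx <- tiling_fixture(genome_length = 6000L, repeat_length = 600L, seed = 10L)
sam <- tempfile(fileext = ".sam")
write_sam(fx$records, sam)
out <- tempfile(fileext = ".sam")
res <- resolve_multimappers(sam, out, resolver_config(init = "order"))
res
glance(res)
coverage_report(out)
```

The duplicated 600 bp segment makes `r sum(fx$truth$n_candidates > 1)`
of the `r nrow(fx$reads)` reads ambiguous; after resolution every
interior position sits at coverage 50 again.
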