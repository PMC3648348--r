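---
title: "Evaluating mate-pair libraries for genome structure analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating mate-pair libraries for genome structure analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matescaffold)
```

## The problem

Mammalian genome assemblies consist of contigs that must be ordered and
oriented into scaffolds. The long-range information for this comes from
paired-tag sequencing: paired-end (PE) libraries span a few hundred bp,
mate-pair (MP) libraries -- built by circularizing large fragments and
sequencing the junction -- span kilobases to tens of kilobases. Because
roughly half of a mammalian genome is repetitive, with LINE retroelements
up to ~8 kb, the choice of insert size determines which repeats a library
can bridge and hence how far scaffolding can proceed.

`matescaffold` provides a simulation-backed re-implementation of the
analysis pipeline used to compare such libraries: a synthetic-genome and
library simulator with known truth, read-pair classification, library QC
(insert-size estimation, duplicate marking, complexity saturation,
physical coverage, coverage normalization), repeat-bridging profiles, an
SSPACE-like greedy scaffolder with N50 bookkeeping over library
combinations, and restriction-map (optical-map-like) concordance scoring.

## The model, piece by piece

### Read-pair classification

All libraries are normalized to one orientation convention: after the
mate-pair circularization chemistry is accounted for, a correct pair has
facing-in tags (leftmost tag on `+`, rightmost on `-`). Classification is
a fixed cascade, applied after clonal marking:

1. **clonal** -- identical coordinates and strands of both tags
   (PCR/optical duplicate); one representative (smallest `pair_id`, so the
   result is independent of input order) survives.
2. **ambiguous** -- a tag without a unique mapping; excluded from every
   downstream quantity, mirroring single-best-hit filtering.
3. **remote** -- tags on different chromosomes, or proper orientation with
   an outer span outside the insert bounds (default the 1st--99th
   percentile of the library's own fitted distribution; always < 100 kb).
4. **consistent** -- proper orientation, span within bounds.
5. **inverted** / **everted** -- one tag flipped (same-strand pattern) /
   both flipped with tag order swapped (outward-facing pattern).

The classes partition every pair set; a brute-force per-pair re-check of
the cascade is kept in the test suite as an oracle.

### Library QC

*Insert sizes* are estimated from non-clonal, uniquely mapped,
proper-orientation pairs with spans below 100 kb. *Physical coverage* is
clone-coverage arithmetic: the summed outer spans of qualifying pairs
(trimmed to the 1st--99th insert percentiles) divided by the genome
length. The closed form `n_pairs * insert / effective_genome` reproduces
the published per-library coverage column with an effective genome of
2.4715 Gb (the unique constant, to row-level printed precision, that fits
every insert size at once); the full assembly length is 2.51 Gb -- both
constants are exported, and the discrepancy (unplaced/unmappable
sequence) is the reason the smaller value is the default for coverage
arithmetic.

*Library complexity* is measured by subsampling: the number of distinct
coordinate signatures versus pairs drawn. The saturation model
`unique(n) = C (1 - e^{-n/C})` -- sampling with replacement from `C`
equally likely molecules -- is fitted by least squares. When the observed
curve reaches 90% of the fitted plateau the library is called saturated
and `C` is reported; otherwise only a lower bound (the observed unique
count) is claimed, the ">131 M"-style of reporting. The estimator behind
the published complexity column is unstated, so these values are treated
as consistency checks, not exact targets.

*Normalization*: libraries are made comparable by drawing random
qualifying pairs until a target physical coverage (8.5x in the published
design, the maximum the PE data allowed) is first reached.

### Repeat bridging

An element is **bridged** when a qualifying pair fully contains it: the
left tag ends at or before the element start, the right tag begins at or
after its end, both tags uniquely mapped in the flanks, and the span at
most the 99th insert percentile. This strict both-tags-in-flanks reading
is adopted deliberately: it is the only reading under which a 170-bp PE
library bridges essentially no multi-kb element, which is the observed
behaviour. Elements are binned by their own annotated length into 500-bp
windows per class. For isolated elements with unique flanks the bridging
probability has a Lander--Waterman closed form,
`1 - exp(-n (I - L - 2r + 1)_+ / G)`, used as the simulation oracle.

### Greedy scaffolding

SSPACE itself is a black box used with default parameters in the original
study; this package implements a documented simplified equivalent:

* inter-contig pairs (non-clonal, unique, mapped to two contigs) are
  aggregated per (contig end, contig end, library) into edges with
  support counts and a gap estimate
  (`insert_median - d_a - d_b`, median over pairs; floored at 1 bp in
  output, raw value retained);
* libraries are processed smallest insert first, so large-insert edges
  act on scaffold ends that smaller inserts have already grown;
* within a library, edges run in descending support order; an edge joins
  two exposed scaffold ends only when it is the strongest link at both its
  ends and the runner-up support is at most 0.7 of its own
  (second-best/best ratio; `min_support` 5 and ratio 0.7 are the
  SSPACE-like defaults). Ties make an end ambiguous, so output is
  deterministic given the (support desc, contig id) tie-break.

N50 is the largest `L` such that scaffolds of length at least `L` contain
half the assembled bases; scaffold spans include estimated gaps.

### Restriction-map concordance

Scaffold sequences are digested in silico with SwaI (site `ATTTAAAT`,
palindromic, blunt centre cut -- the cut coordinate is `site_start + 4`
0-based). Fragment lengths sum exactly to the sequence length; `N` runs
never match the site. A noise model for optical-map-like data applies cut
misses, Poisson false cuts, multiplicative `Normal(1, cv)` sizing error
and a detection limit; its defaults (cv 0.05) are stated constants, since
no error model is published. Two ordered maps are compared by a global
dynamic program that may merge up to `max_merge` consecutive fragments per
side when block sums agree within a relative tolerance, with per-bp
penalties for skipped fragments; `concordant_fraction` is the matched
share of the first map's length. Windowed inconsistency reports compare
two arrangements of the same contigs: each junction of the alternative is
consistent only if its contigs are adjacent in the reference with the same
order and relative orientation (whole-scaffold flips allowed); each
inconsistent junction is counted once, attributed to the 100-kb reference
window containing the junction midpoint, and split into within- versus
between-scaffold changes.

## What the generator emulates -- and what it does not

`simulate_genome()` places non-overlapping repeat copies uniformly
(longest first, batched rejection sampling) from a configurable per-class
landscape. `rat_like_repeats()` encodes a stylized mammalian landscape:
49% repetitive, LINE share 474.6/1240 of repeat bp with element sizes up
to 8 kb, then LTR, with the remaining classes filling the rest. Copy
numbers are derived from target bp and the truncated-normal mean element
length, so realized fractions land within a couple of points of target.

`simulate_library()` emits mapped coordinates, not base-level reads: tags
carry positions directly, and mapping ambiguity is modelled by a rule, not
an aligner -- a tag is non-unique iff it lies fully inside a repeat copy
whose family has at least two copies and whose divergence amounts to less
than one mismatch over the tag. The default copy divergence is 2%: with
50-bp tags that is exactly one expected mismatch, so copies remain
distinguishable and tags unique; setting a class below `1/read_length`
emulates young unmappable families. Duplicates are exact coordinate clones
of previously emitted pairs (a pure PCR model); remote pairs have one tag
repositioned at least 100 kb away; inverted/everted pairs flip one/both
strands. Insert distributions are truncated normal on
`[2 * read_length, 100 kb]` by default (lognormal optional); published
sources give only medians and distribution shapes, so spreads default to
~10% of the median in the seven-library preset and are configurable, not
inferred.

Consequences for interpreting green tests: base-call errors, chimeric
*reads* (as opposed to chimeric molecules), GC and shearing biases,
mapping-quality subtleties and multi-chromosome structure are all outside
the generator, so a passing property establishes the correctness of the
*pipeline logic* under the stated artifact model, not platform realism.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere in memory and in BED/TSV
  output; SAM output converts to 1-based.
* A fixed-insert library (`insert_spread = 0`) makes the fitted p1/p99
  degenerate; classification bounds must then be widened by the caller
  (the test helpers widen by 1 bp).
* `estimate_max_unique()` warns on non-concave curves (sampling noise) but
  still fits; the fit is a 1-D least squares over `log C`, bracketed at
  `[0.8, 1000] x` the observed maximum.
* Gap estimates may be negative (overlap candidates); they are floored at
  1 bp in emitted layouts with the raw median kept in `gap_raw`.
* `n50()` rejects empty or non-positive inputs; a single scaffold is its
  own N50.
* Map alignment scores are `(matched a + matched b)/2 - skipped bp`;
  identical maps always score every fragment as a 1:1 block.

## Known limitations

* **Skip joins at 8.5x.** With contigs whose sizes are comparable to the
  insert sizes, a short contig's junction support is capped by its length
  (`~ coverage * min(contig, insert - gap - 2r) / insert`). At 8.5x
  normalized coverage and `min_support = 5`, a small fraction of junctions
  flanking 2--3-kb contigs falls below threshold in *all* mid-size
  libraries simultaneously; large-insert edges then legitimately join the
  two neighbours across the unplaced contig. Under adjacency-based truth
  scoring such a join counts as a misjoin even though the relative order
  and orientation of the joined contigs are correct. On a 50-Mb, 5000-
  contig, seven-library benchmark this affects on the order of 1 in 1000
  joins; it is a property of the stated coverage/threshold regime (SSPACE
  would do the same), not of the implementation, and it disappears at
  higher normalization targets or smaller insert-to-contig ratios.
* The clustering of inconsistent pairs uses single-linkage with
  `max_gap` defaulting to the library insert median; published cluster
  percentages depend on real-genome properties and an unstated `max_gap`,
  so they are not reproduced quantitatively.
* The optical-map error model is invented plumbing; only limit behaviour
  (zero noise = identity; all cuts missed = one fragment; folded-normal
  mean sizing error) is guaranteed.
* Single-chromosome genomes: inter-chromosomal remote pairs are supported
  in classification and clustering (for imported data) but the simulator
  plants remoteness by distance only.

## Worked micro-example

```{r example, eval = FALSE}
g <- simulate_genome(2e6, rat_like_repeats(2e6), seed = 11)
lay <- fragment_into_contigs(g, 150, list(mean_gap = 400), seed = 12,
                             min_contig = 2000)
libs <- list(
  "3kb"  = simulate_library(g, library_spec("3kb", 3000, 300, 4e4),
                            seed = 13),
  "15kb" = simulate_library(g, library_spec("15kb", 15000, 1500, 1.2e4),
                            seed = 14))
combination_sweep(libs, lay, 2e6, target_coverage = 8.5,
                  combinations = list("3kb", "15kb", c("3kb", "15kb")),
                  seed = 15)
```

The sweep table reports, per combination, the scaffold count, N50 and the
truth-evaluation counts; on this toy genome the 3 kb + 15 kb combination
roughly doubles the best single-library N50, the qualitative effect the
package exists to measure.
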