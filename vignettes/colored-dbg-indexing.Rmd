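---
title: "Indexing pangenomes with a colored compacted de Bruijn graph"
author: "ccdbg package authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Indexing pangenomes with a colored compacted de Bruijn graph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccdbg)
```

## The problem

Given a collection of N reference sequences (typically a bacterial
pangenome: hundreds to thousands of genomes of one species), we want to
answer, for any k-mer x, the query

> Color(x) = the set of references that contain x (on either strand),

and, built on that primitive, to *pseudoalign* sequencing reads: report for
each read the set of references its k-mer content supports, without
base-level alignment. The challenge is scale — the k-mer sets are huge and
the color sets highly repetitive — so the index has to exploit the structure
the data actually has.

## The model: monochromatic unitigs

The central observation is that k-mers do not need individual color
annotations. Consecutive k-mers of a genome overlap in k−1 characters and
almost always occur in exactly the same set of references, so color is close
to constant along paths of the de Bruijn graph. `buildCcdbg()` makes this
exact: it computes the *colored compacted de Bruijn graph*, the set of
maximal unitigs (non-branching paths) that are additionally

1. **monochromatic** — all k-mers of a unitig share one color. Where the
   color would change along a path (for example where one reference ends and
   another continues), the unitig is cut. K-mers at a reference or fragment
   boundary terminate their unitig on that side ("sentinel" cuts), which is
   what makes property 3 possible;
2. **a partition** — every distinct canonical k-mer occurs at exactly one
   position of exactly one unitig (so `sum(width(unitigs) - k + 1)` equals
   the distinct-k-mer count n);
3. **a tiling alphabet** — each reference is a chain of whole unitig
   occurrences, consecutive occurrences overlapping in k−1 characters, so
   gluing a reference's tiling re-spells it exactly
   (`spellTilings()`).

All sequence is handled canonically: a k-mer and its reverse complement are
the same object, represented by the lexicographic minimum of the two. With
the order-preserving 2-bit encoding (A=0, C=1, G=2, T=3) that minimum equals
the integer minimum, so canonicalization is two integer comparisons.

The m unitigs are laid out *color-sorted*: unitigs with the same color are
consecutive, color ids 1..M are assigned by (cardinality, content) and
unitigs within a group by spelling, making construction deterministic.

```{r}
refs <- c(a = "ACGTTGCAACGGTTACGCTAGT",
          b = "ACGTTGCAACGGTTACGCTAGT",
          c = "ACGTTGCAACGCTTACGCTAGT")
g <- buildCcdbg(refs, k = 11)
g
```

## The three components of the index

`buildIndex()` composes Color(x) out of three structures, each sized by what
it stores:

**1. An order-preserving k-mer dictionary.** The unitig spellings are
concatenated in layout order into one text. Lookup of a k-mer goes through a
minimizer index — the k-mer's minimizer (its smallest w-mer under a hashed
order, `w < k`) selects a bucket of candidate (unitig, offset) positions,
and every candidate is verified by comparing the query (and its reverse
complement) against the stored text, so membership answers are exact: no
false positives, ever. Queries over consecutive k-mers of a read
(`streamingLookup()`) exploit locality twice: a hit at (unitig, offset) is
first extended to the adjacent offset (a *position-cache hit*, no search at
all), and failing that an unchanged minimizer reuses the previous bucket. A
miss invalidates only the position cache.

**2. A unitig-to-color-id rank map.** Because the layout is color-sorted,
the map from unitig id to color id needs only one bit per unitig: bit-vector
B with B[i] = 1 iff unitig i closes its color group (so B[m] = 1 and
popcount(B) = M), and

    Color-ID(i) = Rank1(i, B) + 1,

where Rank1 counts ones in the half-open prefix B[1, i). A directory of
absolute counts per 512-bit superblock plus one word popcount answers rank
in constant time — 1 + o(1) bits per unitig in total.

```{r}
cr <- buildColorRank(c(1, 1, 1, 2, 3, 3, 3))
bitVector(cr)
colorId(cr, 6)
```

**3. A hybrid compressed color store.** Each distinct color is a strictly
increasing set C ⊆ [1..N], and its best encoding depends on its density
d = |C|/N:

* d < 1/4 (strictly): *sparse* — Elias-delta code of the first value, then
  delta codes of the gaps;
* d > 3/4 (strictly): *dense-complement* — the complement [1..N] \\ C encoded
  as sparse (a color containing all N references costs only its header);
* otherwise: the characteristic *bit-vector* of N bits.

A 2-bit tag and the delta-coded cardinality precede each payload; the M
encodings are concatenated and delimited by an Elias-Fano directory of M+1
bit offsets. Iterators decode lazily and support Value / Next / Next-GEQ
with the sentinel value N+1 after exhaustion; the dense-complement iterator
walks the complement without ever materializing the color.

## Querying reads

All query modes first map the read's k-mers to unitigs by streaming lookup,
deduplicate to the distinct color ids hit, and then combine iterators:

* **full-intersection** (`pseudoalign(..., mode = "full-intersection")`):
  references containing *every* positive k-mer — a leapfrog intersection
  driven by Next-GEQ, skipping over non-candidates instead of decoding.
* **threshold-union** (`mode = "threshold-union"`, default τ = 0.8):
  references covered by at least ⌈s·τ⌉ k-mers, with s either the positive
  k-mer count (`sMode = "positive"`) or all k-mer positions
  (`sMode = "all"`). Per-color scores ride along a min-value merge of the
  iterators; the threshold ⌈s·τ⌉ is computed in exact integer arithmetic
  (τ scaled to parts-per-million) so ties never depend on floating point.
* **skipping heuristics** (`mode = "skip-kallisto-like"` /
  `"skip-backoff-like"`): instead of querying every position, a hit at
  (unitig, offset) implies where that unitig must end in the read
  (orientation-aware), and the walk jumps there. The kallisto-like preset
  re-anchors immediately on an unexpected unitig and steps past misses; the
  backoff-like preset halves the jump distance on either event, up to
  `backOffLimit` times. Jumped-over k-mers are *assumed*, not verified —
  faster, but on erroneous reads the result may differ from
  full-intersection. The result is always the intersection of the colors of
  the k-mers the policy actually confirmed (returned in `confirmed`), and
  per-position memoization keeps the lookup count at or below |Q|−k+1.
* **two-pass batching** (`twoPass = TRUE`): many reads of one sequencing run
  induce the same distinct color-id list. Pass one maps reads to their
  lists and collates identical ones; pass two intersects each distinct
  non-empty list exactly once and fans results back out. Output is
  identical to one-pass; `metadata()$intersections` shows the saving.

```{r}
idx <- buildIndex(g, w = 5)
res <- pseudoalign(idx, c(r1 = "ACGTTGCAACGGTTACG"), mode = "full-intersection")
res$refs[[1]]
```

## The synthetic pangenome generator

`generatePangenome()` provides the study conditions for testing and
benchmarking. It deliberately models a *population*, not independent noise:
one seeded base genome plus a pool of variants (SNPs, geometric-length
insertions and deletions), each variant carrying a population frequency
drawn uniformly on (0, 1), and each reference carrying each variant
independently with that frequency. This matters for the color store: under
independent per-reference mutation almost every color would be either
near-empty or near-full, whereas real pangenomes — and this generator —
produce the full density spectrum: private variants (sparse colors), common
variants (mid-density), and a conserved backbone shared by (nearly) all
references, the >90%-dense regime the complement encoding exists for.

Defaults are n = 50 references, a 20 kb base genome, SNP rate 0.005 per
base and indel rate 5·10⁻⁴ (mean length 5), values in the range reported
for within-species bacterial diversity; the test suite scales the genome
length down (2 kb, and an 8 × 500 bp instance for query tests) while keeping
the rates, which preserves every code path including all three color
encodings. `simulateReads()` draws positive reads from random (reference,
position, strand) with substitution errors and rejection-samples negative
reads until they share no canonical k-mer with the collection, so negatives
are unmappable by construction and false-positive rates are measured against
a hard guarantee. Everything is deterministic given the seed and independent
of R's global RNG state.

## Serialization

`saveIndex()` writes a single binary file: magic bytes, format version, a
bit-order flag, then little-endian sections (header, reference names,
dictionary, rank bit-vector, color store), each closed by a checksum.
`loadIndex()` verifies all of them and refuses corrupted files; the
minimizer index and the rank directory are rebuilt in memory rather than
stored. A load/save round trip is byte-identical.

## Parameters and limitations

* **k** (default 31) must be odd — so no k-mer equals its own reverse
  complement — and at most 31, keeping a k-mer in one 64-bit word. Larger k
  would need multi-word k-mers; out of scope here.
* **w** (default 15) trades dictionary speed for bucket sizes; any
  1 ≤ w < k is valid.
* **τ** (default 0.8) is the threshold-union coverage fraction.
* Non-ACGT characters split references into fragments; k-mers never span
  them, and fragment boundaries terminate unitigs the same way reference
  ends do.
* Queries are single-threaded; index construction holds the k-mer map in
  memory, which is comfortable for bacterial-pangenome scale but not sized
  for, say, a human pangenome in 8 GiB.
* The skipping modes are heuristics by design: their contract is
  consistency with what they confirmed, not equality with the exhaustive
  mode on erroneous reads.

## Reproducing the statistics report

```{r}
refs <- generatePangenome(n = 50, length = 2000, seed = 42)
idx50 <- buildIndex(refs, k = 21, w = 11)
statsReport(idx50)
```

The report buckets colors by density decile and accounts bits per stored
integer; the `total` row additionally charges the Elias-Fano offset
directory, so it is the true cost of the color store per stored reference
id.

## Session information

```{r}
sessionInfo()
```
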