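---
title: "Block-based referential genome compression: model, heuristics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Block-based referential genome compression: model, heuristics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refcomp)
```

## The problem

Two genomes of the same species are overwhelmingly similar — for human,
roughly 99.9% identical. Storing each genome as plain text therefore wastes
almost all of its bytes on information already present in any other genome
of that species. Referential compression encodes an input genome only as
its *differences* against a pre-selected reference: long stretches that
match the reference become position/length pointers, and the rare novel
characters are stored literally. Decompression replays those pointers
against the reference and is exact — the original sequence is recovered
byte for byte.

`refcomp` implements this scheme with a *block-partitioned* reference. Each
chromosome is split into blocks of at most `BS` characters (every block
except the last of a chromosome is exactly `BS` long), and each block gets
its own match index. Bounding the indexed unit bounds memory: compression
never needs more than a handful of blocks resident, regardless of genome
size.

## The entry model

A compressed stream is an ordered list of three entry kinds:

* `BC(i)` — *block change*: subsequent matches refer to reference block `i`;
* `RM(p, l)` — *relative match*: the next `l` input characters equal the
  active block at 0-based position `p`;
* `R(s)` — *raw*: the characters `s` appear literally.

Decompression processes entries in order and needs only the raw blocks,
never the match indexes. Losslessness is the central contract: for every
input and every parameter setting,
`decompress(compress(x)) == x`.

## The match query

The core primitive is the *longest prefix–suffix match*: given a query
string (the not-yet-encoded remainder of the input) and a block, find the
longest prefix of the query that occurs anywhere in the block. `refcomp`
answers this with a per-block suffix array: the maximal common prefix with
the query is attained at a lexicographic neighbour of the query's insertion
point in suffix order, so one binary search plus two extensions finds the
maximal length, and two more prefix-range searches recover every occurrence.
Among equal-length maxima the smallest block position is returned — a pure
tie-break convention, chosen so that answers are deterministic and testable
against a naive all-positions scan. A chunked minimum over suffix-array
positions makes the tie-break cheap even in degenerate, highly repetitive
blocks.

The suffix array is one of several structures that satisfy this query
contract (compressed suffix trees and hash tables are alternatives with
different space/speed trade-offs); the array was chosen because it is
simple, exact, serializable, and its answers are easy to verify
independently.

## The compression loop

Compression walks the input left to right with two cursors: `P_in` in the
input and `P_raw` in the active reference block.

1. While the current input character equals the current block character,
   extend — one `RM` entry per maximal run (`encode_ref`).
2. If the input character is not one of A, C, G, T (typically `N`), spool
   the whole run of such characters into one `R` entry (`encode_raw`).
3. On any other mismatch, re-anchor (`find_match`):
   a. **Local search first.** Substitutions and small indels displace the
      alignment by only a few characters, so a bounded window scan — input
      offsets `i` in 0..7 (outer loop), reference offsets `j` in −7..+7
      (inner loop), comparing 20-character windows — resolves the common
      case without touching any index. On the first hit, the `i` skipped
      input characters are emitted raw and matching resumes; comparisons
      that would read past either end are skipped.
   b. **Global search as fallback.** Candidate blocks are queried for the
      longest prefix–suffix match of the remaining input. A block qualifies
      only with a match *strictly longer* than `min_long_match` (default
      25): in a mammalian-size reference, shorter matches are
      overwhelmingly random hits that fragment the stream. If a block
      qualifies, a `BC` entry activates it (omitted when the block is
      unchanged) and `P_raw` jumps to the match start; otherwise
      `raw_fallback_len` (default 25) input characters are emitted raw and
      the walk continues.

Candidate blocks are visited in a locality-favouring order: the current
block itself, its left and right neighbours, the remaining blocks of the
same chromosome, then everything else, each group in genome order. The
current block comes first deliberately: it is already resident, and most
re-anchorings (after an `N` run or a deletion longer than the local window)
land a few hundred characters downstream in the same block. In the default
`greedy_first_acceptable` mode the search stops at the first qualifying
block — the point of the traversal heuristic is to avoid loading blocks —
while `exhaustive_best` scans all candidates and keeps the longest match
(ties to the earliest candidate), trading speed for marginally better
output.

Because every step either advances `P_in` or moves to a state that must
advance it on the next iteration, total work is linear in the input length
for fixed parameters; the operation counters attached to every compression
result (`attr(entries, "ops")`) make that measurable.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `BS` | 4 Mb | block size; bounds per-block index memory (1 kb–300 Mb) |
| `min_long_match` | 25 | global matches must be strictly longer than this |
| `raw_fallback_len` | 25 | raw characters emitted when no block qualifies |
| `local_match_len` | 20 | window length of the local search |
| `local_input_window` | 0..7 | input offsets scanned locally |
| `local_ref_window` | −7..+7 | reference offsets scanned locally |
| `search_mode` | greedy | stop at first acceptable block, or scan all |

`min_long_match` should not be set below `local_match_len` (the package
warns): a global anchor weaker than the local windows it is meant to beat
invites random matches. The micro-examples in the documentation do exactly
that, deliberately, to make 8-character worked examples expressible.

## Container format

The on-disk container (`.rgc`) is `"RGC1"` magic, a version, and a JSON
header binding the stream to its reference — name, block count, per-block
MD5 checksums — plus a chunk table. Entries serialize as one tag byte and
base-128 varints (`RM(3,5)` is exactly 3 bytes), and each chunk's
serialized stream is then deflated with zlib before storage; zlib squeezes
the residual redundancy of varint positions and tag patterns and roughly
halves the container at 0.1% divergence. Every chunk records an FNV-1a64
checksum of its stored bytes, so corruption is detected before any output
is produced, and a mismatched reference (different block checksums) is
refused outright. Two serializations of the same entry stream are
byte-identical — nothing in the container depends on time or environment.

Parallel compression is embarrassingly simple by construction: the input is
segmented deterministically (per record, subdividing records beyond
`segment_size`), each segment is compressed independently with its own
cursor state, and the chunk table stitches the results. The output is
therefore byte-invariant to the thread count, and decompression needs no
coordination.

## The synthetic cohort generator

Testing a referential compressor needs reference/input pairs with
controlled divergence. `random_genome()` draws i.i.d. bases at a requested
GC fraction (default 0.41, human-like); `mutate()` applies, per base,
substitutions (default rate 1e-3, emulating the ~99.9% identity of two
human genomes), indels (rate 1e-4, geometric lengths with mean 3, matching
the short-indel regime that dominates within-species variation), and rare
runs of `N` (rate 1e-6, mean length 100) standing in for unknown-base
stretches. Raising the substitution rate to 1e-2 and beyond emulates the
cross-strain regime (e.g. yeast) where referential compression degrades.
Every event is logged with position and payload, and replaying the log
reproduces the mutant exactly, so divergence is verifiable, not assumed.
All randomness flows from a single integer seed.

What the generator does *not* emulate matters for interpreting results:
real genomes carry repeats, segmental duplications and structural variants.
On i.i.d. sequence, every sufficiently long match is unique, so two
consequences follow. First, the greedy and exhaustive search modes behave
almost identically here, while on repeat-rich genomes they can differ.
Second, the block-size trade-off inverts: larger blocks cannot find longer
matches in repeat-free sequence (re-anchoring succeeds within the current
block at any block size), but every match position in a 10 Mb block costs
four varint bytes where a 1 Mb block needs three — so on these fixtures
output grows slightly *with* block size, whereas on real genomes larger
blocks are reported to help. Passing tests on synthetic cohorts therefore
demonstrate correctness, determinism and scaling in divergence, not the
absolute ratios achievable on real data.

## Numerical and degenerate-input choices

* Positions are 0-based throughout the entry model and match queries.
* All window and match comparisons clip at sequence ends; the algorithms
  never read out of bounds.
* An empty chromosome yields no blocks (with a warning); an empty input
  yields an empty entry stream; an empty query matches with length 0 at
  position 0 by convention.
* Input and reference are uppercased on read; soft-masking is not
  distinguished.
* A boundary match of exactly `min_long_match` characters is rejected
  (strict inequality), and the boundary is pinned by tests.
* Consecutive raw entries are merged at emission (pure output-size
  optimisation; decompression is indifferent).
* Block eviction is least-recently-used over a configurable budget of
  resident blocks; evicted blocks are re-verified against their MD5 on
  reload.

## Problem sizes used in the test suite

The packaged tests exercise the full pipeline at sizes a laptop handles in
minutes: randomized oracle comparisons on blocks up to 1 kb; a 500-case
lossless round-trip grid over block sizes 1 kb–1 Mb and substitution rates
0–1e-2 on 20 kb inputs; thread-invariance, similarity scaling and
block-size comparisons on 10 Mb references; and linearity of instrumented
operation counts between 8 Mb and 16 Mb inputs. The compression-ratio
expectations at these sizes (e.g. >100:1 at 0.1% divergence) are
qualitative anchors of the same-species regime, not reproductions of
whole-genome figures, which depend on real cohort data.

## Known limitations

* Only exact matches are encoded; inverse-complement or approximate
  matching would shorten streams further but is out of scope.
* One reference at a time; no multi-reference selection.
* No random access into a compressed stream short of decompressing its
  chunks.
* The suffix array is held fully in memory per block; at the 300 Mb block
  maximum this is ~1.2 GB transient during indexing.

## A worked example

```{r example}
dir <- tempfile()
write_reference_store(c(chr1 = "ACGACGTA"), dir, BS = 8)
store <- load_reference_store(dir)

idx <- build_block_index("ACGACGTA")
longest_prefix_suffix_match(idx, "ACGTAAT")

params <- suppressWarnings(
  compression_params(BS = 8, min_long_match = 2, raw_fallback_len = 1))
entries <- compress_sequence("TACGTAAT", store, params)
format_entries(entries)
decompress_entries(entries, store)
```
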