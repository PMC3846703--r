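---
title: "Quasi-alignment: position-sensitive p-mer clustering for conserved-region discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quasi-alignment methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quasialignr)
```

## The model

`quasialignr` treats a family of unaligned DNA sequences as a stream of
fixed-length segments. A segment starting at 1-based position $i$ with
length $l$ is summarized by its *Numerical Summarization Vector* (NSV): the
vector of occurrence counts of all $4^p$ words of length $p$, indexed
lexicographically over $A < C < G < T$. For a segment free of ambiguity
characters the counts sum to $l - p + 1$; any window containing a non-ACGT
character (such as `N` from sequencing error) is counted in no bin, a
deliberate choice that avoids inventing counts for unknown bases.

The ordered NSV stream — sequence by sequence, segment by segment — is
clustered in one pass. Each NSV joins the nearest existing cluster whose
center lies within the threshold $t$; otherwise it founds a new cluster.
A cluster of segments is a *quasi-alignment*: its members have nearly the
same word-frequency profile. The clusters plus a directed multigraph of
transitions between the clusters of consecutive segments (within one
sequence only; boundaries reset the state) form the *GenModel*. Because the
pass is single and each step costs work proportional to the number of live
clusters, total build time is linear in the number of bases for families
whose cluster count saturates.

### Why the threshold means something

The Manhattan distance between two p-mer profiles lower-bounds the edit
distance between the segments themselves:
$$d_\text{edit}(s_x, s_y) \ge \frac{d_\text{Manhattan}(x, y)}{2p},$$
since one insertion, deletion or substitution destroys at most $p$ existing
p-mers and creates at most $p$ new ones. The default threshold $t = 30$
with $p = 3$ therefore guarantees that segments forced into *different*
clusters differ by at least $30/6 = 5$ edits. Only the Manhattan threshold
carries this interpretation; the other measures (below) need empirical
calibration.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `l` | 100 | bases | segment length; all NSVs summarize equally many windows |
| `stride` | `l` | bases | distance between segment starts; `stride = l` tiles without overlap |
| `p` | 3 | — | word size; $4^p$-dimensional NSVs; larger $p$ sharpens similarity at higher cost |
| `measure` | manhattan | — | NSV comparison; also euclidean, squared euclidean, symmetric KL, matching p-mers |
| `threshold` | 30 | counts | join-or-found radius; edit-separation guarantee $t/2p$ |
| `update_rule` | mean | — | center = running mean of members; `first` keeps the founder fixed |
| `min_consensus` | 0.9 | fraction | conserved-region calling threshold |
| `top_k` | 5 | — | clusters shown in ranking and plots |

Choices worth explaining:

* **Trailing partial segments are dropped** (`drop_partial = TRUE`). A
  shorter trailing window would have a smaller count total, biasing every
  distance to it; equal-length segments keep one threshold meaningful
  everywhere. The flag exists for users who prefer completeness over
  comparability.
* **Assignment goes to the *nearest* qualifying cluster**, not the first
  one found, with ties broken by the lowest cluster id. This makes the
  build deterministic and insensitive to cluster creation order within one
  stream. The strategy sits behind an explicit argument because the
  alternative (first-qualifying) is equally defensible for pure streaming.
* **Centers are running means.** The mean keeps a cluster's center
  representative of all members as it grows; `update_rule = "first"` is
  provided for users who want hard founder-anchored radii.
* **No merging, fading or pruning.** General stream-clustering frameworks
  offer all three; omitting them keeps one-pass semantics exact, so
  incrementally adding sequences (`add_sequence()`) is provably identical
  to rebuilding from the concatenated stream — a property the test suite
  asserts structurally.
* **Distance measures accept real-valued arguments**, since centers are
  means. The matching-p-mers similarity is expressed as a dissimilarity,
  `max(sum(x), sum(y)) - sum(pmin(x, y))`, so a single "join if below
  threshold" rule serves every measure; for clean equal-length segments
  this equals $(l - p + 1)$ minus the shared-word count. KL discrepancy is
  symmetrized and computed on add-one-smoothed frequencies so zero counts
  are well-defined.
* **`min_consensus = 0.9`**: an index is called conserved when at most
  roughly one sequence in ten escapes the modal quasi-alignment — for a
  family of a dozen sequences, "all but one". Full-identity screening uses
  `min_consensus = 1`.

## Consensus and conserved regions

Consensus is indexed by segment ordinal, not base position: at ordinal $j$,
the fraction of sequences (among those long enough to have a segment $j$)
whose segment lies in the modal cluster. It depends only on the partition
of segments, not on cluster labels. Maximal runs of ordinals at or above
`min_consensus` become regions on the base grid,
$[1 + j \cdot \text{stride},\; j \cdot \text{stride} + l]$; coordinates are
1-based inclusive throughout (BED exports convert to 0-based half-open).
Region boundaries are *not* refined inside segments — the method sees
word-frequency profiles, not alignments, so sub-segment resolution would be
false precision. With `stride < l` ordinals overlap and the base-coordinate
reading of the profile is approximate; the machinery runs but should be
considered experimental.

The built-in `v_regions()` annotation carries the nine 16S rRNA
hypervariable intervals (V1 69–99 through V9 1435–1465, 1-based inclusive),
the standard frame of reference for conserved flanks in mixed-species 16S
families.

## The synthetic generator

`generate_family()` draws one uniform-random ancestor of
`n_segments * segment_length` bases and derives each family member window
by window: windows listed in `conserved_windows` are copied verbatim;
every other window receives exactly `n_substitutions` random substitutions
(each to a different base), plus optional per-base indels. The defaults —
20 sequences, 10 windows of 100 bases, conserved windows {2, 5, 8}, 15
substitutions per background window, no indels — are chosen so the
separation argument is engineered, not hoped for: each substitution moves a
3-mer profile by at most $2p = 6$, and empirically 15 substitutions put
same-index background segments from different family members beyond
Manhattan distance 30 in essentially all pairs (the suite asserts ≥ 95%
over 10 seeds; the observed median distance is ≈ 66). Divergence is an
exact substitution count rather than a rate precisely so this argument is
checkable.

What the generator does *not* emulate: realistic substitution matrices,
phylogenetic correlation between family members (all descendants are
independent draws from one ancestor), GC heterogeneity, and — unless
`indel_rate > 0` — length variation. Passing recovery tests on these
families therefore demonstrates the clustering and calling machinery, not
robustness to evolutionary indel drift. Indels are the documented failure
mode of non-overlapping segmentation: an insertion shifts every downstream
base, so segments fall off the grid and mis-cluster; `indel_rate` exists to
reproduce that limitation deliberately.

## Numerical and degenerate-input choices

* Equal distances to several qualifying centers: lowest cluster id wins.
* Ties for the modal cluster at an index: lowest cluster id.
* Sequences shorter than `l`: a warning and zero segments, never an error,
  so one fragment cannot abort a collection.
* Empty input: an empty model (0 clusters), not an error.
* Center-mean equality is maintained to ~1e-9 by incremental update;
  serialization writes full precision so rebuilds are byte-identical.
* All computation in the model build is deterministic; the only randomness
  in the package lives in the generator and is fully driven by its single
  seed, which never touches the caller's RNG state.

## Problem sizes used by the test suite

The suite exercises the q-gram bound on 1000+ mutated 100-base pairs
(p ∈ {2, 3, 4}) against an independent dynamic-programming edit distance;
planted-window recovery on 20-sequence families across 20 generator seeds;
and the linear-time claim by regressing log build time on log total bases
over families of 10–80 sequences of 3000 bases (30 segments), using
low-divergence families (2 substitutions per background window) so the
cluster count stays constant and the measured exponent reflects the
per-base pass. The expected slope is ≈ 1; the suite bounds it at 1.3
because the cluster count enters the constant.

## Known limitations

* Order sensitivity: permuting input sequences can change cluster ids and,
  near threshold boundaries, cluster composition. The model fixes input
  order; comparisons between models should use the partition, not ids.
* Indel drift: shifts larger than the threshold's edit allowance move
  segments into different clusters (see the generator section). Overlapping
  segments (`stride < l`) mitigate this at `l`-fold cost but their
  consensus grid is experimental here.
* Quasi-alignment is a lower-bound argument: members of one cluster are
  *likely* near-identical, but profile equality does not imply string
  equality; regions are candidates for, not proof of, base-level identity.
* No significance testing: consensus is a descriptive fraction. With few
  sequences, high consensus arises easily by chance.
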