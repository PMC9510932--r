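---
title: "Detecting complex structural variants with signal-graph pattern growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting complex structural variants with signal-graph pattern growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graphsv)
```

## The problem and the model

Complex structural variants (CSVs) are rearrangements with more than two
breakpoints — a deletion flanking an inverted spacer, a dispersed
duplication paired with a deletion, adjacent segment swaps, and so on.
Callers built around fixed simple-SV models fragment such events into
partial calls or miss them outright, because no single model matches the
compound signal.

`graphsv` instead encodes all abnormal-alignment evidence in one *signal
graph* $G=(V, E)$ and detects CSVs bottom-up, without event models:

* **Nodes** $v = (type, pos, weight)$: clusters of same-kind abnormal
  signals — left/right clips, split-read junctions, and discordant
  read-pair ends classed as large-insert, small-insert, reverse-forward,
  or same-orientation (FF/RR). `weight` is the number of distinct
  supporting reads; `pos` is kept as a `[start, end)` span of the
  clustered coordinates.
* **Paired edges** $e_{pe} = (v_i, v_j, rp)$ connect two nodes supported
  by $rp$ read pairs or split reads that span both loci. Each paired edge
  carries a connection type derived from the generating signal kind:
  large-insert pairs imply a Del connection, small-insert pairs Ins,
  reverse-forward pairs Dup, same-orientation pairs Inv, split-read
  co-occurrence Split. Parallel edges of different types between the same
  node pair are all retained.
* **Adjacency edges** $e_{ae} = (v_i, v_j, dist)$ join consecutive
  same-contig nodes with their genomic gap — the reference-induced
  backbone of the graph.

A CSV is then a *maximal subgraph*: starting from every node, the
subgraph grows by one node at a time in increasing position order. A
candidate after the current frontier joins when its gap to the last
member is below `minDist` (adjacency branch), or when a paired edge links
it to any member, scanned from the last member backwards (backtracking
branch). Growth stops when no node can be appended; subgraphs contained
in a larger grown subgraph are discarded. With `minFreq = 1` (the
default) every instance is kept, so rare CSVs are not lost.

Each maximal subgraph becomes a call with:

* boundary = leftmost node start to rightmost node end,
* complexity score $CXS = (\#\text{distinct node types}) \times
  (\#\text{paired edges})$,
* a type label from the union of its edge connection types (an adjacency
  edge joining two same-orientation nodes contributes the implied Inv/Dup
  type), e.g. `"Del,Inv"` or `"Dup,Ins"`.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_clip_frac` | 0.10 | minimum clipped fraction of the read length for a clip signal |
| `min_split_mapq` | 20 | minimum MAPQ for split-read signals ("high mapping quality", unquantified upstream) |
| `insert_sd_mult` | 3 | $k$ in the insert-size discordance band $\mu \pm k\sigma$ |
| `clip_merge_window` | 5 bp | merge window for clip/split clustering |
| `min_weight` | 2 | minimum clip/split node weight |
| `min_weight_ratio` | 0.10 | minimum node weight / local read depth |
| `min_pair_support` | 2 | minimum pairs per discordant cluster |
| `min_cluster_distance_floor` | 50 bp | floor of the discordant clustering distance |
| `min_dist` | `max(2·mean insert, 1 kb)` | pattern-growth adjacency cap |
| `min_freq` | 1 | minimum pattern frequency |
| `min_link_types` | 1 | connection-type filter on reported calls |

The discordant clustering distance is the estimated mean insert size
minus twice the read length (floored): pairs spanning the same junction
can start at most that far apart. The insert profile itself is estimated
from proper pairs with a 1%/99% trim before taking moments — the trim is
a plain robustness guard against stray extreme template lengths.

The random-discordance control is implemented as the pair-support
threshold *plus* the weight/coverage ratio filter applied to discordant
clusters: both suppress sporadic discordant pairs (insert-size tails)
without modelling them explicitly. ARP signal positions use the pair's
*inner* coordinates (left read end, right read start), the coordinates
closest to the junction, so node spans stay within a clustering distance
of the true breakpoint.

## Design choices where the design was open

* **Clip coordinate**: the last aligned reference base of the clipped
  side (alignment start for left clips, alignment end for right clips).
  Hard clips count toward the 10% fraction, since the missing bases
  equally indicate a junction.
* **Node kinds are never mixed**: a clip node and a split node at the
  same coordinate stay distinct, matching the $(type, pos, weight)$
  tuple; their co-location is still visible to growth via a zero-gap
  adjacency edge.
* **Interchromosomal discordant pairs are dropped**; the method targets
  intrachromosomal CSVs.
* **Index projection**: growth candidates are held as a per-type seed
  index plus adjacency lists restricted to nodes after the frontier — the
  standard projected-database construction of pattern growth. Candidates
  are the Eae successor of the frontier and the paired-edge neighbours of
  all members; acceptance is re-checked by the distance/backtracking rule.
* **Candidate frequency check** is `freq(v) >= minFreq`; the strict
  reading (`>`) would contradict `minFreq = 1` keeping rare subgraphs.
* **Maximality** is applied globally: every grown subgraph whose node set
  is contained in another grown subgraph is dropped. Chained distant
  paired-edge hops are allowed — acceptance only requires one edge into
  the current subgraph.
* **Boundary** uses the rightmost node's *end* (clusters are spans, and
  the end is the coordinate estimate nearest the junction for left-side
  ARP nodes).
* **Edge-less singleton subgraphs are not reported as calls**: a CSV call
  must carry at least one connection type.

## Evaluation

Two tiers, both at a 500 bp per-breakpoint tolerance (inclusive):

* **unique-interval match** — the prediction's outer breakpoints each
  fall within 500 bp of the benchmark CSV's outermost breakpoints.
  Scoring is a greedy one-to-one assignment by smallest summed shift, so
  one prediction cannot satisfy two truth records.
* **all-breakpoint match** — every subcomponent of the benchmark CSV is
  matched, start and end each within 500 bp, by at least one prediction
  (predictions may be reused). The prediction set here is the callset's
  component-level intervals: the span of each paired edge (a paired edge
  *is* a predicted breakpoint pair), orientation-typed adjacency edges,
  and the outer interval — see `breakpoint_intervals()`.

A `recall_only` mode suppresses FP-based metrics for real-data-style
scoring without a curated negative set.

## The simulator: what it emulates, what it does not

`sim_config()` + `simulate_csv_dataset()` reproduce the published
benchmark workflow offline: basic operations (Del, Inv, Invdup, Tandup,
Disdup) and their reported compositions (Disdup, Invdup, DelInv,
DelDisdup, DelInvdup, DisdupInvdup, InsInv, Tantrans, DelSpaDel,
TanDisdup — drawn uniformly) are implanted on a seeded i.i.d. reference
with at least 10 kb spacing; heterozygous events modify one random
haplotype, homozygous both; wgsim-style paired-end reads are sampled and
placed back on the reference.

Default study conditions: 2 Mb reference, 50 events, 30× diploid
coverage, 2×100 bp reads, insert 500 ± 50 bp, 1% substitution errors.
Event-part lengths are log-uniform: Del/Inv/Tandup 200–2000 bp
(basic-operation implants 300–3000 bp), duplication sources 200–1500 bp,
dispersal distances 500–4000 bp, retained spacers 50–500 bp, novel
insertions 100–300 bp, and a 150–400 bp gap between the insertion and
inversion of InsInv so the insertion stays read-pair-detectable — values
a short-read caller is realistically expected to face, chosen once.
Randomized mode composes 2–4 random basic operations with 100–5000 bp
parts. Scaled-down runs use these sizes because they already produce
hundreds of signal nodes per replicate; the acceptance protocol averages
three replicates per zygosity.

**Truth components** are the breakpoint pairs each operation creates on
the reference: interval operations (Del, Inv, Tandup, spacers, Ins)
contribute their reference interval, whose endpoints are exactly the
created breakpoints; dispersed duplications contribute their two
source-edge-to-insertion-site junction spans, because the source interval
itself leaves the reference adjacency unchanged and no read-level
evidence of it exists. DelSpaDel keeps its classic three-component
decomposition (Del, inverted spacer, Del). DelDisdup/DelInvdup are
realized as cut-and-paste (source excised, copy reinserted downstream), a
real CSV class whose deletion component is observable from reads.

**Truth-guided alignment** inverts the variant map instead of running an
external aligner: full-length alignments inside segments; soft-clipped
primaries plus supplementary (`SA`-tagged) records at junctions
(secondary piece ≥ 30 bp); orientation/insert discordance follows from
coordinates; reads wholly inside novel sequence are unmapped. An
`external_aligner` mode substitutes any user command on the emitted
FASTQ. Consequences for interpretation: mapping ambiguity, repeat
mismapping, and alignment noise of real data are *not* emulated, so
simulated recall is an upper bound on real-data recall — passing tests
demonstrate the graph construction and growth machinery, not robustness
to alignment artifacts. Microhomology at junctions and error profiles
beyond uniform substitutions are likewise out of scope.

## Numerical and degenerate-input notes

* Coordinates are 0-based half-open internally; conversion to 1-based
  happens only in the VCF writer.
* Equal-position nodes order stably by `(start, kind)`; growth recursion
  and output are therefore permutation-invariant.
* Adjacency gaps clamp at 0 for overlapping spans.
* An empty graph, an empty region, or an empty callset all yield valid
  empty outputs (a header-only VCF, empty streams), never errors;
  missing BAM indexes and insufficient proper pairs for the insert
  profile are hard errors.
* The insert-profile sd of a degenerate template-length distribution is
  0, which simply collapses the discordance band to the mean.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(genome_length = 5e5, n_events = 12, coverage = 30,
                  seed = 7, zygosity = "het")
rep <- run_benchmark_replicate(cfg)
rep$unique_interval
rep$all_breakpoint
head(calls_table(rep$callset$calls))
```

On simulated data the caller recovers essentially all implanted events
whose signals exceed the support filters; residual misses come from
insert-size-tail discordant clusters that chain into a call via
adjacency edges and stretch its boundary past the tolerance — visible in
any run as calls slightly wider than their event.

## Known limitations

* Intrachromosomal events only; no breakend decomposition, no
  genotyping.
* Boundary precision is limited by the discordant clustering distance
  when no clip/split node marks the outermost breakpoint.
* Growth cost is linear in nodes on adjacency-only chains but can grow
  with dense paired-edge clusters; the maximality filter is exact, not
  heuristic.
* The simulator's truth-guided alignment makes mapping ideal (see
  above); real-data performance additionally depends on the upstream
  aligner.
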