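---
title: "Methods: hub discovery and annotation in PML-NB interactomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hub discovery and annotation in PML-NB interactomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`nbhub` turns per-protein interaction snapshots into an evidence-filtered
hub network around PML nuclear bodies, clusters it, and annotates the
hubs with phase-separation and disorder predictions. This vignette is the
package's account of the underlying procedures, the choices that were
genuinely open, and what the synthetic benchmarks do and do not show.

## Evidence model

An interactome is a focal protein's partner set. Public PPI databases
record one row per supporting experiment, so the same pair appears many
times; `read_interaction_table()` collapses these to a single **evidence
count**: the number of distinct (publication, experimental system)
combinations supporting the pair. This definition is deterministic,
recomputable from any snapshot, and deliberately ignores database-specific
confidence fields, whose semantics drift between export flavors. Exact
duplicate records therefore never inflate evidence, and row order never
matters. Self-interactions are dropped; identifiers are uppercased
official gene symbols with no alias resolution (alias mapping would pull
in an external service and make runs irreproducible).

## The hub rule

A candidate protein is a **hub** when at least `k_min` core interactomes
contain it with evidence `>= evidence_min`; defaults are `k_min = 4`,
`evidence_min = 2`. The candidate universe is the union of the
evidence-filtered partner sets, excluding the core proteins themselves
(hubs are *partners* of cores; a flag restores cores as candidates for
the alternative reading). One or two shared cores are weak evidence of
organelle association, and a threshold of three remains dominated by
proteins whose only support is a single anomalously large interactome
(TP53-like, > 2500 partners); the rule handles such cores by raising the
core count required, not by excluding them. Output order is descending
core count, then symbol — ties are broken lexicographically everywhere in
the package so that reports are byte-stable. `hub_sensitivity()` exposes
the full (k, evidence) grid; hub counts are provably non-increasing in
both thresholds, and the test suite asserts this on generated data.

## MCODE

The hub graph takes its nodes from hubs plus cores and its edges from
every supplied snapshot at the same evidence threshold (boundary
inclusive). When one pair occurs in several snapshots the edge keeps the
maximum per-snapshot evidence; distinct-record union across files is not
recoverable once snapshots are aggregated. Clustering runs on the
unweighted simple graph, the standard MCODE setting.

The MCODE implementation follows the original algorithm:

* **weighting** — for vertex `v` with degree `>= degree_cutoff`, take the
  subgraph induced by the closed neighborhood `N[v]`, find its highest
  k-core, and set `w(v) = k_max * density` of that core, with
  `density = 2E / (V(V-1))` (zero below two vertices);
* **expansion** — seeds are processed in decreasing weight (ties
  lexicographic, a determinism choice that the original leaves
  unspecified); a neighbor joins iff `w > (1 - node_score_cutoff) *
  w(seed)` and lies within `max_depth` of the seed; a vertex joins at
  most one complex pre-fluff;
* **post-processing** — complexes without a `k_core`-core are discarded;
  `haircut` removes degree-1 members; `fluff` adds boundary vertices
  whose closed-neighborhood density exceeds `fluff_density_cutoff`.
  Complexes are scored `density * size` and ranked descending.

Defaults are degree cutoff 2, node score cutoff 0.2, k-core 2, max depth
100, haircut and fluff off.

A structural property of this expansion rule worth knowing: two dense
blocks joined by even a handful of bridge edges merge into one complex
whenever their vertex weights are within `node_score_cutoff` (20%) of
each other, because the joining test compares only against the *seed's*
weight. On planted-partition benchmarks with within-block density 0.9 and
block sizes 20/16/14/11, adjacent blocks sit within that 20% window, so a
faithful MCODE reports two merged complexes rather than four — the
acceptance script reports the complex count and the per-block Jaccard it
actually computes. Blocks separate cleanly once their weights differ by
more than the cutoff (for example, perfect cliques of sizes 20 and 10),
which the unit suite demonstrates. This is a property of the algorithm,
not of the implementation.

`topology_summary()` reports the average local clustering coefficient
(isolates contribute zero), the characteristic path length of the largest
component, and small-world sigma `(C/C_r)/(L/L_r)` averaged over a seeded
degree-preserving rewired ensemble (default 20 rewires); sigma is `NA`
below four nodes or when rewiring is impossible.

## Enrichment statistics

`hypergeom_tail(k, n, K, N)` is the upper tail `P(X >= k)` of the
hypergeometric distribution, evaluated through log-space tail routines so
small p-values keep full precision; the test suite verifies it against
direct closed-form summation for every configuration with `N <= 30` at
relative error below 1e-12. Adjustment is Benjamini–Hochberg across all
terms of the library. The odds ratio uses the 2x2 table
(`k`, `n-k`, `K-k`, `N-n-K+k`) with the Haldane–Anscombe 0.5 correction
applied exactly when a cell is zero. The combined score is
`-ln(p) * z`; the web platforms that popularized this score calibrate `z`
by a rank-deviation scheme that cannot be reproduced offline, so `z` here
standardizes the overlap count by its hypergeometric mean and standard
deviation (`z = 0` when the standard deviation is zero). p-values and
BH-adjusted p-values are the primary comparable quantities; the combined
score is reported for completeness.

The background universe defaults to the union of the library's terms and
can be overridden. Query symbols outside the universe are dropped and
counted, never added to `N` — adding untestable genes to the background
would bias every term toward significance.

## Annotation thresholds

All thresholds reproduce the predictors' published usage, including
strict-versus-inclusive boundaries:

| call | rule |
|---|---|
| catGRANULE | LLPS iff score > 0.5 (strict) |
| PSPHunter | likely iff > 0.61; non-LLPS iff < 0.36; else unlikely (band endpoints are "unlikely") |
| combined | LLPS iff PSPredictor > 0.5 AND FuzDrop > 0.6; non-LLPS iff both fail; exactly one → controversial |
| driver | FuzDrop pLLPS >= 0.60 (inclusive) |
| client | not a driver, and a run of >= `min_region_length` consecutive residues with pDP >= 0.60 |
| PPIDR | 100 x fraction of residues with disorder score > 0.5 (strict); < 10% highly ordered, 10–30% moderately disordered (bounds belong to the middle class), > 30% highly disordered |

A missing score yields `"unknown"`, never a default label, and unknowns
are excluded from summary counts rather than coerced. The
droplet-promoting-region rule says only "consecutive residues"; the
package defaults to `min_region_length = 10`, since a one-residue
"region" is biologically meaningless, and surfaces the parameter rather
than hiding the choice. PPIDR feeds from a configurable track predictor
(default name `disorder`, intended for VSL2-style profiles).

GRAVY is the mean Kyte–Doolittle hydropathy; a non-standard residue is a
hard error naming its position, because silently skipping residues would
shift the average. Net charge at pH is a Henderson–Hasselbalch sum over
both termini and the D/E/C/Y/H/K/R side chains using a single
Bjellqvist-style pKa table shipped as the exported `pka_table` constant
(published tables differ by a few tenths of a pK unit; shipping exactly
one, named, keeps results comparable across runs).

## Synthetic data: what it shows and what it does not

Every input has a seeded generator with a recorded ledger, and all
generators are pure functions of (spec, seed) that leave the caller's RNG
untouched. The defaults emulate the shape of the targeted study: 10 core
interactomes, 61 planted hubs versus 500 decoys, evidence counts from a
truncated geometric (most pairs 1–2 records, a short tail to 6),
four planted dense blocks of sizes 20/16/14/11, a 50-term library with a
planted term containing 90% of a 30-gene query, tracks of 80–300
residues, and label frequencies in the range reported for nuclear-body
hub proteins (≈ 50/45/5% driver/client/neither, 80/13/7% disorder
classes, 70% SUMO, 23% ubiquitin, 5% unknown PTM flags). Decoys violate
the hub rule in a recorded way: either too few qualifying cores, or
presence in enough cores but with sub-threshold evidence in all but
`k_min - 1` of them.

Scores are sampled strictly inside the correct side of every threshold,
with a margin of a few hundredths, so planted labels are realized
exactly; the FuzDrop score feeds both the combined LLPS call and the
driver/client role, so those labels are sampled jointly and are always
mutually consistent. Consequently the benchmarks demonstrate correctness
of the *decision logic and plumbing* — they cannot show robustness to
scores that sit on a boundary (covered instead by explicit ±epsilon
truth-table tests), to identifier mismatches between resources, or to
the heavy-tailed, correlated structure of real interactomes. Reported
reference figures from live database snapshots are reproducible only
with those snapshots as inputs.

Problem sizes in the shipped tests were chosen to keep the full suite
around a minute: the hub benchmark runs at full scale (61/500/10), the
enrichment calibration uses 100 planted and 200 null seeded runs on
50-term libraries, and the exhaustive hypergeometric check covers all
`N <= 30`.

## Determinism and degenerate inputs

All orderings are total (count/score descending, then lexicographic);
every file writer emits sorted, fixed-format tables; and
`run_pipeline()` is byte-deterministic in (inputs, config, seed), which
the suite verifies by hashing two runs' output trees. Degenerate inputs
are defined rather than accidental: empty interaction tables produce
empty interactomes with a warning; an empty hub set is a valid empty
graph; complexes disjoint from the enrichment universe are recorded as
"no testable genes"; out-of-range predictor scores are hard errors
naming protein and predictor, because a clamped score would silently
change a classification.

## Known limitations

* Evidence counts approximate experimental support; they do not model
  assay quality or throughput.
* The combined enrichment score is not numerically comparable to web
  platforms that use rank-calibrated z-scores.
* MCODE at the default node score cutoff merges bridged blocks of
  similar density (see above); when block separation matters, inspect
  the sensitivity of the complex list to `node_score_cutoff`.
* No alias resolution: symbols must already be consistent across inputs.
* PTM flags are taken from an annotation table; the package does not
  predict modification sites from sequence.
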