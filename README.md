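# nbhub

Interactome comparison and hub discovery around PML nuclear bodies.

PML nuclear bodies (PML-NBs) are membraneless nuclear organelles built
around the PML protein; deubiquitinases such as USP7 and a set of core
PML-NB-associated proteins (PML, UBC9, CREBBP, DAXX, SUMO1, MDM2, PIAS1,
TP53, HIPK2, SLX4) share large numbers of interaction partners. `nbhub`
implements, as a tested and reusable R pipeline, the analysis that turns
per-protein interaction snapshots into a picture of that shared
neighborhood:

1. **Interactome I/O** — BioGRID TAB3-style snapshots are collapsed to
   partner sets with an *evidence count* per pair: the number of distinct
   (publication, experimental system) records supporting the interaction.
2. **Overlap analysis** — pairwise intersections, three-way Venn
   partitions (e.g. against senescence/aging gene lists), and the full
   pairwise overlap matrix across interactomes and proteome lists.
3. **Hub discovery** — a protein is called a *hub* when it appears in at
   least `k_min = 4` core interactomes with evidence count
   `>= evidence_min = 2`. Both thresholds are configurable and a
   sensitivity scan over the (k, evidence) grid is provided.
4. **Hub network + MCODE** — the hub/core interaction graph is clustered
   with a full implementation of the MCODE algorithm (vertex weight =
   `k * density` of the highest k-core of the closed neighborhood; greedy
   seeded expansion at a node score cutoff; k-core/haircut/fluff
   post-processing) at the standard parameters (degree cutoff 2, node
   score cutoff 0.2, k-core 2, max depth 100). Topology summaries include
   a small-world sigma against degree-preserving rewired nulls.
5. **Enrichment** — hypergeometric over-representation against GMT
   libraries: for overlap `k` of a query of size `n` against a term of
   size `K` in a universe of size `N`, `p = P(X >= k)`,
   Benjamini–Hochberg adjustment across the library, Haldane–Anscombe
   corrected odds ratio, and a combined score `-ln(p) * z` with `z` the
   standardized overlap count.
6. **Sequence annotation** — consensus liquid–liquid phase separation
   (LLPS) calls from predictor scores (catGRANULE > 0.5; PSPHunter
   > 0.61 / < 0.36; PSPredictor > 0.5 AND FuzDrop > 0.6, conflicts
   labeled *controversial*), FuzDrop driver/client roles (pLLPS >= 0.60,
   droplet-promoting regions of consecutive pDP >= 0.60), PPIDR disorder
   percentage (residues with disorder score > 0.5; < 10% ordered, 10–30%
   moderate, > 30% highly disordered), Kyte–Doolittle GRAVY, and
   Henderson–Hasselbalch net charge at pH.
7. **Synthetic data** — seeded generators plant hubs, decoys, dense graph
   blocks, enriched terms and threshold-respecting predictor scores with
   a recorded ground-truth ledger, so the entire pipeline is testable
   offline. External predictors are score *inputs*; none are
   re-implemented here.

Everything is tibble-first: results are tibbles (or carry `tidy()` /
`glance()` methods) and each major result type has an `autoplot()`.

## Worked example

A fully synthetic run with 12 planted hubs across 6 cores:

```r
library(nbhub)

spec <- synthetic_spec(seed = 42, n_planted_hubs = 12, n_decoys = 60, n_cores = 6)
gi   <- gen_interactomes(spec)
hubs <- select_hubs(gi$cores, hub_params(k_min = 4, evidence_min = 2))
glance(hubs)
#> # A tibble: 1 × 5
#>   n_candidates n_hubs n_cores k_min evidence_min
#> 1           69     12       6     4            2
```

Of 69 candidate partners, exactly the 12 planted hubs reach four
evidence-filtered cores. Enriching the hub set against a synthetic
library with one planted term:

```r
gl  <- gen_geneset_library(spec,
  universe = c(gi$ledger$planted_hubs, gi$ledger$decoys$protein),
  query = hub_proteins(hubs))
enrich(hub_proteins(hubs), gl$library, top = 3)
#>   term          k     K  p_value adjusted_p odds_ratio
#> 1 T_PLANTED    11    30 0.000155    0.00790      23.7
#> 2 T007         10    38 0.0201     0.482         5.71
#> 3 T046          6    17 0.0283     0.482         4.45
```

The planted term ranks first: 11 of the 12 hubs fall in it, raw
`p = 1.6e-4`, and it is the only term surviving BH adjustment. The whole
study design runs end-to-end from one call —
`run_pipeline(synthetic_run_config(spec)$config)` — writing TSV tables,
GraphML, and a JSON run report whose counts (overlap size, hub count,
complex count, annotation categories) can be compared against any input
snapshot set.

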