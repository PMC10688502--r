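# sesn

Essential protein prediction by seed expansion over active
protein-protein interaction (PPI) sub-networks.

## What this is for

Essential proteins are indispensable for cell survival, and finding them
computationally matters because knockout experiments are slow, costly
and species-limited. Network-based prediction is attractive but
high-throughput PPI data are riddled with false-positive interactions.
`sesn` is for systems-biology researchers who have a PPI edge list, a
gene expression time course, and standard annotations (GO terms, protein
complexes, subcellular localizations, plus a gold standard for
evaluation), and who want a ranked list of candidate essential proteins
that is robust to noisy edges.

## The method

The package decomposes the network into one *active sub-network* per
expression sample point: a gene is active at a sample when its averaged
expression clears a per-gene k-sigma threshold

```
Thr_k(g) = Avg(g) + k * sigma(g) * (1 - 1/(1 + sigma(g)^2)),  k = 1, 2, 3
```

and each sample gets a discretized activity probability
`Ap ∈ {0, 0.68, 0.95, 0.99}` by threshold band. An edge belongs to
sub-network `i` iff both endpoints are active there.

Biological evidence weights everything: GO term overlap `GOW`,
co-expression `GW = (PCC + 1)/2`, complex membership `PCW`, and a
subcellular weight `SW` from compartments enriched in essential
proteins. These combine into a whole-network node score
`score_initial_v = (Σ_u GOW·GW·PCW) · SW_v` and a per-sub-network edge
weight `Wmatrix_i(v,u) = GOW · Ap_i(v)Ap_i(u) · PCW · SW_v SW_u`, each
factor switchable by a 0/1 exponent for ablation studies.

Prediction seeds one random protein per sub-network and grows the set
`K`: each iteration adds the frontier protein best connected to `K`
under `Wmatrix` (maximized across all sub-networks simultaneously), then
an *error-correction* step on the whole network swaps the
lowest-`score_initial` member of `K` for the highest-scoring frontier
protein (each protein removable at most once). Earlier addition means
higher rank. Output quality is measured with SN/SP/PPV/NPV/F/ACC and
jackknife curves.

A deterministic synthetic-data generator produces self-contained
benchmarks (planted essential community, shared periodic expression,
enriched annotations), so the whole pipeline runs without downloads.

## Worked example

```r
library(sesn)

ds <- generate_dataset(synthetic_config(rng_seed = 7))
ds
#> <sesn_dataset> 200 proteins, 842 interactions, 30 essential, 36 raw expression columns

run <- run_pipeline(ds$ppi, ds$expression, ds$bundle,
                    variant = "sesn", rng_seed = 7)
run$prediction
#> <ranked_prediction> 47 proteins (12 seeds, 16 removed during correction) [truncated]
#>    rank protein provenance step
#> 1     1   P0200       seed    0
#> 2     2   P0182       seed    0
#> 3     3   P0179 correction    2
#> 4     4   P0148  expansion    3
#> 5     5   P0042 correction    4
#> ...

run$measures
#> <measures> SN=0.6667 SP=0.8412 PPV=0.4255 NPV=0.9346 F=0.5195 ACC=0.8150
```

The 36-column matrix (three cycles of twelve time points) yields twelve
active sub-networks, so `K` starts from twelve random seeds. The
`provenance` column records which mechanism added each protein; here the
run recovered 20 of the 30 planted essentials (SN = 0.67) in a ranking
of 47 — the expansion stalled three short of the requested
`n = |V|/4 = 50` because no remaining frontier protein carried positive
weight, and the ranking is truncated rather than padded (a warning says
so). The jackknife curve `run$jackknife` climbs to the same 20.

Component-removal variants (`rm_sub`, `rm_correction`, `wmatrix_only`,
`score_initial_only`, `all_subcellular`) and the nine-way exponent
ablation (`run_ablation_sweep()`) reuse the same interface. A thin
command-line wrapper lives at `inst/cli/sesn`
(`sesn synth|run|ablate|eval`).

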