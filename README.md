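# phosphowalk

Random-walk phosphorylation-chain inference for pan- and phosphosite-specific
antibody microarray screens.

Antibody microarrays of the Kinexus KAM-1325 / KAM-2000 style measure the
expression and phosphorylation state of hundreds of signalling proteins in a
treated lysate against a control lysate. A single screen yields, per antibody
probe, a treated signal, a control signal and their reported errors — but no
information about *which kinase* produced each phosphorylation change.
`phosphowalk` turns such a screen, together with a prior signed
kinase–substrate network, into ranked *phosphorylation chains*: root-anchored
paths of phosphorylation events that occur more (or less) often than expected
when the measured changes are placed on the network at random. It is aimed at
systems-biology analysts who have a probe table and a kinase–substrate
relation table and want a reproducible, seeded, testable version of this
style of network deconvolution.

## The method

For each probe, the percent change from control and the log2 fold change are

    %CFC = 100 · (S_treated − S_control) / S_control
    log2FC = log2(S_treated / S_control)

after three quality filters: (i) *low signal* — either channel strictly below
the array design's threshold (1,000 units for KAM-1325, 500 for KAM-2000);
(ii) *relative error* — `(e_t + e_c) / |S_t − S_c| > 1`; (iii) *total error*
— a probe whose summed error across the treatment arrays strictly exceeds
its summed error across the control arrays (applied when replicate arrays
are available).

Measurements are attached to a signed directed kinase–substrate network:
every edge delivering phosphorylation to a measured `(substrate, site)`
inherits that site's %CFC, relations of unknown effect count as activating,
pan (expression) probes annotate nodes only, and chains may start only at
*root kinases* (in-degree 0). The network is split into up- and
down-regulated subnetworks, analysed independently.

Chains are sampled by seeded, edge-self-avoiding random walks: from a
uniformly chosen root, each step takes an untraversed outgoing edge with
probability ∝ (|%CFC| + ε), stopping when the last edge is inhibitory, when
no untraversed edge remains, or at a length cap. A node with a single
unmeasured downstream option receives an imputed fold change (uniform in
[0, 20]% for the treated condition, exactly 20% for the control). Observed
chain frequencies are compared with a permutation null — the measured
site-level values are reshuffled across the measured sites, the subnetwork
re-derived, and the walks re-run — giving per-chain `enrichment =
observed / expected`. Chains outside the enrichment band whose counts pass a
BH-corrected binomial test are resolved for parallel phosphorylation (the
greater-magnitude delivery to a site wins) and selected if they have more
than 2 intermediates and every per-edge |%CFC| (measured or imputed)
exceeds 5%. Selected chains from both directions are assembled into a
comparative pathway map styled by log2 fold change, exportable as GraphML,
DOT or JSON, alongside a lead table of the measured phosphosites involved.

An exact enumeration oracle (`enumerate_chains()`) and a synthetic-array
generator with planted cascades (`synthetic_scenario()`, `run_scenario()`)
make the whole pipeline testable end to end.

## Worked example

The package bundles a 16-relation regression network around the AKT
(growth/survival) and CDK1 (cell-cycle) signalling arms with a synthetic,
sign-consistent probe table:

```r
library(phosphowalk)

pre <- preprocess_pipeline(fig2_probe_table(), array_spec("KAM-1325"))
net <- attach_measurements(build_network(fig2_relations()), pre$measurements)
net
#> <signed_network> 15 nodes, 16 edges (16 measured, 5 inhibitory)

parts <- split_signed(net)
res <- infer_direction_run(parts$up, parts$down,
                           walk_config(min_intermediates = -1, seed = 11))
res
#> <infer_result> 6 up chains, 7 down chains, 11 hits

print(res$up_chains[[1]])
#> <phospho_chain up> PDK1 -> AKT@S473 -| BAD@S75
#>   intermediates: 1, score: 25, ends by inhibition

head(res$hits, 5)
#>   target site direction cfc_percent n_chains
#> 1    AKT S473        up          25        4
#> 2    AKT Y326        up          18        2
#> 3    BAD  S75        up          30        3
#> 4   CDK1 T161      down         -20        2
#> 5   CDK1  Y15      down         -25        2
```

The up-regulated arm activates AKT at S473 (via PDK1 and MAPK14) and Y326
(via SRC), ending at the inhibitory phosphorylation of BAD S75 — chains
never continue past an inhibitory edge — while the down-regulated arm
carries CDK1 (T161/Y15), JUN S73 and the RPS6KB1 sites. The depth filter is
disabled here because this 16-relation excerpt holds no chain with more
than 2 intermediates; at full scale the default `walk_config()` applies.

The same analysis runs from the shell:

```sh
Rscript inst/cli/phosphowalk.R infer \
  --probes inst/extdata/fig2_probes.tsv \
  --relations inst/extdata/fig2_relations.tsv \
  --seed 11 --out out/
```

writing chain tables (TSV/JSON), the lead table and the styled pathway map
(GraphML/DOT/JSON) plus a provenance record; `simulate` and `all` run the
synthetic benchmark end to end.

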