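# radhub

Hub-gene discovery for short expression time courses of bone marrow
recovering from ionizing radiation.

After a high sub-lethal radiation dose, bone marrow regenerates over roughly
three weeks. Profiling whole marrow at 0 (sham), 3, 7, 11 and 21 days after
irradiation yields a genes × samples matrix in which the recovery program is
buried among thousands of unchanged genes. `radhub` implements the analysis
funnel that narrows such a matrix down to candidate *hub genes*, together
with a ground-truthed synthetic-data generator for benchmarking every stage.
It is aimed at computational biologists who want the whole chain — from
differential calling to k-core hubs — as tested, scriptable R functions
rather than a string of web tools.

## The method

Six stages, each an exported function over data frames, chained by
`run_pipeline()`:

1. **Differential calling** — per timepoint *t* vs baseline, Welch's
   *t* on log2 intensities (pooled Student via `equal_var = TRUE`); a gene
   is selected if *p* < α at **any** timepoint; Benjamini–Hochberg *q*
   reported per timepoint.
2. **Temporal clustering** — trajectories (per-timepoint mean log2 ratio to
   baseline) are matched by correlation distance *d* = 1 − *r* to *m* = 50
   integer model profiles chosen greedily (max–min) from the
   (2c+1)^(T−1) − 1 unit-change candidates. A profile's member count is
   tested against an exact timepoint-permutation expectation (4! = 24
   permutations at T = 5) via a Binomial upper tail, Bonferroni-corrected,
   significant at corrected *p* < 0.001.
3. **Enrichment** — one-tailed Fisher exact *p* = P(X ≥ k) from the
   hypergeometric tail for each GMT term (χ² reported alongside; EASE and
   DAVID-style display for pathway tables), plus the transitive-reduction
   map of significant terms over a child→parent term DAG.
4. **Co-expression network** — Pearson *r* between trajectories of the
   genes inside significant terms; edge iff |r| ≥ 0.8 and correlation-test
   *p* < 0.05; per-node degree, clustering coefficient, connected
   component and k-core level (iterative peeling). The genes at each
   component's maximum coreness are its **core genes**.
5. **PPI overlap** — case-insensitive intersection of the differential
   genes with a literature-mined radiation gene list; the overlap seeds a
   subnetwork (seeds + first neighbours, induced) of a PPI edge list; nodes
   with within-subnetwork degree ≥ 11 are reported as hubs.
6. **qPCR validation** — 2^−ΔΔCt relative quantification (Livak
   convention, Gapdh-style reference) and sign concordance with the array
   fold changes.

## Worked example

Everything below is generated — no real data needed:

```r
library(radhub)
library(dplyr)

bundle <- simulate_study_inputs(sim_config(seed = 7))
report <- run_pipeline(
  bundle$sim$expr, bundle$annotations$sets, bundle$annotations$dag,
  bundle$ppi$ppi, bundle$ppi$literature, ct = bundle$qpcr,
  config = run_config(seed = 7)
)
#> inputs: 1000 genes, 20 samples
#> diffexpr: 304 of 1000 genes differential at any timepoint
#> stem_clustering: 5 significant profiles holding 141 of 304 genes
#> enrichment: 3 of 21 terms significant; 43 genes inside significant terms
#> coexpression_network: 43 genes, 173 edges, 5 component(s), 43 core genes
#> ppi_overlap: 42 overlapping genes, subnetwork of 303 nodes, 30 hubs at degree >= 11
#> qpcr: 6 gene-timepoint folds; direction concordance 1.00
```

The log is the funnel: 1000 simulated genes → 304 differential (100 were
planted; the permissive any-timepoint raw-p rule deliberately over-calls,
and the reported q-values let you tighten that) → 141 genes in 5
significant temporal profiles → 43 genes inside significant annotation
terms → a 43-gene correlation network whose k-core structure exposes the
planted module. The 42-gene literature overlap was planted exactly, and all
6 simulated qPCR assays agree with the array in direction.

```r
tidy(report$stem) |> filter(significant) |>
  select(profile_id, steps, n_genes, n_expected, p_bonferroni)
#> # A tibble: 5 × 5
#>   profile_id steps         n_genes n_expected p_bonferroni
#>        <int> <chr>           <int>      <dbl>        <dbl>
#> 1          0 0,-2,-4,-6,-8      33      11.4      3.12e- 6
#> 2          3 0,-2,0,0,-1        29       4.25     5.69e-14
#> 3         12 0,1,0,0,2          27       4.75     3.94e-11
#> 4         29 0,2,2,1,3          30       6.25     1.34e-10
#> 5         33 0,-1,1,0,0         22       3.38     4.25e-10
```

Each row is one model profile: its unit-change step vector, the observed
member count, the count expected under timepoint permutation, and the
Bonferroni-corrected Binomial tail.

```r
tidy(report$enrichment) |> select(term_id, k, K, p_fisher, q, enrichment_ratio) |> head(3)
#> # A tibble: 3 × 6
#>   term_id          k     K p_fisher        q enrichment_ratio
#>   <chr>        <int> <int>    <dbl>    <dbl>            <dbl>
#> 1 TERM:PLANTED    29    50 7.96e-14 1.67e-12             4.11
#> 2 TERM:0013       10    40 4.38e- 2 3.07e- 1             1.77
#> 3 TERM:0015       10    40 4.38e- 2 3.07e- 1             1.77
```

The planted enriched term ranks first by more than ten orders of magnitude
(k of its K = 50 members hit by the 141-gene study set, enrichment ratio
4.1). `report$core_genes` lists each network component with its maximum
k-core and the genes attaining it; `report$hubs` holds the degree-ranked PPI
hubs; `autoplot()` methods draw the volcano, profile, enrichment, network
and qPCR figures, and `tidy()`/`glance()` give broom-style tables for every
result.

## Package layout

| Where | What |
|---|---|
| `R/simulate.R` | ground-truthed generators (`sim_config`, `simulate_timecourse`, `simulate_annotations`, `simulate_ppi_and_literature`, `simulate_qpcr`, `simulate_study_inputs`) |
| `R/diffexpr.R` | `welch_t`, `bh_fdr`, `call_differential`, `differential_genes` |
| `R/profiles.R` | `enumerate_candidate_profiles`, `select_model_profiles`, `logratio_trajectories`, `assign_profiles`, `profile_significance`, `cluster_timecourse` |
| `R/enrichment.R` | `fisher_enrichment`, `chi2_enrichment`, `pathway_enrichment`, `build_go_map` |
| `R/network.R` | `pairwise_correlation`, `build_network`, `clustering_coefficient`, `kcore_decomposition`, `core_genes` |
| `R/ppi.R` | `overlap_genes`, `extract_seed_subnetwork`, `hub_nodes` |
| `R/qpcr.R` | `ddct_fold`, `concordance` |
| `R/io.R`, `R/config.R`, `R/pipeline.R` | TSV/GMT/edge-list/Ct readers and writers, `run_config`, `run_pipeline`, `write_report` |

The methods vignette (`vignettes/hub-gene-discovery.Rmd`) documents the
model assumptions, the generator's design choices and the package's
numerical conventions in detail.
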