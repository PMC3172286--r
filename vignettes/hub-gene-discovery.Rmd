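---
title: "Hub-gene discovery in post-irradiation bone-marrow time courses: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hub-gene discovery: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radhub)
library(dplyr)
```

## The analysis problem

After a high, sub-lethal dose of ionizing radiation, bone marrow passes
through an injury phase (days) into a recovery phase (weeks) during which
hematopoietic stem cells re-expand and blood-cell counts normalise. A short
expression time course over this window — sham-irradiated baseline at day 0
and irradiated samples at days 3, 7, 11 and 21 — carries the transcriptional
signature of that recovery. `radhub` implements the multi-stage funnel that
turns such a matrix into a small set of candidate *hub genes*:

1. **Differential calling** per timepoint against baseline, with a gene
   selected when it is significant at *any* timepoint.
2. **Temporal clustering** of the selected genes against integer model
   profiles, keeping genes in profiles that hold significantly more genes
   than expected by chance.
3. **Term enrichment** of the clustered genes (Fisher's exact test over a
   GMT collection) and a subsumption map of the significant terms.
4. **Co-expression network** over the genes inside significant terms,
   with k-core decomposition; the genes at each subnetwork's maximum k-core
   level are its core genes.
5. **Literature cross-check**: the differential genes are intersected with a
   text-mined radiation gene list; the overlap seeds a subnetwork of a
   protein-protein interaction (PPI) network, whose high-degree nodes are a
   second hub list.
6. **qPCR validation** of selected fold changes by the 2^-ddCt method.

Every stage is an exported function over data frames; `run_pipeline()`
chains them and logs the gene counts entering and surviving each stage.

## Statistical machinery, stage by stage

### Differential calling

Tests run on log2 intensities. For gene $g$ and timepoint $t$ the two-sample
statistic compares the $n_t$ irradiated replicates with the $n_0$ baseline
replicates. The default is Welch's unequal-variance $t$ with
Welch–Satterthwaite degrees of freedom — the safer choice for 4-vs-4 designs
with no variance pooling across genes — and `equal_var = TRUE` restores the
classical pooled (Student) form. Degenerate rows are resolved by convention:
both groups constant and equal gives $p = 1$; both constant but different
gives $p = 0$.

Two calibration facts matter for interpreting the tests in this package.
Under the global null the pooled statistic is exact, so its rejection rate
at $p<0.05$ sits at the nominal 5%. The Welch approximation at these tiny
group sizes is slightly *conservative* (empirically ≈4.2% at 4-vs-4); the
acceptance suite therefore checks nominal calibration on the pooled form and
one-sided conservativeness for the Welch default.

Benjamini–Hochberg q-values are computed per timepoint across genes and
reported alongside. The selection rule (`significant_any`) follows the raw
p-at-any-timepoint criterion the funnel is designed around; callers wanting
an FDR rule can use `differential_genes(de, rule = "q_any")`.

A note on the baseline: a design that hybridises a single sham chip per
batch cannot support a per-timepoint t test. All baseline chips are pooled
into one control group (they are all recorded at day 0); `call_differential`
refuses to run with fewer than two of them, and the `baseline_pooled` flag
only switches which of the two explanatory errors is raised. The synthetic
generator sidesteps the problem by giving the baseline the same replicate
count as every other timepoint.

### Model temporal profiles

A model profile is an integer trajectory starting at 0 whose per-step change
is bounded by $c$ (`max_unit_change`, default 2): there are
$(2c+1)^{T-1}-1$ non-flat candidates for $T$ timepoints (624 at $T=5$,
$c=2$). From these, `select_model_profiles()` picks $m$ (default 50)
prototypes by greedy max–min selection under the distance
$d(x,y) = 1 - r(x,y)$, starting from the lexicographically smallest
candidate, with lexicographic tie-breaks — fully deterministic, no seed
involved.

Genes enter as log-ratio trajectories (per-timepoint mean log2 minus the
baseline mean, so the first element is exactly 0) and are assigned to the
closest profile by the same correlation distance, ties to the lowest profile
id. Zero-variance trajectories cannot be correlated and land in a reserved
unassigned bucket.

Significance follows the short time-series clustering logic: the expected
share of genes per profile is what assignment yields after permuting the
order of the non-baseline timepoints. At $T=5$ all $4! = 24$ permutations
are enumerated exactly, so there is no Monte-Carlo noise in the expectation;
longer courses fall back to 240 sampled permutations (seeded). The observed
member count is then tested against an upper Binomial tail at the expected
fraction, Bonferroni-corrected across the $m$ profiles, significant at
corrected $p < 0.001$ by default. A profile with no members — observed or
under any permutation — gets $p = 1$ by convention.

### Enrichment and the term map

Over-representation only: for a term with $K$ background members, $k$ hits
in a study set of $n$ from a universe of $N$, the Fisher exact p is the
upper hypergeometric tail $P(X \ge k)$. The universe defaults to all genes
on the array. A Pearson chi-squared p (no continuity correction) is reported
for reference but never used for selection; it is flagged unreliable when an
expected cell drops below 1. The enrichment ratio is $(k/n)/(K/N)$.
`pathway_enrichment()` is the same machinery with two DAVID-style options:
the conservative EASE variant (Fisher on $k-1$) and a percentage-scale FDR
display column. Term selection uses raw $p < 0.05$, mirroring the selection
convention of the stage this feeds (q-values are reported).

The map of significant terms connects term $a$ to significant ancestor $b$
when no other significant term lies on a path between them — the transitive
reduction of the ancestor relation restricted to significant terms. The DAG
carrier is a plain child–parent table; full ontology parsing is out of
scope.

### Co-expression network and k-cores

Pairwise Pearson correlation is computed, by default, between per-timepoint
mean log-ratio trajectories — the same 5-point object the profiles are
matched against, which is the reading of "normalized signal intensity"
consistent with trajectory-level clustering; `per_sample = TRUE` switches to
per-sample correlation. An edge requires both $|r| \ge 0.8$ and a
correlation-test $p < 0.05$ (both configurable; with 5 points the p-gate
effectively raises the threshold to $|r| \gtrsim 0.88$).

Node degree, local clustering coefficient
($2 \cdot \text{closed pairs}/(d(d-1))$, 0 when $d<2$), coreness (iterative
peeling) and connected components are attached to every node. Core genes are
the nodes attaining their component's maximum coreness, ranked by degree;
components below 3 nodes are reported but yield no core genes, since a
2-node subnetwork has trivial coreness 1.

### PPI overlap subnetwork

Symbol lists from different species conventions are joined after
uppercasing (an explicit mapping table can be supplied for true orthology
mapping — the package deliberately does not guess one). The overlap of the
differential genes with the literature list seeds the PPI subnetwork: seeds
plus first neighbours, then the induced subgraph. The induced reading (which
keeps neighbour–neighbour edges) is the default because published
subnetwork figures of this kind show such edges; `star = TRUE` restricts to
seed-incident edges. Hub nodes are those with within-subnetwork degree of at
least 11 ("degree above 10"); computing degree within the subnetwork rather
than the full PPI is a documented choice — the alternative is one
`igraph`-free line on the full edge table.

### qPCR validation

The 2^-ddCt rule with the reference gene measured in every well:
$\Delta Ct = Ct_{target} - Ct_{reference}$ per replicate, then
$\Delta\Delta Ct$ as the difference of condition means, then
$2^{-\Delta\Delta Ct}$ — means are taken on the $\Delta Ct$ scale before
exponentiation (the Livak convention), not as a mean of per-replicate folds.
Amplification efficiency is fixed at 2. The standard deviation shown on fold
bars comes from per-replicate treated folds computed against the control
mean $\Delta Ct$; this propagation convention is documented rather than
asserted as the only possible one. Direction concordance with the array is
the fraction of shared gene/timepoint pairs whose log fold changes agree in
sign.

## The synthetic-data generator

`simulate_timecourse()` emulates the structure of a normalized two-colour
bead-array recovery course: per-gene baseline log2 intensity
$\sim N(8, 1.5^2)$ (so values are log-normal on the intensity scale),
additive per-sample log2 noise (default sd 0.2), five timepoints at 0, 3, 7,
11, 21 days, four replicates per group. Planted differential genes follow
integer model profiles scaled by `effect_log2` (default 1). Choices worth
knowing:

* **Planted profiles come from the 50 selected model profiles**, not from
  all 624 candidates, so "assigned to its true profile" is well-posed when
  the clustering stage runs with default settings.
* **Profile concentration.** Non-module differential genes draw their
  profile from a pool of `n_active_profiles` (default 6). Real recovery
  courses concentrate in a handful of temporal patterns; spreading 100
  genes uniformly over 50 profiles would produce clusters of 2 genes that
  no permutation test should call significant.
* **Modules are carved out of the differential genes**; each module shares
  one reserved profile, and module profiles are constrained to pairwise
  $|r| < 0.5$ so different modules do not merge into one network component
  by construction.
* The generator is seed-deterministic throughout, and the annotation, PPI
  and Ct generators take their own seeds derived from the simulation seed.

What the generator does **not** emulate: probe-level effects, batch or
spatial artifacts, heavy-tailed noise, correlated null genes, and the
mouse/human symbol mess of real cross-database joins (its symbols are
synthetic). Recovery rates measured on this generator therefore say that the
pipeline's inference machinery is correct and well-calibrated — not that it
would achieve the same recall on hybridisation data.

## Numerical and design conventions

* Gene-symbol joins across lists are case-insensitive (uppercased) —
  mouse-cased array symbols meet human-cased PPI/literature symbols.
* Assignment and selection tie-breaks are deterministic (lowest profile id,
  lexicographic candidates, alphabetical gene order at equal degree).
* Correlation ties in greedy selection and profile assignment use a
  $10^{-12}$ tolerance so exact ties resolve identically across platforms.
* BH q-values come from the standard step-up implementation; Fisher tails
  from the hypergeometric distribution function. Both are verified against
  brute-force re-implementations in the test suite (step-up by definition;
  explicit sums of hypergeometric point masses).
* k-core peeling and the local clustering coefficient are implemented in
  the package and cross-checked against both brute-force oracles and
  independent graph-library results.
* Degenerate inputs (constant genes, empty networks, terms without
  background members, missing qPCR conditions) are either resolved by the
  documented conventions above or rejected with errors naming the offender.

## Problem sizes used by the tests and the acceptance script

Calibration and recovery experiments run at 500 genes (100 planted, one
30-gene module) over 20 seeds, null calibration at 500 genes x 20 seeds and
200 genes x 100 seeds for the profile null, and oracle checks on 100 random
graphs (n ≤ 50), 1,000 random 2x2 tables and 1,000 random p-vectors. These
sizes give Monte-Carlo errors well below the decision margins (e.g. the
planted-recovery thresholds of 90–95%) while keeping a full run in the
tens of seconds on a single core.

## Known limitations

* The exact thresholds of the motivating study (its array platform, its
  database snapshots, its unstated correlation cutoff) are not recoverable;
  the package exposes every such knob in `run_config()` instead of
  hard-coding one guess.
* The permutation expectation is exact only for 5-point courses; longer
  courses use sampled permutations.
* Under-representation, weighted (soft-threshold) co-expression networks,
  moderated t statistics and ontology-aware enrichment weighting are out of
  scope by design.

## A minimal worked run

```{r pipeline, eval = FALSE}
bundle <- simulate_study_inputs(sim_config(seed = 7), dir = "sim_inputs")
report <- run_pipeline(
  bundle$sim$expr, bundle$annotations$sets, bundle$annotations$dag,
  bundle$ppi$ppi, bundle$ppi$literature, ct = bundle$qpcr,
  config = run_config(seed = 7), out_dir = "results"
)
glance(report$differential)
tidy(report$stem) |> filter(significant)
report$core_genes
autoplot(report$network)
```
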