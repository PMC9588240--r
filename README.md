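# lineagetraj

Quantitative comparison of lineage trajectories in time-resolved bulk
RNA-seq.

When pluripotent cells are steered toward different fates and sampled at a
shared series of developmental stages in replicate, each lineage traces a
trajectory through expression space. `lineagetraj` is for developmental
biologists and computational groups who want to interrogate such designs
quantitatively: it measures how far each lineage travels and whether one
trajectory is significantly shorter, detects when a lineage reaches
transcriptional equilibrium, classifies per-gene temporal dynamics,
scores gene-set overrepresentation along stage transitions, nominates
candidate regulators with lineage-restricted dynamics, and extracts signed
co-expression modules — all validated end to end against a synthetic
four-lineage study generator with complete ground truth.

## The statistics at its core

* **Differential expression**: per-gene negative-binomial Wald tests
  (variance μ + αμ²) between successive stages within each lineage and
  between lineage pairs at matched stages, with median-of-ratios size
  factors s_j, trend-shrunken method-of-moments dispersions α_g, and
  within-contrast Benjamini–Hochberg adjustment; significance is
  padj ≤ 0.05 with no fold-change cutoff.
* **Trajectory geometry**: PCA of log2(TPM + 1) (genes centered), and stage
  9 → 13 displacement measured as Euclidean distances between all
  replicate pairs (9 for triplicates), identical over all retained PCs and
  in the full log-expression space; lineages compared with exact Wilcoxon
  rank-sum tests and between- vs within-type distances with a KS test.
* **Equilibrium**: the earliest stage from which every later transition
  changes fewer than θ = 100 genes.
* **Overrepresentation**: upper-tail hypergeometric P(X ≥ k) per transition
  with N the tested universe, K the set, n the significant genes, k the
  overlap.
* **Pattern modelling**: orthogonal-polynomial (degree ≤ 3) fits of
  log2(TPM + 1) on the minutes axis with empirical-Bayes moderated t
  statistics ((d₀s₀² + d s²)/(d₀ + d)); archetype classification
  (flat / monotone / transient), a monotone ≥ 25-fold decrease filter,
  30-TPM onset calling, and GRN-candidate nomination by differential
  linear + quadratic dynamics.
* **Networks**: signed adjacency ((1 + r)/2)^β, scale-free soft-threshold
  selection, topological overlap TOM_ij = (Σ_u a_iu a_uj + a_ij)/
  (min(k_i,k_j) + 1 − a_ij), static-cut module detection with a 30-gene
  floor and eigengene merging at height 0.25, and module–trait correlation.

Homeolog-aware preprocessing (summing `.L`/`.S` subgenome copies of
allotetraploid genomes) and a minimum raw count of 15 in any sample come
before everything else.

## Worked example

Simulate the default four-lineage study (2,000 genes, 6 stages, 3
replicates, seeded), preprocess, and ask the headline questions:

```r
library(lineagetraj)
library(dplyr)

sim   <- simulate_study(sim_config(seed = 1))
study <- merge_homeologs(filter_min_count(sim$study, 15))
study
#> <expression_study> 1964 genes x 72 samples
#>   lineages: epidermis, neural, endoderm, ventral_mesoderm
#>   stages:   9 < 10 < 10.5 < 11 < 12 < 13

scan <- run_de_scan(study, alpha = 0.05)
detect_equilibrium(de_count_profile(scan), theta = 100)
#> # A tibble: 4 x 3
#>   lineage          equilibrium_stage theta
#>   <chr>            <chr>             <dbl>
#> 1 endoderm         none                100
#> 2 epidermis        none                100
#> 3 neural           11                  100
#> 4 ventral_mesoderm none                100

pca   <- run_pca(study)
dists <- trajectory_distances(pca, "9", "13")
dists |> select(lineage, n_pairs, mean, sem)
#> # A tibble: 4 x 4
#>   lineage          n_pairs  mean    sem
#> 1 epidermis              9  61.2 0.0483
#> 2 neural                 9  42.6 0.0794
#> 3 endoderm               9  62.5 0.0728
#> 4 ventral_mesoderm       9  67.6 0.0843

distance_tests(dists, pca)$wilcoxon |>
  filter(lineage_a == "neural" | lineage_b == "neural")
#> # A tibble: 3 x 3
#>   lineage_a lineage_b                p
#> 1 epidermis neural           0.0000411
#> 2 neural    endoderm         0.0000411
#> 3 neural    ventral_mesoderm 0.0000411

length(monotonic_decrease_filter(summarize_replicates(study)))
#> [1] 40
```

Reading the output: the neural lineage reaches equilibrium at stage 11
(every later transition moves fewer than 100 genes) while the other three
keep changing through stage 13; its stage 9 → 13 displacement (42.6, SEM
over the 9 replicate pairs) is significantly shorter than every other
lineage's (exact Wilcoxon p = 4.1e-5, the smallest two-sided p attainable
with 9 + 9 observations); and the monotone ≥ 25-fold filter recovers
exactly the 40 genes designed as pluripotency-decay archetypes. The same
calls on real data replace the simulated input with
`load_study(counts.tsv, tpm.tsv, samples.csv, grid)`.

`run_pipeline(pipeline_config(...))` executes the whole chain —
preprocess, DE scan, trajectory, dynamics, patterns, networks — writing
every table plus a JSON manifest; identical config and seed give
byte-identical outputs.

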