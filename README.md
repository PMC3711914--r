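# divpart

Divergence partitioning and refugial-origin tests for clade-structured
sequence data.

`divpart` is for phylogeographers who have per-locus multiple sequence
alignments, a table mapping specimens to localities and mitochondrial
clades, and a biogeographic question: are the populations beyond the
classical glacial barriers (Pyrenees, Alps, Apennines, central Balkans)
postglacial colonists from southern refugia, or independent lineages that
survived glaciations in situ? The package implements the distance-based
statistical pipeline for that question:

* **Uncorrected p-distances** with pairwise deletion (`distance_matrix`),
  per-pair counts of jointly resolved sites, and group-mean summaries in
  both the clade-pair-mean and pooled-pair conventions.
* **Diversity statistics** per group — segregating sites *S*, nucleotide
  diversity π = 2/(N(N−1)) Σ<sub>i&lt;j</sub> d<sub>ij</sub>, haplotype
  number *h* and diversity Hd = N/(N−1)(1 − Σ p<sub>k</sub>²) — with
  **rarefaction** to the smallest compared sample size (mean over 100
  subsets drawn without replacement) so groups of unequal size are
  comparable (`standardized_diversity`, `diversity_report`).
* **AMOVA Φ<sub>ST</sub>** from squared p-distances with permutation
  significance (`amova_phist`, `fst_permutation_test`).
* **Permutation tests on the divergence partition**: whether the pooled
  between-clade mean distance D<sub>bc</sub> exceeds the within-clade mean
  D<sub>wc</sub> (`test_bc_vs_wc`), and, per northern locality *i*, whether
  its mean distance D<sub>i</sub> to a southern reference set sits at the
  between- or within-clade level (`northern_origin_test`,
  `run_origin_battery`, `classify_origin`). All tests use
  p = (exceedances + 1)/(n<sub>perm</sub> + 1), one-sided, ties counted.
* A **clade-structured simulator** with known ground truth
  (`simulate_dataset`, `scenario_suite`) covering panmixia, refugial
  structure at the study scale, and the two contrasting northern-locality
  histories (recent expansion from a southern source vs in-situ
  divergence).
* A **pipeline driver** (`run_pipeline`) that takes a YAML config (input
  FASTA/TSV files or a simulation block), writes TSV reports, and records
  a reproducibility manifest.

The package ships the study-system metadata
(`inst/extdata/podarcis_samples.tsv`: specimen → locality → clade, with
per-locus GenBank accessions, for the common wall lizard *Podarcis
muralis*) and the northern/southern locality classification
(`inst/extdata/regions.yaml`), so a full replication of the published
analysis only requires downloading the accession FASTAs.

## Worked example

Simulate a dataset in which a northern locality (code 99) harbours an
independently diverged lineage (ancestor divergence d = 0.03, within-clade
diversity θ = 0.005, 1284 bp — the scale of a combined two-fragment
mitochondrial dataset), then run the core analyses:

```r
library(divpart)

cfg <- sim_config(seed = 7, loci = c(mtdna = 1284L),
                  clades = data.frame(clade_id = c(1:4, 5L),
                                      locality_code = c(1:4, 99L), n = 6L),
                  d = 0.03, theta = 0.005,
                  scenario = "northern_in_situ", northern_locality = 99L)
ds <- simulate_dataset(cfg)
ds$alignments$mtdna
#> <locus_alignment> mtdna: 30 sequences x 1284 bp

D <- distance_matrix(ds$alignments$mtdna)
grouping <- setNames(ds$samples$clade_id, ds$samples$specimen_id)

fst_permutation_test(D, grouping, n_perm = 1000, seed = 1)
#> <amova_phist> Phi_ST = 0.9781 (5 groups, 30 sequences)
#>   variance among 0.000542732, within 1.21715e-05
#>   p = 0.000999 (1000 permutations, seed 1)

test_bc_vs_wc(D, grouping, n_perm = 1000, seed = 1)
#> <perm_test> D_bc - D_wc: observed 0.0288 (D_bc 0.0332, D_wc 0.0045)
#>   p = 0.000999 over 1000 permutations (seed 1)

sch <- sim_scheme(ds)
northern_origin_test(D, sch, 99,
                     southern_set = sch$contiguous$source_region$southern,
                     n_perm = 1000, seed = 1)
#> <origin_test> locality 99 vs 1 southern localities
#>   D_i = 0.0344 (D_bc 0.0332, D_wc 0.0045)
#>   p_bc = 0.7652, p_wc = 0.000999 (1000 permutations)
#>   -> in_situ
```

Reading the last result: the locality's mean distance to the adjacent
southern region (D_i = 0.034) is significantly above the within-clade
level (p_wc = 0.001) and indistinguishable from the between-clade level
(p_bc = 0.77) — the signature of a lineage that diverged in place rather
than a recent colonist. Rerunning with
`scenario = "northern_recent_expansion"` flips the verdict: D_i collapses
to the within-clade level and p_wc becomes non-significant.

The same analyses run end-to-end from a config file:

```r
run_pipeline("config.yaml", out_dir = "results/")
# -> diversity.tsv, distances.tsv, clade_distances.tsv, origin_tests.tsv,
#    manifest.json (config hash, input digests, seeds, package version)
```

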