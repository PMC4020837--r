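# strpop

Population-structure analysis for multi-allelic STR (microsatellite) panels.

`strpop` takes tabular diploid STR genotypes (one row per individual, a
population label, two repeat-number alleles per locus — e.g. the nine core
CODIS loci D3S1358, TH01, D5S818, D13S317, D7S820, CSF1PO, vWA, TPOX, FGA)
and carries them through the full classical population-genetics workflow
used in regional human-diversity studies:

- **Allele frequencies** by gene counting, with per-cell missing-data
  exclusion, plus exact tests of Hardy–Weinberg equilibrium (full
  enumeration of the Levene conditional distribution for small problems,
  Monte Carlo permutation of gene copies otherwise).
- **Diversity and forensic parameters**: unbiased gene diversity
  `h = n/(n−1)(1 − Σxᵢ²)`, matching probability `PM = Σ f_g²`, Brenner's
  power of exclusion `PE = h²(1 − 2hH²)`, panel-combined
  `PM = Π PMₗ` and `EPP = 1 − Π(1 − EPPₗ)`, and Nei's
  `G_ST = (H_T − H_S)/H_T`.
- **Genetic distance and trees**: Nei's
  `D_A = 1 − (1/L) Σ_loci Σ_alleles √(xₐyₐ)`, Saitou–Nei neighbor joining
  with deterministic tie-breaking, locus-bootstrap bipartition supports,
  Newick export.
- **Structure**: PCA of the locus-averaged covariance matrix of allele
  frequencies (closure-safe), and the Harpending–Ward R matrix
  `R_ij = (1/L′) Σ (p_i − p̄)(p_j − p̄)/(p̄(1 − p̄))`, whose diagonal `r_ii`
  measures each population's distance from the gene-frequency centroid and
  whose regression `E[H_i] = H_t(1 − r_ii)` diagnoses above/below-average
  external gene flow.
- **Geography and language**: haversine great-circle distance matrices,
  ordinal 0–4 linguistic dissimilarities from classification paths (with a
  reviewable, overridable pair coding), and Mantel / partial Mantel
  permutation tests decomposing genetic variance into geographic and
  linguistic components.
- **Synthetic data**: a multi-allelic Balding–Nichols simulator (Dirichlet
  drift with controllable F, optional admixture from an external source,
  optional spatially correlated drift for isolation-by-distance), so every
  stage is testable without access to restricted human data.
- Packaged fixtures for the 13-population Northwest-China study system
  (published pairwise D_A matrix, coordinates, linguistic affiliations,
  chromosome counts) and an end-to-end pipeline driver plus `strpop` CLI.

## Worked example

```r
library(strpop)

# Published 13-population D_A matrix + metadata
d    <- nwc_da_matrix()
meta <- nwc_population_meta()
meta <- meta[match(rownames(d), meta$name), ]

geo <- geographic_distances(meta)     # km, haversine
lan <- linguistic_distances(meta)     # ordinal 0-4

report_table4(list(
  "Dgen and Dgeo"                = mantel_test(d, geo, 9999, seed = 1),
  "Dgen and Dlan"                = mantel_test(d, lan, 9999, seed = 1),
  "Dgen and Dgeo, Dlan constant" = partial_mantel_test(d, geo, lan, 9999, seed = 1, controlled = "Dlan"),
  "Dgen and Dlan, Dgeo constant" = partial_mantel_test(d, lan, geo, 9999, seed = 1, controlled = "Dgeo")))
#>              matrices_compared correlation_coefficient p_value variance_explained
#> 1                Dgen and Dgeo                  0.6133  0.0003             0.3762
#> 2                Dgen and Dlan                  0.1507  0.1261             0.0227
#> 3 Dgen and Dgeo, Dlan constant                  0.6104  0.0005                 NA
#> 4 Dgen and Dlan, Dgeo constant                  0.1304  0.1519                 NA
```

Geography correlates strongly with the genetic distances (r = 0.61,
p ≈ 3e-4, 37.6 % of variance), and the correlation barely moves when
language is held constant; the language signal is weak and not significant.
Genetic differentiation in this system tracks geographic isolation far more
than linguistic barriers.

A fully synthetic run (no external data needed):

```r
cfg   <- sim_config(n_populations = 5, n_loci = 9, sample_sizes = 100,
                    drift_f = 0.05, seed = 42)
g     <- simulate_panel(cfg)           # genotype_table + generating truth
panel <- allele_frequencies(g)

combine_panel(locus_stats(g, hwe_reps = 2000, seed = 1))
#>   population n_loci mean_gene_diversity total_alleles combined_epp combined_pm
#> 1      Pop01      9              0.7554            71       0.9998   4.567e-10
#> 2      Pop02      9              0.7967            69       0.9998   4.982e-11
#> ...
gst(panel)
#> [1] 0.04739524        # recovers the generating F = 0.05

tree <- bootstrap_tree(panel, reps = 200, seed = 1)
write_newick(tree, "tree.nwk")
```

Per-population mean gene diversities ~0.73–0.80, ~70 alleles over 9 loci,
combined EPP > 0.999 and combined PM ~1e-9/-10 — the magnitudes typical of
real 9-locus CODIS panels — and `gst()` recovers the simulator's drift
parameter.

Pipeline and CLI:

```r
run_pipeline(list(da_matrix = "fixture", meta = "fixture",
                  out_dir = "results", n_permutations = 9999, seed = 1))
```

```sh
inst/cli/strpop simulate --config sim.yaml --seed 2 -o genotypes.csv
inst/cli/strpop tree --genotypes genotypes.csv --bootstrap 1000 --seed 4 -o tree.nwk
inst/cli/strpop mantel --gen da.csv --meta meta.csv --perms 9999 --seed 3 -o mantel.csv
```

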