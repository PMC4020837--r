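---
title: "Methods: STR population structure with strpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: STR population structure with strpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strpop)
```

This vignette is the package's own account of the statistical methods it
implements, the choices made where the methodology was genuinely open, and
what its tests do and do not establish.

## The data model

The raw input is a diploid genotype table: individuals × loci with two
allele labels per locus and a population label. Allele labels are opaque
text, never coerced to numbers — STR microvariants such as `"9.3"` must
survive round-trips — and ordered numerically-then-lexicographically for
deterministic output. A missing genotype is missing in both slots; a
half-missing call (one allele recorded) is rejected as a data error rather
than silently repaired, because it almost always indicates an export
problem and would bias gene counting by a single copy.

Allele frequencies are estimated by gene counting per (population, locus)
cell, excluding missing genotypes cell-wise. A cell with no data is
*excluded and logged*, never imputed. How missing data enter gene counting
is rarely stated in published tables; per-cell exclusion is the only choice
that keeps each cell's estimate a maximum-likelihood multinomial estimate
of that cell's frequencies.

## Diversity and forensic statistics

- Gene diversity uses the unbiased estimator `h = n/(n−1)(1 − Σxᵢ²)` with
  `n` the number of **gene copies** (2 × typed individuals). Whether `n`
  counts copies or individuals is often left implicit in the literature;
  copies is the standard convention for the unbiased estimator and is what
  this package uses throughout.
- Matching probability is `PM = Σ f_g²` over genotype classes. From
  genotype data, `f_g` are **observed** genotype proportions (the
  convention of forensic summary software); from frequency-only input they
  are HWE-expected proportions. The mode is recorded in the output
  (`pm_mode`), because the two can differ materially at casework scale.
- Power of exclusion uses Brenner's formula `PE = h²(1 − 2hH²)` on observed
  heterozygosity (expected heterozygosity in frequency-only mode).
- Panel combination: `PM = Π PMₗ`, `EPP = 1 − Π(1 − EPPₗ)`. Both are
  monotone in panel size, which the test suite checks as a property.
- `G_ST = (H_T − H_S)/H_T`: `H_S` and `H_T` are computed per locus
  (uncorrected `1 − Σx²` quantities, with equal or sample-size weights over
  populations), averaged across loci, and the ratio formed from the
  averages (the classical multi-locus convention). Averaging per-locus
  ratios instead is exposed as an option since both appear in practice.
  A panel monomorphic everywhere has `H_T = 0` and `G_ST` undefined: this
  is an error, not 0/0 → `NaN`.

## Hardy–Weinberg exact testing

Conditional on allele counts, genotype tables follow the Levene
distribution; the exact p-value is the total probability of tables no more
probable than the one observed. Full enumeration (recursion over
heterozygote counts; homozygotes are then forced) is used for ≤ 3 alleles
and ≤ 200 gene copies; beyond that the test permutes the gene-copy vector
and re-pairs it (Monte Carlo, default 100 000 replicates, seed recorded).
A tolerance of `1e-9` on the probability comparison absorbs floating-point
ties, which are common because many distinct tables share a probability.
Monomorphic cells return p = 1. The two modes are tested against each
other and against an independently coded two-allele oracle.

## Distances and trees

Nei's `D_A = 1 − (1/L) Σ_l Σ_a √(xₐyₐ)` is used as the genetic distance; it
resolves closely related populations well. It is symmetric with zero
self-distance but **not** a metric (the triangle inequality can fail), so
no test asserts metricity.

Neighbor joining follows the Saitou–Nei Q-criterion with the standard
branch-length and update formulas. Two determinism choices:

- **Tie-breaking**: when several pairs minimize Q within `1e-12`, the pair
  whose (cluster-minimum-leaf) labels sort lexicographically smallest is
  joined. NJ is otherwise order-sensitive under ties, which would make
  bootstrap supports irreproducible.
- **Negative branch lengths** are retained in memory (they carry
  information about non-additivity) but clamped to zero on Newick export,
  with a warning — the display convention of mainstream tree software.

Bootstrap supports resample **loci** with replacement (the natural unit for
frequency data; 9 loci is the default panel size), rebuild the D_A matrix
and NJ tree per replicate, and annotate each internal edge of the full-data
tree with the percentage of replicates containing the same bipartition.
Supports are mapped onto the point-estimate tree, not a consensus tree.
Bipartitions are keyed canonically (the side not containing the
alphabetically first taxon), making supports invariant to population input
order, which is tested.

## PCA on the averaged covariance matrix

Allele frequencies are compositional: within each locus they sum to one, so
a naive population × (locus, allele) matrix is rank-deficient ("closure").
The package therefore centers each locus's population × allele sub-matrix
by column means, forms its population × population covariance contribution,
and averages contributions over loci before eigendecomposition. No allele
is dropped; centering alone removes the constraint direction. Scores are
eigenvectors scaled by root eigenvalues; each component is oriented so its
largest-magnitude entry is positive (a pure sign convention, for
reproducible plots). A panel of identical populations has zero total
variance and is reported as degenerate with an explicit flag rather than
returning 0/0 ratios.

## The R matrix and gene-flow regression

The R matrix is the scaled covariance of population allele frequencies
about their weighted centroid,

```
R_ij = (1/L') Σ_{loci, alleles} (p_i − p̄)(p_j − p̄) / (p̄ (1 − p̄)),
```

where `p̄` is the weighted centroid frequency and `L'` counts the
(locus, allele) terms with `0 < p̄ < 1` (fixed alleles carry no information
and are skipped; if everything is fixed, that is an error). The published
formula images in the motivating literature are frequently illegible; this
is the canonical scaled-covariance definition, consistent with the model's
named quantities `r_ii`, `H_i`, `H_t`. Default weights are proportional to
mean gene-copy counts (sample size as the available proxy for population
size), with an equal-weights option.

Two algebraic identities hold by construction and are tested: weighted row
sums of R are zero (centering), and R is positive semidefinite (it is a sum
of weighted outer products).

`H_i` is the population's average heterozygosity — unbiased expected
heterozygosity averaged over loci — and `H_t` the weighted mean of the
`H_i`. The theoretical regression `E[H_i] = H_t(1 − r_ii)` classifies
populations by residual sign: above the line → more-than-average external
gene flow; below → relative isolation. Because it is unclear in practice
whether published regression plots draw the theoretical line or a fitted
one, both the theoretical line and an OLS fit of `H_i` on `r_ii` are
reported.

Note one subtlety: the weighted residual sum is not exactly zero; the exact
identity is `Σ w_i resid_i = H_t · Σ w_i r_ii`, which approaches zero only
as overall differentiation does. The test suite asserts the exact identity.

## Geographic and linguistic distances; Mantel tests

Geographic distances are haversine great-circle distances on a sphere of
radius 6371.0 km. Mantel correlations are invariant to the radius (any
positive rescaling), which is tested.

Linguistic distances use the ordinal 0–4 scheme: different phyla 4,
branches 3, families 2, languages 1, same language 0, applied to each
population's classification path. The packaged metadata carries
(phylum, family, language) paths, under which the default coding is:
same population or shared language 0 (the three Sinitic-speaking
populations score 0 among themselves); different languages within Turkic or
within Mongolian 1; Turkic vs Mongolian 2; Sino-Tibetan vs Altaic 4. Where
any such coding is debatable (it is: sub-branch granularity within Turkic
and Mongolic, and whether distinct Sinitic-speaking ethnic groups share a
"language", are judgment calls), every pair is overridable, and the full
pair coding is emitted as a reviewable table (`attr(x, "coding")`, written
to CSV by the pipeline).

The Mantel statistic is the Pearson correlation over the `n(n−1)/2`
unordered off-diagonal pairs (the diagonal zeros would inflate
correlation). Inference permutes one matrix's rows/columns simultaneously;
`p = (hits + 1)/(B + 1)` with default `B = 9999`, giving resolution 1e-4.
The default is one-tailed positive — isolation-by-distance hypotheses are
directional — with a two-tailed option; published P values rarely state
sidedness, so the default is documented rather than guessed. The partial
Mantel statistic is the standard three-correlation partial formula;
permutation re-permutes the first matrix and recomputes the full partial
statistic, with a residual-permutation variant exposed as an option.
Constant matrices yield an explicit degenerate result (simple test) or a
degeneracy error (partial, when a controlling correlation is ±1) — never a
silent number.

## The synthetic-data generator

`simulate_panel()` is a multi-allelic Balding–Nichols generator: per locus,
population frequencies are drawn from `Dirichlet(ancestral · (1−F)/F)`, so
`E[p] = ancestral` and `Var(p_a) = F·p̄ₐ(1−p̄ₐ)` — `F` is a Wright-style
fixation index with closed-form control. Genotypes are two independent
copies per individual (within-population HWE, which the suite verifies at
the nominal type-I rate). Optional admixture mixes a fraction `m` of an
external source population's frequencies into a recipient. Defaults mirror
the motivating study's scale: 13 populations, 9 loci, 6–12 alleles per
locus, and the study's per-population chromosome counts; ancestral
frequencies default to symmetric Dirichlet(1) draws, a reasonable stand-in
for the flat-ish, many-allele frequency profiles of forensic STRs.

`simulate_ibd_panel()` adds isolation by distance: log-scale perturbations
`p ∝ ancestral · exp(z)` where `z` has an independent component (sd
`σ = √(2F)`) plus a spatially correlated Gaussian field (sd `ibd_slope·σ`,
correlation `exp(−d/d_scale)` with `d_scale` the median pairwise
great-circle distance). Far-apart pairs share less of the field, so
differentiation increases with distance; `ibd_slope = 0` reduces to
independent drift with no geographic signal. The generating parameters are
attached to every simulated table (`attr(x, "truth")`) for recovery tests.

What the generator does **not** emulate: stepwise mutation (allele
identity-in-state vs identity-by-descent), linkage, inbreeding or
population-size dynamics, genotyping error, and null alleles. A green
recovery test therefore establishes that the pipeline's estimators recover
the drift/structure parameters of this idealized model — not that they are
robust to real-data pathologies.

Two measurement points worth knowing:

- **Sampling-noise floor of D_A**: with `k` alleles and `n` gene copies per
  cell, estimated frequencies give `E[D_A] ≈ (k−1)/(4n)` per locus between
  *identical* populations (≈ 0.01–0.02 at study-scale sample sizes). The
  no-drift limit test therefore evaluates D_A on the generator's realized
  frequencies, where drift alone is measured.
- **Specificity of the partial Mantel**: with 13 populations the null
  spread of the partial correlation is ≈ 0.12, so the *mean absolute*
  null correlation sits near 0.1 by construction; "centered on zero" is
  tested on the signed mean, which is the quantity that detects a
  systematic artifact.

## Reproduction limits (the honest-red criterion)

Three published quantities of the motivating study cannot be reproduced at
desk scale, and the package does not pretend otherwise:

1. **Mantel coefficients.** Computing from the *published* distance matrix
   and coordinates gives r(gen, geo) = 0.6133 versus the published 0.4769,
   r(gen, lan) = 0.1507 versus 0.2100, and partial r(gen, geo | lan) =
   0.6104 versus 0.4516. No reading we tried — rank correlation,
   log/Euclidean distances, coordinate swaps, leave-one-out, alternative
   linguistic codings including a finer four-level one — closes the gap,
   and the published table is internally inconsistent (its "variance
   explained" 0.2158 ≠ 0.4769²). The published analysis evidently used
   unpublished full-precision inputs. The acceptance test asserts the
   published values at their stated tolerances and fails; the
   implementation itself is validated against an exhaustive-permutation
   oracle and `vegan::mantel`. Notably the qualitative conclusion —
   geography dominates, language adds little — is *stronger* in our
   reproduction.
2. **Per-population diversity/EPP/PM, overall G_ST, PCA variance ratios,
   bootstrap percentages** require the unpublished genotype/frequency
   tables. These are covered by property-based acceptance instead: oracle
   equivalence of each estimator, parameter recovery (G_ST within 0.015 of
   a generating F = 0.05 over 50 replicates), nominal Mantel type-I error
   over 200 null replicates, and ≥ 90 % detection of a designated
   migrant-receiving population by R-matrix residual sign over 100
   replicates.
3. The published distance table itself contains a suspect entry (the
   Uzbek–Han_XA distance 0.0188 exactly duplicates Uzbek–Kazakh, against
   the geographic and historical grain); it is shipped verbatim.

## Runtime scaling of stochastic tests

To keep the default suite fast on one CPU, some sweeps run at reduced
scale with unchanged nominal levels: the HWE calibration runs 150
(population, locus) cells at 1000 Monte-Carlo replicates; the
enumeration-vs-Monte-Carlo sweep covers all two-allele tables at n = 8; the
IBD power check runs 10 replicates in the module suite and the full 50 in
the acceptance suite. Binomial acceptance bounds are always computed for
the size actually run.

## Known limitations

- No mutation-model-aware distances (e.g. stepwise-weighted), no
  F_ST-based or chord distances; D_A only.
- No admixture-proportion estimation; the R-matrix regression diagnoses
  relative gene flow, not sources or proportions.
- Geographic distances ignore terrain and travel routes.
- The HWE enumeration bound (3 alleles, 200 copies) is conservative;
  beyond it the Monte Carlo p has resolution `1/(reps + 1)`.
- Linguistic coding is inherently judgment-laden; the package's default is
  documented and overridable rather than authoritative.
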