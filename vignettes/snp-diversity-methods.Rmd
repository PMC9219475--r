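---
title: "Methods: SNP-array population diversity in snppop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SNP-array population diversity in snppop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snppop)
```

`snppop` implements the standard population-diversity workup for
multi-breed SNP-array data: QC filtering, per-population heterozygosity
and F-statistics, pairwise differentiation with a gene-flow transform,
allele-sharing distances with a neighbour-joining tree, and genotype PCA.
This vignette records the models, the estimator choices, the numerical
conventions, and the places where the design was genuinely open.

## Data model

Genotypes are diploid, biallelic, autosomal SNP calls stored as
alternate-allele dosage c ∈ {0, 1, 2} with `NA` for missing, individuals
in rows and markers in columns, plus a population label per individual
(taken from the PED family-ID column — breed codes map naturally onto
it). The dosage coding makes the allele-sharing kernel a one-line
computation and keeps everything invariant, by construction or by test,
under swapping which allele is counted (c → 2 − c).

PED/MAP parsing is whitespace-delimited and tolerant of repeated
separators; `"0"` is a missing allele and a half-missing genotype is
treated as fully missing. Per marker, the second (counted) allele is the
lexicographically larger of the observed states. One consequence: a
marker observed monomorphic carries no information about its second
allele, so it is read back as fixed for the counted allele. Binary
BED/BIM/FAM, VCF, and chip strand harmonization are out of scope.

## QC cascade

Stage order, applied sequentially with recomputation after individual
removal:

1. individuals with call rate < `indiv_call_rate` (default 0.95);
2. markers with call rate < `snp_call_rate_per_pop` (default 0.75) in
   *any* population;
3. markers with pooled MAF < `maf_min` (default 0.01);
4. markers failing the Hardy–Weinberg exact test at
   p < `hwe_p_min` (default 0.001).

All comparisons are strict, and a marker is attributed to the first stage
that removes it, so stage counts are disjoint and sum to the total. The
ordering of the individual filter relative to the marker filters is not
dictated by the underlying statistics; we follow the order in which the
thresholds are conventionally quoted and make every threshold
configurable. A second individual call-rate knob
(`indiv_call_rate_prefilter`, e.g. 0.90) exists because array pipelines
often quote both a "minimal genotyping call rate" and a stricter animal
filter without specifying their interaction; it is disabled by default.

HWE and SNP call rate are evaluated **per population** by default
(removal on failure in any one), because pooling breeds mixes allele
frequencies and produces spurious heterozygote deficits (Wahlund effect);
MAF is evaluated pooled, since rarity in the combined panel is what makes
a marker uninformative. Both scopes are switchable (`hwe_scope`).

The exact test uses Levene's conditional distribution of the heterozygote
count given the allele counts, computed in log space over all counts of
matching parity and renormalized (the suite asserts the distribution sums
to 1 and that the test matches a plain-factorial enumeration oracle to
1e−12 for every genotype triple with total ≤ 30). The two-sided p-value
follows the "probability ≤ observed" summation convention, with a
1 + 1e−12 relative guard on the comparison so ties are not lost to
floating-point noise.

## Diversity and F-statistics

Per locus with n genotyped individuals and allele frequency p̂ in a
population: observed heterozygosity is the heterozygote fraction and
expected heterozygosity is Nei's unbiased estimator
(2n/(2n−1))·2p̂(1−p̂). `Ho` and `He` are unweighted means over loci with
n ≥ 2 in that population; each population uses its own usable locus set,
matching the per-locus definition (a global-set alternative would count
monomorphic loci as zero and systematically deflate comparisons between
populations with different missingness).

Fis and Fst are the Weir–Cockerham (1984) variance-component estimators.
For one population, f = 1 − Σc / Σ(b + c) with per-locus
c = h/2 and b = n/(n−1)·(p̂(1−p̂) − (2n−1)/(4n)·h). For a pair of
populations, θ̂ = Σa / Σ(a + b + c) with the standard sample-size-weighted
components. Multi-locus combination is by ratio of sums — the W&C
recommendation — rather than averaging per-locus ratios, which is
unstable at low MAF. Loci monomorphic across both populations are
excluded; negative θ̂ (estimator noise around zero differentiation) is
reported as-is, never clamped. A second, naive scalar transcription of
the same formulas serves as a test oracle (agreement to 1e−10).

Gene flow is Wright's island-model equilibrium migrant number:

**Nm = (1 − Fst) / (4 · Fst)**

The formula is sometimes typeset ambiguously as "1 − Fst/4 Fst"; the
parenthesization used here is the standard island-model result and is the
only reading consistent with published Fst/Nm matrices this package's
acceptance values are drawn from (0.044 → 5.432, 0.028 → 8.679 at
3-decimal rounding). Nm is undefined (NA) for Fst ≤ 0, and is strictly
decreasing on (0, 1]. Note that an Nm computed from a *rounded* Fst can
differ visibly from one computed from the unrounded estimate — at
Fst ≈ 0.003 a rounding change in the fourth decimal moves Nm by tens of
migrants — so tables report Nm from full-precision Fst.

## Allele-sharing distances and neighbour joining

Per locus the proportion of alleles alike in state between dosages ci and
cj is s = 1 − |ci − cj|/2 (identical genotypes 1, het vs hom 0.5,
opposite homozygotes 0); x̄ij averages s over the loci genotyped in
*both* individuals, and ASD = 1 − x̄ij. Pairwise-complete loci were
chosen over a globally complete locus set because per-pair averaging uses
all available calls; the cost is that different pairs average over
different (recorded) locus counts, guarded by a minimum-overlap threshold
(default 100 loci — below that, sharing proportions are too noisy to
rank pairs, and the function fails loudly naming the pair).

Neighbour joining is implemented from scratch: Studier–Keppler criterion
Q(i,j) = (m−2)d(i,j) − Ri − Rj, standard branch lengths, distance update
d(u,k) = (d(i,k) + d(j,k) − d(i,j))/2. Determinism: exact ties in Q are
resolved by the lowest (row, column) pair. Negative computed branch
lengths (possible on non-additive input) are clamped to zero with the
deficit transferred to the sister branch, preserving the path length
between the joined nodes. The root is the arbitrary trifurcation left by
the final join; Newick output carries branch lengths at 6 significant
digits and quotes labels that need it. On additive matrices NJ is
consistent, and the suite verifies exact recovery (topology and path
lengths to 1e−9) on random 8-leaf trees.

## PCA

Patterson normalization: center each locus by 2p̂ and scale by
√(p̂(1−p̂)), the drift-scale weighting used by the classical ancestry-PCA
software; plain covariance PCA is available behind `scaling = "none"`.
Missing calls are set to the post-centering mean (zero) — the standard
treatment, but a documented bias source at high missingness since it
shrinks incomplete samples toward the origin. Monomorphic loci are
dropped. The decomposition is of K = XX′/L; reported percent variance is
each eigenvalue over the sum of positive eigenvalues. Sign per component
is fixed by forcing the largest-magnitude coordinate positive, so runs
are reproducible. Outlier-removal iterations, Tracy–Widom significance
tests and sample projection are not implemented.

## The simulator: a stated world

The generator exists so every estimator can be tested against known
truth. It is the Balding–Nichols model: ancestral frequencies uniform on
`ancestral_maf_range` (default [0.05, 0.5], mimicking an ascertained SNP
chip's depletion of rare variants); per-population frequencies
Beta(p(1−F)/F, (1−p)(1−F)/F), mean p and variance F·p(1−p), so the
per-population parameter F is exactly the quantity Weir–Cockerham θ
targets — that is what makes parameter-recovery acceptance possible.
Genotypes are drawn with probability `fis` of copying a single
Bernoulli(q) allele (identical by descent) and otherwise two independent
draws; missingness is applied independently per call at rate
1 − (1 − rate_snp)(1 − rate_indiv), i.e. a call must survive both a
SNP-level and an individual-level mask.

Defaults describe a four-breed panel echoing a small village-sheep
study: sizes 11/12/12/12, 5000 loci, one strongly drifted population
(F = 0.15) against three weakly differentiated ones (F = 0.05, 0.02,
0.02), low inbreeding (fis 0.02–0.03) and array-typical missingness
(2% SNP-level, 1% individual-level). 5000 loci is a deliberate
desk-scale stand-in for a 50K chip; estimator standard errors scale as
1/√L, so conclusions about correctness transfer.

What the simulator does *not* emulate — and therefore what a green test
does not establish: linkage disequilibrium (loci are independent, so
real-data effective marker counts are lower), ascertainment bias beyond
the uniform MAF window, mutation, selection, pedigree structure within
populations, and non-random (e.g. chemistry-batch) missingness. A single
seeded RNG stream is threaded through all draws in documented order
(ancestral freqs, then per population: frequencies, alleles, IBD mask,
missing mask), so a fixed seed gives bit-identical datasets.

## Determinism and degenerate inputs

Every stochastic entry point takes or derives from one integer seed;
`run_full_analysis` reruns are byte-identical. Degenerate inputs fail
loudly rather than silently: all-zero genotype counts in the HWE test, a
population with all loci monomorphic (Fis undefined), a pair with zero
total variance (Fst undefined), pairs below the ASD overlap minimum,
non-symmetric or negative distance matrices, and QC runs that remove
every sample or marker (the error carries the stage and counts).

## Known limitations

* Ho > He patterns with *positive* Fis, as sometimes printed in published
  diversity tables, cannot be produced by the estimators implemented here
  (W&C f and 1 − Ho/He are both negative under heterozygote excess);
  such tables likely reflect a different or modified estimator and are
  not reproduction targets.
* No bootstrap/jackknife confidence intervals over loci, no hierarchical
  F-statistics, no admixture-style model-based clustering.
* The PED reader loses the allele identity of markers observed
  monomorphic (inherent to the format).
* NJ is O(n³) in pure R; fine for hundreds of individuals, not for
  biobank-scale panels.
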