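---
title: "Estimating the heritability of symbiont community diversity"
author: "divherit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the heritability of symbiont community diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divherit)
```

## The scientific problem

Corals host communities of dinoflagellate endosymbionts (*Symbiodinium*)
whose composition affects host physiology and stress tolerance. In brooding
corals, larvae can inherit symbionts from the dam (vertical transmission)
and acquire additional types from the environment (horizontal acquisition).
Two questions drive the analysis this package implements:

* how different are larval symbiont communities from adult ones, and
* how much of the variation among larval communities is under host genetic
  control?

The second question requires expressing a whole community as a single
quantitative host phenotype, and then applying the standard machinery of
quantitative genetics — an animal model over a pedigree of related larvae —
to that phenotype.

## The diversity trait

For one sample, let $p$ be the vector of relative OTU abundances and $Z$
the matrix of pairwise sequence similarities between OTU representatives,
$Z_{ij} = 1 - d_{ij}$ with $d_{ij}$ the raw (uncorrected) proportion of
differing sites, computed with pairwise deletion of `N` and gap positions
(`ape::dist.dna`, model `"raw"`). The similarity-sensitive diversity of
order $q$ is

$$ {}^q D^Z(p) \;=\; \Big( \sum_{i : p_i > 0} p_i \,(Zp)_i^{\,q-1} \Big)^{1/(1-q)},
\qquad (Zp)_i = \sum_j Z_{ij} p_j, $$

with the limit $\prod_i (Zp)_i^{-p_i}$ at $q = 1$ and $1/\max_i (Zp)_i$ at
$q = \infty$. $(Zp)_i$ is the *ordinariness* of type $i$: how much of the
community looks like it. The measure simultaneously reflects richness,
evenness and how genetically distinct the co-occurring types are: at
$Z = I$ it reduces to the classical Hill numbers, and a community of
near-identical sequences counts as barely more than one effective type
regardless of its OTU count.

Choices made here:

* **Order of the exported trait.** The scalar trait handed to the
  heritability model is the profile value at `trait_q = 1` (the effective
  number weighting types exactly by abundance, the exponential-Shannon
  analogue). No single order is canonical; the full profile over a `q_grid`
  is computed so any order can be analysed, and 1 is the default because it
  neither privileges rare types (as $q = 0$ does) nor only the dominants
  (as $q \to \infty$).
* **Abundances.** $p$ is built from median-of-ratios-normalized counts
  renormalized to proportions, so the trait matches the
  variance-normalized abundances used by the distance-based analyses.
* **Unequal sequence lengths** are compared over their leading overlap
  (minimum 80% of the longer sequence, else an error); no alignment is
  attempted internally, so real data should provide pre-aligned or
  equal-length representatives. Conventions $0^0 = 1$ and $0\log 0 = 0$
  apply at support boundaries.

## Relatedness

Two constructions of the relatedness matrix $A$ are provided:

* **Sib-class convention** (`relatedness_matrix_sibclass`, the default): pairwise
  coefficients read off the parentage classes — 0.25 for half sibs, 0.5
  for full sibs, 1.0 for larvae produced by selfing of the same colony
  (clone-like), 0 otherwise, with unit diagonal. This matrix is not
  guaranteed positive semi-definite, so it is projected by eigenvalue
  clipping at $10^{-10}$ before use as a covariance.
* **Tabular method** (`relatedness_tabular`): the textbook recursive
  numerator relationship matrix, with inbreeding accumulating on the
  diagonal (a selfed offspring of a non-inbred parent has $a_{jj} = 1.5$).
  PSD by construction; validated in the test suite against a gene-dropping
  Monte-Carlo identity-by-descent oracle.

The two agree on non-inbred sib pairs and diverge under selfing (the
tabular matrix has inflated diagonals and assigns 0.5, not 0.25, between a
selfed larva and an outcrossed maternal sib). Both are exposed because the
discrete convention is what the coefficients of the study system denote,
while the tabular matrix is the standard quantitative-genetic object.

## The animal model

`fit_animal_model` Gibbs-samples

$$ y = 1\mu + a + (m) + e, \quad a \sim N(0, \sigma^2_a A), \quad
   m \sim N(0, \sigma^2_m I_{\text{dams}}), \quad e \sim N(0, \sigma^2_e I), $$

with a flat prior on $\mu$ and inverse-gamma(0.001, 0.001) priors on all
variance components — the conventional "non-informative" inverse-gamma
reading, exposed as `prior_shape`/`prior_scale` because parametrizations
differ across packages. Heritability is derived per retained sample as
$h^2 = \sigma^2_a / (\sigma^2_a + \sigma^2_e [+ \sigma^2_m])$.

Implementation notes:

* The sampler works in the eigenbasis of $A$: with $A = U D U^\top$ and
  $b = U^\top a$, every full conditional is diagonal and one sweep costs
  $O(n)$ (plus $O(n \cdot n_\text{dams})$ with the maternal effect). The
  1.5-million-iteration protocol (thinning 50, 10% burn-in) is therefore
  feasible on one core; the desk default is $2 \times 10^4$ iterations
  with the same thinning and burn-in fractions.
* Marginally negative eigenvalues of $A$ are floored at $10^{-8}$;
  genuinely indefinite matrices are rejected with a pointer to
  `nearest_psd`.
* Posterior summaries: mean, SD, mode from a Gaussian-kernel density
  (Silverman bandwidth, 512-point grid, restricted to $[0, 1]$ for $h^2$),
  and a 95% highest-posterior-density interval (shortest window). The mode
  is reported because skewed $h^2$ posteriors make mean and mode differ
  substantially.
* A single seeded chain is the default; `mcmc_diagnostics` supplies lag
  autocorrelations and Geyer's initial-monotone-sequence effective sample
  size.
* **DIC** uses the deviance conditional on the random effects,
  $D(\theta) = -2 \log N(y;\, 1\mu + a + m,\, \sigma^2_e I)$, with
  $p_D = \bar D - D(\bar\theta)$; DIC variants differ and this is a
  convention choice. `compare_dic` declares "no improvement" when the
  added maternal effect fails to lower DIC by 2 units.

### What the validation shows — and its limits

The test suite validates parameter recovery on a 300-larva pedigree of 50
selfed sibships of 6. Under the sib-class convention selfed sibs are
clone-like blocks (pairwise coefficient 1.0), so within-brood contrasts
carry no additive variance and pin $\sigma^2_e$, while between-brood
variation pins $\sigma^2_a$: the most informative family design available
at this size, and the right bench for asking whether the sampler finds
truth when the data permit it. Posterior modes land within $\pm 0.15$ of
true $h^2 \in \{0.2, 0.5, 0.8\}$ in at least 80% of seeded replicates.

Two caveats discovered while building that bench are worth recording.
First, with weakly informative family structures (few effective families,
or coefficients that make $A$ close to a scaled identity), the $h^2$
posterior is extremely diffuse at $n = 300$ and its mode is not a reliable
point estimate — replicate modes swing to the boundaries. Second, the
inverse-gamma(0.001, 0.001) prior diverges at zero variance; when the
likelihood cannot firmly exclude $\sigma^2_e \approx 0$ (or
$\sigma^2_a \approx 0$), that spike pulls the posterior mode of $h^2$
toward 1 (or 0). Both behaviours are properties of the model-plus-prior,
not sampler defects: the Gibbs output was checked against an exact
two-dimensional grid integration of the marginal posterior during
development. Practical reading: interior modes with tight HPD intervals
can be trusted; boundary-hugging modes signal an under-informative design.

The maternal-effect DIC comparison is validated on broods combining a
selfed block with a full-sib block by an outside sire, so the maternal
effect (shared by both blocks) is separable from the additive structure,
with a weak additive background ($\sigma^2_a = 0.1$) against
$\sigma^2_m = \sigma^2_e = 1$. The conditional-deviance DIC has limited
power for random-effect selection when the additive effect can mimic brood
means, which is why the power scenario uses a stiff additive component.

## Normalization and differential abundance

Size factors follow the median-of-ratios estimator: $s_j =
\text{median}_i\, k_{ij} / g_i$ over reference OTUs with positive
geometric mean $g_i$ across all samples. Sparse tables where no OTU is
ubiquitous can opt into a pseudo-reference (geometric means over positive
counts only); the strict estimator is the default and is cross-checked in
the tests against `DESeq2::estimateSizeFactorsForMatrix`.

Differential abundance fits, per OTU, a negative-binomial GLM with the
size factors as offsets and a two-level group coefficient tested by Wald
$z$; dispersion is estimated per OTU by method of moments on normalized
counts, floored at $10^{-8}$. This is a deliberate simplification of the
reference tooling — no empirical-Bayes dispersion shrinkage, no
independent filtering, no outlier replacement — because the package's
guarantees are stated as simulation calibration (type-I error within
[0.025, 0.075] at nominal 0.05; fold-change recovery; permutation
uniformity), not as replication of another tool's output. Multi-group
contrasts are run as all-pairs tests pooled into a single
Benjamini–Hochberg family; all-zero OTUs are excluded from the family
size.

## Community statistics

Bray–Curtis distances, PERMANOVA and the dispersion test delegate to
`vegan` (`vegdist`, `adonis2`, `betadisper`/`permutest`) behind thin
validated wrappers; permutation schemes are free (no strata), seeded, and
use the $+1/+1$ p-value convention including the observed statistic. PCoA
is computed directly from the eigen-decomposition of the Gower-centred
matrix so that negative eigenvalues — routine for Bray–Curtis — are
retained and reported rather than corrected away; "imaginary" axes are
returned separately and the dispersion test's squared distances subtract
their contribution (floored at zero). Presence for the prevalence network
and the stage partition is defined on raw counts ($> 0$), not normalized
values, so that presence does not depend on size factors; network edges
keep OTUs at brood prevalence $\ge$ 0.5 by default and OTUs at 100%
prevalence in every brood are flagged as core (the convention under which
such edges are hidden in network figures). Spatial models regress
square-root-transformed abundance on centred coordinates and their
interaction; Spearman screens use average-rank ties with t-approximation
p-values.

## The synthetic-data generator

`simulate_dataset` emulates the statistical structure of the target study
rather than any particular dataset:

* **Mating design.** 9 dams among 45 candidate sire colonies, 60 larvae in
  roughly balanced broods, exactly 4 selfed larvae, full sibs guaranteed;
  an option reproduces the study's unbalanced reality (two single-larva
  broods). A lone colony can only self.
* **Sequences.** 161 OTU representatives in 5 clade-like clusters
  (ancestors mutated at a high between-cluster rate, leaves at a low
  within-cluster rate), giving within-cluster p-distances smaller than
  between-cluster ones in expectation.
* **Adults.** Uniform coordinates on a 16 m × 40 m plot;
  Dirichlet-multinomial communities over the adult pool (shared +
  adult-only types) with a stable dominant head — the same few types
  dominate every colony, over a colony-variable background tail — and a
  logistic spatial tilt for designated OTUs; lognormal library sizes so
  that depth normalization genuinely matters; five size-class bins.
* **Larvae.** Expected composition $v \cdot \text{maternal} + (1 - v)
  \cdot \text{environment}$. The maternal component is the dam's realized
  community restricted to transmissible types (adult-only types are
  defined as non-transmissible, otherwise they could not remain absent
  from larvae) and sharpened by squaring the proportions — a one-parameter
  winnowing kernel encoding preferential transmission of the dominant
  symbionts. The environmental pool is a single Dirichlet draw shared by
  all larvae and includes the larva-only types. The study does not
  quantify the vertical fraction; `v = 0.9` encodes predominantly vertical
  transmission and is deliberately conservative about horizontal input.
* **Heritability channel.** Breeding values $a \sim N(0, \sigma^2_a A)$
  (convention-consistent, drawn through an eigen-factorization) and an iid
  jitter enter the larva's Dirichlet concentration $c_l = \exp(\gamma_0 +
  a_l + e_l)$: larvae with higher genetic merit draw more even communities,
  so the scalar diversity trait is heritable with latent-scale
  $h^2 = \sigma^2_a/(\sigma^2_a + \sigma^2_e)$, recorded in the truth
  channel. The map from latent scale to realized trait is monotone but
  non-linear, which is why end-to-end checks are qualitative (e.g.
  $\sigma^2_a = 0$ must yield low estimated $h^2$) while quantitative
  recovery is validated on the direct trait channel
  (`simulate_trait_direct`).
* **Observed-table semantics.** An OTU table only ever contains detected
  OTUs, so any stage-pool OTU that the multinomial draw missed everywhere
  is seeded with a single read in one reachable sample; OTUs that are
  structurally absent (larva-only types under $v = 1$) are never seeded.

What the generator does *not* emulate: sequencing error and chimeras,
intragenomic ITS2 copy variation, indels or alignment artefacts,
phylogenetic (tree-based) structure beyond the cluster design, overdispersed
taxon-specific depth biases, and any selection acting on larvae. Passing
tests on synthetic data therefore demonstrate correctness of the
statistical machinery under the stated generative model, not robustness to
those real-data complications.

## Problem sizes used in the validation suite

The suite runs the heritability recovery at $2 \times 10^4$ iterations per
fit on the 300-larva benchmarks (20 replicates per scenario), the
PERMANOVA type-I calibration at 400 null replicates with 99 permutations,
and the differential-abundance calibrations at 150–200 OTUs per scenario —
sizes chosen so the full suite completes in a few minutes on one core
while keeping every Monte-Carlo margin far from its decision threshold.
The study-scale MCMC protocol ($1.5 \times 10^6$ iterations) is available
by passing `iterations = 1.5e6`.

## Known limitations

* The discrete sib-class matrix ignores inbreeding of selfed
  individuals (unit diagonal); the tabular alternative models it. Neither
  is asserted to be "the" matrix used by any particular historical
  analysis.
* The NB Wald test without dispersion shrinkage is anti-conservative for
  very low counts; its calibration is demonstrated at moderate depths.
* The conditional-deviance DIC is a weak instrument for random-effect
  selection when effects can substitute for one another; treat small
  differences as noise (the package's own verdict threshold is 2 units).
* `leinster_cobbold` is exact but dense: cost is $O(S^2)$ per sample in
  the number of OTUs on the support.
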