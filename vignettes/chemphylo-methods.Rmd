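---
title: "Methods: pollen sterol chemodiversity and phylogenetic comparative analysis"
author: "chemphylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pollen sterol chemodiversity and phylogenetic comparative analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemphylo)
```

`chemphylo` analyses a species × compound table of pollen phytosterol
amounts along three axes: the structure of the compositional profiles
themselves, their phylogenetic signal, and their association with
pollinator guilds and the abiotic environment. This vignette explains the
models and procedures the package implements, the assumptions they make,
the tunable parameters with their defaults, what the synthetic-data
generator does and does not emulate, and the numerical choices made in
places where the design was genuinely open.

## 1. Profile metrics

The raw datum is an absolute amount $x_{sc} \ge 0$ of compound $c$ in the
pollen of species $s$, in µg per mg pollen. Within-species proportions are
$p_{sc} = x_{sc} / \sum_c x_{sc}$; a species with an all-zero row is
rejected (it carries no compositional information, and Bray–Curtis is
undefined between two empty profiles).

**Shannon equitability.** Chemodiversity is summarised as
$H_s = -\sum_{p_{sc}>0} p_{sc} \ln p_{sc} / \ln S_s$, where $S_s$ is the
number of compounds *present in that species*. Using the profile's own
richness as the log base makes $H$ a unitless equitability in $[0,1]$: 1
when all present compounds are equally abundant, 0 for a one-compound
profile. We define $H=0$ at $S=1$ (the log-base-1 limit) because zero
diversity is the unambiguous continuation. An alternative convention uses
a fixed, study-wide $S$ (e.g. all 25 assayed compounds); that is available
via `shannonEquitability(p, globalS =)`, but the per-profile base is the
default because it is what makes a near-monomorphic profile score exactly 0
and a uniform profile exactly 1 regardless of panel size.

**Presence and averages.** Commonness of a compound is the fraction of
species whose amount exceeds a threshold (default 0; settable because
chromatography zeros are censored values, not exact zeros — a detection
floor such as 0.01 µg/mg is a reasonable alternative). Relative abundance
is the mean of $p_{sc}$ over species and sums to 1 over compounds.
Richness summaries use the sample standard deviation ($n-1$).

**Biosynthetic group sums.** Each compound carries two class labels that
mirror the sterol biosynthesis pathway: the C-24 side-chain alkylation
state (C0 none, C1 methyl, C2 ethyl) and the ring-B double-bond position
(Δ0 stanols, Δ5, Δ7, Δ8). Per-species sums of proportions within each
class partition the composition twice: the C sums and the Δ sums each
total 1 when every compound is classified, and an unclassified compound is
an error rather than a silent drop.

**Factor analysis.** Co-variation among compounds is summarised by
principal-component extraction: eigen-decomposition of the Pearson
correlation matrix of the proportions, retention of factors with
eigenvalue strictly greater than 1 (so proportion of variance is
eigenvalue / number of compounds), and Kaiser-normalized varimax rotation
of the retained loadings (via `stats::varimax`). Rotation preserves each
compound's communality, which the tests assert to 1e-8. Maximum-likelihood
factor extraction is a known alternative; principal-component extraction
is used because the retention criterion and variance proportions are
defined on correlation-matrix eigenvalues. Constant compounds make the
correlation undefined and are an error at this level; `runPipeline()`
drops them with a warning first, since a compound below detection in every
species is expected in censored survey data.

## 2. Distance-based analyses

**Bray–Curtis.** $d(x,y)=\sum_c |x_c-y_c| / \sum_c (x_c+y_c) \in [0,1]$,
computed by default on the *absolute* amounts so that species differing
mainly in total sterol content are far apart even with similar
compositional shape; `proportions = TRUE` switches to pure shape.

**ANOSIM.** All $M = n(n-1)/2$ distances are ranked once (midranks for
ties) and $R = (\bar r_{between} - \bar r_{within}) / (M/2)$, bounded in
$[-1,1]$ and exactly 0 when all off-diagonal distances are tied.
Significance comes from permuting group labels, one-sided on $R \ge
R_{obs}$, with the add-one convention $p = (1 + \#\{R^\ast \ge R\}) /
(1 + n_{perm})$ so $p$ is never 0 and the test is exact under
exchangeability. Groups below a minimum size (default 2) are dropped with
a message — a singleton guild contributes no within-group ranks — mirroring
the practice of excluding single-representative pollinator guilds.

**MRM.** Multiple regression on distance matrices unfolds the lower
triangles and fits an ordinary additive linear model (intercept +
predictor distances). Significance permutes the *response matrix's* rows
and columns simultaneously, which preserves its internal dependence
structure, and recomputes coefficients and $r^2$: coefficients are tested
two-sided on $|b|$, $r^2$ one-sided, both with the add-one convention.
Collinear predictors abort with the condition number. With a single
predictor the coefficients equal the simple regression of one unfolded
triangle on the other, which the tests verify against `lm`.

**NMDS.** The 2-D ordination minimises Kruskal stress-1,
$\sqrt{\sum (\hat d_{ij} - \delta_{ij})^2 / \sum \hat d_{ij}^2}$, where
$\hat d$ are configuration distances and $\delta$ the disparities from a
pool-adjacent-violators isotonic regression on the rank order of the
input dissimilarities (ties handled by Kruskal's primary approach: within
a tie block the fit is not constrained). Configurations update by the
Guttman transform, which decreases raw stress at each step; because the
*normalized* stress can fluctuate at convergence, a start stops as soon as
an update fails to improve it, guaranteeing a non-increasing stress path.
Defaults: 8 starts (the first seeded from classical metric scaling, which
already solves exactly embeddable inputs; the rest random), 500-iteration
cap, relative tolerance 1e-8, best start returned with its stress and
seed.

## 3. Phylogenetic comparative methods

All signal statistics are built on the Brownian-motion covariance of a
rooted tree with branch lengths: $C_{ij}$ is the shared root-to-MRCA path
length, the diagonal holds root-to-tip depths, and patristic distances
follow from $d_{ij} = C_{ii}+C_{jj}-2C_{ij}$. Trees are `ape::phylo`
objects; polytomies are resolved randomly (seeded) into zero-length
bifurcations, and a configurable epsilon (`bmCov(epsilon =)`, in units of
tree depth) can pad zero branches so $C$ stays invertible — 1e-8 is used
internally where inversion is required, small enough to leave inference
untouched. Undated topologies get Grafen lengths: node height
$((\text{clade size}-1)/(n-1))^\rho$, giving an ultrametric tree of depth
1 for any $\rho > 0$ (default 1).

**Pagel's λ** multiplies the off-diagonal of $C$ by $\lambda$; the
likelihood is profiled over the GLS root $\hat a = (1'V^{-1}z)/(1'V^{-1}1)$
and rate $\hat\sigma^2 = (z-\hat a)'V^{-1}(z-\hat a)/n$, and maximized
over $\lambda \in [0,1]$ by bounded scalar optimization (tolerance 1e-8,
endpoints checked explicitly because the optimum is frequently at a
bound). The search is capped at 1 by convention — on ultrametric trees
slightly larger values remain positive-definite, and the bound is a
parameter for users who want them. On ultrametric trees
$V(\lambda) = \lambda C + (1-\lambda)T I$ shares $C$'s eigenvectors, so
one eigen-decomposition makes each likelihood evaluation $O(n)$; the
generic Cholesky path handles non-ultrametric input. Two p-values are
offered, since randomization wording and likelihood-ratio practice both
circulate for this statistic: the default likelihood-ratio test against
$\lambda = 0$ ($\chi^2_1$), and an optional tip-shuffling randomization
(re-estimating $\lambda$ per permutation) with the add-one rule. A star
tree makes the likelihood constant in $\lambda$; the estimate is returned
as `NA` with `identifiable = FALSE` rather than an arbitrary number.

**Blomberg's K** is the observed-to-expected ratio of variance
partitioning: $K = (MSE_0/MSE)/E$ with $MSE_0$ the raw mean squared
deviation from the GLS root, $MSE$ the phylogenetically corrected one, and
$E = (\mathrm{tr}\,C - n/(1'C^{-1}1))/(n-1)$ its Brownian expectation.
$K = 1$ under Brownian motion, exactly 1 on a star tree for any trait, and
invariant to affine trait transforms. The p-value shuffles trait values
across tips (default 999 permutations, add-one, one-sided on
$K \ge K_{obs}$).

**Independent contrasts and contrast regression.** Felsenstein's pruning
produces $n-1$ standardized contrasts that are i.i.d. $N(0,\sigma^2)$
under Brownian motion; $\sum u^2/(n-1)$ is the (REML-type) rate estimate
used wherever a rate is needed (e.g. to scale the phylogenetic-ANOVA
simulations). Trait–trait association across species is the through-origin
OLS of one contrast set on the other — slope $\sum xy / \sum x^2$, t-test
on $m-1$ residual degrees of freedom for $m$ contrasts, matching
`lm(y ~ x - 1)`. The tests verify the algebraic identity that this slope
equals the GLS slope of the tip data under $C$, by direct matrix
inversion, to 1e-8 on random instances.

**Phylogenetic ANOVA.** The observed statistic is the ordinary one-way
$F$; its null distribution is generated by simulating Brownian traits on
the tree at the empirically estimated rate and recomputing $F$ with the
same labels (1000 simulations by default, add-one p). Pairwise post-hoc
pooled-variance t statistics are compared two-sided to their own simulated
nulls and Holm-corrected via `p.adjust`. On a star tree the simulated
traits are i.i.d., and the tests confirm the simulated $F$ follows
$F(k-1, n-k)$.

## 4. Occurrence cleaning and niche quantification

The cleaning chain applies, in a fixed order: drop missing coordinates;
drop lat = lon = 0; drop lat = lon; drop records before 1950 (missing
years kept); drop provenance-flagged records (fossil, centroid, sea,
cultivated — flags are expected as boolean columns, since deriving them
requires gazetteers outside this package's scope); drop coordinate
uncertainty > 20 km (missing kept); drop exact species+coordinate
duplicates; thin to one record per 10 × 10 arc-minute cell per species
(cell index $\lfloor 6 \cdot \text{coord} \rfloor$, half-open, first record
in input order kept — deterministic by construction). The order is fixed
because per-filter counts are order-dependent; the chain is idempotent and
the counts always sum to input minus output, both asserted in tests.

Environmental layers are plain-text ESRI-ASCII grids (nearest-cell
lookup, nodata-aware), avoiding heavyweight geospatial dependencies; the
environmental space is a correlation-matrix PCA (variables standardized —
they are on incommensurable scales, so covariance PCA would let one
variable dominate), with the loading sign convention that each vector's
largest-magnitude element is positive. The first three axes are retained
by default. Niche position is the arithmetic mean of a species' points on
those axes — the simplest reading of "mean position of the shape"; a
volume-weighted shape centroid would differ for strongly asymmetric
clouds, and the mean-of-points was chosen for transparency.

**Niche breadth** is the volume of the three-dimensional alpha shape of
the species' occurrence points in PC space at $\alpha = 2$: the union of
Delaunay tetrahedra whose circumsphere radius is at most $\alpha$. At
$\alpha = \infty$ this is the convex-hull volume (asserted against a
brute-force facet-enumeration oracle); as $\alpha \to 0$ it vanishes; it
is monotone non-decreasing in $\alpha$. At least five distinct,
non-coplanar points are required; species below that are reported with an
explicit reason and an `NA` breadth, never a fabricated volume.

The tetrahedralization is built in-package (no computational-geometry
dependency is assumed): a randomized-incremental Bowyer–Watson
construction carrying one symbolic vertex at infinity, with circumsphere
conflicts for finite cells and outward-facet visibility conflicts for
infinite cells. Inputs are deterministically joggled (starting at 1e-9 of
the cloud's extent and escalating to 1e-6/1e-4 only if the result fails an
empty-sphere and face-manifold validation, as happens for exactly
degenerate inputs such as grids or cospherical shells), while volumes and
circumradii are always evaluated on the unperturbed coordinates — so
well-posed clouds lose no accuracy and degenerate ones still triangulate.
One caveat inherited from the definition itself: alpha-complex conventions
differ between implementations (circumradius filtering versus regular
triangulations), so absolute breadths at intermediate $\alpha$ are
comparable within this package, not across packages; the hull limit and
monotonicity are implementation-independent and are what the tests pin
down.

## 5. The synthetic-data generator

The generator exists so that every stage of the pipeline can be exercised,
calibrated and power-checked without any external data. It emulates the
statistical structure of a ~122-species, 25-compound pollen sterol survey
with phylogenetic covariance, guild labels and occurrence records:

* `simYuleTree(n, birthRate, seed)` — pure-birth trees, simulated forward
  from the root split (two lineages at time zero, waiting times
  exponential in the lineage count), hence always rooted, binary and
  ultrametric. The tests check the closed-form expected depth
  $\sum_{k=2}^{n} 1/(kb)$.
* `simBMTraits(tree, sigma2, lambdaTrue, root, seed)` — multivariate-normal
  draws with covariance $\sigma^2 V(\lambda)$ via Cholesky; the tests
  check elementwise covariance recovery and the i.i.d. limit at
  $\lambda = 0$.
* `simProfiles(...)` — a logistic-normal composition: each compound gets a
  latent Brownian trait (rate `sigma2Phylo = 1.5` per unit depth, signal
  `lambdaTrue = 1`) around a compound baseline (sd `baselineSD = 1.5`,
  creating dominant versus rare compounds) plus i.i.d. tip noise
  (`sigmaEnv = 0.5`); a softmax across compounds yields proportions, so
  per-compound proportions inherit phylogenetic covariance — which is why
  a softmax link was chosen over a Dirichlet, whose draws would be
  conditionally independent given the concentration. Total content is
  lognormal (meanlog 1, sdlog 0.8, i.e. a median of ~2.7 µg/mg with a
  realistic right tail), optionally Brownian-structured (the default,
  since total content itself can carry signal). Amounts below a detection
  limit (default 0.01 µg/mg, a plausible chromatography quantification
  floor) are censored to zero and the detected amounts re-closed to the
  species total, so profiles contain genuine absences and richness,
  commonness and presence thresholds are non-trivial.
* `simGuilds(...)` — balanced guild labels; `delta = 0` yields labels
  exchangeable with respect to the profiles (the null used for
  calibration), `delta > 0` shifts chosen compounds' latent traits in one
  group (the alternative used for power checks).
* `simOccurrences(...)` — clean records, one per 10-arcmin cell, plus
  planted violations of each cleaning filter in known numbers, with the
  ground-truth survivor count returned for end-to-end verification.
* `canonicalFixtures()` — the hand-derived instances used throughout the
  tests: the balanced four-tip tree with $K = 1.8$ exactly, the
  ((A,B),C) Grafen tree, distance sets with ANOSIM $R = 1$ and $R = 0$
  exactly, the $3/7$ Bray–Curtis pair, the unit-cube corners (alpha-shape
  volume 1 at $\alpha = 2$), and the eight-record cleaning table with one
  survivor.

What the generator does *not* emulate: chromatography noise, retention
times or spectra; non-random taxon sampling; correlated compound baselines
along real biosynthetic pathways; spatial autocorrelation of occurrence
records beyond the planted cell structure; and real environmental layers.
Passing tests therefore demonstrate that the estimators are correct and
calibrated under their stated models — not that any particular empirical
dataset satisfies those models.

## 6. Reproducibility conventions, problem sizes, and limitations

Every stochastic function requires a seed and records it (with the
iteration count) in its result; `runPipeline()` derives per-stage
substreams from one master seed via a fixed integer hash, so stages can be
re-run independently, and writes a manifest with the package version,
parameters and MD5 hashes of all inputs. Permutation p-values always use
the add-one convention. Matrix solves go through Cholesky with a tiny
jitter fallback and fail loudly past condition 1e12.

The test suite exercises the estimators at sizes chosen to make
Monte-Carlo checks sharp yet quick on a single CPU: λ recovery uses 200
replicates on 200-tip trees at planted λ ∈ {0, 0.5, 1} (tolerance ±0.1 on
the mean), mean-K calibration uses 500 Brownian replicates on a 100-tip
Yule tree (band [0.9, 1.1]), and the type-I calibration of
ANOSIM/MRM/phylogenetic-ANOVA/K-permutation uses 500 null datasets with
99 permutations each, so a calibrated test rejects at exactly 5% and the
observed rate is judged against the binomial 95% band. The acceptance
script runs the full pipeline at the survey's own dimensions (122 species,
25 compounds).

Known limitations: λ estimation is bounded to [0,1] by default; the
phylogenetic ANOVA assumes a common Brownian rate across groups; the MRM
permutation scheme tests the association between matrices, not causal
structure; clouds that are numerically coplanar are rejected rather than
assigned a near-zero breadth; and the cleaning chain trusts the provenance
flags it is given rather than deriving them from gazetteers.
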