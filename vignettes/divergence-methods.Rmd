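---
title: "Models and methods for the divergence-continuum analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for the divergence-continuum analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

reefdiverge reconstructs how closely related, often sympatric, coral taxa
diverged: whether gene flow continued during divergence, how much of the
genome resists it, how long ago populations split, and whether taxa sort
along environmental gradients. The motivating system is the *Stylophora
pistillata* species complex on the Great Barrier Reef — a nominal species
that genomic data resolve into several taxa spread along a continuum from
weakly differentiated populations (F~ST~ below 0.02) to well-separated
species (F~ST~ above 0.5). This vignette documents the models, the numerical
choices, and what the synthetic-data validation does and does not establish.

## The divergence models

A pair of populations of relative sizes $\nu_1, \nu_2$ (in units of the
ancestral size $N_{ref}$) splits from a common ancestor $T$ time units ago
(one unit = $2N_{ref}$ generations). Symmetric migration is scaled as
$M = 2N_{ref}m$, with $m$ the migrant fraction per generation. Five
histories are supported:

* **SI** — strict isolation: no gene flow since the split.
* **IM** — isolation with migration: constant symmetric flow $M$.
* **IM2M** — IM with two migration classes: a proportion $Q$ of loci
  exchanges migrants at a reduced rate $M_e \le M$, the complement at $M$.
  This captures genomic semi-permeability: loci linked to barriers resist
  introgression.
* **SC** — secondary contact: isolation from the split until $T_{phase}$
  before present, migration $M$ since.
* **AM** — ancient migration: migration $M$ from the split until
  $T_{phase}$ before present, isolation since. (With this clock convention
  AM reduces to IM as $T_{phase} \to 0$ and to SI as $T_{phase} \to T$.)

Inference works on the folded joint allele-frequency spectrum (JAFS): the
table of SNP counts indexed by minor-allele counts in the two populations.
Folding is exact for genotype data without an outgroup; spectra are built
on arbitrary ref/alt orientation and folded afterwards. Sites with missing
genotypes contribute through hypergeometric projection to fixed haploid
sample sizes; sites with fewer called alleles than the projection are
dropped and tallied.

## The expected-spectrum engine

`expected_jafs()` integrates the two-population diffusion approximation of
the joint allele-frequency density $\phi(x, y)$: drift with variance
$x(1-x)/\nu_1$ per axis, migration advection $M(y-x)$, influx of new
mutations at the low-frequency corner of each axis, and the ancestral
equilibrium density $\theta/x$ placed on the diagonal at the split. The
solver uses implicit tridiagonal sweeps per direction (operator splitting)
on a boundary-crowded (Chebyshev-extrema) grid; spectra are evaluated on a
sequence of grids (default 60, 70, 80 points) and Richardson-extrapolated
to zero spacing, with the time step tied to the grid so temporal error
extrapolates away with spatial error.

Two numerical choices matter and are easy to get wrong:

* The advective flux is discretised in $\psi = V\phi$ with
  Scharfetter–Gummel weights. On the neutral profile $\phi \sim \theta/x$,
  $\psi \propto (1-x)$ is smooth, so the advective divergence vanishes
  identically there; interpolating $\phi$ itself instead produces a
  grid-independent spurious drain of low-frequency variants whenever
  migration is non-zero.
* Mass absorbed at the frequency boundaries (lost or fixed variants)
  accumulates at the boundary nodes. Its advective exchange is gated to
  inward velocities only: migration may reintroduce a locally extinct
  variant, but the absorbed pile must never be advected against its own
  boundary, where its (large) density would drain the neighbouring live
  cells.

The engine's independent oracle is the structured-coalescent simulator
(`expected_jafs_mc()`), which averages exact per-genealogy branch-length
spectra — a Rao-Blackwellised Monte-Carlo estimate. The two routes agree
cell-for-cell within Monte-Carlo error (mean |z| below 1 at $10^5$
replicate genealogies), and both match msprime, which we used as an
additional cross-check during development.

## Fitting, model choice and uncertainty

`fit_divergence()` maximises a Poisson composite likelihood over unmasked
spectrum cells, profiling the scale $\hat\theta = \sum d / \sum m$
analytically. Optimisation runs multi-round perturbed restarts (factors
$2^{u}$, $u \sim U(-fold, fold)$, by default folds 3, 2, 1 with 30 runs
each) around the incumbent best, each followed by Nelder–Mead in
log-parameter space with bound clipping; the coarse search engine is
re-evaluated with the fine extrapolated engine for the reported likelihood.
AIC counts the profiled $\theta$ among the free parameters so all models
are penalised consistently. Composite-likelihood ratio tests are rescaled
in the Godambe style from bootstrap spectra (RAD tags resampled with
replacement, preserving within-tag linkage), with boundary-mixture nulls
when the nested model sits on a bound; Fisher-information standard
deviations come from a central-difference Hessian in log-parameter space
(relative step $10^{-3}$).

Parameter identifiability deserves emphasis. With gene flow, the folded
spectrum constrains parameters only weakly at realistic RAD-scale data:
the profile likelihood along the ridge $(c\nu_1, c\nu_2, cT, M/c)$ is
nearly flat, broken only by the ancestral-epoch signal, and local optima
walk that ridge even when started at the truth.
`identifiable_params()` screens any design by the expected Fisher
information of the noise-free spectrum. Its information unit matters: SNPs
on one RAD tag share a single genealogy, so the composite likelihood's
independent unit is the tag (the same unit the bootstrap resamples), and
counting SNPs individually overstates precision — the measured estimator
spread under IM matches the tag-level screen, not the per-SNP one. At the
package's reference scale (2,000 tags, ~5,300 SNPs), strict-isolation
parameters are identified to ~9% expected relative SD, while no IM or
IM2M parameter reaches the 25% level formally (IM2M's sizes and $Q$
nonetheless recover to ~7–15% median error in practice).
`recovery_study()` verifies that identifiable parameters are recovered
(median relative error across seeded replicates below 25%) and that the
generating model wins on AIC. The same weak identifiability under gene
flow should be kept in mind when interpreting fitted divergence times
from real data of this size.

Singleton and doubleton cells are masked by default (`mask_low_counts()`),
mirroring the standard guard against sequencing-error artefacts in
RAD-seq; the diagonal doubleton (1,1) is included in the mask by default
because total minor-allele count is the error-relevant quantity, with a
switch to exclude it. The synthetic recovery studies fit the unmasked
spectrum: simulated genotypes carry no sequencing error, and at small
projection sizes the masked cells carry most of the information that
separates the $(\nu, T)$ scaling ridge.

## Unit conversions

With $\theta$ from the fit and the effective sequence length
$L = SNP_{fit} \times (tags \times tag\ length) / SNP_{original}$, the
conversions are $N_{ref} = \theta / (4\mu L)$ individuals,
$\nu_k^{ind} = \nu_k N_{ref}$, $m = M / (2N_{ref})$ per generation,
$T^{years} = T \cdot 2 N_{ref} \cdot T_{gen}$, and migrant numbers
$M_{21} = m\nu_1$, $M_{12} = m\nu_2$ per generation. Defaults are
$\mu = 1.2\times10^{-8}$ per base per generation (an Acroporid coral
estimate) and $T_{gen} = 3$ years (young-reproducing brooding corals);
both are acknowledged approximations and are carried in the output.
Reporting rounds to two significant figures, the convention of published
demographic tables; internal values keep full precision. Several cells of
the published worked-example table are internally inconsistent with
$M = m\nu$ at printed precision (the migrant fraction was evidently
rounded upstream); the package reproduces the consistent cells exactly
and documents the rest.

## The synthetic-data generator

`simulate_pair()` draws one exact structured-coalescent genealogy per RAD
tag (no recombination within tags — tags are the linkage unit), drops
infinite-sites mutations at rate $\theta_{tag}/2$ per unit branch length,
and pairs haplotypes into diploids. Defaults emulate the study conditions:
tag length 110 bp; 2,000 tags with $\theta_{tag} = 0.4$ at ten diploids per
population yield roughly 5,300 SNPs, matching the scale of the real
filtered dataset (5,332 SNPs); scenario magnitudes
($\nu_1 = 1.5, \nu_2 = 1.2, T = 1.2, M = 2.5, M_e = 0.1, Q = 0.25$) follow
the published intraspecific fits with the heterogeneity contrast at the
detectable end of the published range. `inject_missing_and_clones()` adds
the artefacts the filters must remove; `simulate_env()` draws spatially
autocorrelated Gaussian environmental fields (exponential covariance,
default range 0.3 on the unit square) and tilts allele frequencies at a
configurable subset of SNPs, with the default single-variable effect (0.5
per environmental SD at 80 of ~750 response SNPs) calibrated so the
partial-RDA adjusted R² lands near the published 12%.

What passing tests on this generator do *not* show: real ddRAD data carry
sequencing error, allele dropout, depth-dependent genotype quality and
within-tag recombination histories, none of which are simulated; spatial
coordinates are planar and uniform; and environmental fields are Gaussian.
The validation demonstrates correctness of the estimators and inference
machinery under the assumed model, not robustness to those artefacts.

## Filtering

`filter_pipeline()` applies, in order: stage-1 site filters (biallelic;
per-genotype depth masking to missing outside 5–100 reads when depths are
present; minor allele count ≥ 3 recomputed from the individuals present;
≤ 50% missing per site), individual removal above 70% missing (strict
inequality), clone removal at ≥ 99% genotype identity over co-called sites
keeping the least-missing member of each clonal group, stage-2 site
filters (≤ 5% missing; minor allele frequency ≥ 0.01), and VIF-based
linkage pruning (windows of 50 SNPs shifted by 5; greedy removal of the
highest-VIF site, recomputing after each removal, until all VIFs ≤ 2).
Because the referenced pipelines do not state whether allele counts are
computed before or after individual removal, counts are recomputed at
every stage and each stage's removals are tallied.

## Divergence statistics

`wc_fst()` implements the Weir–Cockerham variance components for diploids
($a$, $b$, $c$ per site, observed heterozygosity in $c$), with the
genome-wide estimate as the ratio of sums and negative per-locus values
retained. `dxy_windows()` counts between-population allele differences per
site — invariant sites included — in 1,000 bp windows tiling each tag, and
`dxy_genomewide()` takes the comparison-weighted ratio of sums rather than
the mean of window values. `pair_distances()` computes squared Euclidean
dosage distances over co-called sites, rescaled by total/co-called site
count; `distance_gap_peaks()` fits a Gaussian kernel density (Silverman
bandwidth) and counts modes separated by "barcode gaps" — minima below 0.1
of the smaller adjacent mode — so minor density wiggles do not count as
evidence of sympatric taxa. `pca_kmeans_assign()` mean-imputes, takes
principal components and K-means-clusters the leading axes under a fixed
seed.

## Niche partitioning

The genotype–environment analysis follows the standard constrained-
ordination chain, with vegan doing the ordination arithmetic: complete-case
allele frequencies (the response keeps both allele columns so rows have
constant sums), Hellinger transformation, environmental variables centred,
standardised and screened for collinearity (|r| ≥ 0.7), spatial
conditioning by distance-based Moran eigenvector maps (truncation at the
longest minimum-spanning-tree edge, distances beyond it replaced by four
times the truncation, positive-eigenvalue vectors retained; `n_mem = 3`
mirrors the published choice, with all positive vectors available),
permutation tests with $p = (exceedances + 1)/(permutations + 1)$, forward
selection under the double stopping rule (candidate p-value and the
full-model adjusted-R² cap, applied after accepting the significant
candidate), and adjusted-R² variance partitioning into pure-environment,
pure-space, shared and unexplained fractions, which is additive to the
joint model's adjusted R² by construction. R² follows vegan's convention
(constrained variance over total variance, Peres-Neto adjustment under
conditioning). When a known effect is recovered under spatial conditioning,
the comparison variable is residualised on the conditioning space first —
the conditioned ordination cannot, by construction, retain the spatial
component of the driver.

## Problem sizes used by the validation suite

The acceptance checks run at: $10^5$ replicate genealogies for the
engine-oracle comparison (10 + 10 haploid samples); ten seeded replicates
per generating history at 2,000 tags (~5,300 SNPs) for parameter recovery;
twenty panmictic null reefs for the F~ST~ envelope; five mixed and five
null reefs at 800 tags for sympatry detection; ten replicates at 50
individuals and ~750 response SNPs for the niche-effect recovery; and 200
small null replicates for the permutation-test size. These sizes were
chosen to match the study's data volume where it is known (SNP counts,
RDA response size, adjusted R²) and to keep every Monte-Carlo bound
comfortably away from its threshold elsewhere.

## Known limitations

* No recombination within tags and free recombination between them; real
  RAD loci violate both in small ways.
* The diffusion engine shares the usual boundary approximations of
  diffusion-based spectrum solvers; accuracy was verified for the
  parameter magnitudes of the published fits ($M \le 20$, $T \le 10$).
* $T$ (and anything scaled with it) is weakly identified under gene flow
  at RAD-scale data; report its Fisher-information or bootstrap
  uncertainty, not the point estimate alone.
* The LRT's Godambe rescaling uses the bootstrap score covariance of the
  full model's extra parameters at the constrained optimum; with very few
  bootstrap replicates the adjustment itself is noisy.
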