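# reefdiverge

Population-genomic analysis of divergence continua in corals (and other
sympatric taxon complexes genotyped by RAD-seq). The package covers the
full chain from genotypes to interpreted demography:

- **Synthetic data**: an exact structured-coalescent generator of RAD-tag
  genotypes under five divergence histories, plus missingness/clone
  artefacts and spatially structured environmental covariates
  (`sim_scenario()`, `simulate_pair()`, `inject_missing_and_clones()`,
  `simulate_env()`).
- **Filtering**: VCF I/O and the standard post-assembly filters — biallelic
  sites, minor allele count, per-genotype depth, missingness, clone removal
  at 99% genotype identity, and VIF-based linkage pruning
  (`filter_pipeline()`).
- **Divergence statistics**: Weir–Cockerham F_ST (global and per locus),
  windowed D_XY over all sites, pairwise genetic distances with
  barcode-gap multi-peak detection, PCA + K-means taxon assignment.
- **Demographic inference**: folded joint allele-frequency spectra with
  hypergeometric projection (`build_jafs()`), a diffusion-approximation
  engine for expected spectra under SI / IM / IM2M / SC / AM histories,
  composite-likelihood fitting with multi-round perturbed optimisation
  (`fit_divergence()`), AIC comparison, Godambe-adjusted likelihood-ratio
  tests, Fisher-information and bootstrap uncertainties.
- **Unit conversion**: scaled parameters to individuals, years and
  migrants per generation (`convert_params()`, `gene_flow_rates()`).
- **Niche partitioning**: Hellinger-transformed genotype matrices, dbMEM
  spatial conditioning, partial RDA with permutation tests, forward
  selection and variance partitioning (`partial_rda()` and friends, on top
  of vegan).

## The model at the core

A population pair of relative sizes (nu1, nu2) splits from an ancestor of
size N_ref at scaled time T (units of 2 N_ref generations) and exchanges
symmetric migrants at scaled rate M = 2 N_ref m; under the heterogeneous
model IM2M a proportion Q of loci migrates at a reduced rate M_e. The
expected folded joint allele-frequency spectrum under a parameter set is
computed by numerical diffusion approximation and fitted to the observed
spectrum by Poisson composite likelihood with the scale theta profiled
analytically; theta then anchors the conversion to demographic units via
N_ref = theta / (4 mu L).

## Worked example

Simulate an isolation-with-migration pair, fit two models, and convert the
winner to demographic units:

```r
library(reefdiverge)

sc  <- sim_scenario("IM", nu1 = 1.5, nu2 = 1.2, T_total = 1.2, M = 2.5,
                    n1 = 5, n2 = 5, n_tags = 2000, theta_per_tag = 0.4,
                    seed = 11)
dat <- simulate_pair(sc)
sp  <- build_jafs(dat$genotypes, c("pop1", "pop2"), mask_low = FALSE)

fit_si <- fit_divergence(sp, "SI", rounds = c(2, 1), runs = 3, seed = 1)
fit_im <- fit_divergence(sp, "IM", rounds = c(2, 1), runs = 3, seed = 1)
compare_models(fit_si, fit_im)
#>   model    loglik k      aic delta_aic tied_with_best
#> 1    IM -226.6885 5 463.3769    0.0000           TRUE
#> 2    SI -290.0657 4 588.1313  124.7544          FALSE

fit_im
#> Divergence model fit: IM
#>   log composite likelihood -226.688, AIC 463.377 (k = 5)
#>   theta_hat 5363
#>   parameters:
#>     nu1     1.552
#>     nu2     1.278
#>     T       1.216
#>     M       2.292

L <- total_seq_length(snp_dadi = sum(sp$counts[!sp$mask]),
                      snp_original = ncol(dat$genotypes$dosage),
                      n_rad_tags = 2000, rad_tag_length = 110)
convert_params(fit_im, L = L)
#> converted IM parameters (mu = 1.2e-08, T_gen = 3 y, L = 220000 bp):
#>   N_ref 510000  nu1 790000  nu2 650000 individuals
#>   m 2.3e-06 per generation (m_e 0); M21 1.8, M12 1.5 migrants/gen
#>   T 3700000 years
```

The simulated truth (nu1 = 1.5, nu2 = 1.2, T = 1.2, M = 2.5) is recovered
closely on this dataset (fitted 1.55, 1.28, 1.22, 2.29 — though see the
methods vignette on how weakly such parameters are identified in general
under gene flow), the IM model beats SI by 125 AIC points, and the
conversion reports roughly two migrants per generation in each direction,
the same order as published coral intraspecific pairs.

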