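test_that("simulation is bit-identical under a fixed seed", {
  sc <- sim_scenario("IM2M", n1 = 4, n2 = 4, n_tags = 40, seed = 42)
  d1 <- simulate_pair(sc)
  d2 <- simulate_pair(sc)
  expect_identical(d1$genotypes$dosage, d2$genotypes$dosage)
  expect_identical(d1$tag_class, d2$tag_class)
  sc2 <- sim_scenario("IM2M", n1 = 4, n2 = 4, n_tags = 40, seed = 43)
  expect_false(identical(simulate_pair(sc2)$genotypes$dosage,
                         d1$genotypes$dosage))
})

test_that("scenario invariants are enforced", {
  expect_error(sim_scenario("IM", nu1 = -1), "nu1")
  expect_error(sim_scenario("IM2M", M = 1, M_e = 2), "M_e")
  expect_error(sim_scenario("SC", T_total = 1, T_phase = 2), "T_phase")
  expect_error(sim_scenario("IM", n1 = 1), "two diploid")
  expect_error(sim_scenario("XX"))
})

test_that("folded single-population SFS matches the neutral closed form", {
  # a vanishingly recent split leaves one panmictic population of size N_ref;
  # the folded SFS entry i is then proportional to 1/i + 1/(2n - i)
  sc <- sim_scenario("SI", nu1 = 1, nu2 = 1, T_total = 1e-9, n1 = 3, n2 = 3,
                     theta_per_tag = 1, n_tags = 1)
  s <- expected_jafs_mc(sc, n_reps = 30000, seed = 5, fold = FALSE)
  tot <- outer(0:6, 0:6, "+")
  use <- !s$mask
  sfs <- tapply(s$counts[use], tot[use], sum)
  se <- sqrt(tapply(s$se[use]^2, tot[use], sum))
  n <- 12
  expected <- 1 / (1:11)
  expected <- expected / sum(expected)
  z <- (sfs - expected) / se
  expect_lt(max(abs(z)), 3.5)
})

test_that("F_ST responds to migration and split age as theory predicts", {
  mean_fst <- function(model, T, M, seeds = 1:4) {
    mean(vapply(seeds, function(s) {
      d <- simulate_pair(sim_scenario(model, nu1 = 1, nu2 = 1, T_total = T,
                                      M = M, n1 = 5, n2 = 5, n_tags = 120,
                                      theta_per_tag = 0.5, seed = s))
      wc_fst(d$genotypes, c("pop1", "pop2"))$fst
    }, numeric(1)))
  }
  near_panmixia <- mean_fst("IM", T = 0.5, M = 50)
  long_isolation <- mean_fst("SI", T = 5, M = 0)
  expect_lt(near_panmixia, 0.05)
  expect_gt(long_isolation, 0.5)
  # monotone in M and in T
  fst_M <- vapply(c(0.5, 5, 50), function(M) mean_fst("IM", T = 1, M = M),
                  numeric(1))
  fst_T <- vapply(c(0.2, 1, 5), function(T) mean_fst("SI", T = T, M = 0),
                  numeric(1))
  expect_true(all(diff(fst_M) < 0))
  expect_true(all(diff(fst_T) > 0))
})

test_that("expected_jafs_mc degenerate and symmetry properties hold", {
  sc0 <- sim_scenario("IM", n1 = 3, n2 = 3, n_tags = 1, theta_per_tag = 0)
  s0 <- simulate_pair(sc0)
  expect_equal(ncol(s0$genotypes$dosage), 0)
  # swapping (nu1, n1) with (nu2, n2) transposes the spectrum
  scA <- sim_scenario("IM", nu1 = 2, nu2 = 0.5, T_total = 1, M = 1,
                      n1 = 3, n2 = 2)
  scB <- sim_scenario("IM", nu1 = 0.5, nu2 = 2, T_total = 1, M = 1,
                      n1 = 2, n2 = 3)
  sA <- expected_jafs_mc(scA, n_reps = 30000, seed = 9)
  sB <- expected_jafs_mc(scB, n_reps = 30000, seed = 10)
  use <- !sA$mask & !t(sB$mask)
  z <- (sA$counts[use] - t(sB$counts)[use]) /
    sqrt(sA$se[use]^2 + t(sB$se)[use]^2)
  expect_lt(max(abs(z)), 3.5)
  # IM2M with Q = 0 nests into IM
  sc_im <- sim_scenario("IM", nu1 = 1, nu2 = 1, T_total = 1, M = 2,
                        n1 = 3, n2 = 3)
  sc_2m <- sim_scenario("IM2M", nu1 = 1, nu2 = 1, T_total = 1, M = 2,
                        M_e = 0.1, Q = 0, n1 = 3, n2 = 3)
  s1 <- expected_jafs_mc(sc_im, n_reps = 30000, seed = 11)
  s2 <- expected_jafs_mc(sc_2m, n_reps = 30000, seed = 12)
  use <- !s1$mask
  z <- (s1$counts[use] - s2$counts[use]) / sqrt(s1$se[use]^2 + s2$se[use]^2)
  expect_lt(max(abs(z)), 3.5)
})

test_that("Monte-Carlo spectra converge as replicates grow", {
  sc <- sim_scenario("IM", n1 = 3, n2 = 3, T_total = 1, M = 1)
  s1 <- expected_jafs_mc(sc, n_reps = 4000, seed = 3)
  s2 <- expected_jafs_mc(sc, n_reps = 16000, seed = 4)
  r <- mean(s2$se[!s2$mask]) / mean(s1$se[!s1$mask])
  expect_lt(abs(r - 0.5), 0.12)
})

test_that("missingness and clone injection behave as constructed", {
  d <- simulate_pair(sim_scenario("IM", n1 = 6, n2 = 6, n_tags = 150,
                                  theta_per_tag = 0.5, seed = 2))
  expect_identical(inject_missing_and_clones(d, 0, 0), d)
  dc <- inject_missing_and_clones(d, miss_rate = 0.1, n_clones = 3, seed = 7)
  expect_equal(nrow(dc$genotypes$dosage), 15)
  # each clone pair is near-identical at co-called sites
  ids <- dc$genotypes$ind_meta$id
  clones <- grep("_clone$", ids, value = TRUE)
  expect_length(clones, 3)
  for (cl in clones) {
    i <- match(cl, ids); j <- match(sub("_clone$", "", cl), ids)
    a <- dc$genotypes$dosage[i, ]; b <- dc$genotypes$dosage[j, ]
    cc <- !is.na(a) & !is.na(b)
    expect_gte(mean(a[cc] == b[cc]), 0.99)
  }
  # realised missingness within the binomial 99% CI of the target rate
  dm <- inject_missing_and_clones(d, miss_rate = 0.2, n_clones = 0, seed = 8)
  m <- mean(is.na(dm$genotypes$dosage))
  N <- length(dm$genotypes$dosage)
  expect_lt(abs(m - 0.2), 2.58 * sqrt(0.2 * 0.8 / N))
})

test_that("environmental simulation has the advertised structure", {
  d <- simulate_pair(sim_scenario("IM", n1 = 8, n2 = 8, n_tags = 60,
                                  theta_per_tag = 0.5, seed = 4))
  d0 <- simulate_env(d, effect_sizes = 0, n_vars = 3, seed = 5)
  expect_identical(d0$genotypes$dosage, d$genotypes$dosage)
  expect_equal(dim(d0$env), c(16, 3))
  # spatial_range -> 0 gives (near) independent values across individuals
  di <- simulate_env(d, effect_sizes = 0, n_vars = 200, spatial_range = 0,
                     seed = 6)
  R <- cor(t(as.matrix(di$env)))   # individuals x individuals over variables
  off <- abs(R[upper.tri(R)])
  expect_lt(mean(off), 0.1)
  # large range gives strong correlation between nearby individuals
  ds <- simulate_env(d, effect_sizes = 0, n_vars = 200, spatial_range = 5,
                     seed = 6)
  Rs <- cor(t(as.matrix(ds$env)))
  expect_gt(mean(Rs[upper.tri(Rs)]), 0.5)
  # effectful variables shift genotypes only at their target sites
  de <- simulate_env(d, effect_sizes = c(0.5, 0), n_vars = 2, seed = 7,
                     n_effect_sites = 20)
  changed <- which(colSums(de$genotypes$dosage != d$genotypes$dosage,
                           na.rm = TRUE) > 0)
  targets <- match(attr(de$env, "effect_sites")$env1,
                   colnames(d$genotypes$dosage))
  expect_true(all(changed %in% targets))
})

test_that("all-sites expansion preserves SNPs and fills invariant sites", {
  d <- simulate_pair(sim_scenario("IM", n1 = 3, n2 = 3, n_tags = 5,
                                  tag_length = 50, theta_per_tag = 1,
                                  seed = 3))
  allgm <- all_sites_matrix(d)
  expect_equal(ncol(allgm$dosage), 5 * 50)
  snp_cols <- match(colnames(d$genotypes$dosage), colnames(allgm$dosage))
  expect_identical(unname(allgm$dosage[, snp_cols]),
                   unname(d$genotypes$dosage))
  expect_true(all(allgm$dosage[, -snp_cols] == 0))
})
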