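test_that("VCF write/read round-trips dosages, positions and sample ids", {
  dos <- rbind(c(0, 1, 2, 0, 1), c(1, 1, 0, NA, 2), c(0, 0, 1, 1, 0))
  gm <- toy_gm(dos, contig = c("tag1", "tag1", "tag1", "tag2", "tag2"),
               pos = c(1, 5, 9, 2, 4))
  path <- tempfile(fileext = ".vcf")
  write_vcf(gm, path)
  gm2 <- read_vcf(path)
  expect_identical(unname(gm2$dosage), unname(gm$dosage))
  expect_equal(gm2$site_meta$pos, gm$site_meta$pos)
  expect_identical(gm2$ind_meta$id, gm$ind_meta$id)
})

test_that("missing genotypes and multiallelic records follow convention", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=t1,length=100>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", sep = "\t"),
    paste("t1", "10", ".", "A", "T", ".", "PASS", ".", "GT", "./.", "0|1",
          sep = "\t"),
    paste("t1", "20", ".", "A", "T,G", ".", "PASS", ".", "GT", "0/1", "1/2",
          sep = "\t")), path)
  gm <- read_vcf(path)
  expect_true(is.na(gm$dosage[1, 1]))
  expect_equal(gm$dosage[2, 1], 1L)
  expect_false(gm$site_meta$biallelic[2])       # retained but flagged
  expect_true(all(is.na(gm$dosage[, 2])))
})

test_that("stage-1 site filters remove the enumerated violations", {
  # 10 sites, 8 individuals: 2 multiallelic, 2 below MAC 3 (one of them
  # monomorphic), 1 removed through depth masking (which pushes its
  # missingness over 50%), 1 with >50% missing, 4 clean survivors
  dos <- cbind(
    rep(NA_integer_, 8),              # s1 multiallelic (dosage NA)
    rep(NA_integer_, 8),              # s2 multiallelic
    c(1, 1, 0, 0, 0, 0, 0, 0),        # s3 MAC 2
    rep(0L, 8),                       # s4 monomorphic (MAC 0)
    c(1, 1, 1, 1, 1, 1, 1, 0),        # s5 depth-masked below at 5/8
    c(NA, NA, NA, NA, NA, 1, 1, 1),   # s6 5/8 missing, MAC 3 among called
    c(1, 1, 1, 0, 0, 0, 0, 0),        # s7 clean
    c(2, 1, 0, 1, 0, 0, 0, 0),        # s8 clean
    c(1, 1, 1, 2, 0, 0, 0, 0),        # s9 clean
    c(0, 1, 1, 1, 0, 0, 0, 0))        # s10 clean
  dos[, 6] <- c(NA, NA, NA, NA, NA, 1L, 1L, 1L)
  depth <- matrix(10, 8, 10)
  depth[1:5, 5] <- 2                  # below depth_min -> masked
  dos[6:8, 5] <- c(1L, 1L, 1L)        # survivors of masking keep MAC 3
  alt <- c("T,G", "T,G", rep("T", 8))
  gm <- toy_gm(dos, alt = alt, depth = depth)
  out <- filter_sites(gm, filter_config(), stage = 1)
  expect_equal(ncol(out$dosage), 4)
  rep <- attr(out, "report")
  expect_equal(rep$sites_removed[rep$filter == "biallelic"], 2)
  expect_equal(rep$sites_removed[rep$filter == "mac"], 2)
  expect_equal(rep$sites_removed[rep$filter == "site_missing"], 2)
  expect_gt(attr(rep, "genotypes_masked"), 0)
  # idempotent
  again <- filter_sites(out, filter_config(), stage = 1)
  expect_equal(ncol(again$dosage), 4)
})

test_that("stage-2 filters apply the tight missingness and MAF thresholds", {
  dos <- cbind(c(1, 1, 1, 0, 0, 0, 0, 0, 0, 2, 0, 1, 1, 0, 2, 1, 0, 1, 0, 1),
               c(1, NA, NA, 0, 0, 0, 0, 0, 0, 2, 0, 1, 1, 0, 2, 1, 0, 1, 0, 1),
               c(rep(0, 19), 1))
  gm <- toy_gm(dos)
  out <- filter_sites(gm, filter_config(), stage = 2)
  # site 2 has 10% missing (> 5%); site 3 has MAF 1/40 = 0.025 >= 0.01 kept
  expect_equal(ncol(out$dosage), 2)
  out2 <- filter_sites(gm, filter_config(maf_min = 0.05), stage = 2)
  expect_equal(ncol(out2$dosage), 1)
})

test_that("individual filter uses a strict threshold and errors when empty", {
  dos <- matrix(0L, 6, 10)
  dos[2, ] <- 1L                     # keeps variation
  dos[1, 1:8] <- NA                  # 80% missing -> removed
  dos[3, 1:8] <- NA                  # 80% missing -> removed
  dos[4, 1:7] <- NA                  # exactly 70% -> retained
  gm <- toy_gm(dos)
  out <- filter_individuals(gm, filter_config())
  expect_equal(nrow(out$dosage), 4)
  expect_true("i04" %in% out$ind_meta$id)
  gm_all <- toy_gm(matrix(NA_integer_, 2, 4))
  expect_error(filter_individuals(gm_all, filter_config()), "all individuals")
})

test_that("clone detection keeps the least-missing member of each group", {
  dos <- rbind(c(0, 1, 2, 0, 1, 2),
               c(0, 1, 2, 0, NA, NA),   # clone of i01, more missing
               c(2, 2, 0, 1, 0, 0))
  gm <- toy_gm(dos)
  cl <- detect_clones(gm, filter_config())
  expect_equal(nrow(cl$pairs), 1)
  expect_equal(cl$pairs$similarity, 1)
  expect_setequal(cl$kept, c("i01", "i03"))
  # a pair at similarity 0.98 with threshold 0.99 is not clonal
  dos2 <- rbind(rep(c(0, 1), 25), c(rep(c(0, 1), 24), 1, 0),
                rep(2, 50))
  gm2 <- toy_gm(dos2)
  cl2 <- detect_clones(gm2, filter_config())
  expect_equal(nrow(cl2$pairs), 0)
  expect_equal(nrow(cl2$gm$dosage), 3)
})

test_that("VIF pruning matches a brute-force oracle and its invariant", {
  set.seed(42)
  base <- matrix(rbinom(120, 2, 0.5), 30, 4)
  # site 5 nearly collinear with site 1
  X <- cbind(base, ifelse(runif(30) < 0.95, base[, 1], 2 - base[, 1]))
  gm <- toy_gm(X)
  cfg <- filter_config(ld_window = 5, ld_step = 5, vif_max = 2)
  pruned <- ld_prune(gm, cfg)
  # brute-force greedy VIF with lm
  vif_lm <- function(M) vapply(seq_len(ncol(M)), function(j) {
    r2 <- summary(stats::lm(M[, j] ~ M[, -j]))$r.squared
    1 / (1 - min(r2, 1 - 1e-12))
  }, numeric(1))
  keep <- seq_len(5)
  Xc <- scale(X, scale = FALSE)
  repeat {
    v <- vif_lm(Xc[, keep, drop = FALSE])
    if (max(v) <= 2) break
    keep <- keep[-which.max(v)]
  }
  expect_setequal(colnames(pruned$dosage), colnames(gm$dosage)[keep])
  # invariant: no window in the output violates the threshold
  v_final <- vif_lm(Xc[, keep, drop = FALSE])
  expect_lte(max(v_final), 2)
  # mutually independent sites are all retained
  gm_ind <- toy_gm(base)
  expect_equal(ncol(ld_prune(gm_ind, cfg)$dosage), 4)
  # perfectly correlated duplicate: exactly one of the pair removed
  gm_dup <- toy_gm(cbind(base[, 1], base[, 1], base[, 2]))
  expect_equal(ncol(ld_prune(gm_dup, filter_config(ld_window = 3,
                                                   ld_step = 1))$dosage), 2)
})

test_that("the full filter pipeline is order-stable and tallies add up", {
  d <- simulate_pair(sim_scenario("IM", n1 = 8, n2 = 8, n_tags = 120,
                                  theta_per_tag = 0.5, seed = 6))
  d <- inject_missing_and_clones(d, miss_rate = 0.08, n_clones = 2, seed = 7)
  cfg <- filter_config(site_missing_max_2 = 0.2, ld_window = 20, ld_step = 5)
  out <- suppressWarnings(filter_pipeline(d$genotypes, cfg))
  rep <- attr(out, "report")
  expect_equal(sum(rep$sites_removed),
               ncol(d$genotypes$dosage) - ncol(out$dosage))
  expect_equal(sum(rep$individuals_removed),
               nrow(d$genotypes$dosage) - nrow(out$dosage))
  expect_gte(nrow(attr(out, "clones")), 2)
  # re-applying stages changes nothing
  out2 <- suppressWarnings(filter_sites(out, cfg, stage = 2))
  expect_equal(dim(out2$dosage), dim(out$dosage))
})
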