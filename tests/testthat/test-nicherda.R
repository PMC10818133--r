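test_that("Hellinger transformation matches closed forms", {
  expect_equal(unname(hellinger(matrix(c(4, 0), 1))), cbind(1, 0))
  expect_equal(unname(hellinger(matrix(c(1, 1, 2), 1))),
               cbind(0.5, 0.5, sqrt(0.5)), tolerance = 1e-7)
  set.seed(1)
  X <- matrix(rpois(40, 3) + 1, 5, 8)
  H <- hellinger(X)
  expect_equal(rowSums(H^2), rep(1, 5))
  expect_equal(H, vegan::decostand(X, "hellinger"), ignore_attr = TRUE)
  expect_error(hellinger(matrix(0, 2, 2)), "positive")
})

test_that("dbMEM truncation equals the brute-force MST longest edge", {
  set.seed(7)
  xy <- cbind(runif(6), runif(6))
  D <- as.matrix(dist(xy))
  # Prim's algorithm, written out
  intree <- 1; edges <- numeric(0)
  while (length(intree) < 6) {
    out <- setdiff(1:6, intree)
    sub <- D[intree, out, drop = FALSE]
    k <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    edges <- c(edges, min(sub))
    intree <- c(intree, out[k[2]])
  }
  mb <- dbmem(xy)
  expect_equal(mb$truncation, max(edges))
  expect_lt(max(abs(crossprod(mb$vectors) - diag(ncol(mb$vectors)))), 1e-10)
  expect_true(all(mb$values > 0))
})

test_that("dbMEM on an equally spaced transect is sinusoidal", {
  # with truncation at the nearest-neighbour spacing the leading spatial
  # eigenfunction of a transect is one full sine period
  u <- seq(0, 1, length.out = 40)
  mb <- dbmem(cbind(u, 0))
  expect_gt(abs(cor(mb$vectors[, 1], sin(2 * pi * u))), 0.95)
})

test_that("duplicate coordinates are jittered, with a message", {
  xy <- rbind(c(0, 0), c(0, 0), c(1, 0), c(0.4, 0.7), c(0.8, 0.2))
  expect_message(mb <- dbmem(xy), "jitter")
  expect_true(ncol(mb$vectors) >= 1)
})

test_that("partial RDA reduces to its definitions", {
  set.seed(3)
  n <- 24
  Y <- matrix(rnorm(n * 30), n)
  X <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("a", "b", "c")))
  # empty conditioning equals an unconditioned RDA
  r1 <- partial_rda(Y, X)
  expect_equal(r1$adj_r2, vegan::RsquareAdj(vegan::rda(Y, X))$adj.r.squared)
  # independent least-squares oracle: R2 = SS(fitted) / SS(total) and the
  # Ezekiel adjustment with n rows and p predictors
  fit0 <- lm(scale(Y, scale = FALSE) ~ X)
  r2_manual <- sum(fitted(fit0)^2) / sum(scale(Y, scale = FALSE)^2)
  expect_equal(r1$r2, r2_manual, tolerance = 1e-10)
  p <- ncol(X)
  expect_equal(r1$adj_r2, 1 - (1 - r1$r2) * (n - 1) / (n - 1 - p),
               tolerance = 1e-10)
  expect_lte(r1$adj_r2, r1$r2)
  # conditioned case: the constrained variance equals that of the
  # residualised regression (vegan reports it against the total variance)
  Z <- matrix(rnorm(n * 2), n)
  r2 <- partial_rda(Y, X, Z)
  Yr <- resid(lm(Y ~ Z)); Xr <- resid(lm(X ~ Z))
  fitp <- lm(Yr ~ Xr)
  expect_equal(r2$r2, sum(fitted(fitp)^2) / sum(scale(Y, scale = FALSE)^2),
               tolerance = 1e-10)
  expect_lte(r2$adj_r2, r2$r2)
})

test_that("a known niche effect is recovered through the full chain", {
  d <- simulate_pair(sim_scenario("SI", nu1 = 1, nu2 = 1, T_total = 1e-6,
                                  n1 = 25, n2 = 25, n_tags = 80,
                                  theta_per_tag = 1, seed = 1))
  d <- simulate_env(d, effect_sizes = c(0.5, 0, 0, 0), n_vars = 4,
                    n_effect_sites = 80, seed = 21)
  Y <- rda_response(d$genotypes)
  E <- env_matrix(d$env)
  Z <- dbmem(d$coords)$vectors[, 1:3]
  rr <- partial_rda(Y, E, Z)
  e1_cond <- resid(lm(d$env$env1 ~ Z))
  expect_gt(abs(cor(rr$lc_scores[, 1], e1_cond)), 0.9)
  sel <- forward_select(Y, E, Z, n_perm = 199, seed = 5)
  expect_true("env1" %in% sel)
  pt <- permutation_test(rr, n_perm = 199, seed = 6)
  expect_lt(pt$p_value[1], 0.05)
})

test_that("forward selection respects its stopping switches", {
  set.seed(8)
  n <- 20
  Y <- matrix(rnorm(n * 10), n)
  X <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("a", "b", "c")))
  all_in <- forward_select(Y, X, alpha = 1, r2_stop = FALSE, n_perm = 49,
                           seed = 1)
  expect_setequal(as.character(all_in), c("a", "b", "c"))
  # alpha-level control on pure noise
  n_sel <- vapply(1:8, function(s) {
    set.seed(s + 100)
    Yn <- matrix(rnorm(n * 10), n)
    Xn <- matrix(rnorm(n * 4), n, dimnames = list(NULL, paste0("v", 1:4)))
    length(forward_select(Yn, Xn, n_perm = 99, seed = s))
  }, numeric(1))
  expect_gte(mean(n_sel <= 1), 0.9)
})

test_that("permutation p-values follow the add-one formula and shuffle
           invariance", {
  set.seed(2)
  n <- 20
  X <- matrix(rnorm(n * 2), n)
  Y <- cbind(X %*% rbind(c(2, 0.5), c(-1, 1)), matrix(rnorm(n * 5), n)) +
    matrix(rnorm(n * 7, sd = 0.3), n)
  rr <- partial_rda(Y, X)
  pt <- permutation_test(rr, n_perm = 19, seed = 3)
  expect_equal(pt$p_value[1], 1 / 20)  # saturated at the minimum
  # permuting the rows of the whole dataset leaves the statistic unchanged
  perm <- sample(n)
  rr2 <- partial_rda(Y[perm, ], X[perm, ])
  pt2 <- permutation_test(rr2, n_perm = 19, seed = 3)
  expect_equal(pt2$F[1], pt$F[1], tolerance = 1e-10)
  expect_equal(pt2$p_value[1], pt$p_value[1])
})

test_that("variance partition fractions are additive and detect confounding", {
  set.seed(5)
  n <- 30
  Z <- matrix(rnorm(n * 2), n)
  X <- matrix(rnorm(n * 2), n)
  Y <- Z %*% matrix(c(1, -1, 0.5, 0.2, 0.3, -0.6, 0.2, 0.1), 2, 4) +
    matrix(rnorm(n * 4, sd = 0.4), n)
  vp <- variance_partition(Y, X, Z)
  joint <- partial_rda(Y, cbind(X, Z))$adj_r2
  expect_equal(unname(vp["pure_env"] + vp["pure_space"] + vp["shared"]),
               joint, tolerance = 1e-10)
  # duplicating the predictors into the conditioning kills the pure fraction
  vp2 <- variance_partition(Y, X, cbind(Z, X + matrix(rnorm(n * 2, sd = 1e-6), n)))
  expect_lt(abs(vp2["pure_env"]), 0.02)
  # orthogonal-by-construction environment explains ~ nothing
  null_r2 <- vapply(1:5, function(s) {
    set.seed(s)
    partial_rda(matrix(rnorm(n * 8), n), matrix(rnorm(n * 2), n))$adj_r2
  }, numeric(1))
  expect_true(all(abs(null_r2) < 0.1))
})

test_that("environment screening flags collinear variables", {
  set.seed(4)
  e1 <- rnorm(40); e2 <- e1 * 0.95 + rnorm(40, sd = 0.2); e3 <- rnorm(40)
  E <- cbind(t1 = e1, t2 = e2, t3 = e3)
  X <- env_matrix(E)
  expect_equal(attr(X, "collinear"), "t2")
  expect_equal(unname(colMeans(X)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(X, 2, sd)), rep(1, 3), tolerance = 1e-12)
  X2 <- env_matrix(E, drop = TRUE)
  expect_false("t2" %in% colnames(X2))
})

test_that("divergent niches separate taxa on the first constrained axis", {
  d <- simulate_pair(sim_scenario("SI", nu1 = 1, nu2 = 1, T_total = 0.45,
                                  n1 = 15, n2 = 15, n_tags = 100,
                                  theta_per_tag = 1, seed = 2))
  # taxon-linked environmental contrast: shift env1 by taxon
  d <- simulate_env(d, effect_sizes = 0, n_vars = 3, seed = 3)
  d$env$env1 <- d$env$env1 + rep(c(-1.5, 1.5), each = 15)
  Y <- rda_response(d$genotypes)
  E <- env_matrix(d$env)
  rr <- partial_rda(Y, E)
  ax <- rr$lc_scores[, 1]
  lab <- rep(c(0, 1), each = 15)
  auc <- mean(outer(ax[lab == 1], ax[lab == 0], ">"))
  expect_gt(max(auc, 1 - auc), 0.9)
})
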