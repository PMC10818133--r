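test_that("profiled theta and the composite likelihood behave analytically", {
  data <- jafs(rbind(c(0, 2, 3), c(5, 0, 0)))
  model <- jafs(rbind(c(0, 0.2, 0.3), c(0.5, 0, 0)))
  cl <- composite_loglik(model, data)
  expect_equal(cl$theta_hat, 10, tolerance = 1e-9)
  # theta_hat maximises the Poisson likelihood over a theta grid
  use <- !model$mask & !data$mask & model$counts > 0
  m <- model$counts[use]
  d <- data$counts[use]
  ll <- function(th) sum(d * log(th * m) - th * m - lgamma(d + 1))
  grid <- seq(1, 30, by = 0.25)
  expect_equal(grid[which.max(vapply(grid, ll, numeric(1)))], 10)
  expect_equal(cl$loglik, ll(10))
  # proportional data recover the proportionality constant
  d2 <- model; d2$counts <- model$counts * 7
  expect_equal(composite_loglik(model, d2)$theta_hat, 7)
})

test_that("engine nesting identities hold", {
  sizes <- c(8, 8)
  ctl <- engine_control(pts = c(30, 40))
  si <- expected_jafs(dadi_params("SI", nu1 = 1.3, nu2 = 0.8, T = 1), sizes, ctl)
  im0 <- expected_jafs(dadi_params("IM", nu1 = 1.3, nu2 = 0.8, T = 1, M = 0),
                       sizes, ctl)
  expect_equal(im0$counts, si$counts, tolerance = 1e-6)
  im <- expected_jafs(dadi_params("IM", nu1 = 1.3, nu2 = 0.8, T = 1, M = 2),
                      sizes, ctl)
  q0 <- expected_jafs(dadi_params("IM2M", nu1 = 1.3, nu2 = 0.8, T = 1, M = 2,
                                  M_e = 0.5, Q = 0), sizes, ctl)
  expect_equal(q0$counts, im$counts, tolerance = 1e-6)
  me_eq <- expected_jafs(dadi_params("IM2M", nu1 = 1.3, nu2 = 0.8, T = 1,
                                     M = 2, M_e = 2, Q = 0.4), sizes, ctl)
  expect_equal(me_eq$counts, im$counts, tolerance = 1e-6)
  sc <- expected_jafs(dadi_params("SC", nu1 = 1.3, nu2 = 0.8, T = 1, M = 2,
                                  T_phase = 1), sizes, ctl)
  expect_equal(sc$counts, im$counts, tolerance = 1e-6)
  # under the clock convention used (migration before T_phase for AM),
  # AM nests into IM at T_phase = 0 and into SI at T_phase = T
  am0 <- expected_jafs(dadi_params("AM", nu1 = 1.3, nu2 = 0.8, T = 1, M = 2,
                                   T_phase = 0), sizes, ctl)
  expect_equal(am0$counts, im$counts, tolerance = 1e-6)
  amT <- expected_jafs(dadi_params("AM", nu1 = 1.3, nu2 = 0.8, T = 1, M = 2,
                                   T_phase = 1), sizes, ctl)
  expect_equal(amT$counts, si$counts, tolerance = 1e-6)
})

test_that("expected spectra transpose under population swap", {
  ctl <- engine_control(pts = c(30, 40))
  a <- expected_jafs(dadi_params("IM", nu1 = 2, nu2 = 0.5, T = 0.8, M = 1),
                     c(6, 8), ctl)
  b <- expected_jafs(dadi_params("IM", nu1 = 0.5, nu2 = 2, T = 0.8, M = 1),
                     c(8, 6), ctl)
  # exact up to the operator-splitting order (the x sweep precedes the y
  # sweep within each time step)
  expect_equal(a$counts, t(b$counts), tolerance = 1e-3)
})

test_that("engine agrees with the coalescent oracle on a small case", {
  sc <- sim_scenario("IM", nu1 = 1, nu2 = 1, T_total = 1, M = 1, n1 = 3, n2 = 3)
  mc <- expected_jafs_mc(sc, n_reps = 40000, seed = 3)
  en <- expected_jafs(dadi_params("IM", nu1 = 1, nu2 = 1, T = 1, M = 1),
                      c(6, 6))
  use <- !(mc$mask | en$mask) & mc$se > 0
  z <- (en$counts[use] - mc$counts[use]) / mc$se[use]
  expect_lt(mean(abs(z)), 1.5)
  expect_lt(max(abs(z)), 4)
})

test_that("fitting is deterministic and recovers an easy optimum", {
  d <- simulate_pair(sim_scenario("IM", nu1 = 1.5, nu2 = 1.2, T_total = 1.2,
                                  M = 2.5, n1 = 5, n2 = 5, n_tags = 800,
                                  theta_per_tag = 0.5, seed = 4))
  sp <- build_jafs(d$genotypes, c("pop1", "pop2"), mask_low = FALSE)
  ctl <- engine_control(pts = 25, dt_fac = 6)
  f1 <- fit_divergence(sp, "IM", rounds = 1, runs = 2, seed = 3,
                       opt_control = ctl, final_control = ctl, maxit = 80)
  f2 <- fit_divergence(sp, "IM", rounds = 1, runs = 2, seed = 3,
                       opt_control = ctl, final_control = ctl, maxit = 80)
  expect_identical(f1$trace, f2$trace)
  expect_identical(coef(f1), coef(f2))
  expect_s3_class(f1, "div_fit")
  expect_equal(f1$aic, 2 * f1$k - 2 * f1$loglik)
  expect_equal(attr(logLik(f1), "df"), f1$k)
  expect_error(fit_divergence(sp, "IM", lower = c(M = -1)), "positive")
})

test_that("model comparison applies the AIC formula and flags ties", {
  mkfit <- function(model, ll, k) structure(
    list(model = model, loglik = ll, k = k, aic = 2 * k - 2 * ll),
    class = "div_fit")
  tab <- compare_models(mkfit("SI", -100, 3), mkfit("IM", -100, 3),
                        mkfit("IM2M", -120, 5))
  expect_equal(tab$aic[tab$model == "SI"], 206)
  expect_true(all(tab$tied_with_best[tab$model %in% c("SI", "IM")]))
  expect_false(tab$tied_with_best[tab$model == "IM2M"])
})

test_that("likelihood-ratio machinery handles nesting and degeneracy", {
  mkfit <- function(model, ll) {
    pn <- reefdiverge:::model_free_params(model)
    structure(list(model = model, loglik = ll, k = length(pn) + 1,
                   free = stats::setNames(rep(1, length(pn)), pn),
                   bounds = reefdiverge:::default_bounds(pn)),
              class = "div_fit")
  }
  r <- lrt_adjusted(mkfit("IM", -100), mkfit("SI", -100))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  r2 <- lrt_adjusted(mkfit("IM", -95), mkfit("SI", -100))
  expect_equal(r2$statistic, 10)
  expect_lt(r2$p_value, 0.01)
  expect_error(lrt_adjusted(mkfit("SI", -90), mkfit("IM", -100)), "nested")
})

test_that("information-matrix standard deviations match an analytic case", {
  # exactly quadratic log-likelihood in log-parameters: known curvature
  fn <- function(x) -0.5 * (8 * log(x[1])^2 + 2 * log(x[2])^2)
  H <- reefdiverge:::num_hessian_log(fn, c(1, 1), rel_step = 1e-3)
  sd <- sqrt(diag(solve(-H)))
  expect_equal(sd, c(1 / sqrt(8), 1 / sqrt(2)), tolerance = 1e-4)
})

test_that("FIM standard deviations shrink like sqrt(data mass)", {
  p <- dadi_params("SI", nu1 = 1.2, nu2 = 0.9, T = 0.8)
  ctl <- engine_control(pts = c(30, 40))
  ed <- expected_jafs(p, c(8, 8), ctl)
  mkfit <- function(mass) {
    dat <- ed; dat$counts <- ed$counts * mass
    structure(list(model = "SI", free = c(nu1 = 1.2, nu2 = 0.9, T = 0.8),
                   sizes = c(8, 8), data = dat, final_control = ctl,
                   at_bound = c(nu1 = FALSE, nu2 = FALSE, T = FALSE)),
              class = "div_fit")
  }
  f1 <- fim_sd(mkfit(2000))
  f2 <- fim_sd(mkfit(4000))
  expect_equal(unname(f1$fim$sd / f2$fim$sd), rep(sqrt(2), 3),
               tolerance = 0.05)
})

test_that("bootstrap refits return one parameter row per replicate", {
  d <- simulate_pair(sim_scenario("IM", nu1 = 1, nu2 = 1, T_total = 1, M = 1,
                                  n1 = 4, n2 = 4, n_tags = 200,
                                  theta_per_tag = 0.5, seed = 2))
  sp <- build_jafs(d$genotypes, c("pop1", "pop2"), mask_low = FALSE)
  ctl <- engine_control(pts = 25, dt_fac = 6)
  fit <- fit_divergence(sp, "SI", rounds = 1, runs = 1, seed = 1,
                        opt_control = ctl, final_control = ctl, maxit = 60)
  boots <- bootstrap_jafs(d$genotypes, c("pop1", "pop2"), n_boot = 3,
                          seed = 4, mask_low = FALSE)
  fit <- bootstrap_params(fit, boots, maxit = 40)
  expect_equal(nrow(fit$boot), 3)
  expect_true(all(c("nu1", "nu2", "T", "loglik") %in% names(fit$boot)))
})
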