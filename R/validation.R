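# Self-validation utilities: expected-information identifiability screening
# and seeded parameter-recovery studies on synthetic data.  These are what
# the package's acceptance checks run; they are exported because the same
# questions (which parameters does my design identify? does the fit recover
# known truth?) arise for any study design.

#' Expected-information identifiability screen
#'
#' Computes, for a parameter set treated as truth, the noise-free expected
#' spectrum scaled to `n_snps` sites, the Fisher information of the profile
#' composite likelihood at the truth (numerical Hessian in log-parameter
#' space) and the implied relative standard deviation of each free
#' parameter. Parameters whose expected relative SD exceeds the threshold
#' are reported as not identifiable at this design size.
#'
#' @param p a [dadi_params()] truth.
#' @param sizes haploid sample sizes of the spectrum.
#' @param n_snps number of independent information units the design yields.
#'   For RAD data fitted by composite likelihood this should be the number
#'   of independent linkage blocks (tags): SNPs on one tag share a single
#'   genealogy, so counting them individually overstates precision.
#' @param threshold relative-SD cutoff for calling a parameter identifiable.
#' @param control,control_h engine settings for the expected spectrum and
#'   the Hessian evaluations.
#' @return A list with `rel_sd` (named vector) and `identifiable` (names).
#' @export
identifiable_params <- function(p, sizes, n_snps, threshold = 0.25,
                                control = engine_control(pts = c(50, 60, 70)),
                                control_h = engine_control(pts = c(40, 50))) {
  stopifnot(inherits(p, "dadi_params"))
  ed <- expected_jafs(p, sizes, control = control)
  ed$counts <- ed$counts * n_snps
  pn <- model_free_params(p$model)
  v <- c(nu1 = p$nu1, nu2 = p$nu2, T = p$T, M = p$M, M_e = p$M_e, Q = p$Q,
         T_frac = if (p$T > 0) p$T_phase / p$T else 0.5)[pn]
  fn <- function(x) {
    names(x) <- pn
    composite_loglik(expected_jafs(vec_to_params(x, p$model), sizes,
                                   control_h), ed)$loglik
  }
  H <- num_hessian_log(fn, v, rel_step = 2e-2)
  rel_sd <- tryCatch(sqrt(diag(solve(-H))),
                     error = function(e) rep(NA_real_, length(v)))
  names(rel_sd) <- pn
  list(rel_sd = rel_sd, identifiable = pn[!is.na(rel_sd) &
                                            rel_sd <= threshold])
}

#' Seeded parameter-recovery study
#'
#' Simulates datasets under a known scenario, rebuilds the folded spectrum
#' (unmasked: synthetic data carry no sequencing error), fits a menu of
#' divergence models to each and reports per-seed relative errors of the
#' generating model's parameters plus how often the generating model is
#' AIC-preferred.
#'
#' @param scenario a [sim_scenario()] giving the truth (its `model` is the
#'   generating model).
#' @param n_seeds number of replicate datasets.
#' @param seed base seed; per-replicate seeds are derived from it.
#' @param fit_models models fitted to every dataset.
#' @param rounds,runs,maxit,opt_control,final_control passed to
#'   [fit_divergence()].
#' @return A list with `errors` (seeds x parameters relative errors),
#'   `median_abs_error`, `aic_best` (winner per seed), `aic_pref_rate`, and
#'   the per-seed fitted parameter table.
#' @export
recovery_study <- function(scenario, n_seeds = 10, seed = 1,
                           fit_models = c("SI", "IM", "IM2M"),
                           rounds = c(2, 1), runs = 3, maxit = 150,
                           opt_control = engine_control(pts = 25, dt_fac = 6),
                           final_control = engine_control(pts = c(40, 50, 60))) {
  stopifnot(inherits(scenario, "sim_scenario"))
  model <- scenario$model
  pn <- model_free_params(model)
  truth <- c(nu1 = scenario$nu1, nu2 = scenario$nu2, T = scenario$T_total,
             M = scenario$M, M_e = scenario$M_e, Q = scenario$Q,
             T_frac = scenario$T_phase / scenario$T_total)[pn]
  errors <- matrix(NA_real_, n_seeds, length(pn),
                   dimnames = list(NULL, pn))
  fitted <- errors
  aic_best <- character(n_seeds)
  for (i in seq_len(n_seeds)) {
    sc <- scenario
    sc$seed <- derive_seed(seed, paste0("recov", model, i))
    dat <- simulate_pair(sc)
    sp <- build_jafs(dat$genotypes, c("pop1", "pop2"), mask_low = FALSE)
    fits <- lapply(fit_models, function(m)
      fit_divergence(sp, m, rounds = rounds, runs = runs,
                     seed = derive_seed(sc$seed, m),
                     opt_control = opt_control,
                     final_control = final_control, maxit = maxit))
    names(fits) <- fit_models
    aic_best[i] <- compare_models(fits)$model[1]
    est <- fits[[model]]$free[pn]
    fitted[i, ] <- est
    errors[i, ] <- est / truth - 1
  }
  list(truth = truth, errors = errors, fitted = fitted,
       median_abs_error = apply(abs(errors), 2, stats::median),
       aic_best = aic_best,
       aic_pref_rate = mean(aic_best == model))
}
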