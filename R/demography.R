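#' Coalescent-scaled demographic parameters
#'
#' Parameters of the five two-population divergence models, in the scaling
#' used throughout the package: population sizes relative to the ancestral
#' reference `N_ref`, times in units of `2 * N_ref` generations, migration as
#' `M = 2 * N_ref * m`. For `IM2M`, a proportion `Q` of loci exchanges
#' migrants at the reduced rate `M_e <= M` (the complement `P = 1 - Q`
#' evolves at `M`). For `SC`/`AM`, `T_phase <= T` is the age of the epoch
#' change (migration active since `T_phase` for `SC`, before it for `AM`).
#'
#' @param model one of `"SI"`, `"IM"`, `"IM2M"`, `"SC"`, `"AM"`.
#' @param nu1,nu2 relative population sizes (> 0).
#' @param T scaled total divergence time (> 0).
#' @param M scaled symmetric migration rate (>= 0).
#' @param M_e scaled reduced migration rate (IM2M; `0 <= M_e <= M`).
#' @param Q proportion of loci in the reduced class (IM2M; in `[0, 1]`).
#' @param T_phase epoch boundary (SC/AM; in `[0, T]`).
#' @return A list of class `dadi_params`.
#' @export
dadi_params <- function(model = c("IM", "SI", "IM2M", "SC", "AM"),
                        nu1 = 1, nu2 = 1, T = 1, M = 0, M_e = 0, Q = 0,
                        T_phase = T / 2) {
  model <- match.arg(model)
  if (!(nu1 > 0 && nu2 > 0 && T > 0)) stop("nu1, nu2, T must be > 0")
  if (M < 0 || M_e < 0) stop("migration rates must be >= 0")
  if (M_e > M) stop("M_e must not exceed M")
  if (Q < 0 || Q > 1) stop("Q must lie in [0, 1]")
  if (T_phase < 0 || T_phase > T) stop("T_phase must lie in [0, T]")
  structure(list(model = model, nu1 = nu1, nu2 = nu2, T = T, M = M,
                 M_e = M_e, Q = Q, T_phase = T_phase),
            class = "dadi_params")
}

# Free parameters per model (T_phase is optimised as the fraction T_phase/T).
model_free_params <- function(model) {
  switch(model,
    SI = c("nu1", "nu2", "T"),
    IM = c("nu1", "nu2", "T", "M"),
    IM2M = c("nu1", "nu2", "T", "M", "M_e", "Q"),
    SC = c("nu1", "nu2", "T", "M", "T_frac"),
    AM = c("nu1", "nu2", "T", "M", "T_frac"))
}

default_bounds <- function(names) {
  lo <- c(nu1 = 1e-2, nu2 = 1e-2, T = 1e-2, M = 1e-4, M_e = 1e-6,
          Q = 1e-2, T_frac = 1e-2)
  hi <- c(nu1 = 100, nu2 = 100, T = 10, M = 20, M_e = 20,
          Q = 0.99, T_frac = 0.99)
  list(lower = lo[names], upper = hi[names])
}

# Neutral starting point used when no start is supplied: demographic
# equivalence with the ancestor and order-one rates.
default_start <- function(names) {
  c(nu1 = 1, nu2 = 1, T = 1, M = 1, M_e = 0.1, Q = 0.5, T_frac = 0.5)[names]
}

vec_to_params <- function(v, model) {
  p <- dadi_params(model, nu1 = v[["nu1"]], nu2 = v[["nu2"]], T = v[["T"]],
                   M = if ("M" %in% names(v)) v[["M"]] else 0,
                   M_e = if ("M_e" %in% names(v)) min(v[["M_e"]], v[["M"]]) else 0,
                   Q = if ("Q" %in% names(v)) v[["Q"]] else 0,
                   T_phase = if ("T_frac" %in% names(v))
                     v[["T_frac"]] * v[["T"]] else v[["T"]] / 2)
  p
}

#' Poisson composite log-likelihood of a spectrum
#'
#' Treats unmasked data cells as independent Poisson counts with intensity
#' `theta_hat * model`, profiling the scaling analytically:
#' `theta_hat = sum(data) / sum(model)` over the shared unmasked cells.
#' Model cells that are zero where data are positive are floored at a small
#' epsilon.
#'
#' @param model,data [jafs] objects of matching shape; masks are combined.
#' @param eps floor for model cells (default `1e-12` of the model mass).
#' @return A list with `loglik` and `theta_hat`.
#' @export
composite_loglik <- function(model, data, eps = 1e-12) {
  stopifnot(inherits(model, "jafs"), inherits(data, "jafs"),
            all(dim(model$counts) == dim(data$counts)))
  use <- !(model$mask | data$mask)
  m <- model$counts[use]
  d <- data$counts[use]
  m <- pmax(m, eps * sum(m))
  theta_hat <- sum(d) / sum(m)
  loglik <- sum(d * log(theta_hat * m) - theta_hat * m - lgamma(d + 1))
  list(loglik = loglik, theta_hat = theta_hat)
}

#' Fit a divergence model to a joint allele-frequency spectrum
#'
#' Maximises the Poisson composite likelihood of the folded spectrum under
#' one of the five divergence models by multi-round perturbed restarts:
#' within each round, each run perturbs the incumbent best parameters by a
#' factor `2^u` per parameter, `u ~ Uniform(-fold, fold)` with `fold` the
#' round's label, clips to bounds and then runs a Nelder-Mead local search in
#' log-parameter space. First-round runs with no incumbent draw starting
#' points log-uniformly between the bounds. The best solution is re-evaluated
#' with the (finer) `final_control` engine settings for the reported
#' log-likelihood and AIC.
#'
#' @param data a folded [jafs] (typically from [build_jafs()]).
#' @param model one of `"SI"`, `"IM"`, `"IM2M"`, `"SC"`, `"AM"`.
#' @param start optional [dadi_params()] (or named vector) of starting values.
#' @param lower,upper optional named bound vectors over the model's free
#'   parameters (`nu1`, `nu2`, `T`, `M`, `M_e`, `Q`, `T_frac`).
#' @param rounds integer vector of perturbation folds, e.g. `c(3, 2, 1)`.
#' @param runs local searches per round (default 30).
#' @param seed integer seed for the perturbations.
#' @param opt_control engine settings used inside the optimisation (coarse by
#'   default for speed).
#' @param final_control engine settings for the final reported likelihood.
#' @param maxit Nelder-Mead iteration cap per run.
#' @return An object of class `div_fit`: fitted parameters (`$par`, a
#'   [dadi_params()]), `$loglik`, `$aic`, `$theta_hat`, `$trace` (one row per
#'   run), the data and sizes, and slots for bootstrap and Fisher-information
#'   results filled by [bootstrap_params()] and [fim_sd()].
#' @seealso [compare_models()], [lrt_adjusted()], [convert_params()]
#' @export
fit_divergence <- function(data, model = c("IM", "SI", "IM2M", "SC", "AM"),
                           start = NULL, lower = NULL, upper = NULL,
                           rounds = c(3, 2, 1), runs = 30, seed = NULL,
                           opt_control = engine_control(pts = c(30, 40)),
                           final_control = engine_control(),
                           maxit = 500) {
  model <- match.arg(model)
  stopifnot(inherits(data, "jafs"))
  if (!data$folded) stop("fit requires a folded spectrum")
  pn <- model_free_params(model)
  bd <- default_bounds(pn)
  if (!is.null(lower)) bd$lower[names(lower)] <- lower
  if (!is.null(upper)) bd$upper[names(upper)] <- upper
  if (any(!is.finite(bd$lower)) || any(bd$lower <= 0))
    stop("bounds must be finite and positive")
  llo <- log(bd$lower); lhi <- log(bd$upper)
  sizes <- c(data$n1, data$n2)

  negll <- function(lv) {
    v <- exp(pmin(pmax(lv, llo), lhi))
    names(v) <- pn
    p <- vec_to_params(v, model)
    -composite_loglik(expected_jafs(p, sizes, opt_control), data)$loglik
  }

  start_lv <- NULL
  if (!is.null(start)) {
    sv <- if (inherits(start, "dadi_params"))
      unlist(start[intersect(names(start), c("nu1", "nu2", "T", "M", "M_e", "Q"))])
    else start
    if (inherits(start, "dadi_params") && "T_frac" %in% pn)
      sv <- c(sv, T_frac = start$T_phase / start$T)
    start_lv <- pmin(pmax(log(sv[pn]), llo), lhi)
  }

  if (is.null(start_lv))
    start_lv <- pmin(pmax(log(default_start(pn)), llo), lhi)
  trace <- NULL
  best_lv <- start_lv
  best_val <- negll(start_lv)

  with_seed(seed, {
    for (fold in rounds) {
      for (run in seq_len(runs)) {
        if (run == 1) {
          lv0 <- best_lv
        } else {
          lv0 <- best_lv + stats::runif(length(pn), -fold, fold) * log(2)
        }
        lv0 <- pmin(pmax(lv0, llo), lhi)
        opt <- stats::optim(lv0, negll, method = "Nelder-Mead",
                            control = list(maxit = maxit, reltol = 1e-8))
        trace <- rbind(trace, data.frame(round = fold, run = run,
                                         loglik = -opt$value,
                                         t(exp(opt$par))))
        if (opt$value < best_val) {
          best_val <- opt$value
          best_lv <- opt$par
        }
      }
    }
  })
  if (!is.finite(best_val))
    warning("no run improved on the starting point")
  v <- exp(pmin(pmax(best_lv, llo), lhi))
  names(v) <- pn
  p <- vec_to_params(v, model)
  final_model <- expected_jafs(p, sizes, final_control)
  cl <- composite_loglik(final_model, data)
  k <- length(pn) + 1  # profiled theta counts as estimated
  names(trace)[-(1:3)] <- pn
  at_bound <- v <= bd$lower * (1 + 1e-6) | v >= bd$upper * (1 - 1e-6)
  structure(list(model = model, par = p, free = v, loglik = cl$loglik,
                 theta_hat = cl$theta_hat, aic = 2 * k - 2 * cl$loglik,
                 k = k, trace = trace, data = data, sizes = sizes,
                 bounds = bd, at_bound = at_bound,
                 final_control = final_control, opt_control = opt_control,
                 expected = final_model, boot = NULL, fim = NULL),
            class = "div_fit")
}

#' Rank fitted divergence models by AIC
#'
#' @param ... `div_fit` objects (or one list of them).
#' @param tie_delta AIC difference below which models are flagged as tied
#'   (default 1).
#' @return A data.frame ordered by AIC with columns `model`, `loglik`, `k`,
#'   `aic`, `delta_aic` and `tied_with_best`.
#' @export
compare_models <- function(..., tie_delta = 1) {
  fits <- list(...)
  if (length(fits) == 1 && !inherits(fits[[1]], "div_fit")) fits <- fits[[1]]
  stopifnot(all(vapply(fits, inherits, logical(1), "div_fit")))
  tab <- data.frame(model = vapply(fits, `[[`, character(1), "model"),
                    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
                    k = vapply(fits, `[[`, numeric(1), "k"),
                    aic = vapply(fits, `[[`, numeric(1), "aic"))
  tab <- tab[order(tab$aic), ]
  tab$delta_aic <- tab$aic - tab$aic[1]
  tab$tied_with_best <- tab$delta_aic < tie_delta
  rownames(tab) <- NULL
  tab
}

# models whose parameter space contains the nested model's
nesting_ok <- function(full, nested) {
  allowed <- list(SI = c("IM", "IM2M", "SC", "AM"),
                  IM = c("IM2M", "SC", "AM"))
  full %in% (allowed[[nested]] %||% character(0))
}

#' Composite-likelihood ratio test between nested divergence models
#'
#' The raw statistic is `2 * (lnL_full - lnL_nested)`. Because the
#' composite likelihood treats linked sites as independent, the statistic is
#' rescaled in the Godambe style when bootstrap spectra are supplied: with
#' `u_b` the score of the full model's extra parameters at the constrained
#' optimum evaluated on bootstrap replicate `b`, `J = cov(u_b)` and `H` the
#' negative Hessian on the original data, the adjusted statistic is
#' `D * d / tr(J H^-1)` with `d` extra parameters. When the nested model
#' lies on a boundary of the full parameter space (e.g. `M = 0`), the null
#' is the boundary mixture `0.5 chi2_{d-1} + 0.5 chi2_d`.
#'
#' @param full,nested `div_fit` objects; `nested`'s model must nest within
#'   `full`'s (SI in IM/SC/AM/IM2M, IM in SC/AM/IM2M).
#' @param boots optional list of bootstrap [jafs] (from [bootstrap_jafs()]).
#' @param control engine settings for the score evaluations.
#' @return A list with `statistic`, `statistic_adj`, `df`, `p_value`,
#'   `boundary` and `adjustment`.
#' @export
lrt_adjusted <- function(full, nested, boots = NULL,
                         control = full$opt_control) {
  stopifnot(inherits(full, "div_fit"), inherits(nested, "div_fit"))
  if (!nesting_ok(full$model, nested$model))
    stop("models are not nested (need SI within IM-family or IM within IM2M/SC/AM)")
  D <- 2 * (full$loglik - nested$loglik)
  if (D < 0) D <- 0
  pn_full <- model_free_params(full$model)
  pn_nest <- model_free_params(nested$model)
  extra <- setdiff(pn_full, pn_nest)
  d <- length(extra)
  # constrained embedding of the nested optimum in the full space
  v0 <- full$free
  v0[pn_nest] <- nested$free[pn_nest]
  boundary <- TRUE  # all implemented nestings lie on a boundary
  v0[extra] <- vapply(extra, function(nm) switch(nm,
    M = full$bounds$lower[["M"]],
    M_e = v0[["M"]],           # M_e = M recovers homogeneous flow
    Q = 0.5, T_frac = 0.5), numeric(1))
  adj <- 1
  if (!is.null(boots) && length(boots) >= 3 && d > 0) {
    sizes <- full$sizes
    ll_at <- function(v, dat) {
      p <- vec_to_params(v, full$model)
      composite_loglik(expected_jafs(p, sizes, control), dat)$loglik
    }
    score <- function(dat) {
      vapply(extra, function(nm) {
        h <- 1e-3
        vp <- v0; vp[nm] <- v0[nm] * exp(h)
        vm <- v0; vm[nm] <- v0[nm] * exp(-h)
        two_sided <- !(nm %in% c("M")) # M sits at its lower bound
        if (two_sided) (ll_at(vp, dat) - ll_at(vm, dat)) / (2 * h)
        else (ll_at(vp, dat) - ll_at(v0, dat)) / h
      }, numeric(1))
    }
    U <- t(vapply(boots, score, numeric(d)))
    J <- stats::cov(U)
    fn <- function(x) { v <- v0; v[extra] <- x; ll_at(v, full$data) }
    H <- -num_hessian_log(fn, v0[extra], rel_step = 1e-3)
    tr <- sum(diag(J %*% solve(H)))
    if (is.finite(tr) && tr > 0) adj <- d / tr
  }
  D_adj <- D * adj
  p <- if (boundary && d >= 1)
    0.5 * stats::pchisq(D_adj, df = d, lower.tail = FALSE) +
      0.5 * (if (d > 1) stats::pchisq(D_adj, df = d - 1, lower.tail = FALSE)
             else as.numeric(D_adj == 0))
  else stats::pchisq(D_adj, df = d, lower.tail = FALSE)
  if (D == 0) p <- 1
  list(statistic = D, statistic_adj = D_adj, df = d, p_value = p,
       boundary = boundary, adjustment = adj)
}

#' Fisher-information standard deviations of fitted parameters
#'
#' Numerical Hessian of the profile composite log-likelihood at the optimum
#' (central differences, relative step `1e-3`, i.e. uniform steps in
#' log-parameter space); standard deviations are the square roots of the
#' diagonal of the inverse information, mapped to the natural scale by the
#' delta method. Parameters at a bound are flagged with a warning.
#'
#' @param fit a `div_fit`.
#' @param control engine settings for the likelihood evaluations.
#' @param rel_step relative step for the central differences.
#' @return The fit, with `$fim` holding `sd` (natural scale), `sd_log`,
#'   the log-scale covariance matrix and a `one_sided` flag per parameter.
#' @export
fim_sd <- function(fit, control = fit$final_control, rel_step = 1e-3) {
  stopifnot(inherits(fit, "div_fit"))
  v <- fit$free
  pn <- names(v)
  fn <- function(x) {
    names(x) <- pn
    p <- vec_to_params(x, fit$model)
    composite_loglik(expected_jafs(p, fit$sizes, control), fit$data)$loglik
  }
  H <- num_hessian_log(fn, v, rel_step = rel_step)
  info <- -H
  ev <- eigen(info, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop(sprintf("information matrix not positive definite (condition number %.3g)",
                 max(ev) / abs(min(ev))))
  cov_log <- solve(info)
  sd_log <- sqrt(diag(cov_log))
  sd_nat <- sd_log * v
  names(sd_nat) <- names(sd_log) <- pn
  if (any(fit$at_bound))
    warning("parameter(s) at a bound: ",
            paste(pn[fit$at_bound], collapse = ", "),
            "; their uncertainties are one-sided")
  fit$fim <- list(sd = sd_nat, sd_log = sd_log, cov_log = cov_log,
                  one_sided = fit$at_bound)
  fit
}

#' Refit bootstrap spectra from the fitted optimum
#'
#' Local Nelder-Mead polish (no perturbation rounds) of each bootstrap
#' spectrum, started at the fitted parameters.
#'
#' @param fit a `div_fit`.
#' @param boots list of bootstrap [jafs] from [bootstrap_jafs()].
#' @param maxit iteration cap per replicate.
#' @return The fit with `$boot` set to a data.frame of one parameter row per
#'   replicate.
#' @export
bootstrap_params <- function(fit, boots, maxit = 300) {
  stopifnot(inherits(fit, "div_fit"))
  pn <- names(fit$free)
  llo <- log(fit$bounds$lower); lhi <- log(fit$bounds$upper)
  rows <- lapply(boots, function(b) {
    negll <- function(lv) {
      v <- exp(pmin(pmax(lv, llo), lhi)); names(v) <- pn
      -composite_loglik(expected_jafs(vec_to_params(v, fit$model), fit$sizes,
                                      fit$opt_control), b)$loglik
    }
    opt <- stats::optim(log(fit$free), negll, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-8))
    c(exp(opt$par), loglik = -opt$value)
  })
  tab <- as.data.frame(do.call(rbind, rows))
  names(tab) <- c(pn, "loglik")
  fit$boot <- tab
  fit
}
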