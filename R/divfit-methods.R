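# Methods for div_fit objects.

#' @export
print.div_fit <- function(x, ...) {
  cat(sprintf("Divergence model fit: %s\n", x$model))
  cat(sprintf("  log composite likelihood %.3f, AIC %.3f (k = %d)\n",
              x$loglik, x$aic, x$k))
  cat(sprintf("  theta_hat %.4g\n", x$theta_hat))
  cat("  parameters:\n")
  v <- x$free
  for (nm in names(v)) {
    sd <- if (!is.null(x$fim)) sprintf(" (sd %.3g)", x$fim$sd[[nm]]) else ""
    cat(sprintf("    %-7s %.4g%s%s\n", nm, v[[nm]], sd,
                if (x$at_bound[[nm]]) " [at bound]" else ""))
  }
  invisible(x)
}

#' @export
summary.div_fit <- function(object, ...) {
  tab <- data.frame(estimate = object$free)
  if (!is.null(object$fim)) {
    tab$sd <- object$fim$sd[rownames(tab)]
    tab$one_sided <- object$fim$one_sided[rownames(tab)]
  }
  if (!is.null(object$boot)) {
    q <- apply(object$boot[rownames(tab)], 2, stats::quantile,
               probs = c(0.025, 0.975))
    tab$boot_lo <- q[1, ]; tab$boot_hi <- q[2, ]
  }
  out <- list(model = object$model, coefficients = tab,
              loglik = object$loglik, aic = object$aic, k = object$k,
              theta_hat = object$theta_hat,
              n_sites = sum(object$data$counts[!object$data$mask]))
  class(out) <- "summary.div_fit"
  out
}

#' @export
print.summary.div_fit <- function(x, ...) {
  cat(sprintf("%s model, %.4g spectrum mass, lnL %.3f, AIC %.3f\n",
              x$model, x$n_sites, x$loglik, x$aic))
  print(x$coefficients)
  invisible(x)
}

#' @export
coef.div_fit <- function(object, ...) object$free

#' @export
logLik.div_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, class = "logLik")
}

#' @export
vcov.div_fit <- function(object, ...) {
  if (is.null(object$fim))
    stop("run fim_sd() first to compute the information matrix")
  v <- object$free
  # delta method from the log scale to the natural scale
  object$fim$cov_log * outer(v, v)
}

#' Pearson residuals of a fitted spectrum
#'
#' `(data - theta_hat * model) / sqrt(theta_hat * model)` per unmasked cell.
#'
#' @param object a `div_fit`.
#' @param ... unused.
#' @return A matrix with `NA` in masked cells.
#' @export
residuals.div_fit <- function(object, ...) {
  mu <- object$theta_hat * object$expected$counts
  r <- (object$data$counts - mu) / sqrt(pmax(mu, .Machine$double.eps))
  r[object$data$mask | object$expected$mask] <- NA
  r
}

#' @export
plot.div_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  show <- function(m, main, cols = grDevices::hcl.colors(64, "YlOrRd",
                                                         rev = TRUE)) {
    z <- m
    z[x$data$mask] <- NA
    graphics::image(0:x$sizes[1], 0:x$sizes[2],
                    z, col = cols, xlab = "pop1 allele count",
                    ylab = "pop2 allele count", main = main, useRaster = FALSE)
  }
  show(log1p(x$data$counts), "data (log1p)")
  show(log1p(x$theta_hat * x$expected$counts), "model (log1p)")
  r <- residuals(x)
  cols <- grDevices::hcl.colors(64, "Blue-Red 2")
  z <- r
  graphics::image(0:x$sizes[1], 0:x$sizes[2], z, col = cols,
                  xlab = "pop1 allele count", ylab = "pop2 allele count",
                  main = "Pearson residuals")
  invisible(x)
}

#' Simulate datasets from a fitted divergence model
#'
#' Draws structured-coalescent datasets at the fitted parameters via
#' [simulate_pair()].
#'
#' @param object a `div_fit`.
#' @param nsim number of datasets.
#' @param seed integer seed.
#' @param n_tags,theta_per_tag,tag_length generator settings.
#' @param ... unused.
#' @return A list of `sim_dataset` objects.
#' @export
simulate.div_fit <- function(object, nsim = 1, seed = 1, n_tags = 2000,
                             theta_per_tag = 1, tag_length = 110, ...) {
  p <- object$par
  lapply(seq_len(nsim), function(i) {
    sc <- sim_scenario(model = p$model, nu1 = p$nu1, nu2 = p$nu2,
                       T_total = p$T, M = max(p$M, 0), M_e = min(p$M_e, p$M),
                       Q = p$Q, T_phase = p$T_phase,
                       n1 = ceiling(object$sizes[1] / 2),
                       n2 = ceiling(object$sizes[2] / 2),
                       n_tags = n_tags, tag_length = tag_length,
                       theta_per_tag = theta_per_tag,
                       seed = derive_seed(seed, paste0("simfit", i)))
    simulate_pair(sc)
  })
}
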