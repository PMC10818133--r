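#' Total sequence length represented by a fitted SNP set
#'
#' RAD-tag datasets genotype `n_rad_tags * rad_tag_length` bases, but only
#' the fraction of originally detected SNPs that survives projection enters
#' the spectrum, so the effective length is scaled accordingly:
#' `L = snp_dadi * (n_rad_tags * rad_tag_length) / snp_original`.
#'
#' @param snp_dadi SNPs retained for the spectrum after projection.
#' @param snp_original SNPs originally detected.
#' @param n_rad_tags number of RAD tags.
#' @param rad_tag_length bases per tag.
#' @return Effective sequence length in bases.
#' @export
total_seq_length <- function(snp_dadi, snp_original, n_rad_tags,
                             rad_tag_length) {
  if (snp_original <= 0) stop("snp_original must be positive")
  if (snp_dadi > snp_original) stop("snp_dadi cannot exceed snp_original")
  if (snp_dadi == 0) warning("no SNPs retained: effective length is 0")
  snp_dadi * (n_rad_tags * rad_tag_length) / snp_original
}

#' Convert scaled fit parameters to demographic units
#'
#' Applies the standard conversions from the coalescent scaling to
#' demographic units: `N_ref = theta / (4 mu L)` individuals;
#' `nu_k = nu_k_scaled * N_ref` individuals; `m = M / (2 N_ref)` migrant
#' fraction per generation; `T = T_scaled * 2 * N_ref * T_gen` years;
#' `M21 = m * nu1` and `M12 = m * nu2` migrants per generation (from
#' population 2 into 1 and from 1 into 2 respectively). Defaults use a
#' mutation rate of `1.2e-8` per base per generation (an estimate for
#' Acroporid corals) and a 3-year generation time (young-reproducing
#' brooding corals); both are approximations and are recorded in the output.
#'
#' @param p a [dadi_params()] or `div_fit`.
#' @param theta fitted spectrum scaling (taken from the fit when `p` is a
#'   `div_fit`).
#' @param L effective sequence length in bases, from [total_seq_length()].
#' @param mu mutation rate per base per generation.
#' @param T_gen generation time in years.
#' @return A list of class `converted_params` with `N_ref`, `nu1`, `nu2`
#'   (individuals), `m`, `m_e` (per generation), `M21`, `M12` (migrants per
#'   generation), `T_years`, `Q`, `P` and the constants used.
#' @export
convert_params <- function(p, theta, L, mu = 1.2e-8, T_gen = 3) {
  if (inherits(p, "div_fit")) {
    if (missing(theta)) theta <- p$theta_hat
    p <- p$par
  }
  stopifnot(inherits(p, "dadi_params"))
  if (!(L > 0 && mu > 0 && T_gen > 0)) stop("L, mu, T_gen must be positive")
  if (theta <= 0) stop("theta must be positive")
  N_ref <- theta / (4 * mu * L)
  nu1 <- p$nu1 * N_ref
  nu2 <- p$nu2 * N_ref
  m <- p$M / (2 * N_ref)
  m_e <- p$M_e / (2 * N_ref)
  structure(list(model = p$model, N_ref = N_ref, nu1 = nu1, nu2 = nu2,
                 m = m, m_e = m_e, M21 = m * nu1, M12 = m * nu2,
                 T_years = p$T * 2 * N_ref * T_gen,
                 Q = p$Q, P = 1 - p$Q,
                 theta = theta, L = L, mu = mu, T_gen = T_gen),
            class = "converted_params")
}

# Algebraic inverse of convert_params (used for round-trip checks).
deconvert_params <- function(cp) {
  N_ref <- cp$N_ref
  theta <- N_ref * 4 * cp$mu * cp$L
  dadi_params(cp$model,
              nu1 = cp$nu1 / N_ref, nu2 = cp$nu2 / N_ref,
              T = cp$T_years / (2 * N_ref * cp$T_gen),
              M = cp$m * 2 * N_ref,
              M_e = cp$m_e * 2 * N_ref,
              Q = cp$Q)
}

#' Gene-flow rates from printed migration fraction and sizes
#'
#' The number of migrants entering each population per generation from a
#' per-generation migrant fraction `m` and population sizes in individuals:
#' `M21 = m * nu1` (into population 1), `M12 = m * nu2` (into population 2),
#' reported at a chosen number of significant figures (demographic tables
#' conventionally print two).
#'
#' @param m migrant fraction per generation.
#' @param nu1,nu2 population sizes in individuals.
#' @param digits significant figures for reporting (default 2).
#' @return A named vector `c(M21, M12)`.
#' @export
gene_flow_rates <- function(m, nu1, nu2, digits = 2) {
  c(M21 = signif(m * nu1, digits), M12 = signif(m * nu2, digits))
}

#' @export
print.converted_params <- function(x, digits = 2, ...) {
  cat(sprintf("converted %s parameters (mu = %g, T_gen = %g y, L = %g bp):\n",
              x$model, x$mu, x$T_gen, x$L))
  cat(sprintf("  N_ref %s  nu1 %s  nu2 %s individuals\n",
              signif(x$N_ref, digits), signif(x$nu1, digits),
              signif(x$nu2, digits)))
  cat(sprintf("  m %s per generation (m_e %s); M21 %s, M12 %s migrants/gen\n",
              signif(x$m, digits), signif(x$m_e, digits),
              signif(x$M21, digits), signif(x$M12, digits)))
  cat(sprintf("  T %s years", signif(x$T_years, digits)))
  if (x$model == "IM2M")
    cat(sprintf("; P %s, Q %s", signif(x$P, digits), signif(x$Q, digits)))
  cat("\n")
  invisible(x)
}
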