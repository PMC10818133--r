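# Expected-JAFS diffusion engine.
#
# The joint density phi(x, y) of derived-allele frequencies in the two
# populations is integrated forward in time under drift, symmetric migration
# and new-mutation influx, starting from the single-population neutral
# equilibrium density phi(x) = theta0 / x placed on the diagonal at the
# split.  The expected spectrum is the binomial sampling integral of phi.
# Accuracy is controlled by evaluating on a sequence of boundary-crowded
# grids and Richardson-extrapolating each spectrum cell to zero grid spacing
# (the time step is tied to the grid so its first-order error extrapolates
# away together with the spatial error).

#' Engine settings for expected-spectrum computation
#'
#' @param pts grid sizes for the frequency mesh; with more than one value the
#'   spectrum is Richardson-extrapolated to zero spacing across them.
#'   Defaults `(60, 70, 80)` with quadratic extrapolation.
#' @param dt_fac time-step multiplier: the step is `dt_fac` times the first
#'   interior grid point (so halving the spacing also refines the step).
#' @return A list of class `engine_control`.
#' @export
engine_control <- function(pts = c(60, 70, 80), dt_fac = 3) {
  stopifnot(length(pts) >= 1, all(pts >= 20), dt_fac > 0)
  structure(list(pts = sort(pts), dt_fac = dt_fac), class = "engine_control")
}

# Boundary-crowded frequency grid on [0, 1] (Chebyshev-extrema spacing).
default_grid <- function(pts) {
  u <- seq(0, 1, length.out = pts)
  (1 - cos(pi * u)) / 2
}

# Neutral equilibrium density theta0/x placed on the 2-D diagonal.
phi_split <- function(xx, theta0 = 1) {
  G <- length(xx)
  phi1 <- c(0, theta0 / xx[-1])
  delta <- numeric(G)
  delta[1] <- (xx[2] - xx[1]) / 2
  delta[G] <- (xx[G] - xx[G - 1]) / 2
  delta[2:(G - 1)] <- (xx[3:G] - xx[1:(G - 2)]) / 2
  phi2 <- matrix(0, G, G)
  diag(phi2) <- phi1 / delta
  phi2
}

# Forward-time epochs (duration, migration) for a parameter set.
forward_epochs <- function(p) {
  switch(p$model,
    SI = list(list(dur = p$T, mig = 0)),
    IM = list(list(dur = p$T, mig = p$M)),
    IM2M = list(list(dur = p$T, mig = p$M)),   # reduced class handled by mixture
    SC = list(list(dur = p$T - p$T_phase, mig = 0),
              list(dur = p$T_phase, mig = p$M)),
    AM = list(list(dur = p$T - p$T_phase, mig = p$M),
              list(dur = p$T_phase, mig = 0)))
}

# Single-grid expected spectrum for one migration history.
spectrum_one_grid <- function(epochs, nu1, nu2, sizes, pts, dt_fac) {
  xx <- default_grid(pts)
  dt0 <- dt_fac * xx[2]
  phi <- phi_split(xx)
  for (e in epochs)
    if (e$dur > 0)
      phi <- phi_integrate_cpp(phi, xx, e$dur, nu1, nu2, e$mig, 1, dt0)
  phi_to_spectrum_cpp(phi, xx, sizes[1], sizes[2])
}

# Richardson extrapolation of per-cell spectra to zero grid spacing, using
# the first interior grid point as the spacing measure.
extrapolate_spectra <- function(specs, us) {
  k <- length(specs)
  if (k == 1) return(specs[[1]])
  S <- 0
  for (g in seq_len(k)) {
    w <- prod(-us[-g] / (us[g] - us[-g]))
    S <- S + w * specs[[g]]
  }
  S
}

#' Expected joint allele-frequency spectrum under a divergence model
#'
#' Computes the normalised expected folded spectrum for a parameter set by
#' numerical diffusion approximation. For `IM2M` the spectrum is the mixture
#' `(1 - Q) * E[JAFS | M] + Q * E[JAFS | M_e]` computed on shared grids.
#' Deterministic for fixed engine settings. The independent Monte-Carlo
#' oracle is [expected_jafs_mc()].
#'
#' @param p a [dadi_params()] parameter set.
#' @param sizes haploid sample sizes `(n1, n2)` of the spectrum.
#' @param control an [engine_control()].
#' @param fold fold the spectrum (default `TRUE`).
#' @param normalise scale to unit mass over unmasked cells (default `TRUE`).
#' @return A [jafs] object of expected densities.
#' @export
expected_jafs <- function(p, sizes, control = engine_control(), fold = TRUE,
                          normalise = TRUE) {
  stopifnot(inherits(p, "dadi_params"), length(sizes) == 2)
  pts <- control$pts
  us <- vapply(pts, function(G) default_grid(G)[2], numeric(1))
  run <- function(par) {
    specs <- lapply(pts, function(G)
      spectrum_one_grid(forward_epochs(par), par$nu1, par$nu2, sizes, G,
                        control$dt_fac))
    extrapolate_spectra(specs, us)
  }
  S <- run(p)
  if (p$model == "IM2M" && p$Q > 0) {
    p_red <- p; p_red$M <- p$M_e; p_red$model <- "IM"
    S <- (1 - p$Q) * S + p$Q * run(p_red)
  }
  S[S < 0] <- 0
  out <- jafs(S, folded = FALSE)
  if (fold) out <- fold_jafs(out)
  if (normalise) {
    tot <- sum(out$counts[!out$mask])
    if (!is.finite(tot) || tot <= 0)
      stop("expected spectrum has no usable mass; engine settings too coarse")
    out$counts <- out$counts / tot
  }
  out
}
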