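# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

#' Derive an independent per-stage seed from a global seed
#'
#' Counter-based derivation of stage seeds from one global seed, so that
#' adding a stage to a pipeline does not perturb the draws of earlier
#' stages. Always returns a non-negative integer below `2^31`.
#'
#' @param seed integer global seed.
#' @param stage character stage label.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 1103) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Central-difference numerical Hessian of fn at x in log-parameter space
# (steps are relative, i.e. uniform in log x). fn takes the natural-scale
# vector. Returns the Hessian with respect to log(x).
num_hessian_log <- function(fn, x, rel_step = 1e-3) {
  stopifnot(all(x > 0))
  lx <- log(x)
  p <- length(x)
  h <- rep(rel_step, p)
  f0 <- fn(x)
  H <- matrix(NA_real_, p, p)
  for (i in seq_len(p)) {
    ei <- replace(numeric(p), i, h[i])
    fpp <- fn(exp(lx + ei)); fmm <- fn(exp(lx - ei))
    H[i, i] <- (fpp - 2 * f0 + fmm) / h[i]^2
    if (i > 1) for (j in seq_len(i - 1)) {
      ej <- replace(numeric(p), j, h[j])
      fa <- fn(exp(lx + ei + ej)); fb <- fn(exp(lx + ei - ej))
      fc <- fn(exp(lx - ei + ej)); fd <- fn(exp(lx - ei - ej))
      H[i, j] <- H[j, i] <- (fa - fb - fc + fd) / (4 * h[i] * h[j])
    }
  }
  H
}
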