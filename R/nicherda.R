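# Genotype-environment association by partial redundancy analysis with
# spatial conditioning.  The ordination machinery is vegan's (rda,
# anova.cca, varpart, spantree); this module assembles the response and
# conditioning matrices, runs forward selection with the double stopping
# rule, and reports variance partitions.

#' Hellinger transformation
#'
#' Each entry becomes the square root of its row-proportion:
#' `sqrt(x / rowSums(x))`, so every transformed row has unit sum of squares.
#'
#' @param freqs non-negative matrix (individuals x alleles/frequencies).
#' @return The transformed matrix.
#' @export
hellinger <- function(freqs) {
  freqs <- as.matrix(freqs)
  rs <- rowSums(freqs)
  if (any(rs <= 0)) stop("rows must have positive sums")
  sqrt(sweep(freqs, 1, rs, "/"))
}

#' Genotypes to a complete-case allele-frequency response matrix
#'
#' Keeps only sites genotyped in every individual (the ordination cannot
#' carry missing cells), converts dosages to within-individual alternate
#' allele frequencies (dosage / 2) and appends the complementary reference
#' frequencies so rows sum to the site count, then Hellinger-transforms.
#'
#' @param gm a [geno_matrix()].
#' @return The transformed response matrix (individuals x 2*sites).
#' @export
rda_response <- function(gm) {
  complete <- colSums(is.na(gm$dosage)) == 0
  if (!any(complete)) stop("no complete-case sites")
  X <- gm$dosage[, complete, drop = FALSE] / 2
  Y <- cbind(X, 1 - X)
  colnames(Y) <- c(paste0(colnames(gm$dosage)[complete], "_alt"),
                   paste0(colnames(gm$dosage)[complete], "_ref"))
  hellinger(Y)
}

#' Standardise environmental variables and screen collinearity
#'
#' Centres and scales each variable and reports pairwise Pearson
#' correlations; variables exceeding the collinearity threshold against an
#' earlier-listed variable are flagged (and dropped if `drop = TRUE`).
#'
#' @param env data.frame or matrix, individuals x variables.
#' @param r_max collinearity threshold (default 0.70).
#' @param drop drop flagged variables (default `FALSE`: flag only).
#' @return The standardised matrix with attributes `"correlations"` and
#'   `"collinear"`.
#' @export
env_matrix <- function(env, r_max = 0.70, drop = FALSE) {
  X <- scale(as.matrix(env))
  R <- stats::cor(X)
  coll <- character(0)
  p <- ncol(X)
  if (p > 1) for (j in 2:p) {
    if (any(abs(R[j, seq_len(j - 1)]) >= r_max)) coll <- c(coll, colnames(X)[j])
  }
  if (drop && length(coll)) X <- X[, setdiff(colnames(X), coll), drop = FALSE]
  attr(X, "correlations") <- R
  attr(X, "collinear") <- coll
  X
}

#' Distance-based Moran's eigenvector maps
#'
#' Builds the spatial eigenfunction basis used to absorb spatial
#' autocorrelation: Euclidean distances are truncated at the longest edge of
#' the minimum spanning tree (larger distances replaced by four times the
#' truncation), the truncated matrix is double-centred and
#' eigen-decomposed, and eigenvectors with positive eigenvalues are
#' retained.
#'
#' @param coords matrix or data.frame of (x, y) coordinates (a `sim_dataset`
#'   `coords` table may be passed directly).
#' @param seed seed for the infinitesimal jitter applied when duplicate
#'   coordinates collapse the distance matrix.
#' @return A list of class `mem_basis` with `vectors` (individuals x
#'   retained), `values` and `truncation`.
#' @export
dbmem <- function(coords, seed = 1) {
  if (is.data.frame(coords) && all(c("x", "y") %in% names(coords)))
    coords <- as.matrix(coords[, c("x", "y")])
  coords <- as.matrix(coords)
  if (anyDuplicated(coords)) {
    message("duplicate coordinates: applying infinitesimal jitter")
    coords <- with_seed(seed,
      coords + matrix(stats::rnorm(length(coords), sd = 1e-9), nrow(coords)))
  }
  d <- stats::dist(coords)
  trunc <- max(vegan::spantree(d)$dist)
  pc <- vegan::pcnm(d, threshold = trunc)
  # pcnm already returns only the positive-eigenvalue vectors
  npos <- ncol(pc$vectors)
  structure(list(vectors = pc$vectors[, seq_len(npos), drop = FALSE],
                 values = pc$values[seq_len(npos)], truncation = trunc),
            class = "mem_basis")
}

#' @export
print.mem_basis <- function(x, ...) {
  cat(sprintf("dbMEM basis: %d positive-eigenvalue vectors, truncation %.4g\n",
              ncol(x$vectors), x$truncation))
  invisible(x)
}

as_cond_matrix <- function(Z, n_mem = NULL) {
  if (is.null(Z)) return(NULL)
  if (inherits(Z, "mem_basis")) Z <- Z$vectors
  Z <- as.matrix(Z)
  if (!is.null(n_mem)) Z <- Z[, seq_len(min(n_mem, ncol(Z))), drop = FALSE]
  Z
}

#' Partial redundancy analysis
#'
#' Redundancy analysis of a (Hellinger-transformed) response on
#' environmental predictors after removing conditioning (spatial)
#' covariates: both sides are residualised on `Z` by least squares and the
#' canonical axes are the eigenvectors of the fitted-value covariance.
#' Adjusted R-squared uses the Ezekiel correction.
#'
#' @param Y response matrix (e.g. [rda_response()]).
#' @param X predictor matrix (e.g. [env_matrix()]).
#' @param Z conditioning matrix, [dbmem()] basis, or `NULL` for an
#'   unconditioned RDA.
#' @param n_mem optionally use only the first `n_mem` conditioning vectors.
#' @return A list of class `rda_result` wrapping the vegan ordination, with
#'   `r2`, `adj_r2`, `site_scores`, `biplot_scores`, eigenvalues and the
#'   aligned inputs.
#' @export
partial_rda <- function(Y, X, Z = NULL, n_mem = NULL) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  Z <- as_cond_matrix(Z, n_mem)
  ord <- if (is.null(Z)) vegan::rda(Y, X) else vegan::rda(Y, X, Z)
  r2 <- vegan::RsquareAdj(ord)
  ax <- vegan::scores(ord, display = "sites",
                      choices = seq_len(max(1, ord$CCA$rank)))
  lc <- vegan::scores(ord, display = "lc",
                      choices = seq_len(max(1, ord$CCA$rank)))
  structure(list(ord = ord, r2 = r2$r.squared, adj_r2 = r2$adj.r.squared,
                 site_scores = ax, lc_scores = lc,
                 biplot_scores = vegan::scores(ord, display = "bp",
                                               choices = seq_len(max(1, ord$CCA$rank))),
                 eig = ord$CCA$eig, Y = Y, X = X, Z = Z),
            class = "rda_result")
}

#' @export
print.rda_result <- function(x, ...) {
  cat(sprintf("partial RDA: %d predictors, %s conditioning, R2 %.4f, adj R2 %.4f\n",
              ncol(x$X), if (is.null(x$Z)) "no" else paste0(ncol(x$Z), "-vector"),
              x$r2, x$adj_r2))
  invisible(x)
}

#' Permutation test of a (partial) RDA
#'
#' Permutes the rows of the residualised response with the conditioning held
#' fixed (vegan's reduced-model scheme) and reports pseudo-F with
#' `p = (exceedances + 1) / (n_perm + 1)`.
#'
#' @param rdares an [partial_rda()] result.
#' @param n_perm number of permutations.
#' @param scope `"global"` (whole model), `"axis"` or `"term"`.
#' @param seed integer seed.
#' @return A data.frame with `F` and `p_value` per tested component.
#' @export
permutation_test <- function(rdares, n_perm = 999,
                             scope = c("global", "axis", "term"), seed = 1) {
  scope <- match.arg(scope)
  by <- switch(scope, global = NULL, axis = "axis", term = "terms")
  an <- with_seed(seed,
    vegan::anova.cca(rdares$ord, permutations = n_perm, by = by))
  out <- data.frame(component = rownames(an), F = an$F,
                    p_value = an[["Pr(>F)"]])
  out[!is.na(out$F), , drop = FALSE]
}

#' Forward selection of environmental predictors
#'
#' Adds variables one at a time (largest marginal fit first) under the
#' double stopping rule: stop when the best candidate's permutation p-value
#' reaches `alpha`, or when the cumulative adjusted R-squared of the
#' selected set exceeds that of the full model (`r2_stop = TRUE`).
#'
#' @param Y,X,Z as in [partial_rda()].
#' @param alpha significance threshold for adding a variable.
#' @param r2_stop enforce the adjusted-R-squared stopping criterion.
#' @param n_perm permutations per candidate test.
#' @param seed integer seed.
#' @return Character vector of selected variable names (attribute `"trace"`
#'   records each step).
#' @export
forward_select <- function(Y, X, Z = NULL, alpha = 0.05, r2_stop = TRUE,
                           n_perm = 999, seed = 1) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  Z <- as_cond_matrix(Z)
  vars <- colnames(X) %||% paste0("X", seq_len(ncol(X)))
  colnames(X) <- vars
  full_adj <- partial_rda(Y, X, Z)$adj_r2
  selected <- character(0)
  trace <- NULL
  with_seed(seed, {
    repeat {
      remaining <- setdiff(vars, selected)
      if (!length(remaining)) break
      cond <- cbind(Z, X[, selected, drop = FALSE])
      if (!is.null(cond) && ncol(cond) == 0) cond <- NULL
      stat <- lapply(remaining, function(v) {
        r <- partial_rda(Y, X[, v, drop = FALSE], cond)
        an <- vegan::anova.cca(r$ord, permutations = n_perm)
        list(F = an$F[1], p = an[["Pr(>F)"]][1])
      })
      Fs <- vapply(stat, `[[`, numeric(1), "F")
      best <- which.max(Fs)
      p_best <- stat[[best]]$p
      cand <- c(selected, remaining[best])
      adj_cand <- partial_rda(Y, X[, cand, drop = FALSE], Z)$adj_r2
      trace <- rbind(trace, data.frame(variable = remaining[best],
                                       F = Fs[best], p_value = p_best,
                                       cum_adj_r2 = adj_cand))
      if (p_best >= alpha) break
      selected <- cand
      # adjusted-R2 cap: do not continue past the full model's fit
      if (r2_stop && adj_cand > full_adj) break
    }
  })
  structure(selected, trace = trace, full_adj_r2 = full_adj)
}

#' Variance partition between environment and space
#'
#' Adjusted-R-squared partition of the response into pure-environment,
#' pure-space, shared and unexplained fractions from the three nested
#' models (joint, environment-given-space, space-given-environment).
#'
#' @param Y,X,Z as in [partial_rda()] (`Z` required here).
#' @return A named vector with `pure_env`, `pure_space`, `shared`,
#'   `unexplained` and `total_adj_r2` (joint model).
#' @export
variance_partition <- function(Y, X, Z) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  Z <- as_cond_matrix(Z)
  if (is.null(Z)) stop("variance partition needs a conditioning matrix")
  joint <- partial_rda(Y, cbind(X, Z))$adj_r2
  pure_env <- partial_rda(Y, X, Z)$adj_r2
  pure_space <- partial_rda(Y, Z, X)$adj_r2
  shared <- joint - pure_env - pure_space
  c(pure_env = pure_env, pure_space = pure_space, shared = shared,
    unexplained = 1 - joint, total_adj_r2 = joint)
}
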