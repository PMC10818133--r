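#' Weir-Cockerham F_ST between two populations
#'
#' Per-site variance components for diploids — `a` (among populations), `b`
#' (among individuals within populations), `c` (within individuals, from
#' observed heterozygosity) — with the genome-wide estimate computed as the
#' ratio of sums `sum(a) / sum(a + b + c)` across sites. Sites need at least
#' two genotyped individuals in each population to contribute. Negative
#' per-locus values are retained.
#'
#' @param gm a [geno_matrix()].
#' @param pops character vector of the two population labels.
#' @param per_locus also return the per-site values.
#' @return A list with `fst` (global) and, if requested, `per_locus` (named
#'   numeric vector, `NA` for non-contributing sites) and the summed
#'   variance components.
#' @export
wc_fst <- function(gm, pops, per_locus = FALSE) {
  stopifnot(length(pops) == 2)
  i1 <- which(gm$ind_meta$population == pops[1])
  i2 <- which(gm$ind_meta$population == pops[2])
  if (!length(i1) || !length(i2)) stop("population label not found")
  D1 <- gm$dosage[i1, , drop = FALSE]
  D2 <- gm$dosage[i2, , drop = FALSE]
  n1 <- colSums(!is.na(D1)); n2 <- colSums(!is.na(D2))
  ok <- n1 >= 2 & n2 >= 2
  p1 <- colSums(D1, na.rm = TRUE) / (2 * n1)
  p2 <- colSums(D2, na.rm = TRUE) / (2 * n2)
  h1 <- colMeans(D1 == 1, na.rm = TRUE)
  h2 <- colMeans(D2 == 1, na.rm = TRUE)
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a[!ok] <- b[!ok] <- cc[!ok] <- NA
  denom <- a + b + cc
  fst <- sum(a[ok]) / sum(denom[ok])
  out <- list(fst = fst, a_sum = sum(a[ok]), abc_sum = sum(denom[ok]))
  if (per_locus) {
    pl <- a / denom
    names(pl) <- colnames(gm$dosage)
    out$per_locus <- pl
  }
  out
}

#' Pairwise squared Euclidean genetic distances at a reef
#'
#' Distances between all individuals sharing a reef label, computed on
#' dosage vectors restricted to sites co-called in both individuals and
#' scaled by `total sites / co-called sites` so pairs with different
#' missingness remain comparable.
#'
#' @param gm a [geno_matrix()].
#' @param reef_label reef to analyse.
#' @return A data.frame of class `pair_distances` with columns `ind_i`,
#'   `ind_j`, `distance`, `co_called`.
#' @export
pair_distances <- function(gm, reef_label) {
  idx <- which(gm$ind_meta$reef == reef_label)
  if (length(idx) < 2) stop("need at least two individuals at the reef")
  D <- gm$dosage[idx, , drop = FALSE]
  S <- ncol(D)
  n <- length(idx)
  res <- list(); k <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    cc <- !is.na(D[i, ]) & !is.na(D[j, ])
    ncc <- sum(cc)
    d <- if (ncc == 0) NA_real_
    else sum((D[i, cc] - D[j, cc])^2) * S / ncc
    k <- k + 1
    res[[k]] <- data.frame(ind_i = gm$ind_meta$id[idx[i]],
                           ind_j = gm$ind_meta$id[idx[j]],
                           distance = d, co_called = ncc)
  }
  out <- do.call(rbind, res)
  attr(out, "reef") <- reef_label
  attr(out, "n_sites") <- S
  class(out) <- c("pair_distances", "data.frame")
  out
}

#' Multi-peak gap detection in a distance distribution
#'
#' Fits a Gaussian kernel density (Silverman's bandwidth) to the pairwise
#' distances and finds local maxima (peaks) and the local minima between
#' them; a minimum is a "gap" when its density falls below `gap_frac` of the
#' smaller adjacent peak, the analogue of the DNA-barcode gap separating
#' within-taxon from between-taxon comparisons. Pairs below the first gap
#' are labelled conspecific, pairs above heterospecific.
#'
#' Modes that are not separated by a qualifying gap are counted as one peak,
#' so `n_peaks` is the number of gap-separated components (`n_gaps + 1`);
#' the raw density maxima are returned in `modes`.
#'
#' @param d a [pair_distances()] table (or numeric vector of distances).
#' @param gap_frac relative-depth criterion for a gap (default 0.1).
#' @return A list with `n_peaks`, `peaks` (highest mode per component),
#'   `modes` (all raw density maxima), `gaps` (distance locations) and
#'   `assignment` per pair.
#' @export
distance_gap_peaks <- function(d, gap_frac = 0.1) {
  x <- if (inherits(d, "pair_distances")) d$distance else as.numeric(d)
  x <- x[is.finite(x)]
  if (length(x) < 3) stop("need at least three pairwise distances")
  if (stats::sd(x) == 0 || length(unique(x)) == 1)
    return(list(n_peaks = 1L, peaks = x[1], modes = x[1], gaps = numeric(0),
                assignment = rep("conspecific", length(x))))
  de <- stats::density(x, bw = "nrd0")
  y <- de$y; g <- de$x
  n <- length(y)
  is_max <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1
  if (y[1] > y[2]) is_max <- c(1, is_max)
  if (y[n] > y[n - 1]) is_max <- c(is_max, n)
  gaps <- numeric(0)
  # components of modes separated by qualifying gaps
  comp <- rep(1L, length(is_max))
  if (length(is_max) >= 2) {
    for (k in seq_len(length(is_max) - 1)) {
      seg <- seq(is_max[k], is_max[k + 1])
      imin <- seg[which.min(y[seg])]
      # depth relative to the highest mode on each side within components
      left <- max(y[is_max[comp == comp[k] & seq_along(is_max) <= k]])
      right <- y[is_max[k + 1]]
      if (y[imin] < gap_frac * min(left, right)) {
        gaps <- c(gaps, g[imin])
        comp[(k + 1):length(comp)] <- comp[k] + 1L
      } else comp[k + 1] <- comp[k]
    }
  }
  peaks <- vapply(unique(comp), function(cc) {
    mm <- is_max[comp == cc]
    g[mm[which.max(y[mm])]]
  }, numeric(1))
  assignment <- if (length(gaps))
    ifelse(x <= gaps[1], "conspecific", "heterospecific")
  else rep("conspecific", length(x))
  list(n_peaks = length(unique(comp)), peaks = peaks, modes = g[is_max],
       gaps = gaps, assignment = assignment)
}

#' Windowed absolute divergence D_XY
#'
#' Per site, with alternate-allele counts `c_k` out of `n_k` called alleles
#' in population `k`, the between-population difference count is
#' `c1 * (n2 - c2) + (n1 - c1) * c2` and the comparison count `n1 * n2`;
#' windows tile each contig in fixed steps (default 1000 bp, window `w`
#' covering positions `[start, start + w - 1]`) and `D_XY` is the ratio of
#' summed differences to summed comparisons. The input must include
#' invariant sites (an all-sites matrix per RAD tag), otherwise divergence
#' per base is overestimated.
#'
#' @param gm a [geno_matrix()] including invariant sites.
#' @param pops the two population labels.
#' @param window window width in bp.
#' @return A data.frame with one row per window: `contig`, `start`, `end`,
#'   `diff_sum`, `comp_sum`, `dxy` (`NA` where no comparisons).
#' @export
dxy_windows <- function(gm, pops, window = 1000) {
  stopifnot(length(pops) == 2)
  i1 <- which(gm$ind_meta$population == pops[1])
  i2 <- which(gm$ind_meta$population == pops[2])
  if (!length(i1) || !length(i2)) stop("population label not found")
  D1 <- gm$dosage[i1, , drop = FALSE]
  D2 <- gm$dosage[i2, , drop = FALSE]
  n1 <- 2 * colSums(!is.na(D1)); c1 <- colSums(D1, na.rm = TRUE)
  n2 <- 2 * colSums(!is.na(D2)); c2 <- colSums(D2, na.rm = TRUE)
  diffs <- c1 * (n2 - c2) + (n1 - c1) * c2
  comps <- n1 * n2
  win_start <- (gm$site_meta$pos - 1) %/% window * window + 1
  key <- paste(gm$site_meta$contig, win_start, sep = "@")
  ds <- tapply(diffs, key, sum)
  cs <- tapply(comps, key, sum)
  parts <- strsplit(names(ds), "@", fixed = TRUE)
  out <- data.frame(contig = vapply(parts, `[`, "", 1),
                    start = as.integer(vapply(parts, `[`, "", 2)),
                    diff_sum = as.numeric(ds), comp_sum = as.numeric(cs))
  out$end <- out$start + window - 1L
  out$dxy <- ifelse(out$comp_sum > 0, out$diff_sum / out$comp_sum, NA_real_)
  out <- out[order(out$contig, out$start),
             c("contig", "start", "end", "diff_sum", "comp_sum", "dxy")]
  rownames(out) <- NULL
  out
}

#' Genome-wide D_XY from window statistics
#'
#' Count-weighted ratio of sums over all windows with comparisons (not the
#' unweighted mean of window values).
#'
#' @param ws a [dxy_windows()] table.
#' @return A single number.
#' @export
dxy_genomewide <- function(ws) {
  ok <- ws$comp_sum > 0
  sum(ws$diff_sum[ok]) / sum(ws$comp_sum[ok])
}

#' Taxon assignment by PCA and K-means
#'
#' Mean-imputes missing dosages per site, centres, takes principal
#' components of the individual covariance, and K-means-clusters the leading
#' axis scores (multiple restarts under a fixed seed).
#'
#' @param gm a [geno_matrix()].
#' @param k number of clusters.
#' @param n_axes number of PC axes used (default 10, capped at the rank).
#' @param seed integer seed for the K-means restarts.
#' @param nstart K-means restarts.
#' @return A list with `labels`, `pcs` (scores), `var_explained`, `inertia`.
#' @export
pca_kmeans_assign <- function(gm, k, n_axes = 10, seed = 1, nstart = 20) {
  X <- gm$dosage
  n <- nrow(X)
  if (k > n) stop("more clusters than individuals")
  mu <- colMeans(X, na.rm = TRUE)
  for (s in seq_len(ncol(X))) X[is.na(X[, s]), s] <- mu[s]
  X <- scale(X, center = TRUE, scale = FALSE)
  pc <- stats::prcomp(X, center = FALSE)
  n_axes <- min(n_axes, ncol(pc$x))
  scores <- pc$x[, seq_len(n_axes), drop = FALSE]
  km <- with_seed(seed, stats::kmeans(scores, centers = k, nstart = nstart))
  list(labels = stats::setNames(km$cluster, gm$ind_meta$id),
       pcs = scores,
       var_explained = pc$sdev^2 / sum(pc$sdev^2),
       inertia = km$tot.withinss)
}
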