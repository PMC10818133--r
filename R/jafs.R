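#' Joint allele-frequency spectrum (JAFS) objects
#'
#' A JAFS is an `(n1 + 1) x (n2 + 1)` table of site counts (or expected
#' densities) indexed by the derived/alternate allele count in each of two
#' populations, `n1` and `n2` being haploid sample sizes. A logical mask
#' marks cells excluded from all sums: the monomorphic corners `(0, 0)` and
#' `(n1, n2)` always, the redundant partner cells of a folded spectrum, and
#' any cells masked by [mask_low_counts()].
#'
#' @param counts numeric matrix, `(n1 + 1) x (n2 + 1)`.
#' @param folded logical; is the spectrum folded onto minor-allele classes?
#' @param mask optional logical matrix of additional masked cells.
#' @return An object of class `jafs`.
#' @export
jafs <- function(counts, folded = FALSE, mask = NULL) {
  counts <- as.matrix(counts)
  n1 <- nrow(counts) - 1L
  n2 <- ncol(counts) - 1L
  m <- matrix(FALSE, n1 + 1L, n2 + 1L)
  m[1, 1] <- TRUE
  m[n1 + 1L, n2 + 1L] <- TRUE
  if (folded) {
    tot <- outer(0:n1, 0:n2, "+")
    m[tot > (n1 + n2) / 2] <- TRUE
  }
  if (!is.null(mask)) m <- m | mask
  dimnames(counts) <- list(0:n1, 0:n2)
  structure(list(counts = counts, mask = m, n1 = n1, n2 = n2,
                 folded = folded, se = NULL,
                 n_sites_used = NA_real_, n_sites_dropped = NA_real_,
                 projection = c(n1, n2)),
            class = "jafs")
}

#' @export
print.jafs <- function(x, ...) {
  cat(sprintf("jafs: sample sizes (%d, %d) haploid, %s, %.6g unmasked mass",
              x$n1, x$n2, if (x$folded) "folded" else "unfolded",
              sum(x$counts[!x$mask])))
  if (!is.na(x$n_sites_used))
    cat(sprintf(" (%g sites used, %g dropped)", x$n_sites_used,
                x$n_sites_dropped))
  cat("\n")
  invisible(x)
}

#' Build a two-population JAFS from genotypes
#'
#' Each site contributes the hypergeometric expectation of its down-sampled
#' joint allele counts (the standard projection to sample sizes `(n1', n2')`
#' in haploid copies), which lets sites with missing genotypes contribute.
#' Sites with fewer called alleles than the projection size in either
#' population are dropped and tallied. Genotypes are unpolarised, so the
#' spectrum is built on arbitrary ref/alt orientation and then folded
#' (exact for folded analyses); singleton/doubleton masking is applied by
#' default via [mask_low_counts()].
#'
#' @param gm a [geno_matrix()].
#' @param pops character vector of the two population labels.
#' @param projection integer vector `(n1', n2')` of haploid projection sizes;
#'   default is the full sample size of each population.
#' @param fold fold the spectrum (default `TRUE`).
#' @param mask_low apply [mask_low_counts()] (default `TRUE`).
#' @param mask_diagonal_doubleton also mask the `(1, 1)` cell (default
#'   `TRUE`); see [mask_low_counts()].
#' @return A [jafs] object.
#' @export
build_jafs <- function(gm, pops, projection = NULL, fold = TRUE,
                       mask_low = TRUE, mask_diagonal_doubleton = TRUE) {
  stopifnot(length(pops) == 2)
  i1 <- which(gm$ind_meta$population == pops[1])
  i2 <- which(gm$ind_meta$population == pops[2])
  if (!length(i1) || !length(i2)) stop("population label not found")
  if (is.null(projection)) projection <- c(2L * length(i1), 2L * length(i2))
  np1 <- projection[1]; np2 <- projection[2]
  if (np1 > 2 * length(i1) || np2 > 2 * length(i2))
    stop("projection size exceeds available alleles")
  D1 <- gm$dosage[i1, , drop = FALSE]
  D2 <- gm$dosage[i2, , drop = FALSE]
  a1 <- 2 * colSums(!is.na(D1)); c1 <- colSums(D1, na.rm = TRUE)
  a2 <- 2 * colSums(!is.na(D2)); c2 <- colSums(D2, na.rm = TRUE)
  usable <- a1 >= np1 & a2 >= np2
  if (!any(usable)) stop("no site retains enough called alleles for this projection")
  counts <- matrix(0, np1 + 1, np2 + 1)
  # P(i alt in subsample of np from a alleles with c alt) = dhyper
  for (s in which(usable)) {
    p1 <- stats::dhyper(0:np1, c1[s], a1[s] - c1[s], np1)
    p2 <- stats::dhyper(0:np2, c2[s], a2[s] - c2[s], np2)
    counts <- counts + outer(p1, p2)
  }
  out <- jafs(counts, folded = FALSE)
  out$n_sites_used <- sum(usable)
  out$n_sites_dropped <- sum(!usable)
  out$projection <- c(np1, np2)
  if (fold) out <- fold_jafs(out)
  if (mask_low) out <- mask_low_counts(out, diagonal = mask_diagonal_doubleton)
  out
}

#' Fold a JAFS onto minor-allele classes
#'
#' Cell `(i, j)` with `i + j > (n1 + n2) / 2` is added into its partner
#' `(n1 - i, n2 - j)`; cells exactly on the fold line keep the symmetrised
#' half-weight. Mass over unmasked cells is conserved. Folding an already
#' folded spectrum is a no-op with a warning.
#'
#' @param s a [jafs] object.
#' @return The folded [jafs].
#' @export
fold_jafs <- function(s) {
  stopifnot(inherits(s, "jafs"))
  if (s$folded) {
    warning("spectrum is already folded; returning unchanged")
    return(s)
  }
  n1 <- s$n1; n2 <- s$n2
  cnt <- s$counts
  rev_cnt <- cnt[(n1 + 1):1, (n2 + 1):1, drop = FALSE]
  tot <- outer(0:n1, 0:n2, "+")
  half <- (n1 + n2) / 2
  folded <- ifelse(tot < half, cnt + rev_cnt,
                   ifelse(tot == half, (cnt + rev_cnt) / 2, 0))
  out <- jafs(folded, folded = TRUE)
  out$se <- if (!is.null(s$se)) {
    rse <- s$se[(n1 + 1):1, (n2 + 1):1, drop = FALSE]
    ifelse(tot < half, sqrt(s$se^2 + rse^2),
           ifelse(tot == half, sqrt(s$se^2 + rse^2) / 2, 0))
  }
  out$mask <- out$mask | (s$mask & rev(s$mask))  # both partners masked
  out$n_sites_used <- s$n_sites_used
  out$n_sites_dropped <- s$n_sites_dropped
  out$projection <- s$projection
  out
}

#' Mask low-count (singleton and doubleton) cells
#'
#' Masks folded cells whose total minor-allele count across both populations
#' is 1 or 2 — `(1,0)`, `(0,1)`, `(2,0)`, `(0,2)` and, because the motive is
#' sequencing error on rare variants, also the diagonal doubleton `(1,1)`
#' unless `diagonal = FALSE`.
#'
#' @param s a folded [jafs] object.
#' @param diagonal mask the `(1, 1)` cell too (default `TRUE`).
#' @return The masked [jafs]; attribute `"masked_mass"` reports the mass
#'   removed from the unmasked sums.
#' @export
mask_low_counts <- function(s, diagonal = TRUE) {
  stopifnot(inherits(s, "jafs"))
  cells <- rbind(c(1, 0), c(0, 1), c(2, 0), c(0, 2))
  if (diagonal) cells <- rbind(cells, c(1, 1))
  cells <- cells[cells[, 1] <= s$n1 & cells[, 2] <= s$n2, , drop = FALSE]
  idx <- cbind(cells[, 1] + 1L, cells[, 2] + 1L)
  newly <- idx[!s$mask[idx], , drop = FALSE]
  masked_mass <- sum(s$counts[newly])
  s$mask[idx] <- TRUE
  if (sum(s$counts[!s$mask]) == 0)
    warning("no usable mass remains after masking low-count cells")
  attr(s, "masked_mass") <- masked_mass
  s
}

#' Bootstrap spectra by resampling RAD tags
#'
#' RAD tags (contigs), not sites, are resampled with replacement and the
#' spectrum rebuilt per replicate, preserving within-tag linkage.
#'
#' @inheritParams build_jafs
#' @param n_boot number of bootstrap replicates (default 100).
#' @param seed integer seed.
#' @param ... further arguments passed to [build_jafs()].
#' @return A list of [jafs] objects of length `n_boot`.
#' @export
bootstrap_jafs <- function(gm, pops, projection = NULL, n_boot = 100,
                           seed = 1, ...) {
  tags <- unique(gm$site_meta$contig)
  if (length(tags) == 1)
    warning("single tag: all bootstrap replicates are identical")
  with_seed(seed, {
    lapply(seq_len(n_boot), function(b) {
      pick <- sample(tags, length(tags), replace = TRUE)
      idx <- unlist(lapply(pick, function(tg)
        which(gm$site_meta$contig == tg)), use.names = FALSE)
      build_jafs(gm_subset(gm, sites = idx), pops, projection, ...)
    })
  })
}

#' Write / read a JAFS as a plain-text table
#'
#' Format: a header line `n1 n2 folded`, the row-major counts, then the
#' row-major mask as 0/1.
#'
#' @param s a [jafs] object.
#' @param path file path.
#' @return `write_jafs` returns `path` invisibly; `read_jafs` a [jafs].
#' @export
write_jafs <- function(s, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d %s", s$n1, s$n2,
                     if (s$folded) "folded" else "unfolded"), con)
  writeLines(paste(signif(as.vector(t(s$counts)), 12), collapse = " "), con)
  writeLines(paste(as.integer(as.vector(t(s$mask))), collapse = " "), con)
  invisible(path)
}

#' @rdname write_jafs
#' @export
read_jafs <- function(path) {
  ln <- readLines(path)
  hd <- strsplit(trimws(ln[1]), "\\s+")[[1]]
  n1 <- as.integer(hd[1]); n2 <- as.integer(hd[2])
  folded <- identical(hd[3], "folded")
  cnt <- matrix(as.numeric(strsplit(trimws(ln[2]), "\\s+")[[1]]),
                n1 + 1, n2 + 1, byrow = TRUE)
  msk <- matrix(as.integer(strsplit(trimws(ln[3]), "\\s+")[[1]]) > 0,
                n1 + 1, n2 + 1, byrow = TRUE)
  jafs(cnt, folded = folded, mask = msk)
}
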