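#' Genotype matrix container
#'
#' Holds diploid allele-count dosages (0, 1, 2 or `NA` for missing) for
#' individuals at biallelic SNP sites, together with site metadata (contig =
#' RAD tag, 1-based position, alleles), individual metadata (id, population,
#' reef) and an optional per-genotype read-depth matrix.
#'
#' @param dosage integer matrix, individuals x sites, values in `{0,1,2,NA}`.
#' @param site_meta data.frame with columns `contig`, `pos`, `ref`, `alt` and
#'   logical `biallelic`; positions must be strictly increasing within contig.
#' @param ind_meta data.frame with columns `id`, `population`, `reef`.
#' @param depth optional numeric matrix of per-genotype read depths, same
#'   shape as `dosage`.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosage, site_meta, ind_meta, depth = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  stopifnot(nrow(site_meta) == ncol(dosage), nrow(ind_meta) == nrow(dosage))
  if (is.null(site_meta$biallelic)) site_meta$biallelic <- !grepl(",", site_meta$alt)
  ok <- dosage %in% c(0L, 1L, 2L) | is.na(dosage)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA")
  # positions strictly increasing within contig
  sp <- split(site_meta$pos, site_meta$contig)
  if (any(vapply(sp, function(p) any(diff(p) <= 0), logical(1))))
    stop("positions must be strictly increasing within contig")
  rownames(dosage) <- ind_meta$id
  if (ncol(dosage) > 0)
    colnames(dosage) <- paste0(site_meta$contig, ":", site_meta$pos)
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    stopifnot(all(dim(depth) == dim(dosage)))
    dimnames(depth) <- dimnames(dosage)
  }
  structure(list(dosage = dosage, site_meta = site_meta,
                 ind_meta = ind_meta, depth = depth),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d individuals x %d sites (%d tags), %.1f%% missing\n",
              nrow(x$dosage), ncol(x$dosage),
              length(unique(x$site_meta$contig)),
              100 * mean(is.na(x$dosage))))
  pops <- table(x$ind_meta$population)
  if (length(pops)) cat("populations:",
                        paste(names(pops), pops, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

# subset a geno_matrix by individual and/or site index
gm_subset <- function(gm, ind = NULL, sites = NULL) {
  if (!is.null(ind)) {
    gm$dosage <- gm$dosage[ind, , drop = FALSE]
    gm$ind_meta <- gm$ind_meta[ind, , drop = FALSE]
    if (!is.null(gm$depth)) gm$depth <- gm$depth[ind, , drop = FALSE]
  }
  if (!is.null(sites)) {
    gm$dosage <- gm$dosage[, sites, drop = FALSE]
    gm$site_meta <- gm$site_meta[sites, , drop = FALSE]
    if (!is.null(gm$depth)) gm$depth <- gm$depth[, sites, drop = FALSE]
  }
  gm
}

#' Read a VCF file into a genotype matrix
#'
#' Parses GT (and DP, when present) fields of a VCF 4.x file. Multiallelic
#' records are retained but flagged non-biallelic with missing dosage, so the
#' biallelic site filter can tally them.
#'
#' @param path path to an (uncompressed or gzipped) VCF file.
#' @param popmap optional data.frame with columns `id`, `population` and
#'   optionally `reef`, matched to VCF sample names.
#' @return A [geno_matrix()].
#' @export
read_vcf <- function(path, popmap = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  ploidy <- nchar(gsub("[^0-9.]", "", gt[!is.na(gt)][1]))
  if (length(ploidy) && !is.na(ploidy) && ploidy != 2)
    stop("only diploid VCFs are supported")
  alt_n <- function(g) {
    al <- strsplit(gsub("\\|", "/", g), "/", fixed = TRUE)
    vapply(al, function(a) {
      if (length(a) != 2 || any(a == ".")) return(NA_integer_)
      sum(a != "0")
    }, integer(1))
  }
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt))
  for (j in seq_len(ncol(gt))) dos[, j] <- alt_n(gt[, j])
  dos <- t(dos)  # individuals x sites
  biallelic <- !grepl(",", fix$ALT) & fix$ALT != "." & !is.na(fix$ALT)
  dos[, !biallelic] <- NA_integer_
  site_meta <- data.frame(contig = fix$CHROM, pos = as.integer(fix$POS),
                          ref = fix$REF, alt = fix$ALT,
                          biallelic = biallelic, stringsAsFactors = FALSE)
  ids <- colnames(gt)
  ind_meta <- data.frame(id = ids, population = NA_character_,
                         reef = NA_character_, stringsAsFactors = FALSE)
  if (!is.null(popmap)) {
    m <- match(ids, popmap$id)
    ind_meta$population <- popmap$population[m]
    if (!is.null(popmap$reef)) ind_meta$reef <- popmap$reef[m]
  }
  depth <- NULL
  if (any(grepl("DP", v@gt[, "FORMAT"]))) {
    dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
    if (!all(is.na(dp))) depth <- t(dp)
  }
  geno_matrix(dos, site_meta, ind_meta, depth = depth)
}

#' Write a genotype matrix as VCF 4.2
#'
#' @param gm a [geno_matrix()].
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  sm <- gm$site_meta
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  writeLines("##source=reefdiverge", con)
  for (ctg in unique(sm$contig)) {
    len <- max(sm$pos[sm$contig == ctg])
    writeLines(sprintf("##contig=<ID=%s,length=%d>", ctg, len), con)
  }
  writeLines('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">', con)
  has_dp <- !is.null(gm$depth)
  if (has_dp)
    writeLines('##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read Depth">', con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", gm$ind_meta$id), collapse = "\t"), con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (s in seq_len(nrow(sm))) {
    d <- gm$dosage[, s]
    g <- ifelse(is.na(d), "./.", gt_code[d + 1L])
    if (has_dp) {
      dp <- gm$depth[, s]
      g <- paste0(g, ":", ifelse(is.na(dp), ".", as.character(dp)))
    }
    writeLines(paste(c(sm$contig[s], sm$pos[s], ".", sm$ref[s], sm$alt[s],
                       ".", "PASS", ".", if (has_dp) "GT:DP" else "GT", g),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Filtering thresholds for the post-assembly pipeline
#'
#' Defaults follow standard stringent RAD-seq filtering: stage 1 keeps
#' biallelic sites with minor allele count >= 3, per-genotype read depth in
#' 5-100 and at most 50% missing data per site; individuals with more than
#' 70% missing data are then dropped; clonal duplicates at >= 99% genotype
#' similarity are reduced to their least-missing member; stage 2 tightens to
#' 5% missing data per site and minor allele frequency >= 0.01; linked SNPs
#' are pruned in 50-SNP windows shifted by 5 SNPs at a variance inflation
#' factor threshold of 2.
#'
#' @param mac_min minimum minor allele count (sites with fewer are removed).
#' @param depth_min,depth_max per-genotype read-depth bounds (genotypes
#'   outside are set missing when depths are available).
#' @param site_missing_max_1,site_missing_max_2 maximum missing fraction per
#'   site at stages 1 and 2 (strict `>` removes).
#' @param ind_missing_max maximum missing fraction per individual (strict `>`).
#' @param clone_similarity genotype-identity threshold declaring clones (`>=`).
#' @param maf_min minimum minor allele frequency at stage 2.
#' @param ld_window,ld_step sliding-window size and shift, in SNPs.
#' @param vif_max variance inflation factor threshold for pruning.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(mac_min = 3, depth_min = 5, depth_max = 100,
                          site_missing_max_1 = 0.5, ind_missing_max = 0.7,
                          clone_similarity = 0.99, site_missing_max_2 = 0.05,
                          maf_min = 0.01, ld_window = 50, ld_step = 5,
                          vif_max = 2) {
  frac <- c(site_missing_max_1, ind_missing_max, clone_similarity,
            site_missing_max_2, maf_min)
  if (any(frac < 0 | frac > 1)) stop("fractions must lie in [0, 1]")
  if (depth_min > depth_max) stop("depth_min must not exceed depth_max")
  structure(as.list(environment()), class = "filter_config")
}

site_missing <- function(gm) colMeans(is.na(gm$dosage))
site_mac <- function(gm) {
  alt <- colSums(gm$dosage, na.rm = TRUE)
  called <- 2L * colSums(!is.na(gm$dosage))
  pmin(alt, called - alt)
}

#' Site filters (two-stage)
#'
#' Stage 1 applies the biallelic, allele-count, read-depth and loose
#' missingness filters; stage 2 applies the tight missingness and allele
#' frequency filters. Allele counts are recomputed at each stage from the
#' individuals present. A per-filter removal tally is attached as attribute
#' `"report"`.
#'
#' @param gm a [geno_matrix()].
#' @param cfg a [filter_config()].
#' @param stage `1` or `2`.
#' @return The filtered [geno_matrix()].
#' @export
filter_sites <- function(gm, cfg = filter_config(), stage = 1) {
  stopifnot(stage %in% c(1, 2))
  report <- data.frame(filter = character(0), sites_removed = integer(0))
  tally <- function(name, keep) {
    report <<- rbind(report, data.frame(filter = name,
                                        sites_removed = sum(!keep)))
    gm_subset(gm, sites = which(keep))
  }
  if (stage == 1) {
    gm <- tally("biallelic", gm$site_meta$biallelic)
    if (!is.null(gm$depth)) {
      bad <- !is.na(gm$depth) &
        (gm$depth < cfg$depth_min | gm$depth > cfg$depth_max)
      gm$dosage[bad] <- NA_integer_
      report <- rbind(report, data.frame(filter = "depth_genotypes_masked",
                                         sites_removed = 0L))
      attr(report, "genotypes_masked") <- sum(bad)
    } else {
      warning("no per-genotype depths; depth filter skipped")
    }
    gm <- tally("mac", site_mac(gm) >= cfg$mac_min)
    gm <- tally("site_missing", !(site_missing(gm) > cfg$site_missing_max_1))
  } else {
    gm <- tally("site_missing", !(site_missing(gm) > cfg$site_missing_max_2))
    called <- 2L * colSums(!is.na(gm$dosage))
    maf <- ifelse(called > 0, site_mac(gm) / called, 0)
    gm <- tally("maf", maf >= cfg$maf_min)
  }
  attr(gm, "report") <- report
  gm
}

#' Drop individuals with excessive missing data
#'
#' Individuals with a missing-genotype fraction strictly greater than
#' `cfg$ind_missing_max` are removed; an individual exactly at the threshold
#' is retained.
#'
#' @inheritParams filter_sites
#' @return The filtered [geno_matrix()] with a removal report attribute.
#' @export
filter_individuals <- function(gm, cfg = filter_config()) {
  miss <- rowMeans(is.na(gm$dosage))
  keep <- !(miss > cfg$ind_missing_max)
  if (!any(keep)) stop("all individuals exceed the missing-data threshold")
  out <- gm_subset(gm, ind = which(keep))
  attr(out, "report") <- data.frame(filter = "ind_missing",
                                    individuals_removed = sum(!keep))
  out
}

#' Detect and remove clonal duplicates
#'
#' Pairwise similarity is the fraction of co-called sites with identical
#' dosage. Pairs at or above `cfg$clone_similarity` form clonal groups (by
#' transitive closure), and the member with the least missing data is kept
#' from each group. Pairs with no co-called sites have undefined similarity
#' and are treated as non-clonal.
#'
#' @inheritParams filter_sites
#' @return A list with `pairs` (data.frame of clonal pairs), `kept` ids, and
#'   `gm`, the reduced [geno_matrix()].
#' @export
detect_clones <- function(gm, cfg = filter_config()) {
  n <- nrow(gm$dosage)
  if (n < 2) stop("need at least two individuals")
  D <- gm$dosage
  pairs <- data.frame(ind_i = character(0), ind_j = character(0),
                      similarity = numeric(0), co_called = integer(0))
  undefined <- 0L
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    cc <- !is.na(D[i, ]) & !is.na(D[j, ])
    ncc <- sum(cc)
    if (ncc == 0) { undefined <- undefined + 1L; next }
    sim <- mean(D[i, cc] == D[j, cc])
    if (sim >= cfg$clone_similarity) {
      pairs <- rbind(pairs, data.frame(ind_i = gm$ind_meta$id[i],
                                       ind_j = gm$ind_meta$id[j],
                                       similarity = sim, co_called = ncc))
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  miss <- rowMeans(is.na(D))
  keep <- logical(n)
  for (r in unique(roots)) {
    grp <- which(roots == r)
    keep[grp[which.min(miss[grp])]] <- TRUE
  }
  out <- gm_subset(gm, ind = which(keep))
  if (undefined > 0)
    message(undefined, " pair(s) had no co-called sites; treated as non-clonal")
  list(pairs = pairs, kept = gm$ind_meta$id[keep], gm = out)
}

# VIFs of the columns of a (mean-imputed, centred) dosage matrix.
vif_of <- function(X) {
  p <- ncol(X)
  if (p == 1) return(1)
  sds <- apply(X, 2, stats::sd)
  vif <- rep(1, p)
  act <- which(sds > 0)
  if (length(act) >= 2) {
    R <- stats::cor(X[, act, drop = FALSE])
    inv <- tryCatch(solve(R), error = function(e)
      solve(R + diag(1e-10, nrow(R))))
    vif[act] <- diag(inv)
  }
  vif
}

#' Prune linked SNPs by variance inflation factor
#'
#' Slides a window of `cfg$ld_window` SNPs shifted by `cfg$ld_step` along the
#' site ordering. Within each window the site with the highest VIF (from
#' regressing each site's mean-imputed dosage on the window's other sites) is
#' removed, recomputing greedily, until all VIFs are at or below
#' `cfg$vif_max`.
#'
#' @inheritParams filter_sites
#' @return The pruned [geno_matrix()] with a removal report attribute.
#' @export
ld_prune <- function(gm, cfg = filter_config()) {
  S <- ncol(gm$dosage)
  X <- gm$dosage
  mu <- colMeans(X, na.rm = TRUE)
  for (s in seq_len(S)) X[is.na(X[, s]), s] <- mu[s]
  X <- scale(X, center = TRUE, scale = FALSE)
  keep <- rep(TRUE, S)
  starts <- if (S <= cfg$ld_window) 1L else seq(1L, S, by = cfg$ld_step)
  for (st in starts) {
    win0 <- seq(st, min(st + cfg$ld_window - 1L, S))
    repeat {
      win <- win0[keep[win0]]
      if (length(win) < 2) break
      v <- vif_of(X[, win, drop = FALSE])
      if (max(v) <= cfg$vif_max) break
      keep[win[which.max(v)]] <- FALSE
    }
  }
  out <- gm_subset(gm, sites = which(keep))
  attr(out, "report") <- data.frame(filter = "ld_vif",
                                    sites_removed = sum(!keep))
  out
}

#' Run the full post-assembly filtering pipeline
#'
#' Applies, in order: stage-1 site filters, individual missingness filter,
#' clone removal, stage-2 site filters and VIF-based linkage pruning.
#'
#' @inheritParams filter_sites
#' @return The filtered [geno_matrix()]; attribute `"report"` tabulates the
#'   sites/individuals removed by each filter and `"clones"` lists the clonal
#'   pairs found.
#' @export
filter_pipeline <- function(gm, cfg = filter_config()) {
  n0 <- nrow(gm$dosage); s0 <- ncol(gm$dosage)
  gm1 <- filter_sites(gm, cfg, stage = 1)
  rep1 <- attr(gm1, "report")
  gm2 <- filter_individuals(gm1, cfg)
  rep2 <- attr(gm2, "report")
  cl <- detect_clones(gm2, cfg)
  gm3 <- cl$gm
  gm4 <- filter_sites(gm3, cfg, stage = 2)
  rep4 <- attr(gm4, "report")
  gm5 <- ld_prune(gm4, cfg)
  rep5 <- attr(gm5, "report")
  report <- data.frame(
    filter = c(rep1$filter, "ind_missing", "clones", rep4$filter, rep5$filter),
    sites_removed = c(rep1$sites_removed, 0L, 0L, rep4$sites_removed,
                      rep5$sites_removed),
    individuals_removed = c(rep(0L, nrow(rep1)), rep2$individuals_removed,
                            nrow(gm2$dosage) - nrow(gm3$dosage),
                            rep(0L, nrow(rep4)), 0L))
  stopifnot(sum(report$sites_removed) == s0 - ncol(gm5$dosage),
            sum(report$individuals_removed) == n0 - nrow(gm5$dosage))
  attr(gm5, "report") <- report
  attr(gm5, "clones") <- cl$pairs
  gm5
}
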