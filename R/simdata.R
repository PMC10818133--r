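#' Define a two-population divergence scenario
#'
#' Describes one of five divergence histories for a pair of demes that split
#' from a common ancestor: strict isolation (`SI`), isolation with constant
#' symmetric migration (`IM`), isolation with two migration classes (`IM2M`:
#' a proportion `Q` of RAD tags exchanges migrants at the reduced rate `M_e`,
#' the rest at `M`), secondary contact (`SC`: no gene flow from the split
#' until `T_phase` before present, migration `M` since) and ancient migration
#' (`AM`: migration `M` from the split until `T_phase` before present, none
#' since).
#'
#' All times are in units of `2 * N_ref` generations, population sizes
#' relative to the ancestral reference size `N_ref`, and migration is scaled
#' as `M = 2 * N_ref * m`, matching the parameterisation fitted by
#' [fit_divergence()]. Defaults are set to magnitudes typical of fitted
#' intraspecific coral population pairs (relative sizes near 1, split age
#' near one coalescent unit, a few scaled migrants).
#'
#' @param model one of `"SI"`, `"IM"`, `"IM2M"`, `"SC"`, `"AM"`.
#' @param nu1,nu2 relative sizes of populations 1 and 2.
#' @param T_total split age.
#' @param M scaled symmetric migration rate (ignored for `SI`).
#' @param M_e scaled reduced migration rate (IM2M only; must be `<= M`).
#' @param Q proportion of tags in the reduced-migration class (IM2M only).
#' @param T_phase epoch boundary for `SC`/`AM`, `0 <= T_phase <= T_total`.
#' @param n1,n2 diploid sample sizes per population.
#' @param n_tags number of RAD tags.
#' @param tag_length bases per tag.
#' @param theta_per_tag population mutation rate `4 N_ref mu L` per tag.
#' @param seed integer seed.
#' @return A list of class `sim_scenario`.
#' @export
sim_scenario <- function(model = c("IM", "SI", "IM2M", "SC", "AM"),
                         nu1 = 1.5, nu2 = 1.2, T_total = 1.2, M = 2.5,
                         M_e = 0.1, Q = 0.25, T_phase = T_total / 2,
                         n1 = 10, n2 = 10, n_tags = 2000, tag_length = 110,
                         theta_per_tag = 1, seed = 1) {
  model <- match.arg(model)
  if (!(nu1 > 0 && nu2 > 0 && T_total > 0)) stop("nu1, nu2, T_total must be > 0")
  if (Q < 0 || Q > 1) stop("Q must lie in [0, 1]")
  if (T_phase < 0 || T_phase > T_total) stop("T_phase must lie in [0, T_total]")
  if (model == "IM2M" && M_e > M) stop("M_e must not exceed M")
  if (n1 < 2 || n2 < 2) stop("need at least two diploid individuals per population")
  structure(list(model = model, nu1 = nu1, nu2 = nu2, T_total = T_total,
                 M = M, M_e = M_e, Q = Q, T_phase = T_phase,
                 n1 = n1, n2 = n2, n_tags = n_tags, tag_length = tag_length,
                 theta_per_tag = theta_per_tag, seed = seed),
            class = "sim_scenario")
}

# Backwards-time epochs for the structured coalescent / diffusion engine.
# Returns list(end, mig, mig_alt, q_alt): migration mig[e] is active while
# t < end[e]; the demes merge at the last boundary.
scenario_epochs <- function(sc) {
  with(sc, switch(model,
    SI   = list(end = T_total, mig = 0, mig_alt = 0, q_alt = 0),
    IM   = list(end = T_total, mig = M, mig_alt = 0, q_alt = 0),
    IM2M = list(end = T_total, mig = M, mig_alt = M_e, q_alt = Q),
    SC   = list(end = c(T_phase, T_total), mig = c(M, 0), mig_alt = c(0, 0),
                q_alt = 0),
    AM   = list(end = c(T_phase, T_total), mig = c(0, M), mig_alt = c(0, 0),
                q_alt = 0)))
}

#' Simulate a RAD-tag genotype dataset under a divergence scenario
#'
#' Runs an exact structured-coalescent simulation per RAD tag (two demes with
#' symmetric lineage migration, merging into the ancestral deme at the split
#' age), drops infinite-sites mutations on branches at rate
#' `theta_per_tag / 2` per unit branch length, and pairs haplotypes within
#' demes into diploid genotypes. Under `IM2M`, each tag is independently
#' assigned to the reduced-migration class with probability `Q`. Individuals
#' receive uniform coordinates on the unit square (both taxa sympatric).
#'
#' @param scenario a [sim_scenario()].
#' @return A list of class `sim_dataset` with elements `genotypes` (a
#'   [geno_matrix()]), `truth` (the scenario), `coords` (per-individual x, y),
#'   `env` (`NULL` until [simulate_env()] is called) and `tag_class`
#'   (per-tag migration class).
#' @export
simulate_pair <- function(scenario) {
  sc <- scenario
  stopifnot(inherits(sc, "sim_scenario"))
  ep <- scenario_epochs(sc)
  k1 <- 2L * sc$n1; k2 <- 2L * sc$n2
  with_seed(sc$seed, {
    tag_class <- if (sc$model == "IM2M")
      ifelse(stats::runif(sc$n_tags) < sc$Q, "reduced", "neutral")
    else rep("neutral", sc$n_tags)
    dos_list <- vector("list", sc$n_tags)
    meta_list <- vector("list", sc$n_tags)
    dropped <- 0L
    for (tg in seq_len(sc$n_tags)) {
      mig <- if (tag_class[tg] == "reduced") ep$mig_alt else ep$mig
      res <- coal_tag_cpp(k1, k2, sc$nu1, sc$nu2, ep$end, mig,
                          sc$theta_per_tag, TRUE)
      muts <- res$mutations
      nm <- length(muts)
      if (nm == 0) next
      if (nm > sc$tag_length) {          # infinite-sites overflow
        dropped <- dropped + (nm - sc$tag_length)
        muts <- muts[seq_len(sc$tag_length)]
        nm <- sc$tag_length
      }
      pos <- sort(sample.int(sc$tag_length, nm))
      # haplotypes 1..k1 belong to pop1, k1+1..k1+k2 to pop2; haplotype pairs
      # (2i-1, 2i) form individual i (random pairing by exchangeability)
      dos <- matrix(0L, sc$n1 + sc$n2, nm)
      for (m in seq_len(nm)) {
        hap <- muts[[m]]
        ind <- (hap + 1L) %/% 2L
        for (i in ind) dos[i, m] <- dos[i, m] + 1L
      }
      dos_list[[tg]] <- dos
      meta_list[[tg]] <- data.frame(contig = sprintf("tag%05d", tg), pos = pos,
                                    ref = "A", alt = "T", biallelic = TRUE,
                                    stringsAsFactors = FALSE)
    }
    keep <- !vapply(dos_list, is.null, logical(1))
    if (any(keep)) {
      dosage <- do.call(cbind, dos_list[keep])
      site_meta <- do.call(rbind, meta_list[keep])
    } else {
      dosage <- matrix(integer(0), sc$n1 + sc$n2, 0)
      site_meta <- data.frame(contig = character(0), pos = integer(0),
                              ref = character(0), alt = character(0),
                              biallelic = logical(0))
    }
    ids <- c(sprintf("p1_%03d", seq_len(sc$n1)), sprintf("p2_%03d", seq_len(sc$n2)))
    ind_meta <- data.frame(id = ids,
                           population = rep(c("pop1", "pop2"), c(sc$n1, sc$n2)),
                           reef = "reef1", stringsAsFactors = FALSE)
    gm <- geno_matrix(dosage, site_meta, ind_meta)
    coords <- data.frame(id = ids, x = stats::runif(sc$n1 + sc$n2),
                         y = stats::runif(sc$n1 + sc$n2))
    if (dropped > 0)
      warning(dropped, " mutations exceeded tag_length positions and were dropped")
    structure(list(genotypes = gm, truth = sc, coords = coords, env = NULL,
                   tag_class = tag_class),
              class = "sim_dataset")
  })
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("sim_dataset: model %s, %d tags, %d SNPs, %d + %d individuals\n",
              x$truth$model, x$truth$n_tags, ncol(x$genotypes$dosage),
              x$truth$n1, x$truth$n2))
  invisible(x)
}

#' Monte-Carlo expected joint allele-frequency spectrum
#'
#' Averages the per-cell branch lengths of `n_reps` independent
#' structured-coalescent tag genealogies (a Rao-Blackwellised estimate of the
#' expected folded spectrum: the expected number of mutations subtending a
#' frequency class is proportional to the expected branch length above it).
#' This is the simulation oracle against which the diffusion engine of
#' [expected_jafs()] is validated.
#'
#' @param scenario a [sim_scenario()]; `n1`, `n2` give the diploid sample
#'   sizes, so the spectrum has `2*n1 + 1` by `2*n2 + 1` cells.
#' @param n_reps number of replicate tags.
#' @param seed integer seed.
#' @param fold fold the spectrum (default `TRUE`).
#' @return A [jafs] object, normalised to unit mass over unmasked cells, with
#'   a per-cell Monte-Carlo standard-error matrix in field `se` (on the same
#'   normalised scale).
#' @export
expected_jafs_mc <- function(scenario, n_reps = 10000, seed = 1, fold = TRUE) {
  sc <- scenario
  stopifnot(inherits(sc, "sim_scenario"), n_reps >= 1)
  ep <- scenario_epochs(sc)
  k1 <- 2L * sc$n1; k2 <- 2L * sc$n2
  res <- with_seed(seed,
    coal_branch_reps_cpp(n_reps, k1, k2, sc$nu1, sc$nu2, ep$end,
                         ep$mig, ep$mig_alt, ep$q_alt, fold))
  mean_b <- res$sum / n_reps
  var_b <- pmax(res$sumsq / n_reps - mean_b^2, 0)
  se_b <- sqrt(var_b / n_reps)
  s <- jafs(mean_b * sc$theta_per_tag / 2, folded = fold)
  s$se <- se_b * sc$theta_per_tag / 2
  tot <- sum(s$counts[!s$mask])
  if (tot > 0) {
    s$counts <- s$counts / tot
    s$se <- s$se / tot
  }
  s
}

#' Inject missing genotypes and clonal duplicates
#'
#' Emulates the artefacts the filtering pipeline must remove: genotypes are
#' set to missing independently at `miss_rate`, and `n_clones` randomly
#' chosen individuals are duplicated, with missingness redrawn independently
#' for each copy.
#'
#' @param data a [simulate_pair()] dataset.
#' @param miss_rate missing-genotype probability, in `[0, 1)`.
#' @param n_clones number of individuals to duplicate.
#' @param seed integer seed.
#' @return The modified `sim_dataset`.
#' @export
inject_missing_and_clones <- function(data, miss_rate = 0, n_clones = 0,
                                      seed = 1) {
  stopifnot(inherits(data, "sim_dataset"),
            miss_rate >= 0, miss_rate < 1,
            n_clones < nrow(data$genotypes$dosage))
  if (miss_rate == 0 && n_clones == 0) return(data)
  gm <- data$genotypes
  with_seed(seed, {
    n <- nrow(gm$dosage)
    if (n_clones > 0) {
      src <- sample.int(n, n_clones)
      dup <- gm$dosage[src, , drop = FALSE]
      gm$dosage <- rbind(gm$dosage, dup)
      im <- gm$ind_meta[src, , drop = FALSE]
      im$id <- paste0(im$id, "_clone")
      gm$ind_meta <- rbind(gm$ind_meta, im)
      rownames(gm$dosage) <- gm$ind_meta$id
      cd <- data$coords[src, , drop = FALSE]
      cd$id <- im$id
      data$coords <- rbind(data$coords, cd)
    }
    if (miss_rate > 0) {
      drop <- matrix(stats::runif(length(gm$dosage)) < miss_rate,
                     nrow(gm$dosage))
      gm$dosage[drop] <- NA_integer_
    }
    data$genotypes <- gm
    data
  })
}

#' Simulate spatially structured environmental covariates
#'
#' Draws `n_vars` environmental variables as Gaussian random fields over the
#' individuals' coordinates with exponential covariance
#' `exp(-d / spatial_range)`, then (optionally) tilts allele frequencies at a
#' subset of SNPs along each variable with non-zero effect size, so that
#' genotype-environment association analyses can recover known drivers.
#' Genotypes at unaffected sites are untouched.
#'
#' @param data a [simulate_pair()] dataset.
#' @param effect_sizes numeric vector (recycled to `n_vars`) of per-variable
#'   allele-frequency shifts per environmental SD.
#' @param n_vars number of environmental variables.
#' @param spatial_range range of the exponential spatial covariance; `0`
#'   gives spatially independent variables.
#' @param n_effect_sites number of SNPs tilted per effectful variable.
#' @param seed integer seed.
#' @return The `sim_dataset` with `env` filled in (individuals x variables)
#'   and attribute `"effect_sites"` naming the tilted SNPs per variable.
#' @export
simulate_env <- function(data, effect_sizes = 0, n_vars = 7,
                         spatial_range = 0.3, n_effect_sites = 50, seed = 1) {
  stopifnot(inherits(data, "sim_dataset"), n_vars >= 1)
  effect_sizes <- rep_len(effect_sizes, n_vars)
  gm <- data$genotypes
  n <- nrow(gm$dosage)
  with_seed(seed, {
    D <- as.matrix(stats::dist(data$coords[, c("x", "y")]))
    Sigma <- if (spatial_range > 0) exp(-D / spatial_range) else diag(n)
    L <- chol(Sigma + diag(1e-8, n))
    env <- crossprod(L, matrix(stats::rnorm(n * n_vars), n, n_vars))
    colnames(env) <- paste0("env", seq_len(n_vars))
    rownames(env) <- gm$ind_meta$id
    eff <- which(effect_sizes != 0)
    effect_sites <- list()
    if (length(eff) > 0) {
      S <- ncol(gm$dosage)
      avail <- sample.int(S)
      taken <- 0L
      for (v in eff) {
        ns <- min(n_effect_sites, S - taken)
        if (ns <= 0) break
        sites <- avail[taken + seq_len(ns)]
        taken <- taken + ns
        effect_sites[[colnames(env)[v]]] <- colnames(gm$dosage)[sites]
        p0 <- colMeans(gm$dosage[, sites, drop = FALSE], na.rm = TRUE) / 2
        for (si in seq_along(sites)) {
          p <- pmin(pmax(p0[si] + effect_sizes[v] * env[, v], 0.02), 0.98)
          redraw <- stats::rbinom(n, 2, p)
          keep_na <- is.na(gm$dosage[, sites[si]])
          gm$dosage[, sites[si]] <- as.integer(redraw)
          gm$dosage[keep_na, sites[si]] <- NA_integer_
        }
      }
    }
    data$genotypes <- gm
    data$env <- as.data.frame(env)
    attr(data$env, "effect_sites") <- effect_sites
    data
  })
}

#' Expand a simulated dataset to an all-sites matrix
#'
#' D_XY needs invariant sites. This expands each RAD tag to its full length,
#' inserting monomorphic, fully called reference sites at unmutated
#' positions (the simulator is an infinite-sites model, so every position
#' not carrying a SNP is invariant).
#'
#' @param data a [simulate_pair()] dataset.
#' @return A [geno_matrix()] with `n_tags * tag_length` sites.
#' @export
all_sites_matrix <- function(data) {
  stopifnot(inherits(data, "sim_dataset"))
  gm <- data$genotypes
  sc <- data$truth
  n <- nrow(gm$dosage)
  tags <- sprintf("tag%05d", seq_len(sc$n_tags))
  dos <- matrix(0L, n, sc$n_tags * sc$tag_length)
  contig <- rep(tags, each = sc$tag_length)
  pos <- rep(seq_len(sc$tag_length), sc$n_tags)
  col_of <- function(ctg, p) (match(ctg, tags) - 1L) * sc$tag_length + p
  snp_cols <- col_of(gm$site_meta$contig, gm$site_meta$pos)
  dos[, snp_cols] <- gm$dosage
  site_meta <- data.frame(contig = contig, pos = pos, ref = "A", alt = ".",
                          biallelic = FALSE, stringsAsFactors = FALSE)
  site_meta$alt[snp_cols] <- "T"
  site_meta$biallelic[snp_cols] <- TRUE
  geno_matrix(dos, site_meta, gm$ind_meta)
}
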