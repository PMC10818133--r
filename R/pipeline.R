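#' Run the end-to-end analysis pipeline
#'
#' Executes the stage DAG `simulate -> filter -> {stats, jafs -> fit ->
#' convert, rda}` from a single configuration (an R list or a YAML file
#' path), writing per-stage outputs and a manifest (inputs, parameters,
#' per-stage seeds, package version, output checksums) into `out_dir`.
#' One global seed is expanded into independent per-stage streams by a
#' counter scheme, so re-running the same configuration is bit-identical
#' and adding a stage does not perturb earlier stages.
#'
#' @param config list or path to a YAML file. Recognised blocks:
#'   `seed` (global), `stages` (subset of simulate, filter, stats, jafs,
#'   fit, convert, rda), `simulate` ([sim_scenario()] arguments), `filter`
#'   ([filter_config()] arguments), `jafs` (`projection`), `fit` (`models`,
#'   `rounds`, `runs`), `convert` (`mu`, `T_gen`), `rda` (`effect_sizes`,
#'   `n_vars`, `n_perm`).
#' @param out_dir output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  seed <- config$seed %||% 1
  stages <- config$stages %||% c("simulate", "filter", "stats", "jafs",
                                 "fit", "convert", "rda")
  known <- c("simulate", "filter", "stats", "jafs", "fit", "convert", "rda")
  if (!all(stages %in% known))
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  deps <- list(filter = "simulate", stats = "filter", jafs = "filter",
               fit = "jafs", convert = "fit", rda = "filter")
  for (st in stages)
    if (!all(deps[[st]] %in% stages))
      stop(sprintf("stage '%s' requires upstream stage '%s'", st,
                   setdiff(deps[[st]], stages)[1]))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "reefdiverge",
                   version = as.character(utils::packageVersion("reefdiverge")),
                   seed = seed, stages = stages, config = config,
                   stage_seeds = list(), outputs = list())
  state <- new.env()
  pth <- function(f) file.path(out_dir, f)
  note <- function(f) manifest$outputs[[f]] <<-
    unname(tools::md5sum(pth(f)))

  for (st in stages[order(match(stages, known))]) {
    sseed <- derive_seed(seed, st)
    manifest$stage_seeds[[st]] <- sseed
    switch(st,
      simulate = {
        args <- config$simulate %||% list()
        args$seed <- args$seed %||% sseed
        sc <- do.call(sim_scenario, args)
        dat <- simulate_pair(sc)
        extra <- config$simulate_extra %||% list()
        dat <- inject_missing_and_clones(dat,
          miss_rate = extra$miss_rate %||% 0,
          n_clones = extra$n_clones %||% 0,
          seed = derive_seed(sseed, "artefacts"))
        env_args <- config$rda %||% list()
        dat <- simulate_env(dat,
          effect_sizes = env_args$effect_sizes %||% 0,
          n_vars = env_args$n_vars %||% 4,
          spatial_range = env_args$spatial_range %||% 0.3,
          seed = derive_seed(sseed, "env"))
        state$data <- dat
        write_vcf(dat$genotypes, pth("sim.vcf"))
        utils::write.table(dat$genotypes$ind_meta, pth("popmap.tsv"),
                           sep = "\t", row.names = FALSE, quote = FALSE)
        utils::write.table(dat$coords, pth("coords.tsv"), sep = "\t",
                           row.names = FALSE, quote = FALSE)
        utils::write.table(cbind(id = rownames(dat$env), dat$env),
                           pth("env.tsv"), sep = "\t", row.names = FALSE,
                           quote = FALSE)
        note("sim.vcf"); note("popmap.tsv"); note("coords.tsv"); note("env.tsv")
      },
      filter = {
        cfg <- do.call(filter_config, config$filter %||% list())
        gm <- filter_pipeline(state$data$genotypes, cfg)
        state$gm <- gm
        write_vcf(gm, pth("filtered.vcf"))
        utils::write.table(attr(gm, "report"), pth("filter_report.tsv"),
                           sep = "\t", row.names = FALSE, quote = FALSE)
        note("filtered.vcf"); note("filter_report.tsv")
      },
      stats = {
        pops <- unique(state$gm$ind_meta$population)
        fst <- wc_fst(state$gm, pops[1:2], per_locus = TRUE)
        utils::write.table(
          data.frame(site = names(fst$per_locus), fst = fst$per_locus),
          pth("fst_per_locus.tsv"), sep = "\t", row.names = FALSE,
          quote = FALSE)
        writeLines(sprintf("global_fst\t%.6f", fst$fst), pth("fst.tsv"))
        dists <- pair_distances(state$gm, state$gm$ind_meta$reef[1])
        utils::write.table(dists, pth("distances.tsv"), sep = "\t",
                           row.names = FALSE, quote = FALSE)
        note("fst.tsv"); note("fst_per_locus.tsv"); note("distances.tsv")
      },
      jafs = {
        pops <- unique(state$gm$ind_meta$population)
        proj <- config$jafs$projection %||% NULL
        sp <- build_jafs(state$gm, pops[1:2], projection = proj)
        state$jafs <- sp
        write_jafs(sp, pth("pair.fs"))
        note("pair.fs")
      },
      fit = {
        fa <- config$fit %||% list()
        models <- fa$models %||% c("SI", "IM")
        fits <- lapply(models, function(m)
          fit_divergence(state$jafs, m,
                         rounds = fa$rounds %||% c(2, 1),
                         runs = fa$runs %||% 5,
                         seed = derive_seed(sseed, m)))
        names(fits) <- models
        state$fits <- fits
        for (m in models) {
          f <- fits[[m]]
          jsonlite::write_json(list(model = m, par = f$free,
                                    loglik = f$loglik, aic = f$aic,
                                    theta_hat = f$theta_hat),
                               pth(sprintf("fit_%s.json", m)),
                               auto_unbox = TRUE, digits = NA)
          note(sprintf("fit_%s.json", m))
        }
        cmp <- compare_models(fits)
        utils::write.table(cmp, pth("model_compare.tsv"), sep = "\t",
                           row.names = FALSE, quote = FALSE)
        note("model_compare.tsv")
      },
      convert = {
        ca <- config$convert %||% list()
        best <- state$fits[[compare_models(state$fits)$model[1]]]
        snp_used <- sum(best$data$counts[!best$data$mask])
        snp_orig <- ncol(state$data$genotypes$dosage)
        L <- total_seq_length(snp_used, max(snp_orig, snp_used),
                              state$data$truth$n_tags,
                              state$data$truth$tag_length)
        cp <- convert_params(best, L = L, mu = ca$mu %||% 1.2e-8,
                             T_gen = ca$T_gen %||% 3)
        jsonlite::write_json(unclass(cp), pth("converted.json"),
                             auto_unbox = TRUE, digits = NA)
        note("converted.json")
      },
      rda = {
        ra <- config$rda %||% list()
        dat <- state$data
        keep <- dat$genotypes$ind_meta$id %in% state$gm$ind_meta$id
        Y <- rda_response(state$gm)
        E <- env_matrix(dat$env[keep, , drop = FALSE])
        mem <- dbmem(dat$coords[keep, c("x", "y")])
        Zc <- as_cond_matrix(mem, ra$n_mem %||% 3)
        rr <- partial_rda(Y, E, Zc)
        pt <- permutation_test(rr, n_perm = ra$n_perm %||% 999,
                               seed = derive_seed(sseed, "perm"))
        sel <- forward_select(Y, E, Zc, n_perm = ra$n_perm %||% 999,
                              seed = derive_seed(sseed, "fwd"))
        jsonlite::write_json(list(adj_r2 = rr$adj_r2, r2 = rr$r2,
                                  F = pt$F[1], p_value = pt$p_value[1],
                                  selected = as.character(sel)),
                             pth("rda.json"), auto_unbox = TRUE, digits = NA)
        note("rda.json")
      })
  }
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
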