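# Small genotype fixtures built in code.

toy_gm <- function(dosage, pops = NULL, reef = "r1", contig = NULL,
                   pos = NULL, alt = NULL, depth = NULL) {
  n <- nrow(dosage); S <- ncol(dosage)
  if (is.null(pops)) pops <- rep("p1", n)
  if (is.null(contig)) contig <- rep("tag1", S)
  if (is.null(pos)) pos <- stats::ave(seq_len(S), contig, FUN = seq_along)
  if (is.null(alt)) alt <- rep("T", S)
  geno_matrix(dosage,
              data.frame(contig = contig, pos = pos, ref = "A", alt = alt,
                         biallelic = !grepl(",", alt),
                         stringsAsFactors = FALSE),
              data.frame(id = sprintf("i%02d", seq_len(n)), population = pops,
                         reef = reef, stringsAsFactors = FALSE),
              depth = depth)
}

# the two-population oracle table used for the frozen Weir-Cockerham values
wc_toy <- function() {
  toy_gm(rbind(c(0, 1, 2), c(1, 1, 0), c(0, 0, 1), c(2, 1, 0),
               c(2, 2, 1), c(1, 2, 2), c(2, 1, 1), c(1, 2, 2)),
         pops = rep(c("p1", "p2"), each = 4))
}

# mixed-taxon reef at moderate divergence (global F_ST ~ 0.3)
mixed_reef_sim <- function(seed, n_tags = 800) {
  simulate_pair(sim_scenario("SI", nu1 = 1, nu2 = 1, T_total = 0.45,
                             n1 = 8, n2 = 8, n_tags = n_tags,
                             theta_per_tag = 0.5, seed = seed))
}

# single panmictic population presented as two labelled halves
panmictic_sim <- function(seed, n1 = 8, n2 = 8, n_tags = 300,
                          theta_per_tag = 0.5) {
  simulate_pair(sim_scenario("SI", nu1 = 1, nu2 = 1, T_total = 1e-9,
                             n1 = n1, n2 = n2, n_tags = n_tags,
                             theta_per_tag = theta_per_tag, seed = seed))
}
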