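#' Published divergence estimates for GBR Stylophora pistillata pairs
#'
#' Worked-example table of divergence statistics and best-fit demographic
#' parameters (heterogeneous-gene-flow model, converted to demographic
#' units) reported for population pairs of the *Stylophora pistillata*
#' species complex on the Great Barrier Reef. Columns: global Weir-Cockerham
#' `fst`; genome-wide `dxy`; ancestral size `N_ref` and population sizes
#' `nu1`, `nu2` in individuals; migrant fraction per generation `m` (reduced
#' class `m_e`); gene-flow rates `M21`, `M12` in migrants per generation;
#' divergence time `T_Myr` in million years; and the neutral/reduced locus
#' proportions `P`, `Q`. Several printed gene-flow cells are inconsistent
#' with `M = m * nu` at printed precision because `m` was rounded upstream;
#' [gene_flow_rates()] reproduces the internally consistent cells.
#'
#' @format Tab-separated file `extdata/gbr_stylophora_pairs.tsv`.
#' @examples
#' tab <- read.delim(system.file("extdata", "gbr_stylophora_pairs.tsv",
#'                               package = "reefdiverge"))
#' with(tab[3, ], gene_flow_rates(m, nu1, nu2))
#' @name gbr_stylophora_pairs
#' @keywords datasets
NULL
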